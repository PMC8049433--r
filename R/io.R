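#' Read an ECG record
#'
#' Reads a multi-lead record from one of three on-disk representations:
#'
#' * `"array"` — the package's lossless RDS container (exact round-trip of
#'   signal, rate, labels and annotations);
#' * `"delimited"` — plain text, one sample per row, leads as columns, with
#'   `# key: value` header lines for sampling rate, lead labels and R peaks
#'   (values written with 6 decimal places, i.e. nV-level precision);
#' * `"wfdb"` — a minimal PhysioNet waveform-database subset: `.hea` header,
#'   format-16 (little-endian int16) `.dat` signal, and an optional `.atr`
#'   beat-annotation file in the MIT byte format. `path` is the record name
#'   without extension. Amplitude resolution is 1/gain mV (default gain
#'   1000, i.e. 1 µV).
#'
#' Readers never resample: a record whose declared rate differs from 500 Hz
#' is passed through unchanged and flagged with `metadata$nonstandard_rate`.
#' Beat annotations of any subtype are treated as R peaks. All indices are
#' 0-based.
#'
#' @param path File path (for `"wfdb"`, the record name without extension).
#' @param format One of `"array"`, `"delimited"`, `"wfdb"`.
#' @param sampling_rate Override/fallback rate in Hz for delimited files
#'   lacking a header; a delimited file without either is a validation
#'   error.
#' @return An [ecg_record()].
#' @export
read_record <- function(path, format = c("array", "delimited", "wfdb"),
                        sampling_rate = NULL) {
  format <- match.arg(format)
  rec <- switch(format,
    array = read_record_array(path),
    delimited = read_record_delimited(path, sampling_rate),
    wfdb = read_record_wfdb(path)
  )
  if (!isTRUE(all.equal(rec$sampling_rate, 500))) {
    rec$metadata$nonstandard_rate <- TRUE
  }
  rec
}

#' Write an ECG record
#'
#' Counterpart of [read_record()]; see that help page for the formats.
#' The `"array"` format round-trips losslessly; `"delimited"` is exact to
#' 6 decimal places; `"wfdb"` quantizes amplitudes to 1/gain mV.
#'
#' @param record An [ecg_record()].
#' @param path Output path (for `"wfdb"`, the record name without
#'   extension; `.hea`, `.dat` and, when annotations are present, `.atr`
#'   files are created next to it).
#' @param format One of `"array"`, `"delimited"`, `"wfdb"`.
#' @param gain ADC units per mV for the wfdb format.
#' @return `invisible(path)`.
#' @export
write_record <- function(record, path, format = c("array", "delimited", "wfdb"),
                         gain = 1000) {
  stopifnot(inherits(record, "ecg_record"))
  format <- match.arg(format)
  switch(format,
    array = write_record_array(record, path),
    delimited = write_record_delimited(record, path),
    wfdb = write_record_wfdb(record, path, gain = gain)
  )
  invisible(path)
}

# ---- array (RDS) container ------------------------------------------------

write_record_array <- function(record, path) {
  saveRDS(list(schema = "ecgvae-record-1", signal = record$signal,
               sampling_rate = record$sampling_rate,
               lead_labels = record$lead_labels, r_peaks = record$r_peaks,
               metadata = record$metadata),
          path)
}

read_record_array <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  obj <- readRDS(path)
  check_that(identical(obj$schema, "ecgvae-record-1"), "schema",
             sprintf("unsupported record container schema '%s'", obj$schema %||% "<missing>"))
  ecg_record(obj$signal, obj$sampling_rate, obj$lead_labels, obj$r_peaks,
             metadata = obj$metadata %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- delimited text -------------------------------------------------------

write_record_delimited <- function(record, path) {
  hdr <- c(
    sprintf("# sampling_rate: %s", format(record$sampling_rate)),
    sprintf("# leads: %s", paste(record$lead_labels, collapse = ","))
  )
  if (!is.null(record$r_peaks)) {
    hdr <- c(hdr, sprintf("# r_peaks: %s", paste(record$r_peaks, collapse = ",")))
  }
  body <- apply(record$signal, 1, function(row) paste(sprintf("%.6f", row), collapse = "\t"))
  writeLines(c(hdr, body), path)
}

read_record_delimited <- function(path, sampling_rate = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  lines <- readLines(path)
  is_hdr <- startsWith(lines, "#")
  hdr <- lines[is_hdr]
  parse_hdr <- function(key) {
    hit <- grep(sprintf("^#\\s*%s:", key), hdr, value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub(sprintf("^#\\s*%s:", key), "", hit[1]))
  }
  fs <- parse_hdr("sampling_rate")
  fs <- if (!is.null(fs)) as.numeric(fs) else sampling_rate
  check_that(!is.null(fs) && is.finite(fs) && fs > 0, "sampling_rate",
             "not declared in the file header and no override supplied")
  body <- lines[!is_hdr]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(body, "[\t ,]+")
  widths <- lengths(rows)
  check_that(length(unique(widths)) <= 1, "signal",
             "rows have inconsistent numbers of columns")
  signal <- matrix(as.numeric(unlist(rows)), nrow = length(rows),
                   ncol = if (length(rows)) widths[1] else 0, byrow = TRUE)
  leads <- parse_hdr("leads")
  leads <- if (!is.null(leads)) strsplit(leads, ",")[[1]] else NULL
  rp_raw <- parse_hdr("r_peaks")
  r_peaks <- if (is.null(rp_raw)) NULL
             else if (!nzchar(rp_raw)) integer(0)
             else as.integer(strsplit(rp_raw, ",")[[1]])
  ecg_record(signal, fs, leads, r_peaks)
}

# ---- minimal PhysioNet waveform-database subset ---------------------------
# Header (.hea): "name nsig fs nsamp" plus one line per signal in the
# standard field order. Signal (.dat): format 16, interleaved little-endian
# int16 frames. Annotations (.atr): MIT byte pairs, 6-bit type + 10-bit time
# increment, SKIP (type 59) escape for long intervals, zero word terminator.

wfdb_paths <- function(path) {
  base <- sub("\\.hea$", "", path)
  list(base = base, name = basename(base),
       hea = paste0(base, ".hea"), dat = paste0(base, ".dat"),
       atr = paste0(base, ".atr"))
}

write_record_wfdb <- function(record, path, gain = 1000) {
  p <- wfdb_paths(path)
  nsig <- ncol(record$signal)
  nsamp <- nrow(record$signal)
  adc <- round(record$signal * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  storage.mode(adc) <- "integer"
  sig_lines <- vapply(seq_len(nsig), function(j) {
    sprintf("%s.dat 16 %g(0)/mV 16 0 %d 0 0 %s",
            p$name, gain, adc[1, j], record$lead_labels[j])
  }, character(1))
  writeLines(c(sprintf("%s %d %g %d", p$name, nsig, record$sampling_rate, nsamp),
               sig_lines), p$hea)
  con <- file(p$dat, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  if (!is.null(record$r_peaks)) {
    write_wfdb_annotations(record$r_peaks, p$atr)
  }
  invisible(p$base)
}

read_record_wfdb <- function(path) {
  p <- wfdb_paths(path)
  if (!file.exists(p$hea)) {
    stop(sprintf("cannot read '%s': no such file", p$hea), call. = FALSE)
  }
  lines <- readLines(p$hea)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  nsamp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  labels <- character(nsig)
  gains <- numeric(nsig)
  baselines <- numeric(nsig)
  for (j in seq_len(nsig)) {
    f <- strsplit(trimws(lines[1 + j]), "\\s+")[[1]]
    check_that(f[2] == "16", "format",
               sprintf("only wfdb signal format 16 is supported (got '%s')", f[2]))
    gspec <- f[3]                               # gain(baseline)/units
    g <- sub("\\(.*$", "", sub("/.*$", "", gspec))
    gains[j] <- as.numeric(g)
    if (!is.finite(gains[j]) || gains[j] == 0) gains[j] <- 200  # wfdb default
    b <- regmatches(gspec, regexec("\\(([-0-9]+)\\)", gspec))[[1]]
    baselines[j] <- if (length(b) == 2) as.numeric(b[2]) else 0
    labels[j] <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else paste0("L", j)
  }
  raw <- readBin(p$dat, "integer", n = file.size(p$dat) / 2, size = 2,
                 endian = "little", signed = TRUE)
  n_frames <- length(raw) %/% nsig
  if (!is.na(nsamp) && nsamp < n_frames) n_frames <- nsamp
  adc <- matrix(raw[seq_len(n_frames * nsig)], nrow = n_frames, ncol = nsig, byrow = TRUE)
  signal <- sweep(sweep(adc, 2, baselines, "-"), 2, gains, "/")
  r_peaks <- if (file.exists(p$atr)) read_wfdb_annotations(p$atr) else NULL
  ecg_record(signal, fs, labels, r_peaks)
}

WFDB_NORMAL <- 1L  # beat code "N"
WFDB_SKIP <- 59L   # long-interval escape

write_wfdb_annotations <- function(indices, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  word <- function(code, time) {
    w <- bitwOr(bitwShiftL(code, 10), time)
    writeBin(as.integer(c(bitwAnd(w, 255L), bitwShiftR(w, 8))), con, size = 1)
  }
  prev <- 0L
  for (idx in as.integer(indices)) {
    d <- idx - prev
    if (d > 1023L) {
      word(WFDB_SKIP, 0L)
      hi <- d %/% 65536L
      lo <- d %% 65536L
      writeBin(as.integer(c(hi %% 256L, hi %/% 256L)), con, size = 1)  # high word
      writeBin(as.integer(c(lo %% 256L, lo %/% 256L)), con, size = 1)  # low word
      word(WFDB_NORMAL, 0L)
    } else {
      word(WFDB_NORMAL, d)
    }
    prev <- idx
  }
  word(0L, 0L)  # terminator
}

read_wfdb_annotations <- function(path) {
  bytes <- readBin(path, "integer", n = file.size(path), size = 1, signed = FALSE)
  out <- integer(0)
  t <- 0L
  i <- 1L
  while (i + 1L <= length(bytes)) {
    w <- bytes[i] + 256L * bytes[i + 1L]
    i <- i + 2L
    code <- w %/% 1024L
    dt <- w %% 1024L
    if (w == 0L) break
    if (code == WFDB_SKIP) {
      hi <- bytes[i] + 256L * bytes[i + 1L]
      lo <- bytes[i + 2L] + 256L * bytes[i + 3L]
      i <- i + 4L
      t <- t + hi * 65536L + lo
    } else if (code >= 60L && code <= 63L) {
      # NUM/SUB/CHN/AUX pseudo-annotations: skip payload where applicable
      if (code == 63L) i <- i + dt + (dt %% 2L)  # AUX: dt bytes, word-aligned
    } else {
      t <- t + dt
      out <- c(out, t)
    }
  }
  out
}

# ---- cycle matrices -------------------------------------------------------

#' Read or write a cycle matrix
#'
#' The `"array"` format is the package's lossless RDS container and
#' round-trips values bit-exactly together with the metadata map. `"csv"`
#' is plain comma-separated text with a `V1..VL` header row (so that a
#' 0-row matrix still round-trips); metadata is not stored in csv.
#'
#' @param path File path.
#' @param format One of `"array"`, `"csv"`.
#' @return `read_cycles()` returns a [cycle_matrix()]; `write_cycles()`
#'   returns `invisible(path)`.
#' @export
read_cycles <- function(path, format = c("array", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path), call. = FALSE)
  if (format == "array") {
    obj <- readRDS(path)
    check_that(identical(obj$schema, "ecgvae-cycles-1"), "schema",
               sprintf("unsupported cycle container schema '%s'", obj$schema %||% "<missing>"))
    return(cycle_matrix(obj$values, metadata = obj$metadata %||% list()))
  }
  lines <- readLines(path)
  check_that(length(lines) >= 1, "file", "empty csv file (header row expected)")
  rows <- strsplit(lines, ",")
  widths <- lengths(rows)
  check_that(length(unique(widths)) == 1, "values",
             sprintf("ragged rows: widths %s", paste(unique(widths), collapse = ", ")))
  ncols <- widths[1]
  values <- matrix(as.numeric(unlist(rows[-1])), nrow = length(lines) - 1,
                   ncol = ncols, byrow = TRUE)
  cycle_matrix(values)
}

#' @param matrix A [cycle_matrix()] or plain numeric matrix.
#' @rdname read_cycles
#' @export
write_cycles <- function(matrix, path, format = c("array", "csv")) {
  format <- match.arg(format)
  cm <- if (inherits(matrix, "cycle_matrix")) matrix else cycle_matrix(matrix)
  if (format == "array") {
    saveRDS(list(schema = "ecgvae-cycles-1", values = cm$values,
                 metadata = cm$metadata), path)
  } else {
    hdr <- paste(paste0("V", seq_len(cm$cycle_length)), collapse = ",")
    body <- apply(cm$values, 1, function(row) {
      paste(format(row, digits = 17, scientific = FALSE, trim = TRUE), collapse = ",")
    })
    writeLines(c(hdr, if (nrow(cm$values)) body), path)
  }
  invisible(path)
}
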