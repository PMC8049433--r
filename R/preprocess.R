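#' Cycle-extraction configuration
#'
#' @param half_width Samples on either side of the R peak; each extracted
#'   cycle has `2 * half_width` samples (default 200, i.e. a 400-sample /
#'   800 ms window at 500 Hz).
#' @param lead Lead selector: a 1-based column index or a lead label.
#' @param detector `"annotations"` uses the record's stored R peaks
#'   verbatim; `"builtin"` runs the band-pass/energy detector (see
#'   [detect_r_peaks()]).
#' @param min_peak_distance Minimum distance between detected peaks in
#'   samples (default 200, i.e. 0.4 s at 500 Hz — a 150 bpm ceiling).
#' @param detection_threshold Fraction of the maximum detection energy a
#'   candidate must exceed, in (0, 1].
#' @return An object of class `extraction_config`.
#' @export
extraction_config <- function(half_width = 200L, lead = 1L,
                              detector = c("annotations", "builtin"),
                              min_peak_distance = 200L,
                              detection_threshold = 0.4) {
  detector <- match.arg(detector)
  check_that(is.numeric(half_width) && length(half_width) == 1L && half_width >= 1,
             "half_width", "must be at least 1 sample")
  check_that(is.numeric(min_peak_distance) && length(min_peak_distance) == 1L &&
               min_peak_distance >= 1,
             "min_peak_distance", "must be at least 1 sample")
  check_that(is.numeric(detection_threshold) && length(detection_threshold) == 1L &&
               detection_threshold > 0 && detection_threshold <= 1,
             "detection_threshold", "must lie in (0, 1]")
  structure(list(half_width = as.integer(half_width), lead = lead,
                 detector = detector,
                 min_peak_distance = as.integer(min_peak_distance),
                 detection_threshold = detection_threshold),
            class = "extraction_config")
}

select_lead <- function(record, lead) {
  if (is.character(lead)) {
    j <- match(lead, record$lead_labels)
    check_that(!is.na(j), "lead",
               sprintf("label '%s' not found among: %s", lead,
                       paste(record$lead_labels, collapse = ", ")))
  } else {
    j <- as.integer(lead)
    check_that(j >= 1 && j <= ncol(record$signal), "lead",
               sprintf("index %d outside 1..%d", j, ncol(record$signal)))
  }
  record$signal[, j]
}

#' Locate R peaks in a record
#'
#' With `detector = "annotations"` the record's stored annotations are
#' returned verbatim (this is the reference path; a record without
#' annotations is a validation error). With `detector = "builtin"` a
#' Pan-Tompkins-style detector runs on the selected lead: 5–15 Hz
#' Butterworth band-pass, squared first difference, 150 ms moving-average
#' energy, threshold at `detection_threshold` times the maximum energy,
#' then refinement of each candidate to the local signal maximum within
#' ±`half_width`/4 samples. Returned indices are 0-based, strictly
#' increasing, and at least `min_peak_distance` apart.
#'
#' @param record An [ecg_record()].
#' @param config An [extraction_config()].
#' @return Integer vector of 0-based R-peak sample indices.
#' @export
detect_r_peaks <- function(record, config = extraction_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "extraction_config"))
  if (config$detector == "annotations") {
    check_that(!is.null(record$r_peaks), "r_peaks",
               "record has no annotations; use detector = \"builtin\"")
    return(record$r_peaks)
  }
  x <- select_lead(record, config$lead)
  fs <- record$sampling_rate
  if (length(x) < 10 || max(abs(x - x[1])) == 0) return(integer(0))
  ny <- fs / 2
  bp <- signal::filtfilt(signal::butter(3, c(5, 15) / ny, type = "pass"), x)
  energy <- c(0, diff(bp))^2
  w <- max(1L, as.integer(round(0.15 * fs)))
  ma <- stats::filter(energy, rep(1 / w, w), sides = 2)
  ma[is.na(ma)] <- 0
  ma <- as.numeric(ma)
  peak_max <- max(ma)
  if (peak_max <= 0) return(integer(0))
  thr <- config$detection_threshold * peak_max
  above <- ma >= thr
  # candidate = energy maximum of each contiguous above-threshold run
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  for (k in which(runs$values)) {
    seg <- starts[k]:ends[k]
    cand <- c(cand, seg[which.max(ma[seg])])
  }
  # refine to the raw-signal maximum near the energy peak
  r <- max(1L, config$half_width %/% 4L)
  refined <- vapply(cand, function(i) {
    lo <- max(1L, i - r)
    hi <- min(length(x), i + r)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory distance, keeping the taller peak of a close pair
  keep <- integer(0)
  for (i in refined) {
    if (length(keep) && i - keep[length(keep)] < config$min_peak_distance) {
      if (x[i] > x[keep[length(keep)]]) keep[length(keep)] <- i
    } else {
      keep <- c(keep, i)
    }
  }
  as.integer(keep - 1L)  # 0-based
}

#' Extract fixed-length R-centered cycles
#'
#' For each peak `p` (0-based) with `p - half_width >= 0` and
#' `p + half_width <= n_samples`, emits the half-open window
#' `[p - half_width, p + half_width)` of the selected lead as one row;
#' peaks violating the margins are dropped, not fatal, and counted in
#' `metadata$dropped`. At the defaults every row has
#' `2 * half_width = 400` samples.
#'
#' @param record An [ecg_record()].
#' @param peaks Integer vector of 0-based R-peak indices, sorted ascending;
#'   defaults to [detect_r_peaks()] under `config`.
#' @param config An [extraction_config()].
#' @return A [cycle_matrix()]; `metadata$dropped` counts discarded peaks so
#'   that `nrow + dropped == length(peaks)`.
#' @export
extract_cycles <- function(record, peaks = NULL, config = extraction_config()) {
  stopifnot(inherits(record, "ecg_record"), inherits(config, "extraction_config"))
  if (is.null(peaks)) peaks <- detect_r_peaks(record, config)
  peaks <- as.integer(peaks)
  check_that(!is.unsorted(peaks, strictly = FALSE), "peaks", "must be sorted ascending")
  x <- select_lead(record, config$lead)
  hw <- config$half_width
  n <- length(x)
  ok <- peaks - hw >= 0L & peaks + hw <= n
  kept <- peaks[ok]
  values <- matrix(0, length(kept), 2L * hw)
  for (i in seq_along(kept)) {
    p <- kept[i]
    values[i, ] <- x[(p - hw + 1L):(p + hw)]  # 0-based [p-hw, p+hw)
  }
  if (length(kept) == 0L) values <- matrix(0, 0L, 2L * hw)
  cycle_matrix(values,
               metadata = list(source = "extract_cycles",
                               half_width = hw, lead = config$lead,
                               detector = config$detector,
                               n_peaks = length(peaks),
                               dropped = sum(!ok)))
}

#' Normalize a cycle matrix
#'
#' `mode = "none"` is the identity (the default training mode);
#' `"per_cycle_zscore"` centers and scales each row by its own mean and
#' (sample) sd; `"global_zscore"` uses one mean and one population sd over
#' the whole matrix. Both z-score modes return the parameters needed to
#' invert the transform with [denormalize_cycles()].
#'
#' @param matrix A [cycle_matrix()] or plain numeric matrix.
#' @param mode One of `"none"`, `"per_cycle_zscore"`, `"global_zscore"`.
#' @return A list with `cycles` (the transformed [cycle_matrix()]) and
#'   `params` (class `normalization_params`).
#' @export
normalize_cycles <- function(matrix, mode = c("none", "per_cycle_zscore", "global_zscore")) {
  mode <- match.arg(mode)
  v <- as_cycle_values(matrix, "matrix")
  meta <- if (inherits(matrix, "cycle_matrix")) matrix$metadata else list()
  if (mode == "none") {
    params <- structure(list(mode = mode), class = "normalization_params")
    return(list(cycles = cycle_matrix(v, meta), params = params))
  }
  if (mode == "per_cycle_zscore") {
    mu <- rowMeans(v)
    s <- apply(v, 1, stats::sd)
    bad <- which(s == 0)
    if (length(bad)) {
      stop(sprintf("per_cycle_zscore: row %d has zero variance", bad[1]), call. = FALSE)
    }
    out <- (v - mu) / s
    params <- structure(list(mode = mode, mean = mu, sd = s),
                        class = "normalization_params")
  } else {
    mu <- mean(v)
    s <- sqrt(mean((v - mu)^2))  # population sd
    check_that(s > 0, "values", "global_zscore on a constant matrix")
    out <- (v - mu) / s
    params <- structure(list(mode = mode, mean = mu, sd = s),
                        class = "normalization_params")
  }
  meta$normalization <- mode
  list(cycles = cycle_matrix(out, meta), params = params)
}

#' Invert a normalization
#'
#' @param matrix A [cycle_matrix()] or numeric matrix in normalized units.
#' @param params The `normalization_params` returned by [normalize_cycles()].
#' @return A [cycle_matrix()] in the original units.
#' @export
denormalize_cycles <- function(matrix, params) {
  stopifnot(inherits(params, "normalization_params"))
  v <- as_cycle_values(matrix, "matrix")
  out <- switch(params$mode,
    none = v,
    per_cycle_zscore = v * params$sd + params$mean,
    global_zscore = v * params$sd + params$mean
  )
  cycle_matrix(out)
}
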