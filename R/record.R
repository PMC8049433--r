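#' Multi-lead ECG record container
#'
#' A sampled multi-lead signal with its sampling rate, lead labels, and
#' optional R-peak annotations. Sample indices are 0-based throughout the
#' package, and all windows are half-open `[start, end)`.
#'
#' @param signal Numeric samples-by-leads matrix (mV); a plain vector is
#'   treated as one lead.
#' @param sampling_rate Sampling rate in Hz; must be positive.
#' @param lead_labels Character vector of lead names, one per column;
#'   defaults to `"L1"`, `"L2"`, ...
#' @param r_peaks Optional integer vector of 0-based R-peak sample indices;
#'   `NULL` means "no annotations", `integer(0)` means "annotated, none
#'   found" — the two are kept distinct.
#' @param metadata Free-form provenance list.
#' @return An object of class `ecg_record` with fields `signal`,
#'   `sampling_rate`, `lead_labels`, `r_peaks`, `metadata`.
#' @export
ecg_record <- function(signal, sampling_rate, lead_labels = NULL,
                       r_peaks = NULL, metadata = list()) {
  if (is.vector(signal) && is.numeric(signal)) signal <- matrix(signal, ncol = 1)
  check_that(is.matrix(signal) && is.numeric(signal), "signal",
             "must be a numeric samples-by-leads matrix")
  check_that(is.numeric(sampling_rate) && length(sampling_rate) == 1L && sampling_rate > 0,
             "sampling_rate", "must be positive (Hz)")
  if (is.null(lead_labels)) lead_labels <- paste0("L", seq_len(ncol(signal)))
  check_that(length(lead_labels) == ncol(signal), "lead_labels",
             sprintf("length %d does not match %d lead(s)", length(lead_labels), ncol(signal)))
  if (!is.null(r_peaks)) {
    r_peaks <- as.integer(r_peaks)
    check_that(all(r_peaks >= 0 & r_peaks < nrow(signal)), "r_peaks",
               sprintf("every index must lie in [0, %d)", nrow(signal)))
  }
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 lead_labels = as.character(lead_labels), r_peaks = r_peaks,
                 metadata = metadata),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples x %d lead(s) @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$sampling_rate,
              nrow(x$signal) / x$sampling_rate))
  cat("  leads:", paste(x$lead_labels, collapse = ", "), "\n")
  if (is.null(x$r_peaks)) {
    cat("  r_peaks: <none>\n")
  } else {
    cat(sprintf("  r_peaks: %d annotated\n", length(x$r_peaks)))
  }
  invisible(x)
}

#' Cycle matrix container
#'
#' An n-by-L matrix of fixed-length single-cycle waveforms (mV), one row per
#' cardiac cycle, plus free-form provenance metadata.
#'
#' @param values Numeric matrix; every row is one cycle. Zero rows are
#'   allowed (an empty training set is representable); the row length must
#'   be at least 2.
#' @param metadata Free-form provenance list.
#' @return An object of class `cycle_matrix` with fields `values`,
#'   `cycle_length`, `metadata`.
#' @export
cycle_matrix <- function(values, metadata = list()) {
  if (is.vector(values) && is.numeric(values)) values <- matrix(values, nrow = 1)
  check_that(is.matrix(values) && is.numeric(values), "values", "must be a numeric matrix")
  check_that(ncol(values) >= 2, "cycle_length", "must be at least 2")
  structure(list(values = values, cycle_length = ncol(values), metadata = metadata),
            class = "cycle_matrix")
}

#' @export
print.cycle_matrix <- function(x, ...) {
  cat(sprintf("<cycle_matrix> %d cycle(s) x %d samples\n", nrow(x$values), x$cycle_length))
  if (length(x$metadata)) {
    keys <- names(x$metadata)
    cat("  metadata:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.matrix.cycle_matrix <- function(x, ...) x$values

#' @export
dim.cycle_matrix <- function(x) dim(x$values)

# Accept either a cycle_matrix or a plain numeric matrix.
as_cycle_values <- function(x, arg = "cycles") {
  if (inherits(x, "cycle_matrix")) return(x$values)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop(sprintf("%s: must be a cycle_matrix or a numeric matrix", arg), call. = FALSE)
}
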