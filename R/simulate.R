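#' Parameters of one Gaussian ECG wave
#'
#' A single wave of the cardiac cycle (P, Q, R, S, T or U) modelled as a
#' Gaussian bump `amplitude * exp(-(t - center)^2 / (2 * width^2))` on the
#' time axis of one cycle.
#'
#' @param label Wave label, one of `"P"`, `"Q"`, `"R"`, `"S"`, `"T"`, `"U"`.
#' @param amplitude Signed peak amplitude in mV.
#' @param center Offset of the peak from the start of the cycle, in ms.
#' @param width Gaussian standard deviation in ms; must be positive.
#' @return An object of class `wave_params`.
#' @examples
#' wave_params("R", amplitude = 1.0, center = 400, width = 10)
#' @export
wave_params <- function(label, amplitude, center, width) {
  label <- match.arg(label, c("P", "Q", "R", "S", "T", "U"))
  check_that(is.numeric(amplitude) && length(amplitude) == 1L && is.finite(amplitude),
             "amplitude", "must be a single finite number (mV)")
  check_that(is.numeric(center) && length(center) == 1L && is.finite(center) && center >= 0,
             "center", "must be a single nonnegative number (ms)")
  check_that(is.numeric(width) && length(width) == 1L && is.finite(width) && width > 0,
             "width", "must be a single positive number (ms)")
  structure(list(label = label, amplitude = amplitude, center = center, width = width),
            class = "wave_params")
}

#' Default single-cycle wave morphology
#'
#' A fixture convention for a plausible normal-looking cycle on an 800 ms
#' window with the R peak at its center (400 ms): P 0.15 mV at 160 ms, Q
#' -0.10 mV at 370 ms, R 1.00 mV at 400 ms, S -0.15 mV at 430 ms, T 0.30 mV
#' at 600 ms, with widths between 8 and 40 ms. These values are simulator
#' conventions chosen to look like textbook lead-II morphology; they are not
#' measurements.
#'
#' @return A list of [wave_params()] objects.
#' @export
default_morphology <- function() {
  list(
    wave_params("P", amplitude = 0.15, center = 160, width = 25),
    wave_params("Q", amplitude = -0.10, center = 370, width = 8),
    wave_params("R", amplitude = 1.00, center = 400, width = 10),
    wave_params("S", amplitude = -0.15, center = 430, width = 8),
    wave_params("T", amplitude = 0.30, center = 600, width = 40)
  )
}

#' Specification of one synthetic cardiac cycle
#'
#' @param waves List of [wave_params()]; labels must be unique and every
#'   center must fall inside the cycle window.
#' @param baseline Constant baseline level in mV.
#' @param noise_sd Standard deviation of i.i.d. Gaussian sample noise in mV
#'   (0 for a noise-free cycle).
#' @param n_samples Samples per cycle (default 400, i.e. 800 ms at 500 Hz).
#' @param sampling_rate Sampling rate in Hz (default 500).
#' @return An object of class `cycle_spec`.
#' @export
cycle_spec <- function(waves = default_morphology(), baseline = 0,
                       noise_sd = 0, n_samples = 400L, sampling_rate = 500) {
  check_that(is.list(waves) && all(vapply(waves, inherits, logical(1), "wave_params")),
             "waves", "must be a list of wave_params objects")
  check_that(is.numeric(baseline) && length(baseline) == 1L && is.finite(baseline),
             "baseline", "must be a single finite number (mV)")
  check_that(is.numeric(noise_sd) && length(noise_sd) == 1L && is.finite(noise_sd) && noise_sd >= 0,
             "noise_sd", "must be a single nonnegative number (mV)")
  check_that(is.numeric(n_samples) && length(n_samples) == 1L && n_samples >= 2,
             "n_samples", "must be at least 2")
  check_that(is.numeric(sampling_rate) && length(sampling_rate) == 1L && sampling_rate > 0,
             "sampling_rate", "must be positive (Hz)")
  labels <- vapply(waves, `[[`, character(1), "label")
  check_that(!anyDuplicated(labels), "waves", "wave labels must be unique within a cycle")
  duration_ms <- n_samples / sampling_rate * 1000
  for (w in waves) {
    check_that(w$center < duration_ms, "center",
               sprintf("wave %s center %.1f ms lies outside the %.1f ms cycle window",
                       w$label, w$center, duration_ms))
  }
  structure(list(waves = waves, baseline = baseline, noise_sd = noise_sd,
                 n_samples = as.integer(n_samples), sampling_rate = sampling_rate),
            class = "cycle_spec")
}

# Noise-free waveform of a spec at its sample times (the closed-form oracle).
cycle_template <- function(spec) {
  t_ms <- (seq_len(spec$n_samples) - 1) / spec$sampling_rate * 1000
  y <- rep(spec$baseline, spec$n_samples)
  for (w in spec$waves) {
    y <- y + w$amplitude * exp(-(t_ms - w$center)^2 / (2 * w$width^2))
  }
  y
}

#' Generate one synthetic cardiac cycle
#'
#' Evaluates the sum-of-Gaussians waveform of `spec` at its sample times and
#' adds i.i.d. Gaussian noise of sd `noise_sd`. With `noise_sd = 0` the
#' output is the closed-form template and is independent of `seed`.
#'
#' @param spec A [cycle_spec()].
#' @param seed Optional integer seed controlling the noise draw; the caller's
#'   RNG state is left untouched when a seed is given.
#' @return Numeric vector of length `spec$n_samples` (mV).
#' @export
generate_cycle <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cycle_spec"))
  y <- cycle_template(spec)
  if (spec$noise_sd > 0) {
    y <- y + with_seed(seed, rnorm(spec$n_samples, 0, spec$noise_sd))
  }
  y
}

# One jittered copy of the wave list: every field (amplitude, center, width)
# is perturbed multiplicatively by an independent 1 + N(0, jitter) factor.
# Center jitter therefore acts on the offset from the window start, so it is
# dominated by timing shifts of the late waves — the main source of
# beat-to-beat variability the simulator emulates. Width stays strictly
# positive and centers are clamped to the window.
jitter_waves <- function(waves, jitter, duration_ms) {
  if (jitter == 0) return(waves)
  lapply(waves, function(w) {
    amp <- w$amplitude * (1 + rnorm(1, 0, jitter))
    wid <- w$width * max(1 + rnorm(1, 0, jitter), 0.05)
    cen <- min(max(w$center * (1 + rnorm(1, 0, jitter)), 0), duration_ms * (1 - 1e-9))
    wave_params(w$label, amp, cen, wid)
  })
}

#' Generate a matrix of jittered synthetic cycles
#'
#' Each row is an independent cycle whose wave parameters are perturbed by
#' the relative jitter (see Details) before sampling, plus fresh Gaussian
#' noise of sd `spec$noise_sd`.
#'
#' @details Jitter perturbs every wave field — amplitude, center and width —
#'   multiplicatively by an independent factor `1 + N(0, jitter)` per cycle.
#'   Because the center field is an offset from the window start, the
#'   resulting variability is dominated by timing shifts of the late waves
#'   (R, S, T), which is the main beat-to-beat variation the simulator
#'   emulates. Note that under timing jitter the per-sample mean of many
#'   cycles is a smoothed version of the jitter-free template, not the
#'   template itself.
#'
#' @param spec A [cycle_spec()].
#' @param n Number of cycles (rows); at least 1.
#' @param jitter Nonnegative relative standard deviation of the per-wave
#'   parameter perturbations (0 disables jitter).
#' @param seed Optional integer seed; a fixed seed makes the whole matrix
#'   bit-reproducible.
#' @return A [cycle_matrix()] with `n` rows of length `spec$n_samples`.
#' @export
generate_dataset <- function(spec, n, jitter = 0, seed = NULL) {
  stopifnot(inherits(spec, "cycle_spec"))
  check_that(is.numeric(n) && length(n) == 1L && n >= 1, "n", "must be at least 1")
  check_that(is.numeric(jitter) && length(jitter) == 1L && jitter >= 0,
             "jitter", "must be nonnegative")
  n <- as.integer(n)
  duration_ms <- spec$n_samples / spec$sampling_rate * 1000
  values <- with_seed(seed, {
    m <- matrix(0, n, spec$n_samples)
    for (i in seq_len(n)) {
      spec_i <- spec
      spec_i$waves <- jitter_waves(spec$waves, jitter, duration_ms)
      m[i, ] <- generate_cycle(spec_i, seed = NULL)
    }
    m
  })
  cycle_matrix(values, metadata = list(source = "simulator", n = n,
                                       jitter = jitter, seed = seed,
                                       noise_sd = spec$noise_sd))
}

#' Generate a continuous annotated ECG record
#'
#' Concatenates `n_beats` jittered cycles at a constant RR spacing into one
#' continuous single-lead signal and records the true R-peak sample indices
#' (0-based) as annotations. Cycles are placed back to back when
#' `rr_ms` equals the cycle duration; longer RR intervals are padded with
#' baseline.
#'
#' @param spec A [cycle_spec()].
#' @param n_beats Number of beats; at least 1.
#' @param rr_ms RR interval in ms; must be at least one cycle footprint
#'   (`spec$n_samples / spec$sampling_rate * 1000` ms).
#' @param jitter Relative per-wave jitter as in [generate_dataset()].
#' @param seed Optional integer seed.
#' @param lead_label Label for the single synthesized lead.
#' @return An [ecg_record()] with `r_peaks` of length `n_beats`.
#' @export
generate_record <- function(spec, n_beats, rr_ms = 800, jitter = 0,
                            seed = NULL, lead_label = "II") {
  stopifnot(inherits(spec, "cycle_spec"))
  check_that(is.numeric(n_beats) && length(n_beats) == 1L && n_beats >= 1,
             "n_beats", "must be at least 1")
  check_that(is.numeric(rr_ms) && length(rr_ms) == 1L && rr_ms > 0,
             "rr_ms", "must be positive (ms)")
  footprint_ms <- spec$n_samples / spec$sampling_rate * 1000
  check_that(rr_ms >= footprint_ms, "rr_ms",
             sprintf("RR interval %.1f ms is shorter than one cycle footprint (%.1f ms)",
                     rr_ms, footprint_ms))
  n_beats <- as.integer(n_beats)
  rr_samples <- as.integer(round(rr_ms * spec$sampling_rate / 1000))
  total <- n_beats * rr_samples
  duration_ms <- footprint_ms
  rec <- with_seed(seed, {
    x <- rep(spec$baseline, total)
    r_peaks <- integer(n_beats)
    for (k in seq_len(n_beats)) {
      spec_k <- spec
      spec_k$waves <- jitter_waves(spec$waves, jitter, duration_ms)
      cyc <- generate_cycle(spec_k, seed = NULL)
      offset <- (k - 1L) * rr_samples            # 0-based start of this beat
      x[offset + seq_len(spec$n_samples)] <- cyc
      r_peaks[k] <- offset + which.max(cyc) - 1L # 0-based true R-peak index
    }
    list(x = x, r_peaks = r_peaks)
  })
  ecg_record(matrix(rec$x, ncol = 1), sampling_rate = spec$sampling_rate,
             lead_labels = lead_label, r_peaks = rec$r_peaks,
             metadata = list(source = "simulator", n_beats = n_beats,
                             rr_ms = rr_ms, jitter = jitter, seed = seed))
}
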