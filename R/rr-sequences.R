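# From ECG to RR intervals and on to the combined-interval RRnI / RRnIm
# sequences that define heart rate n-variability.

#' Construct an RR-interval sequence
#'
#' The raw tachogram: ordered R-R intervals in ms with a cumulative time axis.
#'
#' @param intervals Numeric vector of R-R intervals in ms, all > 0.
#' @param source_id Label of the originating record.
#' @return An object of class `"rri_sequence"` with fields `intervals`,
#'   `onset_times` (cumulative, ms) and `source_id`.
#' @export
rri_sequence <- function(intervals, source_id = "rri") {
  intervals <- as.numeric(intervals)
  if (any(!is.finite(intervals)) || any(intervals <= 0)) {
    stop("all RR intervals must be finite and > 0", call. = FALSE)
  }
  structure(list(intervals = intervals,
                 onset_times = cumsum(intervals),
                 source_id = source_id),
            class = "rri_sequence")
}

#' @export
print.rri_sequence <- function(x, ...) {
  cat(sprintf("<rri_sequence> %s: %d intervals, %.1f s, mean %.1f ms\n",
              x$source_id, length(x$intervals),
              sum(x$intervals) / 1000, mean(x$intervals)))
  invisible(x)
}

#' Detect R peaks in a single-lead ECG
#'
#' A Pan-Tompkins-style detector: high-pass by subtraction of a running mean,
#' differentiate, square, integrate over a 150 ms window, threshold
#' adaptively, then refine each detection to the local signal maximum. A
#' refractory period of at least 200 ms is enforced.
#'
#' @param ecg An `"ecg_record"` (fields `samples`, `sampling_rate`).
#' @param refractory_ms Minimum inter-peak distance, ms (default 200).
#' @param threshold_frac Detection threshold as a fraction of the 99th
#'   percentile of the integrated detection function.
#' @return Strictly increasing 1-based sample indices of detected R peaks;
#'   an empty vector with attribute `"warning"` if nothing is found.
#' @export
detect_r_peaks <- function(ecg, refractory_ms = 200, threshold_frac = 0.3) {
  stopifnot(is.list(ecg), !is.null(ecg$samples), !is.null(ecg$sampling_rate))
  fs <- ecg$sampling_rate
  x <- as.numeric(ecg$samples)
  if (length(x) < 2 * fs) stop("need at least 2 s of signal", call. = FALSE)
  hp <- x - running_mean(x, max(3L, round(0.2 * fs)))
  sm <- running_mean(hp, max(3L, round(0.03 * fs)))  # low-pass vs white noise
  d <- c(0, diff(sm)) * fs
  sq <- d^2
  dint <- running_mean(sq, max(3L, round(0.15 * fs)))
  n <- length(dint)
  if (max(dint) <= 0) return(structure(integer(0), warning = "no peaks found"))
  refr <- round(refractory_ms / 1000 * fs)
  # segment-wise adaptive threshold: robust to localized corruption, which
  # would otherwise dominate a single global threshold
  seg_len <- round(2.5 * fs)
  starts <- seq.int(1L, n, by = seg_len)
  # a short trailing remainder merges into the previous segment so it cannot
  # set its own (noise-floor) threshold
  if (length(starts) > 1L && n - starts[length(starts)] + 1L < seg_len / 2) {
    starts <- starts[-length(starts)]
  }
  thr <- numeric(n)
  for (i in seq_along(starts)) {
    lo <- starts[i]
    hi <- if (i < length(starts)) starts[i + 1L] - 1L else n
    thr[lo:hi] <- threshold_frac * max(dint[lo:hi])
  }
  above <- dint > thr & dint > 0
  # candidate = local maximum of the detection function above threshold
  cand <- which(above &
                  dint >= c(-Inf, dint[-n]) &
                  dint >= c(dint[-1], -Inf))
  if (!length(cand)) return(structure(integer(0), warning = "no peaks found"))
  # enforce refractory on the detection function, keeping the taller candidate
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (dint[i] > dint[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  # refine to the raw-signal maximum near each candidate
  half <- round(0.08 * fs)
  peaks <- vapply(keep, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refractory again after refinement
  if (length(peaks) > 1) {
    out <- peaks[1]
    for (p in peaks[-1]) {
      if (p - out[length(out)] >= refr) out <- c(out, p)
      else if (x[p] > x[out[length(out)]]) out[length(out)] <- p
    }
    peaks <- out
  }
  peaks
}

#' Assess ECG signal quality
#'
#' Splits the record into windows (default 10 s) and labels each window by the
#' mean correlation of its detected beats against the record-wide median beat
#' template; windows with no detectable beats or poor template correlation are
#' flagged as noise. A recording is usable when at most 30% of it is flagged,
#' the exclusion rule applied to the study recordings.
#'
#' @param ecg An `"ecg_record"`.
#' @param peaks Detected R-peak indices; computed if missing.
#' @param window_s Window length in seconds.
#' @param corr_threshold Minimum mean beat-template correlation for a clean
#'   window (default 0.5, which cleanly separates white-noise windows).
#' @return A list of class `"quality_report"`: `noise_fraction`, `usable`,
#'   and per-window `flags` (`"clean"`/`"noise"`).
#' @export
assess_quality <- function(ecg, peaks = NULL, window_s = 10,
                           corr_threshold = 0.5) {
  fs <- ecg$sampling_rate
  x <- as.numeric(ecg$samples)
  if (is.null(peaks)) peaks <- detect_r_peaks(ecg)
  n_win <- max(1L, ceiling(length(x) / (window_s * fs)))
  half <- round(0.1 * fs)
  beat_mat <- NULL
  ok <- peaks[peaks - half >= 1 & peaks + half <= length(x)]
  if (length(ok) >= 3) {
    beat_mat <- vapply(ok, function(p) x[(p - half):(p + half)],
                       numeric(2 * half + 1))
    template <- apply(beat_mat, 1, stats::median)
  }
  flags <- character(n_win)
  for (w in seq_len(n_win)) {
    lo <- (w - 1) * window_s * fs + 1
    hi <- min(w * window_s * fs, length(x))
    in_win <- ok[ok >= lo & ok <= hi]
    if (length(in_win) == 0 || is.null(beat_mat)) {
      flags[w] <- "noise"
      next
    }
    cors <- vapply(in_win, function(p) {
      beat <- x[(p - half):(p + half)]
      if (stats::sd(beat) == 0 || stats::sd(template) == 0) return(0)
      stats::cor(beat, template)
    }, numeric(1))
    flags[w] <- if (mean(cors) >= corr_threshold) "clean" else "noise"
  }
  noise_fraction <- mean(flags == "noise")
  structure(list(noise_fraction = noise_fraction,
                 usable = noise_fraction <= 0.30,
                 flags = flags),
            class = "quality_report")
}

#' Convert detected R peaks to an RR-interval sequence
#'
#' @param peaks Strictly increasing sample indices (>= 2 of them).
#' @param sampling_rate Sampling rate in Hz.
#' @param source_id Label passed through to the sequence.
#' @return An [rri_sequence()]; `intervals[i] = (peaks[i+1] - peaks[i]) *
#'   1000 / sampling_rate`.
#' @export
rri_from_peaks <- function(peaks, sampling_rate, source_id = "ecg") {
  if (length(peaks) < 2) stop("need at least 2 peaks", call. = FALSE)
  if (any(diff(peaks) <= 0)) stop("peaks must be strictly increasing", call. = FALSE)
  rri_sequence(diff(peaks) * 1000 / sampling_rate, source_id = source_id)
}

#' Flag and remove ectopic / artefactual intervals
#'
#' Intervals outside `range_ms` or differing by more than `rel_tol` from an
#' 11-beat running median are excluded before sequence construction. The study
#' excluded non-sinus recordings wholesale; within-recording cleaning is this
#' package's own (optional) rule and is off for synthetic tests.
#'
#' @param rri An [rri_sequence()].
#' @param range_ms Plausible interval range in ms.
#' @param rel_tol Maximum relative deviation from the running median.
#' @return A cleaned [rri_sequence()]; attribute `"n_removed"` counts drops.
#' @export
clean_rri <- function(rri, range_ms = c(300, 2000), rel_tol = 0.2) {
  stopifnot(inherits(rri, "rri_sequence"))
  x <- rri$intervals
  med <- stats::runmed(x, k = min(11L, length(x) - (length(x) + 1) %% 2))
  bad <- x < range_ms[1] | x > range_ms[2] | abs(x - med) / med > rel_tol
  out <- rri_sequence(x[!bad], source_id = rri$source_id)
  attr(out, "n_removed") <- sum(bad)
  out
}

#' An RRnI / RRnIm configuration
#'
#' Each configuration `(n, m)` defines a combined-interval sequence: windowed
#' sums of `n` consecutive RR intervals taken at stride `m`. `m = n` gives the
#' non-overlapping RRnI sequence; `m < n` the overlapping RRnIm sequence.
#'
#' @param n Window width in beats (>= 1).
#' @param m Stride in beats, `1 <= m <= n`.
#' @return An object of class `"rrni_config"` with a conventional `label`
#'   (`HRV` for (1,1), `HR2V` for (2,2), `HR2V1` for (2,1), ...).
#' @export
rrni_config <- function(n, m = n) {
  n <- as.integer(n); m <- as.integer(m)
  if (is.na(n) || n < 1L) stop("`n` must be an integer >= 1", call. = FALSE)
  if (is.na(m) || m < 1L || m > n) stop("`m` must satisfy 1 <= m <= n", call. = FALSE)
  label <- if (n == 1L) "HRV" else if (m == n) sprintf("HR%dV", n)
           else sprintf("HR%dV%d", n, m)
  structure(list(n = n, m = m, label = label), class = "rrni_config")
}

#' Enumerate all HRnV configurations up to N_max
#'
#' All `(n, m)` pairs with `1 <= n <= N_max`, `1 <= m <= n`, giving
#' `N_max (N_max + 1) / 2` parameter sets. The study used `N_max = 3`:
#' HRV, HR2V1, HR2V, HR3V1, HR3V2, HR3V.
#'
#' @param n_max Upper limit of `n` (>= 1). Default 3.
#' @return A list of [rrni_config()]s in (n ascending, m ascending) order.
#' @export
enumerate_configs <- function(n_max = 3L) {
  n_max <- as.integer(n_max)
  if (is.na(n_max) || n_max < 1L) stop("`n_max` must be >= 1", call. = FALSE)
  out <- list()
  for (n in seq_len(n_max)) for (m in seq_len(n)) {
    out[[length(out) + 1L]] <- rrni_config(n, m)
  }
  out
}

#' Build a combined-interval RRnI / RRnIm sequence
#'
#' Windowed sums of width `n` at stride `m` over the source intervals;
#' trailing intervals that cannot fill a complete window are dropped, so every
#' emitted value is a true sum of `n` measured intervals. The element count is
#' `floor((L - n) / m) + 1` for source length `L >= n`. Each element's time
#' stamp is the end time of its window (used by the spectral estimator).
#'
#' @param rri An [rri_sequence()].
#' @param config An [rrni_config()] (or `n`,`m` via `rrni_config(n, m)`).
#' @return An object of class `"rrni_sequence"`: `config`, `values` (ms),
#'   `times` (window end times, ms), `element_count`.
#' @export
#' @examples
#' r <- rri_sequence(c(800, 810, 790, 805, 795))
#' build_rrni(r, rrni_config(2, 1))$values  # 1610 1600 1595 1600
build_rrni <- function(rri, config) {
  stopifnot(inherits(rri, "rri_sequence"), inherits(config, "rrni_config"))
  L <- length(rri$intervals)
  if (L < config$n) {
    stop(sprintf("sequence has %d intervals; need at least n = %d",
                 L, config$n), call. = FALSE)
  }
  starts <- seq.int(1L, L - config$n + 1L, by = config$m)
  cs <- c(0, cumsum(rri$intervals))
  values <- cs[starts + config$n] - cs[starts]
  structure(list(config = config,
                 values = values,
                 times = rri$onset_times[starts + config$n - 1L],
                 element_count = length(values),
                 source_id = rri$source_id),
            class = "rrni_sequence")
}

#' @export
print.rrni_sequence <- function(x, ...) {
  cat(sprintf("<rrni_sequence> %s (n=%d, m=%d): %d elements\n",
              x$config$label, x$config$n, x$config$m, x$element_count))
  invisible(x)
}
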