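# Synthetic data: IPFM tachograms, template ECG synthesis, and two-group
# cohorts with a known generative model. Everything is seed-deterministic and
# exists so the downstream measurement and modelling stages can be tested
# against planted ground truth.

#' Specify a synthetic sinus-rhythm tachogram
#'
#' Parameters of an integral pulse frequency modulation (IPFM) generator.
#' The instantaneous heart rate is
#' \deqn{r(t) = (\mathrm{mean\_hr}/60)\,(1 + a_{LF}\sin 2\pi f_{LF} t
#'             + a_{HF}\sin 2\pi f_{HF} t)}
#' and beats fire each time the integral of \eqn{r} crosses an integer, so the
#' low- and high-frequency modulation amplitudes directly control LF and HF
#' band power of the resulting RR series.
#'
#' @param duration_s Recording length in seconds (> 0). Default 300 s, the
#'   length of a five-minute single-lead recording.
#' @param mean_hr Mean heart rate in beats/min, in (20, 250).
#' @param lf_freq,hf_freq Modulation frequencies in Hz; `lf_freq < hf_freq`.
#'   Defaults 0.1 and 0.25 Hz, the conventional centres of the LF and HF bands.
#' @param lf_amp,hf_amp Modulation amplitudes as dimensionless fractions of the
#'   mean rate (>= 0; their sum must stay below 1 so the rate stays positive).
#' @param noise_sd Standard deviation of zero-mean Gaussian beat-to-beat noise
#'   added to the intervals, in ms.
#' @param seed Integer seed; every draw flows from it.
#' @return An object of class `"tachogram_spec"`.
#' @export
#' @examples
#' spec <- tachogram_spec(duration_s = 300, mean_hr = 60,
#'                        lf_amp = 0, hf_amp = 0, noise_sd = 0)
#' rri <- generate_rri(spec)
#' head(rri$intervals)  # metronomic 1000 ms beats
tachogram_spec <- function(duration_s = 300, mean_hr = 80,
                           lf_freq = 0.1, hf_freq = 0.25,
                           lf_amp = 0.05, hf_amp = 0.05,
                           noise_sd = 5, seed = 1L) {
  stopifnot_scalar_num(duration_s, "duration_s", 0, Inf, strict = TRUE)
  stopifnot_scalar_num(mean_hr, "mean_hr", 20, 250, strict = TRUE)
  stopifnot_scalar_num(lf_freq, "lf_freq", 0, Inf, strict = TRUE)
  stopifnot_scalar_num(hf_freq, "hf_freq", 0, Inf, strict = TRUE)
  if (lf_freq >= hf_freq) stop("`lf_freq` must be below `hf_freq`", call. = FALSE)
  stopifnot_scalar_num(lf_amp, "lf_amp", 0, Inf)
  stopifnot_scalar_num(hf_amp, "hf_amp", 0, Inf)
  if (lf_amp + hf_amp >= 1) {
    stop("modulation amplitudes must sum to < 1 (rate must stay positive)",
         call. = FALSE)
  }
  stopifnot_scalar_num(noise_sd, "noise_sd", 0, Inf)
  structure(list(duration_s = duration_s, mean_hr = mean_hr,
                 lf_freq = lf_freq, hf_freq = hf_freq,
                 lf_amp = lf_amp, hf_amp = hf_amp,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "tachogram_spec")
}

#' Generate an RR-interval tachogram by IPFM
#'
#' Beat times are the integer crossings of the analytically integrated
#' instantaneous rate; intervals are their successive differences in ms with
#' optional additive Gaussian noise. With zero modulation and zero noise the
#' output is exactly metronomic (SDNN = 0).
#'
#' @param spec A [tachogram_spec()].
#' @return An [rri_sequence()] whose `source_id` records the generator seed.
#' @export
generate_rri <- function(spec) {
  stopifnot(inherits(spec, "tachogram_spec"))
  rate <- spec$mean_hr / 60  # beats per second
  # Closed-form integral of the modulated rate, zero at t = 0.
  R <- function(t) {
    out <- t
    if (spec$lf_amp > 0) {
      w <- 2 * pi * spec$lf_freq
      out <- out - spec$lf_amp * (cos(w * t) - 1) / w
    }
    if (spec$hf_amp > 0) {
      w <- 2 * pi * spec$hf_freq
      out <- out - spec$hf_amp * (cos(w * t) - 1) / w
    }
    rate * out
  }
  tg <- seq(0, spec$duration_s, by = 0.001)
  Rg <- R(tg)
  n_beats <- floor(Rg[length(Rg)])
  if (n_beats < 10) {
    stop("spec yields fewer than 10 beats; lengthen the recording or raise the rate",
         call. = FALSE)
  }
  # R is strictly increasing, so the inverse is well defined; piecewise-linear
  # inversion on a 1 ms grid is exact for the unmodulated case and accurate to
  # well under the grid step otherwise.
  beat_t <- stats::approx(Rg, tg, xout = seq_len(n_beats), ties = "ordered")$y
  intervals <- diff(c(0, beat_t)) * 1000
  if (spec$noise_sd > 0) {
    intervals <- local_seed(spec$seed,
                            intervals + stats::rnorm(length(intervals), 0, spec$noise_sd))
    intervals <- pmax(intervals, 1)
  }
  rri_sequence(intervals, source_id = sprintf("ipfm-seed%d", spec$seed))
}

# Default beat template: a narrow positive Gaussian R deflection.
default_beat_template <- function(sampling_rate, width_ms = 80, amplitude = 1) {
  half <- round(width_ms / 2 * sampling_rate / 1000)
  t <- seq(-half, half) / sampling_rate * 1000  # ms
  amplitude * exp(-(t / (width_ms / 8))^2)
}

#' Synthesize a single-lead ECG from a tachogram
#'
#' Places one beat template (a dominant positive R deflection) at each
#' cumulative beat time and adds optional white amplitude noise. Used to
#' exercise the R-peak detector end to end against planted beat positions.
#'
#' @param rri An [rri_sequence()].
#' @param sampling_rate Sampling rate in Hz (>= 100).
#' @param template Numeric beat waveform centred on its R peak; default is a
#'   Gaussian deflection of 80 ms width and unit amplitude.
#' @param noise_sd Amplitude noise standard deviation (same units as the
#'   template; the default template has R amplitude 1).
#' @param seed Integer seed for the noise draw.
#' @return An object of class `"ecg_record"` with fields `samples`,
#'   `sampling_rate`, `record_id`, and attribute `beat_samples` giving the
#'   planted 1-based R-peak sample indices (ground truth for tests).
#' @export
generate_ecg <- function(rri, sampling_rate = 250, template = NULL,
                         noise_sd = 0, seed = 1L) {
  stopifnot(inherits(rri, "rri_sequence"))
  stopifnot_scalar_num(sampling_rate, "sampling_rate", 100, Inf)
  if (length(rri$intervals) == 0) stop("empty RRI sequence", call. = FALSE)
  if (is.null(template)) template <- default_beat_template(sampling_rate)
  if (length(template) / sampling_rate * 1000 > min(rri$intervals)) {
    stop("beat template is longer than the shortest RR interval", call. = FALSE)
  }
  beat_times_s <- c(0, rri$onset_times) / 1000
  n <- ceiling(sum(rri$intervals) / 1000 * sampling_rate)
  samples <- numeric(n)
  centre <- round(beat_times_s * sampling_rate) + 1L
  half <- (length(template) - 1L) %/% 2L
  planted <- integer(0)
  for (c0 in centre) {
    if (c0 > n) next
    idx <- (c0 - half):(c0 - half + length(template) - 1L)
    keep <- idx >= 1L & idx <= n
    samples[idx[keep]] <- samples[idx[keep]] + template[keep]
    planted <- c(planted, c0)
  }
  if (noise_sd > 0) {
    samples <- local_seed(seed, samples + stats::rnorm(n, 0, noise_sd))
  }
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 record_id = rri$source_id),
            beat_samples = planted, class = "ecg_record")
}

# Table-1-like marginal distributions of the default covariate schema.
default_cohort_covariates <- function() {
  list(
    age         = function(n) stats::rnorm(n, 67, 16),
    male        = function(n) stats::rbinom(n, 1, 0.51),
    temperature = function(n) stats::rnorm(n, 37.8, 1.2),
    resp_rate   = function(n) pmax(round(stats::rnorm(n, 20, 3.5)), 6),
    spo2        = function(n) pmin(round(stats::rnorm(n, 96.5, 2.5)), 100),
    sbp         = function(n) pmax(round(stats::rnorm(n, 108, 28)), 40),
    heart_rate  = function(n) pmax(round(stats::rnorm(n, 114, 24)), 30),
    gcs         = function(n) pmin(pmax(round(stats::rnorm(n, 13.2, 3)), 3), 15),
    supp_o2     = function(n) stats::rbinom(n, 1, 0.3)
  )
}

# Per-unit log odds ratios of the covariates on 30-day mortality; signs follow
# the observed group contrasts (older, tachypnoeic, hypotensive, hypothermic,
# obtunded patients die more).
default_covariate_effects <- function() {
  c(age = 0.03, temperature = -0.35, resp_rate = 0.10, spo2 = -0.08,
    sbp = -0.012, gcs = -0.15)
}

#' Specify a synthetic two-group sepsis cohort
#'
#' The generative model: covariates are drawn from Table-1-like marginal
#' distributions, latent standard-normal HRnV-style features are drawn
#' independently, and the binary 30-day in-hospital mortality outcome follows
#' a logistic model whose intercept is calibrated so the expected prevalence
#' equals `prevalence`. Group contrasts (e.g. the dead being older) emerge by
#' conditioning on the outcome, as in the observational study design.
#'
#' @param n_patients Cohort size (>= 20). Default 342.
#' @param prevalence Target outcome prevalence in (0, 1). Default 0.19.
#' @param n_features Number of latent feature columns (`feat_01`, ...).
#' @param feature_effects Named log-odds ratios (per SD) for the latent
#'   features; names must be a subset of the feature columns. The default
#'   plants an effect of 0.7 on the first five features and zero elsewhere.
#' @param covariates Named list of marginal samplers `function(n)`.
#' @param covariate_effects Named per-unit log-odds ratios for covariates.
#' @param feature_mode `"direct"` samples the latent features as the feature
#'   block (fast; used by model-pipeline tests); `"tachogram"` additionally
#'   generates one five-minute IPFM tachogram per patient, with HF modulation
#'   driven by the first latent feature, and computes the full HRV/HRnV
#'   parameter block from it (slow; exercises the whole measurement path).
#' @param seed Integer seed.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_patients = 342, prevalence = 0.19,
                        n_features = 25,
                        feature_effects = NULL,
                        covariates = default_cohort_covariates(),
                        covariate_effects = default_covariate_effects(),
                        feature_mode = c("direct", "tachogram"),
                        seed = 1L) {
  stopifnot_scalar_num(n_patients, "n_patients", 20, Inf)
  stopifnot_scalar_num(prevalence, "prevalence", 0, 1, strict = TRUE)
  stopifnot_scalar_num(n_features, "n_features", 0, Inf)
  feature_mode <- match.arg(feature_mode)
  feat_names <- if (n_features > 0) sprintf("feat_%02d", seq_len(n_features)) else character(0)
  if (is.null(feature_effects)) {
    feature_effects <- stats::setNames(rep(0, n_features), feat_names)
    if (n_features >= 5) feature_effects[1:5] <- 0.7
  }
  if (length(feature_effects) && is.null(names(feature_effects))) {
    stop("`feature_effects` must be named", call. = FALSE)
  }
  bad <- setdiff(names(feature_effects), feat_names)
  if (length(bad)) {
    stop("feature_effects name(s) not in the feature schema: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(names(covariate_effects), names(covariates))
  if (length(bad)) {
    stop("covariate_effects name(s) not in the covariate schema: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 n_features = as.integer(n_features),
                 feature_names = feat_names,
                 feature_effects = feature_effects,
                 covariates = covariates,
                 covariate_effects = covariate_effects,
                 feature_mode = feature_mode, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' @param spec A [cohort_spec()].
#' @param max_retries Bounded number of outcome redraws if a draw is
#'   degenerate (single-class); exceeded => error.
#' @return A data.frame with columns `id`, `outcome` (0/1), the covariates,
#'   and the feature block; attribute `"spec"` carries the generating spec.
#' @export
generate_cohort <- function(spec, max_retries = 100L) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  local_seed(spec$seed, {
    cov_df <- as.data.frame(lapply(spec$covariates, function(f) f(n)))
    Z <- matrix(stats::rnorm(n * spec$n_features), n, spec$n_features,
                dimnames = list(NULL, spec$feature_names))
    lp <- rep(0, n)
    if (length(spec$covariate_effects)) {
      Xc <- as.matrix(cov_df[, names(spec$covariate_effects), drop = FALSE])
      # centre covariates so the intercept calibration is well-conditioned
      Xc <- scale(Xc, scale = FALSE)
      lp <- lp + drop(Xc %*% spec$covariate_effects)
    }
    if (length(spec$feature_effects)) {
      lp <- lp + drop(Z[, names(spec$feature_effects), drop = FALSE] %*%
                        spec$feature_effects)
    }
    # intercept such that the expected prevalence matches the spec
    a <- stats::uniroot(function(a) mean(stats::plogis(a + lp)) - spec$prevalence,
                        c(-30, 30))$root
    p <- stats::plogis(a + lp)
    y <- stats::rbinom(n, 1, p)
    tries <- 0L
    while (length(unique(y)) < 2L) {
      tries <- tries + 1L
      if (tries > max_retries) {
        stop("degenerate outcome draw (single class) after ", max_retries,
             " retries; increase n_patients or prevalence", call. = FALSE)
      }
      y <- stats::rbinom(n, 1, p)
    }
    out <- cbind(data.frame(id = sprintf("P%05d", seq_len(n)), outcome = y),
                 cov_df, as.data.frame(Z))
    if (spec$feature_mode == "tachogram") {
      feats <- do.call(rbind, lapply(seq_len(n), function(i) {
        ts <- tachogram_spec(
          duration_s = 300,
          mean_hr = min(max(out$heart_rate[i], 40), 180),
          lf_amp = 0.04,
          hf_amp = 0.03 * exp(0.5 * Z[i, 1]),
          noise_sd = 4,
          seed = child_seed(spec$seed, i)
        )
        hrnv_feature_row(generate_rri(ts))
      }))
      out <- cbind(out, feats)
    }
    structure(out, spec = spec)
  })
}
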