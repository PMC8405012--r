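# The HRV / HRnV parameter suite: time domain, Lomb-Scargle frequency domain,
# and nonlinear measures, computed on any RRI / RRnI / RRnIm sequence.
# The novel NN50n / pNN50n measures use a 50 * n ms threshold on combined
# sequences (n > 1) in place of the classical 50 ms.

as_rrni_values <- function(seq) {
  if (inherits(seq, "rrni_sequence")) seq$values
  else if (inherits(seq, "rri_sequence")) seq$intervals
  else as.numeric(seq)
}

rrni_n <- function(seq) if (inherits(seq, "rrni_sequence")) seq$config$n else 1L

#' Time-domain parameters
#'
#' Mean NN, SDNN, mean/SD heart rate (of the combined interval, so mean HR of
#' an (n, n) set is the single-beat rate divided by n), RMSSD, skewness,
#' kurtosis, NN50/pNN50 and -- for combined sequences with n > 1 -- NN50n /
#' pNN50n, whose threshold scales to 50 * n ms. pNN50 and pNN50n use the
#' number of successive differences as denominator (configurable).
#'
#' @param seq An `"rrni_sequence"` (or numeric vector treated as n = 1).
#' @param pnn_denominator `"differences"` (default) or `"elements"`.
#' @return Named list of time-domain fields; `nn50n`/`pnn50n` are `NA` when
#'   n = 1, where they are undefined.
#' @export
time_domain <- function(seq, pnn_denominator = c("differences", "elements")) {
  x <- as_rrni_values(seq)
  n <- rrni_n(seq)
  pnn_denominator <- match.arg(pnn_denominator)
  if (length(x) < 2) stop("need at least 2 elements", call. = FALSE)
  d <- diff(x)
  denom <- if (pnn_denominator == "differences") length(d) else length(x)
  m2 <- mean((x - mean(x))^2)
  nn50 <- sum(abs(d) > 50)
  out <- list(
    mean_nn = mean(x),
    sdnn = stats::sd(x),
    mean_hr = mean(60000 / x),
    sd_hr = stats::sd(60000 / x),
    rmssd = sqrt(mean(d^2)),
    skewness = if (m2 > 0) mean((x - mean(x))^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean((x - mean(x))^4) / m2^2 else NA_real_,
    nn50 = nn50,
    pnn50 = 100 * nn50 / denom,
    nn50n = NA_real_,
    pnn50n = NA_real_
  )
  if (n > 1L) {
    nn50n <- sum(abs(d) > 50 * n)
    out$nn50n <- nn50n
    out$pnn50n <- 100 * nn50n / denom
  }
  out
}

#' HRV triangular index
#'
#' Total element count divided by the modal bin count of the interval
#' histogram. The default bin width is 7.8125 ms (1/128 s), the conventional
#' discretisation; it is kept fixed across n and is configurable.
#'
#' @param seq Sequence or numeric vector.
#' @param bin_width Histogram bin width in ms.
#' @return The triangular index (>= 1; exactly 1 for a constant sequence).
#' @export
triangular_index <- function(seq, bin_width = 7.8125) {
  x <- as_rrni_values(seq)
  if (length(x) < 2) stop("need at least 2 elements", call. = FALSE)
  bins <- floor(x / bin_width)
  length(x) / max(table(bins))
}

#' Spectral band definition
#'
#' Contiguous, non-overlapping `[low, high)` bands in Hz. Defaults follow the
#' short-recording convention: VLF 0.0033-0.04, LF 0.04-0.15, HF 0.15-0.4.
#' The same absolute bands are applied to every n.
#'
#' @param vlf,lf,hf Numeric length-2 band edges in Hz.
#' @return An object of class `"spectral_bands"`.
#' @export
spectral_bands <- function(vlf = c(0.0033, 0.04), lf = c(0.04, 0.15),
                           hf = c(0.15, 0.4)) {
  b <- rbind(vlf, lf, hf)
  if (any(diff(as.vector(t(b))) < 0)) {
    stop("bands must be increasing, contiguous or non-overlapping", call. = FALSE)
  }
  structure(list(vlf = vlf, lf = lf, hf = hf), class = "spectral_bands")
}

#' Lomb-Scargle periodogram
#'
#' Classical Lomb-Scargle normalised so that summing ordinates times
#' `2 / (N * ofac)` over the positive frequencies approximates the series
#' variance (Parseval), giving band powers in ms^2 when the input is in ms.
#'
#' @param times Sample times in seconds (unevenly spaced allowed).
#' @param values Series values (mean is removed internally).
#' @param freqs Frequencies in Hz at which to evaluate.
#' @return Data frame with `freq` and raw ordinate `power`.
#' @export
lomb_scargle <- function(times, values, freqs) {
  x <- values - mean(values)
  vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * times)), sum(cos(2 * w * times))) / (2 * w)
    ct <- cos(w * (times - tau)); st <- sin(w * (times - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1)) -> p
  data.frame(freq = freqs, power = p)
}

#' Frequency-domain parameters
#'
#' Lomb-Scargle periodogram of the (unevenly spaced) sequence on its own time
#' axis, integrated over the VLF / LF / HF bands. Total power is the sum of
#' the three band integrals; normalised units divide LF and HF by their sum.
#'
#' @param seq An `"rrni_sequence"` (needs its time axis) or an
#'   [rri_sequence()].
#' @param bands A [spectral_bands()].
#' @param ofac Frequency oversampling factor (default 4).
#' @return Named list: `total_power`, `vlf_power`, `lf_power`, `hf_power`
#'   (ms^2), `lf_norm`, `hf_norm` (normalised units summing to 100), `lf_hf`,
#'   plus a `flag` (`NA` or `"lf_hf_undefined"` when LF + HF = 0).
#' @export
frequency_domain <- function(seq, bands = spectral_bands(), ofac = 4) {
  if (inherits(seq, "rri_sequence")) {
    times <- seq$onset_times / 1000
    x <- seq$intervals
  } else if (inherits(seq, "rrni_sequence")) {
    times <- seq$times / 1000
    x <- seq$values
  } else {
    stop("`seq` must carry a time axis (rri_sequence or rrni_sequence)",
         call. = FALSE)
  }
  if (length(x) < 8) stop("need at least 8 elements", call. = FALSE)
  span <- max(times) - min(times)
  df <- 1 / (span * ofac)
  f_hi <- bands$hf[2]
  freqs <- seq(df, f_hi, by = df)
  pg <- lomb_scargle(times, x, freqs)
  scale <- 2 / (length(x) * ofac)
  band_power <- function(edges) {
    sel <- pg$freq >= edges[1] & pg$freq < edges[2]
    sum(pg$power[sel]) * scale
  }
  vlf <- band_power(bands$vlf)
  lf <- band_power(bands$lf)
  hf <- band_power(bands$hf)
  flag <- NA_character_
  if (lf + hf > 0) {
    lf_norm <- 100 * lf / (lf + hf)
    hf_norm <- 100 * hf / (lf + hf)
    lf_hf <- lf / hf
  } else {
    lf_norm <- hf_norm <- lf_hf <- NA_real_
    flag <- "lf_hf_undefined"
  }
  list(total_power = vlf + lf + hf, vlf_power = vlf, lf_power = lf,
       hf_power = hf, lf_norm = lf_norm, hf_norm = hf_norm, lf_hf = lf_hf,
       flag = flag)
}

#' Poincare plot dispersions
#'
#' Short- and long-axis dispersions of the lag-1 return map. SD1 is defined
#' through the definition-level identity SD1 = RMSSD / sqrt(2) (root mean
#' square of successive differences, no mean subtraction); SD2 is the sample
#' standard deviation of `(x[i+1] + x[i]) / sqrt(2)`.
#'
#' @param seq Sequence or numeric vector (>= 3 elements).
#' @return Named list `sd1`, `sd2`, `sd1_sd2` (`NA` with flag `"degenerate"`
#'   for a constant sequence).
#' @export
poincare <- function(seq) {
  x <- as_rrni_values(seq)
  if (length(x) < 3) stop("need at least 3 elements", call. = FALSE)
  d <- diff(x)
  s <- x[-length(x)] + x[-1]
  sd1 <- sqrt(mean(d^2)) / sqrt(2)
  sd2 <- stats::sd(s / sqrt(2))
  flag <- NA_character_
  ratio <- if (sd2 > 0) sd1 / sd2 else { flag <- "degenerate"; NA_real_ }
  list(sd1 = sd1, sd2 = sd2, sd1_sd2 = ratio, flag = flag)
}

# Chebyshev-distance template match counts used by both entropies.
# Returns an N-m+1 square logical-count matrix helper via pairwise max-abs
# differences of m-length templates.
template_dist <- function(x, m) {
  n <- length(x)
  nt <- n - m + 1L
  D <- abs(outer(x, x, "-"))
  M <- D[seq_len(nt), seq_len(nt), drop = FALSE]
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      M <- pmax(M, D[seq_len(nt) + k, seq_len(nt) + k, drop = FALSE])
    }
  }
  M
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts pairs of `embed_dim`-length templates within
#' tolerance (Chebyshev distance, self-matches excluded) and `A` the same for
#' length `embed_dim + 1`. Short combined sequences can yield `A = 0`; the
#' blow-up is reported as a fixed large sentinel (1000) with a degeneracy
#' flag rather than an error, mirroring the behaviour observed when the
#' measure is applied to five-minute HR2V/HR3V sequences with too few points.
#'
#' @param seq Sequence or numeric vector.
#' @param embed_dim Template length m (default 2).
#' @param tolerance_frac Tolerance as a fraction of the SD (default 0.2).
#' @return List `value`, `flag` (`NA`, `"degenerate"` or `"sd_zero"`).
#' @export
sample_entropy <- function(seq, embed_dim = 2L, tolerance_frac = 0.2) {
  x <- as_rrni_values(seq)
  m <- as.integer(embed_dim)
  if (length(x) < m + 2L) stop("need at least embed_dim + 2 elements", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) return(list(value = NA_real_, flag = "sd_zero"))
  r <- tolerance_frac * s
  count_pairs <- function(mm) {
    M <- template_dist(x, mm)
    # common template horizon N - m templates for both lengths keeps the
    # standard estimator: use first n - m rows/cols for the m-templates
    nt <- length(x) - m
    M <- M[seq_len(nt), seq_len(nt), drop = FALSE]
    (sum(M <= r) - nt) / 2
  }
  B <- count_pairs(m)
  M1 <- template_dist(x, m + 1L)
  A <- (sum(M1 <= r) - nrow(M1)) / 2
  if (A == 0 || B == 0) {
    return(list(value = 1000, flag = "degenerate"))
  }
  list(value = -log(A / B), flag = NA_character_)
}

#' Approximate entropy
#'
#' `Phi(m) - Phi(m+1)` with self-matches included,
#' `Phi(m) = mean_i log C_i^m(r)`. Exactly 0 for a constant sequence.
#'
#' @inheritParams sample_entropy
#' @return List `value`, `flag`.
#' @export
approximate_entropy <- function(seq, embed_dim = 2L, tolerance_frac = 0.2) {
  x <- as_rrni_values(seq)
  m <- as.integer(embed_dim)
  if (length(x) < m + 2L) stop("need at least embed_dim + 2 elements", call. = FALSE)
  s <- stats::sd(x)
  r <- tolerance_frac * s
  phi <- function(mm) {
    M <- template_dist(x, mm)
    mean(log(rowSums(M <= r) / nrow(M)))
  }
  list(value = phi(m) - phi(m + 1L), flag = NA_character_)
}

#' Detrended fluctuation analysis
#'
#' Integrates the mean-centred series, splits it into non-overlapping boxes of
#' each size, removes a least-squares linear trend per box, and regresses log
#' RMS fluctuation on log box size. `dfa_a1` uses the short scales (default
#' 4-16 elements), `dfa_a2` the long scales (default 16-64); an exponent is
#' flagged missing when fewer than 3 of its scales admit at least 2 boxes.
#'
#' @param seq Sequence or numeric vector.
#' @param short_scales,long_scales Integer box-size ranges.
#' @return List `dfa_a1`, `dfa_a2`, `flag`.
#' @export
dfa <- function(seq, short_scales = 4:16, long_scales = 16:64) {
  x <- as_rrni_values(seq)
  n <- length(x)
  y <- cumsum(x - mean(x))
  fluct <- function(s) {
    nb <- n %/% s
    if (nb < 2) return(NA_real_)
    t <- seq_len(s)
    sxx <- sum((t - mean(t))^2)
    res2 <- 0
    for (b in seq_len(nb)) {
      yy <- y[((b - 1) * s + 1):(b * s)]
      beta <- sum((t - mean(t)) * (yy - mean(yy))) / sxx
      res2 <- res2 + sum((yy - mean(yy) - beta * (t - mean(t)))^2)
    }
    sqrt(res2 / (nb * s))
  }
  alpha <- function(scales) {
    Fs <- vapply(scales, fluct, numeric(1))
    ok <- is.finite(Fs) & Fs > 0
    if (sum(ok) < 3) return(NA_real_)
    stats::coef(stats::lm(log(Fs[ok]) ~ log(scales[ok])))[[2]]
  }
  a1 <- alpha(short_scales)
  a2 <- alpha(long_scales)
  flag <- if (is.na(a2)) "a2_missing" else NA_character_
  list(dfa_a1 = a1, dfa_a2 = a2, flag = flag)
}

param_names <- c("mean_nn", "sdnn", "mean_hr", "sd_hr", "rmssd", "skewness",
                 "kurtosis", "triangular_index", "nn50", "pnn50", "nn50n",
                 "pnn50n", "total_power", "vlf_power", "lf_power", "hf_power",
                 "lf_norm", "hf_norm", "lf_hf", "sd1", "sd2", "sd1_sd2",
                 "sampen", "apen", "dfa_a1", "dfa_a2")

#' Compute one full parameter vector for a combined sequence
#'
#' @param seq An `"rrni_sequence"`.
#' @param bands A [spectral_bands()].
#' @return One-row data.frame with the 26 parameter columns and a `flags`
#'   column collecting per-parameter quality flags (`""` if none). Parameters
#'   whose preconditions fail are `NA` and flagged, never an error.
#' @export
parameter_vector <- function(seq, bands = spectral_bands()) {
  out <- stats::setNames(as.list(rep(NA_real_, length(param_names))),
                         param_names)
  flags <- character(0)
  try_block <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      flags <<- c(flags, paste0(tag, ":", conditionMessage(e)))
      NULL
    })
  }
  td <- try_block("time_domain", time_domain(seq))
  if (!is.null(td)) out[names(td)] <- td
  ti <- try_block("triangular_index", triangular_index(seq))
  if (!is.null(ti)) out$triangular_index <- ti
  fd <- try_block("frequency_domain", frequency_domain(seq, bands))
  if (!is.null(fd)) {
    if (!is.na(fd$flag)) flags <- c(flags, fd$flag)
    out[setdiff(names(fd), "flag")] <- fd[setdiff(names(fd), "flag")]
  }
  pc <- try_block("poincare", poincare(seq))
  if (!is.null(pc)) {
    if (!is.na(pc$flag)) flags <- c(flags, paste0("poincare:", pc$flag))
    out[c("sd1", "sd2", "sd1_sd2")] <- pc[c("sd1", "sd2", "sd1_sd2")]
  }
  se <- try_block("sampen", sample_entropy(seq))
  if (!is.null(se)) {
    if (!is.na(se$flag)) flags <- c(flags, paste0("sampen:", se$flag))
    out$sampen <- se$value
  }
  ae <- try_block("apen", approximate_entropy(seq))
  if (!is.null(ae)) out$apen <- ae$value
  df_ <- try_block("dfa", dfa(seq))
  if (!is.null(df_)) {
    if (!is.na(df_$flag)) flags <- c(flags, paste0("dfa:", df_$flag))
    out$dfa_a1 <- df_$dfa_a1
    out$dfa_a2 <- df_$dfa_a2
  }
  res <- as.data.frame(out)
  res$flags <- paste(flags, collapse = ";")
  res
}

#' Compute every HRV / HRnV parameter set for a tachogram
#'
#' Builds each combined-interval configuration up to `n_max` and computes the
#' full parameter vector for each; `n_max = 3` gives the study's six sets
#' (HRV, HR2V1, HR2V, HR3V1, HR3V2, HR3V). Deterministic: identical input
#' gives bit-identical output.
#'
#' @param rri An [rri_sequence()].
#' @param n_max Upper limit of n (default 3).
#' @param bands A [spectral_bands()].
#' @return Data frame with one row per configuration: `label`, `n`, `m`, the
#'   26 parameter columns and `flags`.
#' @export
compute_all <- function(rri, n_max = 3L, bands = spectral_bands()) {
  stopifnot(inherits(rri, "rri_sequence"))
  configs <- enumerate_configs(n_max)
  rows <- lapply(configs, function(cfg) {
    pv <- parameter_vector(build_rrni(rri, cfg), bands)
    cbind(data.frame(label = cfg$label, n = cfg$n, m = cfg$m), pv)
  })
  do.call(rbind, rows)
}

#' Flatten a tachogram's parameter table to one wide feature row
#'
#' Column names are `<LABEL>_<param>`, e.g. `HR2V1_rmssd`; the undefined
#' `nn50n`/`pnn50n` of the n = 1 set are dropped.
#'
#' @inheritParams compute_all
#' @return One-row data.frame of numeric features.
#' @export
hrnv_feature_row <- function(rri, n_max = 3L, bands = spectral_bands()) {
  tab <- compute_all(rri, n_max, bands)
  cols <- lapply(seq_len(nrow(tab)), function(i) {
    keep <- param_names
    if (tab$n[i] == 1L) keep <- setdiff(keep, c("nn50n", "pnn50n"))
    vals <- as.list(tab[i, keep])
    names(vals) <- paste(tab$label[i], keep, sep = "_")
    vals
  })
  as.data.frame(do.call(c, cols))
}
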