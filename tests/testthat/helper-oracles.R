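# Independent brute-force oracles. These deliberately use explicit loops and
# naive formulations so they share no code path with the implementation.

# explicit window-sum loop for RRnI / RRnIm construction
oracle_window_sums <- function(x, n, m) {
  out <- numeric(0)
  start <- 1
  while (start + n - 1 <= length(x)) {
    s <- 0
    for (j in start:(start + n - 1)) s <- s + x[j]
    out <- c(out, s)
    start <- start + m
  }
  out
}

# O(n^2) template-counting sample entropy
oracle_sampen <- function(x, m = 2, r = 0.2 * sd(x)) {
  N <- length(x)
  count <- function(len) {
    tot <- 0
    for (i in 1:(N - m)) {
      for (j in 1:(N - m)) {
        if (i == j) next
        dmax <- 0
        for (k in 0:(len - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
        if (dmax <= r) tot <- tot + 1
      }
    }
    tot / 2
  }
  B <- count(m); A <- count(m + 1)
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# direct Phi(m) - Phi(m+1) approximate entropy with self-matches
oracle_apen <- function(x, m = 2, r = 0.2 * sd(x)) {
  N <- length(x)
  phi <- function(len) {
    nt <- N - len + 1
    tot <- 0
    for (i in 1:nt) {
      c_i <- 0
      for (j in 1:nt) {
        dmax <- 0
        for (k in 0:(len - 1)) dmax <- max(dmax, abs(x[i + k] - x[j + k]))
        if (dmax <= r) c_i <- c_i + 1
      }
      tot <- tot + log(c_i / nt)
    }
    tot / nt
  }
  phi(m) - phi(m + 1)
}

# DFA fluctuation via lm() per box; slope via lm on log-log
oracle_dfa_alpha <- function(x, scales) {
  y <- cumsum(x - mean(x))
  Fs <- sapply(scales, function(s) {
    nb <- floor(length(y) / s)
    if (nb < 2) return(NA_real_)
    res2 <- 0
    for (b in 1:nb) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      t <- 1:s
      fit <- lm(seg ~ t)
      res2 <- res2 + sum(resid(fit)^2)
    }
    sqrt(res2 / (nb * s))
  })
  ok <- is.finite(Fs) & Fs > 0
  unname(coef(lm(log(Fs[ok]) ~ log(scales[ok])))[2])
}

# DFT periodogram of the tachogram resampled to an even grid; returns the
# frequencies of local power maxima in (f_lo, f_hi)
oracle_spectral_peaks <- function(rri, f_lo = 0.02, f_hi = 0.45, fs = 4) {
  t <- rri$onset_times / 1000
  g <- seq(min(t), max(t), by = 1 / fs)
  x <- approx(t, rri$intervals, xout = g)$y
  x <- x - mean(x)
  p <- Mod(fft(x))^2
  f <- (seq_along(p) - 1) * fs / length(p)
  keep <- f > f_lo & f < f_hi
  f <- f[keep]; p <- p[keep]
  locmax <- which(p > c(-Inf, p[-length(p)]) & p > c(p[-1], -Inf))
  locmax <- locmax[order(p[locmax], decreasing = TRUE)]
  f[locmax]
}

# textbook Yates-corrected chi-square: n (|ad - bc| - n/2)^2 / (r1 r2 c1 c2)
oracle_yates_stat <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  num <- max(abs(a * d - b * c) - n / 2, 0)
  n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

random_rri <- function(n = 50, seed = 1) {
  set.seed(seed)
  rri_sequence(runif(n, 600, 1100))
}
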