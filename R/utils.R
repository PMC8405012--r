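# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the generator, runs `expr`, then restores whatever global RNG state
#' existed before the call, so seeded package functions never perturb the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a user seed; kept below 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + stream * 7919) %% 2147483647
}

stopifnot_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                                 strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok) {
    stop(sprintf("`%s` = %g is outside its valid range (%g, %g)",
                 name, x, lower, upper), call. = FALSE)
  }
  invisible(x)
}

# Moving average with a centred window; edges use partial windows.
running_mean <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  cs <- c(0, cumsum(x))
  half <- width %/% 2L
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

fmt_p <- function(p) {
  ifelse(p < 0.0005, "<0.001", sprintf("%.3f", p))
}
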