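#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, the convention used in
#' the printed epidemiological tables this package reproduces (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` places, ties away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate that a numeric vector is a probability vector.
check_prob_vector <- function(p, name, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop(sprintf("'%s' must be a vector of non-negative probabilities", name),
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("'%s' must sum to 1 (got %.15g)", name, sum(p)),
         call. = FALSE)
  }
  invisible(p)
}

# Normalise percentages printed in a table to a probability vector.
as_prob <- function(p) p / sum(p)

# Draw from an inverse-gamma distribution with shape a and scale (rate) b.
rinvgamma1 <- function(a, b) 1 / stats::rgamma(1L, shape = a, rate = b)

# One-dimensional slice sampler (Neal 2003, stepping out + shrinkage) on an
# unnormalised log density. Used for variance updates on the log scale.
slice_sample1 <- function(logf, x0, w = 1, max_steps = 50L) {
  f0 <- logf(x0)
  if (!is.finite(f0)) stop("slice sampler started at zero density", call. = FALSE)
  z <- f0 - stats::rexp(1L)
  lo <- x0 - w * stats::runif(1L)
  hi <- lo + w
  j <- floor(max_steps * stats::runif(1L))
  k <- max_steps - 1L - j
  while (j > 0L && logf(lo) > z) { lo <- lo - w; j <- j - 1L }
  while (k > 0L && logf(hi) > z) { hi <- hi + w; k <- k - 1L }
  repeat {
    x1 <- lo + stats::runif(1L) * (hi - lo)
    if (logf(x1) > z) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

# Integer group index with stable level order of first appearance.
group_index <- function(ids) {
  f <- match(ids, unique(ids))
  structure(f, levels = unique(ids))
}
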