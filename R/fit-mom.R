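#' Method-of-moments fit of the nested model
#'
#' Henderson-type moment estimation of the variance components from OLS
#' residuals grouped by level (the classical unbalanced nested-ANOVA
#' moment equations), followed by feasible GLS for the fixed effects at
#' those components. Serves as the deterministic starting value for the
#' Gibbs sampler, in the role restricted/iterative GLS plays in the
#' multilevel-software lineage this package follows.
#'
#' Negative moment estimates are floored at `1e-8 * var(y)` (not zero) so
#' that a subsequent MCMC run can move away from the boundary.
#'
#' @param cohort cohort data frame.
#' @param spec a [model_spec()].
#' @return an object of class `"nested_lmm"` with `method = "mom"`:
#'   fixed-effect estimates and GLS standard errors, variance components
#'   (moment SEs are not computed, `se = NA`), and the marginal deviance
#'   at the estimates.
#' @examples
#' coh <- sample_cohort(synth_config(n_countries = 8, n_mothers = 400), seed = 1)
#' fit_mom(coh, model_spec(1))
#' @export
fit_mom <- function(cohort, spec) {
  prep <- prepare_nested(cohort, spec)
  X <- prep$X
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("singular design; collinear terms: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r <- qr.resid(qrX, prep$y)
  floor_at <- 1e-8 * stats::var(prep$y)
  s2 <- moment_components(r, prep, floor_at)
  g <- gls_fixed(prep, s2[["mcb"]] %na0%0, s2[["m"]] %na0%0, s2[["b"]])
  fixed <- data.frame(term = colnames(X), estimate = unname(g$beta),
                      se = sqrt(diag(g$cov)), stringsAsFactors = FALSE)
  vc <- variance_components(s2[["mcb"]], s2[["m"]], s2[["b"]])
  dev <- deviance_from_prep(prep, g$beta, vc$sigma2)
  new_nested_lmm(spec = spec, fixed = fixed, variances = vc,
                 deviance_bar = dev, pD = NA_real_, dic = NA_real_,
                 chains = NULL, method = "mom", prep = prep)
}

`%na0%` <- function(a, b) if (is.na(a)) b else a

# Unbalanced nested / one-way ANOVA moment equations on residuals.
moment_components <- function(r, prep, floor_at) {
  n <- prep$n
  out <- c(mcb = NA_real_, m = NA_real_, b = NA_real_)
  if (prep$use_c && prep$use_m) {
    mi <- prep$mi; ci <- prep$ci
    n_m <- prep$n_m; n_c <- prep$n_c; cm <- prep$cm
    M <- length(n_m); C <- length(n_c)
    mbar <- as.numeric(rowsum(r, mi, reorder = FALSE)) / n_m
    cbar <- as.numeric(rowsum(r, ci, reorder = FALSE)) / n_c
    gbar <- mean(r)
    ss_b <- sum((r - mbar[mi])^2)
    ss_m <- sum(n_m * (mbar - cbar[cm])^2)
    ss_c <- sum(n_c * (cbar - gbar)^2)
    sum_nm2 <- sum(n_m^2)
    sum_nm2_by_c <- sum(as.numeric(rowsum(n_m^2, cm, reorder = FALSE)) / n_c)
    s2b <- ss_b / (n - M)
    k1 <- n - sum_nm2_by_c
    s2m <- (ss_m - (M - C) * s2b) / k1
    k2 <- sum_nm2_by_c - sum_nm2 / n
    k3 <- n - sum(n_c^2) / n
    s2c <- (ss_c - (C - 1) * s2b - k2 * s2m) / k3
    out[] <- c(s2c, s2m, s2b)
  } else {
    # single clustering level: country-only or mother-only
    gi <- if (prep$use_c) prep$ci else prep$mi
    n_g <- if (prep$use_c) prep$n_c else prep$n_m
    G <- length(n_g)
    gbar_g <- as.numeric(rowsum(r, gi, reorder = FALSE)) / n_g
    ss_w <- sum((r - gbar_g[gi])^2)
    ss_b <- sum(n_g * (gbar_g - mean(r))^2)
    s2b <- ss_w / (n - G)
    s2g <- (ss_b - (G - 1) * s2b) / (n - sum(n_g^2) / n)
    out["b"] <- s2b
    if (prep$use_c) out["mcb"] <- s2g else out["m"] <- s2g
  }
  pmax_floor <- function(x) if (!is.na(x) && x < floor_at) floor_at else x
  out["b"] <- max(out[["b"]], floor_at)
  out["mcb"] <- pmax_floor(out[["mcb"]])
  out["m"] <- pmax_floor(out[["m"]])
  out
}
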