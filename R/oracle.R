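#' Dense-covariance maximum-likelihood oracle
#'
#' Maximises the exact multivariate-normal log-likelihood of the nested
#' model with an explicitly assembled dense covariance
#' `s2_mcb Zc Zc' + s2_m Zm Zm' + s2_b I`, profiling the fixed effects out
#' by GLS and optimising the (log) variance components numerically. A
#' brute-force cross-check for the production fitters; limited to small
#' problems (`nrow <= 500`) because the covariance is dense.
#'
#' @param cohort cohort data frame (<= 500 rows).
#' @param spec a [model_spec()].
#' @return an object of class `"nested_lmm"` with `method = "oracle"`:
#'   maximum-likelihood variance components, GLS fixed effects at the
#'   optimum, and the deviance at the optimum.
#' @export
oracle_direct <- function(cohort, spec) {
  if (nrow(cohort) > 500L) {
    stop("oracle_direct is limited to 500 rows (dense covariance)",
         call. = FALSE)
  }
  prep <- prepare_nested(cohort, spec)
  n <- prep$n
  X <- prep$X
  y <- prep$y
  Zc <- outer(prep$ci, seq_along(prep$n_c), "==") * 1
  Zm <- outer(prep$mi, seq_along(prep$n_m), "==") * 1
  use_c <- prep$use_c; use_m <- prep$use_m

  negll <- function(logs2) {
    i <- 1L
    s2c <- if (use_c) exp(logs2[i]) else 0
    if (use_c) i <- i + 1L
    s2m <- if (use_m) exp(logs2[i]) else 0
    if (use_m) i <- i + 1L
    s2b <- exp(logs2[i])
    V <- diag(s2b, n)
    if (use_c) V <- V + s2c * tcrossprod(Zc)
    if (use_m) V <- V + s2m * tcrossprod(Zm)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    Xi <- backsolve(R, X, transpose = TRUE)
    yi <- backsolve(R, y, transpose = TRUE)
    beta <- qr.coef(qr(Xi), yi)
    r <- yi - Xi %*% beta
    0.5 * (n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(r^2))
  }

  start_fit <- fit_mom(cohort, spec)
  s2s <- start_fit$variances$sigma2
  theta0 <- log(c(if (use_c) max(s2s[["mcb"]], 1e-6),
                  if (use_m) max(s2s[["m"]], 1e-6),
                  s2s[["b"]]))
  opt <- stats::optim(theta0, negll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  i <- 1L
  s2c <- if (use_c) exp(opt$par[i]) else NA_real_
  if (use_c) i <- i + 1L
  s2m <- if (use_m) exp(opt$par[i]) else NA_real_
  if (use_m) i <- i + 1L
  s2b <- exp(opt$par[i])
  g <- gls_fixed(prep, s2c %na0% 0, s2m %na0% 0, s2b)
  fixed <- data.frame(term = colnames(X), estimate = unname(g$beta),
                      se = sqrt(diag(g$cov)), stringsAsFactors = FALSE)
  vc <- variance_components(s2c, s2m, s2b)
  new_nested_lmm(spec = spec, fixed = fixed, variances = vc,
                 deviance_bar = 2 * opt$value, pD = NA_real_,
                 dic = NA_real_, chains = NULL, method = "oracle",
                 prep = prep)
}
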