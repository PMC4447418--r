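# Internal data preparation for the nested fits. Rows are sorted by
# (country, mother, baby) so that all estimates are invariant to input row
# order; group indices are dense integers in sorted-level order.
prepare_nested <- function(cohort, spec, ga_center = NULL) {
  need <- c("birthweight", "mother_id", "country_id")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  ord <- order(cohort$country_id, cohort$mother_id,
               if (!is.null(cohort$baby_id)) cohort$baby_id else seq_len(nrow(cohort)))
  cohort <- cohort[ord, , drop = FALSE]
  dm <- design_matrix(cohort, spec, ga_center = ga_center)

  use_c <- "country" %in% spec$random_levels
  use_m <- "mother" %in% spec$random_levels
  clev <- unique(cohort$country_id)
  mkey <- paste(cohort$country_id, cohort$mother_id, sep = "\r")
  mlev <- unique(mkey)
  ci <- match(cohort$country_id, clev)
  mi <- match(mkey, mlev)
  n_c <- tabulate(ci, length(clev))
  n_m <- tabulate(mi, length(mlev))
  cm <- ci[match(seq_along(mlev), mi)]   # country of each mother

  if (use_c && length(clev) < 2L) {
    stop("country random level requires >= 2 countries", call. = FALSE)
  }
  if (use_m && length(mlev) < 2L) {
    stop("mother random level requires >= 2 mothers", call. = FALSE)
  }
  list(y = as.numeric(cohort$birthweight), X = dm$X, terms = dm$terms,
       ga_center = dm$ga_center, ci = ci, mi = mi, n_c = n_c, n_m = n_m,
       cm = cm, country_levels = clev,
       mother_levels = cohort$mother_id[match(seq_along(mlev), mi)],
       use_c = use_c, use_m = use_m, n = nrow(cohort), cohort = cohort)
}

# Level-wise statistics for V = s2b I + s2m Zm Zm' + s2c Zc Zc' on the
# nested structure: returns the quadratic form r' V^-1 r, log|V|, and
# (optionally) V^-1 r, all in O(n) without forming V. Works column-wise
# on a matrix R. Absent levels are handled by s2c = 0 / s2m = 0.
nested_vstats <- function(R, prep, s2c, s2m, s2b, want_vinv = FALSE) {
  R <- as.matrix(R)
  mi <- prep$mi; ci <- prep$ci; n_m <- prep$n_m; cm <- prep$cm
  q <- ncol(R)
  Sm <- rowsum(R, mi, reorder = FALSE)                       # M x q
  w_m <- s2m / (s2b + n_m * s2m)                             # length M
  quad_a <- (colSums(R * R) - colSums(w_m * Sm * Sm)) / s2b
  logdet <- prep$n * log(s2b) + sum(log1p(n_m * s2m / s2b))

  # country step via Woodbury on A = s2b I + s2m Zm Zm'
  d_c <- (prep$n_c - as.numeric(rowsum(n_m^2 * w_m, cm, reorder = FALSE))) / s2b
  Sc <- rowsum(R, ci, reorder = FALSE)                       # K x q
  Tc <- (Sc - rowsum(n_m * w_m * Sm, cm, reorder = FALSE)) / s2b
  denom <- 1 + s2c * d_c
  alpha <- s2c * Tc / denom                                  # K x q
  quad <- quad_a - colSums(alpha * Tc)
  logdet <- logdet + sum(log(denom))

  out <- list(quad = quad, logdet = logdet)
  if (want_vinv) {
    Ainv <- (R - (w_m * Sm)[mi, , drop = FALSE]) / s2b
    a1 <- (1 - (w_m * n_m)[mi]) / s2b                        # A^-1 1 elementwise
    out$vinv <- Ainv - a1 * alpha[ci, , drop = FALSE]
  }
  out
}

#' Marginal deviance of a nested Gaussian model
#'
#' Exact -2 log marginal likelihood of a two- or three-level nested
#' random-intercept Gaussian model at given fixed effects and variance
#' components, computed level-wise in O(n) (no dense covariance matrix is
#' formed).
#'
#' @param cohort cohort data frame.
#' @param spec a [model_spec()].
#' @param fixed named numeric vector of fixed-effect coefficients, in the
#'   column order of [design_matrix()].
#' @param variances a [variance_components()] object or numeric vector
#'   `c(mcb, m, b)`; components of levels absent from `spec` are ignored.
#' @param ga_center gestational-age centering value, when the spec has a
#'   gestational-age term and the fit's value should be reused.
#' @return the deviance (scalar).
#' @export
nested_deviance <- function(cohort, spec, fixed, variances, ga_center = NULL) {
  prep <- prepare_nested(cohort, spec, ga_center = ga_center)
  s2 <- if (inherits(variances, "variance_components")) variances$sigma2
        else stats::setNames(as.numeric(variances), c("mcb", "m", "b"))
  deviance_from_prep(prep, fixed, s2)
}

deviance_from_prep <- function(prep, fixed, s2) {
  s2c <- if (prep$use_c) s2[["mcb"]] else 0
  s2m <- if (prep$use_m) s2[["m"]] else 0
  s2b <- s2[["b"]]
  if (!is.finite(s2b) || s2b <= 0) stop("sigma2_b must be > 0", call. = FALSE)
  if (is.na(s2c)) s2c <- 0
  if (is.na(s2m)) s2m <- 0
  r <- prep$y - as.numeric(prep$X %*% fixed)
  vs <- nested_vstats(r, prep, s2c, s2m, s2b)
  prep$n * log(2 * pi) + vs$logdet + vs$quad
}

# Feasible GLS of the fixed effects at given variance components.
# Returns coefficients and their GLS covariance.
gls_fixed <- function(prep, s2c, s2m, s2b) {
  X <- prep$X
  vs <- nested_vstats(cbind(prep$y, X), prep, s2c, s2m, s2b, want_vinv = TRUE)
  Vy <- vs$vinv[, 1L]
  VX <- vs$vinv[, -1L, drop = FALSE]
  XtVX <- crossprod(X, VX)
  XtVy <- crossprod(X, Vy)
  cov <- solve(XtVX)
  beta <- drop(cov %*% XtVy)
  names(beta) <- colnames(X)
  list(beta = beta, cov = cov)
}
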