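new_nested_lmm <- function(spec, fixed, variances, deviance_bar, pD, dic,
                           chains, method, prep, settings = NULL) {
  structure(list(
    spec = spec, fixed = fixed, variances = variances,
    deviance_bar = deviance_bar, pD = pD, dic = dic,
    chains = chains, method = method, settings = settings,
    ga_center = prep$ga_center,
    n = prep$n,
    n_countries = length(prep$n_c),
    n_mothers = length(prep$n_m),
    country_levels = prep$country_levels,
    country_sizes = prep$n_c,
    prep = prep,
    warnings = character(0)
  ), class = "nested_lmm")
}

#' Fit a nested random-intercept linear mixed model
#'
#' The front end of the package: fits a two- or three-level nested
#' Gaussian random-intercept model of birthweight (babies in mothers in
#' maternal countries of birth) by the blocked Gibbs sampler
#' ([fit_gibbs()]), started from the method-of-moments estimates
#' ([fit_mom()]); or returns the moment fit itself when `method = "mom"`.
#'
#' @param cohort cohort data frame with one row per baby; see
#'   [sample_cohort()] for the column layout.
#' @param spec a [model_spec()]; `model = 1` (the 'empty' model) by
#'   default.
#' @param method `"gibbs"` (posterior summaries via MCMC) or `"mom"`
#'   (moment estimates only).
#' @param settings an [mcmc_settings()], used when `method = "gibbs"`.
#' @param start optional starting fit for the sampler.
#' @return an object of class `"nested_lmm"` with `print()`, `summary()`,
#'   `coef()`, `residuals()`, `predict()`, `deviance()` and `plot()`
#'   methods.
#' @examples
#' coh <- sample_cohort(synth_config(n_countries = 8, n_mothers = 300), seed = 1)
#' fit <- nested_lmm(coh, model_spec(1),
#'                   settings = mcmc_settings(burn_in = 100, n_iter = 300))
#' summary(fit)
#' vpc(fit$variances)
#' @export
nested_lmm <- function(cohort, spec = model_spec(1),
                       method = c("gibbs", "mom"),
                       settings = mcmc_settings(), start = NULL) {
  method <- match.arg(method)
  if (method == "mom") return(fit_mom(cohort, spec))
  fit_gibbs(cohort, spec, settings = settings, start = start)
}

#' @export
print.nested_lmm <- function(x, ...) {
  cat(sprintf("Nested random-intercept linear model (%s fit)\n", x$method))
  cat(sprintf("  %d babies, %d mothers, %d countries; random levels: %s\n",
              x$n, x$n_mothers, x$n_countries,
              paste(x$spec$random_levels, collapse = ", ")))
  cat("  Fixed effects:\n")
  fx <- x$fixed
  est <- sprintf("    %-24s %8.1f (%.1f)", fx$term, fx$estimate, fx$se)
  cat(paste(utils::head(est, 12), collapse = "\n"), "\n")
  if (nrow(fx) > 12) cat(sprintf("    ... %d more terms\n", nrow(fx) - 12))
  s2 <- x$variances$sigma2
  cat("  Variance components (g^2):\n")
  for (lv in names(s2)) {
    if (!is.na(s2[[lv]])) cat(sprintf("    %-6s %12.1f\n", lv, s2[[lv]]))
  }
  if (!is.na(x$dic)) cat(sprintf("  DIC: %.1f (pD = %.1f)\n", x$dic, x$pD))
  invisible(x)
}

#' @export
summary.nested_lmm <- function(object, ...) {
  s2 <- object$variances$sigma2
  out <- list(fixed = object$fixed, variances = object$variances,
              vpc = round_half_up(vpc(object$variances), 1),
              icc = round_half_up(icc(object$variances), 1),
              deviance_bar = object$deviance_bar, pD = object$pD,
              dic = object$dic, method = object$method, n = object$n,
              n_mothers = object$n_mothers,
              n_countries = object$n_countries)
  class(out) <- "summary.nested_lmm"
  out
}

#' @export
print.summary.nested_lmm <- function(x, ...) {
  cat(sprintf("Nested model summary (%s): %d babies / %d mothers / %d countries\n",
              x$method, x$n, x$n_mothers, x$n_countries))
  cat("\nFixed effects (g):\n")
  print(x$fixed, digits = 4, row.names = FALSE)
  cat("\nVariance components (g^2):\n")
  print(x$variances$sigma2)
  cat("\nVPC (%):\n"); print(x$vpc)
  cat("ICC (%):\n"); print(x$icc)
  if (!is.na(x$dic)) cat(sprintf("\nDIC %.1f (deviance_bar %.1f, pD %.1f)\n",
                                 x$dic, x$deviance_bar, x$pD))
  invisible(x)
}

#' @export
coef.nested_lmm <- function(object, ...) {
  stats::setNames(object$fixed$estimate, object$fixed$term)
}

#' @export
deviance.nested_lmm <- function(object, ...) {
  if (object$method == "gibbs") object$deviance_bar else object$deviance_bar
}

#' Marginal residuals of a nested fit
#'
#' `y - X beta-hat`: residuals around the fixed-effect prediction, still
#' containing the country and mother effects (type `"marginal"`), or with
#' the posterior-mean country effects also removed (type `"country"`,
#' Gibbs fits only).
#'
#' @param object a `"nested_lmm"` fit.
#' @param type `"marginal"` or `"country"`.
#' @param ... unused.
#' @return numeric vector in the fit's internal (sorted) row order.
#' @export
residuals.nested_lmm <- function(object, type = c("marginal", "country"), ...) {
  type <- match.arg(type)
  prep <- object$prep
  r <- prep$y - as.numeric(prep$X %*% object$fixed$estimate)
  if (type == "country") {
    if (is.null(object$chains$v)) {
      stop("country-adjusted residuals need retained country chains",
           call. = FALSE)
    }
    r <- r - colMeans(object$chains$v)[prep$ci]
  }
  r
}

#' Fixed-effect predictions for new data
#'
#' Population-level (fixed effects only) predicted birthweight, using the
#' fit's gestational-age centering.
#'
#' @param object a `"nested_lmm"` fit.
#' @param newdata cohort-like data frame; defaults to the training data.
#' @param ... unused.
#' @return numeric vector of predictions in grams.
#' @export
predict.nested_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(as.numeric(object$prep$X %*% object$fixed$estimate))
  }
  dm <- design_matrix(newdata, object$spec, ga_center = object$ga_center)
  cols <- match(object$fixed$term, colnames(dm$X))
  if (anyNA(cols)) {
    stop("newdata lacks design columns: ",
         paste(object$fixed$term[is.na(cols)], collapse = ", "), call. = FALSE)
  }
  as.numeric(dm$X[, cols, drop = FALSE] %*% object$fixed$estimate)
}

#' Caterpillar plot of shrunken country effects
#'
#' Countries ordered by their shrunken deviation from the grand mean, with
#' 95% posterior intervals — the 'league table' view of the country level.
#'
#' @param x a `"nested_lmm"` Gibbs fit including the country level.
#' @param ... passed to [plot()].
#' @return the [country_effects()] table, invisibly.
#' @export
plot.nested_lmm <- function(x, ...) {
  eff <- country_effects(x)
  ord <- order(eff$effect)
  k <- nrow(eff)
  graphics::plot(seq_len(k), eff$effect[ord], pch = 16,
                 ylim = range(eff$lower, eff$upper),
                 xlab = "rank", ylab = "shrunken effect (g)", ...)
  graphics::segments(seq_len(k), eff$lower[ord], seq_len(k), eff$upper[ord])
  graphics::abline(h = 0, lty = 2)
  invisible(eff)
}
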