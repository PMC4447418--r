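#' Apply the self-contained inclusion filters
#'
#' Sequentially removes, in this fixed order: records with missing
#' maternal age (or missing birth order, when a `birth_order` column is
#' present); birthweight below 500 g; missing maternal country of birth;
#' gestational age outside 37-42 completed weeks; and finally — in one
#' pass after all row-level rules — all babies from countries with fewer
#' than 100 remaining observations.
#'
#' @param records raw cohort data frame, possibly with missing fields.
#' @param min_country_n minimum observations per country (default 100).
#' @return list with elements `cohort` (the filtered table, input order
#'   preserved) and `tally`, an `"exclusion_tally"` data frame of
#'   `(rule, removed)` rows with attribute `final_n`.
#' @examples
#' coh <- sample_cohort(synth_config(n_countries = 6, n_mothers = 300), seed = 1)
#' apply_inclusion_filters(coh)$tally
#' @export
apply_inclusion_filters <- function(records, min_country_n = 100L) {
  tally <- data.frame(rule = character(0), removed = integer(0),
                      stringsAsFactors = FALSE)
  keep <- records
  drop_rule <- function(name, bad) {
    tally <<- rbind(tally, data.frame(rule = name, removed = sum(bad),
                                      stringsAsFactors = FALSE))
    keep <<- keep[!bad, , drop = FALSE]
  }
  bad_age <- if (nrow(keep)) is.na(keep$age_cat) else logical(0)
  if (!is.null(keep$birth_order)) bad_age <- bad_age | is.na(keep$birth_order)
  drop_rule("missing_age_or_birth_order", bad_age)
  drop_rule("birthweight_below_500g",
            !is.na(keep$birthweight) & keep$birthweight < 500)
  drop_rule("missing_country",
            is.na(keep$country_id) | keep$country_id == "")
  drop_rule("gestational_age_outside_37_42",
            is.na(keep$gestational_age) | keep$gestational_age < 37 |
              keep$gestational_age > 42)
  cnt <- table(keep$country_id)
  small <- names(cnt)[cnt < min_country_n]
  drop_rule(sprintf("country_below_%d_obs", min_country_n),
            keep$country_id %in% small)
  attr(tally, "final_n") <- nrow(keep)
  class(tally) <- c("exclusion_tally", "data.frame")
  tr <- attr(records, "truth")     # keep generator truth across subsetting
  if (!is.null(tr)) attr(keep, "truth") <- tr
  list(cohort = keep, tally = tally)
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("Inclusion filters:\n")
  print.data.frame(x)
  cat("final included:", attr(x, "final_n"), "\n")
  invisible(x)
}

#' Classify incomes into tertile categories
#'
#' Cut points at the 1/3 and 2/3 quantiles of the non-missing values;
#' values at or below a cut point go to the lower category (so when all
#' values are equal, everything is "lowest"); `NA` maps to "missing".
#'
#' @param incomes numeric vector, possibly with `NA`.
#' @return character vector over
#'   `c("lowest", "middle", "highest", "missing")`.
#' @examples
#' assign_income_tertiles(c(3, 6, 9, NA))
#' @export
assign_income_tertiles <- function(incomes) {
  out <- rep("missing", length(incomes))
  ok <- !is.na(incomes)
  if (any(ok)) {
    q <- stats::quantile(incomes[ok], c(1, 2) / 3, type = 7, names = FALSE)
    x <- incomes[ok]
    out[ok] <- ifelse(x <= q[1L], "lowest",
                      ifelse(x <= q[2L], "middle", "highest"))
  }
  out
}

#' Run the five-model covariate sequence
#'
#' Fits the cumulative Models 1-5 (see [model_spec()]) with the Gibbs
#' sampler, assembles the variance-decomposition report with Model 1 as
#' the PCV reference, and attaches the Model 1 shrunken country effects.
#' Seeds are derived deterministically from `settings$seed` (one offset
#' per model) so the whole report is reproducible from a single seed.
#'
#' @param cohort filtered cohort data frame.
#' @param settings an [mcmc_settings()].
#' @param models integer vector of models to fit (default `1:5`).
#' @param quiet suppress per-model progress messages.
#' @return an object of class `"study_report"`: list with `fits` (named
#'   list of `"nested_lmm"`), `fixed` (per-model coefficient tables),
#'   `partition` (a [partition_report()]), `league`
#'   ([country_effects()] of Model 1), and `settings`.
#' @export
run_model_sequence <- function(cohort, settings = mcmc_settings(),
                               models = 1:5, quiet = FALSE) {
  stopifnot(all(models %in% 1:5))
  fits <- list()
  for (m in models) {
    s <- settings
    s$seed <- settings$seed + (m - 1L)
    if (!quiet) {
      message(sprintf("fitting Model %d (n = %d, seed = %d)",
                      m, nrow(cohort), s$seed))
    }
    fits[[paste0("Model ", m)]] <- fit_gibbs(cohort, model_spec(m),
                                             settings = s)
  }
  vcs <- lapply(fits, function(f) f$variances)
  report <- partition_report(vcs)
  league <- if ("Model 1" %in% names(fits)) country_effects(fits[["Model 1"]])
  structure(list(
    fits = fits,
    fixed = lapply(fits, function(f) f$fixed),
    dic = vapply(fits, function(f) f$dic, numeric(1)),
    partition = report,
    league = league,
    settings = settings
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report:", length(x$fits), "models\n\n")
  print(x$partition)
  if (!all(is.na(x$dic))) {
    cat("\nDIC by model:\n")
    print(round(x$dic, 1))
  }
  invisible(x)
}

empty_spec_for <- function(cohort, settings) {
  fit_gibbs(cohort, model_spec(1), settings = settings)
}

#' Sensitivity analysis: drop the lowest-ranked countries
#'
#' Removes the `k` countries with the lowest Model 1 shrunken effects,
#' refits the empty model on the reduced cohort, and reports the
#' proportional change in variance against the full-cohort empty model.
#'
#' @param cohort cohort data frame.
#' @param k number of lowest-ranked countries to drop (default 9).
#' @param settings an [mcmc_settings()].
#' @param fit_full optional pre-computed full-cohort empty-model Gibbs
#'   fit, to avoid refitting.
#' @return list with `partition` (a [partition_report()] of full vs
#'   reduced), `dropped` (the dropped country ids, lowest first) and both
#'   fits.
#' @export
sensitivity_drop_lowest <- function(cohort, k = 9L,
                                    settings = mcmc_settings(),
                                    fit_full = NULL) {
  if (is.null(fit_full)) fit_full <- empty_spec_for(cohort, settings)
  eff <- country_effects(fit_full)
  if (k >= nrow(eff)) stop("k must be smaller than the number of countries",
                           call. = FALSE)
  dropped <- league_table(eff)$country_id[seq_len(k)]
  sub <- cohort[!cohort$country_id %in% dropped, , drop = FALSE]
  s <- settings; s$seed <- settings$seed + 1L
  fit_sub <- if (k > 0L) empty_spec_for(sub, s) else fit_full
  list(partition = partition_report(list(
         "all countries" = fit_full$variances,
         "lowest dropped" = fit_sub$variances)),
       dropped = dropped, fit_full = fit_full, fit_reduced = fit_sub)
}

#' Sensitivity analysis: two-level model of continuous maternal stature
#'
#' Fits the two-level empty model (mothers in countries) to continuous
#' stature and returns the between-country intra-class correlation
#' `100 * s2_country / (s2_country + s2_within)` in percent.
#'
#' @param stature data frame from [sample_maternal_stature()] (columns
#'   `mother_id`, `country_id`, `stature_cm`).
#' @param settings an [mcmc_settings()].
#' @param method `"gibbs"` or `"mom"`.
#' @return list with `icc` (percent) and the fit.
#' @export
sensitivity_two_level_stature <- function(stature,
                                          settings = mcmc_settings(),
                                          method = c("gibbs", "mom")) {
  method <- match.arg(method)
  dat <- data.frame(baby_id = seq_len(nrow(stature)),
                    mother_id = stature$mother_id,
                    country_id = stature$country_id,
                    birthweight = stature$stature_cm,
                    stringsAsFactors = FALSE)
  spec <- model_spec(fixed_terms = character(0), random_levels = "country")
  fit <- if (method == "mom") fit_mom(dat, spec)
         else fit_gibbs(dat, spec, settings = settings)
  s2 <- fit$variances$sigma2
  list(icc = 100 * s2[["mcb"]] / (s2[["mcb"]] + s2[["b"]]), fit = fit)
}

#' Sensitivity analysis: drop the mother level
#'
#' Compares the three-level empty model with the two-level
#' babies-in-countries empty model: the country-level variance share
#' should be nearly unchanged, the dropped mother variance being absorbed
#' by the residual.
#'
#' @param cohort cohort data frame.
#' @param settings an [mcmc_settings()].
#' @return list with `partition` (three-level vs two-level), both fits,
#'   and `vpc_mcb` per model.
#' @export
sensitivity_drop_mother_level <- function(cohort,
                                          settings = mcmc_settings()) {
  fit3 <- fit_gibbs(cohort, model_spec(1), settings = settings)
  s <- settings; s$seed <- settings$seed + 1L
  fit2 <- fit_gibbs(cohort,
                    model_spec(fixed_terms = character(0),
                               random_levels = "country"),
                    settings = s)
  part <- partition_report(list("three-level" = fit3$variances,
                                "two-level" = fit2$variances))
  list(partition = part, fit_three = fit3, fit_two = fit2,
       vpc_mcb = c(three_level = unname(vpc(fit3$variances)["vpc_mcb"]),
                   two_level = unname(vpc(fit2$variances)["vpc_mcb"])))
}

#' Sensitivity analysis: subsample the dominant country
#'
#' Retains a random fraction of the dominant (largest) country's mothers —
#' whole mothers, never partial sibling sets — leaves every other country
#' intact, and refits the empty model.
#'
#' @param cohort cohort data frame.
#' @param fraction fraction of dominant-country mothers to keep, in
#'   `(0, 1]`.
#' @param seed seed for the mother subsample.
#' @param settings an [mcmc_settings()].
#' @return list with `partition` (full vs subsampled), the subsampled
#'   cohort, and both fits.
#' @export
sensitivity_subsample_reference <- function(cohort, fraction = 0.05,
                                            seed = 1L,
                                            settings = mcmc_settings()) {
  stopifnot(fraction > 0, fraction <= 1)
  sizes <- table(cohort$country_id)
  dominant <- names(sizes)[which.max(sizes)]
  sub <- cohort
  if (fraction < 1) {
    set.seed(seed)
    dom_mothers <- unique(cohort$mother_id[cohort$country_id == dominant])
    keep_m <- sample(dom_mothers, ceiling(fraction * length(dom_mothers)))
    sub <- cohort[cohort$country_id != dominant |
                    cohort$mother_id %in% keep_m, , drop = FALSE]
  }
  fit_full <- empty_spec_for(cohort, settings)
  s <- settings; s$seed <- settings$seed + 1L
  fit_sub <- if (fraction < 1) empty_spec_for(sub, s) else fit_full
  list(partition = partition_report(list(full = fit_full$variances,
                                         subsample = fit_sub$variances)),
       cohort = sub, dominant = dominant,
       fit_full = fit_full, fit_subsample = fit_sub)
}
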