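# Canonical category levels for every covariate in a birth record.
# "missing" is an ordinary category wherever the register carries one.
cohort_levels <- list(
  sex         = c("male", "female"),
  stature_cat = c("<150", "150-159", "160-169", "170-179", ">179", "missing"),
  age_cat     = c("<20", "20-24", "25-34", ">34"),
  marital     = c("married/cohabiting", "single", "widowed/divorced", "missing"),
  smoking     = c("none", "1-9/day", ">9/day", "missing"),
  income_cat  = c("highest", "middle", "lowest", "missing"),
  hypertension = c("no", "yes"),
  diabetes    = c("no", "yes"),
  wb_class    = c("low", "lower-middle", "upper-middle", "high")
)

# Reference categories of the published covariate coding.
default_reference_categories <- c(
  stature = "160-169", age = "25-34", sex = "male", income = "highest",
  marital = "married/cohabiting", smoking = "none", hypertension = "no",
  diabetes = "no", wb_class = "high"
)

# Cohort-wide covariate category frequencies (population proportions of the
# emulated register, "all economies" margin).
default_covariate_freqs <- function() {
  list(
    sex     = as_prob(c(male = 51.04, female = 48.96)),
    stature = as_prob(c("<150" = 0.37, "150-159" = 11.62, "160-169" = 51.65,
                        "170-179" = 29.10, ">179" = 1.95, missing = 5.40)),
    age     = as_prob(c("<20" = 1.63, "20-24" = 12.55, "25-34" = 65.20,
                        ">34" = 20.61)),
    marital = as_prob(c("married/cohabiting" = 90.18, single = 1.67,
                        "widowed/divorced" = 3.56, missing = 4.59)),
    smoking = as_prob(c(none = 87.79, "1-9/day" = 5.58, ">9/day" = 1.82,
                        missing = 4.80)),
    income  = as_prob(c(highest = 33.03, middle = 32.92, lowest = 32.86,
                        missing = 1.19)),
    hypertension = as_prob(c(no = 96.40, yes = 3.60)),
    diabetes     = as_prob(c(no = 99.50, yes = 0.50))
  )
}

# Fixed-effect sizes (grams) of the fully adjusted model; gestational age
# acts per centered week.
default_fixed_effects <- function() {
  list(
    intercept = 3595,
    stature = c("<150" = -184, "150-159" = -98, "160-169" = 0,
                "170-179" = 99, ">179" = 202, missing = 6),
    age = c("<20" = -106, "20-24" = -60, "25-34" = 0, ">34" = 51),
    sex = c(male = 0, female = -123),
    gestational_age = 149,
    income = c(highest = 0, middle = 76, lowest = 107, missing = 12),
    marital = c("married/cohabiting" = 0, single = -39,
                "widowed/divorced" = -44, missing = 7),
    smoking = c(none = 0, "1-9/day" = -129, ">9/day" = -179, missing = 4),
    hypertension = c(no = 0, yes = -108),
    diabetes = c(no = 0, yes = 314),
    wb_class = c(low = -88, "lower-middle" = -52, "upper-middle" = -16,
                 high = 0)
  )
}

#' Configuration of the synthetic birth-register generator
#'
#' Builds the generator configuration. The defaults emulate the structure
#' of a national birth register restricted to term singleton births:
#' 109 maternal countries of birth with one dominant origin holding ~80%
#' of mothers, 1-3 babies per mother (1.42 on average), the published
#' covariate category frequencies, the fully adjusted fixed-effect sizes,
#' and empty-model variance components of 7,699 / 111,583 / 119,871 g^2
#' at the country / mother / baby level.
#'
#' @param n_countries number of maternal countries of birth.
#' @param dominant_country_share fraction of mothers in the dominant
#'   (native) country.
#' @param country_size_concentration symmetric Dirichlet concentration for
#'   the remaining country shares; smaller values give heavier skew.
#' @param n_mothers number of mothers.
#' @param parity_probs probability of a mother contributing 1, 2 or 3
#'   babies to the cohort.
#' @param true_fixed_effects named list of per-term effect sizes in grams
#'   (see `nestvpc:::default_fixed_effects()` for the shape). Set blocks to
#'   0 to simulate pure variance structure.
#' @param true_variances variance components in g^2, named
#'   `c(mcb=, m=, b=)` for the country, mother and baby level.
#' @param covariate_freqs named list of per-covariate category
#'   probabilities; each vector is normalised to sum to 1.
#' @param ga_mean,ga_sd mean and SD (weeks) of gestational age before
#'   rounding and truncation to 37-42 completed weeks.
#' @param stature_icc between-country share of continuous maternal stature
#'   variance, in `[0, 1)`.
#' @param stature_mean,stature_sd mean and total SD (cm) of continuous
#'   maternal stature.
#' @param wb_class_probs probability that a country falls in each World
#'   Bank income class (low / lower-middle / upper-middle / high).
#' @param covariate_sampler optional `function(n_mothers)` returning a
#'   data frame of mother-level covariates (`stature_cat`, `age_cat`,
#'   `marital`, `smoking`, `income_cat`, `hypertension`, `diabetes`),
#'   replacing the independent category draws.
#' @param seed default random seed used when none is passed to the
#'   sampling functions.
#' @return an object of class `"synth_config"`.
#' @examples
#' cfg <- synth_config(n_countries = 20, n_mothers = 500)
#' cfg$true_variances
#' @export
synth_config <- function(n_countries = 109,
                         dominant_country_share = 0.80,
                         country_size_concentration = 0.5,
                         n_mothers = 571876,
                         parity_probs = c(0.62, 0.34, 0.04),
                         true_fixed_effects = default_fixed_effects(),
                         true_variances = c(mcb = 7699, m = 111583, b = 119871),
                         covariate_freqs = default_covariate_freqs(),
                         ga_mean = 39.66, ga_sd = 1.27,
                         stature_icc = 0.24,
                         stature_mean = 165, stature_sd = 6.5,
                         wb_class_probs = c(low = 0.1284,
                                            "lower-middle" = 0.2294,
                                            "upper-middle" = 0.3394,
                                            high = 0.3028),
                         covariate_sampler = NULL,
                         seed = 1L) {
  stopifnot(n_countries >= 1, n_mothers >= 1,
            dominant_country_share > 0, dominant_country_share < 1,
            country_size_concentration > 0,
            ga_sd > 0, stature_icc >= 0, stature_icc < 1, stature_sd > 0)
  parity_probs <- as_prob(parity_probs)
  wb_class_probs <- as_prob(wb_class_probs)
  check_prob_vector(parity_probs, "parity_probs")
  check_prob_vector(wb_class_probs, "wb_class_probs")
  covariate_freqs <- lapply(covariate_freqs, as_prob)
  for (nm in names(covariate_freqs)) {
    check_prob_vector(covariate_freqs[[nm]], paste0("covariate_freqs$", nm))
  }
  tv <- as.numeric(true_variances)
  names(tv) <- c("mcb", "m", "b")
  if (any(!is.finite(tv)) || any(tv < 0)) {
    stop("true_variances must be finite and non-negative", call. = FALSE)
  }
  structure(list(
    n_countries = as.integer(n_countries),
    dominant_country_share = dominant_country_share,
    country_size_concentration = country_size_concentration,
    n_mothers = as.integer(n_mothers),
    parity_probs = parity_probs,
    true_fixed_effects = true_fixed_effects,
    true_variances = tv,
    covariate_freqs = covariate_freqs,
    ga_mean = ga_mean, ga_sd = ga_sd,
    stature_icc = stature_icc,
    stature_mean = stature_mean, stature_sd = stature_sd,
    wb_class_probs = wb_class_probs,
    covariate_sampler = covariate_sampler,
    seed = as.integer(seed)
  ), class = "synth_config")
}

#' Default generator configuration
#'
#' The generator configuration at its published-study defaults; equivalent
#' to [synth_config()] with no arguments.
#'
#' @return a `"synth_config"` object.
#' @examples
#' default_config()$true_variances
#' @export
default_config <- function() synth_config()

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic birth-register configuration\n")
  cat(sprintf("  countries: %d (dominant share %.2f), mothers: %d\n",
              x$n_countries, x$dominant_country_share, x$n_mothers))
  cat(sprintf("  true variances (g^2): mcb %.0f, mother %.0f, baby %.0f\n",
              x$true_variances["mcb"], x$true_variances["m"],
              x$true_variances["b"]))
  cat(sprintf("  gestational age: %.2f (%.2f) weeks; stature ICC %.2f\n",
              x$ga_mean, x$ga_sd, x$stature_icc))
  invisible(x)
}

# Intercept-only variant: same structure, all covariate effects zero.
# Used for pure variance-recovery scenarios.
#' Configuration with all covariate effects removed
#'
#' Convenience wrapper: the same structural configuration but with every
#' fixed effect except the overall mean set to zero, so the marginal
#' variance decomposition of a sampled cohort equals `true_variances`
#' exactly. Used for empty-model variance-recovery experiments.
#'
#' @param ... passed to [synth_config()].
#' @param intercept overall mean birthweight in grams.
#' @return a `"synth_config"` object.
#' @export
synth_config_empty <- function(..., intercept = 3490) {
  cfg <- synth_config(...)
  fe <- cfg$true_fixed_effects
  fe <- lapply(fe, function(v) v * 0)
  fe$intercept <- intercept
  cfg$true_fixed_effects <- fe
  cfg
}

# Country population shares: dominant country first, remaining shares from
# a symmetric Dirichlet.
sample_country_shares <- function(cfg) {
  k <- cfg$n_countries
  if (k == 1L) return(1)
  g <- stats::rgamma(k - 1L, shape = cfg$country_size_concentration, rate = 1)
  if (sum(g) <= 0) g <- rep(1, k - 1L)
  c(cfg$dominant_country_share,
    (1 - cfg$dominant_country_share) * g / sum(g))
}

sample_categories <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

# Gestational age: normal draw rounded to completed weeks, truncated to
# 37-42 by resampling.
sample_gestational_age <- function(n, mean, sd) {
  ga <- round(stats::rnorm(n, mean, sd))
  bad <- which(ga < 37 | ga > 42)
  while (length(bad)) {
    ga[bad] <- round(stats::rnorm(length(bad), mean, sd))
    bad <- bad[ga[bad] < 37 | ga[bad] > 42]
  }
  as.integer(ga)
}

#' Sample a synthetic birth cohort
#'
#' Draws a full nested cohort: countries with skewed population shares and
#' a country-level income class, mothers assigned to countries with 1-3
#' babies each, mother- and baby-level covariates from the configured
#' category frequencies, and birthweight assembled as
#' `intercept + covariate effects + v_country + u_mother + e_baby` with
#' independent Gaussian effects at the configured variances. Covariates
#' are drawn independently of each other and of the latent effects.
#'
#' The true latent structure (country and mother effects, shares) is
#' attached and retrievable with [cohort_truth()] for oracle checks.
#'
#' @param cfg a [synth_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return a `data.frame` of class `"synth_cohort"`, one row per baby,
#'   with columns `baby_id, mother_id, country_id, birthweight,
#'   gestational_age, sex, stature_cat, age_cat, marital, smoking,
#'   income_cat, hypertension, diabetes, wb_class`.
#' @examples
#' coh <- sample_cohort(synth_config(n_countries = 10, n_mothers = 200), seed = 1)
#' head(coh)
#' @export
sample_cohort <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  expected_babies <- cfg$n_mothers * sum(cfg$parity_probs * seq_along(cfg$parity_probs))
  if (expected_babies / cfg$n_countries < 1) {
    stop("expected babies per country < 1: increase n_mothers or reduce n_countries",
         call. = FALSE)
  }
  set.seed(seed)
  K <- cfg$n_countries
  country_id <- sprintf("C%03d", seq_len(K))
  shares <- sample_country_shares(cfg)
  wb_class <- sample_categories(K, cfg$wb_class_probs)
  v <- stats::rnorm(K, 0, sqrt(cfg$true_variances["mcb"]))

  M <- cfg$n_mothers
  mother_country <- sample.int(K, M, replace = TRUE, prob = shares)
  parity <- sample.int(length(cfg$parity_probs), M, replace = TRUE,
                       prob = cfg$parity_probs)
  u <- stats::rnorm(M, 0, sqrt(cfg$true_variances["m"]))

  fr <- cfg$covariate_freqs
  if (is.null(cfg$covariate_sampler)) {
    mother_cov <- data.frame(
      stature_cat = sample_categories(M, fr$stature),
      age_cat = sample_categories(M, fr$age),
      marital = sample_categories(M, fr$marital),
      smoking = sample_categories(M, fr$smoking),
      income_cat = sample_categories(M, fr$income),
      hypertension = sample_categories(M, fr$hypertension),
      diabetes = sample_categories(M, fr$diabetes),
      stringsAsFactors = FALSE
    )
  } else {
    mother_cov <- cfg$covariate_sampler(M)
  }

  mi <- rep.int(seq_len(M), parity)            # mother index per baby
  n <- length(mi)
  ci <- mother_country[mi]                     # country index per baby
  sex <- sample_categories(n, fr$sex)
  ga <- sample_gestational_age(n, cfg$ga_mean, cfg$ga_sd)
  e <- stats::rnorm(n, 0, sqrt(cfg$true_variances["b"]))

  fe <- cfg$true_fixed_effects
  bw <- fe$intercept +
    fe$stature[mother_cov$stature_cat[mi]] +
    fe$age[mother_cov$age_cat[mi]] +
    fe$marital[mother_cov$marital[mi]] +
    fe$smoking[mother_cov$smoking[mi]] +
    fe$income[mother_cov$income_cat[mi]] +
    fe$hypertension[mother_cov$hypertension[mi]] +
    fe$diabetes[mother_cov$diabetes[mi]] +
    fe$sex[sex] +
    fe$gestational_age * (ga - cfg$ga_mean) +
    fe$wb_class[wb_class[ci]] +
    v[ci] + u[mi] + e

  cohort <- data.frame(
    baby_id = seq_len(n),
    mother_id = mi,
    country_id = country_id[ci],
    birthweight = unname(bw),
    gestational_age = ga,
    sex = sex,
    stature_cat = mother_cov$stature_cat[mi],
    age_cat = mother_cov$age_cat[mi],
    marital = mother_cov$marital[mi],
    smoking = mother_cov$smoking[mi],
    income_cat = mother_cov$income_cat[mi],
    hypertension = mother_cov$hypertension[mi],
    diabetes = mother_cov$diabetes[mi],
    wb_class = wb_class[ci],
    stringsAsFactors = FALSE
  )
  attr(cohort, "truth") <- list(
    country = data.frame(country_id = country_id, share = shares,
                         wb_class = wb_class, effect = v,
                         stringsAsFactors = FALSE),
    mother = data.frame(mother_id = seq_len(M),
                        country_id = country_id[mother_country],
                        effect = u, stringsAsFactors = FALSE),
    residual = e,
    sigma2 = cfg$true_variances,
    seed = seed
  )
  class(cohort) <- c("synth_cohort", "data.frame")
  cohort
}

#' True latent structure of a synthetic cohort
#'
#' @param cohort a cohort from [sample_cohort()].
#' @return list with elements `country` (id, share, income class, true
#'   effect), `mother` (id, country, true effect), `residual`, `sigma2`
#'   and `seed`.
#' @export
cohort_truth <- function(cohort) {
  tr <- attr(cohort, "truth")
  if (is.null(tr)) stop("cohort carries no stored truth", call. = FALSE)
  tr
}

#' Plant a low-birthweight signal in selected countries
#'
#' Emulates a register in which a handful of countries sit markedly below
#' the rest (the published league table's nine low-mean countries): the
#' selected countries' latent effects are replaced by a deterministic
#' deviation `shift` grams below the lowest remaining country, so the
#' planted countries are, in truth, strictly below every other country.
#' Used for rank-recovery experiments on league tables and for the
#' drop-the-lowest sensitivity analysis.
#'
#' @param cohort a cohort from [sample_cohort()] (must carry its truth).
#' @param countries country ids to plant; default the `k` last ids
#'   (never the dominant first country).
#' @param k number of countries to plant when `countries` is `NULL`.
#' @param shift grams between the planted countries and the lowest
#'   unplanted country (default -250).
#' @return the modified cohort, with truth updated accordingly.
#' @export
plant_low_countries <- function(cohort, countries = NULL, k = 9L,
                                shift = -250) {
  tr <- cohort_truth(cohort)
  if (is.null(countries)) {
    ids <- tr$country$country_id
    countries <- utils::tail(ids, k)
  }
  j <- match(countries, tr$country$country_id)
  if (anyNA(j)) stop("unknown countries to plant", call. = FALSE)
  target <- min(tr$country$effect[-j]) + shift
  adj <- target - tr$country$effect[j]
  i <- match(cohort$country_id, countries)
  sel <- !is.na(i)
  cohort$birthweight[sel] <- cohort$birthweight[sel] + adj[i[sel]]
  tr$country$effect[j] <- target
  tr$planted <- countries
  attr(cohort, "truth") <- tr
  cohort
}

#' Sample continuous maternal stature with between-country clustering
#'
#' Two-level Gaussian model for mothers' stature: country means drawn with
#' variance `stature_icc * stature_sd^2`, mothers around their country
#' mean with the complementary within-country variance, so the
#' between-country share of total variance is exactly `stature_icc`.
#'
#' @param cfg a [synth_config()]; `stature_icc`, `stature_mean` and
#'   `stature_sd` are used.
#' @param mothers_per_country integer count of mothers per country, either
#'   a scalar or a vector of length `cfg$n_countries`.
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return data frame with columns `mother_id`, `country_id`,
#'   `stature_cm`; the true country means are attached as attribute
#'   `"truth"`.
#' @export
sample_maternal_stature <- function(cfg, mothers_per_country = 200,
                                    seed = cfg$seed) {
  stopifnot(inherits(cfg, "synth_config"))
  K <- cfg$n_countries
  m <- rep_len(as.integer(mothers_per_country), K)
  set.seed(seed)
  tot <- cfg$stature_sd^2
  mu_k <- stats::rnorm(K, cfg$stature_mean, sqrt(cfg$stature_icc * tot))
  ci <- rep.int(seq_len(K), m)
  st <- mu_k[ci] + stats::rnorm(length(ci), 0, sqrt((1 - cfg$stature_icc) * tot))
  out <- data.frame(
    mother_id = seq_along(ci),
    country_id = sprintf("C%03d", ci),
    stature_cm = st,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- list(country_mean = mu_k,
                             between = cfg$stature_icc * tot,
                             within = (1 - cfg$stature_icc) * tot)
  out
}
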