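test_that("default configuration carries the published study quantities", {
  cfg <- default_config()
  expect_equal(unname(cfg$true_variances), c(7699, 111583, 119871))
  expect_equal(c(cfg$ga_mean, cfg$ga_sd), c(39.66, 1.27))
  expect_equal(cfg$covariate_freqs$sex[["female"]], 0.4896)
  expect_equal(cfg$n_countries, 109L)
  expect_equal(cfg$stature_icc, 0.24)
  # expected babies per mother ~ 1.42
  expect_equal(sum(cfg$parity_probs * 1:3), 1.42, tolerance = 1e-12)
  for (p in cfg$covariate_freqs) expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum(cfg$parity_probs), 1, tolerance = 1e-12)
  expect_equal(sum(cfg$wb_class_probs), 1, tolerance = 1e-12)
})

test_that("configs with impossible country occupancy are rejected", {
  cfg <- synth_config(n_countries = 100, n_mothers = 20)
  expect_error(sample_cohort(cfg, seed = 1), "expected babies per country")
})

test_that("no-noise degenerate cohort is constant at the intercept", {
  cfg <- synth_config_empty(n_countries = 5, n_mothers = 100,
                            true_variances = c(0, 0, 0), intercept = 3490)
  coh <- sample_cohort(cfg, seed = 3)
  expect_true(all(coh$birthweight == 3490))
})

test_that("the generator is bit-identical under a fixed seed", {
  cfg <- synth_config(n_countries = 12, n_mothers = 400)
  a <- sample_cohort(cfg, seed = 99)
  b <- sample_cohort(cfg, seed = 99)
  expect_identical(a, b)
  c_ <- sample_cohort(cfg, seed = 100)
  expect_false(identical(a$birthweight, c_$birthweight))
})

test_that("drawn country effects match the configured variance within the chi-square bound", {
  cfg <- synth_config_empty(n_countries = 100, n_mothers = 20000)
  coh <- sample_cohort(cfg, seed = 7)
  v <- cohort_truth(coh)$country$effect
  s2 <- cfg$true_variances[["mcb"]]
  half_width <- 3 * sqrt(2 / 99)        # 3-sigma bound for a variance of 100 draws
  expect_gt(var(v), s2 * (1 - half_width))
  expect_lt(var(v), s2 * (1 + half_width))
})

test_that("nesting is a function: no mother appears in two countries", {
  coh <- sample_cohort(synth_config(n_countries = 20, n_mothers = 5000), seed = 5)
  tab <- unique(coh[, c("mother_id", "country_id")])
  expect_equal(anyDuplicated(tab$mother_id), 0L)
  # mother-level covariates constant within mother
  sm <- tapply(coh$stature_cat, coh$mother_id, function(x) length(unique(x)))
  expect_true(all(sm == 1L))
  # wb_class constant within country
  wc <- tapply(coh$wb_class, coh$country_id, function(x) length(unique(x)))
  expect_true(all(wc == 1L))
})

test_that("removing the stored truth leaves residuals at the baby-level variance", {
  cfg <- synth_config_empty(n_countries = 30, n_mothers = 8000)
  coh <- sample_cohort(cfg, seed = 21)
  tr <- cohort_truth(coh)
  ci <- match(coh$country_id, tr$country$country_id)
  e <- coh$birthweight - cfg$true_fixed_effects$intercept -
    tr$country$effect[ci] - tr$mother$effect[coh$mother_id]
  n <- length(e)
  s2b <- cfg$true_variances[["b"]]
  half_width <- 3 * sqrt(2 / (n - 1))
  expect_gt(var(e), s2b * (1 - half_width))
  expect_lt(var(e), s2b * (1 + half_width))
})

test_that("generated category frequencies converge to the configured probabilities", {
  cfg <- synth_config(n_countries = 10, n_mothers = 12000)
  coh <- sample_cohort(cfg, seed = 13)
  mothers <- !duplicated(coh$mother_id)
  for (blk in c("smoking", "income")) {
    col <- c(smoking = "smoking", income = "income_cat")[[blk]]
    p <- cfg$covariate_freqs[[blk]]
    obs <- table(coh[[col]][mothers])[names(p)] / sum(mothers)
    bound <- 3 * sqrt(p * (1 - p) / sum(mothers))
    expect_true(all(abs(obs - p) <= bound))
  }
  p_f <- cfg$covariate_freqs$sex[["female"]]
  obs_f <- mean(coh$sex == "female")
  expect_lt(abs(obs_f - p_f), 3 * sqrt(p_f * (1 - p_f) / nrow(coh)))
})

test_that("gestational age stays in 37-42 completed weeks", {
  coh <- sample_cohort(synth_config(n_countries = 10, n_mothers = 3000), seed = 2)
  expect_true(all(coh$gestational_age >= 37 & coh$gestational_age <= 42))
  expect_true(is.integer(coh$gestational_age))
})

test_that("stature generator realises the configured between-country share", {
  cfg0 <- synth_config(n_countries = 100, stature_icc = 0)
  st0 <- sample_maternal_stature(cfg0, mothers_per_country = 200, seed = 4)
  cm <- tapply(st0$stature_cm, st0$country_id, mean)
  between_share <- var(cm) / var(st0$stature_cm)
  expect_lt(between_share, 0.02)

  cfg24 <- synth_config(n_countries = 100, stature_icc = 0.24)
  st <- sample_maternal_stature(cfg24, mothers_per_country = 200, seed = 4)
  # brute-force grouped means equal the generator's decomposition exactly
  tr <- attr(st, "truth")
  mu_k <- tr$country_mean
  within <- st$stature_cm - rep(mu_k, each = 200)
  cm_brute <- tapply(st$stature_cm, st$country_id, mean)
  cm_decomp <- mu_k + tapply(within, st$country_id, mean)
  expect_equal(unname(cm_brute[sprintf("C%03d", 1:100)]), unname(cm_decomp),
               tolerance = 1e-12)
  # empirical shares near 24%
  cm <- tapply(st$stature_cm, st$country_id, mean)
  expect_gt(100 * var(cm) / var(st$stature_cm), 15)
  expect_lt(100 * var(cm) / var(st$stature_cm), 35)
})

test_that("cohort and config round-trip through their text formats", {
  cfg <- synth_config(n_countries = 6, n_mothers = 120)
  coh <- sample_cohort(cfg, seed = 8)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(coh, tmp)
  back <- read_cohort(tmp)
  expect_equal(back$birthweight, coh$birthweight)
  expect_equal(names(back)[1:14],
               c("baby_id", "mother_id", "country_id", "birthweight",
                 "gestational_age", "sex", "stature_cat", "age_cat",
                 "marital", "smoking", "income_cat", "hypertension",
                 "diabetes", "wb_class"))

  yml <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_countries: 7", "n_mothers: 250", "stature_icc: 0.1",
               "true_variances: {mcb: 100, m: 200, b: 300}"), yml)
  cfg2 <- read_synth_config(yml)
  expect_equal(cfg2$n_countries, 7L)
  expect_equal(unname(cfg2$true_variances), c(100, 200, 300))
  expect_equal(cfg2$ga_mean, 39.66)      # omitted fields fall back to defaults
  writeLines("not_a_field: 1", yml)
  expect_error(read_synth_config(yml), "unknown config fields")
})
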