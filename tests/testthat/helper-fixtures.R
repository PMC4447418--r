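# Fixture builders and independent oracles used across the suite.

# Balanced nested toy: K countries x Mc mothers x B babies, Gaussian
# effects at the given variances (country, mother, baby).
make_balanced_toy <- function(K, Mc, B, s2 = c(400, 900, 1600), mu = 3000,
                              seed = 1) {
  set.seed(seed)
  ci <- rep(seq_len(K), each = Mc * B)
  mi <- rep(seq_len(K * Mc), each = B)
  y <- mu + rep(stats::rnorm(K, 0, sqrt(s2[1])), each = Mc * B) +
    rep(stats::rnorm(K * Mc, 0, sqrt(s2[2])), each = B) +
    stats::rnorm(K * Mc * B, 0, sqrt(s2[3]))
  data.frame(baby_id = seq_along(y), mother_id = mi,
             country_id = sprintf("C%02d", ci), birthweight = y,
             stringsAsFactors = FALSE)
}

# 200-row unbalanced-free agreement fixture: 20 countries x 5 mothers x 2
# babies with components sized so every level's likelihood is informative
# (cluster-mean noise well below each component).
make_agreement_fixture <- function(seed) {
  make_balanced_toy(K = 20, Mc = 5, B = 2, s2 = c(1500, 1000, 1000),
                    seed = seed)
}

# Dense-covariance deviance oracle: assembles the full n x n covariance
# and evaluates -2 log MVN density directly. Independent of the package's
# level-wise algebra.
dense_deviance_oracle <- function(cohort, beta_vec, s2, spec) {
  dm <- design_matrix(cohort, spec)
  r <- cohort$birthweight - as.numeric(dm$X %*% beta_vec)
  n <- length(r)
  cfac <- match(cohort$country_id, unique(cohort$country_id))
  mfac <- match(paste(cohort$country_id, cohort$mother_id),
                unique(paste(cohort$country_id, cohort$mother_id)))
  V <- diag(s2[3], n)
  if ("country" %in% spec$random_levels) {
    V <- V + s2[1] * outer(cfac, cfac, "==")
  }
  if ("mother" %in% spec$random_levels) {
    V <- V + s2[2] * outer(mfac, mfac, "==")
  }
  R <- chol(V)
  z <- backsolve(R, r, transpose = TRUE)
  n * log(2 * pi) + 2 * sum(log(diag(R))) + sum(z^2)
}

# Sampler settings kept short for unit tests.
quick_settings <- function(seed, burn_in = 200L, n_iter = 800L) {
  mcmc_settings(burn_in = burn_in, n_iter = n_iter, seed = seed,
                compute_dic = FALSE)
}

# Printed empty-model variance components of the emulated study, reused
# across tests (country / mother / baby, g^2).
study_m1_components <- c(7699, 111583, 119871)
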