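test_that("fit_interaction estimates the joint model and per-stratum effects", {
  cfg <- sim_config(n_individuals = 6000, grs_beta = 0.2,
                    interaction_beta = -0.15, trait_sd_resid = 2,
                    pa_probs = c(1, 1, 1) / 3, seed = 31)
  coh <- simulate_cohort(cfg)
  dat <- coh$phenotypes
  score <- rowSums(coh$genotypes)
  covs <- covariate_set(dat, "bmi-set")
  ir <- fit_interaction(dat$bmi, score, dat$pa_level, covs)
  expect_lt(abs(ir$beta_interaction - (-0.15)), 3 * ir$se)
  # joint-model score coefficient is the PA=0 effect: beta - delta*mean(PA)
  pa_bar <- mean(as.integer(dat$pa_level) - 1L)
  expect_lt(abs(ir$beta_main - (0.2 + 0.15 * pa_bar)), 3 * ir$se_main)
  # marginal per-allele effect recovers the generating grs_beta
  marg <- linear_assoc(dat$bmi, score, covs)
  expect_lt(abs(marg$beta - 0.2), 3 * marg$se)
  expect_equal(sum(ir$strata$n), ir$n)
  # stratum betas decrease across PA levels for a negative interaction
  expect_gt(ir$strata$beta[1], ir$strata$beta[3])
  expect_equal(ir$strata$pa_label, c("low", "moderate", "high"))
  expect_false(is.na(ir$attenuation_pct))
})

test_that("interaction p-values are calibrated under a permutation null", {
  cfg <- sim_config(n_individuals = 500, grs_beta = 0.11,
                    interaction_beta = 0, seed = 32)
  coh <- simulate_cohort(cfg)
  dat <- coh$phenotypes
  score <- rowSums(coh$genotypes)
  covs <- covariate_set(dat, "bmi-set")
  set.seed(33)
  rej <- replicate(400, {
    pa_perm <- sample(as.integer(dat$pa_level) - 1L)
    fit_interaction(dat$bmi, score, pa_perm, covs,
                    stratified = FALSE)$p < 0.05
  })
  ci <- stats::binom.test(sum(rej), length(rej))$conf.int
  expect_true(ci[1] <= 0.05 && 0.05 <= ci[2])
})

test_that("a missing PA level is tolerated in the joint fit and marked absent", {
  set.seed(34)
  n <- 200
  score <- stats::rbinom(n, 10, 0.5)
  pa <- sample(0:1, n, replace = TRUE)  # no high stratum
  y <- 23 + 0.2 * score + stats::rnorm(n)
  ir <- fit_interaction(y, score, pa)
  expect_false(is.na(ir$beta_interaction))
  expect_true(ir$strata$absent[3])
  expect_true(is.na(ir$attenuation_pct))
  expect_error(fit_interaction(y, score, rep(5, n)), "0/1/2")
})

test_that("attenuation percentage follows the stated sign convention", {
  expect_equal(attenuation_pct(0.20, 0.08), 60)
  expect_equal(attenuation_pct(0.37, 0.37), 0)
  expect_equal(attenuation_pct(0.10, 0.20), -100)
  expect_error(attenuation_pct(0, 0.1), "undefined")
})

test_that("binomial sign test equals the exact tail and is monotone in k", {
  r <- sign_binomial_test(26, 28)
  expect_equal(signif(r$p_one_sided, 3), 1.52e-6)
  expect_equal(sign_binomial_test(28, 28)$p_one_sided, 2^-28)
  # exact-enumeration oracle: Pascal-triangle coefficients (pure integer
  # additions), tail sum divided by 2^n -- exact in doubles for n = 28
  row <- 1
  for (i in 1:28) row <- c(0, row) + c(row, 0)
  for (k in 0:28) {
    oracle <- sum(row[(k + 1):29]) / 2^28
    expect_equal(sign_binomial_test(k, 28)$p_one_sided, oracle,
                 tolerance = 1e-15)
    # library cross-check, allowing pbinom its own last-ulp rounding
    expect_equal(sign_binomial_test(k, 28)$p_one_sided,
                 stats::pbinom(k - 1, 28, 0.5, lower.tail = FALSE),
                 tolerance = 1e-13)
  }
  p_seq <- vapply(0:20, function(k) sign_binomial_test(k, 20)$p_one_sided,
                  numeric(1))
  expect_true(all(diff(p_seq) < 0))
  expect_error(sign_binomial_test(5, 4), "n_consistent")
})

test_that("count_consistent compares signs to reference directions and flags zeros", {
  betas <- c(rs1 = 0.2, rs2 = -0.1, rs3 = 0, rs4 = 0.3)
  ref <- c(rs1 = 1, rs2 = 1, rs3 = 1, rs4 = -1)
  cc <- count_consistent(betas, ref)
  expect_equal(cc$n_consistent, 1)  # only rs1 matches
  expect_equal(cc$n_total, 4)
  expect_equal(cc$n_zero, 1)
  expect_error(count_consistent(c(rs9 = 0.1), ref), "rs9")
  expect_error(count_consistent(betas, c(rs1 = 2, rs2 = 1, rs3 = 1, rs4 = -1)),
               "\\+1 or -1")
})

test_that("Cochran's Q matches hand computation and its invariances", {
  same <- cochran_q(0.5, 0.1, 0.5, 0.1)
  expect_equal(same$q_statistic, 0)
  expect_equal(same$p, 1)

  # (1, 0.1) vs (-1, 0.1): w = 100 each, pooled 0, Q = 100 + 100 = 200
  opp <- cochran_q(1.0, 0.1, -1.0, 0.1)
  expect_equal(opp$q_statistic, 200, tolerance = 1e-12)
  expect_equal(opp$df, 1L)

  # symmetry under swapping studies; location invariance
  a <- cochran_q(0.3, 0.05, 0.1, 0.08)
  b <- cochran_q(0.1, 0.08, 0.3, 0.05)
  expect_equal(a$p, b$p, tolerance = 1e-14)
  shifted <- cochran_q(0.3 + 5, 0.05, 0.1 + 5, 0.08)
  expect_equal(a$q_statistic, shifted$q_statistic, tolerance = 1e-10)
  expect_gte(a$i_squared, 0)
  expect_error(cochran_q(1, 0, 2, 1), "SEs")
})

test_that("score sensitivity analysis excludes designated SNPs via custom subsets", {
  p <- default_panel()
  g <- simulate_genotypes(p, 100, seed = 35)
  drop <- c("rs574367", "rs9939609", "rs11127485")
  keep <- setdiff(p$rsid, drop)
  full <- compute_grs(g, p, "overall")
  reduced <- compute_grs(g, p, subset = keep)
  expect_equal(attr(reduced, "subset_name"), "custom")
  expect_setequal(attr(reduced, "snps_used"), keep)
  removed <- rowSums(unclass(g)[, drop])
  expect_equal(full$score - reduced$score, unname(removed))
})
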