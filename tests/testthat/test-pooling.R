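test_that("Cochran's Q matches the two-study closed form and edge cases", {
  r <- cochran_q(c(0, log(2)), c(0.1, 0.1))
  expect_equal(r$q, log(2)^2 / (2 * 0.01), tolerance = 1e-12)
  expect_equal(r$df, 1)

  same <- cochran_q(c(0.3, 0.3), c(0.2, 0.2))
  expect_equal(same$q, 0)
  expect_equal(same$tau2, 0)
  expect_equal(same$i2, 0)
  expect_equal(same$p_q, 1)

  expect_error(cochran_q(0.1, 0.1), "at least 2")
})

test_that("Q, I2 and DL tau2 agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(7)
  for (rep in 1:5) {
    yi <- rnorm(8, 0.2, 0.3)
    vi <- runif(8, 0.01, 0.2)
    mine <- cochran_q(yi, sqrt(vi))
    ref <- metafor::rma(yi, vi, method = "DL")
    expect_equal(mine$q, as.numeric(ref$QE), tolerance = 1e-8)
    expect_equal(mine$p_q, as.numeric(ref$QEp), tolerance = 1e-8)
    expect_equal(mine$tau2, as.numeric(ref$tau2), tolerance = 1e-8)
  }
})

test_that("Mantel-Haenszel pooling matches hand arithmetic and identities", {
  # hand MH: (3,7,5,5) and (6,4,4,6) -> R = S -> OR = 1
  tabs <- data.frame(a = c(3, 6), b = c(7, 4), c = c(5, 4), d = c(5, 6))
  expect_equal(pool_fixed_mh(tabs)$or, 1, tolerance = 1e-12)

  # single study: MH OR equals that study's OR exactly
  one <- data.frame(a = 40, b = 60, c = 31, d = 69)
  expect_equal(pool_fixed_mh(one)$or, odds_ratio(40, 60, 31, 69)$or,
               tolerance = 1e-12)

  # m copies of a balanced table stay at OR = 1
  m <- data.frame(a = rep(10, 4), b = 10, c = 10, d = 10)
  expect_equal(pool_fixed_mh(m)$or, 1, tolerance = 1e-12)
})

test_that("MH estimate and RBG variance agree with metafor::rma.mh", {
  skip_if_not_installed("metafor")
  s <- cdkn2b_studies("rs4977574")
  for (m in c("allele", "homozygous")) {
    t <- build_table(s, m)
    mine <- pool_fixed_mh(t)
    ref <- metafor::rma.mh(ai = t$a, bi = t$b, ci = t$c, di = t$d,
                           measure = "OR", correct = FALSE)
    expect_equal(mine$log_or, as.numeric(ref$beta), tolerance = 1e-8)
    expect_equal(mine$se, as.numeric(ref$se), tolerance = 1e-8)
  }
})

test_that("IV and DL pooling agree with metafor and collapse when tau2 = 0", {
  skip_if_not_installed("metafor")
  eff <- effect_estimates(cdkn2b_studies("rs1333049"), "allele")
  dl <- pool_random_dl(eff)
  ref <- metafor::rma(eff$log_or, eff$se^2, method = "DL")
  expect_equal(dl$log_or, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(dl$se, as.numeric(ref$se), tolerance = 1e-8)

  fe <- pool_fixed_iv(eff)
  ref_fe <- metafor::rma(eff$log_or, eff$se^2, method = "FE")
  expect_equal(fe$log_or, as.numeric(ref_fe$beta), tolerance = 1e-8)

  # tau2 = 0 (homogeneous effects): DL is IV to machine precision
  hom <- fake_effects(c(0.2, 0.2, 0.2), c(0.1, 0.2, 0.3))
  expect_equal(pool_random_dl(hom)$log_or, pool_fixed_iv(hom)$log_or,
               tolerance = 1e-12)
  expect_equal(pool_random_dl(hom)$se, pool_fixed_iv(hom)$se,
               tolerance = 1e-12)
})

test_that("MH and IV fixed effects agree closely on the packaged contrasts", {
  for (v in c("rs1333049", "rs4977574")) {
    s <- cdkn2b_studies(v)
    for (m in genetic_models()) {
      eff <- effect_estimates(s, m)
      mh <- pool_fixed_mh(eff[c("a", "b", "c", "d")])
      iv <- pool_fixed_iv(eff)
      expect_true(abs(mh$or / iv$or - 1) < 0.02,
                  label = paste(v, m, "MH vs IV within 2%"))
    }
  }
})

test_that("pooled log OR lies within the per-study range", {
  s <- cdkn2b_studies("rs1333049")
  for (m in genetic_models()) {
    eff <- effect_estimates(s, m)
    for (res in list(pool_fixed_iv(eff), pool_random_dl(eff),
                     pool_fixed_mh(eff[c("a", "b", "c", "d")]))) {
      expect_true(res$log_or >= min(eff$log_or) & res$log_or <= max(eff$log_or))
    }
  }
})

test_that("pool_auto applies the heterogeneity selection rule", {
  s1 <- cdkn2b_studies("rs1333049")
  r <- pool_auto(s1, "allele")
  expect_equal(r$model_used, "random_dl")
  expect_true(r$het$p_q < 0.001)

  # rs4977574 West Asian homozygous: printed heterogeneity P = 0.657 -> fixed
  wa <- cdkn2b_studies("rs4977574")
  wa <- wa[wa$ethnicity == "West Asian", ]
  rf <- pool_auto(wa, "homozygous")
  expect_equal(rf$model_used, "fixed_mh")
  expect_close(rf$het$p_q, 0.657, 0.01)

  # two identical studies: p_q = 1, fixed selected
  expect_equal(pool_auto(balanced_set(2), "allele")$model_used, "fixed_mh")

  expect_error(pool_auto(balanced_set(1), "allele"), "at least 2")
})

test_that("pool_auto is invariant to study ordering", {
  s <- cdkn2b_studies("rs1333049")
  set.seed(3)
  shuffled <- s[sample(nrow(s)), ]
  a <- pool_auto(s, "recessive")
  b <- pool_auto(shuffled, "recessive")
  expect_equal(a$or, b$or, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("HWE-violation exclusion flag drops the flagged studies only", {
  s <- cdkn2b_studies("rs1333049")
  r_all <- pool_auto(s, "allele")
  r_ex <- pool_auto(s, "allele", exclude_hwe_violations = TRUE)
  hw <- hwe_test(s)
  expect_equal(r_ex$k, sum(hw$hwe_p >= 0.05))
  expect_equal(r_all$k, 33)
  expect_true(r_ex$k < r_all$k)
})

test_that("stratify reproduces partition bookkeeping and handles k = 1", {
  s1 <- cdkn2b_studies("rs1333049")
  by_eth <- stratify(s1, "ethnicity", "homozygous")
  expect_setequal(by_eth$stratum,
                  c("West Asian", "Caucasian", "East Asian", "African"))
  expect_equal(by_eth$k[by_eth$stratum == "West Asian"], 8)
  expect_equal(by_eth$k[by_eth$stratum == "East Asian"], 14)
  afr <- by_eth[by_eth$stratum == "African", ]
  expect_equal(afr$model_used, "single_study")
  expect_equal(afr$n_cases, 292)

  expect_equal(nrow(stratify(s1[0, ], "ethnicity", "allele")), 0)
})

test_that("leave_one_out returns k rows and detects stability", {
  s <- cdkn2b_studies("rs4977574")
  loo <- leave_one_out(s, "homozygous")
  expect_equal(nrow(loo), 17)
  expect_setequal(loo$omitted, s$study_id)
  expect_true(attr(loo, "significance_stable"))

  # three identical studies: every reduced pool equals the full pool
  b <- balanced_set(3)
  loo_b <- leave_one_out(b, "dominant")
  full <- attr(loo_b, "full")
  expect_true(all(abs(loo_b$or - full$or) < 1e-12))

  expect_error(leave_one_out(balanced_set(2), "allele"), "at least 3")
})

test_that("omitting the study closest to the pooled mean moves it least", {
  eff_set <- simulate_set(sim_scenario(k = 12, tau2 = 0.05, seed = 11))
  eff <- effect_estimates(eff_set, "allele")
  full <- pool_fixed_iv(eff)
  shifts <- vapply(seq_len(nrow(eff)), function(i) {
    abs(pool_fixed_iv(eff[-i, ])$log_or - full$log_or)
  }, 0)
  closest <- which.min(abs(eff$log_or - full$log_or))
  # the nearest-to-pooled study cannot be the single most influential one
  expect_true(shifts[closest] < max(shifts))
  expect_lt(rank(shifts)[closest], nrow(eff) / 2)
})

test_that("p-value formatter mirrors printed-table conventions", {
  expect_equal(format_p(c(0.0004, 0.076, 0.5)), c("<0.001", "0.076", "0.500"))
})
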