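test_that("CV% conversion reproduces the published variance table rows", {
  # printed log-scale variances -> BSV% row (nearest integer)
  expect_equal(round(cv_percent(0.4450)), 75)
  expect_equal(round(cv_percent(0.2944)), 59)
  expect_equal(round(cv_percent(0.6459)), 95)
  expect_equal(round(cv_percent(1.1466)), 147)
  expect_equal(cv_percent(0), 0)
  expect_error(cv_percent(-0.1), ">= 0")
})

test_that("omega_from_cv is the exact inverse of cv_percent", {
  for (cv in c(0, 5, 26.4, 75, 147, 300)) {
    expect_equal(cv_percent(omega_from_cv(cv)), cv, tolerance = 1e-12)
  }
})

test_that("ilogit bioavailability transform behaves and inverts", {
  expect_equal(ilogit_F(0), 0.5)
  expect_equal(ilogit_F(50), 1, tolerance = 1e-12)
  expect_true(all(diff(ilogit_F(seq(-5, 5, by = 0.1))) > 0))
  # published penethamate bioavailability back-transforms consistently
  expect_equal(logit_F(0.688), log(0.688 / 0.312), tolerance = 1e-12)
  expect_equal(round(logit_F(0.688), 3), 0.791)
})

test_that("exponential covariate model reproduces the per-source clearances", {
  eff <- c(Sweden = -0.68325471, USA1 = -0.12576635, USA2 = -0.13609778)
  expect_equal(round(apply_covariates(481, eff, "Sweden")), 243)
  expect_equal(round(apply_covariates(481, eff, "USA1")), 424)
  expect_equal(round(apply_covariates(481, eff, "USA2")), 420)
  # unknown source is the reference
  expect_equal(apply_covariates(481, eff, "France"), 481)
  expect_equal(apply_covariates(481, NULL, "anything"), 481)
})

test_that("sampling with zero omega returns the typical values", {
  m <- population_model(theta = list(CL = 481, Vc = 106),
                        omega = c(CL = 0, Vc = 0))
  p <- sample_individuals(m, 5, seed = 1)
  expect_true(all(p$CL == 481) && all(p$Vc == 106))
})

test_that("sampled parameters are positive, reproducible, and match the
           requested variability", {
  m <- population_model(theta = list(CL = 481, Vc = 106),
                        omega = c(CL = 26.4, Vc = 174))
  p1 <- sample_individuals(m, 1000, seed = 42)
  p2 <- sample_individuals(m, 1000, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(p1$CL > 0) && all(p1$Vc > 0))
  big <- sample_individuals(m, 100000, seed = 7)
  cv_cl <- 100 * stats::sd(big$CL) / mean(big$CL)
  expect_lt(abs(cv_cl - 26.4), 0.5)
})

test_that("log-scale sample covariance converges to omega", {
  om <- matrix(c(0.4450, 0.3552, 0.3552, 0.2944), 2, 2,
               dimnames = list(c("Vc", "CL"), c("Vc", "CL")))
  m <- population_model(theta = list(Vc = 106, CL = 481), omega = om)
  p <- sample_individuals(m, 200000, seed = 3)
  emp <- stats::cov(cbind(log(p$Vc), log(p$CL)))
  # 3 Monte-Carlo standard errors of a variance estimate ~ sqrt(2/n)*var
  for (i in 1:2) for (j in 1:2) {
    mc_se <- sqrt(2 / 200000) * sqrt(om[i, i] * om[j, j])
    expect_lt(abs(emp[i, j] - om[i, j]), 3 * max(mc_se, 1e-4))
  }
})

test_that("non-PSD omega is rejected by name", {
  om <- matrix(c(1, 2, 2, 1), 2, 2,
               dimnames = list(c("CL", "Vc"), c("CL", "Vc")))
  expect_error(population_model(theta = list(CL = 1, Vc = 1), omega = om),
               "positive semi-definite")
})

test_that("residual model has the stated moments and floors negatives", {
  res <- list(sigma_add = 0, sigma_prop = 0)
  expect_equal(as.numeric(residual_perturb(c(1, 2, 3), res)), c(1, 2, 3))
  set.seed(5)
  res2 <- list(sigma_add = 0, sigma_prop = 0.283)
  y <- residual_perturb(rep(1, 50000), res2)
  expect_lt(abs(stats::sd(y) - 0.283), 0.01)
  set.seed(6)
  res3 <- list(sigma_add = 0.000714, sigma_prop = 0)
  y0 <- residual_perturb(rep(0, 50000), res3)
  # half the draws on a zero concentration get floored at 0
  expect_gt(attr(y0, "n_floored"), 20000)
  expect_true(all(y0 >= 0))
})

test_that("free concentration scales profiles and keeps exact AUC", {
  d <- france_disposition()
  reg <- regimen_shorthand(12.36, 24, 1, "iv_infusion", infusion_h = 24)
  pr <- simulate_conc(d, absorption_scheme("iv_infusion"), reg)
  fp <- free_conc(pr, fu = 0.4)
  expect_equal(fp$conc, 0.4 * pr$conc)
  expect_equal(auc_profile(fp, 24), 0.4 * auc_profile(pr, 24),
               tolerance = 1e-12)
  expect_equal(round(0.4 * (12.36 / 24) / 0.481, 4), 0.4283)
  expect_identical(free_conc(pr, fu = 1)$conc, pr$conc)
})

test_that("packaged model files parse into consistent models", {
  iv <- read_population_model(iv_model_file())
  expect_equal(iv$theta$CL, 481)
  expect_equal(rownames(iv$omega),
               c("Vc", "CL", "V2", "V3", "CL2", "CL3"))
  expect_equal(iv$omega["Vc", "Vc"], 0.4450)
  expect_equal(iv$omega["CL2", "CL2"], 1.1466)
  expect_equal(iv$omega["CL", "Vc"], 0.3552)
  expect_equal(iv$fu, 0.4)
  fin <- read_population_model(final_model_file())
  expect_equal(round(cv_percent(fin$omega["CL", "CL"]), 1), 26.4)
  expect_equal(fin$absorption$procaine_france$Ka, 1 / 21.46)
  expect_equal(fin$absorption$sodium_im$Tlag, 0.471)
  expect_equal(round(apply_covariates(fin$theta$CL,
                                      fin$covariates$CL, "Sweden_IM")),
               351)
  expect_equal(round(apply_covariates(fin$theta$CL,
                                      fin$covariates$CL, "Japan")), 411)
})
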