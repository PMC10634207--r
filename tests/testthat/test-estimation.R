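iv_spec <- function(cl_init = 400, vc_init = 120) {
  fit_spec(theta = list(Vc = vc_init, V2 = 46.3, V3 = 50.4, CL = cl_init,
                        CL2 = 126, CL3 = 25),
           schemes = list(iv = "iv_bolus"),
           fixed = c("V2", "V3", "CL2", "CL3"),
           random = "CL", omega_init = 30,
           residual = list(sigma_add = 0.001, sigma_prop = 0.2))
}

gen_iv_model <- function(sigma_prop = 0.15, cv_cl = 26.4) {
  population_model(theta = list(Vc = 106, V2 = 46.3, V3 = 50.4, CL = 481,
                                CL2 = 126, CL3 = 25),
                   omega = c(CL = cv_cl),
                   residual = list(sigma_add = 0.001,
                                   sigma_prop = sigma_prop),
                   fu = 0.4)
}

gen_iv_data <- function(n, seed, model = gen_iv_model()) {
  des <- design_library()$usa2
  des$n <- as.integer(n)
  des$source <- "France"
  des$lloq <- 1e-6
  generate_study(model, des, seed = seed)
}

test_that("BLOQ filtering drops flagged rows and reports the fraction", {
  d <- data.frame(ID = 1, SOURCE = "France", FORM = "iv",
                  TIME = c(0, 1:100), AMT = c(12.36, rep(0, 100)),
                  RATE = 0, DV = c(NA, rep(1, 97), rep(0.001, 3)),
                  BLQ = 0L, LLOQ = 0.010)
  out <- bloq_filter(d)
  expect_equal(nrow(out), 98)  # dose row + 97 quantifiable
  expect_equal(attr(out, "frac_dropped"), 0.03)
  # no BLOQ rows -> identity
  clean <- d[c(1, 2:98), ]
  expect_equal(nrow(bloq_filter(clean)), 98)
  expect_equal(attr(bloq_filter(clean), "frac_dropped"), 0)
  # above-threshold fraction warns
  d2 <- d
  d2$DV[2:9] <- 0.001
  expect_warning(bloq_filter(d2), "BLOQ")
  # missing LLOQ for a source errors by name
  expect_error(bloq_filter(d[-1, -9], lloq = c(Sweden = 0.0055)),
               "France")
})

test_that("naive pooled fit recovers noiseless identifiable parameters", {
  # 1-compartment noiseless data: exact recovery of Vc and CL
  m1 <- population_model(theta = list(Vc = 100, V2 = 46.3, V3 = 50.4,
                                      CL = 481, CL2 = 0, CL3 = 0),
                         omega = NULL,
                         residual = list(sigma_add = 0, sigma_prop = 0))
  des <- design_library()$usa2
  des$n <- 1L
  des$source <- "France"
  des$lloq <- 1e-9
  dat <- generate_study(m1, des, seed = 1)
  spec <- fit_spec(theta = list(Vc = 80, V2 = 46.3, V3 = 50.4, CL = 300,
                                CL2 = 0, CL3 = 0),
                   schemes = list(iv = "iv_bolus"),
                   fixed = c("V2", "V3", "CL2", "CL3"))
  fit <- fit_naive_pooled(dat, spec)
  expect_equal(fit$theta$Vc, 100, tolerance = 1e-4)
  expect_equal(fit$theta$CL, 481, tolerance = 1e-4)
  # duplicating every row leaves the optimum unchanged
  dat2 <- rbind(dat, dat[(is.na(dat$AMT) | dat$AMT == 0), ])
  dat2$ID <- paste0(dat2$ID)
  fit2 <- fit_naive_pooled(dat2, spec)
  expect_equal(fit2$theta$CL, fit$theta$CL, tolerance = 1e-3)
})

test_that("naive pooled fit recovers triexponential parameters from a
           rich noiseless design within 5%", {
  m <- gen_iv_model(sigma_prop = 0, cv_cl = 0)
  m$residual$sigma_add <- 0
  dat <- gen_iv_data(2, seed = 4, model = m)
  spec <- fit_spec(theta = list(Vc = 90, V2 = 46.3, V3 = 50.4, CL = 400,
                                CL2 = 126, CL3 = 25),
                   schemes = list(iv = "iv_bolus"),
                   fixed = c("V2", "V3", "CL2", "CL3"))
  fit <- fit_naive_pooled(dat, spec)
  expect_lt(abs(fit$theta$CL / 481 - 1), 0.05)
  expect_lt(abs(fit$theta$Vc / 106 - 1), 0.05)
})

test_that("Laplace marginal likelihood is exact for a linear Gaussian
           random-intercept model", {
  # y_ij = theta + eta_i + eps_ij with additive error only: the Laplace
  # approximation equals the closed-form marginal Gaussian likelihood
  set.seed(8)
  theta <- 2
  omega2 <- 0.5
  sigma <- 0.3
  nsub <- 6
  nobs <- 5
  subjects <- lapply(seq_len(nsub), function(i) {
    eta_i <- rnorm(1, 0, sqrt(omega2))
    y <- theta + eta_i + rnorm(nobs, 0, sigma)
    list(y = y, pred = function(eta) rep(theta + eta$X, nobs))
  })
  om <- matrix(omega2, 1, 1, dimnames = list("X", "X"))
  got <- bpcutoff:::laplace_marginal(subjects, "X", om,
                                     sigma_add = sigma, sigma_prop = 0)
  # closed form: y_i ~ N(theta * 1, sigma^2 I + omega2 J)
  exact <- -sum(vapply(subjects, function(s) {
    S <- diag(sigma^2, nobs) + omega2
    mvn_ll <- -0.5 * (nobs * log(2 * pi) +
                        determinant(S)$modulus +
                        t(s$y - theta) %*% solve(S) %*% (s$y - theta))
    as.numeric(mvn_ll)
  }, numeric(1)))
  expect_equal(got$nll, exact, tolerance = 1e-6)
})

test_that("mixed-effects fit recovers clearance and its BSV on a small
           synthetic study", {
  dat <- gen_iv_data(14, seed = 31)
  fit <- bp_nlme(dat, iv_spec(), starts = 1)
  truth <- attr(dat, "truth")
  geo_cl <- exp(mean(log(truth$params$CL)))
  expect_lt(abs(fit$theta$CL / geo_cl - 1), 0.10)
  expect_lt(abs(fit$theta$Vc / 106 - 1), 0.15)
  expect_gt(cv_percent(fit$omega["CL", "CL"]), 26.4 * 0.5)
  expect_lt(cv_percent(fit$omega["CL", "CL"]), 26.4 * 1.5)
  expect_true(all(fit$shrinkage >= 0 & fit$shrinkage <= 1))
  expect_equal(fit$BIC, -2 * fit$logLik + fit$n_par * log(fit$n_obs))
  expect_equal(unclass(stats::BIC(fit)), fit$BIC, ignore_attr = TRUE)
})

test_that("BIC comparison labels evidence strength and rejects
           mismatched datasets", {
  dat <- gen_iv_data(8, seed = 51)
  f1 <- bp_nlme(dat, iv_spec(), starts = 1)
  cmp_same <- compare_bic(f1, f1)
  expect_equal(cmp_same$preferred, "none")
  expect_equal(cmp_same$delta_bic, 0)
  dat2 <- gen_iv_data(8, seed = 52)
  expect_error(compare_bic(f1, bp_nlme(dat2, iv_spec(), starts = 1)),
               "same dataset")
})

test_that("shrinkage rises as per-subject information is thinned", {
  dat <- gen_iv_data(12, seed = 61)
  rich <- bp_nlme(dat, iv_spec(), starts = 1)
  obs <- (is.na(dat$AMT) | dat$AMT == 0)
  keep <- rep(TRUE, nrow(dat))
  # keep a single early observation per subject: it mostly reflects the
  # central volume, so the clearance eta must shrink toward zero
  for (id in unique(dat$ID)) {
    io <- which(obs & dat$ID == id)
    keep[setdiff(io, io[2])] <- FALSE
  }
  sparse <- bp_nlme(dat[keep, ], iv_spec(), starts = 1)
  expect_gt(sparse$shrinkage[["CL"]], rich$shrinkage[["CL"]])
})
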