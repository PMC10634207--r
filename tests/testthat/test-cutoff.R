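make_final_model <- function() read_population_model(final_model_file())

test_that("quantile estimator matches the documented type", {
  expect_equal(index_quantile(1:100, 10), 10.9)
  expect_equal(index_quantile(rep(7, 50), 10), 7)
  expect_equal(index_quantile(rep(7, 50), 90), 7)
  x <- rlnorm(500)
  expect_lte(index_quantile(x, 10), index_quantile(x, 50))
  expect_lte(index_quantile(x, 50), index_quantile(x, 90))
  expect_error(index_quantile(numeric(0), 10), "empty")
  expect_error(index_quantile(1:10, 0), "q must")
})

test_that("PTA and cutoff selection behave at the boundaries", {
  m <- matrix(c(100, 90, 80, 75, 60, 10), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, paste0("MIC_", c(0.125, 0.25, 0.5))))
  pta <- pta_curve(m, 72)
  expect_equal(unname(pta), c(1, 0.5, 0.5))
  # ties at exactly the target count as attainment
  expect_equal(unname(pta_curve(matrix(72, 3, 1), 72)), 1)
  expect_equal(pkpd_cutoff(c(0.125, 0.25, 0.5), c(1, 0.95, 0.2)), 0.25)
  expect_true(is.na(pkpd_cutoff(c(0.125, 0.25), c(0.5, 0.1))))
})

test_that("zero-variability population collapses to the typical horse", {
  mod <- make_final_model()
  mod0 <- population_model(theta = mod$theta, omega = NULL,
                           covariates = mod$covariates,
                           residual = mod$residual, fu = mod$fu,
                           absorption = mod$absorption)
  sc <- scenario("typical", mod0, regimen_shorthand(12.36, 24, 3, "im"),
                 "procaine_france", "France", n_sim = 8, seed = 1)
  mc <- monte_carlo_indices(sc, index = "fauc_mic")
  expect_equal(max(mc$fauc) - min(mc$fauc), 0)
  # typical-horse fAUC equals the analytic value truncated at 72 h
  pr <- simulate_conc(disposition_params(Vc = 106, V2 = 46.3, V3 = 50.4,
                                         CL = 481, CL2 = 126, CL3 = 25),
                      mod$absorption$procaine_france,
                      regimen_shorthand(12.36, 24, 3, "im"))
  expect_equal(mc$fauc[1], f_auc(pr, fu = 0.4, upper = 72),
               tolerance = 1e-9)
  # with omega = 0 the cutoff is the deterministic threshold MIC
  r <- run_cutoff(sc, "fauc_mic", 72, mc = mc)
  det_cut <- max(sc$mic_grid[mc$fauc[1] / sc$mic_grid >= 72])
  expect_equal(r$cutoff, det_cut)
})

test_that("Monte Carlo runs are seed-reproducible and PTA is monotone", {
  mod <- make_final_model()
  sc <- scenario("rep", mod, regimen_shorthand(12.36, 24, 3, "im"),
                 "procaine_france", "France", n_sim = 300, seed = 99)
  mc1 <- monte_carlo_indices(sc)
  mc2 <- monte_carlo_indices(sc)
  expect_identical(mc1$fauc_mic, mc2$fauc_mic)
  expect_identical(mc1$ft_hours, mc2$ft_hours)
  for (pdt in c(72, 21.6, 28.8)) {
    vals <- if (pdt == 72) mc1$fauc_mic else mc1$ft_hours
    expect_true(all(diff(pta_curve(vals, pdt)) <= 0))
  }
})

test_that("the Monte Carlo fAUC mean matches the log-normal moment", {
  mod <- make_final_model()
  sc <- scenario("mom", mod, regimen_shorthand(12.36, 24, 3, "im"),
                 "procaine_france", "France", n_sim = 4000, seed = 5)
  mc <- monte_carlo_indices(sc, index = "fauc_mic")
  # fAUC is driven by 1/CL: E[1/CL] = exp(omega^2/2) / CL_tv. The 72-h
  # truncation couples weakly to Vc, so allow 3 Monte-Carlo SEs + 2%.
  om2 <- omega_from_cv(26.4)
  pr <- simulate_conc(disposition_params(Vc = 106, V2 = 46.3, V3 = 50.4,
                                         CL = 481, CL2 = 126, CL3 = 25),
                      mod$absorption$procaine_france,
                      regimen_shorthand(12.36, 24, 3, "im"))
  expected <- f_auc(pr, fu = 0.4, upper = 72) * exp(om2 / 2)
  mc_se <- stats::sd(mc$fauc) / sqrt(length(mc$fauc))
  expect_lt(abs(mean(mc$fauc) - expected),
            3 * mc_se + 0.02 * expected)
})

test_that("empirical PTA matches the analytic log-normal tail in the
           1-compartment fAUC case", {
  # 1-cpt, BSV on CL only: fAUC = fu*D/CL exactly, CL log-normal
  # fast absorption so the 72-h truncation is negligible and the
  # closed-form log-normal tail applies
  m1 <- population_model(theta = list(Vc = 100, V2 = 0, V3 = 0, CL = 481,
                                      CL2 = 0, CL3 = 0),
                         omega = c(CL = 26.4),
                         fu = 0.4)
  sc <- scenario("lognormal", m1, regimen_shorthand(12.36, 24, 3, "im"),
                 absorption_scheme("first_order", Ka = 2, F = 1),
                 "any", n_sim = 4000, seed = 17)
  mc <- monte_carlo_indices(sc, index = "fauc_mic")
  om2 <- omega_from_cv(26.4)
  fauc_inf <- 0.4 * 3 * 12.36 / 0.481
  for (mic in c(0.25, 0.375)) {
    # P(fAUC_inf/MIC >= 72), ignoring the small 72-h truncation
    p_analytic <- stats::pnorm((log(fauc_inf / (72 * mic))) /
                                 sqrt(om2))
    p_emp <- pta_curve(mc$fauc_mic, 72)[[paste0("MIC_", mic)]]
    se <- sqrt(p_analytic * (1 - p_analytic) / 4000)
    expect_lt(abs(p_emp - p_analytic), 2 * se + 0.02)
  }
})

test_that("cutoff is non-decreasing in dose", {
  mod <- make_final_model()
  cuts <- vapply(c(12.36, 24.72), function(dose) {
    sc <- scenario(paste(dose), mod,
                   regimen_shorthand(dose, 24, 3, "im"),
                   "procaine_france", "France", n_sim = 800, seed = 3)
    run_cutoff(sc, "fauc_mic", 72)$cutoff
  }, numeric(1))
  expect_true(cuts[2] >= cuts[1])
})

test_that("scenario library covers the simulated regimens coherently", {
  mod <- make_final_model()
  lib <- scenario_library(mod, n_sim = 10, seed = 1)
  expect_true(all(c("procaine_france_q24", "sodium_im_q12", "cri_12.36",
                    "iv_bolus_q6", "duplocilline", "penethamate") %in%
                    names(lib)))
  # daily benzylpenicillin load of the standard regimens is 12.36 mg/kg
  expect_equal(sum(lib$procaine_france_q24$regimen$events$amount), 37.08)
  expect_equal(lib$cri_12.36$regimen$events$duration, 24)
  expect_equal(lib$duplocilline$regimen$t_end, 96)
  expect_equal(lib$penethamate$regimen$events$amount,
               c(11.91, 5.96, 5.96))
})
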