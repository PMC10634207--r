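test_that("one-compartment bolus matches the closed form exactly", {
  d1 <- disposition_params(Vc = 100, CL = 100)
  reg <- regimen_shorthand(10, 24, 1, route = "iv_bolus")
  pr <- simulate_conc(d1, absorption_scheme("iv_bolus"), reg)
  expect_equal(pr$conc, 10 / 0.1 * exp(-pr$time), tolerance = 1e-12)
})

test_that("three-compartment run with CL2 = CL3 = 0 equals the 1-cpt form", {
  d <- disposition_params(Vc = 100, V2 = 50, V3 = 50, CL = 100)
  reg <- regimen_shorthand(10, 24, 1, route = "iv_bolus")
  pr <- simulate_conc(d, absorption_scheme("iv_bolus"), reg)
  expect_equal(pr$conc, 10 / 0.1 * exp(-pr$time), tolerance = 1e-10)
})

test_that("constant-rate infusion reaches the Rate/CL plateau", {
  d <- france_disposition()
  reg <- regimen_shorthand(12.36, 24, 1, route = "iv_infusion",
                           infusion_h = 24)
  pr <- simulate_conc(d, absorption_scheme("iv_infusion"), reg)
  css <- (12.36 / 24) / 0.481
  expect_equal(pr$conc[pr$time == 24], css, tolerance = 1e-5)
  expect_equal(round(css, 4), 1.0707)
})

test_that("mass balance AUCinf = F * total dose / CL for every scheme", {
  d <- france_disposition()
  cases <- list(
    list(absorption_scheme("iv_bolus"),
         regimen_shorthand(12.36, 6, 4, "iv_bolus"), 1, 4 * 12.36),
    list(absorption_scheme("iv_infusion"),
         regimen_shorthand(12.36, 24, 1, "iv_infusion", infusion_h = 24),
         1, 12.36),
    list(procaine_france_scheme(),
         regimen_shorthand(12.36, 24, 3, "im"), 1, 3 * 12.36),
    list(absorption_scheme("sequential_dual_lag", Ka1 = 1 / 0.976,
                           Ka2 = 1 / 4.03, Tlag = 0.471, F = 0.891),
         regimen_shorthand(14.07, 12, 7, "im", t_end = 84),
         0.891, 7 * 14.07),
    list(absorption_scheme("parallel_dual", Ka1 = 1 / 12.1, F1 = 0.822,
                           Ka2 = 1 / 107, F2 = 1, p = 0.5),
         regimen_shorthand(12.36, 48, 2, "im", t_end = 96),
         0.5 * 0.822 + 0.5 * 1, 2 * 12.36),
    list(absorption_scheme("per_site_sequential", Ka1 = 0.5,
                           Ka2 = 1 / 45, Tlag = 0.5, F = 0.688),
         regimen_shorthand(11.91, 24, 3, "im"), 0.688, 3 * 11.91))
  for (cs in cases) {
    pr <- simulate_conc(d, cs[[1]], cs[[2]])
    expect_equal(auc_profile(pr, Inf), cs[[3]] * cs[[4]] / 0.481,
                 tolerance = 1e-6)
  }
})

test_that("superposition holds: multi-dose equals sum of single doses", {
  d <- france_disposition()
  sch <- procaine_france_scheme()
  grid <- seq(0, 72, by = 0.25)
  multi <- simulate_conc(d, sch, regimen_shorthand(12.36, 24, 3, "im"),
                         grid = grid)
  singles <- lapply(c(0, 24, 48), function(t0) {
    ev <- dose_event(t0, 12.36, "im")
    simulate_conc(d, sch, regimen(ev, t_end = 72), grid = grid)
  })
  summed <- Reduce(`+`, lapply(singles, `[[`, "conc"))
  expect_equal(multi$conc, summed, tolerance = 1e-8)
})

test_that("closed-form profiles agree with a stiff ODE solver", {
  skip_if_not_installed("deSolve")
  d <- france_disposition()
  times <- c(0.5, 1, 2, 4, 8, 12, 24, 30, 48, 60, 72)
  # single first-order input
  sch1 <- procaine_france_scheme()
  ev1 <- data.frame(time = c(0, 24, 48), amount = 12.36, route = "im",
                    duration = 0)
  ref1 <- ode_reference(d, sch1, ev1, times)
  got1 <- bpcutoff:::predict_conc(d, sch1, ev1, times)
  expect_equal(got1, ref1, tolerance = 1e-7)
  # rate-switching sequential input with lag
  sch2 <- absorption_scheme("sequential_dual_lag", Ka1 = 1 / 0.976,
                            Ka2 = 1 / 4.03, Tlag = 0.471, F = 0.891)
  ev2 <- data.frame(time = c(0, 12), amount = 14.07, route = "im",
                    duration = 0)
  ref2 <- ode_reference(d, sch2, ev2, times[times <= 24])
  got2 <- bpcutoff:::predict_conc(d, sch2, ev2, times[times <= 24])
  expect_equal(got2, ref2, tolerance = 1e-7)
})

test_that("flip-flop: terminal slope of a slow first-order input is Ka", {
  d <- france_disposition()
  sch <- procaine_france_scheme()   # MAT 21.46 h >> MRT_iv 0.42 h
  reg <- regimen(dose_event(0, 12.36, "im"), t_end = 400)
  pr <- simulate_conc(d, sch, reg, grid = seq(0, 400, by = 1))
  late <- pr$time >= 250
  slope <- -stats::coef(stats::lm(log(pr$conc[late]) ~ pr$time[late]))[[2]]
  expect_equal(slope, 1 / 21.46, tolerance = 1e-4)
  expect_lt(slope, min(eigen_rates(d)))  # not the IV terminal rate
})

test_that("grids that miss dose times or negative inputs are rejected", {
  d <- france_disposition()
  reg <- regimen_shorthand(12.36, 24, 3, "im")
  expect_error(simulate_conc(d, procaine_france_scheme(), reg,
                             grid = seq(0, 30, by = 0.5)),
               "cover")
  expect_error(regimen(dose_event(80, 1, "im"), t_end = 72), "t_end")
  expect_error(dose_event(0, 5, "iv_infusion", duration = 0), "duration")
})

test_that("dual-lag absorption with an explicit fraction split integrates
           to the same total exposure as rate switching", {
  d <- france_disposition()
  reg <- regimen_shorthand(14.07, 12, 7, "im", t_end = 84)
  rate_sw <- absorption_scheme("sequential_dual_lag", Ka1 = 1 / 0.976,
                               Ka2 = 1 / 4.03, Tlag = 0.471, F = 0.891)
  frac <- absorption_scheme("sequential_dual_lag", Ka1 = 1 / 0.976,
                            Ka2 = 1 / 4.03, Tlag = 0.471, F = 0.891,
                            frac1 = 0.3)
  a1 <- auc_profile(simulate_conc(d, rate_sw, reg), Inf)
  a2 <- auc_profile(simulate_conc(d, frac, reg), Inf)
  expect_equal(a1, a2, tolerance = 1e-8)  # same bioavailable mass
})
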