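# Shared fixtures: the published IV disposition constants and the
# packaged model files, plus small builders used across tests.

france_disposition <- function() {
  disposition_params(Vc = 106, V2 = 46.3, V3 = 50.4,
                     CL = 481, CL2 = 126, CL3 = 25.0)
}

iv_model_file <- function() {
  system.file("extdata", "table4_iv.yaml", package = "bpcutoff")
}

final_model_file <- function() {
  system.file("extdata", "table6_final.yaml", package = "bpcutoff")
}

procaine_france_scheme <- function() {
  absorption_scheme("first_order", Ka = 1 / 21.46, F = 1)
}

# random valid disposition parameter draws for property-style tests
random_disposition <- function(seed) {
  set.seed(seed)
  disposition_params(Vc = stats::runif(1, 50, 500),
                     V2 = stats::runif(1, 20, 300),
                     V3 = stats::runif(1, 20, 300),
                     CL = stats::runif(1, 100, 900),
                     CL2 = stats::runif(1, 10, 300),
                     CL3 = stats::runif(1, 5, 100))
}

# deSolve reference: numeric ODE solution of the disposition system under
# a first-order (optionally rate-switching dual) depot input; independent
# of the closed-form machinery under test
ode_reference <- function(disposition, scheme, events, times) {
  k <- micro_constants(disposition)
  Vc_L <- disposition$Vc / 1000
  deriv <- function(t, y, parms) {
    ka_t <- function(ev_time) {
      if (scheme$variant == "first_order") {
        scheme$Ka
      } else if (t < ev_time + scheme$Tlag) scheme$Ka1 else scheme$Ka2
    }
    # depot states: one per dose event; y = c(depots, central, p2, p3)
    nd <- nrow(events)
    depots <- y[seq_len(nd)]
    a1 <- y[nd + 1]; a2 <- y[nd + 2]; a3 <- y[nd + 3]
    ddep <- numeric(nd)
    input <- 0
    for (i in seq_len(nd)) {
      if (t >= events$time[i]) {
        kai <- ka_t(events$time[i])
        ddep[i] <- -kai * depots[i]
        input <- input + kai * depots[i]
      }
    }
    da1 <- input - (k[["k10"]] + k[["k12"]] + k[["k13"]]) * a1 +
      k[["k21"]] * a2 + k[["k31"]] * a3
    da2 <- k[["k12"]] * a1 - k[["k21"]] * a2
    da3 <- k[["k13"]] * a1 - k[["k31"]] * a3
    list(c(ddep, da1, da2, da3))
  }
  nd <- nrow(events)
  run_times <- sort(unique(c(0, events$time, times)))
  y0 <- c(rep(0, nd), 0, 0, 0)
  out <- NULL
  # integrate piecewise between dose times, loading depots at each dose
  seg_starts <- c(0, events$time[events$time > 0])
  seg_bounds <- sort(unique(c(seg_starts, max(run_times))))
  state <- y0
  state[seq_len(nd)][events$time == 0] <-
    scheme$F * events$amount[events$time == 0]
  sol <- list()
  for (s in seq_len(length(seg_bounds) - 1)) {
    tt <- sort(unique(c(seg_bounds[s], run_times[run_times >= seg_bounds[s] &
                                                   run_times <= seg_bounds[s + 1]],
                        seg_bounds[s + 1])))
    o <- deSolve::lsoda(state, tt, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
    sol[[s]] <- o
    state <- as.numeric(o[nrow(o), -1])
    newdose <- which(abs(events$time - seg_bounds[s + 1]) < 1e-12)
    if (length(newdose)) {
      state[newdose] <- state[newdose] +
        scheme$F * events$amount[newdose]
    }
  }
  all <- do.call(rbind, sol)
  conc <- all[, nd + 2] / Vc_L
  approx(all[, 1], conc, xout = times, ties = "ordered")$y
}
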