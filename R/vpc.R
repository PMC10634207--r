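# Visual predictive check: replicate the observed study design under the
# fitted model (BSV + residual error) and compare observed quantiles per
# time bin against simulation-based confidence bands.

#' Visual predictive check
#'
#' Simulates `n_rep` replicates of the observed dataset's design (same
#' subjects, dose events and sampling times; fresh random effects and
#' residual errors per replicate), computes per-time-bin quantiles of
#' observed and simulated concentrations, and returns the simulated
#' confidence band for each quantile.
#'
#' @param model a [population_model()] whose `absorption` list covers the
#'   dataset's formulations (FORM values; `"iv"` maps to an IV bolus,
#'   infusion rows are detected via RATE).
#' @param data event-table data frame with observed DV values.
#' @param n_rep number of replicate studies (default 500).
#' @param probs quantiles to track (default 10/50/90%; use
#'   `c(0.2, 0.5, 0.8)` for the 20/50/80 variant).
#' @param ci confidence level of the simulated bands.
#' @param bins number of time bins when binning is needed; observations
#'   sharing nominal times are binned by unique time when there are no
#'   more than `bins` distinct times, otherwise by quantile cuts. Empty
#'   bins are merged with a warning.
#' @param seed integer seed.
#' @return object of class `"bp_vpc"`: data frame with one row per bin and
#'   quantile, columns `bin_mid`, `prob`, `observed`, `sim_lo`, `sim_med`,
#'   `sim_hi`.
#' @export
vpc <- function(model, data, n_rep = 500, probs = c(0.1, 0.5, 0.9),
                ci = 0.90, bins = 8, seed = 1L) {
  stopifnot(inherits(model, "population_model"))
  set.seed(seed)
  subs <- split(data, data$ID, drop = TRUE)
  subs <- lapply(subs, function(d) {
    d <- d[order(d$TIME), ]
    obs <- d[(is.na(d$AMT) | d$AMT == 0) & !is.na(d$DV), , drop = FALSE]
    list(source = d$SOURCE[1], form = obs$FORM[1],
         events = subject_events(d), times = obs$TIME, y = obs$DV)
  })
  all_times <- unlist(lapply(subs, `[[`, "times"))
  all_obs <- unlist(lapply(subs, `[[`, "y"))
  ut <- sort(unique(all_times))
  if (length(ut) <= bins) {
    breaks <- c(ut - diff(c(0, ut)) / 2, max(ut) + 1)
  } else {
    breaks <- unique(stats::quantile(all_times, seq(0, 1, length.out =
                                                      bins + 1)))
    breaks[1] <- breaks[1] - 1e-9
    breaks[length(breaks)] <- breaks[length(breaks)] + 1e-9
    if (length(breaks) < bins + 1) {
      warning("empty or duplicate time bins merged")
    }
  }
  bin_of <- function(tt) findInterval(tt, breaks, rightmost.closed = TRUE)
  bin_id <- bin_of(all_times)
  bin_mid <- tapply(all_times, bin_id, stats::median)

  scheme_for <- function(form) {
    if (form == "iv") {
      absorption_scheme("iv_bolus")
    } else if (form %in% names(model$absorption)) {
      model$absorption[[form]]
    } else {
      stop("model has no absorption scheme for formulation '", form, "'")
    }
  }

  qt_per_bin <- function(values) {
    vapply(split(values, bin_id), stats::quantile, numeric(length(probs)),
           probs = probs, type = 7)
  }
  obs_q <- qt_per_bin(all_obs)

  sim_q <- array(NA_real_, c(length(probs), length(bin_mid), n_rep))
  for (r in seq_len(n_rep)) {
    sim_vals <- unlist(lapply(subs, function(sub) {
      pars <- sample_individuals(model, 1, sub$source)
      ind <- individual_realization(pars, 1, scheme_for(sub$form))
      cc <- predict_conc(ind$disposition, ind$absorption, sub$events,
                         sub$times)
      as.numeric(residual_perturb(cc, model$residual))
    }))
    sim_q[, , r] <- qt_per_bin(sim_vals)
  }
  a <- (1 - ci) / 2
  out <- do.call(rbind, lapply(seq_along(probs), function(k) {
    data.frame(bin_mid = as.numeric(bin_mid), prob = probs[k],
               observed = obs_q[k, ],
               sim_lo = apply(sim_q[k, , , drop = FALSE], 2, stats::quantile,
                              probs = a),
               sim_med = apply(sim_q[k, , , drop = FALSE], 2,
                               stats::quantile, probs = 0.5),
               sim_hi = apply(sim_q[k, , , drop = FALSE], 2, stats::quantile,
                              probs = 1 - a))
  }))
  rownames(out) <- NULL
  structure(out, class = c("bp_vpc", "data.frame"), n_rep = n_rep, ci = ci)
}

#' @export
plot.bp_vpc <- function(x, log = "y", xlab = "Time (h)",
                        ylab = "Concentration (mg/L)", ...) {
  pr <- unique(x$prob)
  ylim <- range(c(x$observed, x$sim_lo, x$sim_hi), finite = TRUE)
  if (log == "y") ylim[1] <- max(ylim[1], 1e-4)
  graphics::plot(NA, xlim = range(x$bin_mid), ylim = ylim, log = log,
                 xlab = xlab, ylab = ylab, ...)
  for (p in pr) {
    d <- x[x$prob == p, ]
    graphics::polygon(c(d$bin_mid, rev(d$bin_mid)),
                      pmax(c(d$sim_lo, rev(d$sim_hi)), 1e-6),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(d$bin_mid, d$observed, col = "red", lwd = 2)
    graphics::lines(d$bin_mid, d$sim_med, col = "black", lty = 2)
  }
  invisible(x)
}
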