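# Synthetic multi-country study generation: the packaged designs emulate
# the structure of the five contributing datasets (arms, crossover
# occasions, doses, LOQs), so that every pipeline stage is testable
# without any external data. Sampling schedules are plausible stand-ins
# (dense early sampling plus troughs and a rich window after the last
# dose) and are overridable per design.

#' Packaged study designs
#'
#' Returns the library of synthetic study designs: a French 3 x 3
#' crossover (procaine BP, procaine + benzathine BP, penethamate) followed
#' by a single IV occasion; a Swedish single-dose IV arm; a Swedish 2 x 2
#' IM crossover (procaine BP q24h x 4, sodium BP q12h x 7); a Japanese
#' single-dose IM arm; a USA1 arm (two IV boluses 6 h apart, then IM
#' procaine BP, observations truncated 12 h after the IM dose); and a USA2
#' single-dose IV arm. Doses are in mg/kg of benzylpenicillin and LOQs in
#' mg/L. Together the designs contribute 63 rich profiles.
#'
#' @return named list of `"study_design"` objects; each has `label`,
#'   `source` (covariate label), `n` (subjects), `lloq` (mg/L), and
#'   `occasions` — a list of occasions, each with `form` (absorption
#'   scheme name, or `"iv"`), `events` (dose event table) and `times`
#'   (sampling times, h).
#' @export
design_library <- function() {
  iv_times <- c(0.083, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8)
  occ <- function(form, events, times) {
    list(form = form, events = events, times = times)
  }
  iv_bolus_ev <- function(dose) dose_event(0, dose, "iv_bolus")
  im_series <- function(dose, interval, n) {
    do.call(rbind, lapply((seq_len(n) - 1) * interval, dose_event,
                          amount = dose, route = "im"))
  }
  designs <- list(
    france = structure(list(
      label = "France: 3x3 crossover (procaine, procaine+benzathine, penethamate) + IV",
      source = "France", n = 6L, lloq = 0.010,
      occasions = list(
        occ("procaine_france", im_series(10, 24, 3),
            c(0.5, 1, 2, 4, 8, 12, 23.5, 24.5, 26, 32, 47.5,
              48.5, 50, 52, 56, 60, 72, 96)),
        occ("duplocilline", im_series(12.4, 48, 2),
            c(0.5, 1, 2, 4, 8, 12, 24, 47.5, 48.5, 50, 56, 72, 96, 120)),
        occ("penethamate",
            rbind(dose_event(0, 11.91, "im"),
                  dose_event(24, 5.96, "im"),
                  dose_event(48, 5.96, "im")),
            c(0.5, 1, 2, 4, 8, 12, 23.5, 24.5, 32, 47.5, 48.5,
              52, 60, 72, 96)),
        occ("iv", iv_bolus_ev(12.36), iv_times))),
      class = "study_design"),
    sweden_iv = structure(list(
      label = "Sweden: single IV sodium BP",
      source = "Sweden", n = 4L, lloq = 0.0055,
      occasions = list(occ("iv", iv_bolus_ev(20.78), iv_times))),
      class = "study_design"),
    sweden_im = structure(list(
      label = "Sweden: 2x2 IM crossover, procaine q24h x 4 and sodium q12h x 7",
      source = "Sweden_IM", n = 8L, lloq = 0.0055,
      occasions = list(
        occ("procaine_sweden", im_series(11.80, 24, 4),
            c(0.5, 1, 2, 4, 8, 12, 23.5, 24.5, 48, 71.5, 72.5,
              74, 78, 84, 96, 120)),
        occ("sodium_im", im_series(14.07, 12, 7),
            c(0.25, 0.5, 1, 2, 4, 6, 8, 11.5, 24, 48, 71.5,
              72.25, 72.5, 73, 74, 76, 78, 80, 84)))),
      class = "study_design"),
    japan = structure(list(
      label = "Japan: single IM procaine BP",
      source = "Japan", n = 6L, lloq = 0.030,
      occasions = list(
        occ("procaine_japan", im_series(5.617, 24, 1),
            c(0.25, 0.5, 1, 2, 4, 6, 8, 12, 24, 36, 48, 72, 96)))),
      class = "study_design"),
    usa1 = structure(list(
      label = "USA1: IV potassium BP x 2 (q6h) then IM procaine BP, truncated 12 h post-IM",
      source = "USA1", n = 7L, lloq = 0.010,
      occasions = list(
        occ("procaine_usa1",
            rbind(dose_event(0, 12.36, "iv_bolus"),
                  dose_event(6, 12.36, "iv_bolus"),
                  dose_event(12, 12.36, "im")),
            c(0.25, 1, 3, 6.25, 7, 9, 12.5, 14, 16, 20, 24)))),
      class = "study_design"),
    usa2 = structure(list(
      label = "USA2: single IV potassium BP",
      source = "USA2", n = 6L, lloq = 0.040,
      occasions = list(occ("iv", iv_bolus_ev(12.36), iv_times))),
      class = "study_design")
  )
  designs
}

#' @export
print.study_design <- function(x, ...) {
  cat(x$label, "\n")
  cat(sprintf("  n = %d subjects, LLOQ = %g mg/L, %d occasion(s)\n",
              x$n, x$lloq, length(x$occasions)))
  invisible(x)
}

#' Generate a synthetic study dataset
#'
#' For each subject: draw the random effects once (shared across crossover
#' occasions — no inter-occasion variability, matching the population
#' model), simulate each occasion's profile at the design's sampling
#' times, add additive + proportional residual error, and flag
#' observations below the design's LLOQ. Emits the estimation-module event
#' table plus a ground-truth sidecar for recovery experiments.
#'
#' @param model a [population_model()] whose `absorption` list covers the
#'   design's formulations.
#' @param design a `"study_design"` from [design_library()].
#' @param seed integer seed.
#' @param censor drop BLOQ rows instead of flagging them (default keeps
#'   them with `BLQ = 1`).
#' @return data frame with columns `ID`, `SOURCE`, `FORM`, `OCC`, `TIME`,
#'   `AMT`, `RATE`, `DV`, `BLQ`, `LLOQ`; dose rows have `AMT > 0` and
#'   `DV = NA`. The attribute `"truth"` is a list with the sampled
#'   individual parameters, the random-effect matrix, the noiseless
#'   concentrations (`conc_true`) and the seed.
#' @export
generate_study <- function(model, design, seed = 1L, censor = FALSE) {
  stopifnot(inherits(model, "population_model"),
            inherits(design, "study_design"))
  for (o in design$occasions) {
    if (o$form != "iv" && !o$form %in% names(model$absorption)) {
      stop("model lacks an absorption scheme for formulation '",
           o$form, "'")
    }
  }
  set.seed(seed)
  pars <- sample_individuals(model, design$n, design$source)
  rows <- list()
  truth_conc <- list()
  for (i in seq_len(design$n)) {
    id <- paste0(design$source, "_", i)
    for (k in seq_along(design$occasions)) {
      o <- design$occasions[[k]]
      scheme <- if (o$form == "iv") {
        absorption_scheme("iv_bolus")
      } else {
        model$absorption[[o$form]]
      }
      ind <- individual_realization(pars, i, scheme)
      cc <- predict_conc(ind$disposition, ind$absorption, o$events,
                         o$times)
      dv <- residual_perturb(cc, model$residual)
      blq <- as.integer(dv < design$lloq)
      dose_rows <- data.frame(
        ID = id, SOURCE = design$source, FORM = o$form, OCC = k,
        TIME = o$events$time, AMT = o$events$amount,
        RATE = ifelse(o$events$duration > 0,
                      o$events$amount / o$events$duration, 0),
        DV = NA_real_, BLQ = 0L, LLOQ = design$lloq)
      obs_rows <- data.frame(
        ID = id, SOURCE = design$source, FORM = o$form, OCC = k,
        TIME = o$times, AMT = 0, RATE = 0,
        DV = as.numeric(dv), BLQ = blq, LLOQ = design$lloq)
      rows[[length(rows) + 1]] <- rbind(dose_rows, obs_rows)
      truth_conc[[paste(id, k, sep = ".")]] <- cc
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$ID, out$OCC, out$TIME, -out$AMT), ]
  rownames(out) <- NULL
  if (censor) {
    out <- out[out$BLQ == 0L, , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "truth") <- list(params = pars,
                             eta = attr(pars, "eta"),
                             conc_true = truth_conc,
                             seed = seed, source = design$source)
  out
}
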