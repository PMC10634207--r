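# Monte Carlo engine: simulate a virtual population, compute PK/PD index
# distributions, PTA curves, and the PK/PD cutoff (highest MIC for which
# 90% of horses attain the pharmacodynamic target).

MIC_GRID_DEFAULT <- c(0.0625, 0.125, 0.25, 0.375, 0.5, 1, 2)

#' Define a simulation scenario
#'
#' Bundles everything one Monte Carlo run needs: the population model, the
#' covariate source, the absorption scheme, the dosing regimen, the MIC
#' grid, the number of simulated subjects and the seed.
#'
#' @param label scenario name (used in outputs).
#' @param model a [population_model()].
#' @param regimen a [regimen()].
#' @param absorption an [absorption_scheme()], or the name of a scheme
#'   stored in `model$absorption`.
#' @param source covariate source label (e.g. `"France"`).
#' @param mic_grid ascending MIC grid (mg/L); defaults to the standard
#'   exploration grid 0.0625-2 mg/L.
#' @param n_sim number of simulated subjects (default 5000).
#' @param seed integer seed.
#' @param dt simulation grid spacing (h).
#' @return object of class `"scenario"`.
#' @export
scenario <- function(label, model, regimen, absorption,
                     source = "reference", mic_grid = MIC_GRID_DEFAULT,
                     n_sim = 5000, seed = 1L, dt = 0.05) {
  stopifnot(inherits(model, "population_model"), inherits(regimen, "regimen"))
  if (is.character(absorption)) {
    if (!absorption %in% names(model$absorption)) {
      stop("model has no absorption scheme named '", absorption, "'")
    }
    absorption <- model$absorption[[absorption]]
  }
  stopifnot(inherits(absorption, "absorption_scheme"))
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (is.unsorted(mic_grid, strictly = TRUE)) {
    stop("mic_grid must be sorted ascending")
  }
  structure(list(label = label, model = model, regimen = regimen,
                 absorption = absorption, source = source,
                 mic_grid = mic_grid, n_sim = n_sim, seed = seed, dt = dt),
            class = "scenario")
}

# build an individual's disposition/absorption from one sampled row
individual_realization <- function(pars, i, template) {
  disp <- disposition_params(Vc = pars$Vc[i], V2 = pars$V2[i],
                             V3 = pars$V3[i], CL = pars$CL[i],
                             CL2 = pars$CL2[i], CL3 = pars$CL3[i])
  a <- template
  for (nm in intersect(names(a), names(pars))) {
    if (nm != "variant") a[[nm]] <- pars[[nm]][i]
  }
  list(disposition = disp, absorption = a)
}

#' Monte Carlo index distributions for a scenario
#'
#' Draws each virtual horse's parameters once, simulates its free
#' concentration profile once, and computes both PK/PD indices for every
#' MIC on that shared profile (reusing one draw across MICs is both faster
#' and variance-reducing). Reproducible under a fixed seed.
#'
#' @param scen a [scenario()].
#' @param index which indices to compute: subset of
#'   `c("fauc_mic", "ft_mic")`. fT>MIC requires dense grid evaluation and
#'   is the slower of the two.
#' @return list with elements `fauc` (length-`n_sim` vector of free AUC
#'   over the window, mg h/L), `fauc_mic` (n_sim x MIC matrix, h),
#'   `ft_hours` (n_sim x MIC matrix of cumulative hours above MIC, present
#'   only when requested), `mic_grid`, `window`, `scenario`.
#' @export
monte_carlo_indices <- function(scen,
                                index = c("fauc_mic", "ft_mic")) {
  stopifnot(inherits(scen, "scenario"))
  index <- match.arg(index, several.ok = TRUE)
  pars <- sample_individuals(scen$model, scen$n_sim, scen$source,
                             seed = scen$seed)
  window <- scen$regimen$t_end
  mic <- scen$mic_grid
  need_ft <- "ft_mic" %in% index
  fu <- scen$model$fu
  grid <- seq(0, window, by = scen$dt)
  if (grid[length(grid)] < window) grid <- c(grid, window)
  fauc <- numeric(scen$n_sim)
  ft <- if (need_ft) {
    matrix(NA_real_, scen$n_sim, length(mic),
           dimnames = list(NULL, paste0("MIC_", mic)))
  }
  events <- scen$regimen$events
  for (i in seq_len(scen$n_sim)) {
    ind <- individual_realization(pars, i, scen$absorption)
    terms <- tryCatch(
      conc_terms(ind$disposition, ind$absorption, events),
      error = function(e) {
        stop("simulation failed for subject ", i, ": ",
             conditionMessage(e))
      })
    fauc[i] <- fu * integrate_terms(terms, window)
    if (need_ft) {
      cc <- fu * eval_terms(terms, grid)
      for (j in seq_along(mic)) {
        ft[i, j] <- time_above(grid, cc, mic[j], 0, window)
      }
    }
  }
  out <- list(fauc = fauc,
              fauc_mic = outer(fauc, mic, "/"),
              mic_grid = mic, window = window, scenario = scen$label)
  colnames(out$fauc_mic) <- paste0("MIC_", mic)
  if (need_ft) out$ft_hours <- ft
  out
}

#' Quantile of an index distribution
#'
#' Linear-interpolation order-statistic estimator (R's default type 7).
#' `q = 10` gives the Q10 value, the index value exceeded by 90% of
#' subjects ("90% quantile of interest").
#'
#' @param values non-empty numeric vector.
#' @param q percentile in (0, 100).
#' @export
index_quantile <- function(values, q) {
  if (length(values) == 0) stop("empty vector")
  if (any(q <= 0 | q >= 100)) stop("q must be in (0, 100)")
  unname(stats::quantile(values, q / 100, type = 7))
}

#' Probability of target attainment per MIC
#'
#' `PTA(MIC)` is the fraction of simulated subjects whose index value is at
#' least the pharmacodynamic target (ties at exactly the target count as
#' attainment). Non-increasing in MIC for both supported indices.
#'
#' @param index_matrix n_sim x MIC matrix of index values.
#' @param pdt pharmacodynamic target, in the same units as the index.
#' @return named vector of PTA values in \[0, 1\].
#' @export
pta_curve <- function(index_matrix, pdt) {
  colMeans(index_matrix >= pdt)
}

#' PK/PD cutoff from a PTA curve
#'
#' The highest MIC on the grid with PTA >= `target` (default 0.90,
#' equivalently Q10 of the index >= PDT). Returns `NA` when even the lowest
#' grid MIC fails ("below grid").
#'
#' @param mic_grid ascending MIC grid (mg/L).
#' @param pta PTA values matching `mic_grid`.
#' @param target attainment probability defining the cutoff.
#' @return the cutoff MIC (mg/L) or `NA_real_`.
#' @export
pkpd_cutoff <- function(mic_grid, pta, target = 0.90) {
  ok <- which(pta >= target)
  if (length(ok) == 0) {
    return(NA_real_)
  }
  mic_grid[max(ok)]
}

#' Run a full cutoff determination for one scenario
#'
#' Monte Carlo simulation, per-MIC Q10 and PTA, and cutoff selection for a
#' chosen PK/PD index and pharmacodynamic target.
#'
#' @param scen a [scenario()].
#' @param index `"fauc_mic"` (free AUC over MIC, h) or `"ft_mic"`
#'   (cumulative time free concentration exceeds MIC).
#' @param pdt pharmacodynamic target: hours for `fauc_mic` (e.g. 72 h over
#'   a 72-h treatment); for `ft_mic` either hours or, with
#'   `pdt_percent = TRUE`, a percentage of the treatment window (30 or 40
#'   are typical).
#' @param pdt_percent interpret `pdt` as % of the window (`ft_mic` only).
#' @param mc optionally, a precomputed [monte_carlo_indices()] result for
#'   this scenario (lets one simulation serve several PDTs/indices).
#' @return object of class `"bp_cutoff"`: list with the per-MIC `table`
#'   (MIC, Q10, PTA), `cutoff` (mg/L or NA), `quantiles` (percentiles 1-99
#'   per MIC), and run metadata.
#' @examples
#' \donttest{
#' mod <- read_population_model(
#'   system.file("extdata", "table6_final.yaml", package = "bpcutoff"))
#' sc <- scenario("procaine France q24h x 3", mod,
#'                regimen_shorthand(12.36, 24, 3, route = "im"),
#'                absorption = "procaine_france", source = "France",
#'                n_sim = 500, seed = 42)
#' run_cutoff(sc, index = "fauc_mic", pdt = 72)
#' }
#' @export
run_cutoff <- function(scen, index = c("fauc_mic", "ft_mic"), pdt,
                       pdt_percent = FALSE, mc = NULL) {
  index <- match.arg(index)
  if (pdt <= 0) stop("pdt must be > 0")
  if (is.null(mc)) {
    mc <- monte_carlo_indices(scen, index = index)
  }
  window <- mc$window
  pdt_h <- pdt
  if (index == "ft_mic" && pdt_percent) {
    pdt_h <- pdt / 100 * window
  }
  values <- if (index == "fauc_mic") mc$fauc_mic else mc$ft_hours
  if (is.null(values)) {
    stop("the supplied Monte Carlo result lacks the ", index, " index")
  }
  pta <- pta_curve(values, pdt_h)
  q10 <- apply(values, 2, index_quantile, q = 10)
  qs <- apply(values, 2, index_quantile, q = 1:99)
  cut <- pkpd_cutoff(mc$mic_grid, pta)
  structure(list(table = data.frame(MIC = mc$mic_grid, Q10 = q10, PTA = pta,
                                    row.names = NULL),
                 cutoff = cut, quantiles = qs, index = index,
                 pdt = pdt_h, window = window,
                 scenario = mc$scenario,
                 n_sim = nrow(values), seed = scen$seed),
            class = "bp_cutoff")
}

#' @export
print.bp_cutoff <- function(x, ...) {
  lab <- if (x$index == "fauc_mic") "fAUC/MIC" else "fT>MIC"
  cat("PK/PD cutoff determination -", x$scenario, "\n")
  cat(sprintf("  index %s, PDT %.4g h over %g h window, n = %d (seed %d)\n",
              lab, x$pdt, x$window, x$n_sim, x$seed))
  print(transform(x$table, Q10 = signif(Q10, 4)), row.names = FALSE)
  if (is.na(x$cutoff)) {
    cat("  PK/PD cutoff: below grid (PTA < 0.90 at the lowest MIC)\n")
  } else {
    cat("  PK/PD cutoff:", x$cutoff, "mg/L\n")
  }
  invisible(x)
}

#' @export
plot.bp_cutoff <- function(x, ...) {
  lab <- if (x$index == "fauc_mic") "fAUC/MIC" else "fT>MIC"
  graphics::plot(x$table$MIC, x$table$PTA, type = "b", log = "x",
                 ylim = c(0, 1), xlab = "MIC (mg/L)", ylab = "PTA",
                 main = paste0(x$scenario, " (", lab, ")"), ...)
  graphics::abline(h = 0.9, lty = 2)
  if (!is.na(x$cutoff)) graphics::abline(v = x$cutoff, lty = 3)
  invisible(x)
}

#' Packaged dosing-regimen scenario library
#'
#' Named scenarios encoding the simulated regimens: procaine BP once or
#' twice daily, doubled dose, sodium BP IM every 6/8/12 h, 24-h
#' constant-rate infusions, IV bolus series, the procaine/benzathine
#' combination (two doses 48 h apart over 96 h), and the penethamate SPC
#' regimen (11.91, then 5.96, 5.96 mg/kg daily).
#'
#' @param model a [population_model()] carrying the named absorption
#'   schemes (see [read_population_model()] and the packaged
#'   `table6_final.yaml`).
#' @param n_sim,seed passed to every [scenario()].
#' @return named list of scenarios.
#' @export
scenario_library <- function(model, n_sim = 5000, seed = 1L) {
  sc <- function(label, reg, absorb, source) {
    scenario(label, model, reg, absorb, source, n_sim = n_sim, seed = seed)
  }
  pen_events <- rbind(dose_event(0, 11.91, "im"),
                      dose_event(24, 5.96, "im"),
                      dose_event(48, 5.96, "im"))
  list(
    procaine_france_q24 = sc("procaine BP 12.36 mg/kg q24h x 3 (France)",
                             regimen_shorthand(12.36, 24, 3, "im"),
                             "procaine_france", "France"),
    procaine_france_q24_double = sc(
      "procaine BP 24.72 mg/kg q24h x 3 (France)",
      regimen_shorthand(24.72, 24, 3, "im"),
      "procaine_france", "France"),
    procaine_france_q12 = sc("procaine BP 12.36 mg/kg q12h x 6 (France)",
                             regimen_shorthand(12.36, 12, 6, "im"),
                             "procaine_france", "France"),
    procaine_sweden_q24 = sc("procaine BP 12.36 mg/kg q24h x 3 (Sweden)",
                             regimen_shorthand(12.36, 24, 3, "im"),
                             "procaine_sweden", "Sweden_IM"),
    procaine_japan_q24 = sc("procaine BP 12.36 mg/kg q24h x 3 (Japan)",
                            regimen_shorthand(12.36, 24, 3, "im"),
                            "procaine_japan", "Japan"),
    procaine_usa1_q24 = sc("procaine BP 12.36 mg/kg q24h x 3 (USA1)",
                           regimen_shorthand(12.36, 24, 3, "im"),
                           "procaine_usa1", "USA1"),
    sodium_im_q6 = sc("sodium BP IM 12.36 mg/kg q6h x 12",
                      regimen_shorthand(12.36, 6, 12, "im"),
                      "sodium_im", "Sweden_IM"),
    sodium_im_q8 = sc("sodium BP IM 12.36 mg/kg q8h x 9",
                      regimen_shorthand(12.36, 8, 9, "im"),
                      "sodium_im", "Sweden_IM"),
    sodium_im_q12 = sc("sodium BP IM 12.36 mg/kg q12h x 6",
                       regimen_shorthand(12.36, 12, 6, "im"),
                       "sodium_im", "Sweden_IM"),
    cri_12.36 = sc("24-h CRI, 12.36 mg/kg total (France)",
                   regimen_shorthand(12.36, 24, 1, "iv_infusion",
                                     infusion_h = 24),
                   absorption_scheme("iv_infusion"), "France"),
    cri_18.84 = sc("24-h CRI, 18.84 mg/kg total (France)",
                   regimen_shorthand(18.84, 24, 1, "iv_infusion",
                                     infusion_h = 24),
                   absorption_scheme("iv_infusion"), "France"),
    cri_24.72 = sc("24-h CRI, 24.72 mg/kg total (France)",
                   regimen_shorthand(24.72, 24, 1, "iv_infusion",
                                     infusion_h = 24),
                   absorption_scheme("iv_infusion"), "France"),
    iv_bolus_q6 = sc("IV bolus 12.36 mg/kg q6h x 4",
                     regimen_shorthand(12.36, 6, 4, "iv_bolus"),
                     absorption_scheme("iv_bolus"), "France"),
    duplocilline = sc("procaine + benzathine BP 12.36 mg/kg x 2, q48h",
                      regimen_shorthand(12.36, 48, 2, "im"),
                      "duplocilline", "France"),
    penethamate = sc("penethamate SPC regimen 11.91/5.96/5.96 mg/kg",
                     regimen(pen_events, t_end = 72),
                     "penethamate", "France")
  )
}
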