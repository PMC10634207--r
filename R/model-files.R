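# YAML/JSON model and regimen file input. Two model files ship with the
# package under inst/extdata: "table4_iv.yaml" (the IV disposition model
# with the full log-scale covariance matrix) and "table6_final.yaml" (the
# full model: disposition + per-formulation absorption schemes + the
# reported between-subject CVs as a diagonal covariance).

parse_absorption_entry <- function(e) {
  inv <- function(mat_h) 1 / mat_h
  v <- e$variant
  if (v == "first_order") {
    absorption_scheme("first_order",
                      Ka = if (!is.null(e$Ka)) e$Ka else inv(e$MAT_h),
                      F = e$F)
  } else if (v %in% c("sequential_dual_lag", "per_site_sequential")) {
    absorption_scheme(v,
                      Ka1 = if (!is.null(e$Ka1)) e$Ka1 else inv(e$MAT1_h),
                      Ka2 = if (!is.null(e$Ka2)) e$Ka2 else inv(e$MAT2_h),
                      Tlag = e$Tlag, F = e$F, frac1 = e$frac1)
  } else if (v == "parallel_dual") {
    absorption_scheme("parallel_dual",
                      Ka1 = if (!is.null(e$Ka1)) e$Ka1 else inv(e$MAT1_h),
                      Ka2 = if (!is.null(e$Ka2)) e$Ka2 else inv(e$MAT2_h),
                      F1 = e$F1, F2 = e$F2, p = e$p)
  } else {
    absorption_scheme(v)
  }
}

#' Read a population model file
#'
#' Parses a YAML (or JSON) population-model file with blocks `theta`
#' (typical values; volumes mL/kg, clearances mL/kg/h), `omega` (either
#' `cv_percent:` a named CV% list giving a diagonal covariance, or
#' `order:` + `matrix:` a full lower-triangle log-scale covariance),
#' `covariates` (per-parameter named log-scale shifts), `residual`
#' (`sigma_add` mg/L, `sigma_prop`), `fu`, and `absorption` (named scheme
#' entries; rate constants may be given as `Ka` (1/h) or as mean
#' absorption times `MAT_h`, with `Ka = 1/MAT`).
#'
#' @param path file path.
#' @return a [population_model()].
#' @export
read_population_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  y <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  theta <- y$theta
  omega <- NULL
  if (!is.null(y$omega)) {
    if (!is.null(y$omega$cv_percent)) {
      omega <- unlist(y$omega$cv_percent)
    } else {
      ord <- unlist(y$omega$order)
      m <- matrix(0, length(ord), length(ord), dimnames = list(ord, ord))
      rows <- y$omega$matrix
      for (i in seq_along(rows)) {
        vals <- unlist(rows[[i]])
        m[i, seq_along(vals)] <- vals
        m[seq_along(vals), i] <- vals
      }
      omega <- m
    }
  }
  covariates <- lapply(y$covariates, unlist)
  absorption <- lapply(y$absorption, parse_absorption_entry)
  residual <- list(
    sigma_add = if (!is.null(y$residual$sigma_add)) y$residual$sigma_add else 0,
    sigma_prop = if (!is.null(y$residual$sigma_prop)) y$residual$sigma_prop else 0)
  population_model(theta = theta, omega = omega, covariates = covariates,
                   residual = residual,
                   fu = if (!is.null(y$fu)) y$fu else 0.4,
                   absorption = absorption)
}

#' Read a regimen file
#'
#' YAML/JSON regimen files either list dose events
#' (`events: [{time, amount, route, duration}, ...]` with `t_end`) or use
#' the shorthand `{dose, unit, interval_h, n_doses, route, infusion_h}`.
#' IU doses are converted to mg of benzylpenicillin at ingestion.
#'
#' @param path file path.
#' @return a [regimen()].
#' @export
read_regimen <- function(path) {
  if (!file.exists(path)) stop("regimen file not found: ", path)
  y <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(y$events)) {
    ev <- do.call(rbind, lapply(y$events, function(e) {
      amt <- e$amount
      if (!is.null(e$unit) && grepl("^IU", e$unit)) {
        amt <- dose_convert(amt, e$unit, "mg/kg")
      }
      dose_event(e$time, amt,
                 route = if (is.null(e$route)) "im" else e$route,
                 duration = if (is.null(e$duration)) 0 else e$duration)
    }))
    regimen(ev, y$t_end)
  } else {
    dose <- y$dose
    if (!is.null(y$unit) && grepl("^IU", y$unit)) {
      dose <- dose_convert(dose, y$unit, "mg/kg")
    }
    regimen_shorthand(dose, y$interval_h, y$n_doses,
                      route = if (is.null(y$route)) "im" else y$route,
                      infusion_h = if (is.null(y$infusion_h)) 0 else y$infusion_h,
                      t_end = y$t_end)
  }
}

#' Write a concentration profile to CSV
#'
#' @param profile a `"conc_profile"`.
#' @param path output path; columns `time_h`, `conc_mg_per_L`.
#' @export
write_profile <- function(profile, path) {
  utils::write.csv(data.frame(time_h = profile$time,
                              conc_mg_per_L = profile$conc),
                   path, row.names = FALSE)
  invisible(path)
}
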