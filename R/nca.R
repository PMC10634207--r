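# Non-compartmental analysis of individual concentration-time profiles:
# linear trapezoidal AUC/AUMC, terminal-slope (lambda_z) regression with
# automatic point selection, IV clearance and volume terms, and
# dose-scaling of observed AUCs.

#' Linear trapezoidal AUC and AUMC
#'
#' @param time,conc observed times (h, strictly increasing) and
#'   concentrations (mg/L).
#' @return area under the curve (mg h/L) or under the first-moment curve
#'   (mg h^2/L).
#' @export
auc_trapezoid <- function(time, conc) {
  if (length(time) < 2) stop("need at least 2 points")
  if (is.unsorted(time, strictly = TRUE)) stop("times must be increasing")
  dt <- diff(time)
  sum(dt * (conc[-1] + conc[-length(conc)]) / 2)
}

#' @rdname auc_trapezoid
#' @export
aumc_trapezoid <- function(time, conc) {
  auc_trapezoid(time, time * conc)
}

#' Terminal-slope regression
#'
#' Estimates the terminal elimination rate constant `lambda_z` by ordinary
#' least squares of `log(C)` on `t` over a terminal window. By default the
#' window is chosen automatically: among all candidate windows of at least
#' `min_points` points ending at the last observation and starting after
#' Tmax, the one maximizing the adjusted R-squared is used. An explicit
#' vector of point indices overrides the rule.
#'
#' @param time,conc observed profile (positive concentrations only are
#'   used).
#' @param min_points minimum number of terminal points (default 3).
#' @param points optional integer indices of the points to regress on.
#' @return list with `lambda_z` (1/h), `t_half` (h), `intercept` (log
#'   scale), `n_points`, `adj_r2`, and `estimable` (FALSE when no valid
#'   window with a negative slope exists; the other fields are then `NA`).
#' @export
lambda_z_fit <- function(time, conc, min_points = 3, points = NULL) {
  pos <- conc > 0
  not_est <- list(lambda_z = NA_real_, t_half = NA_real_,
                  intercept = NA_real_, n_points = NA_integer_,
                  adj_r2 = NA_real_, estimable = FALSE)
  fit_window <- function(idx) {
    if (length(idx) < min_points || !all(pos[idx])) {
      return(NULL)
    }
    x <- time[idx]
    y <- log(conc[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- fit$coefficients[2]
    # a flat profile has no terminal phase (tolerance for rounding noise)
    if (!is.finite(slope) || slope >= -1e-10) {
      return(NULL)
    }
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    n <- length(idx)
    adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
    list(lambda_z = unname(-slope), t_half = log(2) / unname(-slope),
         intercept = unname(fit$coefficients[1]), n_points = n,
         adj_r2 = adj, estimable = TRUE)
  }
  if (!is.null(points)) {
    out <- fit_window(points)
    return(if (is.null(out)) not_est else out)
  }
  n <- length(time)
  i_max <- which.max(conc)
  starts <- seq(i_max + 1, n - min_points + 1)
  starts <- starts[starts >= 1]
  best <- NULL
  for (s in starts) {
    cand <- fit_window(s:n)
    if (!is.null(cand) &&
        (is.null(best) || cand$adj_r2 > best$adj_r2)) {
      best <- cand
    }
  }
  if (is.null(best)) not_est else best
}

#' Non-compartmental analysis of an IV profile
#'
#' Computes Cmax, Tmax, AUClast and AUMClast (linear trapezoidal),
#' `AUCinf = AUClast + Clast / lambda_z` (with `Clast` either the observed
#' or regression-predicted last quantifiable concentration),
#' `MRTinf = AUMCinf / AUCinf`, `CL = dose / AUCinf`, `Vz = CL / lambda_z`,
#' and the extrapolated AUC fraction. When the extrapolated fraction
#' exceeds 20% a flag is set; when `lambda_z` is not estimable the
#' extrapolation-dependent quantities are `NA`.
#'
#' @param time,conc observed profile.
#' @param dose administered dose (mg/kg).
#' @param clast `"observed"` (default) or `"predicted"`.
#' @param back_extrapolate prepend a time-zero concentration obtained by
#'   log-linear back-extrapolation through the first two positive
#'   observations (the usual IV-bolus convention; default TRUE when the
#'   first sample is after time zero).
#' @param ... passed to [lambda_z_fit()].
#' @return object of class `"bp_nca"` (a list of named results).
#' @export
nca_iv <- function(time, conc, dose, clast = c("observed", "predicted"),
                   back_extrapolate = TRUE, ...) {
  clast <- match.arg(clast)
  if (back_extrapolate && time[1] > 0 && length(conc) >= 2 &&
      conc[1] > 0 && conc[2] > 0) {
    c0 <- if (conc[1] > conc[2]) {
      exp(log(conc[1]) - (log(conc[2]) - log(conc[1])) /
            (time[2] - time[1]) * time[1])
    } else {
      conc[1]
    }
    time <- c(0, time)
    conc <- c(c0, conc)
  }
  lz <- lambda_z_fit(time, conc, ...)
  auclast <- auc_trapezoid(time, conc)
  aumclast <- aumc_trapezoid(time, conc)
  i_last <- max(which(conc > 0))
  tlast <- time[i_last]
  c_last <- if (clast == "observed" || !lz$estimable) {
    conc[i_last]
  } else {
    exp(lz$intercept - lz$lambda_z * tlast)
  }
  out <- list(Cmax = max(conc), Tmax = time[which.max(conc)],
              AUClast = auclast, lambda_z = lz$lambda_z,
              t_half = lz$t_half, estimable = lz$estimable)
  if (lz$estimable) {
    aucinf <- auclast + c_last / lz$lambda_z
    aumcinf <- aumclast + c_last * tlast / lz$lambda_z +
      c_last / lz$lambda_z^2
    out$AUCinf <- aucinf
    out$MRTinf <- aumcinf / aucinf
    out$CL <- dose / aucinf
    out$Vz <- out$CL / lz$lambda_z
    out$extrap_pct <- 100 * (1 - auclast / aucinf)
    out$extrap_flag <- out$extrap_pct > 20
  } else {
    out[c("AUCinf", "MRTinf", "CL", "Vz", "extrap_pct")] <- NA_real_
    out$extrap_flag <- NA
  }
  structure(out, class = "bp_nca")
}

#' @export
print.bp_nca <- function(x, ...) {
  cat("Non-compartmental analysis\n")
  cat(sprintf("  Cmax %.4g mg/L at %.3g h; AUClast %.4g mg.h/L\n",
              x$Cmax, x$Tmax, x$AUClast))
  if (isTRUE(x$estimable)) {
    cat(sprintf(
      "  lambda_z %.4g /h (t1/2 %.3g h); AUCinf %.4g (%.2g%% extrapolated)\n",
      x$lambda_z, x$t_half, x$AUCinf, x$extrap_pct))
    if (!is.null(x$CL)) {
      cat(sprintf("  CL %.4g mg/kg per (mg.h/L); MRTinf %.3g h; Vz %.4g\n",
                  x$CL, x$MRTinf, x$Vz))
    }
    if (isTRUE(x$extrap_flag)) {
      cat("  warning: extrapolated AUC fraction exceeds 20%\n")
    }
  } else {
    cat("  lambda_z not estimable\n")
  }
  invisible(x)
}

#' Scale an observed AUC to a reference dose
#'
#' Linear-kinetics proportionality: `AUC * reference / actual`. Used to
#' compare exposures across formulations given at different doses by
#' scaling everything to a common reference (e.g. 12.36 mg/kg).
#'
#' @param auc observed AUC.
#' @param actual_dose administered dose, > 0.
#' @param reference_dose target dose.
#' @export
scale_auc_to_dose <- function(auc, actual_dose, reference_dose) {
  if (any(actual_dose <= 0)) stop("actual dose must be > 0")
  auc * reference_dose / actual_dose
}

#' Harmonic mean
#'
#' The conventional summary for terminal half-lives across subjects; never
#' exceeds the arithmetic mean for positive values.
#'
#' @param x positive values; `NA`s removed.
#' @export
harmonic_mean <- function(x) {
  x <- x[!is.na(x)]
  if (any(x <= 0)) stop("harmonic mean requires positive values")
  length(x) / sum(1 / x)
}

#' Cohort NCA summary table
#'
#' Per-subject NCA over a tidy dataset, summarized per source with mean,
#' SD, CV%, min, median, max and (for the half-life) the harmonic mean.
#'
#' @param data data frame with columns `ID`, `SOURCE`, `TIME`, `DV` and a
#'   per-subject dose column `DOSE` (mg/kg).
#' @param ... passed to [nca_iv()].
#' @return list with `per_subject` (one row per profile) and `summary`
#'   (one row per source and variable).
#' @export
nca_summary <- function(data, ...) {
  req <- c("ID", "SOURCE", "TIME", "DV", "DOSE")
  if (!all(req %in% names(data))) {
    stop("data needs columns ", paste(req, collapse = ", "))
  }
  split_id <- split(data, interaction(data$SOURCE, data$ID, drop = TRUE))
  per <- do.call(rbind, lapply(split_id, function(d) {
    d <- d[order(d$TIME), ]
    res <- nca_iv(d$TIME, d$DV, dose = d$DOSE[1], ...)
    data.frame(ID = d$ID[1], SOURCE = d$SOURCE[1],
               Cmax = res$Cmax, t_half = res$t_half,
               AUCinf = res$AUCinf, MRTinf = res$MRTinf,
               CL = res$CL, Vz = res$Vz)
  }))
  rownames(per) <- NULL
  vars <- c("Cmax", "t_half", "AUCinf", "MRTinf", "CL", "Vz")
  smry <- do.call(rbind, lapply(split(per, per$SOURCE), function(d) {
    do.call(rbind, lapply(vars, function(v) {
      x <- d[[v]]
      data.frame(SOURCE = d$SOURCE[1], variable = v,
                 mean = mean(x, na.rm = TRUE),
                 sd = stats::sd(x, na.rm = TRUE),
                 cv_pct = 100 * stats::sd(x, na.rm = TRUE) /
                   mean(x, na.rm = TRUE),
                 min = suppressWarnings(min(x, na.rm = TRUE)),
                 median = stats::median(x, na.rm = TRUE),
                 max = suppressWarnings(max(x, na.rm = TRUE)),
                 harmonic_mean = if (v == "t_half") {
                   harmonic_mean(x)
                 } else {
                   NA_real_
                 })
    }))
  }))
  rownames(smry) <- NULL
  list(per_subject = per, summary = smry)
}
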