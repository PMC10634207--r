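# Population model: log-normal between-subject variability with full
# covariance, categorical covariate shifts on clearance, ilogit-scale
# bioavailability, additive + proportional residual error and a fixed
# unbound fraction.

#' Convert between a log-scale variance and a CV%
#'
#' Between-subject variability of a log-normally distributed parameter with
#' log-scale variance `omega^2` is reported as
#' `CV% = 100 * sqrt(exp(omega^2) - 1)`. `omega_from_cv()` is the exact
#' inverse, `omega^2 = log(1 + (CV/100)^2)`.
#'
#' @param omega_var log-scale variance (dimensionless), >= 0.
#' @param cv coefficient of variation in percent, >= 0.
#' @return `cv_percent()` returns the CV in %, `omega_from_cv()` the
#'   log-scale variance.
#' @examples
#' cv_percent(0.4450)   # ~75%
#' omega_from_cv(26.4)  # log-variance giving 26.4% BSV
#' @export
cv_percent <- function(omega_var) {
  if (any(omega_var < 0)) stop("omega_var must be >= 0")
  100 * sqrt(exp(omega_var) - 1)
}

#' @rdname cv_percent
#' @export
omega_from_cv <- function(cv) {
  if (any(cv < 0)) stop("cv must be >= 0")
  log(1 + (cv / 100)^2)
}

#' Inverse-logit bioavailability transform
#'
#' Maps an unconstrained real to a bioavailable fraction
#' `F = exp(x) / (1 + exp(x))` in (0, 1), which prevents estimating F > 1.
#' `logit_F()` is the inverse.
#'
#' @param x unconstrained real (ilogit scale).
#' @param F fraction in (0, 1).
#' @export
ilogit_F <- function(x) {
  stats::plogis(x)
}

#' @rdname ilogit_F
#' @export
logit_F <- function(F) {
  stats::qlogis(F)
}

#' Apply a categorical covariate shift to a typical value
#'
#' Exponential covariate model: the typical value for a given source (data
#' set) is the reference typical value times `exp(d_source)`, where `d` is
#' the source's log-scale shift. A source absent from the effects map is
#' treated as the reference (shift 0).
#'
#' @param theta_tv reference typical value.
#' @param effects named numeric vector of log-scale shifts per source.
#' @param source source label.
#' @return adjusted typical value.
#' @examples
#' apply_covariates(481, c(Sweden = -0.68325471), "Sweden")  # ~243
#' @export
apply_covariates <- function(theta_tv, effects, source) {
  d <- if (!is.null(effects) && source %in% names(effects)) {
    effects[[source]]
  } else {
    0
  }
  theta_tv * exp(d)
}

#' Construct a population PK model
#'
#' @param theta named list of typical values: the six disposition constants
#'   (`Vc`, `V2`, `V3`, `CL` in mL/kg and mL/kg/h) and any absorption
#'   parameters.
#' @param omega between-subject variability: either a symmetric positive
#'   semi-definite covariance matrix of the log-scale random effects (with
#'   dimnames naming the parameters; the conventional ordering is Vc, CL,
#'   V2, V3, CL2, CL3, then absorption parameters) or a named vector of
#'   CV% values from which a diagonal matrix is built via
#'   [omega_from_cv()] (correlations then default to 0).
#' @param covariates named list: for each parameter, a named vector of
#'   log-scale source shifts (see [apply_covariates()]).
#' @param residual list with `sigma_add` (mg/L) and `sigma_prop`
#'   (dimensionless), both >= 0.
#' @param fu unbound fraction in (0, 1]; fixed (no BSV), default 0.4.
#' @param absorption optional named list of [absorption_scheme()] objects,
#'   one per formulation, carried along for scenario building.
#' @return object of class `"population_model"`.
#' @export
population_model <- function(theta, omega = NULL, covariates = list(),
                             residual = list(sigma_add = 0, sigma_prop = 0),
                             fu = 0.4, absorption = list()) {
  stopifnot(is.list(theta), !is.null(names(theta)))
  if (fu <= 0 || fu > 1) stop("fu must be in (0, 1]")
  if (residual$sigma_add < 0 || residual$sigma_prop < 0) {
    stop("residual SDs must be >= 0")
  }
  if (!is.null(omega) && !is.matrix(omega)) {
    cvs <- omega
    omega <- diag(omega_from_cv(cvs), nrow = length(cvs))
    dimnames(omega) <- list(names(cvs), names(cvs))
  }
  if (!is.null(omega)) {
    if (is.null(rownames(omega))) {
      stop("omega must have dimnames declaring its parameter ordering")
    }
    if (max(abs(omega - t(omega))) > 1e-10) stop("omega must be symmetric")
    if (!all(rownames(omega) %in% names(theta))) {
      stop("omega names must be a subset of theta names: ",
           paste(setdiff(rownames(omega), names(theta)), collapse = ", "))
    }
    ch <- try(chol(omega, pivot = FALSE), silent = TRUE)
    if (inherits(ch, "try-error")) {
      # allow PSD (zero variance rows): check eigenvalues
      ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10 * max(abs(ev), 1)) {
        stop("omega is not positive semi-definite")
      }
    }
  }
  structure(list(theta = theta, omega = omega, covariates = covariates,
                 residual = residual, fu = fu, absorption = absorption),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model\n")
  cat("  theta:",
      paste(names(x$theta), signif(unlist(x$theta), 4),
            sep = " = ", collapse = ", "), "\n")
  if (is.null(x$omega)) {
    cat("  no between-subject variability\n")
  } else {
    cat("  BSV (CV%):",
        paste(rownames(x$omega),
              round(cv_percent(diag(x$omega))),
              sep = " = ", collapse = ", "), "\n")
  }
  cat(sprintf("  residual: sigma_add = %g mg/L, sigma_prop = %g; fu = %g\n",
              x$residual$sigma_add, x$residual$sigma_prop, x$fu))
  if (length(x$absorption)) {
    cat("  absorption schemes:", paste(names(x$absorption), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# lower Cholesky factor of a PSD matrix (tolerating zero eigenvalues)
psd_chol <- function(S) {
  ch <- suppressWarnings(try(t(chol(S)), silent = TRUE))
  if (!inherits(ch, "try-error")) {
    return(ch)
  }
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  e$vectors %*% diag(sqrt(ev), nrow = length(ev))
}

#' Draw individual parameter sets from a population model
#'
#' Random effects `eta` are drawn from a multivariate normal with mean 0 and
#' covariance `omega` (via its Cholesky factor); each individual parameter
#' is the covariate-adjusted typical value times `exp(eta)`, so sampled
#' parameters are always strictly positive. A bioavailability parameter
#' named `F` with a random effect is sampled on the ilogit scale
#' (`ilogit(logit(F_tv) + eta)`), keeping F below 1.
#'
#' @param model a [population_model()].
#' @param n number of individuals, >= 1.
#' @param source source label used for covariate adjustment.
#' @param seed optional integer seed for reproducibility.
#' @return data frame with one row per individual and one column per theta
#'   parameter; attribute `"eta"` holds the sampled random effects matrix.
#' @export
sample_individuals <- function(model, n, source = "reference", seed = NULL) {
  stopifnot(inherits(model, "population_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  theta_adj <- model$theta
  for (p in names(theta_adj)) {
    theta_adj[[p]] <- apply_covariates(theta_adj[[p]],
                                       model$covariates[[p]], source)
  }
  pars <- as.data.frame(lapply(theta_adj, rep, n))
  eta <- NULL
  if (!is.null(model$omega) && nrow(model$omega) > 0) {
    pnames <- rownames(model$omega)
    L <- psd_chol(model$omega)
    z <- matrix(stats::rnorm(n * length(pnames)), nrow = n)
    eta <- z %*% t(L)
    colnames(eta) <- pnames
    for (p in pnames) {
      if (p == "F") {
        pars[[p]] <- ilogit_F(logit_F(theta_adj[[p]]) + eta[, p])
      } else {
        pars[[p]] <- theta_adj[[p]] * exp(eta[, p])
      }
    }
  }
  attr(pars, "eta") <- eta
  attr(pars, "source") <- source
  pars
}

#' Add residual (observation) error to concentrations
#'
#' Additive plus multiplicative (proportional) residual model:
#' `C_obs = C * (1 + eps_prop) + eps_add`, with independent zero-mean normal
#' errors of SD `sigma_prop` and `sigma_add`. Negative results are floored
#' at 0 and the number floored is reported as an attribute.
#'
#' @param conc numeric vector of true concentrations (mg/L), >= 0.
#' @param residual list with `sigma_add` and `sigma_prop`.
#' @return perturbed concentrations with attribute `"n_floored"`.
#' @export
residual_perturb <- function(conc, residual) {
  if (any(conc < 0)) stop("conc must be >= 0")
  n <- length(conc)
  out <- conc * (1 + stats::rnorm(n, 0, residual$sigma_prop)) +
    stats::rnorm(n, 0, residual$sigma_add)
  nf <- sum(out < 0)
  out[out < 0] <- 0
  attr(out, "n_floored") <- nf
  out
}

#' Free (unbound) concentration
#'
#' Scales a total-concentration profile by the unbound fraction `fu`
#' (default 0.4 for benzylpenicillin in horses, consistent with a reported
#' plasma protein binding of about 63%).
#'
#' @param profile a `"conc_profile"` or numeric vector.
#' @param fu unbound fraction in (0, 1].
#' @return same shape as the input, concentrations multiplied by `fu`. For
#'   profiles, the closed-form terms are rescaled too, so exact AUC remains
#'   available.
#' @export
free_conc <- function(profile, fu = 0.4) {
  if (fu <= 0 || fu > 1) stop("fu must be in (0, 1]")
  if (inherits(profile, "conc_profile")) {
    profile$conc <- profile$conc * fu
    terms <- attr(profile, "terms")
    if (!is.null(terms)) {
      terms[, "coef"] <- terms[, "coef"] * fu
      attr(profile, "terms") <- terms
    }
    profile
  } else {
    profile * fu
  }
}
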