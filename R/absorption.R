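#' Absorption scheme for a dose input
#'
#' Describes how a dose enters the central compartment. The variants mirror
#' the input models used for the different benzylpenicillin formulations:
#'
#' * `iv_bolus` — instantaneous input (IV solutions given as a bolus).
#' * `iv_infusion` — zero-order input over the dose event's infusion
#'   duration (continuous-rate infusion).
#' * `first_order` — single first-order rate constant `Ka` with
#'   bioavailability `F` (procaine BP suspensions).
#' * `sequential_dual_lag` — a depot drains at `Ka1` from dosing until
#'   `Tlag` after the dose, then the remaining depot drains at `Ka2`
#'   (rate-switching; IM sodium BP with rapid then slow absorption).
#'   Alternatively, an explicit `frac1` splits the bioavailable dose into a
#'   `Ka1` fraction and a delayed `Ka2` fraction.
#' * `parallel_dual` — the dose is split `p` / `1 - p` between two parallel
#'   first-order inputs `(Ka1, F1)` and `(Ka2, F2)` (procaine + benzathine
#'   BP combination, one input per prodrug moiety).
#' * `per_site_sequential` — one `sequential_dual_lag` input per dose event
#'   with shared parameters (penethamate, each injection site absorbing
#'   independently).
#'
#' @param variant one of the tags above.
#' @param Ka,Ka1,Ka2 first-order absorption rate constants (1/h), > 0.
#' @param F,F1,F2 bioavailable fractions in (0, 1].
#' @param Tlag lag time (h) separating the two sequential phases, >= 0.
#' @param p dose fraction routed through the first parallel input, in
#'   \[0, 1\].
#' @param frac1 optional explicit phase-1 fraction for the sequential
#'   variants; `NULL` (default) selects rate-switching semantics.
#' @return an object of class `"absorption_scheme"`.
#' @examples
#' absorption_scheme("first_order", Ka = 1 / 21.46, F = 1)
#' absorption_scheme("sequential_dual_lag",
#'                   Ka1 = 1 / 0.976, Ka2 = 1 / 4.03,
#'                   Tlag = 0.471, F = 0.891)
#' @export
absorption_scheme <- function(variant = c("iv_bolus", "iv_infusion",
                                          "first_order",
                                          "sequential_dual_lag",
                                          "parallel_dual",
                                          "per_site_sequential"),
                              Ka = NULL, F = NULL,
                              Ka1 = NULL, Ka2 = NULL, Tlag = NULL,
                              F1 = NULL, F2 = NULL, p = NULL,
                              frac1 = NULL) {
  variant <- match.arg(variant)
  chk_rate <- function(x, nm) {
    if (is.null(x) || !is.finite(x) || x <= 0) {
      stop(nm, " must be a positive rate constant (1/h)")
    }
    x
  }
  chk_frac <- function(x, nm, lo = 0) {
    if (is.null(x) || !is.finite(x) || x <= lo || x > 1) {
      stop(nm, " must be a fraction in (", lo, ", 1]")
    }
    x
  }
  out <- list(variant = variant)
  if (variant == "first_order") {
    out$Ka <- chk_rate(Ka, "Ka")
    out$F <- chk_frac(F, "F")
  } else if (variant %in% c("sequential_dual_lag", "per_site_sequential")) {
    out$Ka1 <- chk_rate(Ka1, "Ka1")
    out$Ka2 <- chk_rate(Ka2, "Ka2")
    if (is.null(Tlag) || !is.finite(Tlag) || Tlag < 0) {
      stop("Tlag must be >= 0")
    }
    out$Tlag <- Tlag
    out$F <- chk_frac(F, "F")
    if (!is.null(frac1)) {
      if (!is.finite(frac1) || frac1 < 0 || frac1 > 1) {
        stop("frac1 must be in [0, 1]")
      }
      out$frac1 <- frac1
    }
  } else if (variant == "parallel_dual") {
    out$Ka1 <- chk_rate(Ka1, "Ka1")
    out$Ka2 <- chk_rate(Ka2, "Ka2")
    out$F1 <- chk_frac(F1, "F1")
    out$F2 <- chk_frac(F2, "F2")
    if (is.null(p) || !is.finite(p) || p < 0 || p > 1) {
      stop("p must be in [0, 1]")
    }
    out$p <- p
  }
  structure(out, class = "absorption_scheme")
}

#' @export
print.absorption_scheme <- function(x, ...) {
  cat("Absorption scheme:", x$variant, "\n")
  pars <- x[setdiff(names(x), "variant")]
  if (length(pars)) {
    cat(" ", paste(names(pars), unlist(pars), sep = " = ", collapse = ", "),
        "\n")
  }
  invisible(x)
}
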