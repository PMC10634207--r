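#' Mammillary disposition parameters
#'
#' Container for the six constants of a mammillary (central + up to two
#' peripheral compartments) disposition model, parameterized in terms of
#' clearances and volumes: central volume `Vc`, peripheral volumes `V2`,
#' `V3` (mL/kg), plasma clearance `CL` and inter-compartmental clearances
#' `CL2`, `CL3` (mL/kg/h). Setting `CL3 = 0` gives a 2-compartment model
#' (`V3` is then inert) and `CL2 = CL3 = 0` a 1-compartment model.
#'
#' @param Vc,V2,V3 volumes (mL/kg); `Vc > 0`; peripheral volumes must be
#'   positive whenever the corresponding inter-compartmental clearance is
#'   non-zero.
#' @param CL plasma clearance (mL/kg/h), strictly positive.
#' @param CL2,CL3 inter-compartmental clearances (mL/kg/h), non-negative.
#' @return an object of class `"disposition"`.
#' @examples
#' disposition_params(Vc = 106, V2 = 46.3, V3 = 50.4,
#'                    CL = 481, CL2 = 126, CL3 = 25)
#' @export
disposition_params <- function(Vc, V2 = 0, V3 = 0, CL, CL2 = 0, CL3 = 0) {
  vals <- c(Vc = Vc, V2 = V2, V3 = V3, CL = CL, CL2 = CL2, CL3 = CL3)
  if (any(!is.finite(vals))) stop("disposition parameters must be finite")
  if (Vc <= 0) stop("Vc must be strictly positive")
  if (CL <= 0) stop("CL must be strictly positive")
  if (CL2 < 0 || CL3 < 0) stop("inter-compartmental clearances must be >= 0")
  if (CL2 > 0 && V2 <= 0) stop("V2 must be > 0 when CL2 > 0")
  if (CL3 > 0 && V3 <= 0) stop("V3 must be > 0 when CL3 > 0")
  structure(as.list(vals), class = "disposition")
}

#' @export
print.disposition <- function(x, ...) {
  cat("Mammillary disposition model (", n_compartments(x), " compartments)\n",
      sep = "")
  cat(sprintf("  Vc = %g, V2 = %g, V3 = %g mL/kg\n", x$Vc, x$V2, x$V3))
  cat(sprintf("  CL = %g, CL2 = %g, CL3 = %g mL/kg/h\n", x$CL, x$CL2, x$CL3))
  invisible(x)
}

n_compartments <- function(disp) {
  1L + (disp$CL2 > 0) + (disp$CL3 > 0)
}

#' Micro rate constants of a mammillary model
#'
#' Standard reparameterization of the clearance/volume form into first-order
#' micro constants: `k10 = CL/Vc`, `k12 = CL2/Vc`, `k21 = CL2/V2`,
#' `k13 = CL3/Vc`, `k31 = CL3/V3`. Constants attached to an absent
#' compartment are zero.
#'
#' @param disposition a [disposition_params()] object.
#' @return named numeric vector `k10, k12, k21, k13, k31` (1/h).
#' @export
micro_constants <- function(disposition) {
  stopifnot(inherits(disposition, "disposition"))
  d <- disposition
  c(k10 = d$CL / d$Vc,
    k12 = d$CL2 / d$Vc,
    k21 = if (d$CL2 > 0) d$CL2 / d$V2 else 0,
    k13 = d$CL3 / d$Vc,
    k31 = if (d$CL3 > 0) d$CL3 / d$V3 else 0)
}

# Rate matrix of the disposition system acting on compartment amounts
# (central first). Eigenvalues are real and non-positive for mammillary
# systems.
disp_matrix <- function(disposition) {
  k <- micro_constants(disposition)
  n <- n_compartments(disposition)
  if (n == 1L) {
    return(matrix(-k[["k10"]], 1, 1))
  }
  if (disposition$CL2 > 0 && disposition$CL3 > 0) {
    matrix(c(-(k[["k10"]] + k[["k12"]] + k[["k13"]]), k[["k21"]], k[["k31"]],
             k[["k12"]], -k[["k21"]], 0,
             k[["k13"]], 0, -k[["k31"]]),
           3, 3, byrow = TRUE)
  } else {
    # one active peripheral compartment (use whichever clearance is non-zero)
    kin <- if (disposition$CL2 > 0) k[["k12"]] else k[["k13"]]
    kout <- if (disposition$CL2 > 0) k[["k21"]] else k[["k31"]]
    matrix(c(-(k[["k10"]] + kin), kout,
             kin, -kout),
           2, 2, byrow = TRUE)
  }
}

#' Exponential rate constants (eigenvalues) of the disposition system
#'
#' Returns the decay rates of the multi-exponential impulse response, i.e.
#' the negated eigenvalues of the mammillary rate matrix, sorted decreasing
#' (`lambda1 >= lambda2 >= lambda3`; the smallest is the terminal rate
#' `lambda_z`). For a system with fewer than three compartments the absent
#' rates are dropped. The rates satisfy the Vieta identities
#' `sum(lambda) = k10 + k12 + k21 + k13 + k31` and
#' `prod(lambda) = k10 * k21 * k31` (3-compartment case).
#'
#' @param disposition a [disposition_params()] object.
#' @return numeric vector of positive rates (1/h), decreasing.
#' @export
eigen_rates <- function(disposition) {
  K <- disp_matrix(disposition)
  lam <- -eigen(K, only.values = TRUE)$values
  if (is.complex(lam)) {
    if (max(abs(Im(lam))) > 1e-8 * max(abs(lam))) {
      stop("complex eigenvalues: disposition matrix is not mammillary")
    }
    lam <- Re(lam)
  }
  sort(lam, decreasing = TRUE)
}

#' Secondary disposition parameters
#'
#' Computes the steady-state volume of distribution `Vss = Vc + V2 + V3`
#' (mL/kg), the mean residence time `MRT = Vss / CL` (h), the terminal
#' half-life `t_half = ln(2) / lambda_z` (h), and, when an absorption scheme
#' is supplied, the mean absorption time `MAT = 1/Ka` (h) for each of its
#' first-order rate constants.
#'
#' @param disposition a [disposition_params()] object.
#' @param absorption optional [absorption_scheme()]; its rate constants give
#'   the MAT entries.
#' @return a list with elements `Vss`, `MRT`, `t_half`, and `MAT` (named
#'   numeric vector, possibly empty).
#' @export
secondary_params <- function(disposition, absorption = NULL) {
  stopifnot(inherits(disposition, "disposition"))
  # V3 only contributes when its compartment is connected; idem V2
  Vss <- disposition$Vc +
    (if (disposition$CL2 > 0) disposition$V2 else 0) +
    (if (disposition$CL3 > 0) disposition$V3 else 0)
  lam <- eigen_rates(disposition)
  mat <- numeric(0)
  if (!is.null(absorption)) {
    stopifnot(inherits(absorption, "absorption_scheme"))
    ka <- unlist(absorption[names(absorption) %in% c("Ka", "Ka1", "Ka2")])
    if (length(ka)) mat <- 1 / ka
  }
  list(Vss = Vss,
       MRT = Vss / disposition$CL,
       t_half = log(2) / min(lam),
       MAT = mat)
}
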