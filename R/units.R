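#' Convert benzylpenicillin doses between international units and mass
#'
#' Doses of benzylpenicillin (BP) products are labelled either in
#' international units (IU) or in mass. Per the second international
#' standard, 1 mg of BP is equivalent to 1780 IU and 1 mg of sodium BP to
#' 1670 IU. Conversion is an exact ratio, so round-tripping a value returns
#' it unchanged.
#'
#' @param value numeric vector of doses (in `from` units; per-kg variants
#'   such as "IU/kg" are accepted and behave identically to "IU").
#' @param from,to units, one of `"IU"`, `"mg"`, `"IU/kg"`, `"mg/kg"`.
#' @param substance `"BP"` (benzylpenicillin base, 1780 IU/mg) or
#'   `"sodium_BP"` (1670 IU/mg).
#' @return numeric vector of converted doses.
#' @examples
#' dose_convert(22000, "IU/kg", "mg/kg")        # 12.36 mg/kg
#' dose_convert(1670, "IU", "mg", "sodium_BP")  # 1 mg
#' @export
dose_convert <- function(value, from, to, substance = c("BP", "sodium_BP")) {
  substance <- match.arg(substance)
  iu_per_mg <- c(BP = 1780, sodium_BP = 1670)[[substance]]
  norm <- function(u) {
    u <- sub("/kg$", "", u)
    if (!u %in% c("IU", "mg")) {
      stop("unsupported unit: ", u, " (use IU, mg, IU/kg or mg/kg)")
    }
    u
  }
  from <- norm(from)
  to <- norm(to)
  if (from == to) {
    return(value)
  }
  if (from == "IU") value / iu_per_mg else value * iu_per_mg
}
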