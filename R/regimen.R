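#' Dose events and dosing regimens
#'
#' A regimen is an ordered list of dose events over a treatment window
#' `[0, t_end]` hours. Each event has a time (h), an amount (mg/kg of
#' benzylpenicillin), a route tag, and an infusion duration (h; non-zero
#' only for `iv_infusion`).
#'
#' @param time administration time (h), >= 0.
#' @param amount dose (mg/kg of benzylpenicillin), >= 0. IU-labelled doses
#'   should be converted first with [dose_convert()].
#' @param route `"iv_bolus"`, `"iv_infusion"` or `"im"`.
#' @param duration infusion duration (h); must be > 0 for `iv_infusion` and
#'   0 otherwise.
#' @return `dose_event()` returns a one-row data frame; [regimen()] an
#'   object of class `"regimen"`.
#' @export
dose_event <- function(time, amount, route = c("iv_bolus", "iv_infusion", "im"),
                       duration = 0) {
  route <- match.arg(route)
  if (time < 0) stop("dose time must be >= 0")
  if (amount < 0) stop("dose amount must be >= 0")
  if (duration < 0) stop("infusion duration must be >= 0")
  if (route == "iv_infusion" && duration <= 0) {
    stop("iv_infusion requires duration > 0")
  }
  if (route != "iv_infusion" && duration != 0) {
    stop("duration must be 0 unless route is iv_infusion")
  }
  data.frame(time = time, amount = amount, route = route,
             duration = duration, stringsAsFactors = FALSE)
}

#' @param events a data frame of dose events (rbind of [dose_event()] rows).
#' @param t_end treatment window end (h); all event times must lie strictly
#'   before `t_end`.
#' @rdname dose_event
#' @export
regimen <- function(events, t_end) {
  stopifnot(is.data.frame(events),
            all(c("time", "amount", "route", "duration") %in% names(events)))
  events <- events[order(events$time), , drop = FALSE]
  rownames(events) <- NULL
  if (t_end <= 0) stop("t_end must be positive")
  if (any(events$time >= t_end)) stop("all dose times must be < t_end")
  structure(list(events = events, t_end = t_end), class = "regimen")
}

#' Build a regimen from the usual shorthand
#'
#' `n_doses` equal doses at `interval_h` spacing starting at time 0; the
#' treatment window defaults to `n_doses * interval_h` (e.g. 72 h for
#' q24h x 3), the convention under which the PK/PD indices are evaluated.
#'
#' @param dose per-administration dose (mg/kg BP), or for
#'   `route = "iv_infusion"` the amount infused per event.
#' @param interval_h dosing interval (h).
#' @param n_doses number of administrations.
#' @param route passed to [dose_event()].
#' @param infusion_h infusion duration per event (h).
#' @param t_end optional explicit window end (h).
#' @return a [regimen()].
#' @examples
#' regimen_shorthand(12.36, interval_h = 24, n_doses = 3, route = "im")
#' @export
regimen_shorthand <- function(dose, interval_h, n_doses, route = "im",
                              infusion_h = 0, t_end = NULL) {
  if (n_doses < 1) stop("n_doses must be >= 1")
  times <- (seq_len(n_doses) - 1) * interval_h
  events <- do.call(rbind, lapply(times, dose_event, amount = dose,
                                  route = route, duration = infusion_h))
  if (is.null(t_end)) t_end <- n_doses * interval_h
  regimen(events, t_end)
}

#' @export
print.regimen <- function(x, ...) {
  cat("Dosing regimen over [0, ", x$t_end, "] h:\n", sep = "")
  print(x$events, row.names = FALSE)
  invisible(x)
}
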