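#' Intravenous dosing regimen
#'
#' An optional loading dose at time zero followed by fixed maintenance
#' doses every `interval` hours over the simulation horizon (72 h for the
#' study). Doses are modelled as instantaneous IV boluses.
#'
#' @param maintenance_dose Maintenance dose in mg (> 0).
#' @param interval Dosing interval in h (> 0); all catalog regimens use
#'   intervals dividing 24.
#' @param loading_dose Optional loading dose in mg given at `t = 0`;
#'   `NA` for none.
#' @param horizon Simulation horizon in h, default 72.
#' @param label Display label; autogenerated when omitted.
#'
#' @return An object of class `dosing_regimen`.
#' @examples
#' dosing_regimen(150, 8)
#' dosing_regimen(250, 12, loading_dose = 300)
#' @export
dosing_regimen <- function(maintenance_dose, interval, loading_dose = NA,
                           horizon = 72, label = NULL) {
  stopifnot(is.numeric(maintenance_dose), maintenance_dose > 0,
            is.numeric(interval), interval > 0,
            is.na(loading_dose) || loading_dose > 0,
            is.numeric(horizon), horizon >= 0)
  if (is.null(label)) {
    label <- if (is.na(loading_dose)) {
      sprintf("%g mg q %g h", maintenance_dose, interval)
    } else {
      sprintf("%g mg LD, %g mg q %g h", loading_dose, maintenance_dose,
              interval)
    }
  }
  structure(list(maintenance_dose = maintenance_dose, interval = interval,
                 loading_dose = loading_dose, horizon = horizon,
                 label = label),
            class = "dosing_regimen")
}

#' @export
print.dosing_regimen <- function(x, ...) {
  cat(sprintf("<dosing_regimen> %s over %g h (%g mg/day maintenance)\n",
              x$label, x$horizon, daily_dose(x)))
  invisible(x)
}

#' Total daily maintenance dose and dosing frequency
#'
#' `daily_dose()` is the maintenance dose times the number of doses per
#' 24 h (the loading dose is excluded: it is a one-off). `doses_per_day()`
#' is `24 / interval`.
#'
#' @param regimen A [dosing_regimen()].
#' @return A scalar (mg/day, or doses/day).
#' @export
daily_dose <- function(regimen) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  regimen$maintenance_dose * 24 / regimen$interval
}

#' @rdname daily_dose
#' @export
doses_per_day <- function(regimen) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  24 / regimen$interval
}

#' Expand a regimen into explicit dose events
#'
#' With a loading dose, the loading dose is given at `t = 0` and
#' maintenance doses at `interval, 2*interval, ...` strictly before the
#' horizon; without one, maintenance doses start at `t = 0`.
#'
#' @param regimen A [dosing_regimen()].
#' @return A `data.frame` with columns `time` (h) and `amount` (mg),
#'   sorted by time; zero rows when the horizon is 0.
#' @examples
#' expand_schedule(dosing_regimen(150, 8))          # 9 doses at 0, 8, ..., 64
#' expand_schedule(dosing_regimen(250, 12, 300))    # 300 at 0; 250 q12h
#' @export
expand_schedule <- function(regimen) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (regimen$horizon <= 0) {
    return(data.frame(time = numeric(0), amount = numeric(0)))
  }
  n_doses <- ceiling(regimen$horizon / regimen$interval - 1e-9)
  times <- regimen$interval * (seq_len(n_doses) - 1L)
  amounts <- rep(regimen$maintenance_dose, length(times))
  if (!is.na(regimen$loading_dose)) amounts[1L] <- regimen$loading_dose
  data.frame(time = times, amount = amounts)
}

#' The study's regimen catalogs
#'
#' `standard_regimens()` lists the six regimens evaluated against the
#' trough (5-10 mg/L) and standard daily-AUC (80.25-143 mg*h/L) targets;
#' `high_target_regimens()` the nine regimens evaluated against the high
#' daily-AUC target (143-231 mg*h/L), which include loading-dose variants.
#'
#' @return A list of [dosing_regimen()]s in catalog order.
#' @export
standard_regimens <- function() {
  list(
    dosing_regimen(100, 8),
    dosing_regimen(150, 8),
    dosing_regimen(200, 12),
    dosing_regimen(200, 8),
    dosing_regimen(300, 12),
    dosing_regimen(250, 8)
  )
}

#' @rdname standard_regimens
#' @export
high_target_regimens <- function() {
  list(
    dosing_regimen(250, 12),
    dosing_regimen(250, 12, loading_dose = 300),
    dosing_regimen(250, 12, loading_dose = 350),
    dosing_regimen(300, 12),
    dosing_regimen(150, 8),
    dosing_regimen(150, 8, loading_dose = 200),
    dosing_regimen(150, 8, loading_dose = 250),
    dosing_regimen(200, 8),
    dosing_regimen(200, 8, loading_dose = 250)
  )
}
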