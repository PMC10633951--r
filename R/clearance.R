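#' CRRT prescription
#'
#' The machine settings that determine extracorporeal drug clearance:
#' modality, weight-scaled effluent rate, blood flow and hematocrit. Blood
#' flow of 200 mL/min and hematocrit 30% are the study's fixed settings;
#' they are prescription fields (not constants) so sensitivity analyses are
#' possible. CVVH is modelled in pre-dilution mode, where replacement fluid
#' equal to the ultrafiltration rate is added before the filter and dilutes
#' the plasma entering it.
#'
#' @param modality `"CVVHD"` (diffusive) or `"CVVH"` (convective,
#'   pre-dilution).
#' @param effluent_rate Effluent dose in mL/kg/h (> 0); the study grid uses
#'   20, 25 and 35.
#' @param blood_flow Blood flow rate in mL/min (> 0), default 200.
#' @param hematocrit Fraction in (0, 1), default 0.30.
#'
#' @return An object of class `crrt_prescription`.
#' @examples
#' crrt_prescription("CVVHD", 25)
#' @export
crrt_prescription <- function(modality = c("CVVHD", "CVVH"),
                              effluent_rate,
                              blood_flow = 200,
                              hematocrit = 0.30) {
  modality <- match.arg(modality)
  stopifnot(is.numeric(effluent_rate), length(effluent_rate) == 1L,
            effluent_rate > 0,
            is.numeric(blood_flow), blood_flow > 0,
            is.numeric(hematocrit), hematocrit > 0, hematocrit < 1)
  structure(list(modality = modality, effluent_rate = effluent_rate,
                 blood_flow = blood_flow, hematocrit = hematocrit,
                 dilution = if (modality == "CVVH") "pre" else NA_character_),
            class = "crrt_prescription")
}

#' @export
print.crrt_prescription <- function(x, ...) {
  cat(sprintf("<crrt_prescription> %s @ %g mL/kg/h (Qb %g mL/min, Hct %g)\n",
              x$modality, x$effluent_rate, x$blood_flow, x$hematocrit))
  invisible(x)
}

#' Effluent flow for a given patient
#'
#' The effluent prescription is dosed per kilogram, so the absolute
#' dialysate/ultrafiltrate flow is `effluent_rate * weight / 1000` L/h.
#'
#' @param prescription A [crrt_prescription()].
#' @param weight Body weight(s) in kg (> 0); vectorised.
#' @return Effluent flow in L/h.
#' @examples
#' effluent_flow(crrt_prescription("CVVHD", 20), 75.4)  # 1.508 L/h
#' @export
effluent_flow <- function(prescription, weight) {
  stopifnot(inherits(prescription, "crrt_prescription"))
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be positive and finite")
  }
  prescription$effluent_rate * weight / 1000
}

#' Transmembrane (CRRT) clearance
#'
#' For CVVHD the dialysate is assumed to saturate to a fixed fraction of the
#' plasma concentration, so `CL = SA * Qd`. For pre-dilution CVVH the
#' ultrafiltrate carries `SC` times the *diluted* plasma concentration, so
#' the convective clearance is corrected by the plasma-flow factor:
#' `CL = SC * Quf * Qplasma / (Qplasma + Qrep)` with
#' `Qplasma = Qblood * (1 - hematocrit)` and replacement flow equal to the
#' ultrafiltration rate. All flows are converted to L/h before combining.
#' At equal settings the pre-dilution factor is < 1, so CVVH always clears
#' less than CVVHD.
#'
#' @param prescription A [crrt_prescription()].
#' @param patient A `virtual_cohort` row set (or any list/data.frame with
#'   `weight_kg` and `sieving_coefficient`); vectorised over patients.
#' @return Clearance in L/h.
#' @examples
#' p <- data.frame(weight_kg = 75.4, vd_per_kg = 0.61,
#'                 clnr_ml_min = 16.6, sieving_coefficient = 0.78)
#' transmembrane_clearance(crrt_prescription("CVVHD", 20), p)  # 1.17624
#' transmembrane_clearance(crrt_prescription("CVVH", 20), p)   # ~0.9972
#' @export
transmembrane_clearance <- function(prescription, patient) {
  stopifnot(inherits(prescription, "crrt_prescription"))
  sc <- patient$sieving_coefficient
  stopifnot(!is.null(sc), !is.null(patient$weight_kg))
  q_eff <- effluent_flow(prescription, patient$weight_kg)  # L/h
  if (prescription$modality == "CVVHD") {
    sc * q_eff
  } else {
    q_plasma <- prescription$blood_flow * (1 - prescription$hematocrit) *
      60 / 1000                                            # mL/min -> L/h
    sc * q_eff * q_plasma / (q_plasma + q_eff)
  }
}

#' Assemble per-patient PK parameters under a CRRT prescription
#'
#' Total clearance is the sum of CRRT clearance and non-renal clearance;
#' native renal clearance is fixed at zero (the model describes anuric
#' patients) unless overridden. Non-renal clearance is converted from
#' mL/min to L/h at this point; volume of distribution is
#' `vd_per_kg * weight`; the elimination rate constant is
#' `k = CL_total / Vd`.
#'
#' @param patient A `virtual_cohort` (vectorised) or single-row equivalent.
#' @param prescription A [crrt_prescription()].
#' @param renal_clearance Native kidney clearance in L/h, default 0.
#' @return A `data.frame` of class `pk_parameters` with columns
#'   `crrt_clearance`, `clnr`, `total_clearance` (L/h), `vd` (L), `k` (1/h).
#' @examples
#' p <- data.frame(weight_kg = 75.4, vd_per_kg = 0.61,
#'                 clnr_ml_min = 16.6, sieving_coefficient = 0.78)
#' derive_pk(p, crrt_prescription("CVVHD", 20))  # k ~ 0.04723 per hour
#' @export
derive_pk <- function(patient, prescription, renal_clearance = 0) {
  stopifnot(inherits(prescription, "crrt_prescription"),
            renal_clearance >= 0)
  cl_crrt <- transmembrane_clearance(prescription, patient)
  clnr <- patient$clnr_ml_min * 60 / 1000                  # mL/min -> L/h
  vd <- patient$vd_per_kg * patient$weight_kg
  total <- cl_crrt + clnr + renal_clearance
  out <- data.frame(crrt_clearance = cl_crrt, clnr = clnr,
                    total_clearance = total, vd = vd, k = total / vd)
  class(out) <- c("pk_parameters", "data.frame")
  out
}
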