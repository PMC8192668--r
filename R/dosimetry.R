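# MIRD non-penetrating absorbed-dose arithmetic for Y-90 microspheres:
# the single-compartment (standard) and two-compartment (partition)
# prescription models. All equations use the rounded 50 J/GBq constant,
# masses in kg, doses in Gy, activities in GBq.

#' Absorbed dose per unit injected activity for a VOI
#'
#' Mean dose rate (Gy per GBq injected) for a volume of interest holding a
#' fraction of the injected activity, under uniform activity and
#' non-penetrating beta radiation:
#' `D/A = 50 * (A_VOI / A) / M_VOI`.
#'
#' @param voi_activity_fraction Fraction of the injected activity residing in
#'   the VOI, in \[0, 1\].
#' @param voi_mass VOI mass in kg, positive.
#' @param energy_per_activity J/GBq constant (default 50).
#' @return Gy/GBq.
#' @export
dose_per_activity <- function(voi_activity_fraction, voi_mass,
                              energy_per_activity = 50) {
  if (any(voi_mass <= 0)) stop("voi_mass must be positive", call. = FALSE)
  if (any(voi_activity_fraction < 0 | voi_activity_fraction > 1)) {
    stop("voi_activity_fraction must lie in [0, 1]", call. = FALSE)
  }
  energy_per_activity * voi_activity_fraction / voi_mass
}

#' Standard-model activity for a prescribed lobe dose
#'
#' Single-compartment prescription: the activity delivering a chosen mean
#' dose to the perfused lobe, `A = D * M_lobe / 50`. As printed, the formula
#' assumes all injected activity sits in the lobe; set `include_lsf = TRUE`
#' to deduct the lung shunt (`A = D * M_lobe / (50 * (1 - LSF))`).
#'
#' @param dose_lobe Prescribed mean dose to the perfused lobe, Gy.
#' @param lobe_mass Perfused lobe mass, kg.
#' @param lsf Lung shunt fraction in \[0, 1); only used when
#'   `include_lsf = TRUE`.
#' @param include_lsf Apply the `(1 - LSF)` hepatic-deposition factor.
#' @param energy_per_activity J/GBq constant (default 50).
#' @return Injected activity in GBq.
#' @export
activity_for_lobe_dose <- function(dose_lobe, lobe_mass, lsf = 0,
                                   include_lsf = FALSE,
                                   energy_per_activity = 50) {
  if (any(dose_lobe <= 0)) stop("dose_lobe must be positive", call. = FALSE)
  if (any(lobe_mass <= 0)) stop("lobe_mass must be positive", call. = FALSE)
  a <- dose_lobe * lobe_mass / energy_per_activity
  if (include_lsf) {
    check_lsf(lsf)
    a <- a / (1 - lsf)
  }
  a
}

check_lsf <- function(lsf) {
  if (any(lsf < 0 | lsf >= 1)) {
    stop("lung shunt fraction must lie in [0, 1)", call. = FALSE)
  }
  invisible(lsf)
}

#' Partition-model activity for a prescribed normal-liver dose
#'
#' Two-compartment prescription: given the normal-liver and pooled tumor
#' masses, the MAA tumor-to-normal uptake ratio (TNR) and the lung shunt
#' fraction, the activity delivering a chosen mean dose to normal liver is
#' `A = D_NL * (M_NL + TNR * M_T) / (50 * (1 - LSF))`.
#'
#' @param dose_nl Prescribed mean dose to normal liver, Gy.
#' @param normal_liver_mass Normal-liver compartment mass, kg.
#' @param tumor_mass Pooled tumor mass, kg (0 allowed).
#' @param tnr Tumor-to-normal uptake ratio, >= 0.
#' @param lsf Lung shunt fraction in \[0, 1).
#' @param energy_per_activity J/GBq constant (default 50).
#' @return Injected activity in GBq.
#' @export
activity_for_partition <- function(dose_nl, normal_liver_mass, tumor_mass,
                                   tnr, lsf, energy_per_activity = 50) {
  if (any(dose_nl <= 0)) stop("dose_nl must be positive", call. = FALSE)
  if (any(normal_liver_mass <= 0)) {
    stop("normal_liver_mass must be positive", call. = FALSE)
  }
  if (any(tumor_mass < 0)) stop("tumor_mass must be >= 0", call. = FALSE)
  if (any(tnr < 0)) stop("tnr must be >= 0", call. = FALSE)
  check_lsf(lsf)
  dose_nl * (normal_liver_mass + tnr * tumor_mass) /
    (energy_per_activity * (1 - lsf))
}

#' Partition-model dose rates for normal liver and tumor
#'
#' Mean absorbed dose per unit injected activity for the two compartments:
#' normal liver receives `50 * (1 - LSF) / (M_NL + TNR * M_T)` Gy/GBq and the
#' tumor compartment receives TNR times that. Inverse of
#' [activity_for_partition()].
#'
#' @inheritParams activity_for_partition
#' @return A list with elements `normal_liver` and `tumor`, both Gy/GBq.
#' @export
partition_dose_rates <- function(normal_liver_mass, tumor_mass, tnr, lsf,
                                 energy_per_activity = 50) {
  if (any(normal_liver_mass <= 0)) {
    stop("normal_liver_mass must be positive", call. = FALSE)
  }
  if (any(tumor_mass < 0)) stop("tumor_mass must be >= 0", call. = FALSE)
  if (any(tnr < 0)) stop("tnr must be >= 0", call. = FALSE)
  check_lsf(lsf)
  nl <- energy_per_activity * (1 - lsf) / (normal_liver_mass + tnr * tumor_mass)
  list(normal_liver = nl, tumor = tnr * nl)
}

#' Scale per-lesion delivered doses to a hypothetical activity
#'
#' Each lesion's mean dose is linear in the injected activity: multiplying
#' the PET-derived delivered dose-per-activity (Gy/GBq) by a hypothetical
#' injected activity yields the dose the lesion would have received under
#' that plan.
#'
#' @param treatment A [treatment()] object.
#' @param hypothetical_activity Injected activity in GBq, >= 0.
#' @return Named numeric vector of lesion doses in Gy (names = lesion ids).
#' @export
scale_lesion_doses <- function(treatment, hypothetical_activity) {
  stopifnot(inherits(treatment, "sirt_treatment"))
  if (hypothetical_activity < 0) {
    stop("hypothetical_activity must be >= 0", call. = FALSE)
  }
  rates <- vapply(treatment$lesions, `[[`, numeric(1),
                  "delivered_dose_per_activity")
  ids <- vapply(treatment$lesions, `[[`, character(1), "lesion_id")
  stats::setNames(rates * hypothetical_activity, ids)
}
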