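# Domain types for per-treatment dosimetry: lesions, treatments, cohorts.
# Plain validated S3 lists, in the style of survival's Surv / ape's phylo.

#' Construct a lesion record
#'
#' One segmented tumor: its volume, and its mean absorbed dose per unit
#' injected activity as measured on post-therapy Y-90 PET (delivered) and as
#' predicted from pre-therapy Tc-99m MAA SPECT (planning). Mass follows from
#' volume via the fixed tissue density.
#'
#' @param lesion_id Identifier (coerced to character).
#' @param volume Lesion volume in ml; must exceed `min_volume` (the 2 ml
#'   segmentation inclusion limit).
#' @param delivered_dose_per_activity Gy/GBq from Y-90 PET, >= 0.
#' @param planning_dose_per_activity Gy/GBq from MAA SPECT, >= 0
#'   (NA allowed when no planning scan value exists).
#' @param density g/cc for mass conversion.
#' @param min_volume Inclusion threshold in ml (default 2).
#' @return Object of class `sirt_lesion` with a computed `mass` field (kg).
#' @export
lesion <- function(lesion_id, volume, delivered_dose_per_activity,
                   planning_dose_per_activity = NA_real_,
                   density = 1.03, min_volume = 2) {
  if (!is.numeric(volume) || length(volume) != 1 || volume <= min_volume) {
    stop(sprintf("lesion '%s': volume must exceed %g ml", lesion_id,
                 min_volume), call. = FALSE)
  }
  if (delivered_dose_per_activity < 0) {
    stop(sprintf("lesion '%s': delivered dose-per-activity must be >= 0",
                 lesion_id), call. = FALSE)
  }
  if (!is.na(planning_dose_per_activity) && planning_dose_per_activity < 0) {
    stop(sprintf("lesion '%s': planning dose-per-activity must be >= 0",
                 lesion_id), call. = FALSE)
  }
  structure(
    list(lesion_id = as.character(lesion_id),
         volume = volume,
         mass = mass_from_volume(volume, density),
         delivered_dose_per_activity = delivered_dose_per_activity,
         planning_dose_per_activity = planning_dose_per_activity),
    class = "sirt_lesion")
}

#' Construct a treatment record
#'
#' One infused lobe or segment: compartment masses, lung shunt fraction,
#' pooled MAA tumor-to-normal uptake ratio, targeted volume fraction, the
#' lesions it covers, and compartment-level dose-per-activity observations.
#'
#' @param treatment_id Identifier (coerced to character).
#' @param lobe_mass Perfused lobe mass, kg.
#' @param normal_liver_mass Non-tumoral liver mass, kg.
#' @param whole_liver_mass Whole liver mass, kg
#'   (`>= normal_liver_mass`).
#' @param lung_shunt_fraction LSF in \[0, 1).
#' @param tnr Pooled tumor-to-normal uptake ratio from MAA SPECT, >= 0.
#' @param lesions List of [lesion()] objects (>= 1).
#' @param targeted_volume_fraction Perfused fraction Vf of the whole liver,
#'   in (0, 1\].
#' @param normal_liver_dose_per_activity_delivered Gy/GBq from Y-90 PET
#'   (NA allowed).
#' @param normal_liver_dose_per_activity_planning Gy/GBq from MAA SPECT
#'   (NA allowed).
#' @param microsphere_specific_activity kBq per sphere at injection
#'   (NA allowed; required for NTCP planning).
#' @param injected_activity Administered activity, GBq (NA allowed).
#' @param patient_id Optional patient identifier (bilobar patients contribute
#'   two treatments).
#' @return Object of class `sirt_treatment` with `tumor_mass_total` computed
#'   as the sum of lesion masses.
#' @export
treatment <- function(treatment_id, lobe_mass, normal_liver_mass,
                      whole_liver_mass, lung_shunt_fraction, tnr, lesions,
                      targeted_volume_fraction,
                      normal_liver_dose_per_activity_delivered = NA_real_,
                      normal_liver_dose_per_activity_planning = NA_real_,
                      microsphere_specific_activity = NA_real_,
                      injected_activity = NA_real_,
                      patient_id = NA_character_) {
  id <- as.character(treatment_id)
  if (!is.list(lesions) || length(lesions) < 1 ||
      !all(vapply(lesions, inherits, logical(1), "sirt_lesion"))) {
    stop(sprintf("treatment '%s': lesions must be a non-empty list of lesion objects",
                 id), call. = FALSE)
  }
  if (lobe_mass <= 0 || normal_liver_mass <= 0 || whole_liver_mass <= 0) {
    stop(sprintf("treatment '%s': masses must be positive", id), call. = FALSE)
  }
  if (normal_liver_mass > whole_liver_mass + 1e-9) {
    stop(sprintf("treatment '%s': normal_liver_mass exceeds whole_liver_mass",
                 id), call. = FALSE)
  }
  if (lung_shunt_fraction < 0 || lung_shunt_fraction >= 1) {
    stop(sprintf("treatment '%s': lung shunt fraction must lie in [0, 1)", id),
         call. = FALSE)
  }
  if (tnr < 0) stop(sprintf("treatment '%s': tnr must be >= 0", id),
                    call. = FALSE)
  if (targeted_volume_fraction <= 0 || targeted_volume_fraction > 1) {
    stop(sprintf("treatment '%s': targeted_volume_fraction must lie in (0, 1]",
                 id), call. = FALSE)
  }
  structure(
    list(treatment_id = id,
         patient_id = as.character(patient_id),
         lobe_mass = lobe_mass,
         normal_liver_mass = normal_liver_mass,
         whole_liver_mass = whole_liver_mass,
         tumor_mass_total = sum(vapply(lesions, `[[`, numeric(1), "mass")),
         lung_shunt_fraction = lung_shunt_fraction,
         tnr = tnr,
         lesions = lesions,
         targeted_volume_fraction = targeted_volume_fraction,
         normal_liver_dose_per_activity_delivered =
           normal_liver_dose_per_activity_delivered,
         normal_liver_dose_per_activity_planning =
           normal_liver_dose_per_activity_planning,
         microsphere_specific_activity = microsphere_specific_activity,
         injected_activity = injected_activity),
    class = "sirt_treatment")
}

#' @export
print.sirt_treatment <- function(x, ...) {
  cat(sprintf("SIRT treatment '%s': %d lesion(s), lobe %.2f kg, NL %.2f kg, LSF %.3f, TNR %.2f, Vf %.2f\n",
              x$treatment_id, length(x$lesions), x$lobe_mass,
              x$normal_liver_mass, x$lung_shunt_fraction, x$tnr,
              x$targeted_volume_fraction))
  invisible(x)
}

#' Bundle treatments into a cohort
#'
#' @param treatments List of [treatment()] objects.
#' @return Object of class `sirt_cohort` (a validated list).
#' @export
sirt_cohort <- function(treatments) {
  if (!is.list(treatments) || length(treatments) == 0 ||
      !all(vapply(treatments, inherits, logical(1), "sirt_treatment"))) {
    stop("treatments must be a non-empty list of treatment objects",
         call. = FALSE)
  }
  ids <- vapply(treatments, `[[`, character(1), "treatment_id")
  if (anyDuplicated(ids)) stop("duplicate treatment ids", call. = FALSE)
  structure(treatments, class = "sirt_cohort")
}

#' @export
print.sirt_cohort <- function(x, ...) {
  nles <- sum(vapply(x, function(t) length(t$lesions), integer(1)))
  npat <- length(unique(vapply(x, `[[`, character(1), "patient_id")))
  cat(sprintf("SIRT cohort: %d treatments, %d patients, %d lesions\n",
              length(x), npat, nles))
  invisible(x)
}

#' @export
`[.sirt_cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "sirt_cohort")
}

#' Per-lesion view of a cohort
#'
#' Flattens a cohort to one row per lesion with the treatment-level fields
#' repeated — the same layout the cohort CSV uses.
#'
#' @param cohort A [sirt_cohort()].
#' @return A data.frame with one row per lesion.
#' @export
cohort_lesions <- function(cohort) {
  stopifnot(inherits(cohort, "sirt_cohort"))
  rows <- lapply(cohort, function(tr) {
    do.call(rbind, lapply(tr$lesions, function(l) {
      data.frame(
        treatment_id = tr$treatment_id,
        patient_id = tr$patient_id,
        lobe_mass_kg = tr$lobe_mass,
        normal_liver_mass_kg = tr$normal_liver_mass,
        whole_liver_mass_kg = tr$whole_liver_mass,
        lung_shunt_fraction = tr$lung_shunt_fraction,
        tnr = tr$tnr,
        targeted_volume_fraction = tr$targeted_volume_fraction,
        injected_activity_gbq = tr$injected_activity,
        microsphere_specific_activity_kbq = tr$microsphere_specific_activity,
        normal_liver_dpa_delivered = tr$normal_liver_dose_per_activity_delivered,
        normal_liver_dpa_planning = tr$normal_liver_dose_per_activity_planning,
        lesion_id = l$lesion_id,
        lesion_volume_ml = l$volume,
        lesion_dpa_delivered = l$delivered_dose_per_activity,
        lesion_dpa_planning = l$planning_dose_per_activity,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
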