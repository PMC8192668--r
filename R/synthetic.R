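# Synthetic patient cohort generator.
#
# Stands in for an imaging-derived lobar glass-microsphere cohort: ~35
# patients (a few treated in both lobes, ~39 treatments), 1-9 lesions per
# patient with volumes on 2-871 ml, non-tumoral liver volumes on 837-5049 ml,
# injected activities within 0.5-12.6 GBq. Delivered (PET) dose-per-activity
# values are generated from partition physics with per-lesion uptake jitter
# and treated as ground truth; planning (MAA) values are the noisy
# observations, with multiplicative log-normal noise whose SD shrinks with
# volume so that planning-vs-delivered concordance is poor for small lesions
# and strong for normal liver.

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the cohort structure the generator emulates; distribution
#' families and spreads not pinned down by that structure are documented
#' package assumptions (see the methods vignette).
#'
#' @param n_patients Number of patients (default 35).
#' @param bilobar_fraction Probability a (multi-lesion) patient is treated in
#'   both lobes, yielding two treatments (default 4/35, targeting ~39
#'   treatments).
#' @param lesion_count_range Min/max lesions per patient (default c(1, 9)).
#' @param lesion_volume_range Truncation bounds for lesion volumes, ml
#'   (default c(2, 871); lower bound exclusive).
#' @param lesion_volume_meanlog,lesion_volume_sdlog Log-normal parameters of
#'   the untruncated lesion-volume distribution.
#' @param normal_liver_volume_range Uniform bounds for the non-tumoral liver
#'   volume, ml (default c(837, 5049)).
#' @param vf_shape Beta shape parameters for the targeted volume fraction;
#'   the default c(2.6, 2.1) puts ~74% of treatments above Vf = 0.4.
#' @param tnr_meanlog,tnr_sdlog Log-normal parameters of the MAA
#'   tumor-to-normal uptake ratio (median exp(meanlog)).
#' @param lsf_max,lsf_shape1,lsf_shape2 Lung shunt fraction is
#'   `lsf_max * Beta(shape1, shape2)` (default: bounded by 0.2).
#' @param msa_range Uniform bounds for microsphere specific activity at
#'   injection, kBq/sphere.
#' @param lesion_uptake_sdlog Per-lesion multiplicative uptake jitter around
#'   the pooled tumor compartment rate.
#' @param tnr_discordance_sdlog Log-scale SD between the MAA (planning) TNR
#'   and the TNR realized at delivery.
#' @param noise_scale,noise_alpha Planning-vs-delivered multiplicative noise:
#'   log-scale SD is `noise_scale * (volume/100 ml)^(-noise_alpha)`.
#' @param injected_activity_range Clinical clip range for injected
#'   activities, GBq (default c(0.5, 12.6)).
#' @param sm_dose_choices Standard-model prescriptions sampled per treatment
#'   to set the injected activity.
#' @param density g/cc.
#' @param seed Integer seed; fully determines the cohort.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 35,
                          bilobar_fraction = 4 / 35,
                          lesion_count_range = c(1, 9),
                          lesion_volume_range = c(2, 871),
                          lesion_volume_meanlog = log(30),
                          lesion_volume_sdlog = 1.15,
                          normal_liver_volume_range = c(837, 5049),
                          vf_shape = c(2.6, 2.1),
                          tnr_meanlog = log(2.5),
                          tnr_sdlog = 0.45,
                          lsf_max = 0.2, lsf_shape1 = 1.5, lsf_shape2 = 8,
                          msa_range = c(0.5, 2.5),
                          lesion_uptake_sdlog = 0.35,
                          tnr_discordance_sdlog = 0.15,
                          noise_scale = 0.25,
                          noise_alpha = 0.35,
                          injected_activity_range = c(0.5, 12.6),
                          sm_dose_choices = seq(80, 150, by = 10),
                          density = 1.03,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              bilobar_fraction = bilobar_fraction,
              lesion_count_range = as.integer(lesion_count_range),
              lesion_volume_range = lesion_volume_range,
              lesion_volume_meanlog = lesion_volume_meanlog,
              lesion_volume_sdlog = lesion_volume_sdlog,
              normal_liver_volume_range = normal_liver_volume_range,
              vf_shape = vf_shape,
              tnr_meanlog = tnr_meanlog, tnr_sdlog = tnr_sdlog,
              lsf_max = lsf_max, lsf_shape1 = lsf_shape1,
              lsf_shape2 = lsf_shape2,
              msa_range = msa_range,
              lesion_uptake_sdlog = lesion_uptake_sdlog,
              tnr_discordance_sdlog = tnr_discordance_sdlog,
              noise_scale = noise_scale, noise_alpha = noise_alpha,
              injected_activity_range = injected_activity_range,
              sm_dose_choices = sm_dose_choices,
              density = density,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (cfg$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (cfg$bilobar_fraction < 0 || cfg$bilobar_fraction > 1) {
    stop("bilobar_fraction must lie in [0, 1]", call. = FALSE)
  }
  rng_ok <- function(r) length(r) == 2 && r[1] < r[2] && all(r > 0)
  if (!rng_ok(cfg$lesion_volume_range) ||
      !rng_ok(cfg$normal_liver_volume_range) ||
      !rng_ok(cfg$msa_range) || !rng_ok(cfg$injected_activity_range)) {
    stop("range parameters must be increasing positive pairs", call. = FALSE)
  }
  if (cfg$lesion_count_range[1] < 1 ||
      cfg$lesion_count_range[2] < cfg$lesion_count_range[1]) {
    stop("lesion_count_range must be an increasing pair with min >= 1",
         call. = FALSE)
  }
  if (cfg$lsf_max < 0 || cfg$lsf_max >= 1) {
    stop("lsf_max must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$noise_scale < 0 || cfg$lesion_uptake_sdlog < 0 ||
      cfg$tnr_discordance_sdlog < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

# truncated log-normal sampler (rejection; bounds exclusive below)
rlnorm_trunc <- function(n, meanlog, sdlog, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(2 * n, meanlog, sdlog)
    out <- c(out, x[x > lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic treatment cohort
#'
#' @param config A [cohort_config()]. The seed inside the config fully
#'   determines the output; the caller's RNG state is untouched.
#' @param rc_curves Optional list with elements `pet` and `spect` (both
#'   [rc_curve()]); when given, the emitted dose-per-activity values are
#'   partial-volume-degraded observations (multiplied by RC at the relevant
#'   volume) that [apply_rc()] can restore.
#' @return A [sirt_cohort()].
#' @export
generate_cohort <- function(config = cohort_config(), rc_curves = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(rc_curves)) {
    if (!is.list(rc_curves) || !all(c("pet", "spect") %in% names(rc_curves)) ||
        !inherits(rc_curves$pet, "rc_curve") ||
        !inherits(rc_curves$spect, "rc_curve")) {
      stop("rc_curves must be a list with rc_curve elements 'pet' and 'spect'",
           call. = FALSE)
    }
  }
  withr::with_seed(config$seed, generate_cohort_impl(config, rc_curves))
}

generate_cohort_impl <- function(cfg, rc_curves) {
  treatments <- list()
  les_counter <- 0L
  n_min <- cfg$lesion_count_range[1]
  n_max <- cfg$lesion_count_range[2]
  # lesion count: shifted binomial on [n_min, n_max], mean ~= 3.4 at defaults
  p_les <- if (n_max > n_min) (3.43 - n_min) / (n_max - n_min) else 0
  p_les <- min(max(p_les, 0), 1)
  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", i)
    n_les <- n_min + stats::rbinom(1, n_max - n_min, p_les)
    vols <- rlnorm_trunc(n_les, cfg$lesion_volume_meanlog,
                         cfg$lesion_volume_sdlog,
                         cfg$lesion_volume_range[1],
                         cfg$lesion_volume_range[2])
    nl_volume <- stats::runif(1, cfg$normal_liver_volume_range[1],
                              cfg$normal_liver_volume_range[2])
    bilobar <- n_les >= 2 &&
      stats::rbinom(1, 1, cfg$bilobar_fraction) == 1
    groups <- if (bilobar) {
      split_at <- sample(seq_len(n_les - 1), 1)
      list(seq_len(split_at), seq(split_at + 1, n_les))
    } else {
      list(seq_len(n_les))
    }
    for (g in seq_along(groups)) {
      idx <- groups[[g]]
      tid <- if (length(groups) == 1) pid else sprintf("%s-%s", pid,
                                                       c("R", "L")[g])
      treatments[[length(treatments) + 1L]] <-
        generate_treatment(cfg, rc_curves, tid, pid, vols[idx], nl_volume,
                           lesion_ids = les_counter + seq_along(idx))
      les_counter <- les_counter + length(idx)
    }
  }
  sirt_cohort(treatments)
}

generate_treatment <- function(cfg, rc_curves, tid, pid, lesion_vols,
                               nl_volume, lesion_ids) {
  tumor_volume <- sum(lesion_vols)
  whole_volume <- nl_volume + tumor_volume
  vf <- stats::rbeta(1, cfg$vf_shape[1], cfg$vf_shape[2])
  # perfused lobe must contain the lesions with some normal-tissue margin
  vf <- min(max(vf, 1.1 * tumor_volume / whole_volume, 0.05), 1)
  lobe_volume <- vf * whole_volume
  m_lobe <- mass_from_volume(lobe_volume, cfg$density)
  m_nl <- mass_from_volume(nl_volume, cfg$density)
  m_wl <- mass_from_volume(whole_volume, cfg$density)
  m_t <- mass_from_volume(tumor_volume, cfg$density)

  tnr_plan <- stats::rlnorm(1, cfg$tnr_meanlog, cfg$tnr_sdlog)
  tnr_plan <- min(max(tnr_plan, 0.5), 15)
  tnr_del <- tnr_plan * stats::rlnorm(1, -cfg$tnr_discordance_sdlog^2 / 2,
                                      cfg$tnr_discordance_sdlog)
  lsf <- cfg$lsf_max * stats::rbeta(1, cfg$lsf_shape1, cfg$lsf_shape2)
  msa <- stats::runif(1, cfg$msa_range[1], cfg$msa_range[2])

  # ground truth at delivery: partition physics + per-lesion uptake jitter
  rates_del <- partition_dose_rates(m_nl, m_t, tnr_del, lsf)
  jit <- stats::rlnorm(length(lesion_vols),
                       -cfg$lesion_uptake_sdlog^2 / 2,
                       cfg$lesion_uptake_sdlog)
  lesion_del <- rates_del$tumor * jit
  nl_del <- rates_del$normal_liver *
    stats::rlnorm(1, -0.05^2 / 2, 0.05)

  # planning = delivered degraded by volume-dependent discordance
  sd_les <- cfg$noise_scale * (lesion_vols / 100)^(-cfg$noise_alpha)
  lesion_plan <- lesion_del *
    stats::rlnorm(length(lesion_vols), -sd_les^2 / 2, sd_les)
  sd_nl <- cfg$noise_scale * (nl_volume / 100)^(-cfg$noise_alpha)
  nl_plan <- nl_del * stats::rlnorm(1, -sd_nl^2 / 2, sd_nl)

  # partial-volume degradation of the emitted observations, if requested
  if (!is.null(rc_curves)) {
    lesion_del <- lesion_del * rc_value(lesion_vols, rc_curves$pet)
    lesion_plan <- lesion_plan * rc_value(lesion_vols, rc_curves$spect)
    nl_del <- nl_del * rc_value(nl_volume, rc_curves$pet)
    nl_plan <- nl_plan * rc_value(nl_volume, rc_curves$spect)
  }

  sm_dose <- sample(cfg$sm_dose_choices, 1)
  act <- min(max(activity_for_lobe_dose(sm_dose, m_lobe),
                 cfg$injected_activity_range[1]),
             cfg$injected_activity_range[2])

  lesions <- lapply(seq_along(lesion_vols), function(j) {
    lesion(lesion_id = sprintf("L%03d", lesion_ids[j]),
           volume = lesion_vols[j],
           delivered_dose_per_activity = lesion_del[j],
           planning_dose_per_activity = lesion_plan[j],
           density = cfg$density)
  })
  treatment(treatment_id = tid, patient_id = pid,
            lobe_mass = m_lobe, normal_liver_mass = m_nl,
            whole_liver_mass = m_wl,
            lung_shunt_fraction = lsf, tnr = tnr_plan,
            lesions = lesions, targeted_volume_fraction = vf,
            normal_liver_dose_per_activity_delivered = nl_del,
            normal_liver_dose_per_activity_planning = nl_plan,
            microsphere_specific_activity = msa,
            injected_activity = act)
}

#' Simulate binary control outcomes from a TCP model
#'
#' Bernoulli draws with success probability `TCP(dose)`; used for
#' parameter-recovery testing of [fit_tcp()].
#'
#' @param doses Mean absorbed doses, Gy.
#' @param true_model A [tcp_model()].
#' @param seed Integer seed.
#' @return Integer vector of 0/1 outcomes.
#' @export
generate_tcp_outcomes <- function(doses, true_model = tcp_model(), seed = 1L) {
  stopifnot(inherits(true_model, "tcp_model"))
  withr::with_seed(as.integer(seed),
                   stats::rbinom(length(doses), 1, tcp(doses, true_model)))
}

#' Simulate phantom recovery-coefficient measurements
#'
#' Six sphere volumes spanning 2-113 ml, sampled from a known RC curve with
#' multiplicative log-normal noise (clipped to 1 from above).
#'
#' @param true_curve An [rc_curve()].
#' @param noise_sd Log-scale noise SD (0 for exact curve samples).
#' @param seed Integer seed.
#' @param volumes Sphere volumes, ml.
#' @return data.frame with `volume_ml`, `rc`.
#' @export
generate_phantom_rc <- function(true_curve, noise_sd = 0, seed = 1L,
                                volumes = c(2, 6, 15, 35, 70, 113)) {
  stopifnot(inherits(true_curve, "rc_curve"), noise_sd >= 0)
  withr::with_seed(as.integer(seed), {
    rc <- rc_value(volumes, true_curve)
    if (noise_sd > 0) {
      rc <- pmin(rc * stats::rlnorm(length(volumes), 0, noise_sd), 1)
    }
    data.frame(volume_ml = volumes, rc = rc)
  })
}
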