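# Standard-vs-partition prescription parameterization: per-lesion TCP change,
# the (SM dose x PM dose) chart, equivalence-line extraction, per-lesion
# histograms, and planning-vs-delivered concordance stratified by volume.
#
# The construction: for a hypothetical standard-model prescription (dose to
# the perfused lobe) and partition-model prescription (dose to normal liver),
# compute the injected activity each implies, scale every lesion's
# PET-measured dose-per-activity by both activities, push the two doses
# through the TCP curve, and difference the probabilities.

#' Default standard-model prescription axis (Gy to perfused volume)
#' @param step Grid step in Gy.
#' @return Increasing vector of doses spanning 80-150 Gy.
#' @export
default_sm_axis <- function(step = 10) {
  seq(80, 150, by = step)
}

#' Default partition-model prescription axis (Gy to normal liver)
#'
#' A regular grid over 40-150 Gy, always augmented with the clinically
#' discussed values 45, 47, 55, 75 Gy when they fall inside the range.
#'
#' @param step Grid step in Gy.
#' @param include Specific doses always included when in range.
#' @return Increasing vector of doses.
#' @export
default_pm_axis <- function(step = 10, include = c(40, 45, 47, 50, 55, 60, 75)) {
  ax <- seq(40, 150, by = step)
  sort(unique(c(ax, include[include >= min(ax) & include <= max(ax)])))
}

#' Per-lesion TCP change between partition and standard prescriptions
#'
#' For each lesion of a treatment: `dTCP = TCP(rate * A_PM) - TCP(rate * A_SM)`
#' where `rate` is the lesion's delivered dose-per-activity,
#' `A_SM = activity_for_lobe_dose(sm_dose, M_lobe)` and
#' `A_PM = activity_for_partition(pm_dose, M_NL, M_T, TNR, LSF)`.
#'
#' @param treatment A [treatment()].
#' @param sm_dose Standard-model prescription to the perfused lobe, Gy.
#' @param pm_dose Partition-model prescription to normal liver, Gy.
#' @param tcp_model A [tcp_model()].
#' @param relative If `FALSE` (default) returns percentage-point differences
#'   (probability difference x 100); if `TRUE`, relative change in percent
#'   `100 * (TCP_PM - TCP_SM) / TCP_SM`.
#' @return Numeric vector, one element per lesion.
#' @export
per_lesion_delta_tcp <- function(treatment, sm_dose, pm_dose,
                                 tcp_model = sirtdose::tcp_model(),
                                 relative = FALSE) {
  stopifnot(inherits(treatment, "sirt_treatment"))
  a_sm <- activity_for_lobe_dose(sm_dose, treatment$lobe_mass)
  a_pm <- activity_for_partition(pm_dose, treatment$normal_liver_mass,
                                 treatment$tumor_mass_total,
                                 treatment$tnr, treatment$lung_shunt_fraction)
  rates <- vapply(treatment$lesions, `[[`, numeric(1),
                  "delivered_dose_per_activity")
  tcp_sm <- tcp(rates * a_sm, tcp_model)
  tcp_pm <- tcp(rates * a_pm, tcp_model)
  if (relative) 100 * (tcp_pm - tcp_sm) / tcp_sm else 100 * (tcp_pm - tcp_sm)
}

cohort_delta_tcp <- function(cohort, sm_dose, pm_dose, tcp_model, relative = FALSE) {
  unlist(lapply(cohort, per_lesion_delta_tcp, sm_dose = sm_dose,
                pm_dose = pm_dose, tcp_model = tcp_model, relative = relative),
         use.names = FALSE)
}

#' Build the SM-vs-PM TCP-change parameterization chart
#'
#' For every combination of standard-model and partition-model prescription
#' doses, pools the per-lesion TCP changes across the whole cohort (every
#' lesion weighted equally) and records mean, SD, min and max.
#'
#' @param cohort A [sirt_cohort()].
#' @param sm_axis Standard-model doses, Gy (strictly increasing).
#' @param pm_axis Partition-model doses, Gy (strictly increasing).
#' @param tcp_model A [tcp_model()].
#' @param relative Report relative change instead of percentage points.
#' @return A data.frame of class `sirt_chart` in long format with columns
#'   `sm_dose`, `pm_dose`, `mean_delta_tcp`, `sd_delta_tcp`, `min_delta_tcp`,
#'   `max_delta_tcp`, `n_lesions`.
#' @export
build_chart <- function(cohort, sm_axis = default_sm_axis(),
                        pm_axis = default_pm_axis(),
                        tcp_model = sirtdose::tcp_model(),
                        relative = FALSE) {
  stopifnot(inherits(cohort, "sirt_cohort"))
  if (length(sm_axis) < 1 || length(pm_axis) < 1 ||
      is.unsorted(sm_axis, strictly = TRUE) ||
      is.unsorted(pm_axis, strictly = TRUE)) {
    stop("axes must be non-empty and strictly increasing", call. = FALSE)
  }
  grid <- expand.grid(sm_dose = sm_axis, pm_dose = pm_axis,
                      KEEP.OUT.ATTRS = FALSE)
  stats_list <- mapply(function(sm, pm) {
    d <- cohort_delta_tcp(cohort, sm, pm, tcp_model, relative)
    c(mean(d), stats::sd(d), min(d), max(d), length(d))
  }, grid$sm_dose, grid$pm_dose)
  out <- data.frame(
    sm_dose = grid$sm_dose,
    pm_dose = grid$pm_dose,
    mean_delta_tcp = stats_list[1, ],
    sd_delta_tcp = ifelse(is.na(stats_list[2, ]), 0, stats_list[2, ]),
    min_delta_tcp = stats_list[3, ],
    max_delta_tcp = stats_list[4, ],
    n_lesions = as.integer(stats_list[5, ]))
  class(out) <- c("sirt_chart", "data.frame")
  attr(out, "sm_axis") <- sm_axis
  attr(out, "pm_axis") <- pm_axis
  attr(out, "relative") <- relative
  out
}

#' Heatmap of a parameterization chart
#'
#' @param x A `sirt_chart` from [build_chart()].
#' @param ... Passed to [graphics::image()].
#' @export
plot.sirt_chart <- function(x, ...) {
  sm <- attr(x, "sm_axis"); pm <- attr(x, "pm_axis")
  z <- matrix(x$mean_delta_tcp, nrow = length(sm), ncol = length(pm))
  graphics::image(sm, pm, z, xlab = "Standard model dose to perfused volume (Gy)",
                  ylab = "Partition model dose to normal liver (Gy)",
                  main = "Mean TCP change, partition vs standard (pp)",
                  col = grDevices::hcl.colors(31, "Blue-Red 2"), ...)
  graphics::contour(sm, pm, z, levels = 0, add = TRUE, lwd = 2)
  invisible(x)
}

#' Equivalent-TCP line between the two prescription models
#'
#' For each standard-model dose, finds the partition-model dose with zero
#' mean TCP change across the cohort, by bisection to `tol` Gy. Mean TCP
#' change is strictly increasing in the PM dose, so the crossing is unique.
#' If the mean change does not change sign inside `pm_range` the point is
#' flagged (`converged = FALSE`) rather than extrapolated.
#'
#' @param cohort A [sirt_cohort()].
#' @param sm_axis Standard-model doses, Gy.
#' @param tcp_model A [tcp_model()].
#' @param pm_range Search interval for the PM dose, Gy.
#' @param tol Bisection tolerance in Gy (default 0.1).
#' @return data.frame with `sm_dose`, `pm_dose` (NA when flagged),
#'   `converged`.
#' @export
equivalence_line <- function(cohort, sm_axis = default_sm_axis(),
                             tcp_model = sirtdose::tcp_model(),
                             pm_range = c(1, 500), tol = 0.1) {
  stopifnot(inherits(cohort, "sirt_cohort"))
  res <- lapply(sm_axis, function(sm) {
    f <- function(pm) mean(cohort_delta_tcp(cohort, sm, pm, tcp_model))
    lo <- pm_range[1]; hi <- pm_range[2]
    flo <- f(lo); fhi <- f(hi)
    if (flo > 0 || fhi < 0) {
      return(data.frame(sm_dose = sm, pm_dose = NA_real_, converged = FALSE))
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    data.frame(sm_dose = sm, pm_dose = (lo + hi) / 2, converged = TRUE)
  })
  do.call(rbind, res)
}

#' Closed-form equivalent PM dose for a single treatment
#'
#' With one treatment the zero-crossing is exactly where the two hypothetical
#' activities coincide: equating the standard-model and partition-model
#' activity formulas gives
#' `pm = sm * M_lobe * (1 - LSF) / (M_NL + TNR * M_T)`. Used as the
#' analytic oracle for [equivalence_line()].
#'
#' @param treatment A [treatment()].
#' @param sm_dose Standard-model dose, Gy (vectorized).
#' @return Equivalent partition-model dose, Gy.
#' @export
equivalent_pm_dose <- function(treatment, sm_dose) {
  stopifnot(inherits(treatment, "sirt_treatment"))
  sm_dose * treatment$lobe_mass * (1 - treatment$lung_shunt_fraction) /
    (treatment$normal_liver_mass + treatment$tnr * treatment$tumor_mass_total)
}

#' Histogram of per-lesion TCP changes at one prescription pair
#'
#' @param cohort A [sirt_cohort()].
#' @param sm_dose,pm_dose The prescription pair, Gy.
#' @param tcp_model A [tcp_model()].
#' @param bin_width Bin width in percentage points.
#' @return A list of class `sirt_delta_hist`: `breaks`, `counts`, `mids`,
#'   `values` (raw per-lesion changes), and summary `n`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
delta_tcp_histogram <- function(cohort, sm_dose, pm_dose,
                                tcp_model = sirtdose::tcp_model(),
                                bin_width = 5) {
  stopifnot(inherits(cohort, "sirt_cohort"), bin_width > 0)
  d <- cohort_delta_tcp(cohort, sm_dose, pm_dose, tcp_model)
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  structure(list(breaks = h$breaks, counts = h$counts, mids = h$mids,
                 values = d, n = length(d), mean = mean(d),
                 sd = if (length(d) > 1) stats::sd(d) else 0,
                 min = min(d), max = max(d),
                 sm_dose = sm_dose, pm_dose = pm_dose),
            class = "sirt_delta_hist")
}

#' @export
print.sirt_delta_hist <- function(x, ...) {
  cat(sprintf("TCP change, PM %g Gy vs SM %g Gy: n = %d lesions, mean %+.1f pp, SD %.1f pp, range [%+.1f, %+.1f] pp\n",
              x$pm_dose, x$sm_dose, x$n, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Planning-vs-delivered dose concordance, stratified by volume
#'
#' Ordinary least-squares fits of delivered absorbed dose (Y-90 PET) on
#' planned absorbed dose (MAA SPECT) in three strata: all lesions (> 2 ml by
#' inclusion), large lesions, and normal-liver compartments. Doses are the
#' per-activity rates scaled by each treatment's injected activity; when the
#' injected activity is missing the rates themselves are compared (same R^2,
#' different slope units).
#'
#' @param cohort A [sirt_cohort()].
#' @param large_lesion_min Volume threshold for the large-lesion stratum, ml.
#' @param min_points Minimum points per stratum; smaller strata are dropped
#'   with a warning.
#' @return data.frame with `stratum`, `n`, `r_squared`, `slope`, `intercept`.
#' @export
volume_stratified_concordance <- function(cohort, large_lesion_min = 100,
                                          min_points = 3) {
  stopifnot(inherits(cohort, "sirt_cohort"))
  df <- cohort_lesions(cohort)
  act <- ifelse(is.na(df$injected_activity_gbq), 1, df$injected_activity_gbq)
  les <- data.frame(volume = df$lesion_volume_ml,
                    planned = df$lesion_dpa_planning * act,
                    delivered = df$lesion_dpa_delivered * act)
  les <- les[stats::complete.cases(les), , drop = FALSE]
  nl <- do.call(rbind, lapply(cohort, function(tr) {
    a <- if (is.na(tr$injected_activity)) 1 else tr$injected_activity
    data.frame(planned = tr$normal_liver_dose_per_activity_planning * a,
               delivered = tr$normal_liver_dose_per_activity_delivered * a)
  }))
  nl <- nl[stats::complete.cases(nl), , drop = FALSE]
  strata <- list(
    "lesions > 2 ml" = les[, c("planned", "delivered")],
    "large lesions" = les[les$volume > large_lesion_min,
                          c("planned", "delivered")],
    "normal liver" = nl)
  names(strata)[2] <- sprintf("lesions > %g ml", large_lesion_min)
  rows <- lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    if (nrow(s) < min_points) {
      warning(sprintf("stratum '%s' has %d < %d points; omitted", nm,
                      nrow(s), min_points), call. = FALSE)
      return(NULL)
    }
    fit <- stats::lm(delivered ~ planned, data = s)
    # R^2 of simple OLS == squared Pearson correlation; avoids the
    # "essentially perfect fit" summary warning on noiseless fixtures
    data.frame(stratum = nm, n = nrow(s),
               r_squared = stats::cor(s$planned, s$delivered)^2,
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
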