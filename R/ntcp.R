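# Walrand NTCP model for radiation-induced liver disease after microsphere
# therapy: killed lobule fraction, microsphere specific-activity scale
# factor, whole-liver tolerance dose, and its numerical inversion in p.

#' Walrand NTCP model constants
#'
#' The six constants of the whole-liver tolerance dose (WLTD) model:
#' `Kf(p) = kf_scale * (p/(1-p))^(1/kf_root)`,
#' `F(msA) = 1 - exp(-(msA/msa_ref)^(1/3))`,
#' `WLTD(p, Vf, msA) = base_dose * (1 + p_coeff*p) * F / (Vf - Kf)^(exp_coeff*F) * Vf`.
#'
#' @param base_dose Gy (default 47.1).
#' @param kf_scale Dimensionless (default 0.4).
#' @param kf_root Dimensionless root order (default 8.29).
#' @param msa_ref Reference specific activity in kBq (default 0.0471).
#' @param p_coeff Dimensionless (default 0.457).
#' @param exp_coeff Dimensionless (default 0.869).
#' @return Object of class `ntcp_params`.
#' @export
ntcp_params <- function(base_dose = 47.1, kf_scale = 0.4, kf_root = 8.29,
                        msa_ref = 0.0471, p_coeff = 0.457,
                        exp_coeff = 0.869) {
  vals <- c(base_dose, kf_scale, kf_root, msa_ref, p_coeff, exp_coeff)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all NTCP constants must be positive and finite", call. = FALSE)
  }
  structure(list(base_dose = base_dose, kf_scale = kf_scale,
                 kf_root = kf_root, msa_ref = msa_ref,
                 p_coeff = p_coeff, exp_coeff = exp_coeff),
            class = "ntcp_params")
}

#' Killed lobule fraction at a complication probability
#'
#' `Kf(p) = 0.4 * (p/(1-p))^(1/8.29)` with default constants: the fraction of
#' liver lobules killed at NTCP level p. Strictly increasing in p; equals the
#' scale constant 0.4 at even odds (p = 0.5).
#'
#' @param p Complication probability in (0, 1) (vectorized).
#' @param params [ntcp_params()].
#' @return Dimensionless killed fraction.
#' @export
killed_fraction <- function(p, params = ntcp_params()) {
  stopifnot(inherits(params, "ntcp_params"))
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  params$kf_scale * (p / (1 - p))^(1 / params$kf_root)
}

#' Microsphere specific-activity scale factor
#'
#' `F(msA) = 1 - exp(-(msA/0.0471)^(1/3))` with default constants; a
#' dimensionless factor in \[0, 1) related to the mean inter-microsphere
#' distance. Higher specific activity (fewer, hotter spheres for the same
#' activity) pushes F toward 1.
#'
#' @param msa Specific activity per microsphere at injection, kBq, >= 0
#'   (vectorized).
#' @param params [ntcp_params()].
#' @return Dimensionless factor in \[0, 1).
#' @export
msa_factor <- function(msa, params = ntcp_params()) {
  stopifnot(inherits(params, "ntcp_params"))
  if (any(msa < 0)) stop("msa must be >= 0", call. = FALSE)
  1 - exp(-(msa / params$msa_ref)^(1 / 3))
}

#' Whole-liver tolerance dose at an NTCP level
#'
#' Mean whole-liver absorbed dose producing complication probability `p`
#' when the fraction `vf` of the liver is targeted with microspheres of
#' specific activity `msa`. Defined only while `vf > Kf(p)`: once the killed
#' lobule fraction reaches the targeted fraction, no finite whole-liver dose
#' attains that NTCP and the prescription is infeasible.
#'
#' @param p NTCP in (0, 1).
#' @param vf Targeted (perfused) volume fraction of the whole liver, (0, 1\].
#' @param msa Microsphere specific activity, kBq, > 0.
#' @param params [ntcp_params()].
#' @return Dose in Gy.
#' @export
wltd <- function(p, vf, msa, params = ntcp_params()) {
  stopifnot(inherits(params, "ntcp_params"))
  if (any(p <= 0 | p >= 1)) stop("p must lie in (0, 1)", call. = FALSE)
  if (any(vf <= 0 | vf > 1)) stop("vf must lie in (0, 1]", call. = FALSE)
  kf <- killed_fraction(p, params)
  if (any(vf - kf <= 0)) {
    stop(sprintf("infeasible prescription: vf (%.3f) <= killed fraction Kf(p) (%.3f); NTCP %.3f is unreachable at this targeted volume fraction",
                 min(vf), max(kf), max(p)), call. = FALSE)
  }
  f <- msa_factor(msa, params)
  params$base_dose * (1 + params$p_coeff * p) * f /
    (vf - kf)^(params$exp_coeff * f) * vf
}

#' Largest NTCP reachable at a targeted volume fraction
#'
#' The supremum of feasible p values: the root of `Kf(p) = vf`. WLTD diverges
#' as p approaches this bound.
#'
#' @inheritParams wltd
#' @return Probability in (0, 1\].
#' @export
max_feasible_ntcp <- function(vf, params = ntcp_params()) {
  stopifnot(inherits(params, "ntcp_params"))
  if (any(vf <= 0 | vf > 1)) stop("vf must lie in (0, 1]", call. = FALSE)
  odds <- (vf / params$kf_scale)^params$kf_root
  odds / (1 + odds)
}

#' NTCP implied by a whole-liver dose (numerical inversion)
#'
#' Inverts [wltd()] in p by bracketed root search ([stats::uniroot()]).
#' WLTD is strictly increasing in p over the feasible range (the numerator
#' grows and the denominator base shrinks), so the root is unique when it
#' exists. Doses outside the attainable WLTD range are flagged rather than
#' clamped.
#'
#' @param whole_liver_dose Mean whole-liver dose in Gy, > 0.
#' @param vf Targeted volume fraction, (0, 1\].
#' @param msa Microsphere specific activity, kBq.
#' @param params [ntcp_params()].
#' @param p_eps Bracket margin away from 0 and from the feasibility bound.
#' @return A list: `p` (probability, NA when out of range) and `status`
#'   (`"ok"`, `"below_range"` or `"above_range"`).
#' @export
ntcp_from_dose <- function(whole_liver_dose, vf, msa, params = ntcp_params(),
                           p_eps = 1e-12) {
  stopifnot(inherits(params, "ntcp_params"))
  if (whole_liver_dose <= 0) {
    stop("whole_liver_dose must be positive", call. = FALSE)
  }
  p_hi <- max_feasible_ntcp(vf, params) * (1 - 1e-9)
  p_lo <- p_eps
  f <- function(p) wltd(p, vf, msa, params) - whole_liver_dose
  flo <- f(p_lo)
  if (flo > 0) {
    return(list(p = NA_real_, status = "below_range"))
  }
  fhi <- f(p_hi)
  if (!is.finite(fhi) || fhi < 0) {
    return(list(p = NA_real_, status = "above_range"))
  }
  root <- stats::uniroot(f, lower = p_lo, upper = p_hi,
                         f.lower = flo, f.upper = fhi,
                         tol = .Machine$double.eps^0.9, maxiter = 2000)
  list(p = root$root, status = "ok")
}
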