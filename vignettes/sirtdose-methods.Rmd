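---
title: "Models and methods in sirtdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in sirtdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirtdose)
```

# The planning problem

In selective internal radiation therapy (SIRT), Y-90 glass microspheres are
infused into the hepatic artery feeding a tumor-bearing lobe or segment. The
prescriber must choose an injected activity. Two compartmental conventions
coexist in clinical practice:

* the **standard (single-compartment) model**, which prescribes a mean
  absorbed dose (80–150 Gy per the glass-sphere package insert) to the whole
  perfused volume, tumors and normal tissue pooled; and
* the **partition (two-compartment) model**, which prescribes a mean dose
  (40–150 Gy in this package's default axis) to the *normal liver*
  compartment, splitting activity between tumor and parenchyma according to
  the tumor-to-normal uptake ratio (TNR) measured on a pre-treatment
  Tc-99m-MAA SPECT, after removing the lung-shunted fraction (LSF).

The same nominal prescription under the two models implies different injected
activities and therefore different tumor doses. `sirtdose` quantifies that
difference on the probability scale — tumor control probability (TCP) and
normal tissue complication probability (NTCP) — and produces the
parameterization chart that maps any standard-model prescription onto any
partition-model prescription.

# Absorbed-dose arithmetic

All dosimetry uses the non-penetrating MIRD formalism. Y-90 decays with mean
beta energy 933 keV and half-life 2.66 days; with microspheres permanently
trapped (no biological clearance) the cumulated energy is

$$E = 10^9 \cdot \frac{T_{1/2}}{\ln 2}\cdot \bar E_\beta
    = 49.6 \approx 50\ \mathrm{J/GBq},$$

which `energy_per_gbq()` computes exactly and the prescription equations use
as the rounded constant 50. Mean dose to any volume of interest holding a
fraction $A_{VOI}/A$ of the injected activity is
$D/A = 50\,(A_{VOI}/A)/M_{VOI}$ Gy/GBq (`dose_per_activity()`), with masses
from volumes at density 1.03 g/cc (`mass_from_volume()`, the single unit
conversion point).

The standard model inverts this for the perfused lobe,
$A = D\,M_{lobe}/50$ (`activity_for_lobe_dose()`). The printed form carries
no lung-shunt term; because the surrounding assumption ("all injected
activity is in the infused lobe and lung") is ambiguous about intent, an
`include_lsf` flag adds the $(1-\mathrm{LSF})$ deduction, default off.

The partition model prescribes to normal liver:
$$A = \frac{D_{NL}\,(M_{NL} + \mathrm{TNR}\cdot M_T)}{50\,(1-\mathrm{LSF})},
\qquad
\frac{D_{NL}}{A} = \frac{50\,(1-\mathrm{LSF})}{M_{NL}+\mathrm{TNR}\,M_T},
\qquad
\frac{D_T}{A} = \mathrm{TNR}\cdot\frac{D_{NL}}{A},$$
implemented by `activity_for_partition()` / `partition_dose_rates()`, which
are exact mutual inverses (property-tested to 1e-9 relative).

# Dose-response models

**TCP.** A logit curve on mean tumor dose:
$\mathrm{TCP}(D) = 1/(1+e^{-(D-D_{50})/s})$ (`tcp_model()`, `tcp()`). The
defaults ($D_{50} = 200$ Gy, $s = 50$ Gy) are an explicit placeholder: the
coefficients behind published institutional fits are not reproduced here, so
the defaults were chosen once to give a curve of plausible shape (half
control near 200 Gy, saturation beyond ~400 Gy) and must be replaced by a
local fit for any clinical use. `fit_tcp()` provides maximum-likelihood
logistic fitting (via `glm`) so the curve-application machinery is testable
by parameter recovery; it refuses single-class data, separation, and fits
with non-increasing dose response.

**NTCP.** The whole-liver tolerance dose model for radiation-induced liver
disease, with killed lobule fraction and microsphere specific-activity
factor:

$$Kf(p) = 0.4\,\left(\tfrac{p}{1-p}\right)^{1/8.29},\qquad
F(msA) = 1 - e^{-\sqrt[3]{msA/0.0471\,\mathrm{kBq}}},$$
$$\mathrm{WLTD}(p, V_f, msA) = 47.1\ \mathrm{Gy}\cdot
\frac{(1+0.457\,p)\,F(msA)}{(V_f - Kf(p))^{0.869\,F(msA)}}\cdot V_f.$$

The model is defined only while $V_f > Kf(p)$; `wltd()` raises an explicit
infeasibility error at or beyond that pole rather than returning NaN.
`ntcp_from_dose()` inverts WLTD in $p$ by bracketed root search
(`uniroot`, no derivatives — robust near the pole): WLTD is strictly
increasing in $p$ on the feasible interval, so the root is unique; doses
below/above the attainable range return `below_range`/`above_range` flags
instead of clamped probabilities. Round-trip accuracy is property-tested to
1e-9 across a $p \times V_f \times msA$ grid. Note the model is unvalidated
clinically; it is included as planning machinery, not as an outcome
predictor.

# Partial-volume correction

Mean uptake in small objects is depressed by finite scanner resolution.
`sirtdose` corrects mean values with volume-dependent recovery coefficients,
using a saturating-exponential curve
$RC(v) = s\,(1-e^{-(v/v_{50})^k})$ — a standard choice for sphere-phantom
recovery data; the measured curves this emulates are published only as
figures, so the form and coefficients are always fit (`fit_rc_curve()`,
nonlinear least squares with box constraints) or supplied, never hard-coded.
`apply_rc()` divides a mean value by $RC(v)$, flooring RC at 0.05 (with a
warning) so corrections near the 2 ml segmentation limit cannot explode.

# The parameterization chart

For a prescription pair $(D_{SM}, D_{PM})$ and a treatment:

1. $A_{SM} = D_{SM} M_{lobe}/50$ and
   $A_{PM} = D_{PM}(M_{NL}+\mathrm{TNR}\,M_T)/(50(1-\mathrm{LSF}))$ — note
   the deliberate asymmetry: only the partition arm carries the shunt term,
   following the printed equations;
2. each lesion's PET-measured delivered dose-per-activity is scaled by both
   activities;
3. both doses go through the TCP curve and are differenced.

`build_chart()` pools all lesions across all treatments with equal weight
and records mean, SD, min and max of the change per cell, in percentage
points by default (`relative = TRUE` switches to relative change). The grid
defaults to 10 Gy steps — 80–150 Gy on the SM axis, 40–150 Gy on the PM axis
— with the clinically discussed PM values (40, 45, 47, 50, 55, 60, 75 Gy)
always inserted. Per-lesion changes are monotone in each axis, so cell means
inherit monotonicity; both are property-tested.

`equivalence_line()` extracts, for each SM dose, the PM dose of zero mean
TCP change by bisection to 0.1 Gy. For a single treatment the crossing has
the closed form $D_{PM} = D_{SM} M_{lobe}(1-\mathrm{LSF})/(M_{NL}+
\mathrm{TNR}\,M_T)$ (`equivalent_pm_dose()`), which serves as the test
oracle; an unbracketed crossing is flagged, never extrapolated.
`delta_tcp_histogram()` gives the per-lesion distribution at one
prescription pair, and `volume_stratified_concordance()` quantifies
planning-vs-delivered agreement (OLS $R^2$) for all lesions, large lesions
(> 100 ml), and normal-liver compartments.

# NTCP-limited planning

`plan_to_ntcp()` compares a reference standard prescription (default 120 Gy
to the perfused volume) with prescribing to a fixed complication probability
(default 15%, i.e. WLTD15). The model itself never defines how a whole-liver
dose maps to an injected activity; the package's convention is a uniform
whole-liver MIRD dose with hepatic activity $A(1-\mathrm{LSF})$ over the
whole-liver mass, $D_{WL} = 50\,A\,(1-\mathrm{LSF})/M_{WL}$, with a
`liver_mass_convention = "parenchyma"` switch that excludes tumor mass from
the denominator. Because tumor and liver doses both scale linearly with
activity, the percent change in either equals the activity ratio minus one —
an invariant the tests assert. Treatments with targeted volume fraction
$V_f \le 0.40$ are excluded (`is_ntcp_eligible()`): the tolerance-dose model
derives from whole-organ external-beam data and is not meaningful for
segmental targets in a parallel organ.

# The synthetic cohort

No usable tabular patient data accompany the study this machinery supports,
so `generate_cohort()` produces cohorts with the *structure* the analysis
assumes: 35 patients, a few bilobar (two treatments), 1–9 lesions each with
volumes on (2, 871] ml, non-tumoral liver volumes on [837, 5049] ml,
injected activities clipped to [0.5, 12.6] GBq. Delivered (PET) values are
generated from partition physics with per-lesion log-normal uptake jitter
and treated as ground truth; planning (MAA) values are delivered values
degraded by multiplicative log-normal noise whose log-SD is
$0.25\,(v/100\,\mathrm{ml})^{-0.35}$, so concordance degrades with
shrinking volume and the stratified ordering (normal liver ≫ large lesions
> small lesions) emerges rather than being imposed.

Where no source states a distribution, the choice was made once and
documented: lesion counts $1+\mathrm{Binom}(8, 0.304)$ (mean 3.43, giving
~120 lesions); lesion volume truncated log-normal (median 30 ml, log-SD
1.15) — small lesions dominate lobar cohorts; $V_f \sim$ Beta(2.6, 2.1),
fixed by requiring $P(V_f > 0.4) \approx 29/39$ in closed form; TNR
log-normal (median 2.5, log-SD 0.45), the typical MAA range; LSF
$0.2\cdot$Beta(1.5, 8) (most shunts a few percent, bounded by the 0.2
clinical action level); msA uniform on [0.5, 2.5] kBq/sphere (glass spheres
decay across their shelf life). The generator does *not* emulate image-level
effects (reconstruction, registration, segmentation error) — a green test
on synthetic data establishes correctness of the computational chain, not
fidelity of any specific clinical dataset; cohort-specific published
percentages are deliberately not reproduction targets. With
`rc_curves` supplied, the generator instead emits partial-volume-degraded
observations which `correct_cohort_rc()` restores exactly — a round-trip
that tests the PVC plumbing end to end.

# Numerical choices and degenerate inputs

* Seeds: all generators take an explicit seed and restore the caller's RNG
  state (`withr::with_seed`); pipeline outputs are byte-reproducible per
  seed.
* `uniroot` tolerance is set near machine precision so the p-round-trip
  meets 1e-9; bisection on the equivalence line stops at 0.1 Gy, matching
  the chart's clinical resolution.
* Ties/degenerate cases: single-lesion cohorts give SD 0 cells; identical
  matched activities give *exactly* zero TCP change (same doubles, no
  tolerance); empty strata in concordance are dropped with a warning;
  ineligible treatments stay in the NTCP table as flagged rows.
* The RC floor (0.05), the TNR truncation [0.5, 15], and the activity clip
  [0.5, 12.6] GBq are guards that mirror clinical limits, not tuning knobs.

# Known limitations

Compartmental mean doses only (no voxel dosimetry or microdosimetry); the
TCP default curve is a placeholder; the NTCP model is unvalidated and
Child-Pugh stratification is out of scope; the cohort generator reproduces
distributional structure, not patient-level truth; DICOM and image handling
are out of scope by design — the cohort schema (CSV/JSON) is the interface
to upstream imaging pipelines.
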