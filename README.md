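# sirtdose

Treatment-planning dosimetry and dose-response analysis for Y-90
glass-microsphere radioembolization (SIRT) of liver tumors.

## The problem

When prescribing Y-90 microsphere activity, clinics choose between the
**standard (single-compartment) model** — a mean dose of 80–150 Gy to the
whole perfused lobe — and the **partition (two-compartment) model** — a mean
dose to the *normal liver*, splitting activity between tumor and parenchyma
via the MAA-SPECT tumor-to-normal uptake ratio (TNR) and correcting for the
lung shunt fraction (LSF). The same nominal numbers imply different injected
activities and hence different tumor control probabilities (TCP).
`sirtdose` is for medical physicists and dosimetrists who want to quantify
that difference for a treatment population and chart how any standard
prescription maps onto any partition prescription.

## What it computes

All dosimetry is non-penetrating MIRD with the Y-90 constant
E = 10⁹ · (T½/ln 2) · Ē_β = 49.6 ≈ 50 J/GBq:

* **Standard model:** A = D·M_lobe / 50
* **Partition model:** A = D_NL·(M_NL + TNR·M_T) / (50·(1−LSF)), with
  compartment dose rates D_NL/A = 50(1−LSF)/(M_NL + TNR·M_T) and
  D_T/A = TNR·D_NL/A
* **TCP:** logit curve TCP(D) = 1/(1 + e^−(D−D₅₀)/s) on mean tumor dose
  (default parameters are a documented placeholder; fit your own with
  `fit_tcp()`)
* **NTCP (whole-liver tolerance dose):**
  Kf(p) = 0.4·(p/(1−p))^(1/8.29), F(msA) = 1 − e^−(msA/0.0471 kBq)^(1/3),
  WLTD(p, Vf, msA) = 47.1 Gy · (1 + 0.457p)·F / (Vf − Kf)^(0.869F) · Vf,
  numerically inverted by `ntcp_from_dose()`
* **Partial-volume correction:** fitted recovery-coefficient curves
  RC(v) = s·(1 − e^−(v/v₅₀)^k), applied to mean uptake values
* **The parameterization chart:** per-lesion ΔTCP (percentage points)
  between the two models across every prescription pair, its equivalence
  line, per-lesion histograms, and volume-stratified planning-vs-delivered
  concordance
* **NTCP-limited planning:** WLTD at 15% complication probability compared
  with a 120 Gy standard plan, for treatments targeting > 40% of the liver
* **Synthetic cohorts:** `generate_cohort()` emulates a lobar treatment
  population (35 patients, ~39 treatments, ~120 lesions of 2–871 ml) with
  volume-dependent planning/delivered discordance, so the whole pipeline
  runs and is testable without patient data

## Worked example

```r
library(sirtdose)

co <- generate_cohort(cohort_config(seed = 1))
co
#> SIRT cohort: 37 treatments, 35 patients, 135 lesions

ch <- build_chart(co)   # 80-150 Gy SM axis x 40-150 Gy PM axis
subset(as.data.frame(ch), sm_dose == 120 & pm_dose %in% c(47, 75))
#>    sm_dose pm_dose mean_delta_tcp sd_delta_tcp min_delta_tcp max_delta_tcp n_lesions
#> 21     120      47      -2.770114     23.04455     -64.22336      81.42207       135
#> 61     120      75      18.099157     25.53570     -23.53107      90.15379       135
```

Moving this synthetic population from 120 Gy (standard) to 47 Gy to normal
liver (partition) leaves mean TCP nearly unchanged (−2.8 percentage points),
while 75 Gy partition raises it by +18 points on average — but the per-lesion
spread is wide (SD ~25 points), which is the chart's whole message.

```r
equivalence_line(co)
#>   sm_dose  pm_dose converged
#> 1      80 32.82709      TRUE
#> ...
#> 5     120 50.79645      TRUE
#> 8     150 63.64911      TRUE
```

A 120 Gy standard prescription is TCP-equivalent to ~51 Gy to normal liver
via the partition model for this cohort (the line is cohort-specific).

```r
delta_tcp_histogram(co, sm_dose = 120, pm_dose = 75)
#> TCP change, PM 75 Gy vs SM 120 Gy: n = 135 lesions, mean +18.1 pp, SD 25.5 pp, range [-23.5, +90.2] pp

s <- ntcp_cohort_summary(co)   # WLTD15 vs a 120 Gy standard plan
sprintf("NTCP-eligible: %d of %d; mean prescribed-dose change %+.1f%%",
        s$n_eligible, s$n_total, s$mean_percent_change)
#> "NTCP-eligible: 24 of 37; mean prescribed-dose change +28.0%"

volume_stratified_concordance(co)
#>            stratum   n r_squared     slope intercept
#> 1   lesions > 2 ml 135 0.8190257 0.7705751 33.862397
#> 2 lesions > 100 ml  23 0.9529443 0.9313402  6.470636
#> 3     normal liver  37 0.9619748 0.9542637  1.435284
```

Planning (MAA) predicts delivered (PET) dose well for normal liver, less
well for lesions — and worst for small lesions, matching the discordance
structure the generator emulates.

## Command line

```sh
Rscript inst/cli/sirtdose.R all --out run1 --seed 7          # full pipeline
Rscript inst/cli/sirtdose.R simulate --out run2 --seed 7     # cohort only
Rscript inst/cli/sirtdose.R chart --cohort run2/cohort.csv --out run3
```

Outputs are long-format CSVs (`chart.csv`, `equivalence.csv`,
`histogram.csv`, `ntcp_summary.csv`, `concordance.csv`), the cohort in a
versioned CSV schema, and a `manifest.json` recording seed, inputs, stage
timings and warnings; runs are byte-reproducible per seed.

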