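# Shared fixtures: hand-sized treatments with exactly controlled masses.

# a lesion whose mass is exactly `mass_kg` (volume backed out via density)
make_lesion <- function(id = "L1", mass_kg = 0.1, rate = 30, planning = NA) {
  lesion(lesion_id = id, volume = mass_kg * 1000 / 1.03,
         delivered_dose_per_activity = rate,
         planning_dose_per_activity = planning)
}

# single-lesion treatment with controllable compartment masses
make_treatment <- function(id = "T1", lobe = 2, nl = 1.5, wl = 2.5,
                           lsf = 0.05, tnr = 3, vf = 0.6,
                           lesion_mass = 0.2, rate = 30, planning = NA,
                           msa = 1.5, activity = 3,
                           nl_del = NA, nl_plan = NA) {
  treatment(treatment_id = id, lobe_mass = lobe, normal_liver_mass = nl,
            whole_liver_mass = wl, lung_shunt_fraction = lsf, tnr = tnr,
            lesions = list(make_lesion(paste0(id, "-L1"), lesion_mass, rate,
                                       planning)),
            targeted_volume_fraction = vf,
            normal_liver_dose_per_activity_delivered = nl_del,
            normal_liver_dose_per_activity_planning = nl_plan,
            microsphere_specific_activity = msa,
            injected_activity = activity)
}

# treatment engineered so A_SM(d) == A_PM(d) for every dose d:
# LSF = 0, TNR = 1, M_NL + M_T = M_lobe = 1 kg
make_matched_treatment <- function(id = "TM", rate = 30) {
  treatment(treatment_id = id, lobe_mass = 1, normal_liver_mass = 0.8,
            whole_liver_mass = 2, lung_shunt_fraction = 0, tnr = 1,
            lesions = list(make_lesion(paste0(id, "-L1"), 0.2, rate)),
            targeted_volume_fraction = 0.5,
            microsphere_specific_activity = 1)
}

default_test_cohort <- function(seed = 1) {
  generate_cohort(cohort_config(seed = seed))
}
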