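# Shared fixtures: bundled model config and the documented reference
# physiologies for the parent (67.5 kg) and metabolite (63.5 kg) chains.
test_cfg <- default_model_config()
chol <- test_cfg$compounds[["cholesterol"]]
bohc <- test_cfg$compounds[["4b-hydroxycholesterol"]]
phys_ref <- test_cfg$physiology

infusion_rate_ref <- 1.73 * phys_ref$body_weight / 24  # mg/h

# CYP3A5 poor-metabolizer-only template with no CYP3A7, isolating the
# CYP3A4 signal; used by genotype population tests.
pm_template <- function(cyp3a4_mean = 137) {
  population_template(
    abundances = list(CYP3A4 = list(mean = cyp3a4_mean, cv = 0.41),
                      CYP3A5 = list(mean = 102, cv = 0.60),
                      CYP3A7 = list(mean = 2, cv = 0.41),
                      CYP27A1 = list(mean = 41.93, cv = 0)),
    cyp3a5_phenotype_freqs = c(EM = 0, IM = 0, PM = 1))
}

# Degenerate template: every draw equals the template means.
cv0_template <- function(cyp3a4_mean = 137, prop_female = 0) {
  population_template(
    prop_female = prop_female,
    weight = list(mean = 67.5, cv = 0),
    liver_weight = list(mean = 1737.11, cv = 0),
    mppgl = list(mean = 39.79, cv = 0),
    q_h = list(mean = 90, cv = 0),
    abundances = list(CYP3A4 = list(mean = cyp3a4_mean, cv = 0),
                      CYP3A5 = list(mean = 102, cv = 0),
                      CYP3A7 = list(mean = 2, cv = 0),
                      CYP27A1 = list(mean = 41.93, cv = 0)),
    cyp3a5_phenotype_freqs = c(EM = 1, IM = 0, PM = 0))
}
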