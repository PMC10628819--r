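# Default synthetic paired-AST cohort configuration.
# Marginal moments and ranges follow the development-cohort descriptive
# statistics (means, SDs, observed ranges) of the source centre; group
# proportions follow its demographic breakdown. Units: cortisol nmol/L,
# ACTH ng/L, days between tests in days.
n_pairs: 258
seed: 1
correlation: 0.7        # latent (log-scale) correlation among cortisol values
acth_correlation: 0.3   # latent correlation of ACTH with same-test cortisol
outcome_noise_sd: 73.4  # residual SD of the generating previous-AST model
acth_missing_rate: 0.081
variables:
  prev_baseline_cortisol: {mean: 186.0, sd: 109.9, min: 2.0, max: 664.0}
  prev_cortisol_30:       {mean: 360.4, sd: 177.2, min: 12.0, max: 826.0}
  new_baseline_cortisol:  {mean: 205.6, sd: 131.3, min: 2.0, max: 836.0}
  prev_baseline_acth:     {mean: 27.6,  sd: 22.7,  min: 2.0, max: 213.0}
  new_baseline_acth:      {mean: 28.5,  sd: 27.5,  min: 1.0, max: 276.0}
  days_between:           {mean: 318.0, sd: 249.0, min: 18.0, max: 1379.0}
group_proportions:
  sex:
    male: 0.4457143
    female: 0.5542857
  ai_type:
    adrenal_sufficient: 0.0457143
    primary: 0.0285714
    secondary: 0.3028571
    tertiary: 0.6228571
  steroid_route:
    oral: 0.3485714
    inhaler: 0.0914286
    oral_and_inhaled: 0.2685714
    none: 0.2914286
  steroid_formulation:
    hydrocortisone: 0.32
    prednisolone: 0.2971429
    none: 0.3828571
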