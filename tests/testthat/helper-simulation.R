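# Shared helpers: small cohorts with the design and missingness applied.

# A cohort taken through the full pre-analysis pipeline.
make_study_cohort <- function(n = 4000, selection = 0.3,
                              mechanism = "dependent", level = "low",
                              setting = "observed", seed = 1L,
                              params = default_generation_params(setting)) {
  cfg <- calibrate_intercepts(
    params, missingness_config(mechanism, level, setting),
    seed = derive_seed(seed, "calib", 0L), n_ref = 50000
  )
  co <- generate_cohort(params, n, seed = derive_seed(seed, "gen", 1L))
  co <- induce_unintended(co, cfg, seed = derive_seed(seed, "miss", 2L))
  select_subset(co, design_config(n, selection), seed = derive_seed(seed, "sel", 3L))
}

# A fully observed cohort with subset selected but no unintended missingness.
make_clean_cohort <- function(n = 3000, selection = 0.3, seed = 1L,
                              params = default_generation_params()) {
  co <- generate_cohort(params, n, seed = derive_seed(seed, "gen", 1L))
  select_subset(co, design_config(n, selection), seed = derive_seed(seed, "sel", 2L))
}

# Expand a 2x2 table (exposed/unexposed x case/non-case) into record data
# on the study's variable names, all other covariates held at zero.
expand_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  data.frame(
    FoodAllergy = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)),
    VDI = c(rep(1, a + b), rep(0, c + d)),
    Eth = 0, FamHx = 0, PetOwn = 0, AnteVD = 0, NSib = 0, SEIFA = 0, MAge = 0
  )
}
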