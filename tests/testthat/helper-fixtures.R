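# Shared fixtures, all generated in code. The default dataset (full
# experimental design, seed 42) is memoized per test run.

.pf_cache <- new.env(parent = emptyenv())

pf_default_records <- function() {
  if (is.null(.pf_cache$records)) {
    .pf_cache$records <- generate_dataset(sim_config(seed = 42))
  }
  .pf_cache$records
}

# Noise-free configuration with management effects switched off: shoot FW is
# then an exact sigmoid of stick volume and fruit FW a pure DAT curve.
pf_clean_config <- function(seed = 1L) {
  sim_config(
    treatment_effects = list(
      CT = list(shoot = 1, fruit = 1),
      RB = list(shoot = 1, fruit = 1),
      FR = list(shoot = 1, fruit = 1)
    ),
    pruning_prob = 0, struct_weight = 0,
    cv_traits = 0, cv_targets = 0, seed = seed
  )
}

# A single-group record table (one season/treatment/DAT cell) of size n.
pf_group <- function(n, dat = 120L, season = "spring", treatment = "CT",
                     seed = 1L) {
  design <- data.frame(
    year = 2021L, season = season, cultivar = "Mavera", treatment = treatment,
    dat = dat, n = n, stringsAsFactors = FALSE
  )
  generate_dataset(sim_config(design = design, seed = seed))
}

# A small multi-group design spanning both sides of the Gaussian/VAE
# threshold without the full experiment's cost.
pf_small_design <- function() {
  data.frame(
    year = 2021L,
    season = c("spring", "spring", "winter", "winter"),
    cultivar = "Mavera",
    treatment = c("CT", "RB", "CT", "FR"),
    dat = c(60L, 100L, 120L, 150L),
    n = c(4L, 8L, 14L, 16L),
    stringsAsFactors = FALSE
  )
}
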