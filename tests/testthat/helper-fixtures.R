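# Shared fixtures: small cohorts and configs built in code.

# A cohort with the given counts of a single genotype.
one_geno_cohort <- function(r, l, females = 0, males = 0) {
  cohort_of(r, l, females = females, males = males)
}

# Selection with equal survival on both diets (the "fully resistant,
# no differential mortality" benchmark).
equal_survival <- function(s = 0.8) {
  selection_params(toxin_survival = c(0, 0, s), refuge_survival = s)
}

# Neutral selection: no toxin mortality, no refuge mortality.
neutral_selection <- function() {
  selection_params(toxin_survival = c(1, 1, 1), refuge_survival = 1)
}

# Small, fast experiment-1 style config.
small_config <- function(...) {
  defaults <- list(founder_pupae = 60, generations = 2, bioassay_n = 20,
                   master_seed = 99,
                   demography = demography_params(eggs_per_female = 20,
                                                  capacity_refuge = 400,
                                                  capacity_toxin = 400,
                                                  eggs_placed_max = 500))
  do.call(experiment_config, utils::modifyList(defaults, list(...)))
}

# Single-locus Mendelian offspring-copy-number distribution, derived
# independently of the package's transmission code by enumerating the four
# gamete pairs.
single_locus_expect <- function(mother_copies, father_copies) {
  pm <- c(1 - mother_copies / 2, mother_copies / 2)
  pf <- c(1 - father_copies / 2, father_copies / 2)
  d <- numeric(3)
  for (a in 0:1) for (b in 0:1) {
    d[a + b + 1] <- d[a + b + 1] + pm[a + 1] * pf[b + 1]
  }
  d
}
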