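test_that("neutral dynamics leave Hardy-Weinberg frequencies invariant", {
  q <- 0.3
  v <- numeric(9)
  v[genotype(0:2, 0)] <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  st <- freq_state(v, v)
  d <- demography_params(capacity_refuge = Inf, capacity_toxin = Inf,
                         eggs_placed_max = Inf)
  for (g in 1:5) {
    st <- deterministic_generation(st, 0.1, selection = neutral_selection(),
                                   demog = d)
    expect_equal(st$female, v, tolerance = 1e-10)
    expect_equal(st$male, v, tolerance = 1e-10)
  }
})

test_that("a single release pulse decays through the male line", {
  st <- freq_state_of(0, 0)
  d <- demography_params()
  st <- deterministic_generation(st, 0.1, release_ratio = 4,
                                 selection = selection_params(), demog = d)
  lfreq <- sum(st$male * genotype_l(1:9)) / 2
  expect_gt(lfreq, 0)
  for (g in 1:6) {
    st <- deterministic_generation(st, 0.1, release_ratio = 0,
                                   selection = selection_params(), demog = d)
    lnew <- sum(st$male * genotype_l(1:9)) / 2
    expect_lt(lnew, lfreq)
    lfreq <- lnew
  }
  # no female ever carries the construct off tetracycline
  expect_equal(sum(st$female * (genotype_l(1:9) >= 1)), 0)
})

test_that("final resistance is monotone in release ratio and refuge size", {
  final_R <- function(ratio) {
    cfg <- experiment_config(
      strategy = if (ratio > 0) release_strategy("everywhere", base_ratio = ratio)
                 else release_strategy("none"))
    res <- run_oracle(cfg)
    res$freq_R[nrow(res)]
  }
  freqs <- vapply(c(0, 1, 2, 4, 8, 12), final_R, numeric(1))
  expect_true(all(diff(freqs) <= 1e-12))

  final_R_refuge <- function(f) {
    cfg <- experiment_config(regime = selection_regime("homogeneous",
                                                       refuge = f))
    res <- run_oracle(cfg)
    res$freq_R[nrow(res)]
  }
  freqs <- vapply(c(0.05, 0.10, 0.20, 0.50), final_R_refuge, numeric(1))
  expect_true(all(diff(freqs) <= 1e-12))
})

test_that("oracle trajectories expose the design's bounds and extinction", {
  # fully resistant cohort at 10% refuge: proportion pinned at the ceiling
  cfg <- experiment_config(founder_r_freq = 1, selection = equal_survival(),
                           strategy = release_strategy("none"))
  res <- run_oracle(cfg)
  expect_true(all(abs(res$toxin_survivor_prop - 0.9) < 1e-12))
  # all-susceptible, no refuge: immediate extinction, flagged and truncated
  cfg <- experiment_config(founder_r_freq = 0,
                           regime = selection_regime("homogeneous", refuge = 0))
  res <- run_oracle(cfg)
  expect_equal(nrow(res), 1)
  expect_true(res$extinct[1])
})

test_that("brute-force enumeration matches convolution arithmetic", {
  # 1 RSww female x 1 RSww male, 2 eggs, no selection
  adults <- cohort_of(1, 0, females = 1, males = 1)
  bf <- brute_force_generation(adults, n_eggs = 2, diet = "none",
                               selection = selection_params(tetracycline = TRUE))
  expect_false(bf$extinct)
  d <- offspring_distribution(genotype(1, 0), genotype(1, 0))
  per_egg <- bf$egg_dist
  geno_marg <- per_egg[paste0(genotype_label(1:9), ".F")] +
    per_egg[paste0(genotype_label(1:9), ".M")]
  expect_equal(unname(geno_marg), unname(d), tolerance = 1e-12)
  expect_equal(sum(bf$cohort_dist$prob), 1, tolerance = 1e-10)
  # P(both eggs RR) = 0.25^2 from the exact cohort distribution
  rr_cols <- c("RRww.F", "RRww.M")
  both_rr <- bf$cohort_dist[rowSums(bf$cohort_dist[, rr_cols, drop = FALSE]) == 2, ]
  expect_equal(sum(both_rr$prob), 0.0625, tolerance = 1e-10)

  # wild female x released male: all surviving offspring are Lw males
  adults <- cohort_of(0, 0, females = 1, base = cohort_of(0, 2, males = 1))
  bf <- brute_force_generation(adults, n_eggs = 2, diet = "refuge",
                               selection = selection_params(refuge_survival = 1))
  alive <- bf$egg_dist[setdiff(names(bf$egg_dist), "dead")]
  alive <- alive[alive > 0]
  expect_equal(names(alive), "SSLw.M")
  expect_equal(unname(alive), 0.5)

  # empty cohort: extinction with probability 1
  expect_true(brute_force_generation(empty_cohort(), 2)$extinct)
})

test_that("oracle and simulator agree at large population size", {
  # quick two-generation check under everywhere release (the full six-
  # generation, three-mode comparison runs in the acceptance suite)
  cfg <- experiment_config(
    n_subpops = 1, n_replicates = 1, founder_pupae = 20000,
    dispersal_fraction = 0, generations = 3, bioassay_n = 50,
    strategy = release_strategy("everywhere", base_ratio = 4),
    demography = demography_params(capacity_refuge = 5e4,
                                   capacity_toxin = 5e4,
                                   eggs_placed_max = Inf))
  orc <- run_oracle(cfg)
  runs <- lapply(1:8, function(i) {
    set.seed(300 + i)
    state <- new_metapop_state(cfg)
    freqs <- matrix(NA_real_, cfg$generations, 2)
    for (g in seq_len(cfg$generations) - 1L) {
      step <- run_generation(state, cfg, g)
      state <- step$state
      pooled <- state$adults[[1]]
      freqs[g + 1L, ] <- c(allele_freq(pooled, "R"), allele_freq(pooled, "L"))
    }
    freqs
  })
  arr <- simplify2array(runs)
  mean_R <- apply(arr[, 1, ], 1, mean)
  se_R <- apply(arr[, 1, ], 1, sd) / sqrt(length(runs))
  # oracle freq_R is the post-release adult-pool frequency
  expect_true(all(abs(mean_R - orc$freq_R) < 4 * se_R + 0.01))
})
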