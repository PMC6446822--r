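test_that("founders are Hardy-Weinberg with no transgene", {
  set.seed(1)
  expect_equal(cohort_size(make_founders(200, 0)),
               sum(make_founders(200, 0)[genotype(0, 0), ]))
  expect_equal(cohort_size(make_founders(200, 1)),
               sum(make_founders(200, 1)[genotype(2, 0), ]))
  freqs <- replicate(10000, allele_freq(make_founders(200, 0.075), "R"))
  se <- sd(freqs) / sqrt(length(freqs))
  expect_lt(abs(mean(freqs) - 0.075), 3 * se)
  expect_equal(allele_freq(make_founders(500, 0.075), "L"), 0)
})

test_that("experiment 1 has the factorial design's shape and labels", {
  cfg <- small_config()
  traj <- run_experiment1(cfg)
  # 3 treatments x 3 replicates x 3 subpops x 2 generations
  expect_equal(nrow(traj), 3 * 3 * 3 * 2)
  expect_setequal(unique(traj$treatment), c("control", "everywhere", "whack"))
  expect_equal(unique(traj$refuge_fraction), 0.10)
  # controls never receive males; generation 0 precedes all releases
  expect_true(all(traj$released_males[traj$treatment == "control"] == 0))
  expect_true(all(traj$released_males[traj$generation == 0] == 0))
  # the transgene is absent before releases begin
  expect_true(all(traj$freq_L[traj$generation <
                                cfg$release_start_generation] == 0))
})

test_that("trajectories are bit-identical under the same master seed", {
  a <- run_experiment1(small_config())
  b <- run_experiment1(small_config())
  expect_identical(a, b)
  c <- run_experiment1(small_config(master_seed = 100))
  expect_false(identical(a, c))
})

test_that("whack releases target exactly one cage per replicate-generation", {
  cfg <- small_config(generations = 3)
  traj <- run_experiment1(cfg)
  wh <- traj[traj$treatment == "whack" & traj$generation >= 1, ]
  tallies <- tapply(wh$whack_target, interaction(wh$replicate, wh$generation),
                    sum)
  expect_true(all(tallies == 1))
  # and released males land only in the flagged cage
  expect_true(all((wh$released_males > 0) == wh$whack_target))
})

test_that("a fully susceptible population never survives toxin", {
  for (seed in 1:5) {
    traj <- run_experiment1(small_config(founder_r_freq = 0,
                                         master_seed = seed))
    expect_true(all(traj$pupae_toxin == 0))
    expect_true(all(traj$bioassay_survivors == 0))
  }
})

test_that("experiment 2 implements the release x regime factorial", {
  cfg <- experiment2_config(founder_pupae = 60, generations = 2,
                            master_seed = 5,
                            demography = demography_params(
                              eggs_per_female = 20, capacity_refuge = 400,
                              capacity_toxin = 400, eggs_placed_max = 500))
  traj <- run_experiment2(cfg)
  expect_equal(nrow(traj), 2 * 2 * 3 * 3 * 2)
  expect_setequal(unique(traj$treatment), c("everywhere", "whack"))
  expect_setequal(unique(traj$regime), c("homogeneous", "heterogeneous"))
  expect_true(all(traj$bioassay_tested == 150))
  hom <- traj[traj$regime == "homogeneous", ]
  expect_true(all(hom$refuge_fraction == 0.12))
  het <- traj[traj$regime == "heterogeneous", ]
  combos <- split(het$refuge_fraction,
                  interaction(het$treatment, het$replicate, het$generation))
  for (cc in combos) expect_equal(sort(cc), c(0.05, 0.10, 0.20))
})

test_that("early-generation bioassays recover the founder R frequency", {
  # with h = 0 the bioassay estimates the RR egg fraction ~ founder_r_freq^2
  set.seed(21)
  cfg <- experiment_config(founder_pupae = 10000, generations = 1,
                           bioassay_n = 5000, n_subpops = 1,
                           dispersal_fraction = 0,
                           demography = demography_params(
                             capacity_refuge = 1e5, capacity_toxin = 1e5,
                             eggs_placed_max = Inf))
  props <- vapply(1:12, function(i) {
    tr <- run_replicate(cfg, seed = 1000 + i)
    tr$bioassay_survivors[1] / tr$bioassay_tested[1]
  }, numeric(1))
  est <- sqrt(mean(props))
  se_est <- sd(sqrt(props)) / sqrt(length(props))
  expect_lt(abs(est - 0.075), 4 * se_est)
})

test_that("network extinction truncates the trajectory with flagged rows", {
  # no refuge and all-susceptible founders: everything dies in generation 0
  cfg <- small_config(founder_r_freq = 0,
                      regime = selection_regime("homogeneous", refuge = 0))
  traj <- run_experiment1(cfg)
  ctrl <- traj[traj$treatment == "control" & traj$replicate == 1, ]
  expect_equal(unique(ctrl$generation), 0)
  expect_true(all(ctrl$extinct))
})
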