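test_that("toxin-survivor proportion handles bounds and empty cages", {
  expect_equal(toxin_survivor_proportion(0, 20), 0)
  expect_equal(toxin_survivor_proportion(45, 55), 0.45)
  expect_true(is.na(toxin_survivor_proportion(0, 0)))
  expect_equal(toxin_survivor_proportion(c(0, 45, 0), c(20, 55, 0)),
               c(0, 0.45, NA))
  expect_error(toxin_survivor_proportion(-1, 5))
})

test_that("the ceiling equals one minus the refuge fraction", {
  # deterministic: a fully resistant cohort with equal survival on both diets
  st <- freq_state_of(2, 0)
  for (f in c(0.10, 0.12)) {
    nxt <- deterministic_generation(st, f, selection = equal_survival(),
                                    demog = demography_params(
                                      capacity_refuge = Inf,
                                      capacity_toxin = Inf,
                                      eggs_placed_max = Inf))
    expect_equal(attr(nxt, "toxin_survivor_proportion"), 1 - f)
    expect_equal(max_toxin_survivor_proportion(f), 1 - f)
  }
  # stochastic: within binomial error at cage scale
  set.seed(31)
  eggs <- cohort_of(2, 0, females = 5000, males = 5000)
  parts <- allocate_eggs(eggs, refuge_fraction = 0.10)
  d <- demography_params(capacity_refuge = Inf, capacity_toxin = Inf)
  ref <- select_and_pupate(parts$refuge, "refuge", equal_survival(), d, 0.10)
  tox <- select_and_pupate(parts$toxin, "toxin", equal_survival(), d, 0.90)
  p <- toxin_survivor_proportion(cohort_size(tox), cohort_size(ref))
  n <- cohort_size(tox) + cohort_size(ref)
  expect_lt(abs(p - 0.9), 4 * sqrt(0.9 * 0.1 / n))
})

test_that("the bioassay estimates phenotypic resistance", {
  sel <- selection_params()
  set.seed(33)
  rr <- cohort_of(2, 0, females = 100, males = 100)
  expect_equal(unname(bioassay(rr, 100, sel)), c(100, 100),
               ignore_attr = TRUE)
  rs <- cohort_of(1, 0, females = 100, males = 100)
  expect_equal(unname(bioassay(rs, 100, sel)), c(100, 0),
               ignore_attr = TRUE)
  # 20% RR sample: survivors are Binomial(100, 0.2)
  mix <- cohort_of(2, 0, females = 200, base = cohort_of(0, 0, females = 800))
  draws <- replicate(10000, bioassay(mix, 100, sel)[["survivors"]])
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 20), 3 * se)
  # empty and undersized samples are flagged
  out <- bioassay(empty_cohort(), 100, sel)
  expect_equal(unname(out), c(0, 0), ignore_attr = TRUE)
  expect_true(attr(out, "empty_sample"))
  small <- cohort_of(2, 0, females = 5)
  out <- bioassay(small, 100, sel)
  expect_true(attr(out, "with_replacement"))
  expect_equal(out[["tested"]], 100)
})

test_that("network population size sums cages and flags extinction", {
  recs <- data.frame(subpop = 1:3, pupae_refuge = c(20, 30, 30),
                     pupae_toxin = c(40, 40, 40))
  expect_equal(network_population_size(recs), 200)
  dead <- data.frame(subpop = 1:3, pupae_refuge = 0, pupae_toxin = 0)
  out <- network_population_size(dead)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "extinct"))
  expect_error(network_population_size(recs[c(1, 1, 2), ]))
  expect_error(network_population_size(recs[, 1:2]))
})

test_that("trajectory summaries aggregate to replicate-generation rows", {
  traj <- run_experiment1(small_config())
  sm <- summarize_trajectory(traj)
  expect_equal(nrow(sm), 3 * 3 * 2)  # treatment x replicate x generation
  one <- traj[traj$treatment == "control" & traj$replicate == 1 &
                traj$generation == 0, ]
  row <- sm[sm$treatment == "control" & sm$replicate == 1 &
              sm$generation == 0, ]
  expect_equal(row$network_size, sum(one$pupae_refuge + one$pupae_toxin))
  expect_equal(row$bioassay_proportion,
               one$bioassay_survivors[1] / one$bioassay_tested[1])
})
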