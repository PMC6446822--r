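test_that("a fixed line breeds true and extinction is flagged", {
  set.seed(1)
  adults <- cohort_of(2, 0, females = 5, males = 5)
  eggs <- mate_and_lay(adults, demography_params(eggs_per_female = 20))
  expect_gt(cohort_size(eggs), 0)
  expect_equal(sum(eggs[genotype(2, 0), ]), cohort_size(eggs))

  no_males <- cohort_of(0, 0, females = 5)
  out <- mate_and_lay(no_males, demography_params())
  expect_equal(cohort_size(out), 0)
  expect_true(attr(out, "extinct"))
})

test_that("transgenic males sire their share of eggs under random mating", {
  # 10 wild females, 40 released LLSS males, 10 wild males: expect 80% of
  # eggs fathered by transgenic males (all such eggs are Lw)
  set.seed(42)
  adults <- cohort_of(0, 0, females = 10, males = 10)
  adults <- cohort_of(0, 2, males = 40, base = adults)
  d <- demography_params(eggs_per_female = 30)
  props <- replicate(200, {
    eggs <- mate_and_lay(adults, d)
    sum(eggs[genotype(0, 1), ]) / cohort_size(eggs)
  })
  se <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - 0.8), 3 * se + 1e-8)
})

test_that("a single RS x RS cross yields a quarter RR eggs", {
  set.seed(7)
  adults <- cohort_of(1, 0, females = 1, males = 1)
  d <- demography_params(eggs_per_female = 50)
  props <- replicate(400, {
    eggs <- mate_and_lay(adults, d)
    if (cohort_size(eggs) == 0) NA else
      sum(eggs[genotype(2, 0), ]) / cohort_size(eggs)
  })
  props <- props[!is.na(props)]
  se <- sd(props) / sqrt(length(props))
  expect_lt(abs(mean(props) - 0.25), 3 * se)
})

test_that("egg allocation partitions its input exactly", {
  set.seed(3)
  eggs <- cohort(matrix(rpois(18, 40), 9, 2))
  parts <- allocate_eggs(eggs, refuge_fraction = 0.1, bioassay_fraction = 0.1)
  back <- unclass(parts$bioassay) + unclass(parts$refuge) +
    unclass(parts$toxin) + unclass(parts$discarded)
  expect_equal(back, unclass(eggs))
  # placement cap conserves too, and places exactly the cap
  parts <- allocate_eggs(eggs, 0.1, 0.1, eggs_placed_max = 100)
  expect_equal(cohort_size(parts$refuge) + cohort_size(parts$toxin), 100)
  back <- unclass(parts$bioassay) + unclass(parts$refuge) +
    unclass(parts$toxin) + unclass(parts$discarded)
  expect_equal(back, unclass(eggs))
  # degenerate fractions: everything to toxin
  parts <- allocate_eggs(eggs, 0, 0)
  expect_equal(unclass(parts$toxin), unclass(eggs))
  expect_equal(cohort_size(parts$bioassay), 0)
  expect_error(allocate_eggs(eggs, 1.3, 0))
})

test_that("refuge allocation of single-genotype eggs is binomial", {
  set.seed(11)
  eggs <- cohort_of(0, 0, females = 10)
  draws <- replicate(10000,
    cohort_size(allocate_eggs(eggs, refuge_fraction = 0.2)$refuge))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 2), 3 * se)
})

test_that("selection on toxin kills susceptibles and identity holds", {
  set.seed(5)
  d <- demography_params()
  # 100 SS eggs on toxin: no survivors under the high-dose default
  eggs <- cohort_of(0, 0, females = 50, males = 50)
  expect_equal(cohort_size(
    select_and_pupate(eggs, "toxin", selection_params(), d, 0.9)), 0)
  # no mortality sources: identity
  eggs <- cohort(matrix(rpois(18, 10), 9, 2))
  id_sel <- selection_params(toxin_survival = c(1, 1, 1), refuge_survival = 1,
                             tetracycline = TRUE)
  id_dem <- demography_params(capacity_refuge = Inf, capacity_toxin = Inf)
  out <- select_and_pupate(eggs, "toxin", id_sel, id_dem, 0.5)
  expect_equal(unclass(out), unclass(eggs))
})

test_that("female lethality removes transgene carriers at the larval stage", {
  # 80 SSLw eggs, half female, perfect refuge survival: all 40 males pupate
  eggs <- cohort_of(0, 1, females = 40, males = 40)
  sel <- selection_params(refuge_survival = 1)
  out <- select_and_pupate(eggs, "refuge", sel,
                           demography_params(capacity_refuge = Inf), 0.1)
  expect_equal(cohort_size(out), 40)
  expect_equal(sum(out[, "F"]), 0)
  expect_equal(sum(out[genotype(0, 1), "M"]), 40)
  # on tetracycline the females survive
  sel_tet <- selection_params(refuge_survival = 1, tetracycline = TRUE)
  out <- select_and_pupate(eggs, "refuge", sel_tet,
                           demography_params(capacity_refuge = Inf), 0.1)
  expect_equal(cohort_size(out), 80)
})

test_that("density regulation truncates to capacity and preserves proportions", {
  set.seed(9)
  eggs <- cohort(matrix(c(rep(0, 8), 600, rep(0, 8), 200), 9, 2))  # RRLL-ish mix
  sel <- selection_params(toxin_survival = c(1, 1, 1), refuge_survival = 1,
                          tetracycline = TRUE)
  d <- demography_params(capacity_refuge = 100)
  outs <- replicate(600, {
    out <- select_and_pupate(eggs, "refuge", sel, d, 1)
    expect_equal(cohort_size(out), 100)
    expect_true(all(unclass(out) <= unclass(eggs)))  # never increases
    sum(out[, "F"]) / 100
  })
  se <- sd(outs) / sqrt(length(outs))
  expect_lt(abs(mean(outs) - 0.75), 3 * se)
})

test_that("multivariate hypergeometric draws conserve totals and means", {
  set.seed(13)
  counts <- c(5, 0, 12, 3)
  draws <- replicate(4000, rmvhyper(counts, 7))
  expect_true(all(colSums(draws) == 7))
  expect_true(all(draws <= counts))
  means <- rowMeans(draws)
  expect_equal(means, 7 * counts / sum(counts), tolerance = 0.1)
  expect_error(rmvhyper(counts, 21))
})
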