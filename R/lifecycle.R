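# Within-generation demography of one cage: mating, egg laying, allocation
# of eggs to bioassay/refuge/toxin, viability selection, female-lethality
# and density regulation. All draws use R's session RNG; callers seed it.

#' Demography parameters
#'
#' @param eggs_per_female Mean Poisson fecundity per mated female. Default
#'   150, a realistic lifetime egg number for *Plutella xylostella*; with
#'   the standard 10% bioassay removal and 10% refuge this keeps an
#'   everywhere-release cage just at replacement while control cages grow
#'   rapidly to carrying capacity.
#' @param capacity_refuge,capacity_toxin Maximum pupae supported per unit of
#'   diet fraction. The cap actually applied to a diet compartment is
#'   `capacity * diet_fraction`, so realized carrying capacity rises with
#'   phenotypic resistance (resistant cages gain access to the toxin
#'   compartment). Defaults (2000 each) put a fully susceptible cage's
#'   equilibrium at the 200-pupae founder scale under a 10% refuge.
#' @param eggs_placed_max Maximum number of eggs placed onto diet per cage
#'   per generation (after the bioassay sample is removed); surplus eggs
#'   are discarded by uniform without-replacement subsampling, which
#'   preserves genotype proportions in expectation. This models the
#'   protocol's bounded egg placement on a fixed quantity of diet; the
#'   default 2500 is self-consistent with the pupal capacities (2500 x 10%
#'   refuge x 0.8 survival = the 200-pupae refuge capacity) and keeps
#'   per-generation selection intensity at the cage scale rather than the
#'   fecundity scale.
#' @param sex_ratio Probability an egg is female.
#' @return An object of class `demography_params`.
#' @export
demography_params <- function(eggs_per_female = 150, capacity_refuge = 2000,
                              capacity_toxin = 2000, eggs_placed_max = 2500,
                              sex_ratio = 0.5) {
  stopifnot(eggs_per_female > 0, capacity_refuge >= 0, capacity_toxin >= 0,
            eggs_placed_max >= 0, sex_ratio >= 0, sex_ratio <= 1)
  structure(list(eggs_per_female = eggs_per_female,
                 capacity_refuge = capacity_refuge,
                 capacity_toxin = capacity_toxin,
                 eggs_placed_max = eggs_placed_max,
                 sex_ratio = sex_ratio),
            class = "demography_params")
}

#' Random mating and egg production
#'
#' Each female is assigned a single mate drawn with probability proportional
#' to male counts (monandry under random mating); her egg number is Poisson
#' with mean `eggs_per_female`; egg genotypes follow the Mendelian cross
#' distribution and egg sex is Bernoulli(`sex_ratio`). Released transgenic
#' males present in the adult cohort compete for matings on equal terms with
#' wild males.
#'
#' @param adults A `sexed_cohort` of adults.
#' @param demog A [demography_params()] object.
#' @return Egg `sexed_cohort`. If either sex is absent the cohort is empty
#'   and carries `attr(, "extinct") = TRUE`.
#' @export
mate_and_lay <- function(adults, demog) {
  stopifnot(inherits(adults, "sexed_cohort"), inherits(demog, "demography_params"))
  fem <- adults[, "F"]
  mal <- adults[, "M"]
  if (sum(fem) == 0 || sum(mal) == 0) {
    out <- empty_cohort()
    attr(out, "extinct") <- TRUE
    return(out)
  }
  eggs <- matrix(0, N_GENO, 2)
  mate_prob <- mal / sum(mal)
  for (i in which(fem > 0)) {
    mates <- as.vector(stats::rmultinom(1, fem[i], mate_prob))
    for (j in which(mates > 0)) {
      n_eggs <- stats::rpois(1, mates[j] * demog$eggs_per_female)
      if (n_eggs == 0) next
      by_geno <- as.vector(stats::rmultinom(1, n_eggs, OFFSPRING[, i, j]))
      daughters <- stats::rbinom(N_GENO, by_geno, demog$sex_ratio)
      eggs[, 1] <- eggs[, 1] + daughters
      eggs[, 2] <- eggs[, 2] + (by_geno - daughters)
    }
  }
  cohort(eggs)
}

#' Allocate eggs to bioassay sample, refuge diet and toxin diet
#'
#' The bioassay sample is removed first (each egg independently with
#' probability `bioassay_fraction`, before any toxin exposure); the
#' remaining eggs are split between refuge and toxin diet, each egg going to
#' refuge independently with probability `refuge_fraction`. With the
#' default unlimited placement the three parts partition the input exactly;
#' with a finite `eggs_placed_max`, eggs beyond the cap are discarded
#' (uniform without-replacement subsample) and returned in the `discarded`
#' component, so the four parts always partition the input.
#'
#' @param eggs Egg `sexed_cohort`.
#' @param refuge_fraction,bioassay_fraction Proportions in `[0, 1]`.
#' @param eggs_placed_max Cap on eggs placed onto diet after the bioassay
#'   removal (see [demography_params()]); `Inf` places all.
#' @return List with `sexed_cohort` components `bioassay`, `refuge`,
#'   `toxin`, `discarded`.
#' @export
allocate_eggs <- function(eggs, refuge_fraction, bioassay_fraction = 0,
                          eggs_placed_max = Inf) {
  stopifnot(inherits(eggs, "sexed_cohort"),
            refuge_fraction >= 0, refuge_fraction <= 1,
            bioassay_fraction >= 0, bioassay_fraction <= 1,
            eggs_placed_max >= 0)
  n <- as.vector(unclass(eggs))
  bio <- stats::rbinom(length(n), n, bioassay_fraction)
  rest <- n - bio
  if (is.finite(eggs_placed_max) && sum(rest) > eggs_placed_max) {
    placed <- rmvhyper(rest, round(eggs_placed_max))
  } else {
    placed <- rest
  }
  disc <- rest - placed
  ref <- stats::rbinom(length(placed), placed, refuge_fraction)
  tox <- placed - ref
  list(bioassay  = cohort(matrix(bio, N_GENO, 2)),
       refuge    = cohort(matrix(ref, N_GENO, 2)),
       toxin     = cohort(matrix(tox, N_GENO, 2)),
       discarded = cohort(matrix(disc, N_GENO, 2)))
}

#' Larval selection, female-lethality and pupation on one diet
#'
#' Each egg survives independently with its genotype's [diet_survival()].
#' Off tetracycline, surviving females carrying the L construct are removed
#' (lethality acts at the larval stage, before the pupal census). If the
#' survivors exceed the compartment's carrying capacity
#' (`capacity * diet_fraction`), a uniform without-replacement subsample of
#' exactly the capacity is retained (hypergeometric thinning, which
#' preserves genotype proportions in expectation).
#'
#' @param eggs_on_diet Egg `sexed_cohort` placed on this diet.
#' @param diet `"toxin"` or `"refuge"`.
#' @param selection A [selection_params()] object.
#' @param demog A [demography_params()] object.
#' @param diet_fraction Fraction of the cage's diet this compartment holds
#'   (scales the capacity).
#' @return Pupal `sexed_cohort`.
#' @export
select_and_pupate <- function(eggs_on_diet, diet = c("toxin", "refuge"),
                              selection, demog, diet_fraction = 1) {
  diet <- match.arg(diet)
  stopifnot(inherits(eggs_on_diet, "sexed_cohort"),
            diet_fraction >= 0, diet_fraction <= 1)
  surv <- diet_survival(seq_len(N_GENO), diet, selection)
  n <- unclass(eggs_on_diet)
  pup <- matrix(stats::rbinom(2L * N_GENO, as.vector(n), rep(surv, 2)),
                N_GENO, 2)
  if (!selection$tetracycline) pup[GENO_L >= 1L, 1] <- 0
  cap <- switch(diet, toxin = demog$capacity_toxin,
                refuge = demog$capacity_refuge) * diet_fraction
  total <- sum(pup)
  if (is.finite(cap) && total > cap) {
    return(cohort_subsample(cohort(pup), round(cap)))
  }
  cohort(pup)
}
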