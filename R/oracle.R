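# Deterministic infinite-population recursion: the expected-value
# counterpart of the stochastic cage, with the identical event order.
# Used to verify the simulator and to explore expected dynamics quickly.

#' Deterministic frequency state
#'
#' Per-sex genotype frequency vectors plus expected population sizes for a
#' single panmictic cage.
#'
#' @param female,male Numeric length-9 genotype frequency vectors (need not
#'   be normalized on input; they are rescaled to sum to 1).
#' @param size_f,size_m Expected adult counts (population-scale bookkeeping).
#' @return An object of class `freq_state`.
#' @export
freq_state <- function(female, male = female, size_f = 100, size_m = 100) {
  stopifnot(length(female) == N_GENO, length(male) == N_GENO,
            all(female >= 0), all(male >= 0), sum(female) > 0, sum(male) > 0)
  structure(list(female = female / sum(female), male = male / sum(male),
                 size_f = size_f, size_m = size_m, extinct = FALSE),
            class = "freq_state")
}

#' Frequency state for a single-genotype cohort
#'
#' @param r_copies,l_copies Genotype of the cohort.
#' @param size_f,size_m Expected adult counts.
#' @return A `freq_state` concentrated on one genotype.
#' @export
freq_state_of <- function(r_copies, l_copies, size_f = 100, size_m = 100) {
  v <- numeric(N_GENO)
  v[genotype(r_copies, l_copies)] <- 1
  freq_state(v, v, size_f, size_m)
}

#' One deterministic generation
#'
#' Expected-value transcription of the cage event order: random-mating
#' offspring distribution, bioassay removal, refuge/toxin egg allocation,
#' diet-specific viability selection, female-lethality off tetracycline,
#' capacity truncation of the expected size, and male release as a
#' frequency injection. A release at count ratio `release_ratio` (rho)
#' shifts the male frequency vector to
#' `(male + rho * e_LLSS) / (1 + rho)`, the expected-value analogue of
#' adding `rho` transgenic males per wild male.
#'
#' @param state A [freq_state()].
#' @param refuge_fraction Refuge diet fraction of the cage.
#' @param release_ratio Transgenic:wild male release ratio applied to the
#'   next mating pool (0 = no release).
#' @param selection A [selection_params()] object.
#' @param demog A [demography_params()] object.
#' @param bioassay_fraction Fraction of eggs removed before the diet split.
#' @return The next `freq_state`, with attributes
#'   `toxin_survivor_proportion` (of the resulting pupal pool) and
#'   `pupae_expected` (expected pupal census before release).
#' @export
deterministic_generation <- function(state, refuge_fraction,
                                     release_ratio = 0,
                                     selection = selection_params(),
                                     demog = demography_params(),
                                     bioassay_fraction = 0) {
  stopifnot(inherits(state, "freq_state"),
            refuge_fraction >= 0, refuge_fraction <= 1, release_ratio >= 0)
  if (state$extinct) return(state)
  f <- refuge_fraction

  # offspring genotype distribution under random mating
  cross <- matrix(OFFSPRING, nrow = N_GENO)  # 9 x 81, [offspring, (mother,father)]
  off <- as.vector(cross %*% as.vector(outer(state$female, state$male)))

  s_ref <- diet_survival(seq_len(N_GENO), "refuge", selection)
  s_tox <- diet_survival(seq_len(N_GENO), "toxin", selection)
  viable_f <- as.numeric(female_is_viable(seq_len(N_GENO),
                                          selection$tetracycline))

  # expected egg numbers on each diet (placement cap mirrored in expectation)
  eggs <- min(state$size_f * demog$eggs_per_female * (1 - bioassay_fraction),
              demog$eggs_placed_max)
  sr <- demog$sex_ratio
  ref_f <- off * s_ref * viable_f * sr * f * eggs
  ref_m <- off * s_ref * (1 - sr) * f * eggs
  tox_f <- off * s_tox * viable_f * sr * (1 - f) * eggs
  tox_m <- off * s_tox * (1 - sr) * (1 - f) * eggs

  # capacity truncation per diet compartment (proportions preserved)
  cap_ref <- demog$capacity_refuge * f
  cap_tox <- demog$capacity_toxin * (1 - f)
  shrink <- function(fv, mv, cap) {
    tot <- sum(fv) + sum(mv)
    if (is.finite(cap) && tot > cap && tot > 0) {
      fv <- fv * cap / tot
      mv <- mv * cap / tot
    }
    list(f = fv, m = mv)
  }
  ref <- shrink(ref_f, ref_m, cap_ref)
  tox <- shrink(tox_f, tox_m, cap_tox)

  pup_f <- ref$f + tox$f
  pup_m <- ref$m + tox$m
  tox_total <- sum(tox$f) + sum(tox$m)
  pup_total <- sum(pup_f) + sum(pup_m)

  if (sum(pup_f) == 0 || sum(pup_m) == 0) {
    state$extinct <- TRUE
    state$size_f <- sum(pup_f)
    state$size_m <- sum(pup_m)
    attr(state, "toxin_survivor_proportion") <-
      if (pup_total > 0) tox_total / pup_total else NA_real_
    attr(state, "pupae_expected") <- pup_total
    return(state)
  }

  male <- pup_m / sum(pup_m)
  size_m <- sum(pup_m)
  if (release_ratio > 0) {
    inj <- numeric(N_GENO)
    inj[genotype(0, 2)] <- 1
    male <- (male + release_ratio * inj) / (1 + release_ratio)
    size_m <- size_m * (1 + release_ratio)
  }

  out <- freq_state(pup_f / sum(pup_f), male,
                    size_f = sum(pup_f), size_m = size_m)
  attr(out, "toxin_survivor_proportion") <-
    if (pup_total > 0) tox_total / pup_total else NA_real_
  attr(out, "pupae_expected") <- pup_total
  out
}

#' Maximum attainable toxin-survivor proportion
#'
#' With equal survival on both diets, a fully resistant cohort's expected
#' toxin-survivor-in-cage proportion is bounded by the toxin diet share:
#' `1 - refuge_fraction` (0.9 at a 10% refuge; 0.88 at the 12% refuge of
#' the homogeneous-selection arm).
#'
#' @param refuge_fraction Refuge fraction in `[0, 1]`.
#' @return `1 - refuge_fraction`.
#' @export
max_toxin_survivor_proportion <- function(refuge_fraction) {
  stopifnot(all(refuge_fraction >= 0 & refuge_fraction <= 1))
  1 - refuge_fraction
}

#' Oracle trajectory for a configuration
#'
#' Runs the deterministic recursion for a single panmictic cage under a
#' config's parameters. Whack-mode configs are interpreted as the target
#' cage (local ratio `base_ratio * whack_multiplier`); heterogeneous
#' regimes use the mean refuge fraction (the oracle has no spatial
#' structure; it exists for verification, not spatial replication).
#'
#' @param cfg An [experiment_config()].
#' @param state Optional initial [freq_state()]; defaults to
#'   Hardy-Weinberg at `cfg$founder_r_freq`, no transgene.
#' @return Data frame, one row per generation: allele frequencies by locus
#'   and sex, toxin-survivor proportion, expected sizes, applied release
#'   ratio, extinction flag.
#' @export
run_oracle <- function(cfg, state = NULL) {
  validate_config(cfg)
  if (is.null(state)) {
    q <- cfg$founder_r_freq
    hw <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    v <- numeric(N_GENO)
    v[genotype(0:2, 0)] <- hw
    half <- cfg$founder_pupae / 2
    state <- freq_state(v, v, size_f = half, size_m = half)
  }
  f <- if (cfg$regime$mode == "homogeneous") cfg$regime$refuge
       else mean(cfg$regime$heterogeneous_refuges)
  ratio_of <- function(gen_next) {
    # a release only feeds a generation that is actually simulated
    if (cfg$strategy$mode == "none" ||
        gen_next < cfg$release_start_generation ||
        gen_next > cfg$release_stop_generation ||
        gen_next > cfg$generations - 1) return(0)
    switch(cfg$strategy$mode,
           everywhere = cfg$strategy$base_ratio,
           whack = cfg$strategy$base_ratio * cfg$strategy$whack_multiplier)
  }
  rows <- vector("list", cfg$generations)
  for (g in seq_len(cfg$generations) - 1L) {
    rho <- ratio_of(g + 1)
    nxt <- deterministic_generation(state, f, release_ratio = rho,
                                    selection = cfg$selection,
                                    demog = cfg$demography,
                                    bioassay_fraction = cfg$bioassay_fraction)
    wf <- nxt$size_f
    wm <- nxt$size_m
    wt <- wf + wm
    freq_R <- if (wt > 0)
      (sum(nxt$female * GENO_R) * wf + sum(nxt$male * GENO_R) * wm) / (2 * wt)
      else NA_real_
    freq_L <- if (wt > 0)
      (sum(nxt$female * GENO_L) * wf + sum(nxt$male * GENO_L) * wm) / (2 * wt)
      else NA_real_
    rows[[g + 1L]] <- data.frame(
      generation = g, refuge_fraction = f, release_ratio = rho,
      freq_R = freq_R, freq_L = freq_L,
      freq_R_female = sum(nxt$female * GENO_R) / 2,
      freq_R_male = sum(nxt$male * GENO_R) / 2,
      freq_L_male = sum(nxt$male * GENO_L) / 2,
      toxin_survivor_prop = attr(nxt, "toxin_survivor_proportion"),
      expected_pupae = attr(nxt, "pupae_expected"),
      extinct = nxt$extinct)
    state <- nxt
    if (state$extinct) {
      rows <- rows[seq_len(g + 1L)]
      break
    }
  }
  do.call(rbind, rows)
}

#' Exact small-cohort generation by exhaustive enumeration
#'
#' Testing oracle: for a cohort of at most 6 adults and a fixed clutch size,
#' enumerates every mate assignment (each female paired with each male with
#' probability proportional to male counts) and computes the exact per-egg
#' outcome distribution over (genotype, sex, survival) and, from it, the
#' exact distribution over surviving-offspring cohorts (multinomial over
#' outcome categories). Independent of the stochastic engine's code paths.
#'
#' @param adults A `sexed_cohort` with at most 6 individuals.
#' @param n_eggs Total egg number conditioned on (small).
#' @param diet `"refuge"` or `"toxin"` diet the eggs develop on, or
#'   `"none"` for no diet mortality.
#' @param selection A [selection_params()] object.
#' @return List with `egg_dist` (exact per-egg probability over 18
#'   genotype-sex categories plus death) and `cohort_dist` (data frame of
#'   surviving cohort compositions and probabilities). An empty or
#'   single-sex cohort returns `extinct = TRUE` with probability 1.
#' @export
brute_force_generation <- function(adults, n_eggs = 2,
                                   diet = c("none", "refuge", "toxin"),
                                   selection = selection_params()) {
  diet <- match.arg(diet)
  stopifnot(inherits(adults, "sexed_cohort"), cohort_size(adults) <= 6,
            n_eggs >= 0)
  fem <- adults[, "F"]
  mal <- adults[, "M"]
  if (sum(fem) == 0 || sum(mal) == 0) {
    return(list(extinct = TRUE, egg_dist = NULL, cohort_dist = NULL))
  }
  # Exact per-egg distribution: mother chosen proportional to female counts
  # (each female contributes equally in expectation), father proportional
  # to male counts.
  p_mother <- fem / sum(fem)
  p_father <- mal / sum(mal)
  egg_geno <- numeric(N_GENO)
  for (i in which(p_mother > 0)) for (j in which(p_father > 0)) {
    egg_geno <- egg_geno + p_mother[i] * p_father[j] * OFFSPRING[, i, j]
  }
  surv <- switch(diet,
                 none = rep(1, N_GENO),
                 refuge = diet_survival(seq_len(N_GENO), "refuge", selection),
                 toxin = diet_survival(seq_len(N_GENO), "toxin", selection))
  viable_f <- as.numeric(female_is_viable(seq_len(N_GENO),
                                          selection$tetracycline))
  p_f <- egg_geno * 0.5 * surv * viable_f
  p_m <- egg_geno * 0.5 * surv
  p_dead <- 1 - sum(p_f) - sum(p_m)
  egg_dist <- c(stats::setNames(p_f, paste0(GENO_LABELS, ".F")),
                stats::setNames(p_m, paste0(GENO_LABELS, ".M")),
                dead = p_dead)

  # Exact cohort distribution: multinomial over the 19 per-egg outcomes.
  cats <- which(egg_dist > 0)
  comp <- compositions(n_eggs, length(cats))
  probs <- apply(comp, 1, function(x) stats::dmultinom(x, prob = egg_dist[cats]))
  cohort_dist <- as.data.frame(comp)
  names(cohort_dist) <- names(egg_dist)[cats]
  cohort_dist$prob <- probs
  list(extinct = FALSE, egg_dist = egg_dist, cohort_dist = cohort_dist)
}

# All compositions of n into k non-negative parts (rows).
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  out <- list()
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1)
    out[[first + 1]] <- cbind(first, rest)
  }
  m <- do.call(rbind, out)
  dimnames(m) <- NULL
  m
}
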