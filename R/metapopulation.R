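# Network layer: pre-mating pupal dispersal among cages, per-generation
# refuge assignment, and the release policies (none / everywhere 4:1 /
# whack-a-mole 12:1 into the cage with most toxin survivors).

#' Release strategy
#'
#' @param mode `"none"` (control), `"everywhere"` (homogeneous release at
#'   `base_ratio`:1 transgenic:wild males into every subpopulation) or
#'   `"whack"` (whack-a-mole: the whole budget at
#'   `base_ratio * whack_multiplier`:1 into the single subpopulation with
#'   the most survivors on toxin diet).
#' @param base_ratio Transgenic:wild male release ratio (default 4).
#' @param whack_multiplier Local ratio multiplier for whack-a-mole releases
#'   (default 3, giving 12:1 into one of three cages, so that total numbers
#'   released are standardized across release treatments).
#' @param release_when_empty If all toxin-survivor counts are zero, still
#'   release the full budget at a random subpopulation (`TRUE`, the
#'   protocol's behaviour) or skip the release (`FALSE`).
#' @param fixed_target Optional persistent target subpopulation id for
#'   whack-mode releases (a fixed-source variant); `NULL` retargets each
#'   generation.
#' @return An object of class `release_strategy`.
#' @export
release_strategy <- function(mode = c("none", "everywhere", "whack"),
                             base_ratio = 4, whack_multiplier = 3,
                             release_when_empty = TRUE, fixed_target = NULL) {
  mode <- match.arg(mode)
  stopifnot(base_ratio >= 0, whack_multiplier >= 0)
  structure(list(mode = mode, base_ratio = base_ratio,
                 whack_multiplier = whack_multiplier,
                 release_when_empty = isTRUE(release_when_empty),
                 fixed_target = fixed_target),
            class = "release_strategy")
}

#' Selection (refuge) regime
#'
#' @param mode `"homogeneous"`: every subpopulation gets `refuge` every
#'   generation. `"heterogeneous"`: each generation the refuge sizes in
#'   `heterogeneous_refuges` are assigned to subpopulations by a fresh
#'   uniform random permutation.
#' @param refuge Homogeneous refuge fraction (0.12 in the factorial
#'   homogeneous-selection arm; 0.10 in the first experiment).
#' @param heterogeneous_refuges Refuge fractions permuted among
#'   subpopulations under heterogeneous selection (default 5%, 10%, 20%,
#'   mean-matched to the 12% homogeneous arm).
#' @return An object of class `selection_regime`.
#' @export
selection_regime <- function(mode = c("homogeneous", "heterogeneous"),
                             refuge = 0.12,
                             heterogeneous_refuges = c(0.05, 0.10, 0.20)) {
  mode <- match.arg(mode)
  stopifnot(refuge >= 0, refuge <= 1,
            all(heterogeneous_refuges >= 0 & heterogeneous_refuges <= 1))
  structure(list(mode = mode, refuge = refuge,
                 heterogeneous_refuges = heterogeneous_refuges),
            class = "selection_regime")
}

#' Refuge fractions for one generation
#'
#' @param regime A [selection_regime()] object.
#' @param n_subpops Number of subpopulations.
#' @return Numeric vector of refuge fractions, one per subpopulation.
#' @export
assign_refuges <- function(regime, n_subpops) {
  stopifnot(inherits(regime, "selection_regime"))
  if (regime$mode == "homogeneous") return(rep(regime$refuge, n_subpops))
  stopifnot(length(regime$heterogeneous_refuges) == n_subpops)
  sample(regime$heterogeneous_refuges)
}

#' Pre-mating pupal dispersal
#'
#' From each subpopulation, `round(fraction * total)` pupae are drawn
#' uniformly without replacement and split as evenly as possible among the
#' other subpopulations (any odd remainder assigned to receivers chosen at
#' random). Movement is computed from the pre-dispersal states, so the
#' exchange is simultaneous and the network total (and every genotype's
#' network-wide count) is conserved exactly.
#'
#' @param pupae List of `sexed_cohort`s, one per subpopulation.
#' @param dispersal_fraction Proportion of each cage's pupae that emigrates.
#' @return List of post-dispersal `sexed_cohort`s.
#' @export
disperse <- function(pupae, dispersal_fraction) {
  stopifnot(dispersal_fraction >= 0, dispersal_fraction <= 1)
  k <- length(pupae)
  if (k < 2 || dispersal_fraction == 0) return(pupae)
  flat <- vapply(pupae, function(x) as.vector(unclass(x)), numeric(2L * N_GENO))
  stay <- flat
  incoming <- matrix(0, 2L * N_GENO, k)
  for (s in seq_len(k)) {
    n_move <- round(dispersal_fraction * sum(flat[, s]))
    if (n_move == 0) next
    migrants <- rmvhyper(flat[, s], n_move)
    stay[, s] <- flat[, s] - migrants
    receivers <- setdiff(seq_len(k), s)
    n_recv <- length(receivers)
    batch <- rep.int(n_move %/% n_recv, n_recv)
    rem <- n_move %% n_recv
    if (rem > 0) {
      extra <- sample(n_recv, rem)
      batch[extra] <- batch[extra] + 1L
    }
    remaining <- migrants
    for (ri in seq_len(n_recv)) {
      part <- rmvhyper(remaining, batch[ri])
      incoming[, receivers[ri]] <- incoming[, receivers[ri]] + part
      remaining <- remaining - part
    }
  }
  lapply(seq_len(k), function(s) cohort(matrix(stay[, s] + incoming[, s],
                                               N_GENO, 2)))
}

#' Choose the whack-a-mole target subpopulation
#'
#' Returns the index of the subpopulation with the highest count of
#' survivors on toxin diet in the current generation (the cage at greatest
#' risk of evolving resistance), ties broken uniformly at random. When all
#' counts are zero a uniformly random id is still returned, since the
#' protocol always deployed the full release budget.
#'
#' @param toxin_counts Integer vector of per-subpopulation toxin-diet pupal
#'   counts (post-selection, pre-dispersal).
#' @return Subpopulation index.
#' @export
choose_whack_target <- function(toxin_counts) {
  stopifnot(length(toxin_counts) >= 1, all(toxin_counts >= 0))
  best <- which(toxin_counts == max(toxin_counts))
  if (length(best) == 1) best else best[sample.int(length(best), 1)]
}

#' Apply a release of transgenic males
#'
#' Releases homozygous self-limiting, homozygous-susceptible (LLSS) males,
#' timed to coincide with emergence of the local wild males: the number
#' released is the configured ratio times the subpopulation's local male
#' pupal count (after dispersal). Everywhere mode releases at
#' `base_ratio`:1 into every subpopulation; whack mode releases at
#' `base_ratio * whack_multiplier`:1 into `target` only. Released males
#' join the mating pool but are not themselves dispersed.
#'
#' @param pupae List of post-dispersal `sexed_cohort`s.
#' @param strategy A [release_strategy()] object.
#' @param target Whack-mode target id (from [choose_whack_target()]);
#'   ignored in other modes. `NA` suppresses the release.
#' @return List with `pupae` (cohorts including released males) and
#'   `released` (integer vector of males released per subpopulation).
#' @export
apply_release <- function(pupae, strategy, target = NULL) {
  stopifnot(inherits(strategy, "release_strategy"))
  k <- length(pupae)
  released <- integer(k)
  g_rel <- genotype(0, 2)  # LLSS
  if (strategy$mode == "everywhere") {
    for (s in seq_len(k)) {
      released[s] <- round(strategy$base_ratio * sum(pupae[[s]][, "M"]))
    }
  } else if (strategy$mode == "whack") {
    if (!is.null(target) && !is.na(target)) {
      ratio <- strategy$base_ratio * strategy$whack_multiplier
      released[target] <- round(ratio * sum(pupae[[target]][, "M"]))
    }
  }
  for (s in seq_len(k)) {
    if (released[s] > 0) {
      pupae[[s]][g_rel, "M"] <- pupae[[s]][g_rel, "M"] + released[s]
    }
  }
  list(pupae = pupae, released = released)
}
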