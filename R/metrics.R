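# The two resistance readouts and population summaries.

#' Toxin survivors in cage
#'
#' The proportional resistance measure: pupae surviving on toxin diet
#' divided by the entire pupal population of the cage. Varies from 0 (no
#' phenotypic resistance) to a maximum of 1 minus the refuge fraction
#' (0.9 at a 10% refuge, 0.88 at 12%) when survival on both diets is equal.
#' An empty cage (both counts zero) cannot be scored and returns `NA`
#' rather than 0, so trend fits can drop it explicitly.
#'
#' @param pupae_toxin,pupae_refuge Non-negative pupal counts (vectorised).
#' @return Proportion, or `NA` where both counts are zero.
#' @export
toxin_survivor_proportion <- function(pupae_toxin, pupae_refuge) {
  stopifnot(all(pupae_toxin >= 0, na.rm = TRUE),
            all(pupae_refuge >= 0, na.rm = TRUE))
  total <- pupae_toxin + pupae_refuge
  ifelse(total > 0, pupae_toxin / total, NA_real_)
}

#' Diagnostic-dose bioassay
#'
#' Tests `n` larvae drawn uniformly from the replicate's pooled egg sample
#' at the diagnostic Cry1Ac dose; each larva survives with its genotype's
#' toxin-diet survival probability (the same dose and `selection_params`
#' as cage selection, so a configured heterozygote survival `h` propagates
#' consistently). With `h = 0` the survivor proportion estimates the
#' phenotypic (RR) resistance frequency of the sample. If the sample holds
#' fewer than `n` individuals the draw is with replacement and flagged.
#'
#' @param sample_eggs Pooled egg `sexed_cohort` (the 10% sample removed
#'   before the refuge/toxin split).
#' @param n Number of larvae to test.
#' @param selection A [selection_params()] object.
#' @return Named numeric vector `c(tested =, survivors =)`. Attribute
#'   `with_replacement` records an undersized sample; an empty sample
#'   returns `c(0, 0)` with attribute `empty_sample = TRUE`.
#' @export
bioassay <- function(sample_eggs, n, selection) {
  stopifnot(inherits(sample_eggs, "sexed_cohort"), n >= 0,
            inherits(selection, "selection_params"))
  total <- cohort_size(sample_eggs)
  if (total == 0 || n == 0) {
    out <- c(tested = 0, survivors = 0)
    attr(out, "empty_sample") <- total == 0
    return(out)
  }
  flat <- as.vector(unclass(sample_eggs))
  if (total >= n) {
    draw <- rmvhyper(flat, n)
    with_repl <- FALSE
  } else {
    draw <- as.vector(stats::rmultinom(1, n, flat / total))
    with_repl <- TRUE
  }
  by_geno <- matrix(draw, N_GENO, 2)
  counts <- by_geno[, 1] + by_geno[, 2]
  surv_p <- diet_survival(seq_len(N_GENO), "toxin", selection)
  survivors <- sum(stats::rbinom(N_GENO, counts, surv_p))
  out <- c(tested = n, survivors = survivors)
  attr(out, "with_replacement") <- with_repl
  out
}

#' Network population size for one replicate-generation
#'
#' Sum of pupae (refuge + toxin) across the replicate's subpopulations.
#'
#' @param records Trajectory rows of exactly one replicate-generation
#'   (one row per subpopulation).
#' @return Integer total; 0 with attribute `extinct = TRUE` if all cages
#'   were empty.
#' @export
network_population_size <- function(records) {
  needed <- c("pupae_refuge", "pupae_toxin", "subpop")
  if (!all(needed %in% names(records))) {
    stop("records must contain columns: ", paste(needed, collapse = ", "))
  }
  if (anyDuplicated(records$subpop)) {
    stop("records must hold exactly one row per subpopulation")
  }
  total <- sum(records$pupae_refuge + records$pupae_toxin)
  if (total == 0) attr(total, "extinct") <- TRUE
  total
}

#' Summarize a trajectory table
#'
#' One row per (experiment, treatment, regime, replicate, generation):
#' network population size, mean toxin-survivor proportion across
#' subpopulations (unscoreable cages dropped), and the replicate-level
#' bioassay proportion.
#'
#' @param traj Trajectory data frame from [run_experiment1()] /
#'   [run_experiment2()].
#' @return Summary data frame.
#' @export
summarize_trajectory <- function(traj) {
  key <- c("experiment", "treatment", "regime", "replicate", "generation")
  stopifnot(all(key %in% names(traj)))
  split_idx <- interaction(traj[key], drop = TRUE, lex.order = TRUE)
  rows <- lapply(split(traj, split_idx), function(d) {
    tsp <- toxin_survivor_proportion(d$pupae_toxin, d$pupae_refuge)
    data.frame(d[1, key, drop = FALSE],
               network_size = sum(d$pupae_refuge + d$pupae_toxin),
               mean_toxin_survivor_prop =
                 if (all(is.na(tsp))) NA_real_ else mean(tsp, na.rm = TRUE),
               bioassay_proportion =
                 if (d$bioassay_tested[1] > 0)
                   d$bioassay_survivors[1] / d$bioassay_tested[1]
                 else NA_real_,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$experiment, out$treatment, out$regime,
                   out$replicate, out$generation), ]
  rownames(out) <- NULL
  out
}
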