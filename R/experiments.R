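# In-silico replication of the two mesocosm selection experiments:
# founder generation, the per-generation event loop, and the full factorial
# designs producing tidy trajectory tables.

#' Experiment configuration
#'
#' Full parameterization of one treatment arm. Defaults reproduce the
#' first selection experiment's design: 3 subpopulations of 200 founder
#' pupae at 7.5% initial R-allele frequency, 10% pre-mating pupal
#' dispersal, 10% bioassay egg sample, four generations (indexed 0..3) with
#' releases starting at the beginning of generation 1 (the whack-a-mole
#' strategy needs generation-0 survivor counts before it can target).
#'
#' @param n_subpops,n_replicates Design size (3 x 3 in both experiments).
#' @param founder_pupae Founder pupae per subpopulation.
#' @param founder_r_freq Initial R allele frequency among founders.
#' @param generations Number of generations simulated (indexed from 0).
#' @param bioassay_n Larvae per replicate tested at the diagnostic dose
#'   (100 in experiment 1, 150 in experiment 2).
#' @param bioassay_fraction Fraction of eggs sampled (pooled per replicate)
#'   for the bioassay, removed before the refuge/toxin split.
#' @param dispersal_fraction Fraction of each cage's pupae shared equally
#'   with the other cages before mating.
#' @param strategy A [release_strategy()].
#' @param regime A [selection_regime()].
#' @param selection A [selection_params()].
#' @param demography A [demography_params()].
#' @param release_start_generation First generation whose matings include
#'   released males.
#' @param release_stop_generation Last generation whose matings include
#'   released males (`Inf` = release throughout).
#' @param master_seed Integer seed; per-replicate seeds are derived from it
#'   by a fixed splitting scheme ([derive_seeds()]).
#' @param experiment Label stored in output records.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_subpops = 3, n_replicates = 3,
                              founder_pupae = 200, founder_r_freq = 0.075,
                              generations = 4, bioassay_n = 100,
                              bioassay_fraction = 0.10,
                              dispersal_fraction = 0.10,
                              strategy = release_strategy("none"),
                              regime = selection_regime("homogeneous", refuge = 0.10),
                              selection = selection_params(),
                              demography = demography_params(),
                              release_start_generation = 1,
                              release_stop_generation = Inf,
                              master_seed = 1,
                              experiment = "experiment1") {
  cfg <- structure(list(n_subpops = as.integer(n_subpops),
                        n_replicates = as.integer(n_replicates),
                        founder_pupae = as.integer(founder_pupae),
                        founder_r_freq = founder_r_freq,
                        generations = as.integer(generations),
                        bioassay_n = as.integer(bioassay_n),
                        bioassay_fraction = bioassay_fraction,
                        dispersal_fraction = dispersal_fraction,
                        strategy = strategy, regime = regime,
                        selection = selection, demography = demography,
                        release_start_generation = release_start_generation,
                        release_stop_generation = release_stop_generation,
                        master_seed = master_seed,
                        experiment = experiment),
                   class = "experiment_config")
  validate_config(cfg)
  cfg
}

#' Validate an experiment configuration
#'
#' Checks ranges of all fields; errors name the offending field.
#'
#' @param cfg An `experiment_config`.
#' @return The config, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  }
  chk(cfg$n_subpops >= 1, "n_subpops", "must be >= 1")
  chk(cfg$n_replicates >= 1, "n_replicates", "must be >= 1")
  chk(cfg$founder_pupae > 0, "founder_pupae", "must be > 0")
  chk(cfg$founder_r_freq >= 0 && cfg$founder_r_freq <= 1,
      "founder_r_freq", "must be in [0, 1]")
  chk(cfg$generations >= 1, "generations", "must be >= 1")
  chk(cfg$bioassay_n >= 0, "bioassay_n", "must be >= 0")
  chk(cfg$bioassay_fraction >= 0 && cfg$bioassay_fraction <= 1,
      "bioassay_fraction", "must be in [0, 1]")
  chk(cfg$dispersal_fraction >= 0 && cfg$dispersal_fraction <= 1,
      "dispersal_fraction", "must be in [0, 1]")
  chk(cfg$release_start_generation >= 0, "release_start_generation",
      "must be >= 0")
  chk(inherits(cfg$strategy, "release_strategy"), "strategy",
      "must be a release_strategy")
  chk(inherits(cfg$regime, "selection_regime"), "regime",
      "must be a selection_regime")
  chk(cfg$regime$mode == "homogeneous" ||
        length(cfg$regime$heterogeneous_refuges) == cfg$n_subpops,
      "regime", "heterogeneous_refuges length must equal n_subpops")
  chk(cfg$regime$refuge >= 0 && cfg$regime$refuge <= 1,
      "regime", "refuge must be in [0, 1]")
  chk(inherits(cfg$selection, "selection_params"), "selection",
      "must be a selection_params")
  chk(inherits(cfg$demography, "demography_params"), "demography",
      "must be a demography_params")
  invisible(cfg)
}

#' Draw a founder cohort at Hardy-Weinberg proportions
#'
#' Founders carry no transgene (all ww); resistance genotypes are
#' multinomial at Hardy-Weinberg proportions for the given R frequency
#' (for 7.5%: RR 0.005625, RS 0.13875, SS 0.855625) and sex is
#' Binomial(n, 1/2), emulating the mass-crossed founder population.
#'
#' @param n Number of founder pupae.
#' @param r_freq Founder R allele frequency.
#' @return A `sexed_cohort`.
#' @export
make_founders <- function(n, r_freq) {
  stopifnot(n > 0, r_freq >= 0, r_freq <= 1)
  p <- c(SS = (1 - r_freq)^2, RS = 2 * r_freq * (1 - r_freq), RR = r_freq^2)
  by_r <- as.vector(stats::rmultinom(1, n, p))
  out <- empty_cohort()
  for (r in 0:2) {
    fem <- stats::rbinom(1, by_r[r + 1], 0.5)
    out <- cohort_of(r, 0, females = fem, males = by_r[r + 1] - fem,
                     base = out)
  }
  out
}

#' Initial metapopulation state for one replicate
#'
#' Draws founder cohorts for every subpopulation and initializes release
#' bookkeeping. Feed the result to [run_generation()].
#'
#' @param cfg An [experiment_config()].
#' @return Metapopulation state list: `adults` (list of `sexed_cohort`s),
#'   `pending_released`, `pending_target`, `extinct`.
#' @export
new_metapop_state <- function(cfg) {
  list(adults = replicate(cfg$n_subpops,
                          make_founders(cfg$founder_pupae, cfg$founder_r_freq),
                          simplify = FALSE),
       pending_released = integer(cfg$n_subpops),
       pending_target = rep(FALSE, cfg$n_subpops),
       extinct = FALSE)
}

# One trajectory row per subpopulation.
record_row <- function(cfg, treatment, replicate, subpop, generation,
                       refuge_fraction, pupae_refuge, pupae_toxin,
                       released_males, bioassay_tested, bioassay_survivors,
                       freq_R, freq_L, whack_target, extinct = FALSE) {
  data.frame(experiment = cfg$experiment, treatment = treatment,
             regime = cfg$regime$mode, replicate = replicate,
             subpop = subpop, generation = generation,
             refuge_fraction = refuge_fraction,
             pupae_refuge = pupae_refuge, pupae_toxin = pupae_toxin,
             released_males = released_males,
             bioassay_tested = bioassay_tested,
             bioassay_survivors = bioassay_survivors,
             freq_R = freq_R, freq_L = freq_L,
             whack_target = whack_target, extinct = extinct,
             stringsAsFactors = FALSE)
}

#' Run one generation of the metapopulation
#'
#' Executes the cage protocol's event order: (1) assign refuge fractions;
#' (2) adults mate and lay; (3) the bioassay egg sample is removed (pooled
#' across the replicate's subpopulations) and the remaining eggs split
#' between refuge and toxin diet; (4) larval selection, female-lethality
#' and density regulation produce the pupal census; (5) cage counts are
#' recorded; (6) pre-mating dispersal; (7) release of transgenic males if
#' the next generation is within the release window (the whack-a-mole
#' target is chosen from this generation's pre-dispersal toxin-survivor
#' counts). Released males recorded in a row are those that joined that
#' generation's mating pool.
#'
#' @param state Metapopulation state (from a previous call, or internal
#'   founder initialization).
#' @param cfg An [experiment_config()].
#' @param generation Generation index (0-based).
#' @param treatment,replicate Labels for the output records.
#' @return List with `state` (input to the next generation) and `records`
#'   (data frame, one row per subpopulation).
#' @export
run_generation <- function(state, cfg, generation, treatment = cfg$strategy$mode,
                           replicate = 1L) {
  k <- cfg$n_subpops
  refs <- assign_refuges(cfg$regime, k)

  eggs <- lapply(state$adults, mate_and_lay, demog = cfg$demography)
  parts <- lapply(seq_len(k), function(s)
    allocate_eggs(eggs[[s]], refuge_fraction = refs[s],
                  bioassay_fraction = cfg$bioassay_fraction,
                  eggs_placed_max = cfg$demography$eggs_placed_max))

  pooled_bio <- Reduce(function(a, b) cohort(unclass(a) + unclass(b)),
                       lapply(parts, `[[`, "bioassay"))
  ba <- bioassay(pooled_bio, cfg$bioassay_n, cfg$selection)

  pup_ref <- lapply(seq_len(k), function(s)
    select_and_pupate(parts[[s]]$refuge, "refuge", cfg$selection,
                      cfg$demography, diet_fraction = refs[s]))
  pup_tox <- lapply(seq_len(k), function(s)
    select_and_pupate(parts[[s]]$toxin, "toxin", cfg$selection,
                      cfg$demography, diet_fraction = 1 - refs[s]))

  toxin_counts <- vapply(pup_tox, cohort_size, numeric(1))
  pupae <- lapply(seq_len(k), function(s)
    cohort(unclass(pup_ref[[s]]) + unclass(pup_tox[[s]])))

  records <- do.call(rbind, lapply(seq_len(k), function(s) {
    record_row(cfg, treatment, replicate, subpop = s,
               generation = generation, refuge_fraction = refs[s],
               pupae_refuge = cohort_size(pup_ref[[s]]),
               pupae_toxin = toxin_counts[s],
               released_males = state$pending_released[s],
               bioassay_tested = ba[["tested"]],
               bioassay_survivors = ba[["survivors"]],
               freq_R = allele_freq(pupae[[s]], "R"),
               freq_L = allele_freq(pupae[[s]], "L"),
               whack_target = state$pending_target[s],
               extinct = cohort_size(pupae[[s]]) == 0)
  }))

  network_extinct <- sum(vapply(pupae, cohort_size, numeric(1))) == 0

  pupae <- disperse(pupae, cfg$dispersal_fraction)

  pending_released <- integer(k)
  pending_target <- rep(FALSE, k)
  next_gen <- generation + 1
  if (!network_extinct && cfg$strategy$mode != "none" &&
      next_gen >= cfg$release_start_generation &&
      next_gen <= cfg$release_stop_generation &&
      next_gen <= cfg$generations - 1) {
    target <- NA_integer_
    if (cfg$strategy$mode == "whack") {
      if (!is.null(cfg$strategy$fixed_target)) {
        target <- cfg$strategy$fixed_target
      } else if (any(toxin_counts > 0) || cfg$strategy$release_when_empty) {
        target <- choose_whack_target(toxin_counts)
      }
    }
    rel <- apply_release(pupae, cfg$strategy, target = target)
    pupae <- rel$pupae
    pending_released <- rel$released
    if (cfg$strategy$mode == "whack" && !is.na(target)) {
      pending_target[target] <- TRUE
    }
  }

  list(state = list(adults = pupae, pending_released = pending_released,
                    pending_target = pending_target,
                    extinct = network_extinct),
       records = records)
}

#' Run one replicate metapopulation
#'
#' Seeds the RNG, draws founders, and iterates [run_generation()] for the
#' configured number of generations. A network extinction truncates the
#' trajectory; the final recorded generation carries `extinct = TRUE` rows.
#'
#' @param cfg An [experiment_config()].
#' @param seed Integer seed for this replicate.
#' @param treatment,replicate Labels for the output records.
#' @return Data frame of trajectory records.
#' @export
run_replicate <- function(cfg, seed, treatment = cfg$strategy$mode,
                          replicate = 1L) {
  set.seed(seed)
  state <- new_metapop_state(cfg)
  out <- vector("list", cfg$generations)
  for (g in seq_len(cfg$generations) - 1L) {
    step <- run_generation(state, cfg, g, treatment = treatment,
                           replicate = replicate)
    out[[g + 1L]] <- step$records
    state <- step$state
    if (state$extinct) break
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Run selection experiment 1 (release strategies)
#'
#' Three release treatments (control, everywhere 4:1, whack-a-mole 12:1)
#' times `n_replicates` replicate metapopulations, four generations, 10%
#' refuge everywhere, 100-larva bioassays. Fully deterministic given
#' `master_seed`: per-replicate seeds are derived by a fixed scheme, so any
#' replicate can be reproduced in isolation.
#'
#' @param cfg Base [experiment_config()]; the strategy field is overridden
#'   per treatment.
#' @return Tidy data frame of trajectory records (with defaults and no
#'   extinction: 3 treatments x 3 replicates x 3 subpops x 4 generations =
#'   108 rows).
#' @export
run_experiment1 <- function(cfg = experiment_config()) {
  validate_config(cfg)
  treatments <- c("control", "everywhere", "whack")
  modes <- c("none", "everywhere", "whack")
  seeds <- derive_seeds(cfg$master_seed, length(treatments) * cfg$n_replicates)
  out <- list()
  idx <- 0L
  for (ti in seq_along(treatments)) {
    tcfg <- cfg
    tcfg$strategy <- release_strategy(modes[ti],
                                      base_ratio = cfg$strategy$base_ratio,
                                      whack_multiplier = cfg$strategy$whack_multiplier,
                                      release_when_empty = cfg$strategy$release_when_empty,
                                      fixed_target = cfg$strategy$fixed_target)
    for (rep_i in seq_len(cfg$n_replicates)) {
      idx <- idx + 1L
      out[[idx]] <- run_replicate(tcfg, seeds[idx],
                                  treatment = treatments[ti],
                                  replicate = rep_i)
    }
  }
  do.call(rbind, out)
}

#' Run selection experiment 2 (release x selection regime factorial)
#'
#' Two release strategies (everywhere, whack-a-mole) crossed with two
#' selection regimes (homogeneous 12% refuge; heterogeneous 5/10/20%
#' refuges permuted among subpopulations each generation), three replicates
#' each, 150-larva bioassays. An optional fifth generation is obtained by
#' setting `generations = 5` in the config.
#'
#' @param cfg Base [experiment_config()]; strategy and regime fields are
#'   overridden per arm. Defaults to experiment-2 settings
#'   (`experiment2_config()`).
#' @return Tidy data frame of trajectory records.
#' @export
run_experiment2 <- function(cfg = experiment2_config()) {
  validate_config(cfg)
  strategies <- c("everywhere", "whack")
  regimes <- c("homogeneous", "heterogeneous")
  seeds <- derive_seeds(cfg$master_seed,
                        length(strategies) * length(regimes) * cfg$n_replicates)
  out <- list()
  idx <- 0L
  for (st in strategies) {
    for (rg in regimes) {
      acfg <- cfg
      acfg$strategy <- release_strategy(st,
                                        base_ratio = cfg$strategy$base_ratio,
                                        whack_multiplier = cfg$strategy$whack_multiplier,
                                        release_when_empty = cfg$strategy$release_when_empty,
                                        fixed_target = cfg$strategy$fixed_target)
      acfg$regime <- selection_regime(rg, refuge = cfg$regime$refuge,
                                      heterogeneous_refuges = cfg$regime$heterogeneous_refuges)
      for (rep_i in seq_len(cfg$n_replicates)) {
        idx <- idx + 1L
        out[[idx]] <- run_replicate(acfg, seeds[idx], treatment = st,
                                    replicate = rep_i)
      }
    }
  }
  do.call(rbind, out)
}

#' @rdname run_experiment2
#' @param ... Overrides passed to [experiment_config()].
#' @export
experiment2_config <- function(...) {
  defaults <- list(bioassay_n = 150,
                   regime = selection_regime("homogeneous", refuge = 0.12),
                   experiment = "experiment2")
  args <- utils::modifyList(defaults, list(...))
  do.call(experiment_config, args)
}
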