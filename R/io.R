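# Configuration files, CSV writers, run manifests, and the command
# entry points behind the `whackamole` CLI script (inst/cli/whackamole).

#' Read an experiment configuration from YAML
#'
#' Keys mirror [experiment_config()] argument names; the nested component
#' parameter sets use maps with keys mirroring their constructors:
#' `strategy` ([release_strategy()]), `regime` ([selection_regime()]),
#' `selection` ([selection_params()]), `demography`
#' ([demography_params()]). Unknown keys are an error naming the key;
#' out-of-range values are errors naming the field.
#'
#' @param path Path to a YAML file.
#' @return A validated [experiment_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping")
  config_from_list(raw)
}

#' @rdname read_config
#' @param raw Named list with the same structure as the YAML document.
#' @export
config_from_list <- function(raw) {
  build <- function(x, ctor, what) {
    if (is.null(x)) return(ctor())
    if (inherits(x, what)) return(x)
    bad <- setdiff(names(x), names(formals(ctor)))
    if (length(bad)) stop("unknown ", what, " key(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    do.call(ctor, x)
  }
  nested <- c("strategy", "regime", "selection", "demography")
  top <- raw[setdiff(names(raw), nested)]
  bad <- setdiff(names(top), names(formals(experiment_config)))
  if (length(bad)) stop("unknown config key(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  args <- c(top,
            list(strategy = build(raw$strategy, release_strategy,
                                  "release_strategy"),
                 regime = build(raw$regime, selection_regime,
                                "selection_regime"),
                 selection = build(raw$selection, selection_params,
                                   "selection_params"),
                 demography = build(raw$demography, demography_params,
                                    "demography_params")))
  do.call(experiment_config, args)
}

# Config as a plain (JSON/YAML-serializable) list.
config_to_list <- function(cfg) {
  out <- unclass(cfg)
  for (f in c("strategy", "regime", "selection", "demography")) {
    out[[f]] <- unclass(out[[f]])
  }
  out$release_stop_generation <-
    if (is.finite(out$release_stop_generation))
      out$release_stop_generation else "Inf"
  out
}

#' Write a trajectory (or any tidy) table as CSV
#'
#' UTF-8, header row, no row names, stable column order as produced by the
#' simulator.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON snapshot of the fully resolved configuration, the master seed, the
#' derived per-replicate seeds, the package version and output paths.
#' Re-running from the manifest's config snapshot reproduces the outputs
#' exactly.
#'
#' @param cfg The resolved [experiment_config()].
#' @param outputs Character vector of output file paths.
#' @param path Manifest path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(cfg, outputs, path) {
  n_runs <- cfg$n_replicates *
    if (cfg$experiment == "experiment2") 4L else 3L
  manifest <- list(
    package = "whackamole",
    version = as.character(utils::packageVersion("whackamole")),
    master_seed = cfg$master_seed,
    derived_seeds = derive_seeds(cfg$master_seed, n_runs),
    config = config_to_list(cfg),
    outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Rebuild a configuration from a manifest
#'
#' @param path Manifest JSON path.
#' @return A validated [experiment_config()].
#' @export
config_from_manifest <- function(path) {
  manifest <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- manifest$config
  if (identical(raw$release_stop_generation, "Inf")) {
    raw$release_stop_generation <- Inf
  }
  raw$selection$toxin_survival <- as.numeric(raw$selection$toxin_survival)
  raw$selection <- raw$selection[setdiff(names(raw$selection),
                                         c("h", "dose_ug_ml"))]
  if (length(raw$strategy$fixed_target) == 0) {
    raw$strategy[["fixed_target"]] <- NULL
  }
  config_from_list(raw)
}

#' Run an experiment from a config file
#'
#' Executes [run_experiment1()] or [run_experiment2()] according to the
#' config's `experiment` field and writes the trajectory CSV plus a JSON
#' manifest alongside it.
#'
#' @param config_path YAML config path, or an [experiment_config()] object.
#' @param seed Optional integer overriding the config's `master_seed`.
#' @param out Output CSV path.
#' @param quiet Suppress per-generation logging.
#' @return Invisibly, the trajectory data frame.
#' @export
cmd_run <- function(config_path, seed = NULL, out = "trajectory.csv",
                    quiet = FALSE) {
  cfg <- if (inherits(config_path, "experiment_config")) config_path
         else read_config(config_path)
  if (!is.null(seed)) cfg$master_seed <- as.integer(seed)
  traj <- if (cfg$experiment == "experiment2") run_experiment2(cfg)
          else run_experiment1(cfg)
  write_trajectory(traj, out)
  manifest_path <- sub("\\.csv$", "", out)
  manifest_path <- paste0(manifest_path, "_manifest.json")
  write_manifest(cfg, outputs = out, path = manifest_path)
  if (!quiet) {
    sm <- summarize_trajectory(traj)
    for (g in sort(unique(sm$generation))) {
      gi <- sm[sm$generation == g, ]
      message(sprintf("generation %d: network sizes %s", g,
                      paste(gi$network_size, collapse = ", ")))
    }
    wt <- traj[traj$whack_target, ]
    if (nrow(wt)) {
      message("whack targets: ",
              paste(sprintf("%s rep %d gen %d -> subpop %d", wt$treatment,
                            wt$replicate, wt$generation, wt$subpop),
                    collapse = "; "))
    }
  }
  invisible(traj)
}

#' Write the deterministic oracle trajectory for a config
#'
#' @param config_path YAML config path or [experiment_config()] object.
#' @param out Output CSV path.
#' @return Invisibly, the oracle data frame.
#' @export
cmd_oracle <- function(config_path, out = "oracle.csv") {
  cfg <- if (inherits(config_path, "experiment_config")) config_path
         else read_config(config_path)
  res <- run_oracle(cfg)
  write_trajectory(res, out)
  invisible(res)
}

#' Analyze a trajectory CSV
#'
#' Reads a trajectory table, validates the schema, and writes the
#' replicate-generation summary and the per-subpopulation trend /
#' autocorrelation tables.
#'
#' @param trajectory_path Trajectory CSV path (or data frame).
#' @param out_prefix Prefix for the two output CSVs
#'   (`<prefix>_summary.csv`, `<prefix>_trends.csv`).
#' @return Invisibly, a list with both tables.
#' @export
cmd_analyze <- function(trajectory_path, out_prefix = "analysis") {
  traj <- if (is.data.frame(trajectory_path)) trajectory_path
          else utils::read.csv(trajectory_path, stringsAsFactors = FALSE)
  required <- c("experiment", "treatment", "regime", "replicate", "subpop",
                "generation", "refuge_fraction", "pupae_refuge",
                "pupae_toxin", "released_males", "bioassay_tested",
                "bioassay_survivors")
  missing <- setdiff(required, names(traj))
  if (length(missing)) {
    stop("trajectory is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  sm <- summarize_trajectory(traj)
  tr <- trend_summary(traj)
  write_trajectory(sm, paste0(out_prefix, "_summary.csv"))
  write_trajectory(tr, paste0(out_prefix, "_trends.csv"))
  invisible(list(summary = sm, trends = tr))
}

#' Oracle parameter sweep
#'
#' Runs the deterministic oracle over a grid of release ratio, refuge
#' fraction, heterozygote toxin survival and R fitness cost, reporting the
#' final-generation outcomes.
#'
#' @param out Output CSV path, or `NULL` to skip writing.
#' @param release_ratios,refuges,h_values,costs Grid values.
#' @param generations Generations per oracle run.
#' @param cfg Base config supplying all other parameters.
#' @return The sweep data frame, invisibly if written.
#' @export
cmd_sweep <- function(out = "sweep.csv", release_ratios = c(0, 1, 2, 4, 8, 12),
                      refuges = c(0.05, 0.10, 0.20, 0.50), h_values = 0,
                      costs = 0, generations = 10,
                      cfg = experiment_config()) {
  grid <- expand.grid(release_ratio = release_ratios, refuge = refuges,
                      h = h_values, cost = costs)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cfg_i <- cfg
    cfg_i$generations <- as.integer(generations)
    cfg_i$strategy <- if (g$release_ratio > 0)
      release_strategy("everywhere", base_ratio = g$release_ratio)
      else release_strategy("none")
    cfg_i$regime <- selection_regime("homogeneous", refuge = g$refuge)
    cfg_i$selection <- selection_params(h = g$h, fitness_cost_r = g$cost)
    res <- run_oracle(cfg_i)
    last <- res[nrow(res), ]
    data.frame(g, final_generation = last$generation,
               final_freq_R = last$freq_R, final_freq_L = last$freq_L,
               final_toxin_survivor_prop = last$toxin_survivor_prop,
               extinct = last$extinct)
  })
  sweep <- do.call(rbind, rows)
  if (!is.null(out)) {
    write_trajectory(sweep, out)
    return(invisible(sweep))
  }
  sweep
}
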