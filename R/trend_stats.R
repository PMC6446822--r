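# Self-contained analysis layer for trajectory tables: variance-stabilized
# quadratic trend fits, lag-1 autocorrelation of detrended resistance
# series, and permutation tests for treatment contrasts. Mixed-effects
# binomial models are deliberately not re-implemented here; users wanting
# GLMMs can fit them externally on the tidy trajectory tables.

#' Quadratic trend fit on arc-sine transformed proportions
#'
#' Ordinary least squares of `asin(sqrt(p))` on generation and generation
#' squared — the variance-stabilizing transform conventional for binomial
#' proportions. With fewer than 3 defined points a linear-only fit is
#' returned and flagged.
#'
#' @param p Per-generation proportions in `[0, 1]` (`NA`s dropped).
#' @param generation Generation index of each value (default `0, 1, ...`).
#' @return An object of class `trend_fit`: list with `coefficients`
#'   (intercept, generation, generation2), `residuals`, `fitted`,
#'   `generation`, and `linear_only` flag.
#' @export
fit_quadratic_trend <- function(p, generation = seq_along(p) - 1) {
  stopifnot(length(p) == length(generation))
  ok <- !is.na(p)
  p <- p[ok]
  generation <- generation[ok]
  stopifnot(all(p >= 0 & p <= 1), length(p) >= 2)
  y <- asin(sqrt(p))
  linear_only <- length(p) < 3
  fit <- if (linear_only) stats::lm(y ~ generation)
         else stats::lm(y ~ generation + I(generation^2))
  coefs <- c(intercept = unname(stats::coef(fit)[1]),
             generation = unname(stats::coef(fit)[2]),
             generation2 = if (linear_only) NA_real_
                           else unname(stats::coef(fit)[3]))
  structure(list(coefficients = coefs,
                 residuals = unname(stats::residuals(fit)),
                 fitted = unname(stats::fitted(fit)),
                 generation = generation,
                 linear_only = linear_only),
            class = "trend_fit")
}

#' Lag-1 autocorrelation of a detrended series
#'
#' The circular lag-1 sample autocorrelation of the centered series,
#' `sum(x_c * rotate(x_c)) / sum(x_c^2)`. For exchangeable (white-noise)
#' data this estimator's null expectation is exactly `-1/(n-1)` — the
#' classical small-sample benchmark (-1/3 for series of length 4) against
#' which an observed negative autocorrelation is judged. Undefined (and
#' flagged) for series with no variance.
#'
#' @param residuals Detrended series (e.g. `trend_fit$residuals`), length
#'   at least 3.
#' @return Correlation in `[-1, 1]`, or `NA` with attribute
#'   `zero_variance = TRUE` for a degenerate series.
#' @export
lag1_autocorrelation <- function(residuals) {
  n <- length(residuals)
  stopifnot(n >= 3)
  xc <- residuals - mean(residuals)
  denom <- sum(xc^2)
  if (denom == 0) {
    out <- NA_real_
    attr(out, "zero_variance") <- TRUE
    return(out)
  }
  sum(xc * xc[c(2:n, 1L)]) / denom
}

#' Permutation test for a treatment contrast
#'
#' Compares replicate-level summaries between treatment groups by random
#' relabeling. For two groups the statistic is the difference in group
#' means (first minus second level); for more, the between-group sum of
#' squares (two-sided only). Random-permutation p-values use the
#' add-one estimator `(1 + #extreme) / (1 + n_perm)`, which is exactly
#' uniform on its support under the null; `exhaustive = TRUE` (two groups)
#' enumerates all assignments and returns the exact proportion at least as
#' extreme, the identity labeling included.
#'
#' @param values Numeric replicate-level summaries.
#' @param groups Treatment label of each value (2+ levels, each with at
#'   least 2 replicates).
#' @param n_perm Number of random relabelings.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (one-sided
#'   alternatives only for two groups).
#' @param exhaustive Enumerate all assignments (two groups only).
#' @return List with `p_value`, `observed` statistic, `n_perm`, and
#'   `exhaustive` flag.
#' @export
permutation_treatment_test <- function(values, groups, n_perm = 999,
                                       alternative = c("two.sided", "less",
                                                       "greater"),
                                       exhaustive = FALSE) {
  alternative <- match.arg(alternative)
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups), nlevels(groups) >= 2,
            all(table(groups) >= 2))
  two <- nlevels(groups) == 2
  if (!two && (alternative != "two.sided" || exhaustive)) {
    stop("one-sided and exhaustive tests require exactly 2 groups")
  }
  stat <- if (two) {
    function(g) mean(values[g == levels(groups)[1]]) -
      mean(values[g == levels(groups)[2]])
  } else {
    function(g) {
      mu <- mean(values)
      sum(tapply(values, g, function(v) length(v) * (mean(v) - mu)^2))
    }
  }
  obs <- stat(groups)
  extreme <- function(s) switch(alternative,
                                two.sided = abs(s) >= abs(obs) - 1e-12,
                                greater = s >= obs - 1e-12,
                                less = s <= obs + 1e-12)
  if (exhaustive) {
    n1 <- sum(groups == levels(groups)[1])
    combs <- utils::combn(length(values), n1)
    stats_all <- apply(combs, 2, function(idx) {
      g <- factor(ifelse(seq_along(values) %in% idx,
                         levels(groups)[1], levels(groups)[2]),
                  levels = levels(groups))
      stat(g)
    })
    p <- mean(extreme(stats_all))
    return(list(p_value = p, observed = obs, n_perm = ncol(combs),
                exhaustive = TRUE))
  }
  perm_stats <- replicate(n_perm, stat(sample(groups)))
  p <- (1 + sum(extreme(perm_stats))) / (1 + n_perm)
  list(p_value = p, observed = obs, n_perm = n_perm, exhaustive = FALSE)
}

#' Treatment contrast on trajectory summaries
#'
#' Convenience wrapper: reduces a trajectory table to one final-generation
#' summary per replicate (network size or mean toxin-survivor proportion)
#' and runs [permutation_treatment_test()] between two treatments.
#'
#' @param traj Trajectory data frame.
#' @param treatments Character vector of two treatment labels to compare.
#' @param statistic `"final_size"` or `"final_resistance"`.
#' @param ... Passed to [permutation_treatment_test()].
#' @return As [permutation_treatment_test()].
#' @export
treatment_contrast <- function(traj, treatments,
                               statistic = c("final_size", "final_resistance"),
                               ...) {
  statistic <- match.arg(statistic)
  stopifnot(length(treatments) == 2)
  sm <- summarize_trajectory(traj[traj$treatment %in% treatments, ])
  gmax <- max(sm$generation)
  # a replicate extinct before the final generation has size 0 there and
  # unscoreable (NA) resistance
  reps <- unique(sm[c("treatment", "replicate")])
  vals <- vapply(seq_len(nrow(reps)), function(i) {
    d <- sm[sm$treatment == reps$treatment[i] &
              sm$replicate == reps$replicate[i] & sm$generation == gmax, ]
    if (nrow(d) == 0) {
      if (statistic == "final_size") 0 else NA_real_
    } else {
      switch(statistic, final_size = d$network_size,
             final_resistance = d$mean_toxin_survivor_prop)
    }
  }, numeric(1))
  keep <- !is.na(vals)
  permutation_treatment_test(vals[keep],
                             factor(reps$treatment[keep], levels = treatments),
                             ...)
}

#' Per-unit trend and autocorrelation summary
#'
#' Fits the arc-sine quadratic trend to each subpopulation's
#' toxin-survivor series and reports coefficients and the lag-1
#' autocorrelation of the detrended residuals (the detrending unit is the
#' subpopulation).
#'
#' @param traj Trajectory data frame.
#' @return Data frame, one row per (treatment, regime, replicate, subpop).
#' @export
trend_summary <- function(traj) {
  key <- c("experiment", "treatment", "regime", "replicate", "subpop")
  stopifnot(all(key %in% names(traj)))
  rows <- lapply(split(traj, interaction(traj[key], drop = TRUE)), function(d) {
    d <- d[order(d$generation), ]
    p <- toxin_survivor_proportion(d$pupae_toxin, d$pupae_refuge)
    ok <- !is.na(p)
    base <- d[1, key, drop = FALSE]
    if (sum(ok) < 2) {
      return(data.frame(base, intercept = NA_real_, generation = NA_real_,
                        generation2 = NA_real_, lag1_autocorr = NA_real_,
                        n_points = sum(ok), row.names = NULL))
    }
    fit <- fit_quadratic_trend(p[ok], d$generation[ok])
    ac <- if (length(fit$residuals) >= 3)
      lag1_autocorrelation(fit$residuals) else NA_real_
    data.frame(base, intercept = fit$coefficients[["intercept"]],
               generation = fit$coefficients[["generation"]],
               generation2 = fit$coefficients[["generation2"]],
               lag1_autocorr = as.numeric(ac), n_points = sum(ok),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
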