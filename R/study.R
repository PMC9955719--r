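#' Simulate a series with a target scaling exponent
#'
#' Maps the scaling exponent onto the ARFIMA difference order and the
#' integrate flag: stationary `alpha` in (0, 1) gives fGn with
#' `d = alpha - 0.5`; nonstationary `alpha` in (1, 2) gives fBm with
#' `d = alpha - 1.5` followed by cumulative summation. `alpha = 1` itself is
#' outside the model; the study grids use 0.99 as the near-boundary value.
#'
#' @param alpha target scaling exponent, in (0, 1) or (1, 2).
#' @param n series length.
#' @param seed integer RNG seed.
#' @return a `"sim_series"` object (see [simulate_fgn()]).
#' @export
simulate_alpha <- function(alpha, n, seed) {
  stopifnot(alpha > 0, alpha < 2, alpha != 1)
  if (alpha < 1) {
    simulate_fgn(alpha - 0.5, n, seed, integrate = FALSE)
  } else {
    simulate_fgn(alpha - 1.5, n, seed, integrate = TRUE)
  }
}

#' Study grids
#'
#' `alpha_grid_coarse()` is the 19-value grid 0.1..0.9, 0.99, 1.1..1.9 used
#' by the estimation, outlier, discrimination and normalization studies;
#' `alpha_grid_fine()` spans the 1/f boundary (0.71..0.99, 1.01..1.29 in
#' steps of 0.01) for the classification follow-up.
#'
#' @return numeric vector of scaling exponents.
#' @export
alpha_grid_coarse <- function() {
  c(seq(0.1, 0.9, by = 0.1), 0.99, seq(1.1, 1.9, by = 0.1))
}

#' @rdname alpha_grid_coarse
#' @export
alpha_grid_fine <- function() {
  g <- round(seq(0.71, 1.29, by = 0.01), 2)
  g[g != 1]
}

study_grid <- function(study_kind, alphas, lengths, replicates, master_seed,
                       seeds_per_cell = 1L) {
  grid <- expand.grid(
    replicate = seq_len(replicates),
    N = lengths,
    alpha_expected = alphas,
    KEEP.OUT.ATTRS = FALSE
  )[, c("alpha_expected", "N", "replicate")]
  grid$counter <- seq_len(nrow(grid)) - 1L
  grid$seed <- child_seed(master_seed, grid$counter * seeds_per_cell)
  grid$study_kind <- study_kind
  grid
}

#' Estimation study: parameter recovery of the scaling exponent
#'
#' For each (alpha, N) cell, simulates `replicates` independent series and
#' estimates alpha with both the ARFIMA-Whittle classifier
#' ([classify_and_estimate()]) and evenly spaced average DFA
#' ([dfa_alpha()]).
#'
#' @param alphas scaling exponents (default [alpha_grid_coarse()]).
#' @param lengths series lengths (default 250, 500, 1000).
#' @param replicates simulations per cell (default 100).
#' @param master_seed master RNG seed, expanded per replicate via
#'   [child_seed()].
#' @return data frame with one row per (alpha, N, replicate, method):
#'   columns `study_kind`, `alpha_expected`, `N`, `replicate`, `seed`,
#'   `method`, `alpha_hat`, `class_label`, `converged`.
#' @seealso [summarize_study()]
#' @export
run_estimation_study <- function(alphas = alpha_grid_coarse(),
                                 lengths = c(250, 500, 1000),
                                 replicates = 100, master_seed = 1) {
  grid <- study_grid("estimation", alphas, lengths, replicates, master_seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    s <- simulate_alpha(g$alpha_expected, g$N, g$seed)
    fit <- classify_and_estimate(s$values)
    dfa <- dfa_alpha(s$values)
    data.frame(
      g[c("study_kind", "alpha_expected", "N", "replicate", "seed")],
      method = c("arfima", "dfa"),
      alpha_hat = c(fit$alpha_hat, dfa$alpha_hat),
      class_label = c(fit$class_label, NA_character_),
      converged = c(fit$converged, NA),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Classification study: proportion of series labelled nonstationary
#'
#' @inheritParams run_estimation_study
#' @param fine use the fine near-boundary grid ([alpha_grid_fine()], 500
#'   replicates) instead of the coarse grid.
#' @return data frame with one row per (alpha, N, replicate): columns as in
#'   [run_estimation_study()] plus `nonstationary` (logical).
#' @export
run_classification_study <- function(alphas = NULL,
                                     lengths = c(250, 500, 1000),
                                     replicates = NULL, master_seed = 1,
                                     fine = FALSE) {
  if (is.null(alphas)) alphas <- if (fine) alpha_grid_fine() else alpha_grid_coarse()
  if (is.null(replicates)) replicates <- if (fine) 500 else 100
  kind <- if (fine) "classification_fine" else "classification"
  grid <- study_grid(kind, alphas, lengths, replicates, master_seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    s <- simulate_alpha(g$alpha_expected, g$N, g$seed)
    fit <- classify_and_estimate(s$values)
    data.frame(
      g[c("study_kind", "alpha_expected", "N", "replicate", "seed")],
      alpha_hat = fit$alpha_hat,
      class_label = fit$class_label,
      nonstationary = fit$class_label == "nonstationary",
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Outlier study: SampEn bias under contamination and after cleaning
#'
#' Each replicate simulates a series, measures baseline SampEn, injects
#' additive outliers ([contaminate()]), and re-measures SampEn under four
#' conditions: `none` (no remedy), `adjust_r` (tolerance shrunk by the SD
#' ratio, outliers retained), `remove` (scaled-MAD removal on the raw
#' series), and `classify_remove` (classification-guided removal,
#' [clean_with_classification()]). The reported `percent_bias` is relative
#' to the same realization's uncontaminated baseline.
#'
#' @inheritParams run_estimation_study
#' @param proportion,amplitude_factor contamination parameters (defaults
#'   0.01 and 3; see [contaminate()]).
#' @param threshold_multiplier scaled-MAD detection threshold (default 5).
#' @param m,r,tau SampEn hyperparameters (defaults 1, 0.25, 1).
#' @param conditions subset of the four condition labels to run.
#' @return data frame with one row per (alpha, N, replicate, condition):
#'   adds `condition`, `sampen`, `baseline`, `percent_bias`,
#'   `removed_count`, `n_flagged`.
#' @export
run_outlier_study <- function(alphas = alpha_grid_coarse(),
                              lengths = c(250, 500, 1000),
                              replicates = 100, master_seed = 1,
                              proportion = 0.01, amplitude_factor = 3,
                              threshold_multiplier = 5,
                              m = 1, r = 0.25, tau = 1,
                              conditions = c("none", "adjust_r", "remove",
                                             "classify_remove")) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  grid <- study_grid("outlier", alphas, lengths, replicates, master_seed,
                     seeds_per_cell = 2L)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cont_seed <- child_seed(master_seed, g$counter * 2L + 1L)
    s <- simulate_alpha(g$alpha_expected, g$N, g$seed)
    base <- sampen(s$values, m, r, tau)$value
    ct <- contaminate(s$values, proportion, amplitude_factor, cont_seed)
    vals <- lapply(conditions, function(cond) {
      switch(cond,
        none = {
          list(se = sampen(ct$values, m, r, tau)$value, removed = 0L,
               flagged = NA_integer_)
        },
        adjust_r = {
          rep_ <- detect_outliers(ct$values, threshold_multiplier)
          list(se = sampen(ct$values, m, adjusted_r(r, rep_), tau)$value,
               removed = 0L, flagged = length(rep_$flagged_indices))
        },
        remove = {
          rep_ <- detect_outliers(ct$values, threshold_multiplier)
          cleaned <- remove_outliers(ct$values, rep_)
          list(se = sampen(cleaned, m, r, tau)$value,
               removed = length(rep_$flagged_indices),
               flagged = length(rep_$flagged_indices))
        },
        classify_remove = {
          out <- clean_with_classification(ct$values, threshold_multiplier)
          list(se = sampen(out$cleaned_values, m, r, tau)$value,
               removed = out$removed_count,
               flagged = length(out$report$flagged_indices))
        }
      )
    })
    data.frame(
      g[c("study_kind", "alpha_expected", "N", "replicate", "seed")],
      condition = conditions,
      sampen = vapply(vals, function(v) v$se, numeric(1)),
      baseline = base,
      percent_bias = percent_bias(vapply(vals, function(v) v$se, numeric(1)),
                                  base),
      removed_count = vapply(vals, function(v) v$removed, integer(1)),
      n_flagged = vapply(vals, function(v) v$flagged, integer(1)),
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Discrimination study: SampEn and estimated alpha across the grid
#'
#' Measures SampEn and the ARFIMA alpha estimate on each simulated series,
#' producing the data behind the many-to-one (inverted parabola)
#' relationship between SampEn and the scaling exponent.
#'
#' @inheritParams run_outlier_study
#' @return data frame with one row per (alpha, N, replicate): adds
#'   `sampen`, `sampen_normalized`, `alpha_hat`, `class_label`.
#' @export
run_discrimination_study <- function(alphas = alpha_grid_coarse(),
                                     lengths = c(250, 500, 1000),
                                     replicates = 100, master_seed = 1,
                                     m = 1, r = 0.25, tau = 1) {
  grid <- study_grid("discrimination", alphas, lengths, replicates, master_seed)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    s <- simulate_alpha(g$alpha_expected, g$N, g$seed)
    se <- sampen(s$values, m, r, tau)
    fit <- classify_and_estimate(s$values)
    data.frame(
      g[c("study_kind", "alpha_expected", "N", "replicate", "seed")],
      sampen = se$value, sampen_normalized = se$normalized,
      alpha_hat = fit$alpha_hat, class_label = fit$class_label,
      row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Normalization study: raw vs maximum-entropy-normalized SampEn across N
#'
#' Identical measurements to [run_discrimination_study()] but with series
#' lengths extended to 5000 and 10000, to expose how the normalized
#' estimate decreases with record length even when the raw estimate is
#' stable.
#'
#' @inheritParams run_outlier_study
#' @export
run_normalization_study <- function(alphas = alpha_grid_coarse(),
                                    lengths = c(250, 500, 1000, 5000, 10000),
                                    replicates = 100, master_seed = 1,
                                    m = 1, r = 0.25, tau = 1) {
  out <- run_discrimination_study(alphas, lengths, replicates, master_seed,
                                  m, r, tau)
  out$study_kind <- "normalization"
  out
}

#' Hyperparameter sweep for SampEn
#'
#' Re-measures SampEn over grids of `m`, `r` and `tau` on the same set of
#' simulated series, for assessing estimator precision as the
#' hyperparameters vary.
#'
#' @inheritParams run_estimation_study
#' @param m_grid,r_grid,tau_grid hyperparameter values to sweep.
#' @return data frame with one row per (alpha, N, replicate, m, r, tau).
#' @export
run_sweep <- function(alphas = c(0.5, 0.7, 0.9),
                      lengths = 1000, replicates = 100, master_seed = 1,
                      m_grid = 1:3, r_grid = c(0.15, 0.2, 0.25, 0.3, 0.35),
                      tau_grid = 1:3) {
  grid <- study_grid("sweep", alphas, lengths, replicates, master_seed)
  pgrid <- expand.grid(m = m_grid, r = r_grid, tau = tau_grid,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    s <- simulate_alpha(g$alpha_expected, g$N, g$seed)
    se <- vapply(seq_len(nrow(pgrid)), function(j) {
      sampen(s$values, pgrid$m[j], pgrid$r[j], pgrid$tau[j])$value
    }, numeric(1))
    data.frame(
      g[c("study_kind", "alpha_expected", "N", "replicate", "seed")],
      pgrid, sampen = se, row.names = NULL
    )
  })
  do.call(rbind, rows)
}

#' Summarize per-replicate study rows into per-cell statistics
#'
#' Aggregates the raw tables produced by the `run_*_study()` functions:
#' mean/SD and bias of the alpha estimates (estimation), proportion
#' nonstationary (classification), mean/SD of percent bias per condition
#' (outlier), and mean/SD of SampEn (discrimination, normalization, sweep).
#' Undefined SampEn values (no template matches) are excluded from means,
#' with the exclusion count reported in `n_excluded`.
#'
#' @param rows a data frame from one of the study runners.
#' @return data frame with one row per study cell.
#' @export
summarize_study <- function(rows) {
  kind <- rows$study_kind[1]
  by_cols <- switch(kind,
    estimation = c("alpha_expected", "N", "method"),
    classification = ,
    classification_fine = c("alpha_expected", "N"),
    outlier = c("alpha_expected", "N", "condition"),
    sweep = c("alpha_expected", "N", "m", "r", "tau"),
    c("alpha_expected", "N")
  )
  value_col <- switch(kind,
    estimation = "alpha_hat",
    classification = ,
    classification_fine = "nonstationary",
    outlier = "percent_bias",
    "sampen"
  )
  f <- rows[by_cols]
  split_rows <- split(rows, f, drop = TRUE)
  out <- do.call(rbind, lapply(split_rows, function(d) {
    v <- d[[value_col]]
    cell <- d[1, by_cols, drop = FALSE]
    cell$n <- nrow(d)
    cell$n_excluded <- sum(is.na(v))
    if (value_col == "nonstationary") {
      cell$prop_nonstationary <- mean(v)
    } else {
      cell$mean <- mean(v, na.rm = TRUE)
      cell$sd <- sd(v, na.rm = TRUE)
      if (value_col == "alpha_hat") cell$bias <- cell$mean - cell$alpha_expected
      if (kind %in% c("discrimination", "normalization")) {
        cell$mean_normalized <- mean(d$sampen_normalized, na.rm = TRUE)
        cell$sd_normalized <- sd(d$sampen_normalized, na.rm = TRUE)
      }
    }
    cell
  }))
  rownames(out) <- NULL
  out[do.call(order, unname(out[by_cols])), , drop = FALSE]
}
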