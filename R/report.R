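ability_columns <- function(judges) {
  intersect(c("era", "steu", "teique"), names(judges))
}

#' Full study report
#'
#' Runs the complete analysis sequence on a dataset and collects every
#' block of the standard report: descriptives for the external measures
#' and the three accuracy indices, one-sample t tests against the
#' chance level, the Spearman intercorrelation matrix (indices,
#' external measures, judge gender), trait and modality subscore tables
#' with their own chance tests and Spearman correlations with the
#' external measures, gender-pairing means with pooled t tests,
#' reliability estimates, and attenuation-corrected correlations.
#' Missing inputs (e.g. no ability columns) produce explicitly absent
#' blocks, never silent zeros.
#'
#' @param cube A [ratings_cube()] (or a `simulated_study`, whose parts
#'   are used directly).
#' @param crit A [criterion_matrix()]; ignored when `cube` is a
#'   simulated study.
#' @param judges Judge data frame; ignored when `cube` is a simulated
#'   study.
#' @param external_rel Named reliabilities of the external measures for
#'   the disattenuation block (defaults to the published alphas of the
#'   three tests the design emulates).
#' @param min_prop,clip Scoring parameters, see [judgment_accuracy()].
#' @param n_splits,seed Replicability settings, see
#'   [profile_replicability()].
#' @return A list of class `study_report`; the underlying fit is in
#'   `$fit`.
#' @export
score_study <- function(cube, crit = NULL, judges = NULL,
                        external_rel = c(era = 0.89, steu = 0.78,
                                         teique = 0.93),
                        min_prop = 0.8, clip = 0.999, n_splits = 200,
                        seed = 1) {
  if (inherits(cube, "simulated_study")) {
    judges <- cube$judges
    crit <- cube$crit
    cube <- cube$cube
  }
  fit <- judgment_accuracy(cube, crit, judges, min_prop = min_prop,
                           clip = clip)
  summ <- summary(fit)
  rel <- accuracy_reliability(fit, n_splits = n_splits, seed = seed)

  descr <- do.call(rbind, lapply(index_names(), function(idx) {
    s <- fit$scores[[idx]]
    data.frame(measure = idx, mean = mean(s, na.rm = TRUE),
               sd = stats::sd(s, na.rm = TRUE), n = sum(!is.na(s)),
               stringsAsFactors = FALSE)
  }))
  abilities <- character()
  corr <- NULL
  corrected <- NULL
  if (!is.null(judges)) {
    abilities <- ability_columns(judges)
    ord <- match(fit$scores$judge_id, judges$judge_id)
    for (ab in abilities) {
      s <- as.numeric(judges[[ab]])[ord]
      descr <- rbind(descr, data.frame(measure = ab, mean = mean(s, na.rm = TRUE),
                                       sd = stats::sd(s, na.rm = TRUE),
                                       n = sum(!is.na(s))))
    }
    ab_mat <- vapply(abilities, function(ab) as.numeric(judges[[ab]])[ord],
                     numeric(nrow(fit$scores)))
    mat <- cbind(matrix(ab_mat, nrow = nrow(fit$scores),
                        dimnames = list(NULL, abilities)),
                 coef(fit))
    jg <- judge_genders(fit)
    if (!is.null(jg)) {
      mat <- cbind(mat, gender = as.numeric(jg == "female"))
    }
    p <- ncol(mat)
    corr <- matrix(NA_real_, p, p, dimnames = list(colnames(mat),
                                                   colnames(mat)))
    corr_n <- corr
    for (i in seq_len(p)) {
      for (k in seq_len(p)) {
        cc <- cor_spearman(mat[, i], mat[, k])
        corr[i, k] <- cc$r
        corr_n[i, k] <- cc$n
      }
    }
    have_rel <- external_rel[intersect(names(external_rel), abilities)]
    if (length(have_rel)) {
      corrected <- corrected_correlation_table(
        fit, external_rel = have_rel,
        index_rel = stats::setNames(rel$value, rel$index))
    }
  }

  subscore_cors <- NULL
  if (!is.null(judges) && length(abilities)) {
    ord <- match(fit$scores$judge_id, judges$judge_id)
    jg <- judge_genders(fit)
    sub_mats <- c(
      stats::setNames(lapply(fit$traits, function(a)
        fit$trait_subscores[, a]), paste0("trait_", fit$traits)),
      stats::setNames(lapply(fit$modalities, function(m)
        fit$trait_modality_subscores[, m]),
        paste0("trait_accuracy_", fit$modalities)),
      stats::setNames(lapply(fit$modalities, function(m)
        fit$profile_modality_subscores$overall[, m]),
        paste0("overall_accuracy_", fit$modalities)),
      stats::setNames(lapply(fit$modalities, function(m)
        fit$profile_modality_subscores$distinctive[, m]),
        paste0("distinctive_accuracy_", fit$modalities)))
    subscore_cors <- do.call(rbind, lapply(names(sub_mats), function(nm) {
      s <- sub_mats[[nm]]
      tt <- t_one_sample(s, 0)
      row <- data.frame(subscore = nm, mean = tt$mean, sd = tt$sd, n = tt$n,
                        t = tt$statistic, p = tt$p_value,
                        stringsAsFactors = FALSE)
      for (ab in abilities) {
        row[[paste0("rho_", ab)]] <-
          cor_spearman(as.numeric(judges[[ab]])[ord], s)$r
      }
      if (!is.null(jg)) {
        row$rho_gender <- cor_spearman(as.numeric(jg == "female"), s)$r
      }
      row
    }))
  }

  structure(list(fit = fit, descriptives = descr,
                 one_sample = summ$totals,
                 intercorrelations = corr,
                 subscores = subscore_cors,
                 gender_tests = summ$gender_tests,
                 pairing_means = summ$pairing_means,
                 pairing_tests = summ$pairing_tests,
                 reliability = rel, corrected = corrected,
                 settings = list(min_prop = min_prop, clip = clip,
                                 n_splits = n_splits, seed = seed,
                                 external_rel = as.list(external_rel)),
                 validation = fit$validation),
            class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  cat("==== Descriptive statistics and chance tests ====\n")
  print(round_df(x$descriptives, digits), row.names = FALSE)
  cat("\nOne-sample t tests against zero:\n")
  for (idx in names(x$one_sample)) {
    tt <- x$one_sample[[idx]]
    cat(sprintf("  %-30s t(%d) = %.3f, p %s\n", idx, as.integer(tt$df),
                tt$statistic, format_p(tt$p_value)))
  }
  if (!is.null(x$intercorrelations)) {
    cat("\n==== Spearman intercorrelations ====\n")
    print(round(x$intercorrelations, digits))
  }
  if (!is.null(x$subscores)) {
    cat("\n==== Subscores (means, chance tests, Spearman correlations) ====\n")
    print(round_df(x$subscores, digits), row.names = FALSE)
  }
  if (!is.null(x$pairing_means)) {
    cat("\n==== Gender pairings ====\n")
    print(round_df(x$pairing_means, digits), row.names = FALSE)
    print(round_df(x$pairing_tests, digits), row.names = FALSE)
  }
  cat("\n==== Reliability ====\n")
  print(round_df(x$reliability, digits), row.names = FALSE)
  if (!is.null(x$corrected)) {
    cat("\n==== Attenuation-corrected correlations ====\n")
    print(round_df(x$corrected, digits), row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `report.json` (full precision, via jsonlite), `scores.csv`
#' (one row per judge), `cells.csv` (long-format per-cell correlations
#' for audit) and `report.txt` (the human-readable tables, rounded to 2
#' decimals).
#'
#' @param report A [score_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fit <- report$fit
  utils::write.csv(cbind(fit$scores,
                         fit$trait_subscores,
                         stats::setNames(as.data.frame(
                           fit$trait_modality_subscores),
                           paste0("trait_", fit$modalities))),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  dn <- dimnames(fit$cells$r)
  cells_long <- data.frame(
    judge_id = dn[[1L]][slice.index(fit$cells$r, 1L)],
    trait = dn[[2L]][slice.index(fit$cells$r, 2L)],
    modality = dn[[3L]][slice.index(fit$cells$r, 3L)],
    r = as.vector(fit$cells$r), n = as.vector(fit$cells$n),
    stringsAsFactors = FALSE)
  utils::write.csv(cells_long, file.path(dir, "cells.csv"),
                   row.names = FALSE)
  json <- list(
    descriptives = report$descriptives,
    one_sample = report$one_sample,
    intercorrelations = report$intercorrelations,
    subscores = report$subscores,
    gender_tests = report$gender_tests,
    pairing_means = report$pairing_means,
    pairing_tests = report$pairing_tests,
    reliability = report$reliability,
    corrected = report$corrected,
    settings = report$settings)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  sink(file.path(dir, "report.txt"))
  on.exit(sink())
  print(report)
  invisible(dir)
}

#' Simulation-based recovery and calibration study
#'
#' Repeats simulate-and-score over several seeds and summarises how well
#' the per-judge accuracy scores recover the latent ability `theta`
#' (Spearman correlation), optionally together with a null-configuration
#' calibration (mean index under zero signal) and a monotonicity grid
#' over `sigma_distinctive`.
#'
#' @param cfg A [sim_config()]; its seed field seeds the first
#'   replicate, subsequent replicates increment it.
#' @param n_seeds Number of replicates (>= 2).
#' @param include_null Also run each seed under [null_config()] and
#'   record the mean of each index.
#' @param sigma_grid Optional numeric vector of `sigma_distinctive`
#'   values for a median-trait-accuracy monotonicity grid.
#' @return A list of class `recovery_summary` with data frames
#'   `recovery` (seed x index Spearman correlations with theta), `null`
#'   (if requested) and `grid`.
#' @export
run_recovery <- function(cfg, n_seeds = 20, include_null = FALSE,
                         sigma_grid = NULL) {
  stopifnot(inherits(cfg, "sim_config"), n_seeds >= 2)
  seeds <- cfg$seed + seq_len(n_seeds) - 1L
  one <- function(cf) {
    study <- simulate_study(cf)
    fit <- judgment_accuracy(study$cube, study$crit, study$judges)
    list(fit = fit, theta = study$theta)
  }
  recovery <- do.call(rbind, lapply(seeds, function(s) {
    cf <- cfg
    cf$seed <- as.integer(s)
    res <- one(cf)
    out <- data.frame(seed = s)
    for (idx in index_names()) {
      out[[paste0("rho_theta_", idx)]] <-
        cor_spearman(res$theta, res$fit$scores[[idx]])$r
    }
    out$mean_trait_accuracy <- mean(res$fit$scores$trait_accuracy,
                                    na.rm = TRUE)
    out$mean_overall <- mean(res$fit$scores$overall_profile_accuracy,
                             na.rm = TRUE)
    out$mean_distinctive <- mean(res$fit$scores$distinctive_profile_accuracy,
                                 na.rm = TRUE)
    out
  }))
  null_df <- NULL
  if (include_null) {
    null_df <- do.call(rbind, lapply(seeds, function(s) {
      cf <- null_config(n_judges = cfg$n_judges, n_targets = cfg$n_targets,
                        n_traits = cfg$n_traits, seed = s)
      res <- one(cf)
      data.frame(seed = s,
                 mean_trait = mean(res$fit$scores$trait_accuracy, na.rm = TRUE),
                 mean_overall = mean(res$fit$scores$overall_profile_accuracy,
                                     na.rm = TRUE),
                 mean_distinctive = mean(
                   res$fit$scores$distinctive_profile_accuracy, na.rm = TRUE))
    }))
  }
  grid_df <- NULL
  if (!is.null(sigma_grid)) {
    grid_df <- do.call(rbind, lapply(sigma_grid, function(sg) {
      med <- vapply(seeds, function(s) {
        cf <- cfg
        cf$seed <- as.integer(s)
        cf$sigma_distinctive <- sg
        res <- one(cf)
        stats::median(res$fit$scores$trait_accuracy, na.rm = TRUE)
      }, numeric(1))
      data.frame(sigma_distinctive = sg,
                 median_trait_accuracy = mean(med))
    }))
  }
  structure(list(recovery = recovery, null = null_df, grid = grid_df),
            class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, digits = 3, ...) {
  cat("Recovery of latent judge ability (Spearman rho with theta):\n")
  means <- colMeans(x$recovery[, -1, drop = FALSE], na.rm = TRUE)
  for (nm in names(means)) {
    cat(sprintf("  %-40s %.3f\n", nm, means[[nm]]))
  }
  if (!is.null(x$null)) {
    cat("Null configuration mean indices (expect ~0):\n")
    print(round(colMeans(x$null[, -1, drop = FALSE], na.rm = TRUE), digits))
  }
  if (!is.null(x$grid)) {
    cat("Monotonicity grid over sigma_distinctive:\n")
    print(round_df(x$grid, digits), row.names = FALSE)
  }
  invisible(x)
}
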