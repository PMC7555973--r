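#' Trait-by-modality cell correlations
#'
#' For every judge, trait and modality, correlates the judge's ratings of
#' that modality's targets with those targets' criterion scores on the
#' trait (Pearson, across targets). A cell is undefined when fewer than 3
#' rated targets remain or the judge rated every target in the modality
#' with the same value.
#'
#' @param cube A [ratings_cube()].
#' @param crit A [criterion_matrix()] with matching target/trait labels.
#' @param target_subset Optional character vector restricting the targets
#'   used (e.g. one target gender); modalities keep their identity.
#' @return A list with numeric arrays `r` and `n`, both
#'   `[judge, trait, modality]`.
#' @export
cell_correlations <- function(cube, crit, target_subset = NULL) {
  eff <- effective_ratings(cube)
  dn <- dimnames(eff)
  crit_m <- crit$criteria[dn$target, dn$trait, drop = FALSE]
  modality <- crit$modality[match(dn$target, rownames(crit$criteria))]
  mods <- unique(crit$modality)
  keep <- if (is.null(target_subset)) rep(TRUE, length(dn$target)) else
    dn$target %in% target_subset
  out_r <- array(NA_real_, c(length(dn$judge), length(dn$trait), length(mods)),
                 dimnames = list(judge = dn$judge, trait = dn$trait,
                                 modality = mods))
  out_n <- out_r
  for (m in seq_along(mods)) {
    sel <- which(modality == mods[m] & keep)
    for (a in seq_along(dn$trait)) {
      y <- crit_m[sel, a]
      for (j in seq_along(dn$judge)) {
        cc <- cor_pearson(eff[j, sel, a], y)
        out_r[j, a, m] <- cc$r
        out_n[j, a, m] <- cc$n
      }
    }
  }
  list(r = out_r, n = out_n)
}

#' Normative rating and criterion profiles
#'
#' The normative rating profile is the per-trait mean of all present
#' ratings across all judges and all targets; the normative criterion
#' profile is the per-trait mean criterion across all targets. Both are
#' always computed over the full target set — they represent the
#' "average person" that distinctive scoring partials out.
#'
#' @inheritParams cell_correlations
#' @param exclude_judge Optional judge label: that judge's ratings are
#'   left out of the normative rating profile (self-exclusion variant;
#'   the default, `NULL`, includes all judges).
#' @return A list with per-trait vectors `rating` and `criterion`.
#' @export
normative_profiles <- function(cube, crit, exclude_judge = NULL) {
  eff <- effective_ratings(cube)
  dn <- dimnames(eff)
  if (!is.null(exclude_judge)) {
    eff <- eff[setdiff(dn$judge, exclude_judge), , , drop = FALSE]
  }
  rating <- apply(eff, 3L, mean, na.rm = TRUE)
  if (anyNA(rating) || any(!is.finite(rating))) {
    stop("a trait has no present ratings; cannot form the normative profile")
  }
  criterion <- colMeans(crit$criteria[, dn$trait, drop = FALSE])
  list(rating = rating, criterion = criterion)
}

#' Per-target profile correlations
#'
#' For each (judge, target) pair, correlates the judge's trait profile
#' for that target with the target's criterion profile across traits.
#' In `"overall"` mode raw profiles are used; in `"distinctive"` mode the
#' normative rating profile is subtracted from the ratings and the
#' normative criterion profile from the criteria first, so the
#' correlation reflects only the target's deviation from the average
#' person. Profiles with fewer than 3 complete trait pairs, or with zero
#' variance (e.g. a judge assigning the normative profile exactly, whose
#' distinctive profile is the zero vector), are undefined.
#'
#' @inheritParams cell_correlations
#' @param mode `"overall"` or `"distinctive"`.
#' @param normative Profiles from [normative_profiles()]; required for
#'   distinctive mode (computed on the fly when omitted).
#' @return A list with judge x target matrices `r` and `n`.
#' @export
profile_correlations <- function(cube, crit,
                                 mode = c("overall", "distinctive"),
                                 normative = NULL) {
  mode <- match.arg(mode)
  eff <- effective_ratings(cube)
  dn <- dimnames(eff)
  crit_m <- crit$criteria[dn$target, dn$trait, drop = FALSE]
  if (mode == "distinctive") {
    if (is.null(normative)) normative <- normative_profiles(cube, crit)
    eff <- sweep(eff, 3L, normative$rating)
    crit_m <- sweep(crit_m, 2L, normative$criterion[dn$trait])
  }
  out_r <- matrix(NA_real_, length(dn$judge), length(dn$target),
                  dimnames = list(judge = dn$judge, target = dn$target))
  out_n <- out_r
  for (j in seq_along(dn$judge)) {
    for (t in seq_along(dn$target)) {
      cc <- cor_pearson(eff[j, t, ], crit_m[t, ])
      out_r[j, t] <- cc$r
      out_n[j, t] <- cc$n
    }
  }
  list(r = out_r, n = out_n)
}

# Row-wise Fisher-z aggregation of a judge x component correlation matrix.
agg_rows <- function(m, min_prop, clip) {
  res <- apply(m, 1L, function(r) {
    a <- aggregate_z(r, min_prop = min_prop, clip = clip)
    c(a$mean_z, a$r_back, a$n_available)
  })
  list(mean_z = res[1L, ], r_back = res[2L, ],
       n_available = as.integer(res[3L, ]))
}

#' Score a judgment-accuracy study
#'
#' The main fitting function. From a ratings cube and a criterion matrix
#' it computes, for every judge, the three accuracy indices —
#' trait accuracy (Fisher-z mean of the trait-by-modality cell
#' correlations), overall profile accuracy (Fisher-z mean of the
#' per-target profile correlations) and distinctive profile accuracy
#' (the same after normative-profile subtraction) — together with their
#' per-trait and per-modality subscores and, when judge and target
#' genders are available, the scores restricted to each target gender.
#'
#' Aggregates follow the availability rule of [aggregate_z()]: a score is
#' missing unless at least `min_prop` of its component correlations are
#' defined (default 0.8, i.e. 20 of 24 cells, 24 of 30 profiles in the
#' classic 30-target, 8-trait, 3-modality design). Subscores apply the
#' same proportional rule. Reported scores are back-transformed to the
#' correlation metric; the underlying mean z values are retained in the
#' returned object.
#'
#' @param cube A [ratings_cube()].
#' @param crit A [criterion_matrix()].
#' @param judges Optional judge data frame (see [read_judges_csv()]) with
#'   at least `judge_id` and `gender`; enables gender analyses.
#' @param min_prop Availability threshold for [aggregate_z()].
#' @param clip Fisher-z clip bound for degenerate correlations.
#' @param exclude_self If `TRUE`, each judge's normative rating profile
#'   excludes their own ratings. Default `FALSE`: the normative profile
#'   is the grand mean over all judges.
#' @return An object of class `judgment_accuracy`; see
#'   [coef.judgment_accuracy()], [summary.judgment_accuracy()].
#' @examples
#' study <- simulate_study(sim_config(n_judges = 20, seed = 1))
#' fit <- judgment_accuracy(study$cube, study$crit, study$judges)
#' fit
#' head(coef(fit))
#' @export
judgment_accuracy <- function(cube, crit, judges = NULL, min_prop = 0.8,
                              clip = 0.999, exclude_self = FALSE) {
  validation <- validate_dataset(cube, crit, judges)
  dn <- dimnames(cube$ratings)
  n_judges <- length(dn$judge)
  mods <- unique(crit$modality)

  cells <- cell_correlations(cube, crit)
  flat <- matrix(cells$r, nrow = n_judges)  # judge x (trait*modality)
  trait_total <- agg_rows(flat, min_prop, clip)

  trait_sub <- sapply(dn$trait, function(a)
    agg_rows(matrix(cells$r[, a, ], nrow = n_judges), min_prop, clip)$r_back)
  trait_sub <- matrix(trait_sub, nrow = n_judges,
                      dimnames = list(dn$judge, dn$trait))
  trait_mod_sub <- sapply(mods, function(m)
    agg_rows(matrix(cells$r[, , m], nrow = n_judges), min_prop, clip)$r_back)
  trait_mod_sub <- matrix(trait_mod_sub, nrow = n_judges,
                          dimnames = list(dn$judge, mods))

  normative <- if (exclude_self) NULL else normative_profiles(cube, crit)
  prof <- list()
  for (mode in c("overall", "distinctive")) {
    if (exclude_self && mode == "distinctive") {
      r <- matrix(NA_real_, n_judges, length(dn$target),
                  dimnames = list(judge = dn$judge, target = dn$target))
      n <- r
      for (j in dn$judge) {
        nv <- normative_profiles(cube, crit, exclude_judge = j)
        pc <- profile_correlations(cube, crit, mode = "distinctive",
                                   normative = nv)
        r[j, ] <- pc$r[j, ]
        n[j, ] <- pc$n[j, ]
      }
      prof[[mode]] <- list(r = r, n = n)
    } else {
      prof[[mode]] <- profile_correlations(cube, crit, mode = mode,
                                           normative = normative)
    }
  }
  overall_total <- agg_rows(prof$overall$r, min_prop, clip)
  distinct_total <- agg_rows(prof$distinctive$r, min_prop, clip)

  target_mod <- crit$modality[match(dn$target, rownames(crit$criteria))]
  prof_mod_sub <- lapply(prof, function(p) {
    out <- sapply(mods, function(m)
      agg_rows(p$r[, target_mod == m, drop = FALSE], min_prop, clip)$r_back)
    matrix(out, nrow = n_judges, dimnames = list(dn$judge, mods))
  })

  by_target_gender <- NULL
  if (!is.null(crit$gender)) {
    tg <- crit$gender[match(dn$target, rownames(crit$criteria))]
    by_target_gender <- lapply(stats::setNames(nm = unique(tg)), function(g) {
      sub_cells <- cell_correlations(cube, crit,
                                     target_subset = dn$target[tg == g])
      cbind(
        trait_accuracy = agg_rows(matrix(sub_cells$r, nrow = n_judges),
                                  min_prop, clip)$r_back,
        overall_profile_accuracy =
          agg_rows(prof$overall$r[, tg == g, drop = FALSE],
                   min_prop, clip)$r_back,
        distinctive_profile_accuracy =
          agg_rows(prof$distinctive$r[, tg == g, drop = FALSE],
                   min_prop, clip)$r_back)
    })
  }

  scores <- data.frame(
    judge_id = dn$judge,
    trait_accuracy = trait_total$r_back,
    overall_profile_accuracy = overall_total$r_back,
    distinctive_profile_accuracy = distinct_total$r_back,
    trait_n_available = trait_total$n_available,
    overall_n_available = overall_total$n_available,
    distinctive_n_available = distinct_total$n_available,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(
    list(scores = scores,
         mean_z = cbind(trait_accuracy = trait_total$mean_z,
                        overall_profile_accuracy = overall_total$mean_z,
                        distinctive_profile_accuracy = distinct_total$mean_z),
         cells = cells,
         profile_r = prof,
         trait_subscores = trait_sub,
         trait_modality_subscores = trait_mod_sub,
         profile_modality_subscores = prof_mod_sub,
         by_target_gender = by_target_gender,
         normative = normative,
         judges = judges,
         modalities = mods,
         traits = dn$trait,
         settings = list(min_prop = min_prop, clip = clip,
                         exclude_self = exclude_self),
         validation = validation),
    class = "judgment_accuracy")
}
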