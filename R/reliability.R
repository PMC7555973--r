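#' Reliability of the trait-accuracy index
#'
#' Cronbach's alpha over the judge x cell matrix of Fisher-z transformed
#' trait-by-modality correlations (complete-case judges). With 8 traits
#' and 3 modalities this is alpha over 24 component scores per judge.
#'
#' @param cells Output of [cell_correlations()].
#' @param clip Fisher-z clip bound.
#' @return A one-row data frame with columns `index`, `method`, `value`,
#'   `n_components`, `n_units`.
#' @export
trait_accuracy_reliability <- function(cells, clip = 0.999) {
  z <- fisher_z(matrix(cells$r, nrow = dim(cells$r)[1L]), clip = clip)
  data.frame(index = "trait_accuracy", method = "alpha_over_components",
             value = cronbach_alpha(z), n_components = ncol(z),
             n_units = sum(stats::complete.cases(z)),
             stringsAsFactors = FALSE)
}

#' Split-half replicability of profile-correlation scores
#'
#' Reliability of a profile-accuracy index estimated by repeated random
#' split-half: targets are split into two halves, each judge's Fisher-z
#' profile correlations are averaged within each half, the two
#' half-scores are correlated across judges, and the half-length
#' correlation is stepped up with the Spearman-Brown formula 2r/(1+r).
#' The estimate is the mean over `n_splits` random splits; the split
#' sequence is fully determined by `seed`.
#'
#' @param profile_z Judge x target matrix of Fisher-z profile
#'   correlations (`NA` for undefined profiles).
#' @param n_splits Number of random splits (default 200).
#' @param seed Integer seed; mandatory, so the estimate is reproducible.
#' @return A one-row data frame as in [trait_accuracy_reliability()]
#'   with `method = "split_half_spearman_brown"`.
#' @export
profile_replicability <- function(profile_z, n_splits = 200, seed) {
  if (missing(seed)) stop("'seed' is required for profile_replicability()")
  profile_z <- as.matrix(profile_z)
  n_targets <- ncol(profile_z)
  if (n_targets < 4L) stop("replicability needs at least 4 targets")
  if (nrow(profile_z) < 3L) stop("replicability needs at least 3 judges")
  half <- floor(n_targets / 2)
  rng <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    replicate(n_splits, sample.int(n_targets, half), simplify = FALSE)
  })
  sb <- vapply(rng, function(sel) {
    a <- rowMeans(profile_z[, sel, drop = FALSE], na.rm = TRUE)
    b <- rowMeans(profile_z[, -sel, drop = FALSE], na.rm = TRUE)
    r <- cor_pearson(a, b)$r
    if (is.na(r)) NA_real_ else 2 * r / (1 + r)
  }, numeric(1))
  data.frame(index = NA_character_, method = "split_half_spearman_brown",
             value = mean(sb, na.rm = TRUE), n_components = n_targets,
             n_units = nrow(profile_z), stringsAsFactors = FALSE)
}

#' Reliability of all three accuracy indices
#'
#' Trait accuracy uses Cronbach's alpha over the 24 trait-by-modality
#' cells; the two profile indices use seeded split-half replicability
#' over targets with Spearman-Brown step-up.
#'
#' @param object A [judgment_accuracy()] fit.
#' @param n_splits Splits for [profile_replicability()].
#' @param seed Integer seed for the split sequence.
#' @return A data frame with one row per index.
#' @export
accuracy_reliability <- function(object, n_splits = 200, seed = 1) {
  stopifnot(inherits(object, "judgment_accuracy"))
  clip <- object$settings$clip
  out <- trait_accuracy_reliability(object$cells, clip = clip)
  for (mode in c("overall", "distinctive")) {
    rel <- profile_replicability(fisher_z(object$profile_r[[mode]]$r,
                                          clip = clip),
                                 n_splits = n_splits, seed = seed)
    rel$index <- paste0(if (mode == "overall") "overall" else "distinctive",
                        "_profile_accuracy")
    out <- rbind(out, rel)
  }
  out
}

#' Attenuation-corrected correlations with external measures
#'
#' For each external ability measure and each accuracy index, computes
#' the raw Spearman rank correlation across judges, then corrects it for
#' the unreliability of both measures with [disattenuate()]. External
#' reliabilities are user inputs (e.g. the published alpha of the
#' ability test); index reliabilities default to [accuracy_reliability()]
#' estimates.
#'
#' @param object A [judgment_accuracy()] fit whose `judges` table holds
#'   the ability score columns.
#' @param external_rel Named numeric vector of reliabilities for the
#'   ability columns, e.g. `c(era = .89, steu = .78, teique = .93)`.
#'   Abilities without a reliability are skipped with a warning; a
#'   non-positive estimated index reliability leaves `corrected_r`
#'   missing (with a warning) while keeping the raw correlation.
#' @param index_rel Optional named numeric vector of reliabilities for
#'   the three indices; computed from the fit when `NULL`.
#' @param n_splits,seed Passed to [accuracy_reliability()] when
#'   `index_rel` is `NULL`.
#' @return A data frame with columns `ability`, `index`, `raw_r`, `n`,
#'   `rel_x`, `rel_y`, `corrected_r`, `out_of_range`.
#' @export
corrected_correlation_table <- function(object, external_rel,
                                        index_rel = NULL, n_splits = 200,
                                        seed = 1) {
  stopifnot(inherits(object, "judgment_accuracy"))
  if (is.null(object$judges)) stop("fit has no judges table")
  if (is.null(index_rel)) {
    rel <- accuracy_reliability(object, n_splits = n_splits, seed = seed)
    index_rel <- stats::setNames(rel$value, rel$index)
  }
  ord <- match(object$scores$judge_id, object$judges$judge_id)
  rows <- list()
  for (ab in names(external_rel)) {
    if (!ab %in% names(object$judges)) {
      warning("ability column '", ab, "' not in judges table; skipped")
      next
    }
    if (!is.finite(external_rel[[ab]]) || external_rel[[ab]] <= 0) {
      warning("no usable reliability for '", ab, "'; skipped")
      next
    }
    x <- as.numeric(object$judges[[ab]])[ord]
    for (idx in index_names()) {
      cc <- cor_spearman(x, object$scores[[idx]])
      rel_ok <- is.finite(index_rel[[idx]]) && index_rel[[idx]] > 0
      if (!rel_ok) {
        # an estimated reliability can come out non-positive in small
        # samples; report the raw correlation with an explicit gap
        warning("non-positive reliability estimate for index '", idx,
                "'; corrected value left missing")
      }
      corr <- NA_real_
      oor <- FALSE
      if (rel_ok && !is.na(cc$r)) {
        corr <- withCallingHandlers(
          disattenuate(cc$r, external_rel[[ab]], index_rel[[idx]]),
          warning = function(w) {
            oor <<- TRUE
            invokeRestart("muffleWarning")
          })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ability = ab, index = idx, raw_r = cc$r, n = cc$n,
        rel_x = unname(external_rel[[ab]]),
        rel_y = unname(as.numeric(index_rel[[idx]])),
        corrected_r = corr, out_of_range = oor, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
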