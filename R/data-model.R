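#' Judges x targets x traits rating cube
#'
#' The central data container: a 3-dimensional numeric array of Likert
#' ratings with dimensions (judge, target, trait), plus a judge x target
#' logical matrix flagging pairs where the judge reported knowing the
#' target. Flagged pairs are treated as missing by every scoring
#' operation, implementing the usual acquaintance-exclusion rule.
#'
#' @param ratings Numeric array `[judge, target, trait]` with dimnames on
#'   all three axes. `NA` marks absent ratings.
#' @param known Logical judge x target matrix; `NULL` means no
#'   acquaintances. Dimnames must match the first two axes of `ratings`.
#' @param scale_min,scale_max Bounds of the rating scale (default 1-5).
#' @param discrete If `TRUE` (default) present ratings must sit on the
#'   integer grid of the scale.
#' @return An object of class `ratings_cube`.
#' @export
ratings_cube <- function(ratings, known = NULL, scale_min = 1, scale_max = 5,
                         discrete = TRUE) {
  if (!is.array(ratings) || length(dim(ratings)) != 3L) {
    stop("'ratings' must be a 3-d array [judge, target, trait]")
  }
  if (is.null(dimnames(ratings)) || any(vapply(dimnames(ratings), is.null, TRUE))) {
    stop("'ratings' needs dimnames on all three axes")
  }
  if (scale_max <= scale_min) stop("'scale_max' must exceed 'scale_min'")
  present <- ratings[!is.na(ratings)]
  if (any(present < scale_min | present > scale_max)) {
    stop("ratings outside the [", scale_min, ", ", scale_max, "] scale")
  }
  if (discrete && any(present != round(present))) {
    stop("ratings must sit on the integer grid of the scale")
  }
  if (is.null(known)) {
    known <- matrix(FALSE, dim(ratings)[1L], dim(ratings)[2L],
                    dimnames = dimnames(ratings)[1:2])
  }
  if (!is.matrix(known) || !identical(dim(known), dim(ratings)[1:2])) {
    stop("'known' must be a judge x target logical matrix matching 'ratings'")
  }
  names(dimnames(ratings)) <- c("judge", "target", "trait")
  dimnames(known) <- dimnames(ratings)[1:2]
  structure(
    list(ratings = ratings, known = known,
         scale_min = scale_min, scale_max = scale_max, discrete = discrete),
    class = "ratings_cube")
}

#' @export
print.ratings_cube <- function(x, ...) {
  d <- dim(x$ratings)
  cat("Ratings cube:", d[1L], "judges x", d[2L], "targets x", d[3L],
      "traits\n")
  cat("  present ratings:", sum(!is.na(x$ratings)), "of", length(x$ratings),
      "\n  acquainted (judge, target) pairs:", sum(x$known), "\n")
  invisible(x)
}

#' Ratings with acquaintance exclusions applied
#'
#' Returns the rating array with every cell of a known (judge, target)
#' pair set to `NA`. All scoring operates on this view; the stored
#' ratings are untouched.
#'
#' @param cube A [ratings_cube()].
#' @return Numeric array `[judge, target, trait]`.
#' @export
effective_ratings <- function(cube) {
  stopifnot(inherits(cube, "ratings_cube"))
  r <- cube$ratings
  if (any(cube$known)) {
    idx <- which(cube$known, arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      r[idx[k, 1L], idx[k, 2L], ] <- NA_real_
    }
  }
  r
}

#' Targets x traits criterion matrix with target metadata
#'
#' Holds the "true" scores each judgment is scored against, on the common
#' 1-5 scale, together with each target's presentation modality and
#' gender. Criterion values may not be missing.
#'
#' @param criteria Numeric targets x traits matrix with dimnames, values
#'   in `[scale_min, scale_max]`.
#' @param modality Character/factor of per-target modality labels
#'   (typically `"photo"`, `"mute_video"`, `"audio_video"`).
#' @param gender Character/factor of per-target gender labels
#'   (`"male"`/`"female"`), or `NULL` when unknown.
#' @param scale_min,scale_max Scale bounds, default 1-5.
#' @return An object of class `criterion_matrix`.
#' @export
criterion_matrix <- function(criteria, modality, gender = NULL,
                             scale_min = 1, scale_max = 5) {
  criteria <- as.matrix(criteria)
  if (is.null(rownames(criteria)) || is.null(colnames(criteria))) {
    stop("'criteria' needs target rownames and trait colnames")
  }
  if (anyNA(criteria)) stop("criterion values may not be missing")
  if (any(criteria < scale_min | criteria > scale_max)) {
    stop("criterion values outside [", scale_min, ", ", scale_max, "]")
  }
  modality <- as.character(modality)
  if (length(modality) != nrow(criteria)) {
    stop("'modality' must have one label per target")
  }
  if (any(table(modality) == 0L)) stop("empty modality group")
  if (!is.null(gender)) {
    gender <- as.character(gender)
    if (length(gender) != nrow(criteria)) {
      stop("'gender' must have one label per target")
    }
  }
  structure(
    list(criteria = criteria, modality = modality, gender = gender,
         scale_min = scale_min, scale_max = scale_max),
    class = "criterion_matrix")
}

#' @export
print.criterion_matrix <- function(x, ...) {
  cat("Criterion matrix:", nrow(x$criteria), "targets x", ncol(x$criteria),
      "traits\n  modalities:",
      paste(sprintf("%s (%d)", names(table(x$modality)), table(x$modality)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Rescale raw criterion scores onto the common rating scale
#'
#' Maps each instrument's raw scores linearly from its theoretical range
#' `[raw_min, raw_max]` onto `[1, 5]`:
#' `1 + 4 * (x - raw_min) / (raw_max - raw_min)`. Using the theoretical
#' rather than the observed range keeps the standardized criteria
#' independent of which targets happen to be in the sample.
#'
#' @param raw Numeric targets x traits matrix of raw instrument scores.
#' @param scales Data frame with columns `trait`, `raw_min`, `raw_max`,
#'   one row per trait column of `raw`.
#' @return Numeric matrix of the same shape with values in `[1, 5]`.
#' @export
standardize_criteria <- function(raw, scales) {
  raw <- as.matrix(raw)
  if (is.null(colnames(raw))) stop("'raw' needs trait colnames")
  need <- c("trait", "raw_min", "raw_max")
  if (!all(need %in% names(scales))) {
    stop("'scales' must have columns trait, raw_min, raw_max")
  }
  out <- raw
  for (tr in colnames(raw)) {
    row <- scales[scales$trait == tr, , drop = FALSE]
    if (nrow(row) != 1L) stop("no unique scale entry for trait '", tr, "'")
    lo <- row$raw_min
    hi <- row$raw_max
    if (hi <= lo) stop("raw_max must exceed raw_min for trait '", tr, "'")
    x <- raw[, tr]
    if (any(x < lo | x > hi, na.rm = TRUE)) {
      stop("raw value outside the instrument range [", lo, ", ", hi,
           "] for trait '", tr, "'")
    }
    out[, tr] <- 1 + 4 * (x - lo) / (hi - lo)
  }
  out
}

read_table_file <- function(path, sep = ",") {
  utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
}

#' Read a long-format ratings table
#'
#' Expects columns `judge_id`, `target_id`, `trait`, `rating` and an
#' optional logical `known` column. Each (judge, target, trait) key may
#' appear at most once; absent keys become missing cells. Judge, target
#' and trait axis orders follow first appearance in the file.
#'
#' @param path Path to a delimited text file with a header row.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @inheritParams ratings_cube
#' @return A [ratings_cube()].
#' @export
read_ratings_csv <- function(path, sep = ",", scale_min = 1, scale_max = 5,
                             discrete = TRUE) {
  df <- read_table_file(path, sep)
  need <- c("judge_id", "target_id", "trait", "rating")
  if (!all(need %in% names(df))) {
    stop("ratings table must have columns ", paste(need, collapse = ", "))
  }
  key <- paste(df$judge_id, df$target_id, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate (judge, target, trait) entry: ", dup$judge_id, ", ",
         dup$target_id, ", ", dup$trait)
  }
  rating <- suppressWarnings(as.numeric(df$rating))
  bad <- which(!is.na(df$rating) & df$rating != "" & is.na(rating))
  if (length(bad)) {
    stop("non-numeric rating '", df$rating[bad[1L]], "' in row ", bad[1L])
  }
  oob <- which(!is.na(rating) & (rating < scale_min | rating > scale_max))
  if (length(oob)) {
    stop("rating ", rating[oob[1L]], " in row ", oob[1L],
         " outside the [", scale_min, ", ", scale_max, "] scale")
  }
  judges <- unique(as.character(df$judge_id))
  targets <- unique(as.character(df$target_id))
  traits <- unique(as.character(df$trait))
  arr <- array(NA_real_, c(length(judges), length(targets), length(traits)),
               dimnames = list(judge = judges, target = targets,
                               trait = traits))
  arr[cbind(match(as.character(df$judge_id), judges),
            match(as.character(df$target_id), targets),
            match(as.character(df$trait), traits))] <- rating
  known <- matrix(FALSE, length(judges), length(targets),
                  dimnames = list(judges, targets))
  if ("known" %in% names(df)) {
    kf <- df[parse_logical(df$known), , drop = FALSE]
    known[cbind(match(as.character(kf$judge_id), judges),
                match(as.character(kf$target_id), targets))] <- TRUE
  }
  ratings_cube(arr, known, scale_min = scale_min, scale_max = scale_max,
               discrete = discrete)
}

parse_logical <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Write a ratings cube to a long-format CSV
#'
#' Emits one row per present rating; (judge, target) pairs flagged as
#' known are also written (with an empty rating field when the rating is
#' absent) so that write-then-read round-trips the missingness pattern.
#'
#' @param cube A [ratings_cube()].
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_ratings_csv <- function(cube, path, sep = ",") {
  stopifnot(inherits(cube, "ratings_cube"))
  dn <- dimnames(cube$ratings)
  idx <- which(!is.na(cube$ratings), arr.ind = TRUE)
  df <- data.frame(judge_id = dn[[1L]][idx[, 1L]],
                   target_id = dn[[2L]][idx[, 2L]],
                   trait = dn[[3L]][idx[, 3L]],
                   rating = cube$ratings[idx],
                   stringsAsFactors = FALSE)
  df$known <- cube$known[cbind(idx[, 1L], idx[, 2L])]
  kidx <- which(cube$known, arr.ind = TRUE)
  if (nrow(kidx)) {
    for (k in seq_len(nrow(kidx))) {
      j <- kidx[k, 1L]; t <- kidx[k, 2L]
      if (all(is.na(cube$ratings[j, t, ]))) {
        df <- rbind(df, data.frame(judge_id = dn[[1L]][j],
                                   target_id = dn[[2L]][t],
                                   trait = dn[[3L]][1L], rating = NA_real_,
                                   known = TRUE))
      }
    }
  }
  df <- df[order(match(df$judge_id, dn[[1L]]), match(df$target_id, dn[[2L]]),
                 match(df$trait, dn[[3L]])), ]
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

#' Read criterion scores and target metadata
#'
#' `values_path` holds long-format columns `target_id`, `trait`,
#' `raw_value`; `targets_path` holds `target_id`, `modality`, `gender`.
#' If `scales` is supplied the raw values are passed through
#' [standardize_criteria()]; otherwise they are taken to be already on
#' the 1-5 scale.
#'
#' @param values_path,targets_path Paths to the two delimited files.
#' @param scales Optional scale table for [standardize_criteria()].
#' @param sep Field separator.
#' @return A [criterion_matrix()].
#' @export
read_criteria_csv <- function(values_path, targets_path, scales = NULL,
                              sep = ",") {
  vals <- read_table_file(values_path, sep)
  meta <- read_table_file(targets_path, sep)
  if (!all(c("target_id", "trait", "raw_value") %in% names(vals))) {
    stop("criteria table must have columns target_id, trait, raw_value")
  }
  if (!all(c("target_id", "modality") %in% names(meta))) {
    stop("target metadata must have columns target_id, modality")
  }
  targets <- unique(as.character(vals$target_id))
  traits <- unique(as.character(vals$trait))
  m <- matrix(NA_real_, length(targets), length(traits),
              dimnames = list(targets, traits))
  m[cbind(match(as.character(vals$target_id), targets),
          match(as.character(vals$trait), traits))] <-
    as.numeric(vals$raw_value)
  if (anyNA(m)) stop("criterion table is not a complete targets x traits grid")
  if (!is.null(scales)) m <- standardize_criteria(m, scales)
  ord <- match(targets, as.character(meta$target_id))
  if (anyNA(ord)) stop("target metadata missing for some targets")
  gender <- if ("gender" %in% names(meta)) as.character(meta$gender)[ord]
  criterion_matrix(m, modality = as.character(meta$modality)[ord],
                   gender = gender)
}

#' Read judge metadata and external test scores
#'
#' Expects columns `judge_id`, `gender` and any of `era`, `steu`,
#' `teique` (missing scores allowed). `era` is validated to lie in
#' `[0, 100]` (a percent-correct score).
#'
#' @param path Path to a delimited file.
#' @param sep Field separator.
#' @return A data frame with one row per judge.
#' @export
read_judges_csv <- function(path, sep = ",") {
  df <- read_table_file(path, sep)
  if (!all(c("judge_id", "gender") %in% names(df))) {
    stop("judges table must have columns judge_id, gender")
  }
  df$judge_id <- as.character(df$judge_id)
  if (anyDuplicated(df$judge_id)) stop("duplicate judge_id in judges table")
  for (col in c("era", "steu", "teique")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  if ("era" %in% names(df) &&
      any(df$era < 0 | df$era > 100, na.rm = TRUE)) {
    stop("era scores must lie in [0, 100]")
  }
  df
}

#' Validate a ratings cube against criteria and judge metadata
#'
#' Checks that the target and trait axes agree between the cube and the
#' criterion matrix (a mismatch is an error), then reports per-judge
#' missing-cell counts (splitting acquaintance exclusions from absent
#' ratings), targets with zero coverage, and judges left without a single
#' usable rating. The dataset passes when labels align and every judge
#' retains at least one present rating.
#'
#' @param cube A [ratings_cube()].
#' @param crit A [criterion_matrix()].
#' @param judges Optional judge data frame ([read_judges_csv()]); if
#'   given, its `judge_id` set must cover the cube's judge axis.
#' @return A list of class `profacc_validation` with elements `ok`,
#'   `issues` (character), and `per_judge` (data frame with columns
#'   `judge_id`, `n_present`, `n_excluded_known`, `n_absent`).
#' @export
validate_dataset <- function(cube, crit, judges = NULL) {
  stopifnot(inherits(cube, "ratings_cube"), inherits(crit, "criterion_matrix"))
  dn <- dimnames(cube$ratings)
  if (!identical(sort(dn$target), sort(rownames(crit$criteria)))) {
    stop("target labels differ between ratings cube and criterion matrix")
  }
  if (!identical(sort(dn$trait), sort(colnames(crit$criteria)))) {
    stop("trait labels differ between ratings cube and criterion matrix")
  }
  if (!is.null(judges) && !all(dn$judge %in% judges$judge_id)) {
    stop("judges table does not cover every judge in the ratings cube")
  }
  eff <- effective_ratings(cube)
  n_traits <- dim(eff)[3L]
  present <- apply(!is.na(eff), 1L, sum)
  known_cells <- rowSums(cube$known) * n_traits
  per_judge <- data.frame(
    judge_id = dn$judge,
    n_present = as.integer(present),
    n_excluded_known = as.integer(known_cells),
    n_absent = as.integer(apply(is.na(cube$ratings), 1L, sum)),
    stringsAsFactors = FALSE)
  issues <- character()
  zero_targets <- dimnames(eff)[[2L]][apply(!is.na(eff), 2L, sum) == 0L]
  if (length(zero_targets)) {
    issues <- c(issues, paste0("targets with zero coverage: ",
                               paste(zero_targets, collapse = ", ")))
  }
  empty_judges <- dn$judge[present == 0L]
  if (length(empty_judges)) {
    issues <- c(issues, paste0("judges with no usable ratings: ",
                               paste(empty_judges, collapse = ", ")))
  }
  structure(list(ok = length(empty_judges) == 0L, issues = issues,
                 per_judge = per_judge),
            class = "profacc_validation")
}

#' @export
print.profacc_validation <- function(x, ...) {
  cat("Dataset validation:", if (x$ok) "PASS" else "FAIL", "\n")
  if (length(x$issues)) cat(paste0("  - ", x$issues, collapse = "\n"), "\n")
  cat("  judges:", nrow(x$per_judge),
      "; total present ratings:", sum(x$per_judge$n_present),
      "; acquaintance-excluded cells:", sum(x$per_judge$n_excluded_known),
      "\n")
  invisible(x)
}
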