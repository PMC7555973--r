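#' @export
print.judgment_accuracy <- function(x, digits = 2, ...) {
  cat("Personality judgment accuracy fit\n")
  cat("  ", nrow(x$scores), " judges, ", length(x$traits), " traits, ",
      length(x$modalities), " modalities (min_prop = ",
      x$settings$min_prop, ")\n", sep = "")
  for (idx in index_names()) {
    s <- x$scores[[idx]]
    cat(sprintf("  %-30s M = %s, SD = %s, N = %d\n", idx,
                format(round(mean(s, na.rm = TRUE), digits), nsmall = digits),
                format(round(stats::sd(s, na.rm = TRUE), digits),
                       nsmall = digits),
                sum(!is.na(s))))
  }
  invisible(x)
}

index_names <- function() {
  c("trait_accuracy", "overall_profile_accuracy",
    "distinctive_profile_accuracy")
}

#' Per-judge accuracy scores
#'
#' @param object A [judgment_accuracy()] fit.
#' @param ... Unused.
#' @return A numeric judges x 3 matrix of index totals (back-transformed
#'   correlation metric), rownames = judge ids.
#' @export
coef.judgment_accuracy <- function(object, ...) {
  m <- as.matrix(object$scores[, index_names()])
  rownames(m) <- object$scores$judge_id
  m
}

#' Summarise a judgment-accuracy fit
#'
#' Produces the study-level summary: descriptives and a one-sample t
#' test against zero (the chance level) for each index, trait and
#' modality subscore descriptives with their own chance tests, and —
#' when judge genders are known — the female-vs-male comparison and the
#' same-gender pairing tests (male judges on male targets vs female
#' judges on female targets), all with pooled-variance t tests.
#'
#' @param object A [judgment_accuracy()] fit.
#' @param ... Unused.
#' @return An object of class `summary.judgment_accuracy`.
#' @export
summary.judgment_accuracy <- function(object, ...) {
  totals <- lapply(stats::setNames(nm = index_names()), function(idx)
    t_one_sample(object$scores[[idx]], mu = 0))

  sub_block <- function(m) {
    do.call(rbind, lapply(colnames(m), function(cn) {
      tt <- t_one_sample(m[, cn], mu = 0)
      data.frame(subscore = cn, mean = tt$mean, sd = tt$sd, n = tt$n,
                 t = tt$statistic, df = tt$df, p = tt$p_value,
                 stringsAsFactors = FALSE)
    }))
  }
  trait_tab <- sub_block(object$trait_subscores)
  modality_tab <- do.call(rbind, lapply(names(c(
    trait_accuracy = 1, overall_profile_accuracy = 2,
    distinctive_profile_accuracy = 3)), function(idx) {
      m <- if (idx == "trait_accuracy") object$trait_modality_subscores
      else object$profile_modality_subscores[[
        if (idx == "overall_profile_accuracy") "overall" else "distinctive"]]
      cbind(index = idx, sub_block(m))
    }))

  gender_tests <- NULL
  pairing_means <- NULL
  pairing_tests <- NULL
  jg <- judge_genders(object)
  if (!is.null(jg) && !is.null(object$by_target_gender)) {
    gender_tests <- do.call(rbind, lapply(index_names(), function(idx) {
      tt <- t_pooled(object$scores[[idx]][jg == "female"],
                     object$scores[[idx]][jg == "male"])
      data.frame(index = idx, mean_female = tt$mean_a, mean_male = tt$mean_b,
                 t = tt$statistic, df = tt$df, p = tt$p_value,
                 stringsAsFactors = FALSE)
    }))
    pairing_means <- gender_pairing_means(object)
    pairing_tests <- do.call(rbind, lapply(index_names(), function(idx) {
      mm <- object$by_target_gender$male[jg == "male", idx]
      ff <- object$by_target_gender$female[jg == "female", idx]
      tt <- t_pooled(mm, ff)
      data.frame(index = idx, mean_male_male = tt$mean_a,
                 mean_female_female = tt$mean_b,
                 t = tt$statistic, df = tt$df, p = tt$p_value,
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(totals = totals, trait_tab = trait_tab,
                 modality_tab = modality_tab, gender_tests = gender_tests,
                 pairing_means = pairing_means, pairing_tests = pairing_tests,
                 n_judges = nrow(object$scores),
                 settings = object$settings),
            class = "summary.judgment_accuracy")
}

judge_genders <- function(object) {
  if (is.null(object$judges) || is.null(object$judges$gender)) return(NULL)
  g <- tolower(as.character(object$judges$gender))
  g[match(object$scores$judge_id, object$judges$judge_id)]
}

#' Gender-pairing mean accuracies
#'
#' Means of each index restricted to one target gender, split by judge
#' gender — the four judge-gender x target-gender cells used to probe an
#' own-gender advantage. Distinctive scoring keeps the full-sample
#' normative profiles.
#'
#' @param object A [judgment_accuracy()] fit with judge and target
#'   genders available.
#' @return A data frame with columns `judge_gender`, `target_gender`,
#'   one mean and SD column per index, and `n_judges`.
#' @export
gender_pairing_accuracy <- function(object) {
  stopifnot(inherits(object, "judgment_accuracy"))
  gender_pairing_means(object)
}

gender_pairing_means <- function(object) {
  jg <- judge_genders(object)
  if (is.null(jg) || is.null(object$by_target_gender)) {
    stop("gender pairing requires judge and target gender labels")
  }
  out <- list()
  for (g in c("male", "female")) {
    for (h in names(object$by_target_gender)) {
      m <- object$by_target_gender[[h]][jg == g, , drop = FALSE]
      row <- data.frame(judge_gender = g, target_gender = h,
                        n_judges = nrow(m), stringsAsFactors = FALSE)
      for (idx in index_names()) {
        row[[paste0("mean_", idx)]] <- mean(m[, idx], na.rm = TRUE)
        row[[paste0("sd_", idx)]] <- stats::sd(m[, idx], na.rm = TRUE)
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' @export
print.summary.judgment_accuracy <- function(x, digits = 3, ...) {
  cat("Judgment accuracy summary (", x$n_judges, " judges)\n\n", sep = "")
  cat("Index totals vs chance (one-sample t against 0):\n")
  for (idx in names(x$totals)) {
    tt <- x$totals[[idx]]
    cat(sprintf("  %-30s M = %.2f (SD = %.2f), N = %d, t(%d) = %.3f, p %s\n",
                idx, tt$mean, tt$sd, tt$n, as.integer(tt$df), tt$statistic,
                format_p(tt$p_value)))
  }
  cat("\nTrait subscores (mean, chance test):\n")
  print(round_df(x$trait_tab, digits), row.names = FALSE)
  cat("\nModality subscores:\n")
  print(round_df(x$modality_tab, digits), row.names = FALSE)
  if (!is.null(x$gender_tests)) {
    cat("\nFemale vs male judges (pooled t):\n")
    print(round_df(x$gender_tests, digits), row.names = FALSE)
    cat("\nSame-gender pairing (male-male vs female-female, pooled t):\n")
    print(round_df(x$pairing_tests, digits), row.names = FALSE)
  }
  invisible(x)
}

format_p <- function(p) {
  if (is.na(p)) return("= NA")
  if (p < .001) "< .001" else paste0("= ", format(round(p, 3), nsmall = 3))
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Histogram panel of the three accuracy indices
#'
#' @param x A [judgment_accuracy()] fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.judgment_accuracy <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(old))
  for (idx in index_names()) {
    s <- x$scores[[idx]]
    graphics::hist(s[!is.na(s)], main = idx, xlab = "accuracy (r metric)",
                   col = "grey80", border = "white", ...)
    graphics::abline(v = 0, lty = 2)
  }
  invisible(x)
}
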