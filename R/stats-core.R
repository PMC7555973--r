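#' Pearson correlation on complete pairs
#'
#' Computes the sample Pearson correlation after dropping pairs with a
#' missing element. The correlation is undefined (returned as `NA`) when
#' fewer than 3 complete pairs remain or when either vector is constant;
#' an undefined correlation is never coerced to zero, because downstream
#' aggregation treats it as a missing component.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with elements `r` (the correlation, or `NA_real_` if
#'   undefined) and `n` (number of complete pairs used).
#' @examples
#' cor_pearson(c(1, 2, 4), c(2, 1, 5))
#' cor_pearson(c(2, 2, 2), c(1, 2, 3))  # constant x: undefined
#' @export
cor_pearson <- function(x, y) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same length (", length(x), " vs ",
         length(y), ")")
  }
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3L) {
    return(list(r = NA_real_, n = n))
  }
  x <- x[ok]
  y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(list(r = NA_real_, n = n))
  }
  list(r = stats::cor(x, y), n = n)
}

#' Spearman rank correlation on complete pairs
#'
#' Pearson correlation of mid-ranks (ties receive their average rank),
#' computed on complete pairs. Undefined cases follow [cor_pearson()]:
#' fewer than 3 complete pairs, or all ties in one vector.
#'
#' @inheritParams cor_pearson
#' @return A list with elements `r` and `n` as in [cor_pearson()].
#' @examples
#' cor_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))  # rho = 0.8
#' @export
cor_spearman <- function(x, y) {
  if (length(x) != length(y)) {
    stop("'x' and 'y' must have the same length (", length(x), " vs ",
         length(y), ")")
  }
  ok <- is.finite(x) & is.finite(y)
  rx <- ry <- rep(NA_real_, length(x))
  rx[ok] <- rank(x[ok])
  ry[ok] <- rank(y[ok])
  cor_pearson(rx, ry)
}

#' Fisher z transform and its inverse
#'
#' `fisher_z()` is artanh(r) after clipping `r` into `[-clip, clip]`, so
#' that degenerate correlations of exactly +/-1 map to a large finite z
#' instead of infinity and cannot dominate an average. `fisher_z_inv()`
#' is tanh(z).
#'
#' @param r Numeric vector of correlations, `|r| <= 1`.
#' @param z Numeric vector of z values.
#' @param clip Clipping bound applied to `|r|` before artanh; default 0.999.
#' @return Numeric vector of transformed values. `NA` propagates.
#' @examples
#' fisher_z(0.5)      # 0.5493
#' fisher_z(1)        # artanh(0.999) = 3.8002
#' fisher_z_inv(fisher_z(0.3))
#' @export
fisher_z <- function(r, clip = 0.999) {
  if (any(!is.na(r) & !is.finite(r))) {
    stop("non-finite correlation passed to fisher_z()")
  }
  if (any(abs(r) > 1, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  atanh(pmin(pmax(r, -clip), clip))
}

#' @rdname fisher_z
#' @export
fisher_z_inv <- function(z) {
  if (any(!is.na(z) & !is.finite(z))) {
    stop("non-finite z passed to fisher_z_inv()")
  }
  tanh(z)
}

#' Aggregate correlations on the Fisher z scale with an availability rule
#'
#' Components that are undefined (`NA`) are dropped; if the proportion of
#' available components falls below `min_prop` the aggregate itself is
#' missing. Otherwise the defined correlations are Fisher z transformed,
#' averaged, and back-transformed. With the default `min_prop = 0.8` a
#' 24-cell score needs at least 20 defined cells and a 30-profile score
#' at least 24 defined profiles.
#'
#' @param r Numeric vector of component correlations (`NA` = undefined).
#' @param min_prop Minimum proportion of defined components, in (0, 1].
#' @param clip Clip bound passed to [fisher_z()].
#' @return A list with `mean_z`, `r_back` (= tanh(mean_z)), `n_components`
#'   (total) and `n_available` (defined). `mean_z` and `r_back` are `NA`
#'   when the availability rule fails.
#' @export
aggregate_z <- function(r, min_prop = 0.8, clip = 0.999) {
  if (length(r) == 0L) stop("cannot aggregate an empty component list")
  if (!is.numeric(min_prop) || min_prop <= 0 || min_prop > 1) {
    stop("'min_prop' must lie in (0, 1]")
  }
  n_total <- length(r)
  avail <- !is.na(r)
  n_avail <- sum(avail)
  if (n_avail == 0L || n_avail / n_total < min_prop) {
    return(list(mean_z = NA_real_, r_back = NA_real_,
                n_components = n_total, n_available = n_avail))
  }
  mz <- mean(fisher_z(r[avail], clip = clip))
  list(mean_z = mz, r_back = tanh(mz),
       n_components = n_total, n_available = n_avail)
}

#' Cronbach's alpha
#'
#' Internal-consistency alpha over a units x components matrix, using
#' sample variances and complete-case rows:
#' alpha = k/(k-1) * (1 - sum(var_i) / var(rowsum)).
#'
#' @param items Numeric matrix, rows = units (e.g. judges), columns =
#'   components (e.g. trait-by-modality cells). Rows containing `NA` are
#'   dropped.
#' @return Alpha as a single number, or `NA_real_` when fewer than 2
#'   complete rows remain or the total-score variance is zero. Alpha can
#'   be negative for badly behaved components.
#' @export
cronbach_alpha <- function(items) {
  items <- as.matrix(items)
  if (ncol(items) < 2L) stop("alpha needs at least 2 components")
  cc <- stats::complete.cases(items)
  items <- items[cc, , drop = FALSE]
  if (nrow(items) < 2L) return(NA_real_)
  total_var <- stats::var(rowSums(items))
  if (total_var == 0) return(NA_real_)
  k <- ncol(items)
  item_var <- sum(apply(items, 2L, stats::var))
  k / (k - 1) * (1 - item_var / total_var)
}

#' Correction for attenuation
#'
#' Divides an observed correlation by the square root of the product of
#' the two measures' reliabilities, estimating the correlation between
#' the underlying true scores. The corrected value can exceed 1 in
#' magnitude when the inputs are noisy; it is reported as-is (a warning
#' is raised) rather than truncated.
#'
#' @param r Observed correlation, `|r| <= 1`.
#' @param rel_x,rel_y Reliabilities of the two measures, in (0, 1].
#' @return The disattenuated correlation.
#' @examples
#' disattenuate(0.11, 0.89, 0.17)  # 0.28 at 2 dp
#' @export
disattenuate <- function(r, rel_x, rel_y) {
  if (!is.finite(r) || abs(r) > 1) stop("'r' must be a correlation in [-1, 1]")
  if (!is.finite(rel_x) || rel_x <= 0 || !is.finite(rel_y) || rel_y <= 0) {
    stop("reliabilities must be positive")
  }
  out <- r / sqrt(rel_x * rel_y)
  if (abs(out) > 1) {
    warning("disattenuated correlation exceeds 1 in magnitude (",
            format(round(out, 3)), "); reported as-is")
  }
  out
}

#' One-sample t test against a fixed mean
#'
#' Thin wrapper around [stats::t.test()] returning a flat result and a
#' defined behaviour for degenerate input: with fewer than 2 complete
#' values or zero variance the statistic is `NA` and the result is
#' flagged undefined.
#'
#' @param x Numeric vector of scores; `NA` dropped.
#' @param mu Null-hypothesis mean (default 0).
#' @return A list with `statistic`, `df`, `p_value`, `mean`, `sd`, `n`,
#'   and logical `undefined`.
#' @export
t_one_sample <- function(x, mu = 0) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || stats::sd(x) == 0) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                mean = if (n) mean(x) else NA_real_, sd = NA_real_,
                n = n, undefined = TRUE))
  }
  tt <- stats::t.test(x, mu = mu)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean = mean(x), sd = stats::sd(x),
       n = n, undefined = FALSE)
}

#' Pooled-variance two-sample t test
#'
#' Student's t test with pooled variance (df = n_a + n_b - 2), matching
#' the classical integer-df group comparison. Wraps
#' [stats::t.test()] with `var.equal = TRUE`.
#'
#' @param a,b Numeric vectors for the two groups; `NA` dropped.
#' @return A list as in [t_one_sample()], plus group means `mean_a`,
#'   `mean_b`.
#' @export
t_pooled <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    return(list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
                mean_a = if (length(a)) mean(a) else NA_real_,
                mean_b = if (length(b)) mean(b) else NA_real_,
                undefined = TRUE))
  }
  pooled <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
    (length(a) + length(b) - 2)
  if (pooled == 0) {
    return(list(statistic = NA_real_, df = length(a) + length(b) - 2,
                p_value = NA_real_, mean_a = mean(a), mean_b = mean(b),
                undefined = TRUE))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_a = mean(a), mean_b = mean(b),
       undefined = FALSE)
}
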