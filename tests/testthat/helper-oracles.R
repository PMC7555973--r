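# Independent brute-force oracles: plain loops over the defining sums,
# no calls into the package's computational path.

bf_pearson <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) return(NA_real_)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# mid-ranks by counting smaller and equal elements
bf_rank <- function(x) {
  vapply(seq_along(x), function(i)
    sum(x < x[i]) + (sum(x == x[i]) + 1) / 2, numeric(1))
}

bf_spearman <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  bf_pearson(bf_rank(x[ok]), bf_rank(y[ok]))
}

bf_var <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- 0
  for (i in seq_len(n)) s <- s + (x[i] - m)^2
  s / (n - 1)
}

bf_alpha <- function(m) {
  keep <- apply(m, 1, function(r) all(is.finite(r)))
  m <- m[keep, , drop = FALSE]
  if (nrow(m) < 2) return(NA_real_)
  k <- ncol(m)
  tot <- apply(m, 1, sum)
  vt <- bf_var(tot)
  if (vt == 0) return(NA_real_)
  vi <- 0
  for (j in seq_len(k)) vi <- vi + bf_var(m[, j])
  k / (k - 1) * (1 - vi / vt)
}

bf_fisher_mean <- function(r, min_prop = 0.8, clip = 0.999) {
  total <- length(r)
  r <- r[!is.na(r)]
  if (length(r) == 0 || length(r) / total < min_prop) return(NA_real_)
  z <- 0
  for (v in r) z <- z + atanh(max(min(v, clip), -clip))
  tanh(z / length(r))
}

# brute-force per-judge profile accuracy totals from raw arrays
bf_profile_total <- function(ratings, criteria, mode, min_prop = 0.8) {
  nj <- dim(ratings)[1]; nt <- dim(ratings)[2]; na_ <- dim(ratings)[3]
  if (mode == "distinctive") {
    norm_rating <- numeric(na_)
    norm_crit <- numeric(na_)
    for (a in seq_len(na_)) {
      vals <- as.vector(ratings[, , a])
      norm_rating[a] <- mean(vals[is.finite(vals)])
      norm_crit[a] <- mean(criteria[, a])
    }
  }
  out <- numeric(nj)
  for (j in seq_len(nj)) {
    rs <- rep(NA_real_, nt)
    for (t in seq_len(nt)) {
      x <- ratings[j, t, ]
      y <- criteria[t, ]
      if (mode == "distinctive") {
        x <- x - norm_rating
        y <- y - norm_crit
      }
      rs[t] <- bf_pearson(x, y)
    }
    out[j] <- bf_fisher_mean(rs, min_prop)
  }
  out
}

# brute-force trait accuracy totals (cells over trait x modality)
bf_trait_total <- function(ratings, criteria, modality, min_prop = 0.8) {
  nj <- dim(ratings)[1]; na_ <- dim(ratings)[3]
  mods <- unique(modality)
  out <- numeric(nj)
  for (j in seq_len(nj)) {
    rs <- c()
    for (m in mods) {
      for (a in seq_len(na_)) {
        sel <- which(modality == m)
        rs <- c(rs, bf_pearson(ratings[j, sel, a], criteria[sel, a]))
      }
    }
    out[j] <- bf_fisher_mean(rs, min_prop)
  }
  out
}

# small continuous-valued cube + criteria for oracle comparisons
random_small_study <- function(nj, nt, na_, p_missing = 0.1,
                               modalities = c("m1", "m2")) {
  ratings <- array(round(runif(nj * nt * na_, 1, 5), 2), c(nj, nt, na_),
                   dimnames = list(paste0("J", seq_len(nj)),
                                   paste0("T", seq_len(nt)),
                                   paste0("A", seq_len(na_))))
  ratings[runif(length(ratings)) < p_missing] <- NA
  criteria <- matrix(round(runif(nt * na_, 1, 5), 2), nt, na_,
                     dimnames = dimnames(ratings)[2:3])
  modality <- rep(modalities, length.out = nt)
  list(cube = ratings_cube(ratings, discrete = FALSE),
       crit = criterion_matrix(criteria, modality),
       modality = modality)
}
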