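test_that("Pearson correlation handles complete pairs, missingness and degeneracy", {
  expect_equal(cor_pearson(c(1, 2, 3), c(1, 2, 3))$r, 1)
  cc <- cor_pearson(c(1, 2, 4), c(2, 1, 5))
  expect_equal(cc$r, 0.838627869378, tolerance = 1e-10)
  expect_equal(cc$n, 3L)
  # constant vector: undefined, never zero
  expect_true(is.na(cor_pearson(c(2, 2, 2), c(1, 2, 3))$r))
  # fewer than 3 complete pairs after dropping missing elements
  expect_true(is.na(cor_pearson(c(1, NA, 3, NA), c(1, 2, NA, 4))$r))
  expect_error(cor_pearson(1:3, 1:4), "length")
  # pairs with a missing element are dropped, not imputed
  expect_equal(cor_pearson(c(1, 2, 4, NA), c(2, 1, 5, 3))$r,
               cor_pearson(c(1, 2, 4), c(2, 1, 5))$r)
})

test_that("Pearson correlation is invariant under positive affine transforms", {
  set.seed(11)
  for (i in 1:25) {
    x <- rnorm(8)
    y <- rnorm(8)
    a <- runif(1, 0.1, 5)
    b <- runif(1, -3, 3)
    expect_equal(cor_pearson(a * x + b, y)$r, cor_pearson(x, y)$r,
                 tolerance = 1e-12)
  }
})

test_that("Spearman correlation is the Pearson correlation of mid-ranks", {
  expect_equal(cor_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  # rank invariance under strictly monotone transforms
  x <- c(0.2, 1.5, 3.1, 4.9, 2.2)
  expect_equal(cor_spearman(exp(x), x)$r, 1)
  expect_true(is.na(cor_spearman(c(3, 3, 3, 3), c(1, 2, 3, 4))$r))
  # ties: agrees with the counting-based oracle on random instances
  set.seed(21)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    x <- sample(1:4, n, replace = TRUE)
    y <- sample(1:4, n, replace = TRUE)
    got <- cor_spearman(x, y)$r
    want <- bf_spearman(x, y)
    if (is.na(want)) expect_true(is.na(got)) else
      expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("Fisher transform matches closed forms and clips degenerate correlations", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306144334, tolerance = 1e-10)
  expect_equal(fisher_z(1), atanh(0.999))
  expect_equal(fisher_z(1), 3.80020116725, tolerance = 1e-9)
  expect_equal(fisher_z(-1), -atanh(0.999))
  expect_error(fisher_z(1.2), "\\[-1, 1\\]")
  # round trip to 1e-12 inside the clip region
  r <- seq(-0.999, 0.999, length.out = 101)
  expect_equal(fisher_z_inv(fisher_z(r)), r, tolerance = 1e-12)
})

test_that("z aggregation enforces the availability proportion", {
  a <- aggregate_z(rep(0.3, 3))
  expect_equal(a$mean_z, atanh(0.3))
  expect_equal(a$r_back, 0.3)
  # 19 of 24 defined: below the 80% rule, aggregate is missing
  a <- aggregate_z(c(rep(0.2, 19), rep(NA, 5)))
  expect_true(is.na(a$r_back))
  expect_equal(a$n_available, 19L)
  # 24 of 30 defined: exactly 80%, aggregate is defined
  a <- aggregate_z(c(rep(0.2, 24), rep(NA, 6)))
  expect_false(is.na(a$r_back))
  expect_equal(a$n_components, 30L)
  expect_error(aggregate_z(numeric(0)), "empty")
  expect_error(aggregate_z(0.5, min_prop = 0), "min_prop")
})

test_that("Cronbach's alpha matches the variance-decomposition formula", {
  # perfectly parallel items
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(1, 2, 3))), 1)
  # hand computation: item vars 1 and 1, total var 4
  expect_equal(cronbach_alpha(cbind(c(1, 2, 3), c(1, 2, 3))),
               2 * (1 - 2 / 4))
  # k parallel duplicates of any column give alpha 1
  set.seed(31)
  col <- rnorm(20)
  for (k in c(2, 5, 9)) {
    expect_equal(cronbach_alpha(matrix(col, 20, k)), 1, tolerance = 1e-12)
  }
  # independent noise columns: expectation 0 at large n
  m <- matrix(rnorm(4000 * 2), 4000, 2)
  expect_lt(abs(cronbach_alpha(m)), 0.12)
  # degenerate cases
  expect_true(is.na(cronbach_alpha(matrix(c(1, NA, 2, 3), 2, 2))))
  expect_true(is.na(cronbach_alpha(cbind(c(1, 2), c(2, 1)))))  # zero total var
  expect_error(cronbach_alpha(matrix(1:5, 5, 1)), "2 components")
})

test_that("attenuation correction applies the reliability product rule", {
  expect_equal(round(disattenuate(0.11, 0.89, 0.17), 2), 0.28)
  expect_equal(disattenuate(0.3, 1, 1), 0.3)
  expect_equal(disattenuate(0.2, 0.25, 1), 0.4)
  expect_error(disattenuate(0.5, 0, 0.8), "positive")
  expect_warning(out <- disattenuate(0.9, 0.5, 0.5), "exceeds 1")
  expect_equal(out, 1.8)
  # monotone decreasing in each reliability for positive r
  rels <- seq(0.4, 1, by = 0.1)
  vals <- vapply(rels, function(x) disattenuate(0.4, x, 0.7), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("t tests match hand-computed statistics and flag degenerate input", {
  tt <- t_one_sample(c(-0.1, 0.1))
  expect_equal(tt$statistic, 0)
  tt <- t_one_sample(c(0.1, 0.2, 0.3))
  expect_equal(tt$statistic, 3.46410161514, tolerance = 1e-10)
  expect_equal(tt$df, 2)
  expect_true(t_one_sample(c(2, 2, 2))$undefined)

  tt <- t_pooled(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$statistic, 0)
  tt <- t_pooled(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$statistic, -1.22474487139, tolerance = 1e-10)
  expect_equal(tt$df, 4)
  expect_true(t_pooled(c(1, 1), c(1, 1))$undefined)
})

test_that("pooled t under a Gaussian null rejects at close to the nominal rate", {
  set.seed(41)
  reps <- 600
  rej <- 0
  for (i in seq_len(reps)) {
    p <- t_pooled(rnorm(47), rnorm(74))$p_value
    if (p < 0.05) rej <- rej + 1
  }
  # binomial 99% band around 0.05 for 600 replicates is roughly +/- 0.023
  expect_gt(rej / reps, 0.05 - 0.025)
  expect_lt(rej / reps, 0.05 + 0.025)
})
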