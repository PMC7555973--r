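# continuous-valued deterministic cube: 2 judges x 6 targets x 4 traits
fixed_study <- function() {
  set.seed(99)
  random_small_study(nj = 4, nt = 6, na_ = 4, p_missing = 0)
}

test_that("cell correlations recover perfect, degenerate and hand-checked cases", {
  st <- fixed_study()
  # judge 1 rates exactly the criteria on trait 1
  arr <- st$cube$ratings
  arr[1, , 1] <- st$crit$criteria[, 1]
  # judge 2 rates a constant in modality m1 on trait 2
  arr[2, st$modality == "m1", 2] <- 3
  cube <- ratings_cube(arr, discrete = FALSE)
  cells <- cell_correlations(cube, st$crit)
  expect_equal(unname(cells$r[1, 1, c("m1", "m2")]), c(1, 1))
  expect_true(is.na(cells$r[2, 2, "m1"]))
  expect_false(is.na(cells$r[2, 2, "m2"]))

  # 3-target modality with hand-computed correlation
  arr2 <- array(NA_real_, c(1, 3, 1),
                dimnames = list("J1", paste0("T", 1:3), "a"))
  arr2[1, , 1] <- c(1, 2, 4)
  crit2 <- criterion_matrix(matrix(c(2, 1, 5), 3, 1,
                                   dimnames = list(paste0("T", 1:3), "a")),
                            modality = rep("m1", 3))
  c2 <- cell_correlations(ratings_cube(arr2, discrete = FALSE), crit2)
  expect_equal(unname(c2$r[1, 1, 1]), 0.838627869378, tolerance = 1e-10)
})

test_that("normative profiles are grand means over present ratings and all targets", {
  arr <- array(NA_real_, c(2, 2, 1),
               dimnames = list(c("J1", "J2"), c("T1", "T2"), "a"))
  arr[1, , 1] <- c(1, 3)
  arr[2, , 1] <- c(2, 4)
  crit <- criterion_matrix(matrix(c(2, 4), 2, 1,
                                  dimnames = list(c("T1", "T2"), "a")),
                           modality = c("m1", "m1"))
  np <- normative_profiles(ratings_cube(arr), crit)
  expect_equal(unname(np$rating), 2.5)
  expect_equal(unname(np$criterion), 3)
  # single judge, single target: normative rating equals that rating
  np1 <- normative_profiles(
    ratings_cube(array(4, c(1, 1, 1),
                       dimnames = list("J1", "T1", "a"))),
    criterion_matrix(matrix(3, 1, 1, dimnames = list("T1", "a")),
                     modality = "m1"))
  expect_equal(unname(np1$rating), 4)
})

test_that("profile correlations hit the clip ceiling, zero-variance and short-profile rules", {
  st <- fixed_study()
  # ratings identical to criteria: every profile r = 1, total = clip bound
  arr <- st$cube$ratings
  for (j in 1:4) arr[j, , ] <- st$crit$criteria
  cube <- ratings_cube(arr, discrete = FALSE)
  fit <- judgment_accuracy(cube, st$crit)
  expect_equal(fit$scores$overall_profile_accuracy, rep(0.999, 4))

  # when every judge assigns the same trait profile to every target, the
  # normative rating profile equals that profile and all distinctive
  # rating profiles are zero vectors: every distinctive correlation is
  # undefined and the distinctive total goes missing (overall stays
  # defined because the shared profile is non-constant)
  arr2 <- st$cube$ratings
  prof <- c(2, 3, 4, 3)
  for (j in 1:4) for (t in 1:6) arr2[j, t, ] <- prof
  fit2 <- judgment_accuracy(ratings_cube(arr2, discrete = FALSE), st$crit)
  expect_true(all(is.na(fit2$scores$distinctive_profile_accuracy)))
  expect_true(all(!is.na(fit2$scores$overall_profile_accuracy)))

  # profiles with fewer than 3 trait pairs are undefined
  st2 <- local({set.seed(4); random_small_study(3, 4, 2, p_missing = 0)})
  pc2 <- profile_correlations(st2$cube, st2$crit, mode = "overall")
  expect_true(all(is.na(pc2$r)))
})

test_that("distinctive equals overall when both normative profiles are zero", {
  set.seed(17)
  arr <- array(rnorm(5 * 6 * 4), c(5, 6, 4),
               dimnames = list(paste0("J", 1:5), paste0("T", 1:6),
                               paste0("A", 1:4)))
  # centre ratings per trait so the normative rating profile is exactly zero
  for (a in 1:4) arr[, , a] <- arr[, , a] - mean(arr[, , a])
  crit_m <- matrix(rnorm(6 * 4), 6, 4, dimnames = dimnames(arr)[2:3])
  crit_m <- sweep(crit_m, 2, colMeans(crit_m))
  cube <- ratings_cube(arr, scale_min = -10, scale_max = 10, discrete = FALSE)
  crit <- criterion_matrix(crit_m, modality = rep(c("m1", "m2"), 3),
                           scale_min = -10, scale_max = 10)
  ov <- profile_correlations(cube, crit, mode = "overall")
  di <- profile_correlations(cube, crit, mode = "distinctive")
  expect_equal(di$r, ov$r, tolerance = 1e-12)
})

test_that("trait and overall accuracy are affine-invariant in one judge's ratings", {
  st <- fixed_study()
  fit <- judgment_accuracy(st$cube, st$crit)
  arr <- st$cube$ratings
  arr[2, , ] <- 0.5 * arr[2, , ] + 1  # stays within the scale
  fit2 <- judgment_accuracy(ratings_cube(arr, discrete = FALSE), st$crit)
  expect_equal(fit2$scores$trait_accuracy[2], fit$scores$trait_accuracy[2],
               tolerance = 1e-12)
  expect_equal(fit2$scores$overall_profile_accuracy[2],
               fit$scores$overall_profile_accuracy[2], tolerance = 1e-12)
  # other judges' scores on judge-local indices are untouched
  expect_equal(fit2$scores$trait_accuracy[-2], fit$scores$trait_accuracy[-2],
               tolerance = 1e-12)
})

test_that("every aggregate matches the brute-force reimplementation on random cubes", {
  set.seed(23)
  for (i in 1:20) {
    st <- random_small_study(nj = sample(3:6, 1), nt = sample(4:8, 1),
                             na_ = sample(3:6, 1), p_missing = 0.15)
    fit <- judgment_accuracy(st$cube, st$crit, min_prop = 0.5)
    eff <- effective_ratings(st$cube)
    expect_equal(fit$scores$trait_accuracy,
                 bf_trait_total(eff, st$crit$criteria, st$modality,
                                min_prop = 0.5), tolerance = 1e-10)
    expect_equal(fit$scores$overall_profile_accuracy,
                 bf_profile_total(eff, st$crit$criteria, "overall",
                                  min_prop = 0.5), tolerance = 1e-10)
    expect_equal(fit$scores$distinctive_profile_accuracy,
                 bf_profile_total(eff, st$crit$criteria, "distinctive",
                                  min_prop = 0.5), tolerance = 1e-10)
  }
})

test_that("shuffling criterion-target links drives all indices to chance", {
  cfg <- sim_config(n_judges = 120, seed = 61)
  st <- simulate_study(cfg)
  perm <- local({set.seed(62); sample(nrow(st$crit$criteria))})
  shuffled <- criterion_matrix(
    matrix(st$crit$criteria[perm, ], nrow(st$crit$criteria),
           ncol(st$crit$criteria),
           dimnames = dimnames(st$crit$criteria)),
    modality = st$crit$modality, gender = st$crit$gender)
  fit <- judgment_accuracy(st$cube, shuffled, st$judges)
  for (idx in c("trait_accuracy", "overall_profile_accuracy",
                "distinctive_profile_accuracy")) {
    s <- fit$scores[[idx]]
    mc_se <- sd(s, na.rm = TRUE) / sqrt(sum(!is.na(s)))
    if (idx == "overall_profile_accuracy") {
      # overall accuracy keeps its normative component under shuffling:
      # only the distinctive part is destroyed, so just check it dropped
      expect_lt(mean(s, na.rm = TRUE), 0.25)
    } else {
      expect_lt(abs(mean(s, na.rm = TRUE)), 3 * mc_se + 0.01)
    }
  }
})

test_that("gender pairing restricted to all targets equals the unrestricted score", {
  set.seed(77)
  st <- random_small_study(nj = 4, nt = 6, na_ = 5, p_missing = 0)
  crit <- criterion_matrix(st$crit$criteria, modality = st$modality,
                           gender = rep("female", 6))
  judges <- data.frame(judge_id = paste0("J", 1:4),
                       gender = c("male", "female", "male", "female"))
  fit <- judgment_accuracy(st$cube, crit, judges)
  expect_equal(unname(fit$by_target_gender$female[, "trait_accuracy"]),
               fit$scores$trait_accuracy, tolerance = 1e-12)
  expect_equal(unname(fit$by_target_gender$female[, "overall_profile_accuracy"]),
               fit$scores$overall_profile_accuracy, tolerance = 1e-12)
  pm <- gender_pairing_accuracy(fit)
  expect_equal(nrow(pm), 2)  # two judge genders x one target gender
})
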