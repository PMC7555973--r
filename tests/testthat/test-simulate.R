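test_that("the simulator is seed-deterministic with independent substreams", {
  cfg <- sim_config(n_judges = 15, seed = 101)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$cube$ratings, b$cube$ratings)
  expect_identical(a$theta, b$theta)
  expect_identical(a$delta, b$delta)
  c <- simulate_study(sim_config(n_judges = 15, seed = 102))
  expect_false(identical(a$delta, c$delta))
  # growing the judge sample leaves the target draws untouched
  big <- simulate_study(sim_config(n_judges = 60, seed = 101))
  expect_identical(big$delta, a$delta)
  expect_identical(big$crit$criteria, a$crit$criteria)
})

test_that("target generation honours the design blocks and sigma_distinctive", {
  cfg <- sim_config(seed = 7)
  tg <- generate_targets(cfg)
  tab <- table(tg$crit$modality, tg$crit$gender)
  expect_true(all(tab == 5))  # 5 male + 5 female per modality
  # sigma 0: all targets share the normative profile exactly
  tg0 <- generate_targets(sim_config(sigma_distinctive = 0, seed = 7))
  expect_equal(unname(tg0$crit$criteria),
               matrix(rep(unname(tg0$crit$criteria[1, ]), each = 30), 30, 8),
               tolerance = 1e-12)
  # large sample: per-trait criterion SD tracks sigma before clipping
  cfg_big <- sim_config(n_targets = 3000, sigma_distinctive = 0.4, seed = 8)
  tgb <- generate_targets(cfg_big)
  expect_equal(mean(apply(tgb$delta, 2, sd)), 0.4, tolerance = 0.05)
})

test_that("judge generation links ability to ERA and centres ERA at 50", {
  cfg <- sim_config(seed = 9)
  jd <- generate_judges(cfg)
  expect_equal(nrow(jd$judges), 121)
  expect_equal(sum(jd$judges$gender == "female"), round(0.61 * 121))
  expect_lt(abs(mean(jd$judges$era) - 50), 4)
  expect_true(all(jd$theta >= 0 & jd$theta <= 1))
  # noise-free monotone link: rank correlation 1
  jd2 <- generate_judges(sim_config(era_noise_sd = 0, seed = 9))
  expect_equal(cor_spearman(jd2$theta, jd2$judges$era)$r, 1)
  # no gender gap: same law (checked as a mean difference bound)
  jd3 <- generate_judges(sim_config(n_judges = 4000, gender_gap = 0,
                                    seed = 10))
  gap <- mean(jd3$theta[jd3$judges$gender == "female"]) -
    mean(jd3$theta[jd3$judges$gender == "male"])
  expect_lt(abs(gap), 0.01)
})

test_that("ratings carry the constructed signal and acquaintance rate", {
  # full ability, no noise, no rounding, unit multipliers, small deltas:
  # ratings reproduce the criteria exactly
  cfg <- sim_config(theta_mean = 1, theta_sd = 0, noise_sd = 0,
                    discretize = FALSE, sigma_distinctive = 0.25,
                    gender_gap = 0,
                    modality_multipliers = c(photo = 1, mute_video = 1,
                                             audio_video = 1),
                    p_known = 0, seed = 11)
  st <- simulate_study(cfg)
  expect_equal(unname(st$cube$ratings[1, , ]), unname(st$crit$criteria),
               tolerance = 1e-12)
  # acquaintance flags: ~34 expected over 10 studies of 121 x 30 pairs
  flags <- vapply(1:10, function(s)
    sum(simulate_study(sim_config(seed = 200 + s))$cube$known), numeric(1))
  expect_gt(mean(flags), 22)
  expect_lt(mean(flags), 46)
  # default study passes validation
  st2 <- simulate_study(sim_config(seed = 12))
  expect_true(validate_dataset(st2$cube, st2$crit, st2$judges)$ok)
})

test_that("study CSVs round-trip through the readers", {
  st <- simulate_study(sim_config(n_judges = 8, seed = 14))
  dir <- tempfile()
  write_study_csvs(st, dir)
  cube <- read_ratings_csv(file.path(dir, "ratings.csv"))
  crit <- read_criteria_csv(file.path(dir, "criteria.csv"),
                            file.path(dir, "targets.csv"))
  judges <- read_judges_csv(file.path(dir, "judges.csv"))
  expect_equal(cube$ratings[dimnames(st$cube$ratings)[[1]],
                            dimnames(st$cube$ratings)[[2]],
                            dimnames(st$cube$ratings)[[3]]],
               st$cube$ratings)
  expect_equal(crit$criteria[rownames(st$crit$criteria),
                             colnames(st$crit$criteria)],
               st$crit$criteria, tolerance = 1e-9)
  expect_identical(judges$judge_id, st$judges$judge_id)
  # identical seed => identical bytes
  st_b <- simulate_study(sim_config(n_judges = 8, seed = 14))
  dir_b <- tempfile()
  write_study_csvs(st_b, dir_b)
  expect_identical(readLines(file.path(dir, "ratings.csv")),
                   readLines(file.path(dir_b, "ratings.csv")))
})

test_that("increasing distinctive signal never decreases median trait accuracy", {
  meds <- vapply(c(0.3, 0.8, 1.4), function(sg) {
    m <- vapply(1:3, function(s) {
      st <- simulate_study(sim_config(n_judges = 40, sigma_distinctive = sg,
                                      seed = 300 + s))
      fit <- judgment_accuracy(st$cube, st$crit)
      median(fit$scores$trait_accuracy, na.rm = TRUE)
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(meds) > -0.01))
})

test_that("photo modality yields the lowest subscores under the default multipliers", {
  st <- simulate_study(sim_config(seed = 20))
  fit <- judgment_accuracy(st$cube, st$crit, st$judges)
  mod_means <- colMeans(fit$trait_modality_subscores, na.rm = TRUE)
  expect_lt(mod_means["photo"], mod_means["mute_video"])
  expect_lt(mod_means["photo"], mod_means["audio_video"])
})
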