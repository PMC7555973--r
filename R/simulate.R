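default_traits <- function(n_traits) {
  base <- c("openness", "conscientiousness", "extraversion", "agreeableness",
            "neuroticism", "empathy", "cooperativeness", "intelligence")
  if (n_traits <= length(base)) base[seq_len(n_traits)]
  else c(base, paste0("trait", seq_len(n_traits - length(base))))
}

# Mean criterion profile on the 1-5 scale: mildly socially desirable
# average person (agreeable/cooperative above midpoint, neuroticism below),
# spread chosen so overall profile accuracy sits moderately above the
# distinctive index, as typical for first-impression designs.
default_normative <- function(traits) {
  base <- c(openness = 3.50, conscientiousness = 3.45, extraversion = 3.30,
            agreeableness = 3.55, neuroticism = 2.95, empathy = 3.50,
            cooperativeness = 3.60, intelligence = 3.35)
  out <- base[traits]
  miss <- is.na(out)
  if (any(miss)) out[miss] <- 3
  names(out) <- traits
  out
}

#' Configuration for the study simulator
#'
#' Collects every parameter of the generative model in one validated
#' list. The defaults emulate the classic design this package scores:
#' 121 judges, 30 targets in three presentation modalities of 10 (photo,
#' mute video, audio video; 5 male and 5 female targets each), 8 traits
#' rated on a 1-5 Likert scale, and a rare acquaintance-driven
#' missingness rate of 34/3630 judge-target pairs.
#'
#' The generative model: each target's criterion is a shared normative
#' trait profile plus a target-specific distinctive deviation
#' `delta ~ N(0, sigma_distinctive^2)` (clipped to the scale). A judge
#' with latent ability `theta in [0, 1]` produces
#' `rating = normative + w * m * delta + noise`, where
#' `w = normative_bias_weight + (1 - normative_bias_weight) * theta`
#' scales how much distinctive signal the judge picks up and `m` is the
#' modality's signal multiplier; ratings are clipped to the scale and,
#' by default, rounded to the Likert grid. Female judges get a `+
#' gender_gap` shift in ability; ERA test scores are a noisy linear
#' image of ability centred on 50.
#'
#' Default signal levels (`theta_mean = 0.06`, `theta_sd = 0.12`,
#' `sigma_distinctive = 0.8`, `noise_sd = 0.9`, multipliers 0.5/1.0/1.1)
#' are calibrated so the three index totals land in the .05-.15 range
#' typical of first-impression accuracy studies while judge ability
#' remains recoverable from the scores.
#'
#' @param n_judges,n_targets,n_traits Design sizes.
#' @param modalities Character vector of modality labels; `n_targets`
#'   must divide evenly into them.
#' @param traits Trait labels (default: the 8 classic dimensions).
#' @param normative_criterion Named per-trait mean criterion profile on
#'   the rating scale.
#' @param sigma_distinctive SD of target-specific trait deviations.
#' @param theta_mean,theta_sd Judge ability distribution (clipped to
#'   `[0, 1]`).
#' @param gender_gap Ability shift added for female judges.
#' @param p_female Proportion of female judges (exact count).
#' @param modality_multipliers Named per-modality distinctive-signal
#'   multipliers.
#' @param normative_bias_weight Floor of the distinctive-signal weight
#'   `w`; 0 means `w = theta` and a zero-ability judge emits pure
#'   normative ratings.
#' @param noise_sd SD of the Gaussian rating noise.
#' @param discretize Round ratings to the Likert grid (default `TRUE`).
#' @param p_known Probability a (judge, target) pair is flagged
#'   acquainted (default 34/3630).
#' @param era_slope,era_noise_sd Link from ability to the ERA
#'   (percent-correct) score.
#' @param steu_mean,steu_sd,teique_mean,teique_sd Distributions of the
#'   unrelated external scores.
#' @param seed Integer seed; mandatory.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_judges = 121, n_targets = 30, n_traits = 8,
                       modalities = c("photo", "mute_video", "audio_video"),
                       traits = default_traits(n_traits),
                       normative_criterion = default_normative(traits),
                       sigma_distinctive = 0.8,
                       theta_mean = 0.06, theta_sd = 0.12,
                       gender_gap = 0.05, p_female = 0.61,
                       modality_multipliers = c(photo = 0.5, mute_video = 1.0,
                                                audio_video = 1.1),
                       normative_bias_weight = 0,
                       noise_sd = 0.9, discretize = TRUE,
                       p_known = 34 / 3630,
                       era_slope = 100, era_noise_sd = 8,
                       steu_mean = 15.7, steu_sd = 3.5,
                       teique_mean = 150, teique_sd = 19,
                       seed) {
  if (missing(seed) || !is.numeric(seed)) stop("'seed' is required")
  if (n_targets %% length(modalities) != 0L) {
    stop("'n_targets' must divide evenly across modalities")
  }
  if (length(traits) != n_traits) stop("'traits' must have n_traits labels")
  if (length(normative_criterion) != n_traits) {
    stop("'normative_criterion' must have one value per trait")
  }
  if (any(normative_criterion < 1 | normative_criterion > 5)) {
    stop("'normative_criterion' must lie on the 1-5 scale")
  }
  for (nm in c("sigma_distinctive", "theta_sd", "noise_sd", "era_noise_sd")) {
    if (get(nm) < 0) stop("'", nm, "' must be >= 0")
  }
  if (any(modality_multipliers < 0)) stop("multipliers must be >= 0")
  if (!setequal(names(modality_multipliers), modalities)) {
    stop("'modality_multipliers' must be named by the modalities")
  }
  for (nm in c("p_known", "p_female")) {
    if (get(nm) < 0 || get(nm) > 1) stop("'", nm, "' must lie in [0, 1]")
  }
  if (normative_bias_weight < 0 || normative_bias_weight > 1) {
    stop("'normative_bias_weight' must lie in [0, 1]")
  }
  names(normative_criterion) <- traits
  structure(list(
    n_judges = as.integer(n_judges), n_targets = as.integer(n_targets),
    n_traits = as.integer(n_traits), modalities = modalities,
    traits = traits, normative_criterion = normative_criterion,
    sigma_distinctive = sigma_distinctive, theta_mean = theta_mean,
    theta_sd = theta_sd, gender_gap = gender_gap, p_female = p_female,
    modality_multipliers = modality_multipliers[modalities],
    normative_bias_weight = normative_bias_weight, noise_sd = noise_sd,
    discretize = discretize, p_known = p_known, era_slope = era_slope,
    era_noise_sd = era_noise_sd, steu_mean = steu_mean, steu_sd = steu_sd,
    teique_mean = teique_mean, teique_sd = teique_sd,
    seed = as.integer(seed)), class = "sim_config")
}

#' Null (chance-level) simulator configuration
#'
#' Convenience wrapper for a configuration in which every accuracy index
#' has expectation zero: zero judge ability, zero ability spread, zero
#' weight floor, no gender gap, and a flat normative criterion profile.
#' The flat profile matters for overall profile accuracy — with a
#' non-constant normative profile, ratings and criteria agree across
#' traits through the average person alone, so overall accuracy stays
#' positive even for zero-ability judges. Distinctive and trait accuracy
#' are nulled by the ability settings alone.
#'
#' @param ... Passed to [sim_config()].
#' @param flat Constant normative criterion level (default 3, the scale
#'   midpoint).
#' @export
null_config <- function(..., flat = 3) {
  args <- list(...)
  n_traits <- if (!is.null(args$n_traits)) args$n_traits
  else if (!is.null(args$traits)) length(args$traits) else 8
  args$theta_mean <- 0
  args$theta_sd <- 0
  args$gender_gap <- 0
  args$normative_bias_weight <- 0
  if (is.null(args$normative_criterion)) {
    args$normative_criterion <- rep(flat, n_traits)
  }
  do.call(sim_config, args)
}

# Independent substreams per generator: adding judges must not perturb
# the target draws. Sub-seeds derived once from the global seed.
sub_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, 3L),
                  c("targets", "judges", "ratings"))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate targets: criteria, modality/gender blocks and latent deviations
#'
#' Criterion = clip(normative + delta, 1, 5) with
#' `delta ~ N(0, sigma_distinctive^2)`. Targets are assigned to
#' modalities in consecutive blocks, with genders balanced within each
#' block (5 male + 5 female per block of 10 under the defaults).
#'
#' @param cfg A [sim_config()].
#' @return A list with `crit` (a [criterion_matrix()]) and `delta`
#'   (targets x traits latent deviation matrix).
#' @export
generate_targets <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seeds(cfg$seed)[["targets"]], {
    ids <- sprintf("T%02d", seq_len(cfg$n_targets))
    delta <- matrix(stats::rnorm(cfg$n_targets * cfg$n_traits,
                                 sd = cfg$sigma_distinctive),
                    cfg$n_targets, cfg$n_traits,
                    dimnames = list(ids, cfg$traits))
    criteria <- pmin(pmax(sweep(delta, 2L, cfg$normative_criterion, "+"),
                          1), 5)
    per_mod <- cfg$n_targets / length(cfg$modalities)
    modality <- rep(cfg$modalities, each = per_mod)
    gender <- rep(rep(c("male", "female"), length.out = per_mod),
                  times = length(cfg$modalities))
    list(crit = criterion_matrix(criteria, modality, gender), delta = delta)
  })
}

#' Generate judges: gender, latent ability and external test scores
#'
#' Ability `theta` is Gaussian with a `gender_gap` shift for female
#' judges, clipped to `[0, 1]`. The ERA score is
#' `50 + era_slope * (theta - mean(theta)) + noise`, clipped to
#' `[0, 100]`; STEU and TEIQue scores are drawn independently of ability
#' (they are unrelated in the emulated design).
#'
#' @param cfg A [sim_config()].
#' @return A list with `judges` (data frame: judge_id, gender, era,
#'   steu, teique) and `theta` (named latent ability vector).
#' @export
generate_judges <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seeds(cfg$seed)[["judges"]], {
    n <- cfg$n_judges
    ids <- sprintf("J%03d", seq_len(n))
    n_female <- round(cfg$p_female * n)
    gender <- sample(rep(c("female", "male"), c(n_female, n - n_female)))
    theta <- stats::rnorm(n, cfg$theta_mean +
                            cfg$gender_gap * (gender == "female"),
                          cfg$theta_sd)
    theta <- pmin(pmax(theta, 0), 1)
    names(theta) <- ids
    era <- 50 + cfg$era_slope * (theta - mean(theta)) +
      stats::rnorm(n, sd = cfg$era_noise_sd)
    era <- pmin(pmax(era, 0), 100)
    steu <- pmin(pmax(round(stats::rnorm(n, cfg$steu_mean, cfg$steu_sd)),
                      0), 25)
    teique <- round(stats::rnorm(n, cfg$teique_mean, cfg$teique_sd))
    list(judges = data.frame(judge_id = ids, gender = gender, era = era,
                             steu = steu, teique = teique,
                             stringsAsFactors = FALSE),
         theta = theta)
  })
}

#' Generate the ratings cube from targets and judges
#'
#' `rating(j, t, a) = normative(a) + w_j * m(t) * delta(t, a) + noise`,
#' with `w_j = normative_bias_weight + (1 - normative_bias_weight) *
#' theta_j` and `m(t)` the target's modality multiplier. Values are
#' clipped to the 1-5 scale after noise and then (if `discretize`)
#' rounded to the Likert grid. Each (judge, target) pair is flagged
#' acquainted with probability `p_known`.
#'
#' @param cfg A [sim_config()].
#' @param targets Output of [generate_targets()].
#' @param judges Output of [generate_judges()].
#' @return A [ratings_cube()].
#' @export
generate_ratings <- function(cfg, targets, judges) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(sub_seeds(cfg$seed)[["ratings"]], {
    theta <- judges$theta
    w <- cfg$normative_bias_weight + (1 - cfg$normative_bias_weight) * theta
    m <- cfg$modality_multipliers[targets$crit$modality]
    jn <- names(theta)
    tn <- rownames(targets$delta)
    an <- cfg$traits
    raw <- array(rep(cfg$normative_criterion,
                     each = length(jn) * length(tn)),
                 c(length(jn), length(tn), length(an)),
                 dimnames = list(judge = jn, target = tn, trait = an))
    # distinctive pickup: outer over judges of the modality-scaled deltas
    signal <- array(0, dim(raw))
    for (a in seq_along(an)) {
      signal[, , a] <- outer(w, m * targets$delta[, a])
    }
    eps <- array(stats::rnorm(length(raw), sd = cfg$noise_sd), dim(raw))
    raw <- pmin(pmax(raw + signal + eps, 1), 5)
    if (cfg$discretize) raw <- pmin(pmax(round(raw), 1), 5)
    known <- matrix(stats::runif(length(jn) * length(tn)) < cfg$p_known,
                    length(jn), length(tn), dimnames = list(jn, tn))
    ratings_cube(raw, known, discrete = cfg$discretize)
  })
}

#' Simulate a complete study
#'
#' Composes [generate_targets()], [generate_judges()] and
#' [generate_ratings()] under independent sub-streams of one global
#' seed: the same seed yields a bit-identical study, and growing the
#' judge sample never perturbs the target draws.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `simulated_study` with observable parts
#'   `cube`, `crit`, `judges` and latent truth `theta` (judge ability)
#'   and `delta` (target deviations) for recovery checks. The latent
#'   parts are never used by any scoring operation.
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  targets <- generate_targets(cfg)
  judges <- generate_judges(cfg)
  cube <- generate_ratings(cfg, targets, judges)
  structure(list(cube = cube, crit = targets$crit, judges = judges$judges,
                 theta = judges$theta, delta = targets$delta, config = cfg),
            class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat("Simulated judgment study (seed ", x$config$seed, ")\n", sep = "")
  print(x$cube)
  print(x$crit)
  invisible(x)
}

#' Write a simulated study to CSV files
#'
#' Writes `ratings.csv`, `criteria.csv`, `targets.csv`, `judges.csv`
#' (the four analysis inputs) plus `latent_judges.csv` and
#' `latent_targets.csv` holding the simulation truth for recovery
#' checks.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_csvs <- function(study, dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ratings_csv(study$cube, file.path(dir, "ratings.csv"))
  crit <- study$crit
  vals <- data.frame(
    target_id = rep(rownames(crit$criteria), ncol(crit$criteria)),
    trait = rep(colnames(crit$criteria), each = nrow(crit$criteria)),
    raw_value = as.vector(crit$criteria), stringsAsFactors = FALSE)
  utils::write.csv(vals, file.path(dir, "criteria.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(target_id = rownames(crit$criteria),
                              modality = crit$modality,
                              gender = crit$gender),
                   file.path(dir, "targets.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(study$judges, file.path(dir, "judges.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(judge_id = names(study$theta),
                              theta = unname(study$theta)),
                   file.path(dir, "latent_judges.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(data.frame(
    target_id = rep(rownames(study$delta), ncol(study$delta)),
    trait = rep(colnames(study$delta), each = nrow(study$delta)),
    delta = as.vector(study$delta)),
    file.path(dir, "latent_targets.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
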