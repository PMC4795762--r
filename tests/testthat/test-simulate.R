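test_that("movement probability equals the closed-form logistic", {
  flat <- movement_params(alpha = 0, beta_c = 0, beta_s = 0, beta_r = 0)
  male <- list(colour_score = 6, length_mm = 24)
  grp <- list(mean_colour = 6, mean_length = 24, sex_ratio = 1)
  expect_equal(move_probability(male, grp, flat), 0.5)

  # a = 1 from a unit colour deficit
  p1 <- move_probability(list(colour_score = 5, length_mm = 24), grp,
                         movement_params(0, 1, 0, 0))
  expect_equal(p1, exp(1) / (1 + exp(1)), tolerance = 1e-12)

  # strong setting: 0.5 colour-units below the group mean, at the mean
  # length, sex ratio 1 -> a = 20*0.5 + 1 = 11
  p11 <- move_probability(list(colour_score = 5.5, length_mm = 24), grp,
                          movement_params(0, 20, 20, 1))
  expect_equal(p11, plogis(11), tolerance = 1e-12)

  # 20 random parameter/state combinations against stats::plogis
  set.seed(14)
  for (i in 1:20) {
    prm <- movement_params(rnorm(1), rnorm(1, 0, 10), rnorm(1, 0, 10),
                           rnorm(1))
    m <- list(colour_score = rnorm(1, 6, 3), length_mm = rnorm(1, 24, 2))
    g <- list(mean_colour = rnorm(1, 6, 3),
              mean_length = rnorm(1, 24, 2),
              sex_ratio = runif(1, 0.2, 5))
    a <- prm$alpha + prm$beta_c * (g$mean_colour - m$colour_score) +
      prm$beta_s * (g$mean_length - m$length_mm) +
      prm$beta_r * g$sex_ratio
    expect_equal(move_probability(m, g, prm), plogis(a),
                 tolerance = 1e-12)
  }
})

test_that("movement probability is numerically stable and bounded", {
  grp <- list(mean_colour = 1e4, mean_length = 24, sex_ratio = 1)
  p_hi <- move_probability(list(colour_score = 0, length_mm = 24), grp,
                           movement_params(0, 20, 0, 0))
  expect_equal(p_hi, 1)
  p_lo <- move_probability(list(colour_score = 2e4, length_mm = 24),
                           grp, movement_params(0, 20, 0, 0))
  expect_equal(p_lo, 0)
  expect_false(any(is.nan(c(p_hi, p_lo))))
  expect_error(group_state(data.frame(colour_score = 1,
                                      length_mm = 2), 0),
               "no females")
})

test_that("movement probability is monotone in each relative deficit", {
  set.seed(20)
  for (i in 1:25) {
    prm <- movement_params(rnorm(1), runif(1, 0.1, 5),
                           runif(1, 0.1, 5), runif(1, 0.1, 2))
    g <- list(mean_colour = rnorm(1, 6, 2), mean_length = rnorm(1, 24, 2),
              sex_ratio = runif(1, 0.5, 3))
    m <- list(colour_score = g$mean_colour - runif(1, 0, 2),
              length_mm = g$mean_length - runif(1, 0, 2))
    base <- move_probability(m, g, prm)
    duller <- m; duller$colour_score <- m$colour_score - 0.5
    smaller <- m; smaller$length_mm <- m$length_mm - 0.5
    g_biased <- g; g_biased$sex_ratio <- g$sex_ratio + 1
    expect_gt(move_probability(duller, g, prm), base)
    expect_gt(move_probability(smaller, g, prm), base)
    expect_gt(move_probability(m, g_biased, prm), base)
  }
})

test_that("a saturated-negative intercept freezes the population", {
  cfg <- population_config(n_groups = 8, n_males = 30, n_steps = 15,
                           movement = movement_params(-30, 0, 0, 0),
                           seed = 4)
  sim <- run_simulation(cfg)
  expect_false(any(sim$events$moved))
  expect_equal(length(unique(sim$var_colour)), 1L)
  expect_equal(length(unique(sim$var_length)), 1L)
})

test_that("steps conserve males and never move a male onto his own group", {
  cfg <- population_config(n_groups = 10, n_males = 60, n_steps = 20,
                           movement = movement_params(0, 2, 2, 1),
                           seed = 9)
  sim <- run_simulation(cfg)
  moved <- sim$events[sim$events$moved, ]
  expect_gt(nrow(moved), 0)
  expect_true(all(moved$to_group != moved$from_group))
  expect_true(all(moved$to_group >= 1 & moved$to_group <= 10))
  st <- sim$final_state
  expect_length(st$group, 60)
  expect_true(all(st$group >= 1 & st$group <= 10))
  expect_identical(sort(st$male_id), sort(sim$phenotypes$male_id))
  # each step performs exactly n_males selections
  expect_equal(as.integer(table(sim$events$step)), rep(60L, 20))
})

test_that("neutral parameters give a one-half per-selection move rate", {
  cfg <- population_config(n_groups = 15, n_males = 200, n_steps = 60,
                           movement = movement_params(0, 0, 0, 0),
                           seed = 12)
  sim <- run_simulation(cfg)
  expect_gte(nrow(sim$events), 1e4)
  expect_equal(mean(sim$events$moved), 0.5, tolerance = 0.02 / 0.5)
  expect_true(all(sim$events$p_move == 0.5))
})

test_that("strong phenotype-dependent rules make dull and small males the movers", {
  sim <- run_simulation(population_config(seed = 31))
  pm <- tapply(sim$events$p_move, sim$events$male_id, mean)
  idx <- match(names(pm), sim$phenotypes$male_id)
  expect_lt(cor(sim$phenotypes$colour_score[idx], pm,
                method = "spearman"), 0)
  expect_lt(cor(sim$phenotypes$length_mm[idx], pm,
                method = "spearman"), 0)
})

test_that("simulation runs are reproducible and record full trajectories", {
  cfg <- population_config(n_groups = 12, n_males = 40, n_steps = 25,
                           seed = 77)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$var_colour, b$var_colour)
  expect_identical(a$events, b$events)
  expect_length(a$var_colour, 25)
  expect_length(a$var_length, 25)
  expect_true(all(a$var_colour >= 0, na.rm = TRUE))
})

test_that("sex-ratio-only movement produces a trend-free variance trajectory", {
  neutral <- movement_params(alpha = 0, beta_c = 0, beta_s = 0,
                             beta_r = 1)
  covered <- 0L
  for (s in 1:3) {
    sim <- run_simulation(population_config(movement = neutral,
                                            record_events = FALSE,
                                            seed = 100 + s))
    tr <- variance_trend(sim$var_colour)
    if (abs(as.numeric(tr)) < 1.96 * attr(tr, "se"))
      covered <- covered + 1L
  }
  expect_gte(covered, 2L)
})

test_that("steps where no group holds two males yield missing variances", {
  cfg <- population_config(n_groups = 5, n_males = 1, n_steps = 4,
                           movement = movement_params(0, 0, 0, 1),
                           seed = 2)
  sim <- run_simulation(cfg)
  expect_true(all(is.na(sim$var_colour)))
  expect_equal(sim$n_degenerate_steps, 4L)
})
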