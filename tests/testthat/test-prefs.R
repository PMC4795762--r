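test_that("treatment classification applies the 1 mm and 0.01 thresholds", {
  mk <- function(dl, dc) list(
    a = list(length_mm = 25 + dl, colour_score = 0.06 + dc),
    b = list(length_mm = 25, colour_score = 0.06))
  # field-typical treatment 1 pair: differs in both traits
  p <- mk(2.57, 0.038)
  expect_identical(classify_treatment(p$a, p$b), "treatment_1")
  # length-matched, colour-different
  p <- mk(0.10, 0.056)
  expect_identical(classify_treatment(p$a, p$b), "treatment_2")
  # colour-matched, length-different
  p <- mk(1.81, 0.003)
  expect_identical(classify_treatment(p$a, p$b), "treatment_3")
  # similar in both -> unclassified
  p <- mk(0.5, 0.005)
  expect_identical(classify_treatment(p$a, p$b), "unclassified")
  # boundary values count as similar (length difference of exactly 1 mm)
  p <- mk(1.0, 0.005)
  expect_identical(classify_treatment(p$a, p$b), "unclassified")
  # colour boundary with an exactly representable threshold
  expect_identical(
    classify_treatment(list(length_mm = 27, colour_score = 0.5078125),
                       list(length_mm = 25, colour_score = 0.5),
                       colour_threshold = 0.0078125),
    "treatment_3")

  a <- data.frame(length_mm = c(27, 25.1), colour_score = c(0.10, 0.10))
  b <- data.frame(length_mm = c(25, 25.0), colour_score = c(0.06, 0.06))
  expect_identical(classify_treatment(a, b),
                   c("treatment_1", "treatment_2"))
})

test_that("arcsine-square-root transform hits its closed-form anchors", {
  expect_identical(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2, tolerance = 1e-15)
  expect_equal(arcsine_sqrt(0.5), pi / 4, tolerance = 1e-15)
  expect_equal(arcsine_sqrt(0.25), pi / 6, tolerance = 1e-15)
  expect_error(arcsine_sqrt(-0.1), "\\[0, 1\\]")
  expect_error(arcsine_sqrt(1.1), "\\[0, 1\\]")

  p <- seq(0, 1, length.out = 201)
  y <- arcsine_sqrt(p)
  expect_true(all(diff(y) > 0))
  expect_equal(sin(y)^2, p, tolerance = 1e-12)
})

test_that("one-sample t matches hand computation and the reference implementation", {
  centred <- one_sample_t(c(0.4, 0.5, 0.6), 0.5)
  expect_equal(centred$statistic, 0)
  expect_equal(centred$p_value, 1)

  hand <- one_sample_t(1:5, 0)
  expect_equal(hand$statistic, 3 / (sqrt(2.5) / sqrt(5)),
               tolerance = 1e-12)
  expect_identical(hand$df, 4L)

  set.seed(42)
  for (i in 1:100) {
    x <- rnorm(sample(3:40, 1), rnorm(1), runif(1, 0.5, 3))
    mu <- rnorm(1)
    mine <- one_sample_t(x, mu)
    ref <- t.test(x, mu = mu)
    expect_equal(mine$statistic, unname(ref$statistic),
                 tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    expect_equal(mine$df, unname(ref$parameter))
  }

  expect_error(one_sample_t(3), "at least two")
  expect_error(one_sample_t(c(2, 2, 2), 0), "zero variance")
})

test_that("paired t is the one-sample t of differences", {
  hand <- paired_t(c(0, 1, 2), c(0, 0, 0))
  expect_equal(hand$statistic, 1 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_identical(hand$df, 2L)

  expect_error(paired_t(1:3, 1:3), "zero variance")
  expect_error(paired_t(1:3, 1:4), "equal length")

  set.seed(43)
  for (i in 1:100) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- paired_t(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic),
                 tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("association proportions condition on sampling both shoals", {
  expect_equal(association_proportion(300, 100), 0.75)
  expect_true(is.na(association_proportion(0, 500)))
  expect_true(is.na(association_proportion(500, 0)))
  expect_equal(association_proportion(300, 100, total_time = 900,
                                      basis = "total"), 1 / 3)
  expect_error(association_proportion(-1, 5), "non-negative")
  expect_error(association_proportion(600, 400, total_time = 900,
                                      basis = "total"), "exceed")
})

test_that("preference model recovers a noiseless planted effect exactly", {
  set.seed(5)
  n <- 40
  dl <- runif(n, -3, 3)
  dc <- runif(n, -0.05, 0.05)
  eta <- 0.6 + 0.04 * dl  # response linear in delta_length only
  tr <- data.frame(delta_length = dl, delta_colour = dc,
                   prop_less = sin(eta)^2)
  pm <- preference_model(tr, "exp1")
  expect_equal(unname(coef(pm)["delta_length"]), 0.04,
               tolerance = 1e-8)
  expect_equal(unname(coef(pm)["(Intercept)"]), 0.6, tolerance = 1e-8)
  expect_lt(sum(residuals(pm)^2), 1e-16)
  # no residual variation to test terms against
  expect_true(all(is.na(pm$anova$F)))
})

test_that("type-II F-tests agree with explicit nested-model comparisons", {
  set.seed(6)
  n <- 60
  tr <- data.frame(delta_length = rnorm(n, 1.5, 1),
                   delta_colour = rnorm(n, 0.03, 0.02),
                   prop_less = pmin(pmax(rnorm(n, 0.5, 0.1), 0.01),
                                    0.99))
  pm <- preference_model(tr, "exp1")
  y <- arcsine_sqrt(tr$prop_less)
  rss <- function(f) sum(resid(lm(f, data = tr))^2)
  full <- rss(y ~ delta_length * delta_colour)
  mains <- rss(y ~ delta_length + delta_colour)
  scale <- full / (n - 4)
  expect_equal(pm$anova$F,
               c((rss(y ~ delta_colour) - mains) / scale,
                 (rss(y ~ delta_length) - mains) / scale,
                 (mains - full) / scale),
               tolerance = 1e-9)

  # exp2 additive design: type II is drop-one
  tr2 <- data.frame(focal_colour = rnorm(n, 0.06, 0.02),
                    focal_length = rnorm(n, 25, 1.5),
                    delta_mean_colour = rnorm(n, 0.03, 0.02),
                    delta_mean_length = rnorm(n, 1.5, 1),
                    prop_less = pmin(pmax(rnorm(n, 0.5, 0.1), 0.01),
                                     0.99))
  pm2 <- preference_model(tr2, "exp2")
  y2 <- arcsine_sqrt(tr2$prop_less)
  rss2 <- function(f) sum(resid(lm(f, data = tr2))^2)
  full2 <- rss2(y2 ~ focal_colour + focal_length + delta_mean_colour +
                  delta_mean_length)
  scale2 <- full2 / (n - 5)
  drops <- c(
    rss2(y2 ~ focal_length + delta_mean_colour + delta_mean_length),
    rss2(y2 ~ focal_colour + delta_mean_colour + delta_mean_length),
    rss2(y2 ~ focal_colour + focal_length + delta_mean_length),
    rss2(y2 ~ focal_colour + focal_length + delta_mean_colour))
  expect_equal(pm2$anova$F, (drops - full2) / scale2, tolerance = 1e-9)
})

test_that("preference model rejects degenerate designs and tiny samples", {
  tr <- data.frame(delta_length = 1:6, delta_colour = (1:6) / 100,
                   prop_less = runif(6, 0.3, 0.7))
  small <- tr[1:4, ]
  expect_error(preference_model(small, "exp1"), "too few")
  coll <- data.frame(delta_length = rep(1, 10),
                     delta_colour = rep(0.02, 10),
                     prop_less = runif(10, 0.3, 0.7))
  expect_error(preference_model(coll, "exp1"), "collinear|rank")
  expect_error(preference_model(data.frame(prop_less = runif(10)),
                                "exp1"), "missing covariate")
})

test_that("planted regression slopes are covered by their confidence intervals", {
  # known slope on the transformed scale; 95% CIs should cover it at
  # close to the nominal rate
  set.seed(8)
  hits <- 0L
  reps <- 200L
  for (r in seq_len(reps)) {
    n <- 200
    dl <- rnorm(n, 1.5, 1)
    dc <- rnorm(n, 0.03, 0.02)
    eta <- 0.65 + 2.5 * dc + rnorm(n, 0, 0.12)
    tr <- data.frame(delta_length = dl, delta_colour = dc,
                     prop_less = pmin(pmax(sin(eta)^2, 1e-6), 1 - 1e-6))
    fit <- preference_model(tr, "exp1")$fit
    ci <- confint(fit)["delta_colour", ]
    if (ci[1] <= 2.5 && 2.5 <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})
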