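#' Classify a stimulus-male pair into a choice-experiment treatment
#'
#' Two stimulus males are deemed similar in body length when their total
#' lengths differ by at most 1 mm, and similar in coloration when their
#' colour scores (proportions) differ by at most 0.01. Pairs differing in
#' both traits are Treatment 1, length-similar but colour-different pairs
#' Treatment 2, colour-similar but length-different pairs Treatment 3;
#' pairs similar in both are unclassified.
#'
#' @param male_a,male_b lists or data frames with `length_mm` and
#'   `colour_score` (vectorized over rows when data frames of equal
#'   height are given).
#' @param length_threshold similarity threshold for length, mm.
#' @param colour_threshold similarity threshold for colour score.
#' @return Character vector of labels `"treatment_1"`, `"treatment_2"`,
#'   `"treatment_3"` or `"unclassified"`.
#' @examples
#' classify_treatment(list(length_mm = 25.0, colour_score = 0.060),
#'                    list(length_mm = 22.4, colour_score = 0.022))
#' @export
classify_treatment <- function(male_a, male_b, length_threshold = 1,
                               colour_threshold = 0.01) {
  dl <- abs(male_a$length_mm - male_b$length_mm)
  dc <- abs(male_a$colour_score - male_b$colour_score)
  if (length(dl) != length(dc) || any(!is.finite(dl)) ||
      any(!is.finite(dc)))
    stop("both males need finite 'length_mm' and 'colour_score'")
  len_sim <- dl <= length_threshold
  col_sim <- dc <= colour_threshold
  ifelse(!len_sim & !col_sim, "treatment_1",
         ifelse(len_sim & !col_sim, "treatment_2",
                ifelse(col_sim & !len_sim, "treatment_3",
                       "unclassified")))
}

#' Arcsine-square-root transform of a proportion
#'
#' `asin(sqrt(p))`, the classical variance-stabilizing transform applied
#' to association-time proportions before t-tests and regressions.
#' Strictly increasing on `[0, 1]`, mapping 0 to 0, 0.5 to pi/4 and 1 to
#' pi/2.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @return Transformed value(s) in radians.
#' @export
arcsine_sqrt <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1]")
  asin(sqrt(p))
}

#' One-sample t-test against a fixed null value
#'
#' `t = (mean - null) / (sd / sqrt(n))` on `n - 1` degrees of freedom,
#' two-sided. Used to compare (transformed) association-time proportions
#' against the chance expectation of 0.50 (pi/4 on the transformed
#' scale).
#'
#' @param values numeric sample (n >= 2, positive variance, no missing
#'   values).
#' @param null_value the hypothesized mean.
#' @return An object of class `ff_ttest`: list with `statistic`, `df`,
#'   `p_value`, `estimate`, `null_value`, `method`.
#' @examples
#' one_sample_t(c(0.4, 0.5, 0.6), 0.5)
#' @export
one_sample_t <- function(values, null_value = 0) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("missing values in sample")
  n <- length(values)
  if (n < 2L) stop("need at least two observations")
  s <- sd(values)
  if (s == 0) stop("degenerate sample: zero variance")
  if (!is.finite(null_value)) stop("'null_value' must be finite")
  m <- mean(values)
  tstat <- (m - null_value) / (s / sqrt(n))
  df <- n - 1L
  structure(list(statistic = tstat, df = df,
                 p_value = 2 * pt(-abs(tstat), df),
                 estimate = m, null_value = null_value,
                 method = "one-sample t-test"),
            class = "ff_ttest")
}

#' Paired t-test
#'
#' One-sample t-test of the pairwise differences `x - y` against 0.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return An `ff_ttest` object.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length")
  out <- one_sample_t(x - y, 0)
  out$method <- "paired t-test"
  out$estimate <- mean(x - y)
  out
}

#' @export
print.ff_ttest <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  t = %.4f, df = %d, two-sided p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  estimate = %.4f (null = %g)\n", x$estimate,
              x$null_value))
  invisible(x)
}

#' Association-time proportion for a dichotomous choice
#'
#' Proportion of association time spent near the less attractive shoal.
#' The default `"zone"` basis conditions on time in the two preference
#' zones, `time_less / (time_less + time_more)`, which makes 0.50 the
#' chance value for a two-zone choice; the `"total"` basis divides by the
#' full trial duration instead. Trials in which the focal male did not
#' sample both stimulus shoals (either zone time is 0) are not
#' analyzable and yield `NA`.
#'
#' @param time_less,time_more seconds near the less/more attractive
#'   shoal (non-negative, vectorized).
#' @param total_time trial duration in seconds (required for the
#'   `"total"` basis).
#' @param basis `"zone"` or `"total"`.
#' @return Numeric proportions, `NA` for non-analyzable trials.
#' @export
association_proportion <- function(time_less, time_more,
                                   total_time = NULL,
                                   basis = c("zone", "total")) {
  basis <- match.arg(basis)
  if (any(time_less < 0, na.rm = TRUE) ||
      any(time_more < 0, na.rm = TRUE))
    stop("association times must be non-negative")
  sampled_both <- time_less > 0 & time_more > 0
  out <- if (basis == "zone") {
    time_less / (time_less + time_more)
  } else {
    if (is.null(total_time))
      stop("'total_time' is required for the \"total\" basis")
    if (any(time_less + time_more > total_time, na.rm = TRUE))
      stop("zone times exceed 'total_time'")
    time_less / total_time
  }
  out[!sampled_both] <- NA_real_
  out
}

#' Linear model of choice strength on phenotype covariates
#'
#' Least-squares fit of the (arcsine-square-root transformed) proportion
#' of association time near the less attractive shoal on phenotype
#' covariates, with type-II F-tests per term. The `"exp1"` design
#' regresses on the stimulus-pair differences in body length and colour
#' score and their interaction (`delta_length * delta_colour`); the
#' `"exp2"` design on the focal male's colour and length plus the
#' differences in stimulus-shoal mean colour and mean length
#' (`focal_colour + focal_length + delta_mean_colour +
#' delta_mean_length`).
#'
#' @param trials data frame with either a `prop_less` column or
#'   `time_less`/`time_more` (from which the zone-basis proportion is
#'   computed), plus the design's covariate columns. Non-analyzable
#'   trials (`NA` proportion) are dropped.
#' @param design `"exp1"` or `"exp2"`.
#' @param transform apply [arcsine_sqrt()] to the proportion (default
#'   `TRUE`).
#' @return An object of class `preference_model`: list with `fit` (the
#'   `lm` object), `anova` (data frame `term`, `df`, `F`, `p`),
#'   `design`, `n`.
#' @export
preference_model <- function(trials, design = c("exp1", "exp2"),
                             transform = TRUE) {
  design <- match.arg(design)
  if (!"prop_less" %in% names(trials)) {
    if (!all(c("time_less", "time_more") %in% names(trials)))
      stop("'trials' needs 'prop_less' or 'time_less'/'time_more'")
    trials$prop_less <- association_proportion(trials$time_less,
                                               trials$time_more)
  }
  covs <- switch(design,
                 exp1 = c("delta_length", "delta_colour"),
                 exp2 = c("focal_colour", "focal_length",
                          "delta_mean_colour", "delta_mean_length"))
  miss <- setdiff(covs, names(trials))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  dat <- trials[c("prop_less", covs)]
  dat <- dat[complete.cases(dat), , drop = FALSE]
  dat$.y <- if (transform) arcsine_sqrt(dat$prop_less) else
    dat$prop_less
  form <- if (design == "exp1")
    .y ~ delta_length * delta_colour
  else
    .y ~ focal_colour + focal_length + delta_mean_colour +
      delta_mean_length
  p <- if (design == "exp1") 4L else 5L  # including intercept
  if (nrow(dat) < p + 2L)
    stop("too few analyzable trials (", nrow(dat), ") for ", p - 1L,
         " predictors")
  fit <- lm(form, data = dat)
  if (fit$rank < p)
    stop("collinear design: model matrix is rank deficient")
  rss <- sum(residuals(fit)^2)
  tss <- sum((dat$.y - mean(dat$.y))^2)
  if (rss > .Machine$double.eps^0.75 * max(tss, 1)) {
    a2 <- car::Anova(fit, type = 2)
    keep <- rownames(a2) != "Residuals"
    tab <- data.frame(term = rownames(a2)[keep],
                      df = a2$Df[keep],
                      F = a2$`F value`[keep],
                      p = a2$`Pr(>F)`[keep],
                      stringsAsFactors = FALSE)
  } else {
    # perfect fit: F statistics are undefined against a zero residual
    terms_lab <- attr(fit$terms, "term.labels")
    tab <- data.frame(term = terms_lab, df = 1L, F = NA_real_,
                      p = NA_real_, stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  structure(list(fit = fit, anova = tab, design = design,
                 n = nrow(dat), transform = transform),
            class = "preference_model")
}

#' @export
print.preference_model <- function(x, ...) {
  cat("Preference linear model (", x$design, " design, n = ", x$n,
      if (x$transform) ", arcsine-sqrt response" else "", ")\n",
      sep = "")
  cat("Coefficients:\n")
  print(coef(x$fit))
  cat("\nType-II F-tests:\n")
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' @export
coef.preference_model <- function(object, ...) coef(object$fit)

#' @export
summary.preference_model <- function(object, ...) summary(object$fit)

#' @export
residuals.preference_model <- function(object, ...)
  residuals(object$fit)

#' @export
predict.preference_model <- function(object, ...)
  predict(object$fit, ...)
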