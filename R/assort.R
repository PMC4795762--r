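#' Pooled within-group variance of a male trait
#'
#' The assortment statistic: the within-group mean square of a standard
#' one-way ANOVA, `SSW / sum(n_g - 1)`, where `SSW` sums squared
#' deviations of each male's trait from his shoal mean. Shoals with a
#' single male contribute nothing to either numerator or denominator.
#' Low values relative to chance indicate positive assortment (groupmates
#' similar), high values negative assortment.
#'
#' @param data a [shoal_data] object, or a data frame with `shoal_id` and
#'   the trait column (`length_mm` or `colour_score`).
#' @param trait `"length"` or `"colour"`.
#' @return The pooled within-group variance (trait units squared).
#' @examples
#' df <- data.frame(shoal_id = c(1, 1, 2, 2), length_mm = c(1, 3, 2, 4))
#' within_group_variance(df, "length")  # 2
#' @export
within_group_variance <- function(data, trait = c("length", "colour")) {
  trait <- match.arg(trait)
  tg <- .pooled_trait(data, trait)
  .msw(tg$x, tg$g)
}

# within-group mean square; error when pooled df is zero
.msw <- function(x, g) {
  m <- ave(x, g)
  df <- length(x) - length(unique(g))
  if (df == 0L)
    stop("within-group degrees of freedom are zero ",
         "(every group holds a single male)")
  sum((x - m)^2) / df
}

# as .msw but NA instead of an error (simulator steps may degenerate)
.msw_or_na <- function(x, g) {
  df <- length(x) - length(unique(g))
  if (df == 0L) return(NA_real_)
  m <- ave(x, g)
  sum((x - m)^2) / df
}

#' Membership-conserving randomization null for the assortment statistic
#'
#' Builds the Monte Carlo null distribution of [within_group_variance()]:
#' each iteration shuffles the pooled male trait values uniformly at
#' random into shoals of exactly the observed sizes (group count and
#' membership sizes are conserved) and records the within-group mean
#' square.
#'
#' @inheritParams within_group_variance
#' @param n_iterations number of random reassignments (default 10000).
#' @param seed optional integer seed.
#' @param .validate when `TRUE`, assert per iteration that the shuffle
#'   conserved the pooled trait multiset and the group-size vector
#'   (slower; for testing).
#' @return Numeric vector of `n_iterations` null variance values.
#' @export
randomize_groups <- function(data, trait = c("length", "colour"),
                             n_iterations = 10000, seed = NULL,
                             .validate = FALSE) {
  trait <- match.arg(trait)
  if (length(n_iterations) != 1L || !is.finite(n_iterations) ||
      n_iterations < 1)
    stop("'n_iterations' must be a positive count")
  n_iterations <- as.integer(n_iterations)
  tg <- .pooled_trait(data, trait)
  x <- tg$x
  g <- tg$g
  n <- length(x)
  df <- n - length(unique(g))
  if (df == 0L)
    stop("within-group degrees of freedom are zero ",
         "(every group holds a single male)")
  if (!is.null(seed)) set.seed(seed)

  # SSW = sum(x^2) - sum_g S_g^2 / n_g; sum(x^2) is shuffle-invariant
  cnt <- as.vector(rowsum(rep(1L, n), g, reorder = FALSE))
  sumsq <- sum(x^2)
  sorted_x <- sort(x)
  out <- numeric(n_iterations)
  for (b in seq_len(n_iterations)) {
    xp <- x[sample.int(n)]
    if (.validate) {
      stopifnot(identical(sort(xp), sorted_x),
                identical(as.vector(rowsum(rep(1L, n), g,
                                           reorder = FALSE)), cnt))
    }
    s <- rowsum(xp, g, reorder = FALSE)
    out[b] <- (sumsq - sum(s * s / cnt)) / df
  }
  out
}

#' Two-tailed percentile decision for the assortment test
#'
#' Locates the observed within-group variance in its randomization null
#' and applies the two-tailed 2.5% rule: an observed value in the lower
#' tail means males are more similar within groups than chance (positive
#' assortment), in the upper tail more dissimilar (negative assortment).
#' The percentile rank uses the add-one convention
#' `(#null <= observed + 1) / (n + 1)`, with ties counted toward the
#' lower tail.
#'
#' @param observed observed within-group variance.
#' @param null_values numeric vector of null variances, as from
#'   [randomize_groups()].
#' @param alpha_tail one-sided tail probability (default 0.025, i.e. a
#'   5% two-tailed test).
#' @return An object of class `assortment_test` with elements
#'   `observed_statistic`, `null_values`, `percentile_rank`, `decision`
#'   (`"positive_assortment"`, `"negative_assortment"` or `"random"`),
#'   `empirical_p`, `alpha_tail`, `n_iterations`.
#' @export
assortment_test <- function(observed, null_values, alpha_tail = 0.025) {
  if (length(null_values) == 0L)
    stop("empty null distribution")
  if (length(observed) != 1L || !is.finite(observed))
    stop("'observed' must be a single finite number")
  if (!is.finite(alpha_tail) || alpha_tail <= 0 || alpha_tail >= 0.5)
    stop("'alpha_tail' must lie in (0, 0.5)")
  n <- length(null_values)
  r <- sum(null_values <= observed)
  rank <- (r + 1) / (n + 1)
  decision <- if (rank <= alpha_tail) "positive_assortment"
              else if (rank >= 1 - alpha_tail) "negative_assortment"
              else "random"
  structure(list(observed_statistic = observed,
                 null_values = null_values,
                 percentile_rank = rank,
                 decision = decision,
                 empirical_p = min(1, 2 * min(rank, 1 - rank)),
                 alpha_tail = alpha_tail,
                 n_iterations = n),
            class = "assortment_test")
}

#' Full randomization test of phenotypic assortment
#'
#' Convenience pipeline: computes the observed [within_group_variance()],
#' simulates its membership-conserving null with [randomize_groups()],
#' and applies the percentile decision of [assortment_test()].
#'
#' @inheritParams randomize_groups
#' @inheritParams assortment_test
#' @return An `assortment_test` object, with `trait` and `seed` recorded.
#' @examples
#' ph <- sample_male_phenotypes(24, seed = 1)
#' st <- sample_shoal_structure(8, c(3, 3), c(2, 2), seed = 2)
#' obs <- assign_males_to_shoals(ph, st, assortment = 1, trait = "length",
#'                               seed = 3)
#' assortment_randomization(obs, "length", n_iterations = 999, seed = 4)
#' @export
assortment_randomization <- function(data, trait = c("length", "colour"),
                                     n_iterations = 10000,
                                     alpha_tail = 0.025, seed = NULL) {
  trait <- match.arg(trait)
  observed <- within_group_variance(data, trait)
  null_values <- randomize_groups(data, trait, n_iterations, seed = seed)
  out <- assortment_test(observed, null_values, alpha_tail)
  out$trait <- trait
  out$seed <- seed
  out
}

#' @export
print.assortment_test <- function(x, ...) {
  cat("Membership-conserving randomization test of phenotypic assortment\n")
  if (!is.null(x$trait)) cat("  trait:", x$trait, "\n")
  cat(sprintf("  observed within-group variance: %g\n",
              x$observed_statistic))
  cat(sprintf("  null: %d iterations, mean %g [%g, %g]\n",
              x$n_iterations, mean(x$null_values),
              quantile(x$null_values, x$alpha_tail),
              quantile(x$null_values, 1 - x$alpha_tail)))
  cat(sprintf("  percentile rank: %.4f  empirical p: %.4f\n",
              x$percentile_rank, x$empirical_p))
  cat("  decision:", x$decision, "\n")
  invisible(x)
}

#' @export
summary.assortment_test <- function(object, ...) print(object, ...)

#' Histogram of the randomization null with the observed statistic
#'
#' @param x an `assortment_test` object.
#' @param ... passed to [graphics::hist()].
#' @export
plot.assortment_test <- function(x, ...) {
  h <- hist(x$null_values, breaks = 40, plot = FALSE)
  lo <- quantile(x$null_values, x$alpha_tail)
  hi <- quantile(x$null_values, 1 - x$alpha_tail)
  cols <- ifelse(h$mids <= lo | h$mids >= hi, "grey40", "grey85")
  plot(h, col = cols, border = "white",
       main = "Randomization null of within-group variance",
       xlab = paste0("within-group variance",
                     if (!is.null(x$trait)) paste0(" (", x$trait, ")")),
       ...)
  abline(v = x$observed_statistic, lwd = 2)
  mtext(sprintf("observed = %.4g (%s)", x$observed_statistic, x$decision),
        side = 3, line = 0, cex = 0.8)
  invisible(x)
}
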