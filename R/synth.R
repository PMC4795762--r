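#' Bivariate phenotype distribution
#'
#' Parameters of the joint (bivariate normal) distribution of male colour
#' score and body length from which synthetic phenotypes are drawn. The
#' defaults are the simulation model's scale: mean colour 6 (sd 3), mean
#' length 24 mm (sd 1.5), trait correlation 0.15. Field colour scores are
#' proportions of lateral body area (~0.06), a different scale; the scale
#' in use is carried as metadata and never silently converted (see
#' [field_phenotype_distribution()]).
#'
#' @param mean_colour,sd_colour mean and standard deviation of the colour
#'   score (model scale by default).
#' @param mean_length,sd_length mean and standard deviation of total body
#'   length, in mm.
#' @param rho correlation between colour and length, in `[-1, 1]`.
#' @param scale `"model"` or `"proportion"`: which colour-score scale the
#'   parameters are on.
#' @return An object of class `phenotype_distribution`.
#' @export
phenotype_distribution <- function(mean_colour = 6, sd_colour = 3,
                                   mean_length = 24, sd_length = 1.5,
                                   rho = 0.15,
                                   scale = c("model", "proportion")) {
  scale <- match.arg(scale)
  vals <- c(mean_colour, sd_colour, mean_length, sd_length, rho)
  if (!all(is.finite(vals)))
    stop("distribution parameters must be finite numbers")
  if (sd_colour < 0 || sd_length < 0)
    stop("standard deviations must be non-negative")
  if (abs(rho) > 1)
    stop("'rho' must lie in [-1, 1]")
  structure(list(mean_colour = mean_colour, sd_colour = sd_colour,
                 mean_length = mean_length, sd_length = sd_length,
                 rho = rho, scale = scale),
            class = "phenotype_distribution")
}

#' Field-scale phenotype distribution
#'
#' Convenience parameterization on the field scale, where colour is a
#' proportion of lateral body area: mean colour 0.062 (sd 0.027), mean
#' length 24.8 mm (sd 1.33), correlation 0.152. Standard deviations are
#' reconstructed from the field standard errors over 177 males.
#'
#' @return A `phenotype_distribution` with `scale = "proportion"`.
#' @export
field_phenotype_distribution <- function() {
  phenotype_distribution(mean_colour = 0.062, sd_colour = 0.027,
                         mean_length = 24.8, sd_length = 1.33,
                         rho = 0.152, scale = "proportion")
}

#' @export
print.phenotype_distribution <- function(x, ...) {
  cat(sprintf("Bivariate phenotype distribution (%s colour scale)\n",
              x$scale))
  cat(sprintf("  colour: mean %g, sd %g\n", x$mean_colour, x$sd_colour))
  cat(sprintf("  length: mean %g mm, sd %g mm\n", x$mean_length,
              x$sd_length))
  cat(sprintf("  correlation: %g\n", x$rho))
  invisible(x)
}

#' Draw male phenotypes from a bivariate normal
#'
#' Samples `n` (colour, length) pairs jointly from the configured
#' bivariate normal. Negative draws are clipped at 0 (traits are
#' non-negative); the number of clipped values is recorded in the
#' `n_clipped` attribute and is negligible under the default parameters.
#'
#' @param n number of males (>= 1).
#' @param dist a [phenotype_distribution()].
#' @param seed optional integer; when given, makes the draw reproducible.
#' @return Data frame with columns `male_id`, `length_mm`, `colour_score`
#'   and attributes `colour_scale` and `n_clipped`.
#' @examples
#' ph <- sample_male_phenotypes(170, phenotype_distribution(), seed = 1)
#' colMeans(ph[c("length_mm", "colour_score")])
#' @export
sample_male_phenotypes <- function(n, dist = phenotype_distribution(),
                                   seed = NULL) {
  if (!inherits(dist, "phenotype_distribution"))
    stop("'dist' must be a phenotype_distribution object")
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("'n' must be a positive count")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  Sigma <- matrix(c(dist$sd_colour^2,
                    dist$rho * dist$sd_colour * dist$sd_length,
                    dist$rho * dist$sd_colour * dist$sd_length,
                    dist$sd_length^2), 2L, 2L)
  xy <- MASS::mvrnorm(n, mu = c(dist$mean_colour, dist$mean_length),
                      Sigma = Sigma)
  if (n == 1L) xy <- matrix(xy, nrow = 1L)
  colour <- xy[, 1L]
  length_mm <- xy[, 2L]
  n_clipped <- sum(colour < 0) + sum(length_mm < 0)
  colour <- pmax(colour, 0)
  length_mm <- pmax(length_mm, 0)
  out <- data.frame(male_id = sprintf("M%05d", seq_len(n)),
                    length_mm = length_mm,
                    colour_score = colour,
                    stringsAsFactors = FALSE)
  attr(out, "colour_scale") <- dist$scale
  attr(out, "n_clipped") <- n_clipped
  out
}

#' Draw a shoal structure
#'
#' Samples per-shoal male and female counts from discrete uniform laws on
#' inclusive integer ranges. The defaults emulate the field structure:
#' 2-6 males and 1-15 females per shoal.
#'
#' @param n_shoals number of shoals (>= 1).
#' @param male_count_range length-1 (constant) or length-2 `c(min, max)`
#'   integer range for males per shoal; minimum must be >= 1.
#' @param female_count_range as above for females; minimum must be >= 0.
#' @param seed optional integer seed.
#' @return Data frame of class `shoal_structure` with columns `shoal_id`,
#'   `n_males`, `n_females`.
#' @export
sample_shoal_structure <- function(n_shoals,
                                   male_count_range = c(2L, 6L),
                                   female_count_range = c(1L, 15L),
                                   seed = NULL) {
  if (length(n_shoals) != 1L || !is.finite(n_shoals) || n_shoals < 1)
    stop("'n_shoals' must be a positive count")
  n_shoals <- as.integer(n_shoals)
  draw <- function(range, lo_min, what) {
    if (length(range) == 1L) range <- c(range, range)
    if (length(range) != 2L || any(!is.finite(range)))
      stop("'", what, "' must be a length-1 or length-2 integer range")
    range <- as.integer(range)
    if (range[1L] > range[2L] || range[1L] < lo_min)
      stop("impossible bounds for '", what, "'")
    if (range[1L] == range[2L]) rep(range[1L], n_shoals)
    else sample(seq(range[1L], range[2L]), n_shoals, replace = TRUE)
  }
  if (!is.null(seed)) set.seed(seed)
  n_males <- draw(male_count_range, 1L, "male_count_range")
  n_females <- draw(female_count_range, 0L, "female_count_range")
  out <- data.frame(shoal_id = sprintf("S%04d", seq_len(n_shoals)),
                    n_males = n_males,
                    n_females = n_females,
                    stringsAsFactors = FALSE)
  class(out) <- c("shoal_structure", "data.frame")
  out
}

# round-robin dealing of sorted males over shoals: one male per shoal
# per round, larger remaining capacities served first so that unequal
# shoal sizes stay balanced in rank (equal sizes reduce to plain
# round-robin dealing)
.stripe_slots <- function(sizes) {
  left <- as.integer(sizes)
  out <- integer(sum(sizes))
  i <- 0L
  while (any(left > 0L)) {
    active <- which(left > 0L)
    active <- active[order(-left[active], active)]
    for (j in active) {
      i <- i + 1L
      out[i] <- j
      left[j] <- left[j] - 1L
    }
  }
  out
}

#' Assign males to shoals with a controlled degree of assortment
#'
#' Places phenotyped males into a shoal structure with tunable phenotypic
#' assortment, the alternative-hypothesis family used to power-test the
#' randomization analysis. `assortment = 0` gives a uniformly random
#' assignment. Positive values start from a sort-and-block assignment
#' (males sorted by the focal trait, dealt into shoals in contiguous
#' blocks, so groupmates are maximally similar); negative values start
#' from round-robin striping of the sorted males (groupmates maximally
#' dissimilar). A random subset of `(1 - |assortment|)` of the males then
#' has its assignments re-shuffled, so |assortment| interpolates between
#' the pure pattern and pure noise.
#'
#' @param phenotypes male phenotype table, as from
#'   [sample_male_phenotypes()].
#' @param structure a [sample_shoal_structure()] table; its total male
#'   count must equal `nrow(phenotypes)`.
#' @param assortment signed strength in `[-1, 1]`.
#' @param trait `"length"` or `"colour"`: the trait driving assortment.
#' @param seed optional integer seed.
#' @return A [shoal_data] object.
#' @examples
#' ph <- data.frame(male_id = letters[1:4],
#'                  length_mm = c(20, 21, 28, 29),
#'                  colour_score = 0.05)
#' st <- data.frame(shoal_id = c("A", "B"), n_males = c(2L, 2L),
#'                  n_females = c(2L, 2L))
#' assign_males_to_shoals(ph, st, assortment = 1, trait = "length")
#' @export
assign_males_to_shoals <- function(phenotypes, structure, assortment = 0,
                                   trait = c("length", "colour"),
                                   seed = NULL) {
  trait <- match.arg(trait)
  if (!all(c("n_males", "shoal_id") %in% names(structure)))
    stop("'structure' must carry shoal_id and n_males columns")
  sizes <- as.integer(structure$n_males)
  n <- sum(sizes)
  if (nrow(phenotypes) != n)
    stop("phenotype rows (", nrow(phenotypes),
         ") do not match the structure's total male count (", n, ")")
  if (length(assortment) != 1L || !is.finite(assortment) ||
      abs(assortment) > 1)
    stop("'assortment' must be a number in [-1, 1]")
  if (!is.null(seed)) set.seed(seed)

  col <- switch(trait, length = "length_mm", colour = "colour_score")
  ord <- order(phenotypes[[col]])
  slot_shoal <- if (assortment >= 0) rep(seq_along(sizes), sizes)
                else .stripe_slots(sizes)
  assign <- integer(n)
  assign[ord] <- slot_shoal

  n_mix <- round((1 - abs(assortment)) * n)
  if (n_mix >= 2L) {
    idx <- sample.int(n, n_mix)
    assign[idx] <- assign[idx][sample.int(n_mix)]
  }

  males <- phenotypes[c("male_id", col,
                        setdiff(c("length_mm", "colour_score"), col))]
  males$shoal_id <- structure$shoal_id[assign]
  shoal_data(males, shoals = structure)
}

#' Generate dichotomous-choice trials
#'
#' Simulates association-time proportions for a two-shoal choice test.
#' Each trial's proportion of time near the focal (less attractive) shoal
#' is drawn so that its arcsine-square-root transform is normal about the
#' transform of `true_preference`, matching the distributional assumption
#' of the downstream t-tests; proportions are clipped to the open (0, 1).
#'
#' @param n_trials number of trials (>= 1).
#' @param true_preference expected proportion, strictly in (0, 1); 0.5 is
#'   the chance (no-choice) value.
#' @param noise_sd standard deviation of trial noise on the transformed
#'   (radian) scale, >= 0.
#' @param seed optional integer seed.
#' @param trial_duration total association time per trial, in seconds
#'   (used only to express the proportion as zone times).
#' @return Data frame with columns `trial_id`, `prop_less`, `time_less`,
#'   `time_more`.
#' @export
generate_choice_trials <- function(n_trials, true_preference, noise_sd,
                                   seed = NULL, trial_duration = 900) {
  if (length(n_trials) != 1L || !is.finite(n_trials) || n_trials < 1)
    stop("'n_trials' must be a positive count")
  if (!is.finite(true_preference) || true_preference <= 0 ||
      true_preference >= 1)
    stop("'true_preference' must lie strictly in (0, 1)")
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("'noise_sd' must be non-negative")
  n_trials <- as.integer(n_trials)
  if (!is.null(seed)) set.seed(seed)
  theta <- asin(sqrt(true_preference)) + rnorm(n_trials, 0, noise_sd)
  prop <- sin(theta)^2
  eps <- 1e-12
  prop <- pmin(pmax(prop, eps), 1 - eps)
  data.frame(trial_id = sprintf("T%05d", seq_len(n_trials)),
             prop_less = prop,
             time_less = prop * trial_duration,
             time_more = (1 - prop) * trial_duration,
             stringsAsFactors = FALSE)
}
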