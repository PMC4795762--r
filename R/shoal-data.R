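#' Shoal observation data
#'
#' Container for gambit-of-the-group samples: each shoal's male members
#' with their phenotypes, plus a per-shoal female count. This is the
#' input to the assortment analysis and the output of the synthetic
#' assignment generator.
#'
#' @param males data frame with columns `male_id`, `shoal_id`,
#'   `length_mm`, `colour_score` (an optional `n_females` column is
#'   folded into the shoal table).
#' @param shoals optional data frame with columns `shoal_id`, `n_females`
#'   (and optionally `n_males`, which is validated against `males`). When
#'   absent, female counts default to 0.
#' @return An object of class `shoal_data`: a list with elements `males`
#'   (one row per male, stable-sorted by shoal then male id) and `shoals`
#'   (`shoal_id`, `n_males`, `n_females`).
#' @examples
#' males <- data.frame(male_id = c("a", "b", "c", "d"),
#'                     shoal_id = c(1, 1, 2, 2),
#'                     length_mm = c(20, 21, 28, 29),
#'                     colour_score = c(0.05, 0.06, 0.07, 0.08))
#' shoal_data(males)
#' @export
shoal_data <- function(males, shoals = NULL) {
  if (!is.data.frame(males)) stop("'males' must be a data frame")
  req <- c("male_id", "shoal_id", "length_mm", "colour_score")
  miss <- setdiff(req, names(males))
  if (length(miss))
    stop("missing column(s) in male table: ", paste(miss, collapse = ", "))
  if (!is.numeric(males$length_mm) || !is.numeric(males$colour_score))
    stop("'length_mm' and 'colour_score' must be numeric")
  if (anyNA(males$length_mm) || anyNA(males$colour_score))
    stop("missing trait values in male table")
  if (anyDuplicated(males$male_id))
    stop("duplicated male_id: each male may appear in exactly one shoal")

  females_col <- NULL
  if ("n_females" %in% names(males)) {
    bad <- tapply(males$n_females, males$shoal_id,
                  function(v) length(unique(v)) != 1L)
    if (any(bad))
      stop("'n_females' must be constant within a shoal")
    females_col <- tapply(males$n_females, males$shoal_id, function(v) v[1L])
  }

  ord <- order(males$shoal_id, males$male_id)
  males <- males[ord, req, drop = FALSE]
  rownames(males) <- NULL

  counts <- table(males$shoal_id)
  ids <- names(counts)
  n_females <- rep(0, length(ids))
  if (!is.null(females_col))
    n_females <- as.numeric(females_col[ids])

  if (!is.null(shoals)) {
    if (!all(c("shoal_id") %in% names(shoals)))
      stop("'shoals' must carry a shoal_id column")
    idx <- match(ids, as.character(shoals$shoal_id))
    if (anyNA(idx))
      stop("male table refers to shoal ids absent from the shoal table")
    if ("n_females" %in% names(shoals))
      n_females <- as.numeric(shoals$n_females[idx])
    if ("n_males" %in% names(shoals) &&
        !all(as.integer(shoals$n_males[idx]) == as.integer(counts)))
      stop("declared n_males disagrees with the male table")
  }
  if (any(n_females < 0) || anyNA(n_females))
    stop("female counts must be non-negative")

  structure(list(
    males = males,
    shoals = data.frame(shoal_id = ids,
                        n_males = as.integer(counts),
                        n_females = n_females,
                        stringsAsFactors = FALSE)
  ), class = "shoal_data")
}

#' @export
print.shoal_data <- function(x, ...) {
  n_sh <- nrow(x$shoals)
  n_m <- nrow(x$males)
  cat("Shoal observations:", n_sh, "shoals,", n_m, "males\n")
  cat(sprintf("  males per shoal: mean %.2f (range %d-%d)\n",
              mean(x$shoals$n_males), min(x$shoals$n_males),
              max(x$shoals$n_males)))
  cat(sprintf("  length_mm: mean %.2f, sd %.3f\n",
              mean(x$males$length_mm), sd(x$males$length_mm)))
  cat(sprintf("  colour_score: mean %.4f, sd %.4f\n",
              mean(x$males$colour_score), sd(x$males$colour_score)))
  invisible(x)
}

# internal: pooled trait values + integer group index, stable shoal order
.pooled_trait <- function(data, trait) {
  col <- switch(trait, length = "length_mm", colour = "colour_score",
                stop("unknown trait: ", trait))
  if (inherits(data, "shoal_data")) {
    df <- data$males
  } else if (is.data.frame(data)) {
    if (!all(c("shoal_id", col) %in% names(data)))
      stop("data must carry 'shoal_id' and '", col, "' columns")
    df <- data
  } else {
    stop("data must be a shoal_data object or a data frame")
  }
  g <- match(df$shoal_id, unique(df$shoal_id))
  list(x = as.numeric(df[[col]]), g = g)
}
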