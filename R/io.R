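# separator by file extension: .csv comma, otherwise tab
.sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a shoal observation table
#'
#' Reads a TSV (or `.csv`) male table with columns `male_id`,
#' `shoal_id`, `length_mm`, `colour_score` and an optional `n_females`
#' column (constant within shoal). A male id appearing in more than one
#' shoal is an error — co-occurrence data must not be pseudo-replicated.
#'
#' @param path file path; `.csv` is read comma-separated, anything else
#'   tab-separated.
#' @return A [shoal_data] object.
#' @export
read_shoal_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.table(path, header = TRUE, sep = .sep_for(path),
                   stringsAsFactors = FALSE)
  req <- c("male_id", "shoal_id", "length_mm", "colour_score")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  for (col in c("length_mm", "colour_score"))
    if (!is.numeric(df[[col]]))
      stop("non-numeric values in column '", col, "'")
  shoal_data(df)
}

#' Write a shoal observation table
#'
#' One row per male with the unit-bearing headers `male_id`, `shoal_id`,
#' `length_mm`, `colour_score`, plus `n_females` when any shoal carries
#' females. Round-trips through [read_shoal_table()].
#'
#' @param x a [shoal_data] object.
#' @param path output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return The path, invisibly.
#' @export
write_shoal_table <- function(x, path) {
  if (!inherits(x, "shoal_data"))
    stop("'x' must be a shoal_data object")
  df <- x$males
  if (any(x$shoals$n_females > 0)) {
    df$n_females <- x$shoals$n_females[match(df$shoal_id,
                                             x$shoals$shoal_id)]
  }
  write.table(df, path, sep = .sep_for(path), quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a shoal structure table
#'
#' Per-shoal counts with headers `shoal_id`, `n_males`, `n_females`.
#'
#' @param x a `shoal_structure` data frame (or the `shoals` element of a
#'   [shoal_data]).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_shoal_structure <- function(x, path) {
  req <- c("shoal_id", "n_males", "n_females")
  if (!all(req %in% names(x)))
    stop("'x' must carry columns ", paste(req, collapse = ", "))
  write.table(as.data.frame(x)[req], path, sep = .sep_for(path),
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an analysis result to disk
#'
#' Scalar-style results (randomization tests, t-tests, preference
#' models) are written as JSON; trajectories and sweep summaries as TSV
#' (`step  var_colour  var_length`; `param  value  trait  mean_slope
#' se_slope  n_reps`). Re-running the producing pipeline with the same
#' configuration and seed reproduces byte-identical files.
#'
#' @param x an `assortment_test`, `ff_sim`, `ff_sweep`, `ff_ttest` or
#'   `preference_model` object.
#' @param path output path.
#' @param ... unused.
#' @return The path, invisibly.
#' @export
write_results <- function(x, path, ...) UseMethod("write_results")

#' @export
write_results.assortment_test <- function(x, path, ...) {
  out <- list(schema = "finfusion/assortment_test/1",
              trait = x$trait,
              observed_statistic = x$observed_statistic,
              percentile_rank = x$percentile_rank,
              decision = x$decision,
              empirical_p = x$empirical_p,
              alpha_tail = x$alpha_tail,
              n_iterations = x$n_iterations,
              seed = x$seed,
              null_values = I(x$null_values))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @export
write_results.ff_sim <- function(x, path, ...) {
  df <- data.frame(step = seq_along(x$var_colour),
                   var_colour = x$var_colour,
                   var_length = x$var_length)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.ff_sweep <- function(x, path, ...) {
  write.table(x$summary, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
write_results.ff_ttest <- function(x, path, ...) {
  out <- list(schema = "finfusion/t_test/1", method = x$method,
              statistic = x$statistic, df = x$df, p_value = x$p_value,
              estimate = x$estimate, null_value = x$null_value)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
write_results.preference_model <- function(x, path, ...) {
  out <- list(schema = "finfusion/preference_model/1",
              design = x$design, n = x$n,
              coefficients = as.list(coef(x$fit)),
              anova = x$anova)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a provenance record beside an output file
#'
#' Machine-readable record of how an output was produced: package
#' version, seed and configuration echo. Written to
#' `<path>.prov.json`. Content is deterministic (no timestamps), so
#' identical runs produce identical records.
#'
#' @param path the output file the record describes.
#' @param config list (or config object) echoing the run configuration.
#' @param seed the run seed, or `NULL`.
#' @return The provenance path, invisibly.
#' @export
write_provenance <- function(path, config = list(), seed = NULL) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  out <- list(schema = "finfusion/provenance/1",
              package = "finfusion",
              version = as.character(packageVersion("finfusion")),
              seed = seed,
              config = strip(config))
  pp <- paste0(path, ".prov.json")
  jsonlite::write_json(out, pp, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(pp)
}
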