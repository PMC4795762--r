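#' OLS trend of a variance trajectory
#'
#' Ordinary least-squares slope of within-group variance on time step
#' (1-based). Missing (degenerate) steps are dropped; at least three
#' non-missing points are required.
#'
#' @param trajectory numeric vector of per-step variances.
#' @return The slope (variance units per step), with attributes `se`
#'   (standard error of the slope) and `n_used` (points retained).
#' @examples
#' variance_trend(c(1, 3, 2, 4))  # 0.8
#' @export
variance_trend <- function(trajectory) {
  v <- as.numeric(trajectory)
  step <- seq_along(v)
  ok <- is.finite(v)
  if (sum(ok) < 3L)
    stop("need at least 3 non-missing variance values for a trend")
  fit <- lm(v ~ step, data = data.frame(v = v[ok], step = step[ok]))
  # a perfectly flat trajectory triggers a spurious perfect-fit warning
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(unname(cf[2L, 1L]), se = unname(cf[2L, 2L]),
            n_used = sum(ok))
}

#' Specification of a one-at-a-time sensitivity sweep
#'
#' Defines which simulator parameter is varied (`n_males`, `beta_c` or
#' `beta_s`), over which values, with how many replicate runs per value.
#' While one of `beta_c`/`beta_s` is varied, the other is held at 0 (the
#' constructor enforces this on the base configuration).
#'
#' @param param `"n_males"`, `"beta_c"` or `"beta_s"`.
#' @param values numeric vector of parameter values (non-empty).
#' @param replicates replicate simulations per value (default 5).
#' @param base a [population_config()] supplying all other parameters.
#' @return An object of class `sweep_spec`.
#' @export
sweep_spec <- function(param = c("n_males", "beta_c", "beta_s"), values,
                       replicates = 5, base = population_config()) {
  param <- match.arg(param)
  if (length(values) < 1L || any(!is.finite(values)))
    stop("'values' must be a non-empty numeric vector")
  if (!is.finite(replicates) || replicates < 1)
    stop("'replicates' must be at least 1")
  if (!inherits(base, "population_config"))
    stop("'base' must be a population_config object")
  if (param == "beta_c") base$movement$beta_s <- 0
  if (param == "beta_s") base$movement$beta_c <- 0
  structure(list(param = param, values = values,
                 replicates = as.integer(replicates), base = base),
            class = "sweep_spec")
}

# counter-based child seed: independent of the other cells, so adding
# values or replicates never shifts existing streams
.child_seed <- function(seed, value_index, replicate) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 2147483647 +
              7919 * value_index + 104729 * replicate) %% 2147483647)
}

#' Run a sensitivity sweep
#'
#' For every value of the varied parameter, runs `replicates` independent
#' simulations (each from a seed derived deterministically from the
#' master seed), computes the [variance_trend()] slope for colour and for
#' length, and aggregates the replicate slopes into a mean and standard
#' error of the mean per value and trait.
#'
#' @param spec a [sweep_spec()].
#' @param seed master integer seed (optional; without it the sweep is
#'   not reproducible).
#' @return An object of class `ff_sweep`: list with `results` (one row
#'   per value x replicate x trait: `param`, `value`, `replicate`,
#'   `trait`, `slope`, `se`) and `summary` (`param`, `value`, `trait`,
#'   `mean_slope`, `se_slope`, `n_reps`), plus the `spec`.
#' @examples
#' base <- population_config(n_groups = 6, n_males = 20, n_steps = 10,
#'                           record_events = FALSE)
#' sw <- run_sweep(sweep_spec("beta_c", c(0, 10), replicates = 2,
#'                            base = base), seed = 1)
#' sw$summary
#' @export
run_sweep <- function(spec, seed = NULL) {
  if (!inherits(spec, "sweep_spec"))
    stop("'spec' must be a sweep_spec object")
  rows <- vector("list", length(spec$values) * spec$replicates)
  idx <- 0L
  for (v in seq_along(spec$values)) {
    val <- spec$values[v]
    for (r in seq_len(spec$replicates)) {
      cfg <- spec$base
      if (spec$param == "n_males") {
        cfg$n_males <- as.integer(val)
      } else {
        cfg$movement[[spec$param]] <- val
      }
      cfg$record_events <- FALSE
      cfg$seed <- .child_seed(seed, v, r)
      sim <- run_simulation(cfg)
      tc <- variance_trend(sim$var_colour)
      tl <- variance_trend(sim$var_length)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        param = spec$param, value = val, replicate = r,
        trait = c("colour", "length"),
        slope = c(as.numeric(tc), as.numeric(tl)),
        se = c(attr(tc, "se"), attr(tl, "se")),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  agg <- function(d) {
    data.frame(param = d$param[1L], value = d$value[1L],
               trait = d$trait[1L], mean_slope = mean(d$slope),
               se_slope = if (nrow(d) > 1L)
                 sd(d$slope) / sqrt(nrow(d)) else NA_real_,
               n_reps = nrow(d), stringsAsFactors = FALSE)
  }
  pieces <- split(results,
                  list(results$value, results$trait), drop = TRUE)
  summ <- do.call(rbind, lapply(pieces, agg))
  summ <- summ[order(summ$trait, summ$value), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ, spec = spec,
                 seed = seed), class = "ff_sweep")
}

#' @export
print.ff_sweep <- function(x, ...) {
  cat("Sensitivity sweep of", x$spec$param, "over",
      paste(x$spec$values, collapse = ", "), "\n")
  cat(" ", x$spec$replicates, "replicate runs per value;",
      "mean (SE) trend slope of within-group variance on time:\n\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Plot replicate-mean trend slopes against the varied parameter
#'
#' @param x an `ff_sweep` object.
#' @param ... unused.
#' @export
plot.ff_sweep <- function(x, ...) {
  s <- x$summary
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  for (tr in unique(s$trait)) {
    d <- s[s$trait == tr, ]
    se <- ifelse(is.na(d$se_slope), 0, d$se_slope)
    ylim <- range(c(d$mean_slope - se, d$mean_slope + se, 0))
    plot(d$value, d$mean_slope, pch = 19, ylim = ylim,
         xlab = x$spec$param,
         ylab = "mean trend slope",
         main = paste("within-group variance trend:", tr))
    segments(d$value, d$mean_slope - se, d$value, d$mean_slope + se)
    abline(h = 0, lty = 2)
  }
  invisible(x)
}
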