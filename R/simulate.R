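# numerically stable logistic; beta = 20 makes |a| large enough to
# overflow a naive exp(a)/(1+exp(a))
.logistic <- function(a) {
  p <- numeric(length(a))
  pos <- a >= 0
  p[pos] <- 1 / (1 + exp(-a[pos]))
  e <- exp(a[!pos])
  p[!pos] <- e / (1 + e)
  p
}

#' Movement-rule parameters
#'
#' Coefficients of the logistic movement rule. The linear predictor for
#' male i in group g is
#' `a = alpha + beta_c (cbar_g - c_i) + beta_s (sbar_g - s_i) + beta_r R_g`,
#' so with positive rates a male who is duller or smaller than his
#' groupmates' average, or who sits in a male-biased group, is more
#' likely to leave. Defaults are the strong phenotype-dependent setting
#' (`alpha = 0`, `beta_c = beta_s = 20`, `beta_r = 1`); set
#' `beta_c = beta_s = 0` for movement driven by sex ratio alone.
#'
#' @param alpha intercept (dimensionless).
#' @param beta_c rate per colour-score unit of relative dullness.
#' @param beta_s rate per mm of relative smallness.
#' @param beta_r rate per unit of group sex ratio (males/females).
#' @return An object of class `movement_params`.
#' @export
movement_params <- function(alpha = 0, beta_c = 20, beta_s = 20,
                            beta_r = 1) {
  vals <- c(alpha = alpha, beta_c = beta_c, beta_s = beta_s,
            beta_r = beta_r)
  if (!all(is.finite(vals)))
    stop("movement parameters must be finite numbers")
  structure(as.list(vals), class = "movement_params")
}

#' Simulation configuration
#'
#' Full configuration of a fission-fusion run: 67 groups each holding 2
#' resident females, 170 males drawn from the bivariate phenotype
#' distribution and randomly allocated over groups, 100 time steps.
#'
#' @param n_groups number of groups (>= 2); females never move.
#' @param n_females_per_group resident females per group (>= 1; the sex
#'   ratio is undefined without females).
#' @param n_males number of males (>= 1).
#' @param dist a [phenotype_distribution()] for male traits.
#' @param movement a [movement_params()] object.
#' @param n_steps number of time steps (>= 1).
#' @param seed optional integer seed; fixes the whole run.
#' @param exclude_focal when `TRUE`, group means in the movement rule
#'   exclude the focal male (leave-one-out); the default `FALSE` includes
#'   him, the literal reading of the rule.
#' @param record_events keep the per-selection event log (turn off for
#'   large sweeps).
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_groups = 67, n_females_per_group = 2,
                              n_males = 170,
                              dist = phenotype_distribution(),
                              movement = movement_params(),
                              n_steps = 100, seed = NULL,
                              exclude_focal = FALSE,
                              record_events = TRUE) {
  if (!is.finite(n_groups) || n_groups < 2)
    stop("'n_groups' must be at least 2")
  if (!is.finite(n_females_per_group) || n_females_per_group < 1)
    stop("'n_females_per_group' must be at least 1")
  if (!is.finite(n_males) || n_males < 1)
    stop("'n_males' must be at least 1")
  if (!is.finite(n_steps) || n_steps < 1)
    stop("'n_steps' must be at least 1")
  if (!inherits(dist, "phenotype_distribution"))
    stop("'dist' must be a phenotype_distribution object")
  if (!inherits(movement, "movement_params"))
    stop("'movement' must be a movement_params object")
  structure(list(n_groups = as.integer(n_groups),
                 n_females_per_group = as.integer(n_females_per_group),
                 n_males = as.integer(n_males),
                 dist = dist, movement = movement,
                 n_steps = as.integer(n_steps), seed = seed,
                 exclude_focal = isTRUE(exclude_focal),
                 record_events = isTRUE(record_events)),
            class = "population_config")
}

#' Summary state of one group
#'
#' @param males data frame of the group's current male members (columns
#'   `colour_score`, `length_mm`).
#' @param n_females resident females in the group (> 0).
#' @return List with `mean_colour`, `mean_length`, `n_males`,
#'   `n_females`, `sex_ratio` (males/females).
#' @export
group_state <- function(males, n_females) {
  if (!is.finite(n_females) || n_females <= 0)
    stop("sex ratio undefined: group has no females")
  if (nrow(males) < 1L)
    stop("group has no male members")
  list(mean_colour = mean(males$colour_score),
       mean_length = mean(males$length_mm),
       n_males = nrow(males),
       n_females = n_females,
       sex_ratio = nrow(males) / n_females)
}

#' Probability that a male leaves his group
#'
#' Evaluates the logistic movement rule for one male against his current
#' group's mean colour, mean length and sex ratio (group means include
#' the focal male). Numerically stable for large `|a|`.
#'
#' @param male a list or one-row data frame with `colour_score` and
#'   `length_mm`.
#' @param group a [group_state()] (or any list with `mean_colour`,
#'   `mean_length`, `sex_ratio`).
#' @param params a [movement_params()] object.
#' @return Movement probability in (0, 1).
#' @examples
#' move_probability(list(colour_score = 6, length_mm = 24),
#'                  list(mean_colour = 6, mean_length = 24,
#'                       sex_ratio = 1),
#'                  movement_params(alpha = 0, beta_c = 0, beta_s = 0,
#'                                  beta_r = 0))  # 0.5
#' @export
move_probability <- function(male, group, params) {
  if (!is.null(group$n_females) &&
      (!is.finite(group$n_females) || group$n_females <= 0))
    stop("sex ratio undefined: group has no females")
  a <- params$alpha +
    params$beta_c * (group$mean_colour - male$colour_score) +
    params$beta_s * (group$mean_length - male$length_mm) +
    params$beta_r * group$sex_ratio
  .logistic(a)
}

#' One time step of the fission-fusion simulator
#'
#' Performs `n_males` selections of a male uniformly at random with
#' replacement (so each male is chosen on average once per step). Each
#' selected male leaves his group with the probability given by
#' [move_probability()]; on leaving he joins one of the other groups
#' chosen uniformly at random (male-empty groups included), and group
#' compositions are recalculated immediately. Total male count, group
#' count and female counts are conserved. Consumes the current R random
#' stream.
#'
#' @param state an `ff_population` state (see [run_simulation()]).
#' @param params a [movement_params()] object.
#' @return List with the updated `state` and an `events` data frame (one
#'   row per selection: `male_id`, `a`, `p_move`, `moved`, `from_group`,
#'   `to_group`).
#' @export
ff_step <- function(state, params) {
  n <- length(state$group)
  k <- state$n_groups
  grp <- state$group
  colour <- state$colour
  len <- state$length
  nf <- state$n_females
  excl <- isTRUE(state$exclude_focal)

  sel <- sample.int(n, n, replace = TRUE)
  ev_a <- numeric(n)
  ev_p <- numeric(n)
  ev_moved <- logical(n)
  ev_from <- integer(n)
  ev_to <- rep(NA_integer_, n)

  for (j in seq_len(n)) {
    i <- sel[j]
    gfrom <- grp[i]
    members <- which(grp == gfrom)
    stat_members <- if (excl && length(members) > 1L)
      members[members != i] else members
    cbar <- mean(colour[stat_members])
    sbar <- mean(len[stat_members])
    R <- length(members) / nf[gfrom]
    a <- params$alpha + params$beta_c * (cbar - colour[i]) +
      params$beta_s * (sbar - len[i]) + params$beta_r * R
    p <- .logistic(a)
    moved <- runif(1) < p
    ev_a[j] <- a
    ev_p[j] <- p
    ev_moved[j] <- moved
    ev_from[j] <- gfrom
    if (moved) {
      gto <- sample.int(k - 1L, 1L)
      if (gto >= gfrom) gto <- gto + 1L
      grp[i] <- gto
      ev_to[j] <- gto
    }
  }
  state$group <- grp
  list(state = state,
       events = data.frame(male_id = state$male_id[sel],
                           a = ev_a, p_move = ev_p, moved = ev_moved,
                           from_group = ev_from, to_group = ev_to,
                           stringsAsFactors = FALSE))
}

#' Run the fission-fusion simulation
#'
#' Initializes males from the configured phenotype distribution,
#' allocates them uniformly at random over the groups, and iterates
#' [ff_step()] for `n_steps` steps. After each step the within-group
#' variance (ANOVA mean square, as in [within_group_variance()]) of
#' colour and of length is recorded over the current groups; male-empty
#' groups are skipped and a step at which every group holds at most one
#' male yields `NA` (counted in `n_degenerate_steps`).
#'
#' @param config a [population_config()].
#' @return An object of class `ff_sim`: list with `var_colour` and
#'   `var_length` (numeric, length `n_steps`), `events` (data frame with
#'   a `step` column, or `NULL`), `phenotypes`, `final_state`, `config`,
#'   `n_degenerate_steps`.
#' @examples
#' cfg <- population_config(n_groups = 6, n_males = 20, n_steps = 10,
#'                          seed = 1)
#' sim <- run_simulation(cfg)
#' head(sim$var_colour)
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "population_config"))
    stop("'config' must be a population_config object")
  if (!is.null(config$seed)) set.seed(config$seed)
  ph <- sample_male_phenotypes(config$n_males, config$dist)
  state <- structure(list(
    male_id = ph$male_id,
    colour = ph$colour_score,
    length = ph$length_mm,
    group = sample.int(config$n_groups, config$n_males, replace = TRUE),
    n_groups = config$n_groups,
    n_females = rep(config$n_females_per_group, config$n_groups),
    exclude_focal = config$exclude_focal
  ), class = "ff_population")

  var_c <- rep(NA_real_, config$n_steps)
  var_l <- rep(NA_real_, config$n_steps)
  ev <- if (config$record_events) vector("list", config$n_steps)
  for (t in seq_len(config$n_steps)) {
    res <- ff_step(state, config$movement)
    state <- res$state
    if (config$record_events) {
      res$events$step <- t
      ev[[t]] <- res$events[c("step", setdiff(names(res$events), "step"))]
    }
    var_c[t] <- .msw_or_na(state$colour, state$group)
    var_l[t] <- .msw_or_na(state$length, state$group)
  }
  structure(list(var_colour = var_c, var_length = var_l,
                 events = if (config$record_events) do.call(rbind, ev),
                 phenotypes = ph, final_state = state, config = config,
                 n_degenerate_steps = sum(is.na(var_c))),
            class = "ff_sim")
}

#' @export
print.ff_sim <- function(x, ...) {
  cfg <- x$config
  cat("Fission-fusion simulation:", cfg$n_males, "males,",
      cfg$n_groups, "groups,", cfg$n_steps, "steps\n")
  cat(sprintf("  movement: alpha=%g beta_c=%g beta_s=%g beta_r=%g\n",
              cfg$movement$alpha, cfg$movement$beta_c,
              cfg$movement$beta_s, cfg$movement$beta_r))
  if (!is.null(x$events))
    cat(sprintf("  moves: %d of %d selections (%.1f%%)\n",
                sum(x$events$moved), nrow(x$events),
                100 * mean(x$events$moved)))
  ok <- is.finite(x$var_colour)
  if (any(ok))
    cat(sprintf("  final within-group variance: colour %.4g, length %.4g\n",
                x$var_colour[max(which(ok))],
                x$var_length[max(which(ok))]))
  if (x$n_degenerate_steps > 0)
    cat("  degenerate steps (variance undefined):",
        x$n_degenerate_steps, "\n")
  invisible(x)
}

#' Trend summary of a simulation run
#'
#' OLS slope (with standard error) of within-group variance on time, per
#' trait — the quantity the sensitivity analysis averages over
#' replicates.
#'
#' @param object an `ff_sim` object.
#' @param ... unused.
#' @return Data frame with one row per trait: `trait`, `slope`, `se`,
#'   `n_steps_used`.
#' @export
summary.ff_sim <- function(object, ...) {
  row <- function(trait, v) {
    tr <- variance_trend(v)
    data.frame(trait = trait, slope = as.numeric(tr),
               se = attr(tr, "se"), n_steps_used = attr(tr, "n_used"),
               stringsAsFactors = FALSE)
  }
  rbind(row("colour", object$var_colour), row("length", object$var_length))
}

#' Plot within-group variance trajectories
#'
#' @param x an `ff_sim` object.
#' @param ... unused.
#' @export
plot.ff_sim <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  t <- seq_along(x$var_colour)
  plot(t, x$var_colour, type = "l", xlab = "time step",
       ylab = "within-group variance (colour)",
       main = "Within-group variance over time")
  plot(t, x$var_length, type = "l", xlab = "time step",
       ylab = "within-group variance (length)")
  invisible(x)
}
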