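# Ensemble experiments: stochastic realizations with summary statistics, the
# four-intervention suppression comparison, and the competitiveness x
# lifespan-reduction elimination sweep.

realization_seed <- function(seed, i) {
  # deterministic per-realization perturbation, kept inside 32-bit range
  as.integer((as.numeric(seed) + 1009 * i) %% .Machine$integer.max)
}

#' Run an ensemble of stochastic realizations
#'
#' Runs `n_realizations` independent seeded simulations and summarizes the
#' daily total adult female counts (mean, median, 2.5% and 97.5% quantiles),
#' the elimination probability (fraction of realizations in which the
#' reproducing population reached zero), and the mean time to elimination
#' among eliminated runs.  Realization `i` uses a seed derived
#' deterministically from `seed` and `i`, so two systems run with the same
#' base seed share per-realization random streams.
#'
#' @param calib a [calibrate_equilibrium()] result.
#' @param cube an `intervention_cube`.
#' @param schedule a `release_schedule` or `NULL`.
#' @param horizon days to simulate.
#' @param n_realizations number of realizations (>= 1).
#' @param seed integer base seed.
#' @param mode simulation mode; `"stochastic"` by default (an ensemble of
#'   deterministic runs is permitted and degenerate).
#' @param keep_trajectories if `TRUE`, the matrix of per-realization adult
#'   female trajectories is retained in the result.
#' @return an object of class `ensemble_summary`.
#' @export
run_ensemble <- function(calib, cube, schedule = NULL, horizon,
                         n_realizations, seed = 1L,
                         mode = "stochastic", keep_trajectories = FALSE) {
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  nd <- horizon + 1
  fem <- matrix(0, n_realizations, nd)
  elim_days <- rep(NA_integer_, n_realizations)
  for (i in seq_len(n_realizations)) {
    tr <- run_simulation(calib, cube, schedule, horizon, mode = mode,
                         seed = realization_seed(seed, i))
    fem[i, ] <- adult_females(tr)
    elim_days[i] <- tr$elimination_day
  }
  summarize_ensemble(fem, elim_days, horizon, cube$name, seed,
                     if (keep_trajectories) fem else NULL)
}

#' Summarize a matrix of adult-female trajectories
#'
#' Recomputes the [run_ensemble()] summary from persisted raw trajectories
#' (realizations in rows, days 0..horizon in columns); the result is
#' bit-identical to the one produced during the run.
#'
#' @param females matrix of daily total adult females, one row per
#'   realization.
#' @param elimination_days integer vector of elimination days (`NA` = never).
#' @param horizon number of simulated days.
#' @param system label for the summarized system.
#' @param seed base seed used (metadata only).
#' @param trajectories optionally, the raw matrix to retain.
#' @return an `ensemble_summary`.
#' @export
summarize_ensemble <- function(females, elimination_days, horizon,
                               system = NA_character_, seed = NA_integer_,
                               trajectories = NULL) {
  qs <- apply(females, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
              names = FALSE)
  structure(
    list(
      day = 0:horizon,
      mean = colMeans(females),
      median = qs[2, ],
      q025 = qs[1, ],
      q975 = qs[3, ],
      elimination_probability = mean(!is.na(elimination_days)),
      mean_time_to_elimination = if (any(!is.na(elimination_days))) {
        mean(elimination_days, na.rm = TRUE)
      } else NA_real_,
      elimination_days = elimination_days,
      n_realizations = nrow(females),
      system = system, seed = seed,
      trajectories = trajectories
    ),
    class = "ensemble_summary"
  )
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat("Ensemble summary (", x$system, ", n = ", x$n_realizations, ")\n", sep = "")
  cat(sprintf("  final-day adult females: mean %.4g [%.4g, %.4g]\n",
              x$mean[length(x$mean)], x$q025[length(x$q025)],
              x$q975[length(x$q975)]))
  cat(sprintf("  elimination probability: %.3f", x$elimination_probability))
  if (!is.na(x$mean_time_to_elimination)) {
    cat(sprintf(" (mean day %.1f)", x$mean_time_to_elimination))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.ensemble_summary <- function(x, ...) {
  data.frame(system = x$system, day = x$day, mean = x$mean, median = x$median,
             q025 = x$q025, q975 = x$q975, stringsAsFactors = FALSE)
}

intervention_defaults <- function() {
  list(
    pgsit = list(ratio = 200),
    fsridl = list(ratio = 200),
    ridl = list(ratio = 10),
    iit = list(ratio = 10)
  )
}

#' Compare the four suppression interventions against no intervention
#'
#' Runs matched ensembles for pgSIT, fsRIDL, RIDL, IIT and a no-intervention
#' baseline under identical per-realization seeds.  Release programs are
#' weekly for 6 months (26 events) at the field-convention ratios: 200 eggs
#' per wild adult for the egg-release systems (pgSIT, fsRIDL) and 10 adult
#' males per wild adult for the adult-release systems (RIDL, IIT), with
#' cube-default fitness parameters (pgSIT c = 0.78; RIDL and fsRIDL c = 0.05;
#' IIT c = 1 with doubled adult hazard).
#'
#' Desk-scale defaults (`scale_factor = 0.1`, i.e. 1,000 equilibrium females,
#' and 100 realizations) keep the experiment tractable on one CPU; pass
#' `full_scale = TRUE` for the cluster-scale configuration (10,000 females,
#' 2,000 realizations).
#'
#' @param scale_factor in (0, 1]; jointly rescales the equilibrium female
#'   count and (through the per-adult ratios) the release sizes.
#' @param n_realizations realizations per system.
#' @param horizon days to simulate (default 200, covering the 6-month program
#'   plus follow-up).
#' @param seed base seed shared by all systems.
#' @param params a [life_history()] parameter set before scaling.
#' @param mode simulation mode.
#' @param full_scale if `TRUE`, override scale and realizations to the
#'   full-scale configuration.
#' @param run if `FALSE`, return the assembled configuration without running
#'   (used to inspect the full-scale setup cheaply).
#' @return a list of class `intervention_comparison`: `summaries` (one
#'   `ensemble_summary` per system, including `"none"`), and `table`, a
#'   data.frame of day-`horizon` mean adult females, first-21-day
#'   area-under-curve of mean adult females, and elimination probabilities.
#' @export
compare_interventions <- function(scale_factor = 0.1, n_realizations = 100,
                                  horizon = 200, seed = 1L,
                                  params = life_history(),
                                  mode = "stochastic",
                                  full_scale = FALSE, run = TRUE) {
  if (full_scale) {
    scale_factor <- 1
    n_realizations <- 2000
  }
  if (scale_factor <= 0 || scale_factor > 1) stop("scale_factor must be in (0, 1]")
  if (n_realizations < 1) stop("n_realizations must be >= 1")
  params$N_F_eq <- params$N_F_eq * scale_factor
  calib <- calibrate_equilibrium(params)
  systems <- names(intervention_defaults())
  config <- list(calib = calib, systems = systems,
                 ratios = vapply(intervention_defaults(), `[[`, 0, "ratio"),
                 n_realizations = n_realizations, horizon = horizon,
                 seed = seed, scale_factor = scale_factor)
  if (!run) return(config)

  summaries <- list()
  for (sys in systems) {
    cube <- build_cube(sys)
    sched <- release_schedule(cube, calib,
                              ratio = intervention_defaults()[[sys]]$ratio)
    summaries[[sys]] <- run_ensemble(calib, cube, sched, horizon,
                                     n_realizations, seed, mode = mode)
  }
  summaries[["none"]] <- run_ensemble(calib, build_cube("wild"), NULL, horizon,
                                      n_realizations, seed, mode = mode)

  tab <- do.call(rbind, lapply(names(summaries), function(sys) {
    s <- summaries[[sys]]
    data.frame(
      system = sys,
      final_mean_females = s$mean[length(s$mean)],
      day180_mean_females = s$mean[min(181, length(s$mean))],
      auc_females_d1_21 = sum(s$mean[2:22]),
      elimination_probability = s$elimination_probability,
      stringsAsFactors = FALSE
    )
  }))
  structure(list(summaries = summaries, table = tab, config = config),
            class = "intervention_comparison")
}

#' @export
print.intervention_comparison <- function(x, ...) {
  cat("Intervention comparison (scale ", x$config$scale_factor, ", ",
      x$config$n_realizations, " realizations)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Elimination-probability sweep over competitiveness and lifespan reduction
#'
#' Sweeps the pgSIT egg-release program over a grid of male mating
#' competitiveness values and adult lifespan reductions.  A lifespan
#' reduction `r` (fraction of mean adult lifespan lost) maps to a mortality
#' hazard multiplier `omega = 1 / (1 - r)`, capped so that the daily survival
#' probability stays non-negative; `r = 1` (infinite hazard) is rejected.
#'
#' @param c_grid competitiveness values in \[0, 1\].
#' @param lifespan_reduction_grid reduction values in \[0, 1).
#' @param egg_ratio released eggs per wild adult (default 200).
#' @param n_realizations realizations per grid cell.
#' @param scale_factor population scale as in [compare_interventions()].
#' @param horizon days to simulate.
#' @param seed base seed (shared across cells, matching realization streams).
#' @param params a [life_history()] parameter set before scaling.
#' @param full_scale if `TRUE`, use the full-scale configuration (10,000
#'   females, 2,000 realizations).
#' @return matrix of elimination probabilities with one row per `c_grid`
#'   value and one column per lifespan reduction, with a
#'   `"mean_time_to_elimination"` attribute of matching shape.
#' @export
parameter_sweep <- function(c_grid, lifespan_reduction_grid, egg_ratio = 200,
                            n_realizations = 40, scale_factor = 0.1,
                            horizon = 200, seed = 1L,
                            params = life_history(), full_scale = FALSE) {
  stopifnot(all(c_grid >= 0 & c_grid <= 1),
            all(lifespan_reduction_grid >= 0))
  if (any(lifespan_reduction_grid >= 1)) {
    stop("lifespan reduction of 1 implies an infinite hazard; values must be < 1")
  }
  if (full_scale) {
    scale_factor <- 1
    n_realizations <- 2000
  }
  params$N_F_eq <- params$N_F_eq * scale_factor
  calib <- calibrate_equilibrium(params)
  ep <- mt <- matrix(NA_real_, length(c_grid), length(lifespan_reduction_grid),
                     dimnames = list(c = c_grid, r = lifespan_reduction_grid))
  for (i in seq_along(c_grid)) {
    for (j in seq_along(lifespan_reduction_grid)) {
      r <- lifespan_reduction_grid[j]
      omega <- min(1 / (1 - r), 1 / calib$params$mu_ad)  # cap at certain daily death
      cube <- build_cube("pgsit", c_male = c_grid[i], omega = omega)
      sched <- if (egg_ratio > 0) {
        release_schedule(cube, calib, ratio = egg_ratio)
      } else NULL
      s <- run_ensemble(calib, cube, sched, horizon, n_realizations, seed)
      ep[i, j] <- s$elimination_probability
      mt[i, j] <- s$mean_time_to_elimination
    }
  }
  attr(ep, "mean_time_to_elimination") <- mt
  ep
}
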