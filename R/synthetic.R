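# Synthetic-data generators with the statistical structure the analyses
# assume: mate-competition assay tables, interval-censored survival records,
# and named scenario fixtures.  All generators are pure functions of their
# parameters and seed.

#' Generate a mate-competition assay table
#'
#' Emulates the replicated-cage design of a sterile-male competition assay.
#' Per replicate, three cages are generated: a two-wild-male control, a
#' one-wild-male control, and a mixed cage with `n_wt_mixed` wild plus
#' `n_test_mixed` test males.  In each cage every female's single mate is a
#' test male with probability `c_true * n_test / (n_wt + c_true * n_test)`;
#' her egg count is Poisson(`eggs_per_female`) and each egg hatches
#' independently at `h0` (fertile-sired) or `h_sterile` (sterile-sired),
#' optionally with beta-binomial overdispersion.
#'
#' @param c_true true relative competitiveness of test males.
#' @param h0 hatch probability of fertile-sired eggs.
#' @param h_sterile hatch probability of sterile-sired eggs (default 0).
#' @param n_replicates number of replicates (default 5).
#' @param n_females females per cage (default 10).
#' @param eggs_per_female mean Poisson egg count per female (default 30).
#' @param overdispersion beta-binomial precision parameter `phi` (hatch
#'   probability drawn per female from `Beta(h*phi, (1-h)*phi)`), or `NULL`
#'   (default) for pure binomial hatching.
#' @param n_wt_mixed,n_test_mixed male composition of the mixed cage.
#' @param seed integer seed.
#' @return a competition-assay data.frame (see [validate_assay_table()]).
#' @export
gen_competition_assay <- function(c_true, h0 = 0.851, h_sterile = 0,
                                  n_replicates = 5, n_females = 10,
                                  eggs_per_female = 30, overdispersion = NULL,
                                  n_wt_mixed = 1, n_test_mixed = 1,
                                  seed = 1L) {
  stopifnot(c_true >= 0, h0 >= 0, h0 <= 1, h_sterile >= 0, h_sterile <= 1,
            n_replicates >= 1, n_females >= 1, eggs_per_female > 0)
  set.seed(seed)
  hatch_count <- function(eggs, h) {
    if (eggs == 0) return(0)
    if (!is.null(overdispersion)) {
      h <- stats::rbeta(1, pmax(h, 1e-12) * overdispersion,
                        pmax(1 - h, 1e-12) * overdispersion)
    }
    stats::rbinom(1, eggs, h)
  }
  cage <- function(rep_id, n_wt, n_test) {
    p_test <- if (n_test > 0) {
      c_true * n_test / (n_wt + c_true * n_test)
    } else 0
    laid <- hatched <- 0
    for (f in seq_len(n_females)) {
      sterile_mate <- stats::runif(1) < p_test
      eggs <- stats::rpois(1, eggs_per_female)
      laid <- laid + eggs
      hatched <- hatched + hatch_count(eggs, if (sterile_mate) h_sterile else h0)
    }
    data.frame(replicate = rep_id, n_wt_males = n_wt, n_test_males = n_test,
               n_females = n_females, eggs_laid = laid, eggs_hatched = hatched,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    rbind(cage(r, 2, 0), cage(r, 1, 0), cage(r, n_wt_mixed, n_test_mixed))
  }))
  validate_assay_table(out)
  out
}

#' Generate interval-censored survival records
#'
#' True death times are drawn from the chosen distribution; deaths are then
#' reported on the inspection grid as intervals
#' `((k-1) * p, k * p]` of width `p = inspection_period` days, and
#' individuals alive at `study_end` are right-censored there.
#'
#' @param distribution `"exponential"` or `"weibull"`.
#' @param median median survival time in days (used to set the scale).
#' @param shape Weibull shape (ignored for exponential).
#' @param inspection_period days between inspections (default 3).
#' @param study_end end of follow-up in days.
#' @param n number of individuals.
#' @param group group label attached to the records.
#' @param seed integer seed.
#' @return a data.frame of records with columns `group`, `left`, `right`.
#' @export
gen_interval_survival <- function(distribution = c("exponential", "weibull"),
                                  median = 30, shape = 2,
                                  inspection_period = 3, study_end = 120,
                                  n = 100, group = "A", seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(median > 0, inspection_period >= 1, study_end > 0, n >= 1)
  set.seed(seed)
  t_death <- switch(distribution,
    exponential = stats::rexp(n, rate = log(2) / median),
    weibull = stats::rweibull(n, shape = shape,
                              scale = median / log(2)^(1 / shape))
  )
  k <- ceiling(t_death / inspection_period)
  left <- (k - 1) * inspection_period
  right <- k * inspection_period
  censored <- right > study_end
  last_insp <- floor(study_end / inspection_period) * inspection_period
  left[censored] <- last_insp
  right[censored] <- Inf
  out <- data.frame(group = group, left = left, right = right,
                    stringsAsFactors = FALSE)
  validate_interval_records(out)
  out
}

#' Named scenario fixtures
#'
#' Returns a fully specified, seeded scenario configuration:
#'
#' * `comparison_scaled` — the desk-scale four-intervention comparison: 1,000
#'   equilibrium females, 26 weekly releases at ratios 200 eggs/adult (pgSIT,
#'   fsRIDL) and 10 adult males/adult (RIDL, IIT), 200-day horizon, 100
#'   stochastic realizations.
#' * `sweep_coarse` — a coarse 3x3 competitiveness x lifespan-reduction
#'   elimination sweep at small population size (200 females, 40
#'   realizations).
#' * `equilibrium_smoke` — no releases, 365 deterministic days at default
#'   parameters.
#'
#' @param name fixture name.
#' @return a scenario config list (see [simulate_scenario()]).
#' @export
gen_scenario_fixture <- function(name = c("comparison_scaled", "sweep_coarse",
                                          "equilibrium_smoke")) {
  name <- match.arg(name)
  switch(name,
    comparison_scaled = list(
      kind = "compare",
      life_history = list(N_F_eq = 10000),
      scale_factor = 0.1,
      horizon = 200,
      mode = "stochastic",
      realizations = 100,
      seed = 1L
    ),
    sweep_coarse = list(
      kind = "sweep",
      life_history = list(N_F_eq = 2000),
      scale_factor = 0.1,
      c_grid = c(0, 0.5, 1),
      lifespan_reduction_grid = c(0, 0.5, 0.8),
      egg_ratio = 200,
      horizon = 200,
      realizations = 40,
      seed = 1L
    ),
    equilibrium_smoke = list(
      kind = "simulate",
      system = "wild",
      life_history = list(),
      schedule = NULL,
      horizon = 365,
      mode = "deterministic",
      realizations = 1,
      seed = 1L
    )
  )
}

#' Read / write a scenario configuration
#'
#' Scenario configs are plain YAML documents with fields `kind`
#' (`simulate`, `compare` or `sweep`), `system`, `overrides`,
#' `life_history`, `schedule` (`ratio`, `period`, `n_releases`,
#' `start_day`, `baseline`), `horizon`, `mode`, `realizations`, `seed`, and
#' the sweep grids.
#'
#' @param path YAML file path.
#' @return the config list.
#' @export
read_scenario_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_scenario_config
#' @param config a scenario config list.
#' @export
write_scenario_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run a scenario configuration
#'
#' Dispatches on `config$kind`: `"simulate"` runs a single system (a
#' trajectory in deterministic mode, an [run_ensemble()] otherwise),
#' `"compare"` runs [compare_interventions()], `"sweep"` runs
#' [parameter_sweep()].
#'
#' @param config a scenario config list (see [gen_scenario_fixture()] for
#'   examples).
#' @return the corresponding result object.
#' @export
simulate_scenario <- function(config) {
  lh <- do.call(life_history, config$life_history %||% list())
  kind <- config$kind %||% "simulate"
  if (kind == "compare") {
    return(compare_interventions(
      scale_factor = config$scale_factor %||% 0.1,
      n_realizations = config$realizations %||% 100,
      horizon = config$horizon %||% 200,
      seed = config$seed %||% 1L,
      params = lh,
      mode = config$mode %||% "stochastic"
    ))
  }
  if (kind == "sweep") {
    return(parameter_sweep(
      c_grid = config$c_grid,
      lifespan_reduction_grid = config$lifespan_reduction_grid,
      egg_ratio = config$egg_ratio %||% 200,
      n_realizations = config$realizations %||% 40,
      scale_factor = config$scale_factor %||% 0.1,
      horizon = config$horizon %||% 200,
      seed = config$seed %||% 1L,
      params = lh
    ))
  }
  calib <- calibrate_equilibrium(lh)
  cube <- do.call(build_cube, c(list(system = config$system %||% "wild"),
                                config$overrides %||% list()))
  sched <- if (!is.null(config$schedule)) {
    do.call(release_schedule, c(list(cube = cube, calib = calib),
                                config$schedule))
  }
  mode <- config$mode %||% "deterministic"
  n_real <- config$realizations %||% 1
  if (mode == "deterministic" || n_real == 1) {
    run_simulation(calib, cube, sched, config$horizon %||% 365, mode,
                   seed = config$seed %||% 1L)
  } else {
    run_ensemble(calib, cube, sched, config$horizon %||% 365, n_real,
                 seed = config$seed %||% 1L, mode = mode)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
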