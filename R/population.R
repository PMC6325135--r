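# Daily-time-step, genotype-explicit, age-within-stage population dynamics
# with density-dependent larval mortality, one-mating female structure,
# release events and equilibrium calibration.  Deterministic and stochastic
# modes share one code path; stochastic draws replace expectations.

#' Life-history parameter set
#'
#' Constructs the parameter set for an *Aedes aegypti*-like population.
#' Defaults: `beta = 20` eggs per female per day, adult daily mortality
#' `mu_ad = 0.123`, stage durations `T_E = 5`, `T_L = 6`, `T_P = 4` days,
#' per-generation growth rate absent density dependence `Rm = 1.1`, and
#' `N_F_eq = 10000` adult females at equilibrium.  The juvenile
#' density-independent daily mortality `mu_aqua` (shared by eggs, larvae and
#' pupae) and the larval density-dependence scale `alpha` are left `NA` until
#' [calibrate_equilibrium()] fills them.
#'
#' @param beta eggs per female per day (> 0).
#' @param mu_ad adult daily mortality probability, in (0, 1).
#' @param T_E,T_L,T_P egg, larval and pupal stage durations in days (>= 1).
#' @param Rm per-generation growth rate in the absence of density dependence
#'   (> 1 for a viable population).
#' @param N_F_eq target equilibrium number of adult females (> 0).
#' @return an object of class `life_history`.
#' @export
life_history <- function(beta = 20, mu_ad = 0.123, T_E = 5, T_L = 6, T_P = 4,
                         Rm = 1.1, N_F_eq = 10000) {
  stopifnot(beta > 0, mu_ad > 0, mu_ad < 1, T_E >= 1, T_L >= 1, T_P >= 1,
            Rm > 1)
  if (N_F_eq <= 0) stop("N_F_eq must be positive")
  structure(
    list(beta = beta, mu_ad = mu_ad, T_E = as.integer(T_E),
         T_L = as.integer(T_L), T_P = as.integer(T_P), Rm = Rm,
         N_F_eq = N_F_eq, mu_aqua = NA_real_, alpha = NA_real_),
    class = "life_history"
  )
}

#' Calibrate juvenile mortality and larval density dependence to equilibrium
#'
#' Fills `mu_aqua` and `alpha` so that the deterministic wild-type model is
#' exactly stationary with `N_F_eq` adult females:
#'
#' 1. `mu_aqua` solves `(beta / (2 * mu_ad)) * (1 - mu_aqua)^(T_E+T_L+T_P) = Rm`,
#'    i.e. density-independent juvenile survival is set by the growth rate a
#'    female lineage would have absent density dependence.
#' 2. The Deredec-form larval survival factor `(alpha / (alpha + L))^(1/T_L)`
#'    is applied on each larval day; stationarity forces its per-stage product
#'    to cancel the growth excess, `alpha / (alpha + L_eq) = 1 / Rm`, hence
#'    `alpha = L_eq / (Rm - 1)` with `L_eq` the equilibrium larval total.
#'
#' @param params a [life_history()] object (with `mu_aqua`, `alpha` unset or
#'   ignored).
#' @return an object of class `sit_calibration`: a list with the completed
#'   `params` and the deterministic equilibrium quantities (`L_eq`, the
#'   per-age equilibrium cohort sizes, and the equilibrium adult totals).
#' @examples
#' cal <- calibrate_equilibrium(life_history(N_F_eq = 1000))
#' cal$params$mu_aqua
#' @export
calibrate_equilibrium <- function(params = life_history()) {
  stopifnot(inherits(params, "life_history"))
  q <- 2 * params$mu_ad * params$Rm / params$beta
  if (q > 1) {
    stop("no root for mu_aqua in (0,1): 2*mu_ad*Rm/beta = ", signif(q, 4),
         " exceeds 1 (parameters inconsistent)")
  }
  Tj <- params$T_E + params$T_L + params$T_P
  mu_aqua <- 1 - q^(1 / Tj)
  s <- 1 - mu_aqua
  f <- params$Rm^(-1 / params$T_L)  # equilibrium daily density-dependent factor
  NF <- params$N_F_eq
  B <- params$beta * NF                       # eggs laid per day
  egg_ages <- B * s^(0:(params$T_E - 1))
  larva_in <- B * s^params$T_E
  larva_ages <- larva_in * (s * f)^(0:(params$T_L - 1))
  pupa_in <- larva_in * (s * f)^params$T_L
  pupa_ages <- pupa_in * s^(0:(params$T_P - 1))
  L_eq <- sum(larva_ages)
  params$mu_aqua <- mu_aqua
  params$alpha <- L_eq / (params$Rm - 1)
  structure(
    list(params = params, L_eq = L_eq, egg_ages = egg_ages,
         larva_ages = larva_ages, pupa_ages = pupa_ages,
         N_F_eq = NF, N_M_eq = NF),
    class = "sit_calibration"
  )
}

#' @export
print.sit_calibration <- function(x, ...) {
  p <- x$params
  cat("Calibrated equilibrium:\n")
  cat(sprintf("  mu_aqua = %.6f, alpha = %.4g\n", p$mu_aqua, p$alpha))
  cat(sprintf("  adults: %.4g females + %.4g males; larvae: %.4g\n",
              x$N_F_eq, x$N_M_eq, x$L_eq))
  invisible(x)
}

#' Equilibrium population state for a cube
#'
#' Builds the pre-intervention deterministic equilibrium state laid out over
#' the cube's genotype:sex classes (intervention genotypes start at zero).
#' In stochastic mode counts are rounded to integers.
#'
#' @param calib a [calibrate_equilibrium()] result.
#' @param cube an `intervention_cube`.
#' @param mode `"deterministic"` (real counts) or `"stochastic"` (integer
#'   counts).
#' @return an object of class `population_state`.
#' @export
equilibrium_state <- function(calib, cube,
                              mode = c("deterministic", "stochastic")) {
  mode <- match.arg(mode)
  stopifnot(inherits(calib, "sit_calibration"),
            inherits(cube, "intervention_cube"))
  p <- calib$params
  cls <- cube$classes
  g <- cube$genotypes
  mk <- function(ages, Tn) {
    m <- matrix(0, length(cls), Tn, dimnames = list(cls, NULL))
    m[paste(WILD, SEXES, sep = ":"), ] <- rep(ages / 2, each = 2)
    m
  }
  eggs <- mk(calib$egg_ages, p$T_E)
  larvae <- mk(calib$larva_ages, p$T_L)
  pupae <- mk(calib$pupa_ages, p$T_P)
  males <- stats::setNames(numeric(length(g)), g)
  males[WILD] <- calib$N_M_eq
  mf <- matrix(0, length(g), length(g),
               dimnames = list(female = g, mate = g))
  mf[WILD, WILD] <- calib$N_F_eq
  unmated <- stats::setNames(numeric(length(g)), g)
  st <- structure(
    list(eggs = eggs, larvae = larvae, pupae = pupae, adult_males = males,
         mated_females = mf, unmated_females = unmated, day = 0L),
    class = "population_state"
  )
  if (mode == "stochastic") st <- round_state(st)
  st
}

round_state <- function(state) {
  state$eggs <- round(state$eggs)
  state$larvae <- round(state$larvae)
  state$pupae <- round(state$pupae)
  state$adult_males <- round(state$adult_males)
  state$mated_females <- round(state$mated_females)
  state$unmated_females <- round(state$unmated_females)
  state
}

state_total <- function(state) {
  sum(state$eggs) + sum(state$larvae) + sum(state$pupae) +
    sum(state$adult_males) + sum(state$mated_females) +
    sum(state$unmated_females)
}

#' Advance the population by one day
#'
#' Substeps, in order: (1) egg laying — each mated-female class lays
#' `beta * count * viable_egg_fraction` eggs (Poisson in stochastic mode),
#' distributed over offspring classes by the cube cross; (2) survival —
#' juveniles survive with probability `1 - mu_aqua`, larvae additionally with
#' the Deredec factor `(alpha / (alpha + L_total))^(1/T_L)` computed from the
#' day's total larval count, adults with `1 - omega * mu_ad` (clamped to
#' \[0, 1\]); (3) aging/promotion — final-age eggs hatch (classes with
#' `death_stage = "egg"` are removed here), final-age larvae pupate
#' (`"larva_exit"` classes removed after consuming larval resources),
#' final-age pupae emerge (`"pupa_exit"` classes removed); (4) mating — each
#' newly emerged female mates exactly once, choosing mate genotype `m` with
#' probability `c_m * M_m / sum_k c_k * M_k` over the current adult males, and
#' joins the mated pool permanently.  Females emerging when no (effective)
#' males are present remain in an unmated, non-laying class and re-attempt
#' mating daily.  Stochastic mode uses binomial draws for survival and
#' multinomial draws for mate choice and offspring classes.
#'
#' @param state a `population_state`.
#' @param params calibrated [life_history()] parameters.
#' @param cube an `intervention_cube` matching the state's class layout.
#' @param mode `"deterministic"` or `"stochastic"` (uses R's global RNG
#'   stream; seed it for reproducibility).
#' @param audit if `TRUE`, attach an `"audit"` attribute with birth/death/cull
#'   counters for conservation checks.
#' @return the successor `population_state`.
#' @export
step_population <- function(state, params, cube,
                            mode = c("deterministic", "stochastic"),
                            audit = FALSE) {
  mode <- match.arg(mode)
  stoch <- mode == "stochastic"
  cls <- cube$classes
  g <- cube$genotypes
  ds <- cube$death_stage

  # --- (1) egg laying ---------------------------------------------------
  eggs_new <- stats::setNames(numeric(length(cls)), cls)
  mf <- state$mated_females
  lay_idx <- which(mf > 0, arr.ind = TRUE)
  for (k in seq_len(nrow(lay_idx))) {
    fg <- lay_idx[k, 1]; mg <- lay_idx[k, 2]
    lam <- params$beta * mf[fg, mg] * cube$vef[fg, mg]
    if (lam <= 0) next
    pr <- cube$cross_probs[, fg, mg]
    if (stoch) {
      tot <- stats::rpois(1, lam)
      if (tot > 0) eggs_new <- eggs_new + drop(stats::rmultinom(1, tot, pr))
    } else {
      eggs_new <- eggs_new + lam * pr
    }
  }

  # --- (2) survival -----------------------------------------------------
  s_aq <- 1 - params$mu_aqua
  L_tot <- sum(state$larvae)
  f_dd <- if (L_tot > 0) {
    (params$alpha / (params$alpha + L_tot))^(1 / params$T_L)
  } else 1
  surv <- function(x, p) {
    if (stoch) {
      out <- x
      out[] <- stats::rbinom(length(x), as.vector(x), p)
      out
    } else x * p
  }
  eggs <- surv(state$eggs, s_aq)
  larvae <- surv(state$larvae, s_aq * f_dd)
  pupae <- surv(state$pupae, s_aq)
  juv_deaths <- sum(state$eggs) - sum(eggs) + sum(state$larvae) - sum(larvae) +
    sum(state$pupae) - sum(pupae)

  p_ad <- pmin(pmax(1 - cube$omega * params$mu_ad, 0), 1)  # per genotype
  males <- surv_named(state$adult_males, p_ad, stoch)
  mated <- state$mated_females
  for (fg in seq_along(g)) {
    mated[fg, ] <- if (stoch) {
      stats::rbinom(length(g), as.vector(state$mated_females[fg, ]), p_ad[fg])
    } else state$mated_females[fg, ] * p_ad[fg]
  }
  unmated <- surv_named(state$unmated_females, p_ad, stoch)
  adult_deaths <- sum(state$adult_males) - sum(males) +
    sum(state$mated_females) - sum(mated) +
    sum(state$unmated_females) - sum(unmated)

  # --- (3) aging / promotion -------------------------------------------
  hatch <- eggs[, params$T_E]
  cull_egg <- sum(hatch[ds == "egg"])
  hatch[ds == "egg"] <- 0
  eggs <- cbind(eggs_new, eggs[, -params$T_E, drop = FALSE], deparse.level = 0)

  pupate <- larvae[, params$T_L]
  cull_larva <- sum(pupate[ds == "larva_exit"])
  pupate[ds == "larva_exit"] <- 0
  larvae <- cbind(hatch, larvae[, -params$T_L, drop = FALSE], deparse.level = 0)

  emerge <- pupae[, params$T_P]
  cull_pupa <- sum(emerge[ds == "pupa_exit"])
  emerge[ds == "pupa_exit"] <- 0
  pupae <- cbind(pupate, pupae[, -params$T_P, drop = FALSE], deparse.level = 0)

  is_f <- class_sex(cls) == "f"
  new_males <- tapply_sum(emerge[!is_f], class_genotype(cls[!is_f]), g)
  new_females <- tapply_sum(emerge[is_f], class_genotype(cls[is_f]), g)
  males <- males + new_males

  # --- (4) mating -------------------------------------------------------
  pool <- new_females + unmated
  unmated <- stats::setNames(numeric(length(g)), g)
  w <- cube$mating_c * males
  if (sum(w) > 0) {
    pw <- w / sum(w)
    for (fg in seq_along(g)) {
      n <- pool[fg]
      if (n <= 0) next
      mated[fg, ] <- mated[fg, ] + if (stoch) {
        drop(stats::rmultinom(1, n, pw))
      } else n * pw
    }
  } else {
    unmated <- pool
  }

  out <- structure(
    list(eggs = eggs, larvae = larvae, pupae = pupae, adult_males = males,
         mated_females = mated, unmated_females = unmated,
         day = state$day + 1L),
    class = "population_state"
  )
  if (audit) {
    attr(out, "audit") <- list(
      births = sum(eggs_new),
      deaths_juvenile = juv_deaths,
      deaths_adult = adult_deaths,
      culled = cull_egg + cull_larva + cull_pupa
    )
  }
  out
}

surv_named <- function(x, p, stoch) {
  out <- if (stoch) stats::rbinom(length(x), as.vector(x), p) else x * p
  stats::setNames(out, names(x))
}

tapply_sum <- function(x, by, levels) {
  out <- stats::setNames(numeric(length(levels)), levels)
  s <- tapply(x, by, sum)
  out[names(s)] <- s
  out
}

#' Release event
#'
#' @param day day of release (>= 1).
#' @param genotype released genotype.
#' @param stage `"egg"` or `"adult_male"`.
#' @param size number of individuals released (>= 0).
#' @return a one-row data.frame; rbind events into a schedule.
#' @export
release_event <- function(day, genotype, stage, size) {
  stopifnot(day >= 1, size >= 0, stage %in% c("egg", "adult_male"))
  data.frame(day = as.integer(day), genotype = genotype, stage = stage,
             size = size, stringsAsFactors = FALSE)
}

#' Build a periodic release schedule
#'
#' Event sizes follow the field convention of a ratio of released individuals
#' per wild adult; the baseline adult count is the pre-intervention
#' equilibrium total (males + females, i.e. `2 * N_F_eq`) fixed for all
#' events, or females only with `baseline = "females"`.
#'
#' @param cube an `intervention_cube`; supplies release genotype and stage.
#' @param calib a [calibrate_equilibrium()] result.
#' @param ratio released individuals per wild adult (e.g. 10 adult males per
#'   adult, or 200 eggs per adult).
#' @param period days between releases (default 7, weekly).
#' @param n_releases number of release events (default 26, a 6-month program).
#' @param start_day day of the first release.
#' @param baseline `"total"` (males + females) or `"females"`.
#' @return a `release_schedule` data.frame of events.
#' @export
release_schedule <- function(cube, calib, ratio, period = 7, n_releases = 26,
                             start_day = 1, baseline = c("total", "females")) {
  baseline <- match.arg(baseline)
  stopifnot(ratio >= 0, period >= 1, n_releases >= 0)
  adults <- if (baseline == "total") calib$N_F_eq + calib$N_M_eq else calib$N_F_eq
  size <- round(ratio * adults)
  days <- start_day + period * seq_len(n_releases) - period
  ev <- do.call(rbind, lapply(days, release_event,
                              genotype = cube$release_genotype,
                              stage = cube$release_stage, size = size))
  if (is.null(ev)) ev <- release_event(1, cube$release_genotype,
                                       cube$release_stage, 0)[0, ]
  class(ev) <- c("release_schedule", class(ev))
  ev
}

#' Apply one release event to a state
#'
#' Adult-male releases add `size` to the genotype's adult male count; egg
#' releases add `size` eggs at age 1, split 1:1 by sex (the cube's
#' `death_stage` labels then govern the fate of each sex class).
#'
#' @param state a `population_state`.
#' @param event a one-row event (see [release_event()]).
#' @param cube the `intervention_cube` in force.
#' @return the updated state.
#' @export
apply_release <- function(state, event, cube) {
  if (!event$genotype %in% cube$genotypes) {
    stop("release genotype '", event$genotype, "' not in cube '", cube$name, "'")
  }
  if (event$stage != cube$release_stage) {
    stop("release stage '", event$stage, "' does not match cube release stage '",
         cube$release_stage, "'")
  }
  if (event$stage == "adult_male") {
    state$adult_males[event$genotype] <- state$adult_males[event$genotype] + event$size
  } else {
    # 1:1 sex split; floor/ceiling keeps stochastic-mode counts integral
    half_f <- floor(event$size / 2)
    half_m <- event$size - half_f
    state$eggs[paste0(event$genotype, ":f"), 1] <-
      state$eggs[paste0(event$genotype, ":f"), 1] + half_f
    state$eggs[paste0(event$genotype, ":m"), 1] <-
      state$eggs[paste0(event$genotype, ":m"), 1] + half_m
  }
  state
}

# Classes whose individuals count as "reproducing" for the elimination
# criterion: fertile females (death_stage none) and males of fertile
# genotypes.  Wild type qualifies on both counts.
reproducing_mask <- function(cube) {
  cls <- cube$classes
  sex <- class_sex(cls)
  gt <- class_genotype(cls)
  fem_ok <- sex == "f" & cube$death_stage[cls] == "none"
  male_ok <- sex == "m" & cube$fertile_male[gt] & cube$death_stage[cls] == "none"
  stats::setNames(fem_ok | male_ok, cls)
}

reproducing_total <- function(state, cube, mask = reproducing_mask(cube)) {
  fertile_g <- cube$genotypes[cube$fertile_male[cube$genotypes]]
  sum(state$eggs[mask, ]) + sum(state$larvae[mask, ]) +
    sum(state$pupae[mask, ]) + sum(state$adult_males[fertile_g]) +
    sum(state$mated_females) + sum(state$unmated_females)
}

#' Run a simulation
#'
#' Iterates [step_population()] from the calibrated equilibrium for `horizon`
#' days, applying scheduled releases at the end of their day (so released
#' eggs sit at age 1 overnight and released adult males join the mating pool
#' from the next day).  In stochastic mode, `elimination_day` is set to the
#' first day on which no reproducing individuals remain at any stage —
#' fertile females (wild-type or otherwise) and males of fertile genotypes,
#' including their juvenile stages.
#'
#' @param calib a [calibrate_equilibrium()] result.
#' @param cube an `intervention_cube`.
#' @param schedule a `release_schedule` (or `NULL` for no intervention).
#' @param horizon number of days to simulate (>= 1).
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed integer seed used in stochastic mode.
#' @return an object of class `sit_trajectory`: per-day adult female, adult
#'   male and larval totals by genotype (day 0 = initial state), plus
#'   `elimination_day` (`NA` if never eliminated or deterministic mode).
#' @export
run_simulation <- function(calib, cube, schedule = NULL, horizon,
                           mode = c("deterministic", "stochastic"),
                           seed = NULL) {
  mode <- match.arg(mode)
  if (horizon < 1) stop("horizon must be >= 1")
  if (mode == "stochastic" && !is.null(seed)) set.seed(seed)
  params <- calib$params
  if (is.na(params$mu_aqua) || is.na(params$alpha)) {
    stop("params are not calibrated; run calibrate_equilibrium() first")
  }
  state <- equilibrium_state(calib, cube, mode)
  g <- cube$genotypes
  nd <- horizon + 1
  females <- males <- larvae <- matrix(
    0, nd, length(g), dimnames = list(NULL, g))
  mask <- reproducing_mask(cube)
  record <- function(i, st) {
    females[i, ] <<- rowSums(st$mated_females) + st$unmated_females
    males[i, ] <<- st$adult_males
    lv <- rowSums(st$larvae)
    larvae[i, ] <<- tapply_sum(lv, class_genotype(names(lv)), g)
  }
  record(1, state)
  has_sched <- !is.null(schedule) && nrow(schedule) > 0
  elim <- NA_integer_
  for (d in seq_len(horizon)) {
    state <- step_population(state, params, cube, mode)
    if (has_sched) {
      ev <- schedule[schedule$day == d, , drop = FALSE]
      for (k in seq_len(nrow(ev))) state <- apply_release(state, ev[k, ], cube)
    }
    record(d + 1, state)
    if (mode == "stochastic" && is.na(elim) &&
        reproducing_total(state, cube, mask) == 0) {
      elim <- d
    }
  }
  structure(
    list(day = 0:horizon, females = females, males = males, larvae = larvae,
         elimination_day = elim, genotypes = g, mode = mode,
         system = cube$name),
    class = "sit_trajectory"
  )
}

#' Tidy a trajectory into a long data.frame
#'
#' @param x a `sit_trajectory`.
#' @param ... unused.
#' @return a data.frame with columns day, genotype, stage
#'   (`adult_female` / `adult_male` / `larva`) and count.
#' @export
as.data.frame.sit_trajectory <- function(x, ...) {
  long <- function(m, stage) {
    data.frame(day = rep(x$day, times = ncol(m)),
               genotype = rep(colnames(m), each = nrow(m)),
               stage = stage, count = as.vector(m),
               stringsAsFactors = FALSE)
  }
  rbind(long(x$females, "adult_female"), long(x$males, "adult_male"),
        long(x$larvae, "larva"))
}

#' @export
print.sit_trajectory <- function(x, ...) {
  cat("Trajectory (", x$mode, ", system '", x$system, "', ",
      length(x$day) - 1, " days)\n", sep = "")
  cat("  final adult females:", signif(sum(x$females[nrow(x$females), ]), 5), "\n")
  if (!is.na(x$elimination_day)) {
    cat("  eliminated on day", x$elimination_day, "\n")
  }
  invisible(x)
}

#' Total adult females per day
#'
#' @param traj a `sit_trajectory`.
#' @return numeric vector, one entry per recorded day (day 0 first).
#' @export
adult_females <- function(traj) rowSums(traj$females)

#' Write a trajectory to a tidy CSV file
#'
#' @param traj a `sit_trajectory`.
#' @param path output file path.
#' @param realization optional realization index column.
#' @export
write_trajectory_csv <- function(traj, path, realization = NA_integer_) {
  df <- as.data.frame(traj)
  df$realization <- realization
  utils::write.csv(df[, c("day", "realization", "genotype", "stage", "count")],
                   path, row.names = FALSE)
}
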