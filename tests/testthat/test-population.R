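test_that("calibration closed forms hold at the boundary and defaults", {
  # 2*mu_ad*Rm/beta = 1 forces mu_aqua = 0
  p <- life_history(beta = 2 * 0.2 * 1.5, mu_ad = 0.2, Rm = 1.5, N_F_eq = 100)
  expect_equal(calibrate_equilibrium(p)$params$mu_aqua, 0)
  # inconsistent parameters have no root in (0,1)
  expect_error(calibrate_equilibrium(life_history(beta = 0.1, Rm = 2)),
               "no root")
  expect_error(life_history(N_F_eq = 0), "positive")
  cal <- calibrate_equilibrium(life_history())
  with(cal$params, expect_equal((beta / (2 * mu_ad)) * (1 - mu_aqua)^(T_E + T_L + T_P),
                                Rm, tolerance = 1e-12))
  expect_gt(cal$params$alpha, 0)
})

test_that("the calibrated state is a deterministic fixed point", {
  cal <- small_calibration()
  cube <- build_cube("wild")
  st <- equilibrium_state(cal, cube)
  nxt <- step_population(st, cal$params, cube)
  for (field in c("eggs", "larvae", "pupae", "adult_males", "mated_females")) {
    expect_equal(nxt[[field]], st[[field]], tolerance = 1e-12, label = field)
  }
})

test_that("without egg laying, adults decay geometrically and juveniles drain", {
  cal <- small_calibration(100)
  p <- cal$params
  p$beta <- 0
  cube <- build_cube("wild")
  st <- equilibrium_state(cal, cube)
  horizon <- p$T_E + p$T_L + p$T_P
  st2 <- st
  for (d in seq_len(horizon)) st2 <- step_population(st2, p, cube)
  expect_equal(sum(st2$eggs) + sum(st2$larvae) + sum(st2$pupae), 0)
  # adults: survivors of the initial cohort plus surviving juvenile emergents,
  # all decaying at (1 - mu_ad) afterwards
  m0 <- sum(st2$adult_males)
  st3 <- step_population(st2, p, cube)
  expect_equal(sum(st3$adult_males), m0 * (1 - p$mu_ad), tolerance = 1e-12)
})

test_that("identical seeds give identical stochastic successors and runs", {
  cal <- small_calibration()
  cube <- build_cube("pgsit")
  sched <- release_schedule(cube, cal, ratio = 50, n_releases = 4)
  t1 <- run_simulation(cal, cube, sched, 60, "stochastic", seed = 99)
  t2 <- run_simulation(cal, cube, sched, 60, "stochastic", seed = 99)
  expect_identical(t1$females, t2$females)
  expect_identical(t1$larvae, t2$larvae)
  st <- equilibrium_state(cal, cube, "stochastic")
  set.seed(5); a <- step_population(st, cal$params, cube, "stochastic")
  set.seed(5); b <- step_population(st, cal$params, cube, "stochastic")
  expect_identical(a, b)
})

test_that("individuals are conserved through each step (audit counters)", {
  cal <- small_calibration()
  cube <- build_cube("fsridl")
  st <- equilibrium_state(cal, cube, "stochastic")
  ev <- release_event(1, "RR", "egg", 20000)
  st <- apply_release(st, ev, cube)
  set.seed(31)
  for (d in 1:25) {
    before <- sum(st$eggs) + sum(st$larvae) + sum(st$pupae) +
      sum(st$adult_males) + sum(st$mated_females) + sum(st$unmated_females)
    st <- step_population(st, cal$params, cube, "stochastic", audit = TRUE)
    au <- attr(st, "audit")
    after <- sum(st$eggs) + sum(st$larvae) + sum(st$pupae) +
      sum(st$adult_males) + sum(st$mated_females) + sum(st$unmated_females)
    expect_equal(after,
                 before + au$births - au$deaths_juvenile - au$deaths_adult -
                   au$culled,
                 tolerance = 1e-9)
  }
})

test_that("mated females never re-mate: mate-genotype marginal is invariant", {
  cal <- small_calibration()
  cube <- build_cube("iit")
  st <- equilibrium_state(cal, cube)
  # empty the juvenile stages so there is no emergence inflow
  st$eggs[] <- 0; st$larvae[] <- 0; st$pupae[] <- 0
  st$adult_males["II"] <- 5000
  st1 <- step_population(st, cal$params, cube)
  marg0 <- colSums(st$mated_females)
  marg1 <- colSums(st1$mated_females)
  expect_equal(marg1, marg0 * (1 - cal$params$mu_ad), tolerance = 1e-12)
})

test_that("females emerging with no males wait unmated and mate when males return", {
  cal <- small_calibration(100)
  cube <- build_cube("wild")
  st <- equilibrium_state(cal, cube)
  st$adult_males[] <- 0
  st$mated_females[] <- 0
  st$pupae["WW:m", ] <- 0  # no males emerge either
  st1 <- step_population(st, cal$params, cube)
  expect_gt(sum(st1$unmated_females), 0)
  expect_equal(sum(st1$mated_females), 0)
  st1$adult_males["WW"] <- 50
  st1$pupae[] <- 0  # isolate the re-attempt path
  st2 <- step_population(st1, cal$params, cube)
  expect_equal(sum(st2$unmated_females), 0)
  expect_equal(sum(st2$mated_females),
               sum(st1$unmated_females) * (1 - cal$params$mu_ad),
               tolerance = 1e-12)
})

test_that("release events modify exactly the targeted class", {
  cal <- small_calibration()
  cube <- build_cube("iit")
  st <- equilibrium_state(cal, cube)
  st2 <- apply_release(st, release_event(1, "II", "adult_male", 200000), cube)
  expect_equal(unname(st2$adult_males["II"] - st$adult_males["II"]), 200000)
  pg <- build_cube("pgsit")
  stp <- equilibrium_state(cal, pg)
  stp2 <- apply_release(stp, release_event(1, "PG", "egg", 1000), pg)
  expect_equal(unname(stp2$eggs["PG:f", 1]), 500)
  expect_equal(unname(stp2$eggs["PG:m", 1]), 500)
  expect_error(apply_release(st, release_event(1, "II", "egg", 10), cube),
               "stage")
  expect_error(apply_release(st, release_event(1, "PG", "adult_male", 10), cube),
               "not in cube")
})

test_that("release sizing follows the per-wild-adult convention", {
  cal <- small_calibration(1000)  # 1000 females + 1000 males at equilibrium
  cube <- build_cube("ridl")
  sched <- release_schedule(cube, cal, ratio = 10)
  expect_equal(nrow(sched), 26)
  expect_true(all(sched$size == 10 * 2000))
  expect_equal(sched$day, seq(1, by = 7, length.out = 26))
  sched_f <- release_schedule(cube, cal, ratio = 10, baseline = "females")
  expect_true(all(sched_f$size == 10 * 1000))
})

test_that("zero-competitiveness released males leave the wild population untouched", {
  cal <- small_calibration()
  # adult-male release isolates the mating channel from larval competition
  cube <- build_cube("pgsit", c_male = 0, release_stage = "adult_male")
  sched <- release_schedule(cube, cal, ratio = 10, n_releases = 8)
  base <- run_simulation(cal, build_cube("wild"), NULL, 80, "deterministic")
  trt <- run_simulation(cal, cube, sched, 80, "deterministic")
  expect_equal(trt$females[, "WW"], base$females[, "WW"], tolerance = 1e-12)
  expect_equal(trt$larvae[, "WW"], base$larvae[, "WW"], tolerance = 1e-12)
})

test_that("bigger releases never leave more wild females at day 180", {
  cal <- small_calibration(200)
  cube <- build_cube("pgsit")
  day180 <- vapply(c(0, 50, 200), function(ratio) {
    sched <- if (ratio > 0) release_schedule(cube, cal, ratio = ratio) else NULL
    tr <- run_simulation(cal, cube, sched, 180, "deterministic")
    adult_females(tr)[181]
  }, 0)
  expect_true(all(diff(day180) <= 1e-9))
})

test_that("stronger density dependence scale supports more larvae", {
  a1 <- calibrate_equilibrium(life_history(N_F_eq = 1000))
  a2 <- calibrate_equilibrium(life_history(N_F_eq = 2000))
  expect_gt(a2$params$alpha, a1$params$alpha)
  expect_gt(a2$L_eq, a1$L_eq)
})

test_that("trajectories tidy into long data frames", {
  cal <- small_calibration(100)
  tr <- run_simulation(cal, build_cube("wild"), NULL, 10, "deterministic")
  df <- as.data.frame(tr)
  expect_setequal(names(df), c("day", "genotype", "stage", "count"))
  expect_equal(nrow(df), 11 * 1 * 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path, realization = 1)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), nrow(df))
})
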