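test_that("a single-realization ensemble is that realization", {
  cal <- small_calibration(200)
  cube <- build_cube("pgsit")
  sched <- release_schedule(cube, cal, ratio = 200, n_releases = 8)
  ens <- run_ensemble(cal, cube, sched, 80, n_realizations = 1, seed = 5,
                      keep_trajectories = TRUE)
  tr <- run_simulation(cal, cube, sched, 80, "stochastic",
                       seed = sitsim:::realization_seed(5, 1))
  expect_equal(ens$mean, adult_females(tr))
  expect_equal(ens$mean, ens$median)
  expect_true(ens$elimination_probability %in% c(0, 1))
  expect_error(run_ensemble(cal, cube, sched, 80, n_realizations = 0),
               "n_realizations")
})

test_that("ensembles are reproducible and recomputable from raw trajectories", {
  cal <- small_calibration(200)
  cube <- build_cube("iit")
  sched <- release_schedule(cube, cal, ratio = 10, n_releases = 6)
  e1 <- run_ensemble(cal, cube, sched, 60, 10, seed = 3,
                     keep_trajectories = TRUE)
  e2 <- run_ensemble(cal, cube, sched, 60, 10, seed = 3)
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$elimination_probability, e2$elimination_probability)
  # summaries recompute bit-identically from the persisted matrix
  re <- summarize_ensemble(e1$trajectories, e1$elimination_days, 60,
                           system = e1$system, seed = e1$seed)
  for (f in c("mean", "median", "q025", "q975", "elimination_probability")) {
    expect_identical(re[[f]], e1[[f]], label = f)
  }
  expect_true(all(e1$q025 <= e1$median & e1$median <= e1$q975))
})

test_that("stochastic ensemble mean tracks the deterministic trajectory", {
  cal <- small_calibration(500)
  cube <- build_cube("wild")
  det <- adult_females(run_simulation(cal, cube, NULL, 100, "deterministic"))
  ens <- run_ensemble(cal, cube, NULL, 100, n_realizations = 50, seed = 7,
                      keep_trajectories = TRUE)
  mc_se <- apply(ens$trajectories, 2, stats::sd) / sqrt(ens$n_realizations)
  expect_true(all(abs(ens$mean - det) <= 3 * pmax(mc_se, 1e-9) + 1))
})

test_that("elimination bookkeeping matches the trajectories", {
  cal <- small_calibration(50)
  cube <- build_cube("pgsit")
  sched <- release_schedule(cube, cal, ratio = 400, n_releases = 12)
  ens <- run_ensemble(cal, cube, sched, 150, 12, seed = 2,
                      keep_trajectories = TRUE)
  expect_equal(ens$elimination_probability,
               mean(!is.na(ens$elimination_days)))
  done <- !is.na(ens$elimination_days)
  if (any(done)) {
    expect_equal(ens$mean_time_to_elimination,
                 mean(ens$elimination_days[done]))
    # after elimination the recorded female count stays at zero
    for (i in which(done)) {
      expect_true(all(ens$trajectories[i, (ens$elimination_days[i] + 1):151] == 0))
    }
  }
})

test_that("egg releases suppress wild recruitment even with unmating males", {
  # zero-competitiveness released males never mate, but their larvae still
  # crowd the habitat and depress wild survival
  cal <- small_calibration(200)
  cube <- build_cube("pgsit", c_male = 0)
  sched <- release_schedule(cube, cal, ratio = 200, n_releases = 12)
  trt <- run_simulation(cal, cube, sched, 120, "deterministic")
  base <- run_simulation(cal, build_cube("wild"), NULL, 120, "deterministic")
  expect_lt(adult_females(trt)[121], 0.9 * adult_females(base)[121])
})

test_that("sweep handles degenerate grids and rejects infinite hazards", {
  expect_error(parameter_sweep(c(0.5), c(1)), "infinite")
  cal_tiny <- life_history(N_F_eq = 300)
  # egg_ratio = 0 is the no-intervention baseline in every cell
  ep0 <- parameter_sweep(c(0, 1), c(0), egg_ratio = 0, n_realizations = 3,
                         scale_factor = 1, horizon = 30, seed = 9,
                         params = cal_tiny)
  expect_true(all(ep0 == ep0[1, 1]))
})

test_that("halving the egg ratio never helps elimination beyond MC noise", {
  ep <- vapply(c(100, 200), function(ratio) {
    parameter_sweep(c(0.78), c(0), egg_ratio = ratio, n_realizations = 30,
                    scale_factor = 1, horizon = 200, seed = 6,
                    params = life_history(N_F_eq = 200))[1, 1]
  }, 0)
  expect_gte(ep[2], ep[1] - 0.2)  # ~2 SE of a difference at n = 30
})

test_that("a sterile population is eliminated in every realization", {
  cal <- small_calibration(50)
  cal$params$beta <- 0  # no reproduction at all
  ens <- run_ensemble(cal, build_cube("wild"), NULL, 250, 5, seed = 4)
  expect_equal(ens$elimination_probability, 1)
  expect_true(all(ens$mean[251] == 0))
})

test_that("comparison assembles the full-scale configuration without running it", {
  cfg <- compare_interventions(full_scale = TRUE, run = FALSE)
  expect_equal(cfg$n_realizations, 2000)
  expect_equal(cfg$calib$N_F_eq, 10000)
  expect_equal(unname(cfg$ratios[c("pgsit", "fsridl", "ridl", "iit")]),
               c(200, 200, 10, 10))
  expect_error(compare_interventions(scale_factor = 0), "scale_factor")
  expect_error(compare_interventions(n_realizations = 0, run = TRUE,
                                     scale_factor = 0.01), "realizations")
})
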