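test_that("distance series reports the planted per-frame separations", {
  traj <- toy_two_frame_traj(c(2, 6))
  ser <- distance_series(traj, 1, 2)
  expect_equal(ser$dist_A, c(2, 6))
  expect_equal(ser$time_ps, c(0, 100))
  expect_error(distance_series(traj, 1, 99), "out of range")

  static <- toy_two_frame_traj(c(3, 3, 3, 3))
  expect_equal(distance_series(static, 1, 2)$dist_A, rep(3, 4))
})

test_that("interval_mean averages the frames inside the window", {
  const <- toy_two_frame_traj(rep(3, 11))
  ser <- distance_series(const, 1, 2)
  expect_equal(interval_mean(ser, 0, 1000), 3)
  expect_equal(interval_mean(ser, 123, 456), 3)

  two <- toy_two_frame_traj(c(2, 4))
  ser2 <- distance_series(two, 1, 2)
  expect_equal(interval_mean(ser2, 0, 1000), 3)

  expect_error(interval_mean(ser2, 500, 100), "t0 < t1")
  expect_error(interval_mean(ser2, 5000, 6000), "no frames")
})

test_that("interval_mean of concatenated windows is their frame-weighted mean", {
  set.seed(12)
  vals <- runif(40, 2, 6)
  traj <- toy_two_frame_traj(vals)
  ser <- distance_series(traj, 1, 2)
  t <- ser$time_ps
  m1 <- interval_mean(ser, t[1], t[15])
  m2 <- interval_mean(ser, t[16], t[40])
  whole <- interval_mean(ser, t[1], t[40])
  expect_equal(whole, (15 * m1 + 25 * m2) / 40, tolerance = 1e-12)
})

test_that("residence time is the end of the initial below-cutoff run", {
  stays <- distance_series(toy_two_frame_traj(rep(3.5, 5)), 1, 2)
  expect_equal(residence_time(stays), 400)

  out_first <- distance_series(toy_two_frame_traj(c(5, 3, 3)), 1, 2)
  expect_equal(residence_time(out_first), 0)

  escapes <- distance_series(toy_two_frame_traj(c(3, 3, 3, 5, 3, 5)), 1, 2)
  expect_equal(residence_time(escapes), 200)   # no re-entry credit
  runs <- residence_runs(escapes)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$t_start, c(0, 400))
  expect_equal(runs$n_frames, c(3, 1))
})

test_that("residence time is monotone non-decreasing in the cutoff", {
  set.seed(9)
  traj <- make_trajectory(tether_params(n_frames = 400, escape_time = 250,
                                        seed = 33), make_active_site(0, 0, seed = 33))
  ser <- distance_series(traj, trajectory_atom(traj, 198, "P"),
                         trajectory_atom(traj, 900, "F"))
  cuts <- seq(2.5, 8, by = 0.5)
  res <- vapply(cuts, function(ct) residence_time(ser, ct), 1.0)
  expect_true(all(diff(res) >= 0))
})

test_that("hydration counting sees planted near waters only", {
  site <- make_active_site(3, 2, seed = 42)
  ion <- select_atom(site, 900, "F")
  expect_equal(hydration_count(site, ion), 3L)
  expect_equal(hydration_count(site, ion, cutoff = 10), 5L)

  dry <- make_active_site(0, 5, seed = 1)
  expect_equal(hydration_count(dry, select_atom(dry, 900, "F")), 0L)
  none <- dry[dry$resname != "HOH", ]
  expect_equal(hydration_count(none, select_atom(none, 900, "F")), 0L)
})

test_that("multi-model PDB trajectories round trip through disk", {
  site <- make_active_site(2, 1, seed = 4)
  traj <- make_trajectory(tether_params(n_frames = 25, escape_time = 20,
                                        seed = 4), site)
  f <- tempfile(fileext = ".pdb")
  write_trajectory(traj, f)
  back <- read_trajectory(f, dt = 1)
  expect_equal(dim(back), dim(traj))
  expect_lt(max(abs(back$coords - traj$coords)), 1e-3)
  ser0 <- distance_series(traj, trajectory_atom(traj, 198, "P"),
                          trajectory_atom(traj, 900, "F"))
  ser1 <- distance_series(back, trajectory_atom(back, 198, "P"),
                          trajectory_atom(back, 900, "F"))
  expect_equal(ser1$dist_A, ser0$dist_A, tolerance = 1e-3)
})

test_that("analyze_trajectory bundles the per-trajectory observables", {
  site <- make_active_site(2, 1, seed = 6)
  traj <- make_trajectory(tether_params(n_frames = 300, escape_time = 200,
                                        tether_sd = 0, seed = 6), site)
  res <- analyze_trajectory(traj, trajectory_atom(traj, 198, "P"),
                            trajectory_atom(traj, 900, "F"), t0 = 0, t1 = 200)
  expect_equal(res$mean_dist, 3, tolerance = 1e-9)
  expect_equal(res$residence_ps, 200)
  expect_equal(res$hydration, 2L)
  expect_gte(nrow(res$runs), 1)
})
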