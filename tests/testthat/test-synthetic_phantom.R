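test_that("phantom landmarks realize the requested metrics exactly", {
  spec <- phantom_spec(seed = 1, plan_angle_deg = 130.03, plan_width_mm = 93.28,
                       undercorrection_deg = 6.31, undercorrection_mm = 3.27)
  case <- make_phantom(spec)
  plan <- measure_craniometry(case$landmarks_plan, "plan")
  expect_equal(plan$interfrontal_angle, 130.03, tolerance = 1e-6)
  expect_equal(plan$transverse_width, 93.28, tolerance = 1e-6)
  post <- measure_craniometry(case$landmarks_postop, "postop")
  err <- outcome_error(plan, post)
  expect_equal(unname(err["angle_error_deg"]), 6.31, tolerance = 1e-6)
  expect_equal(unname(err["width_error_mm"]), 3.27, tolerance = 1e-6)
})

test_that("same seed gives a bit-identical case; spec validation works", {
  a <- make_phantom(phantom_spec(seed = 77))
  b <- make_phantom(phantom_spec(seed = 77))
  expect_identical(a$preop_mesh$vertices, b$preop_mesh$vertices)
  expect_identical(a$guide_points$points, b$guide_points$points)
  sa <- simulate_session(a)
  sb <- simulate_session(b)
  expect_identical(sa$session$primary$rmse, sb$session$primary$rmse)
  expect_identical(sa$scan$vertices, sb$scan$vertices)
  expect_error(phantom_spec(plan_angle_deg = 200), "0, 180")
  expect_error(phantom_spec(tracking_noise_sigma_mm = -1), ">= 0")
  expect_error(phantom_spec(n_pins = 2), "at least 3")
  expect_error(phantom_spec(motion_schedule = data.frame(
    after_repetition = 99L, trans_mm = 1, rot_deg = 1)), "nonexistent")
  # infeasible geometry: angle too acute for the vault scale
  expect_error(make_phantom(phantom_spec(plan_angle_deg = 12, preop_angle_deg = 100)),
               "infeasible")
})

test_that("guide points lie on the preop surface; pins posterior to it", {
  case <- make_phantom(phantom_spec(seed = 2))
  d <- point_to_mesh_distance(case$guide_points, case$preop_mesh)
  expect_lt(max(d), 1e-9)
  # pins sit on healthy bone, posterior to the remodeled frontal region
  expect_lt(max(case$pins$points[, 2]), min(case$guide_points$points[, 2]))
  front <- case$postop_mesh$region %in% c("frontal", "supraorbital")
  fy <- min(case$postop_mesh$vertices[front, 2])
  expect_true(all(case$pins$points[, 2] < fy))
  expect_equal(case$guide_points$labels, paste0("G", 1:6))
  expect_equal(case$pins$labels, paste0("P", 1:6))
})

test_that("simulate_tracked_points: exact at sigma 0, calibrated at sigma 0.5", {
  set.seed(13)
  pts <- random_landmarks(10)
  tf <- random_transform()
  exact <- simulate_tracked_points(pts, tf, sigma = 0, seed = 1)
  expect_equal(exact$points, rt_apply(tf, pts$points), tolerance = 1e-12)
  expect_identical(exact$frame, "tracker")
  big <- landmark_set(paste0("N", 1:10000), matrix(0, 10000, 3))
  noisy <- simulate_tracked_points(big, rt_identity(), sigma = 0.5, seed = 5)
  sds <- apply(noisy$points, 2, sd)
  expect_true(all(abs(sds - 0.5) / 0.5 < 0.02))
  # different seeds: different noise, same distribution
  n2 <- simulate_tracked_points(big, rt_identity(), sigma = 0.5, seed = 6)
  expect_false(identical(noisy$points, n2$points))
  expect_true(all(abs(apply(n2$points, 2, sd) - 0.5) / 0.5 < 0.02))
  expect_error(simulate_tracked_points(pts, tf, sigma = -0.1, seed = 1), ">= 0")
})

test_that("noiseless motion-free session: all RMSE and navigation error zero", {
  case <- make_phantom(quiet_spec(seed = 14))
  sim <- simulate_session(case)
  expect_lt(sim$session$primary$rmse, 1e-9)
  expect_lt(max(vapply(sim$session$secondaries, `[[`, 0, "rmse")), 1e-9)
  ne <- navigation_error(sim$session, sim$scan, sim$scan_pins)
  expect_lt(ne$summaries$pooled$mean, 1e-6)
})

test_that("uncorrected terminal motion inflates the error; re-registration
           restores the noise floor", {
  sigma <- 0.5
  base_mean <- mean(vapply(1:3, function(s) {
    spec <- quiet_spec(seed = 500 + s, sigma = sigma)
    sim <- simulate_session(make_phantom(spec))
    navigation_error(sim$session, sim$scan, sim$scan_pins)$summaries$pooled$mean
  }, numeric(1)))
  # motion after the last secondary is never corrected
  uncorr <- mean(vapply(1:3, function(s) {
    spec <- phantom_spec(seed = 500 + s, tracking_noise_sigma_mm = sigma,
                         n_secondary = 3L, n_recorded_points = 40L,
                         motion_schedule = data.frame(after_repetition = 3L,
                                                      trans_mm = 8, rot_deg = 5))
    sim <- simulate_session(make_phantom(spec))
    navigation_error(sim$session, sim$scan, sim$scan_pins)$summaries$pooled$mean
  }, numeric(1)))
  # same motion one repetition earlier is corrected by the next secondary
  corr <- mean(vapply(1:3, function(s) {
    spec <- phantom_spec(seed = 500 + s, tracking_noise_sigma_mm = sigma,
                         n_secondary = 3L, n_recorded_points = 40L,
                         motion_schedule = data.frame(after_repetition = 2L,
                                                      trans_mm = 8, rot_deg = 5))
    sim <- simulate_session(make_phantom(spec))
    navigation_error(sim$session, sim$scan, sim$scan_pins)$summaries$pooled$mean
  }, numeric(1)))
  expect_gt(uncorr, 3 * corr)
  expect_lt(corr, 1.5 * base_mean)
})

test_that("case directory round trip preserves the analysis", {
  spec <- quiet_spec(seed = 15, sigma = 0.4)
  case <- make_phantom(spec)
  sim <- simulate_session(case)
  dir <- withr::local_tempdir()
  write_case(case, sim, dir)
  back <- read_case(dir)
  expect_equal(back$session$primary$rmse, sim$session$primary$rmse,
               tolerance = 1e-9)
  expect_equal(vapply(back$session$secondaries, `[[`, 0, "rmse"),
               vapply(sim$session$secondaries, `[[`, 0, "rmse"),
               tolerance = 1e-9)
  ne0 <- navigation_error(sim$session, sim$scan, sim$scan_pins)
  ne1 <- navigation_error(back$session, back$scan, back$scan_pins)
  # scan went through float32 OBJ text; tolerance reflects format precision
  expect_equal(ne1$summaries$pooled$mean, ne0$summaries$pooled$mean,
               tolerance = 1e-4)
})
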