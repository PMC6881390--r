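test_that("fit_rigid recovers known transforms exactly on noiseless data", {
  set.seed(1)
  # fixed example: 30 degrees about z, translation (5, -2, 1)
  src <- random_landmarks(6)
  tf <- rt_axis_angle(c(0, 0, 1), 30, c(5, -2, 1))
  fit <- fit_rigid(src, transform_landmarks(src, tf, "tracker"))
  expect_lt(max(abs(fit$transform$rotation - tf$rotation)), 1e-9)
  expect_lt(max(abs(fit$transform$translation - tf$translation)), 1e-9)
  expect_lt(fit$rmse, 1e-9)
  # property: arbitrary proper rigid maps, >= 3 non-collinear points
  for (i in 1:25) {
    n <- sample(3:10, 1)
    src <- random_landmarks(n)
    tf <- random_transform()
    fit <- fit_rigid(src, transform_landmarks(src, tf, "tracker"))
    expect_lt(max(abs(fit$transform$rotation - tf$rotation)), 1e-9)
    expect_lt(fit$rmse, 1e-9)
  }
})

test_that("identity case: source equals target", {
  src <- landmark_set(paste0("F", 1:4),
                      rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)))
  fit <- fit_rigid(src, src)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$rmse, 0, tolerance = 1e-12)
  expect_equal(fit$n_fiducials, 4L)
})

test_that("degenerate and mismatched inputs error informatively", {
  two <- landmark_set(c("A", "B"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(fit_rigid(two, two), "label-matched")
  line <- landmark_set(c("A", "B", "C", "D"),
                       cbind(1:4, 2 * (1:4), -1 * (1:4)))
  expect_error(fit_rigid(line, line), "collinear")
  a <- random_landmarks(5, prefix = "A")
  b <- random_landmarks(5, prefix = "B")
  expect_error(fit_rigid(a, b), "A1|unmatched")
})

test_that("rmse is invariant under a common extra rigid transform", {
  set.seed(2)
  src <- random_landmarks(6)
  tgt <- landmark_set(src$labels, src$points + matrix(rnorm(18, sd = 0.5), ncol = 3),
                      "tracker")
  base <- fit_rigid(src, tgt)$rmse
  for (i in 1:10) {
    extra <- random_transform()
    moved <- fit_rigid(transform_landmarks(src, extra),
                       transform_landmarks(tgt, extra))$rmse
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("no reflection: determinant +1 on near-planar mirror-symmetric noise", {
  set.seed(3)
  for (i in 1:50) {
    # nearly coplanar source, targets perturbed mirror-symmetrically
    p <- cbind(rnorm(6, sd = 30), rnorm(6, sd = 30), rnorm(6, sd = 1e-6))
    src <- landmark_set(paste0("F", 1:6), p)
    tgt <- landmark_set(paste0("F", 1:6),
                        p * cbind(1, 1, sample(c(-1, 1), 6, TRUE)) +
                          matrix(rnorm(18, sd = 0.3), ncol = 3))
    fit <- fit_rigid(src, tgt)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("expected squared FRE matches the closed form 3*sigma^2*(1 - 2/N)", {
  # Monte-Carlo oracle: N = 6 fiducials, sigma = 0.5 mm, 2000 reps
  set.seed(20)
  N <- 6
  sigma <- 0.5
  fre2 <- replicate(2000, {
    src <- random_landmarks(N)
    tgt <- landmark_set(src$labels,
                        src$points + matrix(rnorm(3 * N, sd = sigma), ncol = 3),
                        "tracker")
    fit_rigid(src, tgt)$rmse^2
  })
  expected <- 3 * sigma^2 * (1 - 2 / N)
  expect_lt(abs(mean(fre2) - expected) / expected, 0.05)
})

test_that("session bookkeeping: primary, pin reference, repeated secondaries", {
  set.seed(4)
  guides <- random_landmarks(6, prefix = "G")
  pins <- random_landmarks(6, prefix = "P")
  t0 <- random_transform(max_rot = 20)
  ses <- navigation_session("case-A")
  expect_error(register_secondary(ses, pins), "no primary")
  ses <- register_primary(ses, guides, transform_landmarks(guides, t0, "tracker"))
  expect_identical(ses$primary$step, "primary")
  expect_identical(ses$primary$repetition_index, 1L)
  expect_lt(ses$primary$rmse, 1e-9)
  ses <- record_pin_reference(ses, transform_landmarks(pins, t0, "tracker"))
  # pin reference maps back into the image frame exactly (no noise)
  expect_equal(ses$pins_reference$points, pins$points, tolerance = 1e-9)
  # three secondaries under drifting motion: indices 2, 3, 4; motion recovered
  t_true <- t0
  for (k in 1:3) {
    m <- rt_axis_angle(rnorm(3), runif(1, -5, 5), runif(3, -4, 4))
    t_true <- rt_compose(m, t_true)
    ses <- register_secondary(ses, transform_landmarks(pins, t_true, "tracker"))
    res <- ses$secondaries[[k]]
    expect_identical(res$step, "secondary")
    expect_identical(res$repetition_index, k + 1L)
    expect_lt(res$rmse, 1e-9)
    expect_lt(max(abs(res$transform$rotation - t_true$rotation)), 1e-9)
    pts <- landmark_set("q", matrix(rnorm(3), 1, 3), "tracker")
    ses <- record_points(ses, pts, region = "frontal")
    expect_identical(ses$recorded_points[[k]]$stamp, k)
  }
})

test_that("summarize_sessions pools with repetition-count weighting", {
  set.seed(5)
  mk <- function(id, n_sec) {
    g <- random_landmarks(6, prefix = "G")
    p <- random_landmarks(6, prefix = "P")
    t0 <- random_transform(max_rot = 10)
    s <- navigation_session(id)
    s <- register_primary(s, g, simulate_tracked_points(g, t0, 0.5, seed = id))
    s <- record_pin_reference(s, simulate_tracked_points(p, t0, 0.5, seed = id + 50))
    for (k in seq_len(n_sec)) {
      s <- register_secondary(s, simulate_tracked_points(p, t0, 0.5, seed = id * 100 + k))
    }
    s
  }
  sessions <- list(mk(1, 2), mk(2, 5))
  tab <- summarize_sessions(sessions)
  expect_equal(nrow(tab), 3L)
  per <- tab[tab$case != "Avg.", ]
  avg <- tab[tab$case == "Avg.", ]
  expect_equal(avg$primary_rmse_mm, mean(per$primary_rmse_mm), tolerance = 1e-12)
  expect_equal(avg$secondary_rmse_mean_mm,
               sum(per$n_secondary * per$secondary_rmse_mean_mm) / sum(per$n_secondary),
               tolerance = 1e-12)
  expect_equal(avg$n_secondary, 7L)
  # single case: pooled values equal that case's values
  one <- summarize_sessions(list(mk(3, 1)))
  expect_equal(one$secondary_rmse_mean_mm[1], one$secondary_rmse_mean_mm[2],
               tolerance = 1e-12)
  expect_error(summarize_sessions(list()), "no sessions")
})

test_that("registration result satisfies its own invariants", {
  set.seed(6)
  src <- random_landmarks(6)
  tgt <- landmark_set(src$labels, src$points + matrix(rnorm(18, sd = 1), ncol = 3))
  fit <- fit_rigid(src, tgt)
  expect_equal(fit$rmse, sqrt(mean(fit$residuals^2)), tolerance = 1e-12)
  expect_equal(fit$n_fiducials, length(fit$residuals))
  expect_gte(fit$n_fiducials, 3L)
})
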