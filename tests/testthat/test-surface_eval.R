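test_that("point-triangle distance handles vertex, edge and interior regions", {
  big <- triangle_mesh(rbind(c(-10, -10, 0), c(10, -10, 0), c(0, 10, 0)),
                       rbind(c(1, 2, 3)))
  # coincident with a vertex
  expect_equal(point_to_mesh_distance(c(-10, -10, 0), big), 0, tolerance = 1e-12)
  # 2 mm along the normal above the interior
  expect_equal(point_to_mesh_distance(c(0, 0, 2), big), 2, tolerance = 1e-12)
  # beyond an edge: closest point is on the edge segment
  expect_equal(point_to_mesh_distance(c(0, -11, 0), big), 1, tolerance = 1e-12)
  # beyond a vertex: closest point is the vertex
  expect_equal(point_to_mesh_distance(c(0, 13, 4), big), 5, tolerance = 1e-12)
})

test_that("accelerated query equals brute force on random meshes", {
  set.seed(8)
  for (rep in 1:3) {
    mesh <- random_soup(200, scale = 15)
    pts <- matrix(rnorm(1500, sd = 20), ncol = 3)
    d_fast <- point_to_mesh_distance(pts, mesh)
    d_brute <- point_to_mesh_distance(pts, mesh, method = "brute")
    expect_lt(max(abs(d_fast - d_brute)), 1e-9)
  }
})

test_that("distances are invariant under a common rigid transform", {
  set.seed(9)
  mesh <- random_soup(80)
  pts <- matrix(rnorm(90, sd = 20), ncol = 3)
  base <- point_to_mesh_distance(pts, mesh)
  for (i in 1:5) {
    tf <- random_transform()
    moved <- point_to_mesh_distance(rt_apply(tf, pts), transform_mesh(mesh, tf))
    expect_equal(moved, base, tolerance = 1e-9)
  }
})

test_that("register_scan recovers a known scan displacement", {
  set.seed(10)
  pins <- random_landmarks(6, prefix = "P")
  expect_equal(register_scan(pins, pins)$rotation, diag(3), tolerance = 1e-9)
  tf <- random_transform()
  moved <- transform_landmarks(pins, tf, "scan")
  rec <- register_scan(moved, pins)
  expect_lt(max(abs(rec$rotation - rt_invert(tf)$rotation)), 1e-9)
  two <- landmark_set(c("P1", "P2"), pins$points[1:2, ])
  expect_error(register_scan(two, two), "label-matched")
})

test_that("error_summary statistics are ordered and exact", {
  d <- c(0.2, 0.9, 0.1, 0.4, 0.7)
  s <- error_summary(d, "frontal")
  expect_equal(s$mean, mean(d), tolerance = 1e-12)
  expect_equal(s$q3, unname(quantile(d, 0.75, type = 7)), tolerance = 1e-12)
  expect_true(s$q1 <= s$median && s$median <= s$q3 && s$q3 <= s$max)
  expect_error(error_summary(c(-1, 1)), "non-negative")
})

test_that("navigation error is zero for exact recordings and 0.5 mm for a
           normal offset", {
  spec <- quiet_spec(seed = 21)
  case <- make_phantom(spec)
  sim <- simulate_session(case)
  ne <- navigation_error(sim$session, sim$scan, sim$scan_pins)
  expect_lt(ne$summaries$pooled$mean, 1e-6)
  expect_lt(ne$summaries$pooled$q3, 1e-6)
  expect_error(navigation_error(navigation_session("x"), sim$scan, sim$scan_pins),
               "no recorded")

  # displace recorded points 0.5 mm along local (offset) directions: since the
  # recordings lie exactly on the surface, adding 0.5 mm along the outward
  # vertex normal direction of a convex region gives distance 0.5 within a
  # small flatness tolerance; use the analytic plane fixture for exactness
  tri <- triangle_mesh(rbind(c(-50, -50, 0), c(50, -50, 0), c(0, 80, 0)),
                       rbind(c(1, 2, 3)))
  pts <- cbind(runif(50, -10, 10), runif(50, -10, 10), 0.5)
  expect_equal(point_to_mesh_distance(pts, tri), rep(0.5, 50), tolerance = 1e-6)
})

test_that("pooled mean equals the point-count-weighted mean of region means", {
  spec <- quiet_spec(seed = 22, sigma = 0.5)
  case <- make_phantom(spec)
  sim <- simulate_session(case)
  ne <- navigation_error(sim$session, sim$scan, sim$scan_pins)
  regs <- setdiff(names(ne$summaries), "pooled")
  w <- vapply(ne$summaries[regs], `[[`, 0, "n_points")
  m <- vapply(ne$summaries[regs], `[[`, 0, "mean")
  expect_equal(ne$summaries$pooled$mean, sum(w * m) / sum(w), tolerance = 1e-12)
  expect_equal(ne$summaries$pooled$n_points, sum(w))
})

test_that("pooled error is monotone non-decreasing in tracking noise", {
  means <- vapply(c(0.2, 0.8, 2.0), function(sig) {
    mean(vapply(1:3, function(s) {
      spec <- quiet_spec(seed = 400 + s, sigma = sig)
      case <- make_phantom(spec)
      sim <- simulate_session(case)
      navigation_error(sim$session, sim$scan, sim$scan_pins)$summaries$pooled$mean
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})
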