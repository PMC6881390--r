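### Synthetic skull phantom: deformed half-ellipsoid-like cranial vault with a
### wedge-shaped forehead whose dihedral realizes a target interfrontal angle.
### Anatomical realism is not a goal; metric realism (landmark geometry,
### surface distances, registration regime) is.

# evaluate expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# deterministic child seed
child_seed <- function(seed, k) as.integer((as.double(seed) * 127 + k * 9973) %% 2147483647)

#' Specification of a synthetic surgical case
#'
#' Defaults mirror the published operating regime: six guide points and six
#' pins, planned interfrontal angles around 130-144 degrees with
#' preoperative values 20-30 degrees lower, about ten secondary
#' re-registrations per surgery, a postoperative undercorrection equal to
#' the reported mean outcome error (3.63 degrees, 1.89 mm), and a tracking
#' noise sigma of 0.65 mm per axis so that six-fiducial registration RMSE
#' (approximately sigma * sqrt(2) for N = 6) falls in the reported
#' 0.6-1.3 mm band.
#'
#' @param seed integer RNG seed; the whole case is deterministic given it.
#' @param plan_angle_deg planned (target) interfrontal angle, degrees.
#' @param plan_width_mm planned transverse forehead width, mm.
#' @param preop_angle_deg preoperative interfrontal angle, degrees.
#' @param preop_width_mm preoperative width, mm.
#' @param undercorrection_deg postop angle = plan angle - this, degrees >= 0.
#' @param undercorrection_mm postop width = plan width - this, mm >= 0.
#' @param tracking_noise_sigma_mm isotropic tracking noise SD per axis, mm.
#' @param n_guide_points number of surgical-guide fiducials (>= 3).
#' @param n_pins number of resorbable pins (>= 3).
#' @param n_secondary number of secondary registrations.
#' @param motion_schedule `data.frame(after_repetition, trans_mm, rot_deg)`;
#'   head-motion events applied after the given secondary repetition
#'   (0 = after the primary, `n_secondary` = after the last one, hence
#'   uncorrected).
#' @param n_recorded_points points recorded per region on the remodeled bone.
#' @param subdivisions icosphere subdivision level of the phantom meshes.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L,
                         plan_angle_deg = 135,
                         plan_width_mm = 92,
                         preop_angle_deg = plan_angle_deg - 25,
                         preop_width_mm = plan_width_mm - 8,
                         undercorrection_deg = 3.63,
                         undercorrection_mm = 1.89,
                         tracking_noise_sigma_mm = 0.65,
                         n_guide_points = 6L,
                         n_pins = 6L,
                         n_secondary = 10L,
                         motion_schedule = data.frame(after_repetition = c(3L, 7L),
                                                      trans_mm = c(5, 5),
                                                      rot_deg = c(3, 3)),
                         n_recorded_points = 100L,
                         subdivisions = 3L) {
  chk_angle <- function(a, what) {
    if (!is.finite(a) || a <= 0 || a >= 180) stop(what, " must lie in (0, 180)")
  }
  chk_angle(plan_angle_deg, "plan angle")
  chk_angle(preop_angle_deg, "preop angle")
  chk_angle(plan_angle_deg - undercorrection_deg, "postop angle")
  if (undercorrection_deg < 0 || undercorrection_mm < 0) {
    stop("undercorrection must be >= 0")
  }
  if (tracking_noise_sigma_mm < 0) stop("tracking noise sigma must be >= 0")
  if (n_guide_points < 3L || n_pins < 3L) stop("need at least 3 fiducials")
  if (plan_width_mm - undercorrection_mm <= 0 || preop_width_mm <= 0) {
    stop("widths must stay positive")
  }
  if (!is.data.frame(motion_schedule) ||
      !all(c("after_repetition", "trans_mm", "rot_deg") %in% names(motion_schedule))) {
    stop("motion_schedule must have columns after_repetition, trans_mm, rot_deg")
  }
  if (nrow(motion_schedule) &&
      (any(motion_schedule$after_repetition < 0L) ||
       any(motion_schedule$after_repetition > n_secondary))) {
    stop("motion_schedule references a nonexistent repetition (valid: 0..",
         n_secondary, ")")
  }
  structure(list(seed = as.integer(seed),
                 plan_angle_deg = plan_angle_deg, plan_width_mm = plan_width_mm,
                 preop_angle_deg = preop_angle_deg, preop_width_mm = preop_width_mm,
                 undercorrection_deg = undercorrection_deg,
                 undercorrection_mm = undercorrection_mm,
                 tracking_noise_sigma_mm = tracking_noise_sigma_mm,
                 n_guide_points = as.integer(n_guide_points),
                 n_pins = as.integer(n_pins),
                 n_secondary = as.integer(n_secondary),
                 motion_schedule = motion_schedule,
                 n_recorded_points = as.integer(n_recorded_points),
                 subdivisions = as.integer(subdivisions)),
            class = "phantom_spec")
}

# unit icosphere: subdivided icosahedron, vertices on the unit sphere
icosphere <- function(subdivisions = 3L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "|")
    mids <- new.env()
    midpoint <- function(i, j) {
      k <- edge_key(i, j)
      id <- mids[[k]]
      if (is.null(id)) {
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        v <<- rbind(v, m)
        id <- nrow(v)
        mids[[k]] <- id
      }
      id
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c3 <- f[t, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  list(vertices = v, faces = f)
}

# craniometric landmarks realizing an exact angle/width: symmetric wedge in
# the axial plane z = z0, apex (MSL) anterior on the midline
wedge_landmarks <- function(angle_deg, width_mm, apex_y, z0, frame = "image") {
  half <- width_mm / 2
  d <- half / tan(angle_deg / 2 * pi / 180)
  landmark_set(c("LFL", "RFL", "MSL"),
               rbind(c(-half, apex_y - d, z0),
                     c(half, apex_y - d, z0),
                     c(0, apex_y, z0)),
               frame = frame)
}

# vault mesh: scaled icosphere clamped against the two vertical wedge planes
# through the MSL apex line
vault_mesh <- function(angle_deg, width_mm, radii, apex_y, base, subdivisions) {
  half <- width_mm / 2
  d <- half / tan(angle_deg / 2 * pi / 180)
  if (half >= radii[1] * 0.98 || d >= radii[2] * 0.9 || apex_y - d <= 0) {
    stop(sprintf(paste0("infeasible phantom geometry: width %.1f mm / angle ",
                        "%.1f deg incompatible with vault radii (%.0f, %.0f, %.0f) mm"),
                 width_mm, angle_deg, radii[1], radii[2], radii[3]))
  }
  ico <- base
  v <- sweep(ico$vertices, 2L, radii, "*")
  apex <- c(0, apex_y)
  # left wedge plane: contains the vertical apex line and the LFL edge
  for (sgn in c(-1, 1)) {
    dir <- c(sgn * half, -d)
    n <- c(-dir[2], dir[1]) * sgn     # outward normal in the axial plane
    n <- n / sqrt(sum(n^2))
    off <- (v[, 1] - apex[1]) * n[1] + (v[, 2] - apex[2]) * n[2]
    out <- off > 0
    v[out, 1] <- v[out, 1] - off[out] * n[1]
    v[out, 2] <- v[out, 2] - off[out] * n[2]
  }
  v
}

#' Generate a complete synthetic surgical case
#'
#' Builds preoperative, planned and postoperative-scan meshes whose
#' constructed LFL/RFL/MSL landmarks realize the requested interfrontal
#' angles and widths exactly, places guide fiducials on the preoperative
#' surface and pin fiducials on posterior ("healthy") bone, and tags
#' frontal / supraorbital regions on the postoperative mesh. Deterministic
#' for a given seed.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `synthetic_case`: meshes (`preop_mesh`,
#'   `plan_mesh`, `postop_mesh`), landmark sets (`guide_points`, `pins`,
#'   `landmarks_preop`, `landmarks_plan`, `landmarks_postop`, all image
#'   frame) and the originating `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$plan_width_mm
  radii <- c(0.65, 0.80, 0.60) * w
  apex_y <- 0.92 * radii[2]
  z0 <- 0.25 * radii[3]
  base <- icosphere(spec$subdivisions)
  postop_angle <- spec$plan_angle_deg - spec$undercorrection_deg
  postop_width <- spec$plan_width_mm - spec$undercorrection_mm
  stages <- list(
    preop = list(a = spec$preop_angle_deg, w = spec$preop_width_mm),
    plan = list(a = spec$plan_angle_deg, w = spec$plan_width_mm),
    postop = list(a = postop_angle, w = postop_width))
  meshes <- lapply(stages, function(s) {
    triangle_mesh(vault_mesh(s$a, s$w, radii, apex_y, base, spec$subdivisions),
                  base$faces)
  })
  lms <- lapply(names(stages), function(nm) {
    s <- stages[[nm]]
    wedge_landmarks(s$a, s$w, apex_y, z0, frame = "image")
  })
  names(lms) <- names(stages)
  # region tags on the postop (scanned) mesh
  pv <- meshes$postop$vertices
  region <- rep(NA_character_, nrow(pv))
  front <- pv[, 2] > 0.35 * radii[2]
  region[front & pv[, 3] > 0.35 * radii[3]] <- "frontal"
  region[front & pv[, 3] > 0.05 * radii[3] & pv[, 3] <= 0.35 * radii[3]] <- "supraorbital"
  meshes$postop <- triangle_mesh(pv, meshes$postop$faces, region)
  # guide points: preop-surface vertices nearest to prescribed frontal
  # directions; pins: posterior/lateral vertices, away from the osteotomy
  nearest_vertex <- function(verts, dirs) {
    vn <- verts / sqrt(rowSums(verts^2))
    vapply(seq_len(nrow(dirs)), function(i) {
      d <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
      which.max(vn %*% d)
    }, integer(1))
  }
  gdirs <- with_seed(child_seed(spec$seed, 1L), {
    az <- seq(-0.9, 0.9, length.out = spec$n_guide_points) +
      stats::runif(spec$n_guide_points, -0.05, 0.05)
    cbind(sin(az), cos(az) * 0.9, stats::runif(spec$n_guide_points, 0.25, 0.7))
  })
  pdirs <- with_seed(child_seed(spec$seed, 2L), {
    az <- pi + seq(-1.2, 1.2, length.out = spec$n_pins) +
      stats::runif(spec$n_pins, -0.05, 0.05)
    cbind(sin(az), cos(az), stats::runif(spec$n_pins, 0.1, 0.4))
  })
  gidx <- nearest_vertex(meshes$preop$vertices, gdirs)
  pidx <- nearest_vertex(meshes$preop$vertices, pdirs)
  guide_points <- landmark_set(paste0("G", seq_len(spec$n_guide_points)),
                               meshes$preop$vertices[gidx, , drop = FALSE], "image")
  pins <- landmark_set(paste0("P", seq_len(spec$n_pins)),
                       meshes$preop$vertices[pidx, , drop = FALSE], "image")
  structure(list(preop_mesh = meshes$preop, plan_mesh = meshes$plan,
                 postop_mesh = meshes$postop,
                 guide_points = guide_points, pins = pins,
                 landmarks_preop = lms$preop, landmarks_plan = lms$plan,
                 landmarks_postop = lms$postop,
                 spec = spec),
            class = "synthetic_case")
}

#' Simulate tracked pointer recordings
#'
#' Maps true image-frame points into the tracker frame with the true
#' transform and adds iid isotropic Gaussian localization noise
#' (`sigma` mm per axis). Deterministic per seed.
#'
#' @param true_points image-frame [landmark_set()].
#' @param true_transform [rigid_transform()] image -> tracker.
#' @param sigma noise SD per axis, mm (>= 0).
#' @param seed integer seed.
#' @return tracker-frame [landmark_set()].
#' @export
simulate_tracked_points <- function(true_points, true_transform, sigma, seed) {
  stopifnot(inherits(true_points, "landmark_set"))
  if (sigma < 0) stop("sigma must be >= 0")
  p <- rt_apply(true_transform, true_points$points)
  if (sigma > 0) {
    p <- p + with_seed(seed, matrix(stats::rnorm(length(p), sd = sigma), ncol = 3L))
  }
  landmark_set(true_points$labels, p, frame = "tracker")
}

# random proper rigid transform with bounded magnitude
random_rigid <- function(max_trans_mm, max_rot_deg) {
  ax <- stats::rnorm(3)
  rt_axis_angle(ax, stats::runif(1, -max_rot_deg, max_rot_deg),
                stats::runif(3, -max_trans_mm, max_trans_mm))
}

# sample points uniformly on region-tagged triangles of a mesh
sample_surface_points <- function(mesh, region, n, prefix) {
  tag <- mesh$region
  if (is.null(tag)) stop("mesh has no region tags")
  f <- mesh$faces
  ok <- !is.na(tag[f[, 1]]) & tag[f[, 1]] == region &
    !is.na(tag[f[, 2]]) & tag[f[, 2]] == region &
    !is.na(tag[f[, 3]]) & tag[f[, 3]] == region
  if (!any(ok)) stop("no triangles fully inside region '", region, "'")
  fs <- f[ok, , drop = FALSE]
  v1 <- mesh$vertices[fs[, 1], , drop = FALSE]
  v2 <- mesh$vertices[fs[, 2], , drop = FALSE]
  v3 <- mesh$vertices[fs[, 3], , drop = FALSE]
  area <- sqrt(rowSums(cross3(v2 - v1, v3 - v1)^2)) / 2
  tri <- sample.int(nrow(fs), n, replace = TRUE, prob = area)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  a <- 1 - r1
  b <- r1 * (1 - r2)
  c3 <- r1 * r2
  pts <- a * v1[tri, , drop = FALSE] + b * v2[tri, , drop = FALSE] +
    c3 * v3[tri, , drop = FALSE]
  landmark_set(paste0(prefix, seq_len(n)), pts, frame = "image")
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Simulate a full navigated surgery on a synthetic case
#'
#' Reproduces the intraoperative procedure order: primary registration on
#' the guide points, one-time recording of the pin reference under the
#' primary, repeated secondary registrations interleaved with scheduled
#' rigid head-motion events, recording of outcome points on the remodeled
#' (postoperative) bone surface, and a simulated surface scan of the
#' postoperative anatomy with pin landmarks identified on it.
#'
#' @param case a [make_phantom()] result.
#' @param spec optional [phantom_spec()] override (defaults to `case$spec`).
#' @return list: `session` ([navigation_session()]), `scan`
#'   ([triangle_mesh()], scan frame), `scan_pins` (scan frame), and ground
#'   truth (`truth`): true image->tracker transforms over time, true
#'   image-frame recorded points, and the scan-frame transform.
#' @export
simulate_session <- function(case, spec = case$spec) {
  stopifnot(inherits(case, "synthetic_case"), inherits(spec, "phantom_spec"))
  sig <- spec$tracking_noise_sigma_mm
  sched <- spec$motion_schedule
  t_hist <- list()
  with_seed(child_seed(spec$seed, 3L), {
    t_true <- random_rigid(150, 25)          # initial patient pose in tracker
    t_hist[[1]] <- t_true
    session <- navigation_session(sprintf("phantom-%d", spec$seed))
    guide_tracker <- simulate_tracked_points(case$guide_points, t_true, sig,
                                             child_seed(spec$seed, 10L))
    session <- register_primary(session, case$guide_points, guide_tracker)
    pins_tracker0 <- simulate_tracked_points(case$pins, t_true, sig,
                                             child_seed(spec$seed, 11L))
    session <- record_pin_reference(session, pins_tracker0)
    apply_motion <- function(after_rep) {
      hit <- which(sched$after_repetition == after_rep)
      for (h in hit) {
        m <- random_rigid(sched$trans_mm[h], sched$rot_deg[h])
        t_true <<- rt_compose(m, t_true)
        t_hist[[length(t_hist) + 1L]] <<- t_true
      }
    }
    for (rep_i in seq_len(spec$n_secondary)) {
      apply_motion(rep_i - 1L)
      pins_tracker <- simulate_tracked_points(case$pins, t_true, sig,
                                              child_seed(spec$seed, 100L + rep_i))
      session <- register_secondary(session, pins_tracker)
    }
    apply_motion(spec$n_secondary)           # uncorrected terminal motion, if any
    true_pts <- list()
    for (rg in c("frontal", "supraorbital")) {
      tp <- sample_surface_points(case$postop_mesh, rg, spec$n_recorded_points,
                                  prefix = substr(rg, 1, 1))
      true_pts[[rg]] <- tp
      rec <- simulate_tracked_points(tp, t_true, sig,
                                     child_seed(spec$seed, 200L + nchar(rg)))
      session <- record_points(session, rec, rg)
    }
    scan_tf <- random_rigid(80, 20)          # scan device frame
    scan <- transform_mesh(case$postop_mesh, scan_tf)
    scan_pins <- transform_landmarks(case$pins, scan_tf, frame = "scan")
    list(session = session, scan = scan, scan_pins = scan_pins,
         truth = list(transforms = t_hist, final_transform = t_true,
                      recorded_points = true_pts, scan_transform = scan_tf))
  })
}
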