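# shared fixtures: tiny meshes and landmark generators, all built in code

unit_tetrahedron <- function() {
  triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                rbind(c(1, 3, 2), c(1, 2, 4), c(1, 4, 3), c(2, 3, 4)))
}

# axis-aligned unit cube surface, consistently wound (12 triangles)
cube_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
             c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  f <- rbind(c(1, 3, 2), c(1, 4, 3),   # bottom
             c(5, 6, 7), c(5, 7, 8),   # top
             c(1, 2, 6), c(1, 6, 5),   # front
             c(2, 3, 7), c(2, 7, 6),   # right
             c(3, 4, 8), c(3, 8, 7),   # back
             c(4, 1, 5), c(4, 5, 8))   # left
  triangle_mesh(v, f)
}

icosahedron_mesh <- function(radius = 1) {
  ico <- crannav:::icosphere(0L)
  triangle_mesh(ico$vertices * radius, ico$faces)
}

# random non-degenerate landmark set
random_landmarks <- function(n = 6, scale = 40, prefix = "F", frame = "image") {
  landmark_set(paste0(prefix, seq_len(n)),
               matrix(stats::rnorm(3 * n, sd = scale), ncol = 3), frame)
}

random_transform <- function(max_trans = 100, max_rot = 180) {
  rt_axis_angle(stats::rnorm(3), stats::runif(1, -max_rot, max_rot),
                stats::runif(3, -max_trans, max_trans))
}

# random triangle soup (no shared topology needed for distance tests)
random_soup <- function(n_faces = 200, scale = 20) {
  v <- matrix(stats::rnorm(9 * n_faces, sd = scale), ncol = 3)
  triangle_mesh(v, matrix(seq_len(3 * n_faces), ncol = 3, byrow = TRUE))
}

# quiet phantom defaults for tests: no motion unless asked
quiet_spec <- function(seed = 1L, sigma = 0, ...) {
  phantom_spec(seed = seed, tracking_noise_sigma_mm = sigma,
               motion_schedule = data.frame(after_repetition = integer(),
                                            trans_mm = numeric(),
                                            rot_deg = numeric()),
               n_secondary = 3L, n_recorded_points = 40L, ...)
}
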