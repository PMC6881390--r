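#' Exact distance from one point to many triangles
#'
#' Region-exact point-triangle distance (interior / edge / vertex Voronoi
#' regions all handled), vectorized over triangles. Used both by the
#' brute-force reference path and by the pruned accelerated query.
#'
#' @param p length-3 point.
#' @param v1,v2,v3 T x 3 matrices of triangle corners.
#' @return numeric vector of T unsigned distances (mm).
#' @keywords internal
dist_point_triangles <- function(p, v1, v2, v3) {
  # Eberly-style: minimize |B + s E0 + t E1 - p|^2 over the unit triangle
  E0 <- v2 - v1
  E1 <- v3 - v1
  D <- sweep(-v1, 2L, p, "+")        # p - v1, per triangle (negated below)
  a <- rowSums(E0 * E0)
  b <- rowSums(E0 * E1)
  c <- rowSums(E1 * E1)
  d <- -rowSums(E0 * D)
  e <- -rowSums(E1 * D)
  det <- pmax(a * c - b * b, .Machine$double.xmin)
  s <- b * e - c * d
  t <- b * d - a * e
  # classify and clamp region by region (vectorized with logical masks)
  inside <- s + t <= det & s >= 0 & t >= 0
  s_out <- numeric(length(a))
  t_out <- numeric(length(a))
  # region 0: interior
  i <- inside
  s_out[i] <- s[i] / det[i]
  t_out[i] <- t[i] / det[i]
  # outside: minimize on the boundary; use closed-form edge minimizations
  o <- !inside
  if (any(o)) {
    # candidate minima on each of the 3 edges, take the best
    clamp01 <- function(x) pmin(pmax(x, 0), 1)
    # edge v1-v2: t = 0, s = clamp(-d/a)
    s1 <- clamp01(-d[o] / pmax(a[o], .Machine$double.xmin))
    q1 <- a[o] * s1 * s1 + 2 * d[o] * s1
    # edge v1-v3: s = 0, t = clamp(-e/c)
    t2 <- clamp01(-e[o] / pmax(c[o], .Machine$double.xmin))
    q2 <- c[o] * t2 * t2 + 2 * e[o] * t2
    # edge v2-v3: t = 1 - s; minimizer s = (c + e - b - d) / (a - 2b + c)
    numer <- c[o] + e[o] - b[o] - d[o]
    denom <- pmax(a[o] - 2 * b[o] + c[o], .Machine$double.xmin)
    s3 <- clamp01(numer / denom)
    t3 <- 1 - s3
    q3 <- a[o] * s3 * s3 + c[o] * t3 * t3 + 2 * b[o] * s3 * t3 +
      2 * d[o] * s3 + 2 * e[o] * t3
    best <- pmin(q1, q2, q3)
    so <- ifelse(q1 <= q2 & q1 <= q3, s1, ifelse(q2 <= q3, 0, s3))
    to <- ifelse(q1 <= q2 & q1 <= q3, 0, ifelse(q2 <= q3, t2, t3))
    s_out[o] <- so
    t_out[o] <- to
  }
  closest <- v1 + s_out * E0 + t_out * E1
  sqrt(rowSums(sweep(closest, 2L, p, "-")^2))
}

#' Unsigned point-to-mesh distances
#'
#' Minimum Euclidean distance from each point to the mesh surface (any
#' triangle: interior, edge or vertex). The default `"pruned"` method
#' computes, per query point, lower bounds from each triangle's
#' axis-aligned bounding box and evaluates exact distances best-first,
#' stopping when the bound exceeds the current minimum; it is exactly
#' equivalent to the `"brute"` method, which evaluates every triangle.
#'
#' @param points a [landmark_set()] or N x 3 matrix.
#' @param mesh a [triangle_mesh()].
#' @param method `"pruned"` or `"brute"`.
#' @return numeric vector of unsigned distances (mm), one per point.
#' @export
point_to_mesh_distance <- function(points, mesh, method = c("pruned", "brute")) {
  method <- match.arg(method)
  stopifnot(inherits(mesh, "triangle_mesh"))
  P <- if (inherits(points, "landmark_set")) {
    points$points
  } else if (is.null(dim(points))) {
    matrix(as.numeric(points), nrow = 1L)
  } else {
    as.matrix(points)
  }
  if (ncol(P) != 3L) stop("points must be N x 3")
  f <- mesh$faces
  v1 <- mesh$vertices[f[, 1], , drop = FALSE]
  v2 <- mesh$vertices[f[, 2], , drop = FALSE]
  v3 <- mesh$vertices[f[, 3], , drop = FALSE]
  if (method == "brute") {
    return(vapply(seq_len(nrow(P)),
                  function(i) min(dist_point_triangles(P[i, ], v1, v2, v3)),
                  numeric(1)))
  }
  lo <- pmin(v1, v2, v3)
  hi <- pmax(v1, v2, v3)
  nb <- 64L  # evaluate exact distances in blocks of the bound-sorted order
  vapply(seq_len(nrow(P)), function(i) {
    p <- P[i, ]
    dx <- pmax(lo[, 1] - p[1], 0, p[1] - hi[, 1])
    dy <- pmax(lo[, 2] - p[2], 0, p[2] - hi[, 2])
    dz <- pmax(lo[, 3] - p[3], 0, p[3] - hi[, 3])
    bound <- sqrt(dx * dx + dy * dy + dz * dz)
    ord <- order(bound)
    best <- Inf
    k <- 1L
    nT <- length(ord)
    while (k <= nT) {
      if (bound[ord[k]] >= best) break
      sel <- ord[seq.int(k, min(k + nb - 1L, nT))]
      sel <- sel[bound[sel] < best]
      if (length(sel)) {
        best <- min(best, dist_point_triangles(p, v1[sel, , drop = FALSE],
                                               v2[sel, , drop = FALSE],
                                               v3[sel, , drop = FALSE]))
      }
      k <- k + nb
    }
    best
  }, numeric(1))
}

#' Register the intraoperative surface scan to the navigation data
#'
#' Point-based rigid registration on the resorbable pins, which are
#' identifiable both in the textured surface scan and in the navigation
#' (image-frame) data. Returns the transform mapping scan-frame
#' coordinates into the navigation frame.
#'
#' @param scan_pins pin [landmark_set()] in the scan frame.
#' @param nav_pins pin [landmark_set()] in the navigation (image) frame.
#' @return a [rigid_transform()] (scan -> navigation).
#' @export
register_scan <- function(scan_pins, nav_pins) {
  fit_rigid(scan_pins, nav_pins)$transform
}

#' Distribution summary of point-to-surface errors
#'
#' @param distances non-negative distances (mm).
#' @param region region tag.
#' @return An object of class `error_summary`: `region`, `n_points`,
#'   `mean`, `sd` (sample), quartiles `q1`/`median`/`q3` (linear
#'   interpolation, quantile type 7) and `max`, all in mm.
#' @export
error_summary <- function(distances, region = "pooled") {
  distances <- as.numeric(distances)
  if (!length(distances)) stop("no distances to summarize")
  if (any(distances < 0)) stop("distances must be non-negative")
  q <- stats::quantile(distances, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(region = region,
                 n_points = length(distances),
                 mean = mean(distances),
                 sd = if (length(distances) > 1L) stats::sd(distances) else 0,
                 q1 = q[1], median = q[2], q3 = q[3],
                 max = max(distances)),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("%s: n=%d, mean %.3f +/- %.3f mm, Q1/median/Q3 %.3f/%.3f/%.3f, max %.3f\n",
              x$region, x$n_points, x$mean, x$sd, x$q1, x$median, x$q3, x$max))
  invisible(x)
}

as_df_error_summary <- function(s) {
  data.frame(region = s$region, n_points = s$n_points, mean_mm = s$mean,
             sd_mm = s$sd, q1_mm = s$q1, median_mm = s$median, q3_mm = s$q3,
             max_mm = s$max)
}

#' Navigation accuracy against the intraoperative surface scan
#'
#' The scan is the gold standard: it is registered into the navigation
#' frame via the pins ([register_scan()]), then the navigation error is
#' the unsigned point-to-surface distance from every recorded navigation
#' point (mapped into the image frame with the registration in force when
#' it was recorded) to the scanned surface. Summaries are returned per
#' region and pooled over all points; the pooled mean is by construction
#' the point-count-weighted mean of the region means.
#'
#' @param session a [navigation_session()] with recorded points.
#' @param scan a [triangle_mesh()] in the scan frame.
#' @param scan_pins pin [landmark_set()] in the scan frame.
#' @return list with `summaries` (list of [error_summary()], per region
#'   plus `"pooled"`), `distances` (per-point `data.frame`:
#'   label,x,y,z,distance,region) and `scan_transform`.
#' @export
navigation_error <- function(session, scan, scan_pins) {
  stopifnot(inherits(session, "navigation_session"), inherits(scan, "triangle_mesh"))
  if (!length(session$recorded_points)) stop("session has no recorded points")
  if (is.null(session$pins_reference)) stop("session has no pin reference set")
  tf <- register_scan(scan_pins, session$pins_reference)
  scan_nav <- transform_mesh(scan, tf)
  batches <- recorded_points_in_image(session)
  per <- lapply(batches, function(b) {
    d <- point_to_mesh_distance(b$points, scan_nav)
    data.frame(label = b$points$labels,
               x = b$points$points[, 1], y = b$points$points[, 2],
               z = b$points$points[, 3], distance = d, region = b$region)
  })
  dd <- do.call(rbind, per)
  regions <- unique(dd$region)
  summaries <- lapply(regions, function(r) error_summary(dd$distance[dd$region == r], r))
  names(summaries) <- regions
  summaries$pooled <- error_summary(dd$distance, "pooled")
  list(summaries = summaries, distances = dd, scan_transform = tf)
}
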