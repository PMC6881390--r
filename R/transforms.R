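#' Rigid transforms in 3-D
#'
#' A `rigid_transform` is a proper rotation (3x3, det = +1) plus a translation
#' in millimetres, mapping points of one coordinate frame into another
#' (e.g. CT image frame into the optical-tracker frame). It is the object
#' fitted by fiducial registration and composed/inverted when the patient's
#' head moves between registrations.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric length-3 vector, millimetres.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @examples
#' t1 <- rigid_transform(diag(3), c(5, -2, 1))
#' rt_apply(t1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L)) || !all(is.finite(rotation))) {
    stop("rotation must be a finite 3x3 matrix")
  }
  if (length(translation) != 3L || !all(is.finite(translation))) {
    stop("translation must be a finite length-3 vector")
  }
  ortho_err <- max(abs(crossprod(rotation) - diag(3)))
  if (ortho_err > 1e-9) {
    stop(sprintf("rotation is not orthonormal (max |R'R - I| = %.3g)", ortho_err))
  }
  if (abs(det(rotation) - 1) > 1e-9) {
    stop(sprintf("rotation is not proper (det = %.12f); reflections are not rigid",
                 det(rotation)))
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
#' @rdname rigid_transform
rt_identity <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform()].
#' @param points numeric length-3 vector or N x 3 matrix (mm).
#' @return Points of the same shape, mapped into the target frame.
#' @export
rt_apply <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- if (vec) matrix(as.numeric(points), nrow = 1L) else as.matrix(points)
  if (ncol(p) != 3L) stop("points must be N x 3")
  out <- p %*% t(transform$rotation)
  out <- sweep(out, 2L, transform$translation, "+")
  if (vec) drop(out) else {
    dimnames(out) <- dimnames(p)
    out
  }
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform applying `b` first, then `a`
#' (function composition a o b).
#'
#' @param a,b [rigid_transform()] objects.
#' @return The composed [rigid_transform()].
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform()].
#' @return The inverse [rigid_transform()], so that
#'   `rt_apply(rt_invert(t), rt_apply(t, p)) == p` to numerical precision.
#' @export
rt_invert <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  rt <- t(transform$rotation)
  rigid_transform(rt, drop(-rt %*% transform$translation))
}

#' Build a rotation from an axis and an angle
#'
#' Rodrigues formula; convenience for constructing known ground-truth motions.
#'
#' @param axis numeric length-3, need not be unit length.
#' @param angle_deg rotation angle, degrees.
#' @param translation optional translation (mm), default zero.
#' @return a [rigid_transform()].
#' @export
rt_axis_angle <- function(axis, angle_deg, translation = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero")
  u <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, translation)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid transform (mm)\n")
  cat("rotation:\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(round(x$translation, 4), collapse = ", "), "\n")
  invisible(x)
}
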