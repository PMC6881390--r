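#' Rigid point-set (fiducial) registration
#'
#' Closed-form least-squares rigid registration of two label-matched
#' landmark sets (Kabsch/Umeyama without scale, SVD with determinant sign
#' fix). This realizes both steps of the two-step intraoperative scheme:
#' the *primary* registration on the six characteristic points of the
#' 3D-printed surgical guides and the repeatable *secondary* registration
#' on the six resorbable bone pins.
#'
#' The fitted transform maps `source`-frame coordinates into the `target`
#' frame. Residuals are the per-fiducial Euclidean distances after
#' alignment, and `rmse` is the fiducial registration error
#' `sqrt(mean(residuals^2))`.
#'
#' @param source,target [landmark_set()] objects with >= 3 shared labels.
#' @param step `"primary"` or `"secondary"` tag carried into the result.
#' @param repetition_index repetition counter (>= 1).
#' @param duration_s optional human task duration metadata (never computed).
#' @return An object of class `registration_result`: list with `transform`
#'   ([rigid_transform()]), `residuals` (named, mm), `rmse` (mm),
#'   `n_fiducials`, `step`, `repetition_index`, `duration_s`.
#' @examples
#' src <- landmark_set(paste0("G", 1:4),
#'                     rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1)), "image")
#' tgt <- transform_landmarks(src, rt_axis_angle(c(0,0,1), 30, c(5,-2,1)), "tracker")
#' fit_rigid(src, tgt)$rmse
#' @export
fit_rigid <- function(source, target, step = c("primary", "secondary"),
                      repetition_index = 1L, duration_s = NA_real_) {
  step <- match.arg(step)
  m <- match_landmarks(source, target, min_n = 3L)
  S <- m$a
  Tt <- m$b
  cs <- colMeans(S)
  ct <- colMeans(Tt)
  Sc <- sweep(S, 2L, cs)
  Tc <- sweep(Tt, 2L, ct)
  # collinearity: centered source must span at least a plane
  sv_src <- svd(Sc, nu = 0, nv = 0)$d
  if (sv_src[2] <= 1e-9 * max(sv_src[1], 1)) {
    stop("degenerate fiducial configuration: points are collinear ",
         "(rank of centered source < 2); cannot determine a unique rotation")
  }
  H <- crossprod(Sc, Tc)                    # sum over fiducials of s t'
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- ct - drop(R %*% cs)
  transform <- rigid_transform(R, tr)
  aligned <- rt_apply(transform, S)
  residuals <- sqrt(rowSums((aligned - Tt)^2))
  names(residuals) <- m$labels
  structure(list(transform = transform,
                 residuals = residuals,
                 rmse = sqrt(mean(residuals^2)),
                 n_fiducials = length(residuals),
                 step = step,
                 repetition_index = as.integer(repetition_index),
                 duration_s = duration_s),
            class = "registration_result")
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("%s registration (repetition %d): %d fiducials, RMSE %.3f mm\n",
              x$step, x$repetition_index, x$n_fiducials, x$rmse))
  invisible(x)
}

#' Navigation session bookkeeping
#'
#' A `navigation_session` records, for one surgery, the primary
#' registration, the time-ordered secondary registrations performed as the
#' (non-immobilized) head moves, the pin positions recorded once under the
#' primary registration, and the navigation points recorded on the
#' remodeled bone, each stamped with the registration in force when it was
#' recorded. R value semantics apply: the `register_*` and `record_*`
#' helpers return the updated session.
#'
#' @param case_id case identifier.
#' @return An object of class `navigation_session`.
#' @export
navigation_session <- function(case_id) {
  structure(list(case_id = as.character(case_id),
                 primary = NULL,
                 secondaries = list(),
                 secondary_recordings = list(),
                 pins_reference = NULL,
                 recorded_points = list()),
            class = "navigation_session")
}

#' Primary registration on surgical-guide points
#'
#' Fits the image-to-tracker transform from the six predefined
#' characteristic points of the 3D-printed osteotomy guides, recorded with
#' the tracked pointer, and stores it as the session's primary
#' registration (repetition index 1).
#'
#' @param session a [navigation_session()].
#' @param guide_points_image guide landmarks in the image (CT/plan) frame.
#' @param guide_points_tracker the same landmarks recorded in the tracker
#'   frame.
#' @param duration_s optional task-duration metadata (seconds).
#' @return the updated session; the fit is in `session$primary`.
#' @export
register_primary <- function(session, guide_points_image, guide_points_tracker,
                             duration_s = NA_real_) {
  stopifnot(inherits(session, "navigation_session"))
  res <- fit_rigid(guide_points_image, guide_points_tracker,
                   step = "primary", repetition_index = 1L,
                   duration_s = duration_s)
  session$primary <- res
  session$guide_image <- guide_points_image
  session$guide_tracker <- guide_points_tracker
  session
}

#' Record the pin reference set under the primary registration
#'
#' After the primary registration, the positions of the resorbable pins
#' are recorded once in the tracker frame and mapped back into the image
#' frame with the primary transform; this image-frame set is the fixed
#' reference that every later secondary registration is fitted against.
#'
#' @param session a [navigation_session()] with a primary registration.
#' @param pins_tracker pin landmarks recorded in the tracker frame.
#' @return the updated session (`session$pins_reference`, image frame).
#' @export
record_pin_reference <- function(session, pins_tracker) {
  stopifnot(inherits(session, "navigation_session"))
  if (is.null(session$primary)) stop("session has no primary registration")
  session$pins_reference <- transform_landmarks(
    pins_tracker, rt_invert(session$primary$transform), frame = "image")
  session
}

#' Secondary registration on resorbable pins
#'
#' Re-registers the image frame to the tracker using the bone pins; can be
#' repeated at any time to compensate for head motion. Appends a
#' `registration_result` tagged `secondary` with the next repetition
#' index; that transform is the one in force for subsequently recorded
#' points.
#'
#' @param session a [navigation_session()] with a primary registration and
#'   a pin reference set (see [record_pin_reference()]); alternatively pass
#'   `pins_reference` explicitly.
#' @param pins_tracker pin landmarks freshly recorded in the tracker frame.
#' @param pins_reference optional explicit image-frame pin reference
#'   overriding the stored one.
#' @param duration_s optional task-duration metadata (seconds).
#' @return the updated session; the new fit is the last element of
#'   `session$secondaries`.
#' @export
register_secondary <- function(session, pins_tracker, pins_reference = NULL,
                               duration_s = NA_real_) {
  stopifnot(inherits(session, "navigation_session"))
  if (is.null(session$primary)) stop("session has no primary registration")
  ref <- if (is.null(pins_reference)) session$pins_reference else pins_reference
  if (is.null(ref)) stop("no pin reference set; call record_pin_reference() first")
  rep_idx <- length(session$secondaries) + 2L  # primary is repetition 1
  res <- fit_rigid(ref, pins_tracker, step = "secondary",
                   repetition_index = rep_idx, duration_s = duration_s)
  session$secondaries[[length(session$secondaries) + 1L]] <- res
  session$secondary_recordings[[length(session$secondaries)]] <- pins_tracker
  session
}

# transform in force (image -> tracker) after `stamp` secondaries (0 = primary)
session_transform_in_force <- function(session, stamp) {
  if (stamp == 0L) {
    if (is.null(session$primary)) stop("session has no primary registration")
    session$primary$transform
  } else {
    if (stamp > length(session$secondaries)) {
      stop("recorded-point stamp refers to a nonexistent secondary registration")
    }
    session$secondaries[[stamp]]$transform
  }
}

#' Record navigation points on the remodeled bone
#'
#' Stores tracker-frame pointer samples for an anatomical region, stamped
#' with the index of the secondary registration currently in force (0 if
#' only the primary has been performed).
#'
#' @param session a [navigation_session()].
#' @param points tracker-frame [landmark_set()].
#' @param region region tag, e.g. `"frontal"` or `"supraorbital"`.
#' @return the updated session.
#' @export
record_points <- function(session, points, region) {
  stopifnot(inherits(session, "navigation_session"), inherits(points, "landmark_set"))
  if (is.null(session$primary)) stop("session has no primary registration")
  session$recorded_points[[length(session$recorded_points) + 1L]] <-
    list(region = as.character(region)[1], points = points,
         stamp = length(session$secondaries))
  session
}

#' Recorded navigation points mapped into the image frame
#'
#' Applies, per recorded batch, the inverse of the registration that was
#' in force when the batch was recorded.
#'
#' @param session a [navigation_session()].
#' @return list of `list(region, points)` with image-frame landmark sets.
#' @export
recorded_points_in_image <- function(session) {
  stopifnot(inherits(session, "navigation_session"))
  lapply(session$recorded_points, function(b) {
    tf <- session_transform_in_force(session, b$stamp)
    list(region = b$region,
         points = transform_landmarks(b$points, rt_invert(tf), frame = "image"))
  })
}

# population (divide by n) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Summarize registration accuracy across sessions (Table-1 style)
#'
#' Per case: primary RMSE, mean and SD of the secondary RMSE over
#' repetitions, repetition count, and mean durations when recorded. Pooled
#' row (`case = "Avg."`): unweighted mean of primary RMSE across cases;
#' the pooled secondary mean is the repetition-count-weighted mean of the
#' per-case secondary means. SDs are reported with both the sample (n-1)
#' and population (n) conventions.
#'
#' @param sessions list of [navigation_session()] objects, each with a
#'   primary and at least one secondary registration.
#' @return `data.frame` with one row per case plus the pooled `"Avg."` row.
#' @export
summarize_sessions <- function(sessions) {
  if (!length(sessions)) stop("no sessions to summarize")
  rows <- lapply(sessions, function(s) {
    stopifnot(inherits(s, "navigation_session"))
    if (is.null(s$primary)) stop("session ", s$case_id, " has no primary registration")
    if (!length(s$secondaries)) stop("session ", s$case_id, " has no secondary registration")
    sec <- vapply(s$secondaries, `[[`, 0, "rmse")
    secd <- vapply(s$secondaries, `[[`, 0, "duration_s")
    data.frame(case = s$case_id,
               primary_rmse_mm = s$primary$rmse,
               primary_duration_s = s$primary$duration_s,
               secondary_rmse_mean_mm = mean(sec),
               secondary_rmse_sd_mm = if (length(sec) > 1L) stats::sd(sec) else 0,
               secondary_duration_mean_s = mean(secd),
               n_secondary = length(sec))
  })
  df <- do.call(rbind, rows)
  summarize_registration_table(df)
}

#' Pool a per-case registration table
#'
#' Adds the pooled `"Avg."` row to a per-case registration summary (the
#' layout of the per-surgery RMSE table): unweighted mean and SD of the
#' primary RMSE, and repetition-count-weighted mean of the per-case
#' secondary means, with a pooled secondary SD reconstructed from the
#' within-case SDs by the law of total variance.
#'
#' @param df `data.frame` with columns `case`, `primary_rmse_mm`,
#'   `secondary_rmse_mean_mm`, `secondary_rmse_sd_mm`, `n_secondary` and
#'   optionally duration columns.
#' @return the table with the pooled row appended, plus attributes
#'   `primary_sd_sample` / `primary_sd_population` and
#'   `secondary_sd_sample` / `secondary_sd_population`.
#' @export
summarize_registration_table <- function(df) {
  need <- c("case", "primary_rmse_mm", "secondary_rmse_mean_mm",
            "secondary_rmse_sd_mm", "n_secondary")
  if (!all(need %in% names(df))) {
    stop("registration table needs columns: ", paste(need, collapse = ", "))
  }
  if (!nrow(df)) stop("empty registration table")
  if (!"primary_duration_s" %in% names(df)) df$primary_duration_s <- NA_real_
  if (!"secondary_duration_mean_s" %in% names(df)) df$secondary_duration_mean_s <- NA_real_
  n <- df$n_secondary
  N <- sum(n)
  pooled_sec_mean <- sum(n * df$secondary_rmse_mean_mm) / N
  # law of total variance with population (n) within-case variances
  ex2 <- sum(n * (df$secondary_rmse_sd_mm^2 + df$secondary_rmse_mean_mm^2)) / N
  pooled_sec_var_pop <- max(ex2 - pooled_sec_mean^2, 0)
  pooled_sec_sd_pop <- sqrt(pooled_sec_var_pop)
  pooled_sec_sd_sample <- sqrt(pooled_sec_var_pop * N / max(N - 1L, 1L))
  avg <- data.frame(case = "Avg.",
                    primary_rmse_mm = mean(df$primary_rmse_mm),
                    primary_duration_s = mean(df$primary_duration_s),
                    secondary_rmse_mean_mm = pooled_sec_mean,
                    secondary_rmse_sd_mm = pooled_sec_sd_pop,
                    secondary_duration_mean_s =
                      sum(n * df$secondary_duration_mean_s) / N,
                    n_secondary = N)
  out <- rbind(df[, names(avg)], avg)
  rownames(out) <- NULL
  attr(out, "primary_sd_sample") <- stats::sd(df$primary_rmse_mm)
  attr(out, "primary_sd_population") <- sd_pop(df$primary_rmse_mm)
  attr(out, "secondary_sd_sample") <- pooled_sec_sd_sample
  attr(out, "secondary_sd_population") <- pooled_sec_sd_pop
  out
}
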