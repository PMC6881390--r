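#' Craniometric landmarks
#'
#' The three manually selected landmarks used for outcome assessment of
#' fronto-orbital advancement: left frontal landmark (LFL), right frontal
#' landmark (RFL) and a landmark on the metopic suture (MSL).
#'
#' @param LFL,RFL,MSL length-3 points (mm).
#' @return object of class `craniometric_landmarks`.
#' @export
craniometric_landmarks <- function(LFL, RFL, MSL) {
  p <- rbind(LFL = as.numeric(LFL), RFL = as.numeric(RFL), MSL = as.numeric(MSL))
  if (ncol(p) != 3L || !all(is.finite(p))) stop("landmarks must be finite 3-vectors")
  if (sum((p["LFL", ] - p["RFL", ])^2) == 0) stop("LFL and RFL coincide")
  if (sum((p["MSL", ] - p["LFL", ])^2) == 0 ||
      sum((p["MSL", ] - p["RFL", ])^2) == 0) {
    stop("MSL coincides with a lateral landmark; zero-length frontal segment")
  }
  structure(list(LFL = p["LFL", ], RFL = p["RFL", ], MSL = p["MSL", ]),
            class = "craniometric_landmarks")
}

#' Pick craniometric landmarks out of a landmark set
#'
#' @param lm a [landmark_set()] containing labels `LFL`, `RFL`, `MSL`.
#' @return a [craniometric_landmarks()] object.
#' @export
craniometric_from_set <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  need <- c("LFL", "RFL", "MSL")
  if (!all(need %in% lm$labels)) {
    stop("landmark set lacks: ", paste(setdiff(need, lm$labels), collapse = ", "))
  }
  craniometric_landmarks(lm$points["LFL", ], lm$points["RFL", ], lm$points["MSL", ])
}

#' Interfrontal angle
#'
#' Angle at MSL between the left frontal segment (MSL to LFL) and the
#' right frontal segment (MSL to RFL), in degrees in (0, 180]. A larger
#' angle means a flatter forehead; trigonocephaly presents an abnormally
#' acute angle. Computed with the atan2 of cross-product norm and dot
#' product, which is stable near 0 and 180 degrees.
#'
#' @param lm a [craniometric_landmarks()] object.
#' @return angle in degrees.
#' @export
interfrontal_angle <- function(lm) {
  stopifnot(inherits(lm, "craniometric_landmarks"))
  u <- lm$LFL - lm$MSL
  v <- lm$RFL - lm$MSL
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  atan2(sqrt(sum(cr^2)), sum(u * v)) * 180 / pi
}

#' Transverse forehead width
#'
#' Euclidean distance between the two most lateral landmarks (LFL, RFL).
#'
#' @param lm a [craniometric_landmarks()] object.
#' @return width in mm.
#' @export
transverse_forehead_width <- function(lm) {
  stopifnot(inherits(lm, "craniometric_landmarks"))
  sqrt(sum((lm$LFL - lm$RFL)^2))
}

#' Craniometric measures at one stage
#'
#' @param interfrontal_angle degrees in (0, 180].
#' @param transverse_width mm, > 0.
#' @param stage `"preop"`, `"plan"` or `"postop"`.
#' @return object of class `craniometric_measures`.
#' @export
craniometric_measures <- function(interfrontal_angle, transverse_width,
                                  stage = c("preop", "plan", "postop")) {
  stage <- match.arg(stage)
  if (!is.finite(interfrontal_angle) || interfrontal_angle <= 0 ||
      interfrontal_angle > 180) {
    stop("interfrontal angle must lie in (0, 180]")
  }
  if (!is.finite(transverse_width) || transverse_width <= 0) {
    stop("transverse width must be positive")
  }
  structure(list(interfrontal_angle = interfrontal_angle,
                 transverse_width = transverse_width, stage = stage),
            class = "craniometric_measures")
}

#' Measure both craniometric metrics from landmarks
#'
#' @param lm a [craniometric_landmarks()] or a [landmark_set()] with
#'   labels LFL/RFL/MSL.
#' @param stage stage tag.
#' @return a [craniometric_measures()] object.
#' @export
measure_craniometry <- function(lm, stage = c("preop", "plan", "postop")) {
  if (inherits(lm, "landmark_set")) lm <- craniometric_from_set(lm)
  craniometric_measures(interfrontal_angle(lm), transverse_forehead_width(lm),
                        match.arg(stage))
}

#' Surgical outcome error
#'
#' Absolute differences between the virtually planned and the
#' postoperative values of the interfrontal angle and the transverse
#' forehead width.
#'
#' @param plan [craniometric_measures()] with stage `"plan"`.
#' @param postop [craniometric_measures()] with stage `"postop"`.
#' @return named numeric: `angle_error_deg`, `width_error_mm`.
#' @export
outcome_error <- function(plan, postop) {
  stopifnot(inherits(plan, "craniometric_measures"),
            inherits(postop, "craniometric_measures"))
  if (plan$stage != "plan" || postop$stage != "postop") {
    stop(sprintf("stage mismatch: expected plan/postop, got %s/%s",
                 plan$stage, postop$stage))
  }
  c(angle_error_deg = abs(plan$interfrontal_angle - postop$interfrontal_angle),
    width_error_mm = abs(plan$transverse_width - postop$transverse_width))
}

#' Outcome table across cases (Table-2 style)
#'
#' Per case: interfrontal angle and transverse width at the preoperative,
#' planned and postoperative stages; the plan-vs-postop absolute errors;
#' and an `overcorrected_plan` flag marking cases where the postoperative
#' value is below the planned value for *both* metrics (the expected
#' pattern when intraoperative practical limits reduce the planned
#' overcorrection). The last row (`case = "Avg."`) carries the mean
#' absolute errors across cases.
#'
#' @param cases list; each element is a list with elements `preop`,
#'   `plan`, `postop` ([craniometric_measures()]) and optionally `case`
#'   and `type` labels.
#' @return `data.frame` with one row per case plus the `"Avg."` row.
#' @export
outcome_table <- function(cases) {
  if (!length(cases)) stop("no cases")
  rows <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    err <- outcome_error(cs$plan, cs$postop)
    data.frame(case = if (!is.null(cs$case)) as.character(cs$case) else as.character(i),
               type = if (!is.null(cs$type)) cs$type else NA_character_,
               angle_preop = cs$preop$interfrontal_angle,
               angle_plan = cs$plan$interfrontal_angle,
               angle_postop = cs$postop$interfrontal_angle,
               width_preop = cs$preop$transverse_width,
               width_plan = cs$plan$transverse_width,
               width_postop = cs$postop$transverse_width,
               angle_error_deg = err[["angle_error_deg"]],
               width_error_mm = err[["width_error_mm"]],
               overcorrected_plan =
                 cs$postop$interfrontal_angle < cs$plan$interfrontal_angle &
                 cs$postop$transverse_width < cs$plan$transverse_width)
  })
  df <- do.call(rbind, rows)
  avg <- df[1, ]
  avg[1, ] <- NA
  avg$case <- "Avg."
  avg$angle_error_deg <- mean(df$angle_error_deg)
  avg$width_error_mm <- mean(df$width_error_mm)
  avg$overcorrected_plan <- all(df$overcorrected_plan)
  out <- rbind(df, avg)
  rownames(out) <- NULL
  out
}

#' Build an outcome table from a stage-value data frame
#'
#' Convenience for published-style tables with columns `case`, `type`,
#' `angle_preop`, `angle_plan`, `angle_postop`, `width_preop`,
#' `width_plan`, `width_postop`.
#'
#' @param df the stage-value `data.frame`.
#' @return see [outcome_table()].
#' @export
outcome_table_from_values <- function(df) {
  need <- c("angle_preop", "angle_plan", "angle_postop",
            "width_preop", "width_plan", "width_postop")
  if (!all(need %in% names(df))) {
    stop("need columns: ", paste(need, collapse = ", "))
  }
  cases <- lapply(seq_len(nrow(df)), function(i) {
    list(case = if ("case" %in% names(df)) df$case[i] else i,
         type = if ("type" %in% names(df)) df$type[i] else NA,
         preop = craniometric_measures(df$angle_preop[i], df$width_preop[i], "preop"),
         plan = craniometric_measures(df$angle_plan[i], df$width_plan[i], "plan"),
         postop = craniometric_measures(df$angle_postop[i], df$width_postop[i], "postop"))
  })
  outcome_table(cases)
}
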