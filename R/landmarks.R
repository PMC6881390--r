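#' Labeled 3-D landmark sets
#'
#' A `landmark_set` carries uniquely labeled 3-D points in millimetres in a
#' named coordinate frame. Landmark sets represent the six characteristic
#' points of the surgical guides, the six resorbable bone pins, craniometric
#' landmarks (LFL/RFL/MSL) and recorded navigation samples.
#'
#' @param labels character vector of unique labels.
#' @param points N x 3 numeric matrix (mm), rows matching `labels`.
#' @param frame frame identifier, e.g. `"image"`, `"tracker"`, `"scan"`.
#' @return An object of class `landmark_set`.
#' @examples
#' landmark_set(c("G1", "G2", "G3"), diag(3), frame = "image")
#' @export
landmark_set <- function(labels, points, frame = "image") {
  labels <- as.character(labels)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (is.null(dim(points)) || ncol(points) != 3L) stop("points must be N x 3")
  if (nrow(points) < 1L) stop("landmark set must contain at least one point")
  if (length(labels) != nrow(points)) stop("labels and points disagree in length")
  if (anyDuplicated(labels)) {
    stop("duplicate landmark labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  if (!all(is.finite(points))) stop("landmark coordinates must be finite")
  dimnames(points) <- list(labels, c("x", "y", "z"))
  structure(list(labels = labels, points = points, frame = as.character(frame)[1]),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark set: %d points, frame '%s'\n", nrow(x$points), x$frame))
  print(round(x$points, 4))
  invisible(x)
}

#' Match two landmark sets by label
#'
#' Returns the ordered correspondence shared by both sets; errors if fewer
#' than `min_n` labels are common, naming the unmatched labels.
#'
#' @param a,b [landmark_set()] objects.
#' @param min_n minimum number of required correspondences.
#' @return list with matrices `a`, `b` (rows aligned) and `labels`.
#' @export
match_landmarks <- function(a, b, min_n = 3L) {
  stopifnot(inherits(a, "landmark_set"), inherits(b, "landmark_set"))
  common <- intersect(a$labels, b$labels)
  if (length(common) < min_n) {
    miss <- union(setdiff(a$labels, b$labels), setdiff(b$labels, a$labels))
    stop(sprintf("only %d label-matched landmarks (need >= %d); unmatched: %s",
                 length(common), min_n,
                 if (length(miss)) paste(miss, collapse = ", ") else "<none>"))
  }
  list(a = a$points[common, , drop = FALSE],
       b = b$points[common, , drop = FALSE],
       labels = common)
}

#' Transform a landmark set into another frame
#'
#' @param lm a [landmark_set()].
#' @param transform a [rigid_transform()].
#' @param frame name of the destination frame.
#' @return the transformed [landmark_set()].
#' @export
transform_landmarks <- function(lm, transform, frame = lm$frame) {
  landmark_set(lm$labels, rt_apply(transform, lm$points), frame = frame)
}

#' Read landmarks from CSV or 3D Slicer-style markup files
#'
#' The CSV dialect expects a header `label,x,y,z` with an optional `frame`
#' column. The Slicer markup dialect accepts control-point rows of the
#' `.fcsv` layout (comment lines starting with `#`, fields
#' `id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,...`). Slicer files store RAS
#' coordinates; on read they are converted into the package's internal LPS
#' frame by flipping the signs of x and y unless `ras_to_lps = FALSE`.
#'
#' @param path file path.
#' @param dialect `"csv"`, `"slicer"` or `"auto"` (by extension/content).
#' @param frame frame label for the result; for the CSV dialect a `frame`
#'   column in the file takes precedence.
#' @param ras_to_lps flip x/y signs when reading the Slicer dialect.
#' @return a [landmark_set()].
#' @export
read_landmarks <- function(path, dialect = c("auto", "csv", "slicer"),
                           frame = "image", ras_to_lps = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read landmarks: no such file: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.fcsv$", path, ignore.case = TRUE)) "slicer" else {
      head1 <- readLines(path, n = 1L, warn = FALSE)
      if (startsWith(head1, "#")) "slicer" else "csv"
    }
  }
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("label", "x", "y", "z")
    if (!all(need %in% names(df))) {
      stop("landmark CSV must have columns label,x,y,z; got: ",
           paste(names(df), collapse = ","))
    }
    if (anyNA(df[, c("x", "y", "z")])) stop("missing coordinate in landmark CSV")
    if ("frame" %in% names(df) && length(unique(df$frame)) == 1L) {
      frame <- df$frame[1]
    }
    return(landmark_set(df$label, as.matrix(df[, c("x", "y", "z")]), frame = frame))
  }
  # Slicer control-point rows
  lines <- readLines(path, warn = FALSE)
  rows <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(rows)) stop("no control-point rows in Slicer markup file: ", path)
  parts <- strsplit(rows, ",", fixed = TRUE)
  if (any(vapply(parts, length, 1L) < 12L)) {
    stop("malformed Slicer control-point row (need >= 12 comma-separated fields)")
  }
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("missing coordinate in Slicer markup file")
  labels <- vapply(parts, function(p) p[12], character(1))
  if (ras_to_lps) xyz[, 1:2] <- -xyz[, 1:2]
  landmark_set(labels, xyz, frame = frame)
}

#' Write landmarks to CSV or Slicer markup format
#'
#' @inheritParams read_landmarks
#' @param lm a [landmark_set()].
#' @param lps_to_ras flip x/y signs when writing the Slicer dialect.
#' @return invisibly, `path`.
#' @export
write_landmarks <- function(lm, path, dialect = c("csv", "slicer"),
                            lps_to_ras = TRUE) {
  stopifnot(inherits(lm, "landmark_set"))
  dialect <- match.arg(dialect)
  if (dialect == "csv") {
    df <- data.frame(label = lm$labels, x = lm$points[, 1], y = lm$points[, 2],
                     z = lm$points[, 3], frame = lm$frame)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    xyz <- lm$points
    if (lps_to_ras) xyz[, 1:2] <- -xyz[, 1:2]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("# Markups fiducial file version = 4.11",
                 "# CoordinateSystem = RAS",
                 "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID"),
               con)
    for (i in seq_along(lm$labels)) {
      writeLines(sprintf("vtkMRMLMarkupsFiducialNode_%d,%.9g,%.9g,%.9g,0,0,0,1,1,1,0,%s,,",
                         i, xyz[i, 1], xyz[i, 2], xyz[i, 3], lm$labels[i]), con)
    }
  }
  invisible(path)
}
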