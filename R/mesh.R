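#' Triangle meshes
#'
#' Vertices/faces surface in millimetres: CT-derived skull models (STL),
#' virtual surgical plans, and intraoperative structured-light surface
#' scans (OBJ). An optional per-vertex `region` tag marks anatomical areas
#' such as `"frontal"` and `"supraorbital"`.
#'
#' @param vertices V x 3 numeric matrix (mm).
#' @param faces F x 3 integer matrix of 1-based vertex indices.
#' @param region optional character vector of length V.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces, region = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || nrow(vertices) < 3L) stop("vertices must be V x 3, V >= 3")
  if (ncol(faces) != 3L || nrow(faces) < 1L) stop("faces must be F x 3, F >= 1")
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite")
  if (min(faces) < 1L || max(faces) > nrow(vertices)) {
    stop("face indices out of range [1, V]")
  }
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] | faces[, 1] == faces[, 3]
  if (any(degen)) {
    stop(sprintf("%d degenerate face(s) with repeated vertex indices", sum(degen)))
  }
  if (!is.null(region)) {
    region <- as.character(region)
    if (length(region) != nrow(vertices)) stop("region must have one tag per vertex")
  }
  structure(list(vertices = vertices, faces = faces, region = region),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle mesh: %d vertices, %d faces", nrow(x$vertices), nrow(x$faces)))
  if (!is.null(x$region)) {
    tags <- table(x$region, useNA = "no")
    cat("; regions: ", paste(names(tags), tags, sep = "=", collapse = ", "))
  }
  cat("\n")
  invisible(x)
}

#' Transform a mesh rigidly
#'
#' @param mesh a [triangle_mesh()].
#' @param transform a [rigid_transform()].
#' @return the transformed mesh.
#' @export
transform_mesh <- function(mesh, transform) {
  triangle_mesh(rt_apply(transform, mesh$vertices), mesh$faces, mesh$region)
}

# Directed edge table of a mesh: one row per half-edge (from, to, face).
mesh_half_edges <- function(mesh) {
  f <- mesh$faces
  data.frame(from = c(f[, 1], f[, 2], f[, 3]),
             to = c(f[, 2], f[, 3], f[, 1]),
             face = rep.int(seq_len(nrow(f)), 3L))
}

# Undirected edge usage counts; key "i|j" with i < j.
mesh_edge_counts <- function(mesh) {
  he <- mesh_half_edges(mesh)
  lo <- pmin(he$from, he$to)
  hi <- pmax(he$from, he$to)
  key <- paste(lo, hi, sep = "|")
  table(key)
}

#' Boundary edges of a mesh
#'
#' An edge is a boundary edge when it is used by exactly one face. A closed
#' (watertight) mesh has none.
#'
#' @param mesh a [triangle_mesh()].
#' @return two-column integer matrix of directed boundary edges (from, to),
#'   oriented as traversed by their single incident face.
#' @export
boundary_edges <- function(mesh) {
  he <- mesh_half_edges(mesh)
  key <- paste(pmin(he$from, he$to), pmax(he$from, he$to), sep = "|")
  cnt <- table(key)
  over <- names(cnt)[cnt > 2L]
  if (length(over)) {
    stop("non-manifold edges (used by > 2 faces): ", paste(over, collapse = "; "))
  }
  bkey <- names(cnt)[cnt == 1L]
  sel <- key %in% bkey
  cbind(from = he$from[sel], to = he$to[sel])
}

# Merge vertices closer than `tol` (STL stores facets independently, so
# topology only exists after merging). Rounding to a tol-grid keys duplicates.
merge_mesh_vertices <- function(vertices, faces, tol = 1e-6) {
  key <- apply(round(vertices / tol), 1L, paste, collapse = "|")
  first_id <- match(key, key)                 # row of first occurrence
  kept <- unique(first_id)                    # in order of appearance
  remap <- match(first_id, kept)
  list(vertices = vertices[kept, , drop = FALSE],
       faces = matrix(remap[faces], ncol = 3L))
}

#' Read a triangle mesh from STL or OBJ
#'
#' STL (ASCII or binary) and Wavefront OBJ (geometry only; texture and
#' normal records are tolerated and ignored). STL facets are welded into
#' shared vertices by merging coordinates within `merge_tol`, so the result
#' has edge connectivity usable for smoothing and hole detection.
#' Non-triangular OBJ faces are fan-triangulated by default.
#'
#' @param path file path.
#' @param format `"stl"`, `"obj"` or `"auto"` (by extension).
#' @param merge_tol vertex-welding tolerance for STL, mm.
#' @param strict reject non-triangular OBJ faces instead of triangulating.
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "stl", "obj"),
                      merge_tol = 1e-6, strict = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read mesh: no such file: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "stl"
  }
  if (format == "obj") read_obj(path, strict = strict) else read_stl(path, merge_tol)
}

read_stl <- function(path, merge_tol = 1e-6) {
  # ASCII STL begins with "solid" and contains "facet"; binary often begins
  # with "solid" too, so sniff for the keyword within the first chunk.
  head_raw <- readBin(path, "raw", n = 512L)
  printable <- head_raw %in% c(as.raw(c(9L, 10L, 13L)), as.raw(32:126))
  head_txt <- rawToChar(head_raw[printable])
  is_ascii <- all(printable) && grepl("^\\s*solid", head_txt) &&
    grepl("facet", head_txt, fixed = TRUE)
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path)
  if (nrow(tri) == 0L) stop("empty STL mesh: ", path)
  m <- merge_mesh_vertices(tri, matrix(seq_len(nrow(tri)), ncol = 3L, byrow = TRUE),
                           tol = merge_tol)
  # facets collapsed by welding are dropped
  f <- m$faces
  ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
  if (!any(ok)) stop("all STL facets degenerate after vertex welding")
  triangle_mesh(m$vertices, f[ok, , drop = FALSE])
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl)) return(matrix(numeric(0), 0, 3))
  xyz <- t(vapply(strsplit(trimws(vl), "\\s+"),
                  function(p) as.numeric(p[2:4]), numeric(3)))
  if (nrow(xyz) %% 3L != 0L) stop("corrupt ASCII STL: vertex count not multiple of 3")
  xyz
}

read_stl_binary <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  nf <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (is.na(nf) || nf < 0L) stop("corrupt binary STL header")
  if (nf == 0L) return(matrix(numeric(0), 0, 3))
  # each facet: 12 floats (normal + 3 vertices) + uint16 attribute
  raw <- readBin(con, "raw", n = nf * 50L)
  if (length(raw) < nf * 50L) stop("truncated binary STL")
  idx <- rep(seq.int(0L, nf - 1L) * 50L, each = 48L) + seq_len(48L)
  fl <- readBin(raw[idx], "double", size = 4L, n = nf * 12L, endian = "little")
  m <- matrix(fl, ncol = 12L, byrow = TRUE)
  verts <- rbind(m[, 4:6, drop = FALSE], m[, 7:9, drop = FALSE], m[, 10:12, drop = FALSE])
  ord <- as.vector(t(matrix(seq_len(3L * nf), ncol = 3L)))
  verts[ord, , drop = FALSE]
}

read_obj <- function(path, strict = FALSE) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl) || !length(fl)) stop("empty or faceless OBJ mesh: ", path)
  verts <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(p) as.numeric(p[2:4]), numeric(3)))
  faces <- list()
  for (ln in fl) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]][-1]
    # "f 1/2/3" style: vertex index is the leading field
    idx <- as.integer(vapply(strsplit(toks, "/", fixed = TRUE), `[[`, "", 1L))
    idx[idx < 0L] <- nrow(verts) + 1L + idx[idx < 0L]  # negative = relative
    if (length(idx) < 3L) stop("OBJ face with fewer than 3 vertices")
    if (length(idx) > 3L && strict) stop("non-triangular OBJ face in strict mode")
    for (k in seq_len(length(idx) - 2L)) {
      faces[[length(faces) + 1L]] <- c(idx[1L], idx[k + 1L], idx[k + 2L])
    }
  }
  triangle_mesh(verts, do.call(rbind, faces))
}

#' Write a triangle mesh to STL or OBJ
#'
#' STL is written in the binary layout (80-byte header, uint32 facet count,
#' 50 bytes per facet) unless `ascii = TRUE`. OBJ writes `v`/`f` records.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param format `"stl"`, `"obj"` or `"auto"` (by extension).
#' @param ascii write ASCII STL instead of binary.
#' @return invisibly, `path`.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "stl", "obj"), ascii = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "stl"
  }
  if (format == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g",
                       mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d",
                       mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
    return(invisible(path))
  }
  v <- mesh$vertices
  f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", nrm[i, 1], nrm[i, 2], nrm[i, 3]),
                   "    outer loop",
                   sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, ], 1], v[f[i, ], 2], v[f[i, ], 3]),
                   "    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "binary STL"))[1:80]
  writeBin(header, con)
  writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
  block <- matrix(0, nrow(f), 12L)
  block[, 1:3] <- nrm
  block[, 4:6] <- v[f[, 1], , drop = FALSE]
  block[, 7:9] <- v[f[, 2], , drop = FALSE]
  block[, 10:12] <- v[f[, 3], , drop = FALSE]
  attr_zero <- as.raw(c(0, 0))
  for (i in seq_len(nrow(f))) {
    writeBin(block[i, ], con, size = 4L, endian = "little")
    writeBin(attr_zero, con)
  }
  invisible(path)
}
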