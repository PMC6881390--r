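#' Write a complete synthetic case directory
#'
#' Serializes a phantom case plus its simulated navigation session into a
#' self-contained directory of standard plain formats: STL meshes for the
#' CT-derived preoperative and planned models, an OBJ mesh for the
#' (simulated) intraoperative surface scan, CSV landmark files, and a
#' `session.json` manifest tying recorded point batches to the
#' registration in force. The directory is consumable by [read_case()] and
#' the CLI with no other input.
#'
#' @param case a [make_phantom()] result.
#' @param sim a [simulate_session()] result for that case.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_case <- function(case, sim, dir) {
  stopifnot(inherits(case, "synthetic_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_mesh(case$preop_mesh, p("preop.stl"))
  write_mesh(case$plan_mesh, p("plan.stl"))
  write_mesh(sim$scan, p("postop_scan.obj"))
  write_landmarks(case$guide_points, p("guide_image.csv"))
  write_landmarks(sim$scan_pins, p("scan_pins.csv"))
  for (nm in c("preop", "plan", "postop")) {
    write_landmarks(case[[paste0("landmarks_", nm)]],
                    p(sprintf("landmarks_%s.csv", nm)))
  }
  session <- sim$session
  # store the raw tracker recordings so every registration is refittable
  # from disk with its original residuals
  guide_tracker <- session$guide_tracker
  write_landmarks(session$pins_reference, p("pins_reference.csv"))
  sec_files <- character(0)
  for (k in seq_along(session$secondaries)) {
    fn <- sprintf("pins_tracker_sec%02d.csv", k)
    write_landmarks(session$secondary_recordings[[k]], p(fn))
    sec_files <- c(sec_files, fn)
  }
  rec <- list()
  for (k in seq_along(session$recorded_points)) {
    b <- session$recorded_points[[k]]
    fn <- sprintf("recorded_%02d_%s.csv", k, b$region)
    write_landmarks(b$points, p(fn))
    rec[[k]] <- list(region = b$region, file = fn, stamp = b$stamp)
  }
  manifest <- list(
    case_id = session$case_id,
    seed = case$spec$seed,
    meshes = list(preop = "preop.stl", plan = "plan.stl",
                  postop_scan = "postop_scan.obj"),
    landmarks = list(guide_image = "guide_image.csv",
                     pins_reference = "pins_reference.csv",
                     scan_pins = "scan_pins.csv",
                     craniometric = list(preop = "landmarks_preop.csv",
                                         plan = "landmarks_plan.csv",
                                         postop = "landmarks_postop.csv")),
    primary = list(rmse_mm = session$primary$rmse,
                   residuals_mm = as.list(session$primary$residuals)),
    secondaries = sec_files,
    secondary_rmse_mm = vapply(session$secondaries, `[[`, 0, "rmse"),
    recorded = rec)
  # raw tracker recordings of the guide points for primary refitting
  write_landmarks(guide_tracker, p("guide_tracker.csv"))
  manifest$landmarks$guide_tracker <- "guide_tracker.csv"
  jsonlite::write_json(manifest, p("session.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a case directory back into pipeline inputs
#'
#' Rebuilds the navigation session by *refitting* every registration from
#' the stored recordings (primary from guide points, secondaries from the
#' per-repetition tracker pin files against the stored pin reference), so
#' every reported number is recomputable from the files on disk.
#'
#' @param dir a directory written by [write_case()] (or hand-assembled in
#'   the same layout).
#' @return list: `session`, `scan`, `scan_pins`, `landmarks` (per-stage
#'   craniometric sets), `manifest`.
#' @export
read_case <- function(dir) {
  mf_path <- file.path(dir, "session.json")
  if (!file.exists(mf_path)) stop("missing case manifest: ", mf_path)
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  p <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop("case file referenced by manifest is missing: ", fp)
    fp
  }
  guide_image <- read_landmarks(p(mf$landmarks$guide_image))
  guide_tracker <- read_landmarks(p(mf$landmarks$guide_tracker), frame = "tracker")
  pins_reference <- read_landmarks(p(mf$landmarks$pins_reference))
  session <- navigation_session(mf$case_id)
  session <- register_primary(session, guide_image, guide_tracker)
  session$pins_reference <- pins_reference
  for (fn in mf$secondaries) {
    session <- register_secondary(session, read_landmarks(p(fn), frame = "tracker"))
  }
  rec <- mf$recorded
  if (is.data.frame(rec)) rec <- split(rec, seq_len(nrow(rec)))
  for (b in rec) {
    pts <- read_landmarks(p(b$file), frame = "tracker")
    if (b$stamp != length(session$secondaries)) {
      # honor the stored stamp rather than the default "current" one
      session$recorded_points[[length(session$recorded_points) + 1L]] <-
        list(region = b$region, points = pts, stamp = as.integer(b$stamp))
    } else {
      session <- record_points(session, pts, b$region)
    }
  }
  scan <- read_mesh(p(mf$meshes$postop_scan))
  scan_pins <- read_landmarks(p(mf$landmarks$scan_pins), frame = "scan")
  lmk <- lapply(mf$landmarks$craniometric, function(f) read_landmarks(p(f)))
  list(session = session, scan = scan, scan_pins = scan_pins,
       landmarks = lmk, manifest = mf)
}
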