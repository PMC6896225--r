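#' Write a trajectory in the native extended-XYZ dialect
#'
#' One block per frame: a bead-count line, a comment line
#' `time_ps=<t> box_nm=<x> <y> <z>`, then one line per bead with columns
#' `kind x y z id molecule protomer leaflet` (coordinates in nm, protomer
#' `-` for non-protomer beads). Files ending in `.gz` are gzip-compressed.
#' Round trips are lossless to 1e-5 nm.
#'
#' @param traj a [BeadTrajectory-class].
#' @param path output file (`.xyz` or `.xyz.gz`).
#' @return `path`, invisibly.
#' @export
writeTrajectoryXYZ <- function(traj, path) {
  s <- traj@system
  n <- length(s@beadId)
  prot <- ifelse(is.na(s@protomer), "-", as.character(s@protomer))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj@times)) {
    writeLines(as.character(n), con)
    writeLines(sprintf("time_ps=%.6f box_nm=%.6f %.6f %.6f",
                       traj@times[f], traj@boxes[f, 1], traj@boxes[f, 2],
                       traj@boxes[f, 3]), con)
    writeLines(sprintf("%s %.6f %.6f %.6f %d %d %s %s",
                       s@kind, traj@coords[, 1, f], traj@coords[, 2, f],
                       traj@coords[, 3, f], s@beadId, s@molecule, prot,
                       s@leaflet), con)
  }
  invisible(path)
}

#' Read a trajectory in the native extended-XYZ dialect
#'
#' @param path input file, optionally gzip-compressed (detected by
#'   content, so a `.gz` suffix is not required).
#' @return a [BeadTrajectory-class].
#' @export
readTrajectoryXYZ <- function(path) {
  con <- gzfile(path, "r")  # reads plain files transparently
  lines <- tryCatch(readLines(con, warn = FALSE),
                    finally = close(con))
  times <- numeric(0)
  boxes <- NULL
  frames <- list()
  meta <- NULL
  i <- 1L
  nLines <- length(lines)
  while (i <= nLines) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n) || n < 0)
      rwStop("rw_format_error",
             sprintf("expected bead count at line %d", i))
    if (i + 1L > nLines)
      rwStop("rw_format_error", "truncated frame header")
    hdr <- lines[i + 1L]
    m <- regmatches(hdr, regexec(
      "time_ps=([-0-9.eE+]+)\\s+box_nm=([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)",
      hdr))[[1]]
    if (length(m) != 5)
      rwStop("rw_format_error",
             sprintf("malformed frame comment at line %d", i + 1L))
    if (i + 1L + n > nLines)
      rwStop("rw_format_error", "truncated frame body")
    body <- lines[(i + 2L):(i + 1L + n)]
    tok <- strsplit(body, "[ \t]+")
    if (any(lengths(tok) != 8))
      rwStop("rw_format_error",
             sprintf("expected 8 columns per bead near line %d", i + 2L))
    tok <- matrix(unlist(tok), ncol = 8, byrow = TRUE)
    frames[[length(frames) + 1L]] <- list(
      kind = tok[, 1],
      xyz = matrix(as.numeric(tok[, 2:4]), ncol = 3),
      id = as.integer(tok[, 5]), molecule = as.integer(tok[, 6]),
      protomer = suppressWarnings(as.integer(tok[, 7])),
      leaflet = tok[, 8]
    )
    times <- c(times, as.numeric(m[2]))
    boxes <- rbind(boxes, as.numeric(m[3:5]))
    i <- i + 2L + n
  }
  if (!length(frames)) rwStop("rw_format_error", "no frames found")
  nb <- vapply(frames, function(f) nrow(f$xyz), 1L)
  if (length(unique(nb)) != 1)
    rwStop("rw_format_error", "varying bead count across frames")
  if (length(times) > 1 && any(diff(times) <= 0))
    rwStop("rw_order_error", "frame times must be strictly increasing")
  f1 <- frames[[1]]
  sys <- BeadSystem(coords = f1$xyz, kind = f1$kind, box = boxes[1, ],
                    beadId = f1$id, protomer = f1$protomer,
                    molecule = f1$molecule, leaflet = f1$leaflet)
  arr <- array(0, dim = c(nb[1], 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]$xyz
  BeadTrajectory(sys, times, arr, boxes)
}
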