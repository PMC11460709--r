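#' Write a surface mesh as ASCII STL
#'
#' STL carries no labels; use [write_vtk_polydata()] when region labels must
#' survive the round trip.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  fc <- face_corners(mesh)
  n <- face_normals(mesh)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid laaoflow", con)
  lines <- character(nrow(mesh$faces) * 7L)
  fmt <- function(p) sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
  lines[seq(1, length(lines), by = 7)] <- paste("facet normal", fmt(n))
  lines[seq(2, length(lines), by = 7)] <- "  outer loop"
  lines[seq(3, length(lines), by = 7)] <- paste("    vertex", fmt(fc$a))
  lines[seq(4, length(lines), by = 7)] <- paste("    vertex", fmt(fc$b))
  lines[seq(5, length(lines), by = 7)] <- paste("    vertex", fmt(fc$c))
  lines[seq(6, length(lines), by = 7)] <- "  endloop"
  lines[seq(7, length(lines), by = 7)] <- "endfacet"
  writeLines(lines, con)
  writeLines("endsolid laaoflow", con)
  invisible(path)
}

#' Write a surface mesh as legacy ASCII VTK PolyData with labels
#'
#' Region labels are emitted as an integer cell array `region_id` plus a
#' comment block mapping ids to label strings.
#'
#' @inheritParams write_stl
#' @return `path`, invisibly.
#' @export
write_vtk_polydata <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  labs <- sort(unique(mesh$labels))
  ids <- match(mesh$labels, labs) - 1L
  writeLines(c("# vtk DataFile Version 3.0",
               paste("laaoflow surface;",
                     paste0(seq_along(labs) - 1L, "=", labs, collapse = " ")),
               "ASCII", "DATASET POLYDATA",
               paste("POINTS", nrow(mesh$vertices), "double")), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  nf <- nrow(mesh$faces)
  writeLines(paste("POLYGONS", nf, nf * 4L), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  writeLines(c(paste("CELL_DATA", nf),
               "SCALARS region_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(ids), con)
  invisible(path)
}

#' Read back a legacy ASCII VTK PolyData file written by this package
#'
#' @param path file path.
#' @return a [surface_mesh()].
#' @export
read_vtk_polydata <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[2], "; ", fixed = TRUE)[[1]]
  lab_map <- character()
  if (length(hdr) > 1) {
    kv <- strsplit(strsplit(hdr[2], " ")[[1]], "=", fixed = TRUE)
    lab_map <- vapply(kv, `[`, "", 2)
  }
  ip <- grep("^POINTS", ln)[1]
  np <- as.integer(strsplit(ln[ip], " ")[[1]][2])
  pts <- matrix(scan(text = ln[(ip + 1):(ip + np)], quiet = TRUE),
                ncol = 3, byrow = TRUE)
  ic <- grep("^POLYGONS", ln)[1]
  nf <- as.integer(strsplit(ln[ic], " ")[[1]][2])
  fc <- matrix(scan(text = ln[(ic + 1):(ic + nf)], quiet = TRUE),
               ncol = 4, byrow = TRUE)[, 2:4, drop = FALSE] + 1L
  il <- grep("^LOOKUP_TABLE", ln)[1]
  ids <- as.integer(ln[(il + 1):(il + nf)])
  labs <- if (length(lab_map)) lab_map[ids + 1L] else as.character(ids)
  surface_mesh(pts, fc, labs)
}

#' Write a velocity-field series as VTU-style ASCII files plus a JSON index
#'
#' One legacy VTK structured-points file per stored time step and an index
#' `{step, time_s, path}` as JSON, mirroring common CFD post-processing
#' layouts.
#'
#' @param series a [velocity_series()].
#' @param dir output directory (created if missing).
#' @param steps which time steps to write (default: all).
#' @return the index file path, invisibly.
#' @export
write_flow_series <- function(series, dir, steps = seq_along(series$times)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- series$grid
  nx <- length(g$x); ny <- length(g$y); nz <- length(g$z)
  idx <- data.frame(step = integer(), time_s = numeric(), path = character())
  for (k in steps) {
    p <- file.path(dir, sprintf("flow_%04d.vtk", k))
    con <- file(p, "w")
    writeLines(c("# vtk DataFile Version 3.0", "laaoflow velocity", "ASCII",
                 "DATASET STRUCTURED_POINTS",
                 paste("DIMENSIONS", nx, ny, nz),
                 sprintf("ORIGIN %.9g %.9g %.9g", g$x[1], g$y[1], g$z[1]),
                 sprintf("SPACING %.9g %.9g %.9g",
                         diff(g$x[1:2]), diff(g$y[1:2]), diff(g$z[1:2])),
                 paste("POINT_DATA", nx * ny * nz),
                 "VECTORS velocity double"), con)
    u <- series$u[, , , k, , drop = FALSE]
    dim(u) <- c(nx * ny * nz, 3)
    writeLines(sprintf("%.9g %.9g %.9g", u[, 1], u[, 2], u[, 3]), con)
    close(con)
    idx <- rbind(idx, data.frame(step = k, time_s = series$times[k], path = p))
  }
  ip <- file.path(dir, "index.json")
  jsonlite::write_json(idx, ip, digits = NA)
  invisible(ip)
}
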