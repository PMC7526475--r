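## Mesh and scalar-map readers/writers: legacy-ASCII VTK polydata (with
## point-data arrays), ASCII PLY, CARP-style .pts/.elem/.lon triplets and
## one-value-per-line .dat scalar files.

#' Write a surface as legacy ASCII VTK polydata
#'
#' Point-data arrays (region label as integer code, surface coordinates,
#' plus any named per-vertex scalars) are included.
#'
#' @param surface an `atrial_surface` (or any vertices/triangles mesh)
#' @param path output file
#' @param point_data optional named list of per-vertex numeric vectors
#' @export
write_vtk <- function(surface, path, point_data = NULL) {
  v <- surface$vertices
  f <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "afablate surface", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  utils::write.table(format(v, digits = 8, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  pd <- point_data
  if (!is.null(surface$region_label))
    pd <- c(list(region_label = as.integer(surface$region_label)), pd)
  if (!is.null(surface$surf_coord))
    pd <- c(pd, list(surf_coord_1 = surface$surf_coord[, 1],
                     surf_coord_2 = surface$surf_coord[, 2]))
  if (length(pd) > 0) {
    writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
    for (nm in names(pd)) {
      writeLines(c(sprintf("SCALARS %s float 1", nm),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(pd[[nm]], digits = 8, trim = TRUE), con)
    }
  }
  invisible(path)
}

#' Read a legacy ASCII VTK polydata surface written by [write_vtk()]
#' @param path VTK file
#' @return list(vertices, triangles, point_data)
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  ip <- grep("^POINTS", lines)[1]
  np <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
  pts <- scan(text = lines[(ip + 1):(ip + np)], quiet = TRUE)
  vertices <- matrix(pts, ncol = 3, byrow = TRUE)
  it <- grep("^POLYGONS", lines)[1]
  nt <- as.integer(strsplit(lines[it], "\\s+")[[1]][2])
  tr <- scan(text = lines[(it + 1):(it + nt)], quiet = TRUE)
  tr <- matrix(as.integer(tr), ncol = 4, byrow = TRUE)
  triangles <- tr[, 2:4, drop = FALSE] + 1L
  pd <- list()
  isc <- grep("^SCALARS", lines)
  for (k in isc) {
    nm <- strsplit(lines[k], "\\s+")[[1]][2]
    pd[[nm]] <- scan(text = lines[(k + 2):(k + 1 + np)], quiet = TRUE)
  }
  list(vertices = vertices, triangles = triangles, point_data = pd)
}

#' Write a surface as ASCII PLY
#' @param surface mesh with vertices/triangles
#' @param path output file
#' @export
write_ply <- function(surface, path) {
  v <- surface$vertices
  f <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(v)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, digits = 8, trim = TRUE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a surface as a CARP-style .pts/.elem/.lon triplet
#'
#' `basename.pts` (vertex count then coordinates), `basename.elem`
#' (`Tr v1 v2 v3 region`, zero-based), `basename.lon` (per-element fiber
#' vectors).
#'
#' @param surface an `atrial_surface` with fibers
#' @param basename output path without extension
#' @export
write_carp <- function(surface, basename) {
  v <- surface$vertices
  f <- surface$triangles
  writeLines(c(nrow(v),
               apply(format(v, digits = 8, trim = TRUE), 1, paste,
                     collapse = " ")),
             paste0(basename, ".pts"))
  reg <- if (!is.null(surface$region_label)) {
    tri_lab <- matrix(as.integer(surface$region_label)[as.vector(f)], ncol = 3)
    apply(tri_lab, 1, max)
  } else rep(1L, nrow(f))
  writeLines(c(nrow(f),
               paste("Tr", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L, reg)),
             paste0(basename, ".elem"))
  if (!is.null(surface$fiber))
    writeLines(c("1",
                 apply(format(surface$fiber, digits = 6, trim = TRUE), 1,
                       paste, collapse = " ")),
               paste0(basename, ".lon"))
  invisible(basename)
}

#' Read a CARP-style .pts/.elem (and optional .lon) triplet
#' @param basename path without extension
#' @return list(vertices, triangles, region, fiber)
#' @export
read_carp <- function(basename) {
  pts <- readLines(paste0(basename, ".pts"))
  np <- as.integer(pts[1])
  vertices <- matrix(scan(text = pts[2:(np + 1)], quiet = TRUE),
                     ncol = 3, byrow = TRUE)
  el <- readLines(paste0(basename, ".elem"))
  ne <- as.integer(el[1])
  parts <- strsplit(el[2:(ne + 1)], "\\s+")
  triangles <- t(vapply(parts, function(p) as.integer(p[2:4]),
                        integer(3))) + 1L
  region <- vapply(parts, function(p)
    if (length(p) >= 5) as.integer(p[5]) else 1L, integer(1))
  fiber <- NULL
  lonf <- paste0(basename, ".lon")
  if (file.exists(lonf)) {
    lon <- readLines(lonf)
    fiber <- matrix(scan(text = lon[-1], quiet = TRUE), ncol = 3,
                    byrow = TRUE)
  }
  list(vertices = vertices, triangles = triangles, region = region,
       fiber = fiber)
}

#' Write a per-vertex scalar as a CARP .dat file (one value per line)
#' @param x per-vertex values
#' @param path output file
#' @export
write_dat <- function(x, path) {
  writeLines(format(x, digits = 8, trim = TRUE), path)
  invisible(path)
}

#' Read a CARP .dat per-vertex scalar file
#' @param path file
#' @export
read_dat <- function(path) scan(path, quiet = TRUE)

#' Write PS events as CSV (time_ms, element_id, charge)
#' @param tracks a `ps_tracks`
#' @param path output file
#' @export
write_ps_events <- function(tracks, path) {
  utils::write.csv(tracks$events[, c("time_ms", "element", "charge")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a lesion set as an element list + JSON manifest
#' @param lesions a `lesion_set`
#' @param basename path without extension; writes `.txt` and `.json`
#' @export
write_lesions <- function(lesions, basename) {
  writeLines(as.character(lesions$elements), paste0(basename, ".txt"))
  jsonlite::write_json(
    list(strategy = lesions$strategy, width = lesions$width,
         n_elements = length(lesions$elements),
         ablated_area_cm2 = lesions$ablated_area,
         component_areas_cm2 = lesions$component_areas,
         params = lesions$params),
    paste0(basename, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' Write a voltage movie as per-frame text files plus a JSON header
#'
#' Each frame is a one-value-per-line .dat file (mV, vertex order); the
#' header records units, frame spacing and dimensions.
#'
#' @param result a `simulation_result`
#' @param dir output directory (created if needed)
#' @export
write_voltage_movie <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(units = "mV", dt_output_ms = result$dt_output,
                            duration_ms = result$duration,
                            n_vertices = nrow(result$voltage),
                            n_frames = ncol(result$voltage)),
                       file.path(dir, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_len(ncol(result$voltage)))
    write_dat(result$voltage[, k],
              file.path(dir, sprintf("frame_%05d.dat", k - 1L)))
  invisible(dir)
}
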