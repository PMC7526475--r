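## Instantaneous phase, phase-singularity detection and tracking, PS density
## maps and driver-hotspot segmentation.

#' Instantaneous phase of the voltage movie
#'
#' Phase of the analytic signal (Hilbert transform) of each vertex's
#' mean-subtracted voltage trace. Vertices with flat traces (e.g. ablated or
#' post-termination) are marked invalid and excluded downstream.
#'
#' @param result a `simulation_result`
#' @param min_sd traces with standard deviation below this (mV) are invalid
#' @return list(phase = vertices x frames matrix in (-pi, pi], valid =
#'   logical per vertex)
#' @export
compute_phase <- function(result, min_sd = 1) {
  vm <- result$voltage
  nv <- nrow(vm)
  nt <- ncol(vm)
  if (nt < 4) stop("need at least 4 frames for phase analysis")
  x <- t(vm)                                # frames x vertices
  x <- sweep(x, 2, colMeans(x))
  sds <- sqrt(colMeans(x^2))
  valid <- sds > min_sd & result$active
  ## analytic signal via FFT: zero negative frequencies, double positive
  X <- stats::mvfft(x)
  w <- numeric(nt)
  if (nt %% 2 == 0) {
    w[1] <- 1; w[nt / 2 + 1] <- 1; w[2:(nt / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((nt + 1) / 2)] <- 2
  }
  A <- stats::mvfft(X * w, inverse = TRUE) / nt
  ph <- t(atan2(Im(A), Re(A)))
  ph[!valid, ] <- NA_real_
  list(phase = ph, valid = valid)
}

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Detect phase singularities in one phase frame
#'
#' The topological charge of each element is the wrapped phase circulation
#' around its (consistently oriented) vertex loop divided by 2 pi; elements
#' with charge +/-1 are singular.
#'
#' @param phase_frame per-vertex phase (radians)
#' @param surface the mesh
#' @param exclude_elements optional element indices to skip (e.g. ablated)
#' @return data.frame(element, charge)
#' @export
detect_ps <- function(phase_frame, surface, exclude_elements = NULL) {
  f <- surface$triangles
  p1 <- phase_frame[f[, 1]]
  p2 <- phase_frame[f[, 2]]
  p3 <- phase_frame[f[, 3]]
  circ <- wrap_pi(p2 - p1) + wrap_pi(p3 - p2) + wrap_pi(p1 - p3)
  charge <- as.integer(round(circ / (2 * pi)))
  charge[is.na(charge)] <- 0L
  if (!is.null(exclude_elements)) charge[exclude_elements] <- 0L
  idx <- which(charge != 0L)
  data.frame(element = idx, charge = charge[idx])
}

#' Phase singularities over all frames of a movie
#'
#' @param phase output of [compute_phase()]
#' @param surface the mesh
#' @param times frame times (ms)
#' @param exclude_elements optional element indices to skip
#' @return object of class `ps_tracks`: data.frame(time_ms, element, charge)
#'   plus the analysis window
#' @export
track_ps <- function(phase, surface, times, exclude_elements = NULL) {
  ph <- phase$phase
  out <- vector("list", ncol(ph))
  for (k in seq_len(ncol(ph))) {
    ev <- detect_ps(ph[, k], surface, exclude_elements)
    if (nrow(ev) > 0) out[[k]] <- cbind(time_ms = times[k], ev)
  }
  ev <- do.call(rbind, out)
  if (is.null(ev)) ev <- data.frame(time_ms = numeric(0),
                                    element = integer(0), charge = integer(0))
  structure(list(events = ev,
                 window_ms = diff(range(times)) + times[2] - times[1]),
            class = "ps_tracks")
}

#' @exportS3Method base::print
print.ps_tracks <- function(x, ...) {
  cat(sprintf("PS track set: %d events over %.0f ms\n",
              nrow(x$events), x$window_ms))
  invisible(x)
}

#' Spatial PS density map
#'
#' Geodesic-Gaussian-smoothed event count per vertex, normalized per unit
#' area (cm^2) and per second, so the surface integral of the density map
#' times the window equals the event count.
#'
#' @param tracks a `ps_tracks`
#' @param surface the mesh
#' @param smoothing_radius Gaussian sigma (mm)
#' @return per-vertex density (events / cm^2 / s)
#' @export
ps_density <- function(tracks, surface, smoothing_radius = 5) {
  nv <- nrow(surface$vertices)
  ev <- tracks$events
  if (nrow(ev) == 0) return(numeric(nv))
  va <- vertex_areas(surface$vertices, surface$triangles) / 100  # cm^2
  ## events live at element barycenters; attribute to the nearest vertex
  ## (first vertex of the element) and smooth from unique source vertices
  src_vertex <- surface$triangles[ev$element, 1]
  tab <- table(src_vertex)
  uniq <- as.integer(names(tab))
  counts <- as.numeric(tab)
  g <- mesh_graph(surface$vertices, surface$triangles)
  d <- igraph::distances(g, v = uniq)          # sources x vertices
  dens <- numeric(nv)
  for (i in seq_along(uniq)) {
    k <- exp(-d[i, ]^2 / (2 * smoothing_radius^2))
    k <- k / sum(k * va)                       # unit mass per event
    dens <- dens + counts[i] * k
  }
  dens / (tracks$window_ms / 1000)
}

#' Segment driver hotspots from a PS density map
#'
#' Thresholds the density at mean + k SD over valid vertices and segments
#' supra-threshold vertices by connected-component analysis, sorted by
#' descending area.
#'
#' @param density per-vertex PS density
#' @param surface the mesh
#' @param k_sd threshold in SD units above the mean (default 1)
#' @param valid logical per vertex: vertices entering the mean/SD and
#'   eligible for hotspots (default all)
#' @return object of class `hotspot_map`: a `region_set` plus the density
#'   and threshold
#' @export
find_hotspots <- function(density, surface, k_sd = 1, valid = NULL) {
  if (is.null(valid)) valid <- rep(TRUE, length(density))
  mu <- mean(density[valid])
  sdv <- stats::sd(density[valid])
  if (!is.finite(sdv) || sdv == 0) {
    warning("zero-variance PS density: no hotspots")
    rs <- segment_regions(surface, rep(FALSE, length(density)))
  } else {
    thr <- mu + k_sd * sdv
    rs <- segment_regions(surface, valid & density > thr)
  }
  structure(c(unclass(rs),
              list(density = density,
                   threshold = if (exists("thr")) thr else NA_real_,
                   k_sd = k_sd)),
            class = c("hotspot_map", "region_set"))
}
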