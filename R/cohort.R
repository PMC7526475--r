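## Synthetic virtual-patient generator: left-atrial surface shells with region
## labels, a two-coordinate surface chart, smooth fiber fields and LGE-like
## intensity maps, statistically calibrated to the study-cohort presets.

#' Geometry and intensity presets for the two AF classes
#'
#' Returns the frozen generator parameters for a paroxysmal or persistent
#' virtual patient. Radii are in mm; hole positions are unit-sphere angles
#' (theta = azimuth from +x, phi = polar angle from the roof pole).
#'
#' @param af_class "paroxysmal" or "persistent"
#' @return list of geometry and LGE parameters
#' @export
cohort_preset <- function(af_class = c("paroxysmal", "persistent")) {
  af_class <- match.arg(af_class)
  geo <- list(
    base_radius = if (af_class == "paroxysmal") 32.3 else 35.3,
    radius_jitter_sd = if (af_class == "paroxysmal") 0.093 else 0.097,
    shape = c(1.00, 0.95, 1.05),   # ellipsoid axis multipliers
    shape_jitter_sd = 0.03,
    target_edge_length = 2.0,      # mm; desk-scale resolution
    jitter = 1,                    # master scale on all per-patient variability
    holes = list(                  # MV + four PV ostia clipped from the shell
      MV   = list(theta = 3 * pi / 2, phi = pi,  radius = 0.55),
      LSPV = list(theta = 210 * pi / 180, phi = 1.00, radius = 0.20),
      LIPV = list(theta = 200 * pi / 180, phi = 1.72, radius = 0.20),
      RSPV = list(theta = 330 * pi / 180, phi = 1.00, radius = 0.20),
      RIPV = list(theta = 340 * pi / 180, phi = 1.72, radius = 0.20)),
    hole_jitter_sd = 0.04,         # rad, on PV hole centers
    hole_radius_jitter_sd = 0.05,  # relative, on PV hole radii
    pv_label_width = 0.14,         # rad: PV sleeve annulus beyond the rim
    laa = list(theta = 160 * pi / 180, phi = 0.80, radius = 0.25),
    fiber_corr_len = 15,           # mm
    fiber_modes = 24)
  lge <- list(
    baseline = 100,
    bp_mean = 80, bp_sd = 10,      # synthetic blood-pool reference statistics
    n_blobs_base = if (af_class == "paroxysmal") 5L else 6L,
    n_blobs_jitter = 1L,           # +/- uniform integer jitter
    blob_radius_range = c(6.5, 11), # mm (geodesic Gaussian sigma)
    blob_amp_range = if (af_class == "paroxysmal") c(26, 44) else c(26, 40),
    noise_sd = 2)
  list(af_class = af_class, geometry = geo, lge = lge)
}

## phi/theta -> unit vector
sph_dir <- function(theta, phi) {
  c(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

## angular distance between unit vectors (rows of x) and a unit vector d
ang_dist <- function(x, d) acos(pmin(1, pmax(-1, drop(x %*% d))))

#' Remove pinched vertices / stray components from an open triangle mesh
#' @noRd
clean_open_mesh <- function(vertices, triangles, extra = NULL) {
  repeat {
    changed <- FALSE
    ## keep largest edge-connected element component
    comp <- element_components(triangles, rep(TRUE, nrow(triangles)))
    if (any(comp != 1L)) {
      triangles <- triangles[comp == 1L, , drop = FALSE]
      changed <- TRUE
    }
    ## split pinched vertex links: drop the smaller fan(s)
    n <- nrow(vertices)
    inc <- split(rep(seq_len(nrow(triangles)), 3), as.vector(triangles))
    drop_tris <- integer(0)
    for (vv in names(inc)) {
      tris <- inc[[vv]]
      if (length(tris) < 2) next
      v <- as.integer(vv)
      ## opposite edges of v in each incident triangle
      sub <- triangles[tris, , drop = FALSE]
      opp <- t(apply(sub, 1, function(r) r[r != v]))
      g <- igraph::graph_from_edgelist(
        matrix(match(t(opp), unique(as.vector(opp))), ncol = 2, byrow = TRUE),
        directed = FALSE)
      cc <- igraph::components(g)
      ## triangles grouped by fan: triangle i belongs to component of its edge
      fan <- cc$membership[match(opp[, 1], unique(as.vector(opp)))]
      if (max(fan) > 1) {
        keep_fan <- which.max(tabulate(fan))
        drop_tris <- c(drop_tris, tris[fan != keep_fan])
        changed <- TRUE
      }
    }
    if (length(drop_tris) > 0)
      triangles <- triangles[-unique(drop_tris), , drop = FALSE]
    if (!changed) break
  }
  ## drop unreferenced vertices, remap indices
  used <- sort(unique(as.vector(triangles)))
  map <- integer(nrow(vertices))
  map[used] <- seq_along(used)
  out <- list(vertices = vertices[used, , drop = FALSE],
              triangles = matrix(map[triangles], ncol = 3))
  if (!is.null(extra))
    out$extra <- lapply(extra, function(x) {
      if (is.matrix(x)) x[used, , drop = FALSE] else x[used]
    })
  out$kept_vertices <- used
  out
}

#' Generate a synthetic left-atrial surface
#'
#' Builds an ellipsoid-like closed shell, clips five geodesic disks (mitral
#' valve and four pulmonary veins), labels regions, and attaches the
#' two-coordinate surface chart and a smooth fiber field. Coordinate 1 runs
#' septal--lateral around the chamber (anterior wall < 0.5 <= posterior);
#' coordinate 2 runs from the mitral rim (0) to the roof pole (1), with the
#' roof line at 0.5.
#'
#' @param seed integer RNG seed (per-patient reproducibility)
#' @param params geometry parameter list, see [cohort_preset()]
#' @return an object of class `atrial_surface`
#' @export
generate_surface <- function(seed, params = cohort_preset("paroxysmal")$geometry) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  p <- params
  ## --- parameter validation: holes must not overlap
  hn <- names(p$holes)
  dirs0 <- t(vapply(p$holes, function(h) sph_dir(h$theta, h$phi), numeric(3)))
  for (i in seq_along(hn)) for (j in seq_along(hn)) {
    if (i >= j) next
    sep <- acos(pmin(1, sum(dirs0[i, ] * dirs0[j, ])))
    if (sep < p$holes[[i]]$radius + p$holes[[j]]$radius + 0.1)
      stop("holes overlap: ", hn[i], " and ", hn[j])
  }

  set.seed(as.integer(seed %% 2147483647))
  jit <- p$jitter
  radius <- p$base_radius * exp(stats::rnorm(1, 0, p$radius_jitter_sd * jit))
  shape <- p$shape * exp(stats::rnorm(3, 0, p$shape_jitter_sd * jit))
  ## jittered hole centers and radii (MV kept fixed: the chart depends on it)
  holes <- p$holes
  for (k in seq_along(holes)) {
    if (hn[k] != "MV") {
      holes[[k]]$theta <- holes[[k]]$theta + stats::rnorm(1, 0, p$hole_jitter_sd * jit)
      holes[[k]]$phi <- holes[[k]]$phi + stats::rnorm(1, 0, p$hole_jitter_sd * jit)
      holes[[k]]$radius <- holes[[k]]$radius *
        exp(stats::rnorm(1, 0, p$hole_radius_jitter_sd * jit))
    }
  }
  fiber_seed <- stats::runif(1, 1, 2^30)
  lvl <- max(2L, min(6L, as.integer(round(log2(1.0515 * radius /
                                                 p$target_edge_length)))))
  sph <- icosphere(lvl)
  unit <- sph$vertices

  ## clip the five disks (angular criterion on the unit sphere)
  remove <- rep(FALSE, nrow(unit))
  for (k in seq_along(holes)) {
    d <- ang_dist(unit, sph_dir(holes[[k]]$theta, holes[[k]]$phi))
    remove <- remove | d < holes[[k]]$radius
  }
  keep_tri <- !(remove[sph$triangles[, 1]] | remove[sph$triangles[, 2]] |
                  remove[sph$triangles[, 3]])
  cl <- clean_open_mesh(unit, sph$triangles[keep_tri, , drop = FALSE])
  unit <- cl$vertices
  tris <- cl$triangles

  ## scale to the ellipsoid
  verts <- sweep(unit, 2, radius * shape, `*`)

  ## region labels: PV sleeves > LAA > body
  lab <- rep("LA_body", nrow(unit))
  for (k in hn[hn != "MV"]) {
    d <- ang_dist(unit, sph_dir(holes[[k]]$theta, holes[[k]]$phi))
    lab[d < holes[[k]]$radius + p$pv_label_width] <- k
  }
  d_laa <- ang_dist(unit, sph_dir(p$laa$theta, p$laa$phi))
  lab[d_laa < p$laa$radius & lab == "LA_body"] <- "LAA"
  lab <- factor(lab, levels = c("LA_body", "LAA", "LSPV", "LIPV", "RSPV", "RIPV"))

  ## surface chart from the generating parameterization
  theta <- atan2(unit[, 2], unit[, 1]) %% (2 * pi)
  phi <- acos(pmin(1, pmax(-1, unit[, 3])))
  phi_mv <- pi - holes$MV$radius
  u <- theta / (2 * pi)
  v <- pmin(1, pmax(0, (phi_mv - phi) / phi_mv))
  surf_coord <- cbind(u, v)
  colnames(surf_coord) <- c("c1", "c2")

  ## boundary loops, named by nearest hole center
  loops <- boundary_loops(tris)
  if (length(loops) != 5)
    stop("surface construction failed: expected 5 boundary loops, got ",
         length(loops))
  loop_names <- vapply(loops, function(lp) {
    ctr <- colMeans(unit[lp, , drop = FALSE])
    ctr <- ctr / sqrt(sum(ctr^2))
    hn[which.min(vapply(seq_along(holes), function(k)
      acos(pmin(1, sum(ctr * sph_dir(holes[[k]]$theta, holes[[k]]$phi)))),
      numeric(1)))]
  }, character(1))
  if (anyDuplicated(loop_names))
    stop("surface construction failed: ambiguous boundary-loop labels")
  names(loops) <- loop_names
  loops <- loops[c("MV", "LSPV", "LIPV", "RSPV", "RIPV")]

  surf <- structure(list(
    vertices = verts,
    triangles = tris,
    region_label = lab,
    boundary_loops = loops,
    surf_coord = surf_coord,
    unit_sphere = unit,          # generating parameterization, kept for LGE
    holes = holes,
    radius = radius, shape = shape,
    target_edge_length = p$target_edge_length,
    fiber = NULL), class = "atrial_surface")
  surf$fiber <- generate_fiber_field(surf, seed = fiber_seed,
                                     corr_len = p$fiber_corr_len,
                                     n_modes = p$fiber_modes)
  surf
}

#' @exportS3Method base::print
print.atrial_surface <- function(x, ...) {
  cat("Synthetic atrial surface\n")
  cat(sprintf("  %d vertices, %d triangles, %d boundary loops\n",
              nrow(x$vertices), nrow(x$triangles), length(x$boundary_loops)))
  cat(sprintf("  total area %.1f cm^2; LA body area %.1f cm^2\n",
              surface_area(x) / 100, region_area(x, "LA_body") / 100))
  invisible(x)
}

#' Total surface area (mm^2)
#' @param surface an `atrial_surface`
#' @export
surface_area <- function(surface) {
  sum(triangle_areas(surface$vertices, surface$triangles))
}

#' Area of a labeled region (mm^2), by barycentric vertex-area attribution
#' @param surface an `atrial_surface`
#' @param label region label(s), e.g. "LA_body" or the four PV labels
#' @export
region_area <- function(surface, label) {
  va <- vertex_areas(surface$vertices, surface$triangles)
  sum(va[surface$region_label %in% label])
}

#' Generate a smooth tangent unit fiber field
#'
#' Superposes random vector-valued Gaussian kernels with correlation length
#' `corr_len`, projects onto each triangle plane and normalizes. Infinite
#' correlation length gives a globally parallel field up to projection.
#'
#' @param surface an `atrial_surface`
#' @param seed RNG seed
#' @param corr_len correlation length (mm), > 0 (may be `Inf`)
#' @param n_modes number of random kernels
#' @return matrix (n_triangles x 3) of unit tangent vectors
#' @export
generate_fiber_field <- function(surface, seed, corr_len = 15, n_modes = 24) {
  stopifnot(corr_len > 0)
  set.seed(as.integer(seed %% 2147483647))
  v <- surface$vertices
  f <- surface$triangles
  cen <- (v[f[, 1], ] + v[f[, 2], ] + v[f[, 3], ]) / 3
  ## random kernel centers on the surface, random 3-vector amplitudes
  ctr_idx <- sample(nrow(v), min(n_modes, nrow(v)))
  amp <- matrix(stats::rnorm(3 * length(ctr_idx)), ncol = 3)
  field <- matrix(0, nrow(cen), 3)
  for (i in seq_along(ctr_idx)) {
    d2 <- rowSums(sweep(cen, 2, v[ctr_idx[i], ], `-`)^2)
    w <- if (is.infinite(corr_len)) rep(1, length(d2)) else exp(-d2 / (2 * corr_len^2))
    field <- field + outer(w, amp[i, ])
  }
  n <- triangle_normals(v, f)
  ## project to tangent plane
  field <- field - n * rowSums(field * n)
  nrm <- sqrt(rowSums(field^2))
  ## degenerate projections: fall back to first edge direction
  bad <- nrm < 1e-8
  if (any(bad)) {
    e1 <- v[f[bad, 2], , drop = FALSE] - v[f[bad, 1], , drop = FALSE]
    field[bad, ] <- e1
    nrm[bad] <- sqrt(rowSums(e1^2))
  }
  field / nrm
}

#' Generate a synthetic LGE intensity map
#'
#' Baseline intensity plus a sum of geodesic Gaussian fibrotic blobs plus
#' white noise, with synthetic blood-pool reference statistics stored as
#' metadata (the fibrosis threshold is blood-pool mean + 3 SD).
#'
#' @param surface an `atrial_surface`
#' @param seed RNG seed
#' @param params LGE parameter list, see [cohort_preset()]
#' @return object of class `lge_map`: list(intensity, bp_mean, bp_sd)
#' @export
generate_lge_map <- function(surface, seed,
                             params = cohort_preset("paroxysmal")$lge) {
  p <- params
  if (p$noise_sd < 0 || p$bp_sd <= 0)
    stop("LGE parameters: standard deviations must be positive")
  set.seed(as.integer(seed %% 2147483647))
  nv <- nrow(surface$vertices)
  n_blobs <- max(0L, p$n_blobs_base +
                   sample(seq(-p$n_blobs_jitter, p$n_blobs_jitter), 1))
  intensity <- rep(p$baseline, nv)
  if (n_blobs > 0) {
    body_idx <- which(surface$region_label == "LA_body")
    ## fibrosis concentrates around the PV antra and posterior wall, as in
    ## clinical LGE distributions: sample blob centers with a proximity
    ## weight toward the PV regions plus a uniform floor
    g0 <- mesh_graph(surface$vertices, surface$triangles)
    pv_v <- which(surface$region_label %in% c("LSPV", "LIPV", "RSPV", "RIPV"))
    d_pv <- apply(igraph::distances(g0, v = pv_v[seq(1, length(pv_v), by = 4)],
                                    to = body_idx), 2, min)
    w <- exp(-d_pv^2 / (2 * 15^2)) + 0.15
    centers <- sample(body_idx, n_blobs, prob = w)
    g <- mesh_graph(surface$vertices, surface$triangles)
    d <- igraph::distances(g, v = centers)
    for (i in seq_len(n_blobs)) {
      R <- stats::runif(1, p$blob_radius_range[1], p$blob_radius_range[2])
      A <- stats::runif(1, p$blob_amp_range[1], p$blob_amp_range[2])
      intensity <- intensity + A * exp(-d[i, ]^2 / (2 * R^2))
    }
  }
  if (p$noise_sd > 0) intensity <- intensity + stats::rnorm(nv, 0, p$noise_sd)
  intensity <- pmax(intensity, 0)
  structure(list(intensity = intensity, bp_mean = p$bp_mean, bp_sd = p$bp_sd),
            class = "lge_map")
}

## deterministic child-seed derivation, kept below 2^31
child_seed <- function(seed, i, salt = 0) {
  (as.double(seed) * 1000003 + i * 7919 + salt * 104729) %% 2147483629 + 1
}

#' Generate a cohort of virtual patients
#'
#' @param n_paroxysmal,n_persistent patient counts per AF class
#' @param seed master RNG seed; per-patient seeds derive deterministically
#' @return list of `virtual_patient` objects (id, af_class, surface, lge,
#'   rng_seed)
#' @export
generate_cohort <- function(n_paroxysmal = 20, n_persistent = 30, seed = 1) {
  stopifnot(n_paroxysmal >= 0, n_persistent >= 0)
  classes <- c(rep("paroxysmal", n_paroxysmal), rep("persistent", n_persistent))
  out <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    ps <- child_seed(seed, i)
    preset <- cohort_preset(classes[i])
    surface <- generate_surface(ps, preset$geometry)
    lge <- generate_lge_map(surface, child_seed(seed, i, salt = 1), preset$lge)
    out[[i]] <- structure(list(
      id = sprintf("%s_%02d", substr(classes[i], 1, 4), i),
      af_class = classes[i],
      surface = surface,
      lge = lge,
      rng_seed = ps), class = "virtual_patient")
  }
  out
}

#' @exportS3Method base::print
print.virtual_patient <- function(x, ...) {
  cat(sprintf("Virtual patient %s (%s AF), seed %d\n",
              x$id, x$af_class, as.integer(x$rng_seed)))
  print(x$surface)
  invisible(x)
}
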