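## Translate an LGE intensity map into conduction and ionic heterogeneity:
## normalized-intensity conduction-velocity bands, blood-pool z-scores,
## ionic-conductance multipliers, and connected fibrotic regions.

#' Normalize an LGE map to [0, 1] by its own min and max
#'
#' @param lge an `lge_map`
#' @return per-vertex fraction in [0, 1]
#' @export
normalize_lge <- function(lge) {
  x <- lge$intensity
  rng <- range(x)
  if (!all(is.finite(x))) stop("LGE intensities must be finite")
  if (rng[2] <= rng[1])
    stop("degenerate LGE map: constant intensity, normalization undefined")
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Conduction-velocity band thresholds on normalized LGE intensity
#' @export
cv_band_thresholds <- function() c(0.56, 0.60, 0.64)

#' Assign conduction-velocity bands from normalized LGE intensity
#'
#' Bands are percentages of baseline conduction velocity: 100 for
#' normalized intensity in [0, 0.56), 80 for [0.56, 0.60), 60 for
#' [0.60, 0.64) and 40 for >= 0.64 (half-open, left-closed intervals).
#'
#' @param norm_lge per-vertex values in [0, 1]
#' @return integer per vertex in {100, 80, 60, 40}
#' @export
assign_cv_bands <- function(norm_lge) {
  if (any(norm_lge < 0 | norm_lge > 1, na.rm = TRUE) || anyNA(norm_lge))
    stop("normalized LGE values must lie in [0, 1]")
  thr <- cv_band_thresholds()
  band <- rep(100L, length(norm_lge))
  band[norm_lge >= thr[1]] <- 80L
  band[norm_lge >= thr[2]] <- 60L
  band[norm_lge >= thr[3]] <- 40L
  band
}

#' Blood-pool z-score of LGE intensity
#'
#' @param lge an `lge_map` with blood-pool mean and SD metadata
#' @return per-vertex intensity in blood-pool SD units
#' @export
lge_z_score <- function(lge) {
  if (is.null(lge$bp_sd) || lge$bp_sd <= 0)
    stop("blood-pool SD must be positive")
  (lge$intensity - lge$bp_mean) / lge$bp_sd
}

#' Per-vertex ionic-conductance multipliers
#'
#' Composes, multiplicatively per vertex: left-atrial baseline modifiers
#' (gKr x1.6, gNa x2, gK1 x0.8); region modifiers (appendage: gCaL x1.06,
#' gto x0.67; pulmonary veins: gto x0.75, gCaL x0.75, gKr x1.5, gKs x0.67);
#' AF electrical remodeling in all regions when flagged (gto x0.5, gKur x0.5,
#' gCaL x0.3); and fibrotic TGF-beta1 modifiers where the blood-pool z-score
#' exceeds 3 (gK1 x0.5, gNa x0.6, gCaL x0.5).
#'
#' @param z per-vertex blood-pool z-score
#' @param region_label per-vertex factor with the atrial region labels
#' @param af_remodeling logical flag
#' @param fibrosis_z_threshold z-score above which fibrotic rescaling applies
#' @return matrix (n_vertices x 7) with columns gNa, gCaL, gK1, gto, gKur,
#'   gKr, gKs
#' @export
apply_ionic_remodeling <- function(z, region_label, af_remodeling = TRUE,
                                   fibrosis_z_threshold = 3) {
  valid <- c("LA_body", "LAA", "LSPV", "LIPV", "RSPV", "RIPV")
  if (!all(as.character(region_label) %in% valid))
    stop("unknown region label(s): ",
         paste(setdiff(unique(as.character(region_label)), valid), collapse = ", "))
  n <- length(z)
  m <- matrix(1, n, 7, dimnames = list(NULL, c("gNa", "gCaL", "gK1", "gto",
                                               "gKur", "gKr", "gKs")))
  ## LA baseline
  m[, "gKr"] <- m[, "gKr"] * 1.6
  m[, "gNa"] <- m[, "gNa"] * 2
  m[, "gK1"] <- m[, "gK1"] * 0.8
  ## regional heterogeneity
  laa <- region_label == "LAA"
  m[laa, "gCaL"] <- m[laa, "gCaL"] * 1.06
  m[laa, "gto"] <- m[laa, "gto"] * 0.67
  pv <- region_label %in% c("LSPV", "LIPV", "RSPV", "RIPV")
  m[pv, "gto"] <- m[pv, "gto"] * 0.75
  m[pv, "gCaL"] <- m[pv, "gCaL"] * 0.75
  m[pv, "gKr"] <- m[pv, "gKr"] * 1.5
  m[pv, "gKs"] <- m[pv, "gKs"] * 0.67
  ## AF electrical remodeling, all regions
  if (af_remodeling) {
    m[, "gto"] <- m[, "gto"] * 0.5
    m[, "gKur"] <- m[, "gKur"] * 0.5
    m[, "gCaL"] <- m[, "gCaL"] * 0.3
  }
  ## fibrotic remodeling
  fib <- z > fibrosis_z_threshold
  m[fib, "gK1"] <- m[fib, "gK1"] * 0.5
  m[fib, "gNa"] <- m[fib, "gNa"] * 0.6
  m[fib, "gCaL"] <- m[fib, "gCaL"] * 0.5
  m
}

#' Frozen conductivity scale factors for the four CV bands
#'
#' Scale factors s(band) such that a planar wave on a calibrated strip with
#' conductivities s * (sigma_l, sigma_t) travels at the band's fraction of
#' baseline conduction velocity. Values were obtained once with
#' [calibrate_conductivity()] on the default strip and frozen; in the
#' continuous monodomain limit s = f^2 since CV scales with the square root
#' of conductivity.
#' @return named numeric: scale for bands "100", "80", "60", "40"
#' @export
cv_scale_defaults <- function() {
  c("100" = 1.0, "80" = 0.6400, "60" = 0.3759, "40" = 0.1745)
}

#' Assemble tissue properties from a surface and an LGE map
#'
#' Element conductivities are the baseline longitudinal/transverse values
#' scaled by the conduction-velocity band factor of the element's worst
#' (lowest-CV) vertex band; ionic multipliers are per vertex.
#'
#' @param surface an `atrial_surface`
#' @param lge an `lge_map`
#' @param af_remodeling logical, AF electrical remodeling in all regions
#' @param sigma_l,sigma_t baseline conductivities (S/m)
#' @param cv_scales named scale factors per band, see [cv_scale_defaults()]
#' @param fibrosis_z_threshold blood-pool SD units
#' @return object of class `tissue_properties`
#' @export
build_tissue <- function(surface, lge, af_remodeling = TRUE,
                         sigma_l = 0.4, sigma_t = 0.1,
                         cv_scales = cv_scale_defaults(),
                         fibrosis_z_threshold = 3) {
  norm <- normalize_lge(lge)
  band <- assign_cv_bands(norm)
  z <- lge_z_score(lge)
  mult <- apply_ionic_remodeling(z, surface$region_label, af_remodeling,
                                 fibrosis_z_threshold)
  tri <- surface$triangles
  elem_band <- pmin(band[tri[, 1]], band[tri[, 2]], band[tri[, 3]])
  s <- unname(cv_scales[as.character(elem_band)])
  structure(list(
    sigma_l = sigma_l * s,
    sigma_t = sigma_t * s,
    cv_band = band,
    norm_lge = norm,
    z = z,
    ionic_multipliers = mult,
    band_thresholds = cv_band_thresholds(),
    fibrosis_z_threshold = fibrosis_z_threshold,
    baseline = c(sigma_l = sigma_l, sigma_t = sigma_t),
    af_remodeling = af_remodeling,
    ablated_elements = integer(0),
    inactive_vertices = integer(0)), class = "tissue_properties")
}

#' Uniform tissue for a strip mesh (calibration and convergence runs)
#' @param strip a mesh from `strip_mesh()`
#' @inheritParams build_tissue
#' @export
uniform_strip_tissue <- function(strip, sigma_l = 0.4, sigma_t = 0.1,
                                 scale = 1) {
  m <- nrow(strip$triangles)
  nv <- nrow(strip$vertices)
  structure(list(
    sigma_l = rep(sigma_l * scale, m),
    sigma_t = rep(sigma_t * scale, m),
    cv_band = rep(100L, nv),
    ionic_multipliers = matrix(1, nv, 7, dimnames = list(NULL,
      c("gNa", "gCaL", "gK1", "gto", "gKur", "gKr", "gKs"))),
    baseline = c(sigma_l = sigma_l, sigma_t = sigma_t),
    ablated_elements = integer(0),
    inactive_vertices = integer(0)), class = "tissue_properties")
}

#' Segment fibrotic regions by connected-component analysis
#'
#' Maximal edge-connected components of vertices whose blood-pool z-score
#' exceeds the threshold, with barycentric one-ring area attribution, sorted
#' by descending area.
#'
#' @param z per-vertex blood-pool z-score
#' @param surface an `atrial_surface`
#' @param threshold SD units (default 3)
#' @return object of class `region_set`: list(regions = list of vertex index
#'   sets, areas = cm^2 per region, total_area = cm^2, membership = per-vertex
#'   region id or NA)
#' @export
identify_fibrotic_regions <- function(z, surface, threshold = 3) {
  keep <- z > threshold
  segment_regions(surface, keep)
}

#' Connected components of a vertex predicate with areas (cm^2)
#' @noRd
segment_regions <- function(surface, keep) {
  nv <- nrow(surface$vertices)
  va <- vertex_areas(surface$vertices, surface$triangles)
  if (!any(keep)) {
    return(structure(list(regions = list(), areas = numeric(0),
                          total_area = 0, membership = rep(NA_integer_, nv)),
                     class = "region_set"))
  }
  memb <- vertex_components(nv, surface$triangles, keep)
  ## isolated supra-threshold vertices (no supra-threshold neighbour) get
  ## their own singleton components
  lone <- which(keep & is.na(memb))
  if (length(lone) > 0) {
    memb[lone] <- max(memb, na.rm = TRUE) + seq_along(lone)
  }
  ids <- sort(unique(memb[!is.na(memb)]))
  regions <- lapply(ids, function(i) which(memb == i))
  areas <- vapply(regions, function(idx) sum(va[idx]) / 100, numeric(1))
  ord <- order(areas, decreasing = TRUE)
  regions <- regions[ord]
  areas <- areas[ord]
  memb2 <- rep(NA_integer_, nv)
  for (i in seq_along(regions)) memb2[regions[[i]]] <- i
  structure(list(regions = regions, areas = areas, total_area = sum(areas),
                 membership = memb2), class = "region_set")
}

#' @exportS3Method base::print
print.region_set <- function(x, ...) {
  cat(sprintf("Region set: %d region(s), total area %.2f cm^2\n",
              length(x$regions), x$total_area))
  invisible(x)
}

#' Calibrate a conductivity scale factor for a target CV fraction
#'
#' Finds, by bisection, the scale s such that a planar wave on a uniform
#' strip with conductivities s * (sigma_l, sigma_t) travels at
#' `target_cv_fraction` percent of the baseline-strip conduction velocity
#' (measured between probes at 25 and 75 percent of strip length). The
#' closed-form continuum seed is s = (f/100)^2.
#'
#' @param target_cv_fraction percent of baseline CV, in (0, 100]
#' @param sigma_l,sigma_t baseline conductivities (S/m)
#' @param tol relative CV tolerance (default 0.02)
#' @param max_iter bisection iteration cap
#' @param strip_h strip mesh edge length (mm)
#' @param ionic surrogate ionic parameters, see [ms_params()]
#' @return list(scale, achieved_fraction, baseline_cv, cv)
#' @export
calibrate_conductivity <- function(target_cv_fraction, sigma_l = 0.4,
                                   sigma_t = 0.1, tol = 0.02, max_iter = 30,
                                   strip_h = 0.5, ionic = ms_params()) {
  stopifnot(target_cv_fraction > 0, target_cv_fraction <= 100)
  f <- target_cv_fraction / 100
  base <- strip_cv(scale = 1, sigma_l = sigma_l, sigma_t = sigma_t,
                   h = strip_h, ionic = ionic)
  ratio <- function(s) strip_cv(scale = s, sigma_l = sigma_l,
                                sigma_t = sigma_t, h = strip_h,
                                ionic = ionic) / base
  s <- f^2
  r <- ratio(s)
  if (abs(r - f) / f <= tol)
    return(list(scale = s, achieved_fraction = 100 * r, baseline_cv = base,
                cv = r * base))
  ## bracket around the continuum seed
  lo <- s / 4; hi <- min(4 * s, 1.5)
  rlo <- ratio(lo); rhi <- ratio(hi)
  it <- 0
  while ((rlo - f) * (rhi - f) > 0 && it < 6) {
    lo <- lo / 2; hi <- min(hi * 1.5, 4)
    rlo <- ratio(lo); rhi <- ratio(hi)
    it <- it + 1
  }
  if ((rlo - f) * (rhi - f) > 0)
    stop("conductivity calibration failed to bracket target fraction ",
         target_cv_fraction, " (ratios ", round(rlo, 3), ", ",
         round(rhi, 3), ")")
  for (i in seq_len(max_iter)) {
    s <- sqrt(lo * hi)           # geometric bisection: CV ~ sqrt(sigma)
    r <- ratio(s)
    if (abs(r - f) / f <= tol)
      return(list(scale = s, achieved_fraction = 100 * r,
                  baseline_cv = base, cv = r * base))
    if (r > f) hi <- s else lo <- s
  }
  stop("conductivity calibration did not converge within ", max_iter,
       " iterations (last ratio ", round(r, 4), ", target ", f, ")")
}
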