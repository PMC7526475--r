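## Automated lesion-set construction: pulmonary vein isolation, posterior
## box isolation, and fibrosis-/hotspot-region isolation, plus the electrical
## realization of lesions and the post-ablation tissue partition.
##
## Lesions are element sets. A lesion is electrically transmural when its
## band is at least two element rings wide, so that interior vertices (all
## of whose incident elements are ablated) decouple the two sides; the
## default 3 mm lesion width at desk resolution gives that.

STRATEGIES <- c("pvi", "box", "single_fibrosis", "all_fibrosis",
                "single_hotspot", "all_hotspots")

## elements incident to any of the given vertices
elements_touching <- function(triangles, vertices_idx) {
  which(triangles[, 1] %in% vertices_idx |
          triangles[, 2] %in% vertices_idx |
          triangles[, 3] %in% vertices_idx)
}

## one-ring dilation of an element set
dilate_elements <- function(triangles, elems) {
  vs <- unique(as.vector(triangles[elems, , drop = FALSE]))
  union(elems, elements_touching(triangles, vs))
}

## vertices fully interior to an element set
interior_vertices <- function(triangles, elems, n_vertices) {
  cnt_all <- tabulate(as.vector(triangles), nbins = n_vertices)
  cnt_in <- tabulate(as.vector(triangles[elems, , drop = FALSE]),
                     nbins = n_vertices)
  which(cnt_in > 0 & cnt_in == cnt_all)
}

new_lesion_set <- function(surface, strategy, elems, width, params = list()) {
  elems <- sort(unique(elems))
  ta <- triangle_areas(surface$vertices, surface$triangles)
  keep <- rep(FALSE, nrow(surface$triangles))
  keep[elems] <- TRUE
  comp <- element_components(surface$triangles, keep)
  ids <- sort(unique(comp[!is.na(comp)]))
  comps <- lapply(ids, function(i) which(comp == i))
  areas <- vapply(comps, function(e) sum(ta[e]) / 100, numeric(1))
  structure(list(strategy = strategy, elements = elems,
                 components = comps, component_areas = areas,
                 ablated_area = sum(ta[elems]) / 100,
                 width = width, params = params),
            class = "lesion_set")
}

#' @exportS3Method base::print
print.lesion_set <- function(x, ...) {
  cat(sprintf("Lesion set '%s': %d elements (%.2f cm^2) in %d component(s)\n",
              x$strategy, length(x$elements), x$ablated_area,
              length(x$components)))
  invisible(x)
}

#' Plan wide-area pulmonary vein isolation
#'
#' Ablates the elements lying on the geodesic contour at `distance_threshold`
#' from the PV/body junction (within half the lesion width), forming closed
#' encircling bands; ipsilateral bands merge when they overlap. Errors if a
#' band fails to encircle its vein or reaches the mitral rim.
#'
#' @param surface an `atrial_surface`
#' @param distance_threshold geodesic distance from the junction (mm)
#' @param width lesion width (mm)
#' @return a `lesion_set`
#' @export
plan_pvi <- function(surface, distance_threshold = 5, width = 3) {
  g <- mesh_graph(surface$vertices, surface$triangles)
  tri <- surface$triangles
  lab <- surface$region_label
  pv_labels <- c("LSPV", "LIPV", "RSPV", "RIPV")
  me <- mesh_edges(tri)$edges
  ## junction ring: body-side vertices with an edge into any PV sleeve; the
  ## band is the geodesic contour at the distance threshold from the union
  ## of junctions, so close ipsilateral veins get a single merged wide-area
  ## encirclement
  on_pv <- lab %in% pv_labels
  j_edges <- me[xor(on_pv[me[, 1]], on_pv[me[, 2]]), , drop = FALSE]
  junction <- unique(c(j_edges[, 1], j_edges[, 2]))
  junction <- junction[!on_pv[junction]]
  if (length(junction) == 0) stop("no PV/body junction found")
  d <- geodesic_distance(g, junction)
  d[on_pv] <- 0   # sleeves count as inside the encirclement
  if (min(d[surface$boundary_loops$MV]) <= distance_threshold)
    stop("PVI distance threshold too large: lesions reach the mitral rim")
  ## elements crossed by the d = threshold contour (closed by construction),
  ## dilated one ring for a transmural band of about the lesion width
  dmat <- matrix(d[as.vector(tri)], ncol = 3)
  crossed <- which(apply(dmat, 1, min) <= distance_threshold &
                     apply(dmat, 1, max) >= distance_threshold)
  elems <- dilate_elements(tri, crossed)
  ## drop band elements fully inside the sleeves
  elems <- elems[rowSums(matrix(on_pv[as.vector(tri[elems, , drop = FALSE])],
                                ncol = 3)) < 3]
  ls <- new_lesion_set(surface, "pvi", elems, width,
                       list(distance_threshold = distance_threshold))
  ## validation: each PV rim must be disconnected from the MV rim
  keep <- rep(TRUE, nrow(tri))
  keep[ls$elements] <- FALSE
  comp <- element_components(tri, keep)
  rim_comp <- function(loop_name) {
    e <- elements_touching(tri, surface$boundary_loops[[loop_name]])
    unique(stats::na.omit(comp[e]))
  }
  mv_c <- rim_comp("MV")
  if (length(mv_c) == 0)
    stop("PVI distance threshold too large: lesions reach the mitral rim")
  for (pv in pv_labels) {
    if (length(intersect(rim_comp(pv), mv_c)) > 0)
      stop("PVI band fails to encircle ", pv)
  }
  ls
}

## elements crossed by the surf_coord-2 isocontour v = level within a
## coordinate-1 corridor (periodic interval from u_from to u_to, going up)
isocontour_elements <- function(surface, level, u_from, u_to) {
  tri <- surface$triangles
  v <- surface$surf_coord[, 2]
  u <- surface$surf_coord[, 1]
  crosses <- (pmin(v[tri[, 1]], v[tri[, 2]], v[tri[, 3]]) <= level) &
    (pmax(v[tri[, 1]], v[tri[, 2]], v[tri[, 3]]) >= level)
  uc <- matrix(u[as.vector(tri)], ncol = 3)
  ## element center coordinate 1, periodic-safe
  ang <- atan2(rowMeans(sin(2 * pi * uc)), rowMeans(cos(2 * pi * uc)))
  umid <- (ang / (2 * pi)) %% 1
  in_corr <- if (u_from <= u_to) umid >= u_from & umid <= u_to else
    umid >= u_from | umid <= u_to
  which(crosses & in_corr)
}

#' Plan posterior-wall box isolation
#'
#' PVI plus a roof line and an inferior line placed at fixed surface-chart
#' coordinate-2 values across the cohort, connecting the two ipsilateral PV
#' encirclements and disconnecting the posterior wall.
#'
#' @param surface an `atrial_surface`
#' @param roof_v,inferior_v chart coordinate-2 values of the two lines
#' @param width lesion width (mm)
#' @param pvi optional precomputed PVI `lesion_set`
#' @return a `lesion_set`
#' @export
plan_box <- function(surface, roof_v = 0.5, inferior_v = 0.15, width = 3,
                     pvi = NULL) {
  if (is.null(pvi)) pvi <- plan_pvi(surface, width = width)
  tri <- surface$triangles
  corridor <- pv_corridor(surface)
  roof <- isocontour_elements(surface, roof_v, corridor[1], corridor[2])
  inf_ <- isocontour_elements(surface, inferior_v, corridor[1], corridor[2])
  roof <- dilate_elements(tri, roof)
  inf_ <- dilate_elements(tri, inf_)
  elems <- Reduce(union, list(pvi$elements, roof, inf_))
  ls <- new_lesion_set(surface, "box", elems, width,
                       list(roof_v = roof_v, inferior_v = inferior_v))
  ## the lines must meet the PVI bands: the posterior box must then lie in a
  ## different component from the anterior wall
  part <- partition_post_ablation(surface, ls)
  mid_v <- (roof_v + inferior_v) / 2
  post_e <- element_at_chart(surface, mean_periodic(corridor), mid_v)
  ant_e <- element_at_chart(surface, (mean_periodic(corridor) + 0.5) %% 1, mid_v)
  rp <- part$element_region[post_e]
  ra <- part$element_region[ant_e]
  if (!is.na(rp) && !is.na(ra) && rp == ra)
    stop("box lines fail to meet the PVI bands: posterior wall not isolated")
  ls
}

## circular mean of a periodic [0,1) corridor (midpoint crossing the wrap
## correctly)
mean_periodic <- function(uu) {
  a <- atan2(mean(sin(2 * pi * uu)), mean(cos(2 * pi * uu)))
  (a / (2 * pi)) %% 1
}

## non-ablated element whose center is closest to a chart point
element_at_chart <- function(surface, u0, v0) {
  tri <- surface$triangles
  u <- surface$surf_coord[, 1]
  v <- surface$surf_coord[, 2]
  uc <- matrix(u[as.vector(tri)], ncol = 3)
  ang <- atan2(rowMeans(sin(2 * pi * uc)), rowMeans(cos(2 * pi * uc)))
  umid <- (ang / (2 * pi)) %% 1
  vmid <- rowMeans(matrix(v[as.vector(tri)], ncol = 3))
  du <- abs(umid - u0)
  du <- pmin(du, 1 - du)
  which.min(du^2 + (vmid - v0)^2)
}

## periodic coordinate-1 corridor between the two superior PV centers,
## crossing the posterior wall
pv_corridor <- function(surface) {
  us <- vapply(c("LSPV", "RSPV"), function(k)
    (surface$holes[[k]]$theta / (2 * pi)) %% 1, numeric(1))
  c(us["LSPV"], us["RSPV"])
}

#' Plan isolation of fibrotic or driver regions
#'
#' On top of PVI, ablates the selected region(s) (largest or all, in
#' descending area order) and joins each to the closest mesh boundary or
#' lesion component in the growing set with a geodesic-path connecting
#' lesion.
#'
#' @param surface an `atrial_surface`
#' @param regions a `region_set` (fibrotic regions or hotspot map)
#' @param select `"largest"` or `"all"`
#' @param base base lesion set (default: PVI)
#' @param width lesion width (mm)
#' @return a `lesion_set`
#' @export
plan_region_isolation <- function(surface, regions,
                                  select = c("largest", "all"),
                                  base = NULL, width = 3) {
  select <- match.arg(select)
  if (is.null(base)) base <- plan_pvi(surface, width = width)
  strategy <- if (inherits(regions, "hotspot_map")) {
    if (select == "largest") "single_hotspot" else "all_hotspots"
  } else {
    if (select == "largest") "single_fibrosis" else "all_fibrosis"
  }
  if (length(regions$regions) == 0) {
    warning("empty region set: returning base lesion set")
    ls <- base
    ls$strategy <- strategy
    return(ls)
  }
  tri <- surface$triangles
  nv <- nrow(surface$vertices)
  g <- mesh_graph(surface$vertices, surface$triangles)
  take <- if (select == "largest") 1L else seq_along(regions$regions)
  elems <- base$elements
  boundary_v <- unique(unlist(surface$boundary_loops))
  for (ri in take) {
    rv <- regions$regions[[ri]]
    relems <- elements_touching(tri, rv)
    elems <- union(elems, relems)
    ## join to closest boundary loop or lesion component in the growing set
    lesion_v <- unique(as.vector(tri[elems, , drop = FALSE]))
    targets <- union(boundary_v, setdiff(lesion_v,
                                         as.vector(tri[relems, , drop = FALSE])))
    d <- igraph::distances(g, v = rv, to = targets)
    hit <- which(d == min(d), arr.ind = TRUE)[1, ]
    path <- igraph::shortest_paths(g, from = rv[hit[1]],
                                   to = targets[hit[2]])$vpath[[1]]
    path_e <- elements_touching(tri, as.integer(path))
    elems <- union(elems, path_e)
  }
  new_lesion_set(surface, strategy, elems, width,
                 list(select = select, n_regions = length(take)))
}

#' Apply a lesion set to tissue properties
#'
#' Ablated elements get zero conductivity; vertices interior to the lesion
#' (all incident elements ablated) are made inexcitable.
#'
#' @param tissue a `tissue_properties`
#' @param lesions a `lesion_set` (or NULL for no change)
#' @param surface the mesh the tissue lives on
#' @return modified `tissue_properties`
#' @export
apply_lesions <- function(tissue, lesions, surface) {
  if (is.null(lesions) || length(lesions$elements) == 0) return(tissue)
  tissue$sigma_l[lesions$elements] <- 0
  tissue$sigma_t[lesions$elements] <- 0
  tissue$ablated_elements <- lesions$elements
  tissue$inactive_vertices <- interior_vertices(surface$triangles,
                                                lesions$elements,
                                                nrow(surface$vertices))
  tissue
}

#' Partition the post-ablation tissue into connected regions
#'
#' Connected components of non-ablated elements (sharing an edge), with
#' areas in cm^2, sorted descending; identifies the largest region.
#'
#' @param surface the mesh
#' @param lesions a `lesion_set` (or NULL)
#' @return object of class `post_ablation_partition`: list(element_region =
#'   per element region id (NA for ablated), areas = cm^2 sorted descending,
#'   largest = id 1 elements, ablated_area = cm^2)
#' @export
partition_post_ablation <- function(surface, lesions) {
  ta <- triangle_areas(surface$vertices, surface$triangles)
  keep <- rep(TRUE, nrow(surface$triangles))
  ablated <- if (is.null(lesions)) integer(0) else lesions$elements
  keep[ablated] <- FALSE
  comp <- element_components(surface$triangles, keep)
  ids <- sort(unique(comp[!is.na(comp)]))
  areas <- vapply(ids, function(i) sum(ta[which(comp == i)]) / 100, numeric(1))
  ord <- order(areas, decreasing = TRUE)
  remap <- match(comp, ids[ord])
  structure(list(element_region = remap, areas = areas[ord],
                 ablated_area = sum(ta[ablated]) / 100,
                 total_area = sum(ta) / 100),
            class = "post_ablation_partition")
}

#' @exportS3Method base::print
print.post_ablation_partition <- function(x, ...) {
  cat(sprintf("Post-ablation partition: %d region(s); largest %.1f cm^2; ablated %.1f cm^2\n",
              length(x$areas), if (length(x$areas)) x$areas[1] else 0,
              x$ablated_area))
  invisible(x)
}

#' Plan all six ablation strategies for one patient
#'
#' @param surface an `atrial_surface`
#' @param fibrotic a `region_set` of fibrotic regions
#' @param hotspots a `hotspot_map`
#' @param width lesion width (mm)
#' @param pvi_threshold PVI junction distance (mm)
#' @return named list of six `lesion_set`s
#' @export
plan_all_strategies <- function(surface, fibrotic, hotspots, width = 3,
                                pvi_threshold = 5) {
  pvi <- plan_pvi(surface, distance_threshold = pvi_threshold, width = width)
  list(
    pvi = pvi,
    box = plan_box(surface, width = width, pvi = pvi),
    single_fibrosis = suppressWarnings(
      plan_region_isolation(surface, fibrotic, "largest", pvi, width)),
    all_fibrosis = suppressWarnings(
      plan_region_isolation(surface, fibrotic, "all", pvi, width)),
    single_hotspot = suppressWarnings(
      plan_region_isolation(surface, hotspots, "largest", pvi, width)),
    all_hotspots = suppressWarnings(
      plan_region_isolation(surface, hotspots, "all", pvi, width)))
}
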