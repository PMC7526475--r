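## Acute-outcome classification by dominant frequency, the five lesion
## metrics, pre-ablation imaging/electrical features, and per-patient
## optimal-strategy selection.

#' Welch power spectrum of a single trace
#' @noRd
welch_psd <- function(x, fs, window_s = 2, overlap = 0.5, df_res = 0.05) {
  n <- length(x)
  win <- min(n, as.integer(round(window_s * fs)))
  step <- max(1L, as.integer(round(win * (1 - overlap))))
  nfft <- max(win, as.integer(ceiling(fs / df_res)))
  starts <- seq(1, n - win + 1, by = step)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))  # Hann
  acc <- numeric(nfft)
  for (s in starts) {
    seg <- x[s:(s + win - 1)]
    seg <- (seg - mean(seg)) * taper
    acc <- acc + Mod(stats::fft(c(seg, numeric(nfft - win))))^2
  }
  freq <- (seq_len(nfft) - 1) * fs / nfft
  list(freq = freq, power = acc / length(starts))
}

#' Mean dominant frequency of a voltage movie
#'
#' Per-vertex dominant frequency is the peak of the Welch power spectrum in
#' the 0.5-20 Hz band (2 s Hann windows, 50 percent overlap, zero-padded to
#' 0.05 Hz resolution; shorter signals use a single full-length window);
#' the mean is taken over valid vertices, by default the non-quiescent
#' LA-body vertices.
#'
#' @param result a `simulation_result`
#' @param surface the mesh (used for region restriction; optional)
#' @param body_only restrict to LA body vertices (default TRUE if surface
#'   has labels)
#' @param min_sd quiescence cut on trace SD (mV)
#' @return mean dominant frequency (Hz); NA if no vertex is valid
#' @export
dominant_frequency <- function(result, surface = NULL, body_only = TRUE,
                               min_sd = 1) {
  vm <- result$voltage
  fs <- 1000 / result$dt_output
  keep <- rep(TRUE, nrow(vm))
  if (body_only && !is.null(surface) && !is.null(surface$region_label))
    keep <- surface$region_label == "LA_body"
  keep <- keep & result$active
  sds <- apply(vm, 1, stats::sd)
  keep <- keep & sds > min_sd
  if (!any(keep)) return(NA_real_)
  idx <- which(keep)
  dfs <- vapply(idx, function(v) {
    ps <- welch_psd(vm[v, ], fs)
    sel <- ps$freq >= 0.5 & ps$freq <= 20
    ps$freq[sel][which.max(ps$power[sel])]
  }, numeric(1))
  mean(dfs)
}

#' Classify an acute post-ablation outcome
#'
#' Termination if activity dies out; otherwise atrial tachycardia (AT) when
#' the mean dominant frequency is at or below the threshold, atrial
#' fibrillation (AF) above it. Responders are AT and termination.
#'
#' @param result a `simulation_result`
#' @param surface the mesh (for body-restricted DF)
#' @param df_threshold Hz (default 4.7)
#' @return object of class `outcome_label`: list(category, mean_df,
#'   df_threshold, responder)
#' @export
classify_outcome <- function(result, surface = NULL, df_threshold = 4.7) {
  term <- detect_termination(result)
  if (!is.null(term)) {
    return(structure(list(category = "termination", mean_df = NA_real_,
                          df_threshold = df_threshold, responder = TRUE,
                          terminated_at = term), class = "outcome_label"))
  }
  df <- dominant_frequency(result, surface)
  cat_ <- if (is.na(df) || df <= df_threshold) "AT" else "AF"
  structure(list(category = cat_, mean_df = df, df_threshold = df_threshold,
                 responder = cat_ != "AF", terminated_at = NULL),
            class = "outcome_label")
}

#' @exportS3Method base::print
print.outcome_label <- function(x, ...) {
  cat(sprintf("Outcome: %s (%s)%s\n", x$category,
              if (x$responder) "responder" else "non-responder",
              if (!is.na(x$mean_df)) sprintf(", mean DF %.2f Hz", x$mean_df)
              else ""))
  invisible(x)
}

## conducting length (cm) of the v = level isocontour within the given
## elements, restricted to a periodic u corridor
isocontour_length <- function(surface, elements, level, u_from, u_to) {
  if (length(elements) == 0) return(0)
  tri <- surface$triangles[elements, , drop = FALSE]
  v <- surface$surf_coord[, 2]
  u <- surface$surf_coord[, 1]
  verts <- surface$vertices
  total <- 0
  uc <- matrix(u[as.vector(tri)], ncol = 3)
  ang <- atan2(rowMeans(sin(2 * pi * uc)), rowMeans(cos(2 * pi * uc)))
  umid <- (ang / (2 * pi)) %% 1
  in_corr <- if (u_from <= u_to) umid >= u_from & umid <= u_to else
    umid >= u_from | umid <= u_to
  for (e in which(in_corr)) {
    vv <- v[tri[e, ]]
    lo <- min(vv); hi <- max(vv)
    if (lo > level || hi < level) next
    ## segment endpoints: interpolate on the two crossed edges
    pts <- list()
    for (pair in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- vv[pair[1]]; b <- vv[pair[2]]
      if ((a - level) * (b - level) < 0) {
        t <- (level - a) / (b - a)
        pa <- verts[tri[e, pair[1]], ]
        pb <- verts[tri[e, pair[2]], ]
        pts[[length(pts) + 1]] <- pa + t * (pb - pa)
      }
    }
    if (length(pts) == 2)
      total <- total + sqrt(sum((pts[[1]] - pts[[2]])^2))
  }
  total / 10  # mm -> cm
}

#' Lesion metrics on the post-ablation mesh
#'
#' Five metrics from the largest connected post-ablation region: remaining
#' LA surface area; remaining fibrosis area (normalized LGE > 0.56);
#' remaining (pre-ablation) hotspot area; conducting roof width at chart
#' coordinate-2 = 0.5 within the inter-superior-PV corridor; and the minimum
#' Euclidean distance from the mitral rim to ablation lesion components of
#' significant size (area above `significance_fraction` of the second
#' largest component).
#'
#' @param surface an `atrial_surface`
#' @param lesions a `lesion_set`
#' @param partition a `post_ablation_partition`
#' @param lge_norm per-vertex normalized LGE
#' @param hotspots pre-ablation `hotspot_map`
#' @param significance_fraction default 0.8
#' @return list of the five metrics (cm^2 and cm) of class `lesion_metrics`
#' @export
compute_lesion_metrics <- function(surface, lesions, partition, lge_norm,
                                   hotspots, significance_fraction = 0.8) {
  ta <- triangle_areas(surface$vertices, surface$triangles)
  reg <- partition$element_region
  if (length(partition$areas) == 0 || all(is.na(reg))) {
    warning("empty largest region: all-zero lesion metrics")
    return(structure(list(remaining_la_area = 0, remaining_fibrosis_area = 0,
                          remaining_hotspot_area = 0, roof_width = 0,
                          min_channel_height = 0,
                          mv_distance_flagged = TRUE),
                     class = "lesion_metrics"))
  }
  in_largest <- !is.na(reg) & reg == 1L
  largest_e <- which(in_largest)
  remaining_la <- sum(ta[largest_e]) / 100
  tri <- surface$triangles
  ## vertex-level masks restricted to the largest region
  v_in_largest <- rep(FALSE, nrow(surface$vertices))
  v_in_largest[unique(as.vector(tri[largest_e, , drop = FALSE]))] <- TRUE
  va <- vertex_areas(surface$vertices, surface$triangles)
  fib_v <- lge_norm > cv_band_thresholds()[1]
  remaining_fib <- sum(va[fib_v & v_in_largest]) / 100
  hs_v <- !is.na(hotspots$membership)
  remaining_hs <- sum(va[hs_v & v_in_largest]) / 100
  corridor <- pv_corridor(surface)
  roof_w <- isocontour_length(surface, largest_e, 0.5,
                              corridor[1], corridor[2])
  ## smallest channel: MV rim to significant lesion components (Euclidean)
  mv_pts <- surface$vertices[surface$boundary_loops$MV, , drop = FALSE]
  flagged <- FALSE
  if (is.null(lesions) || length(lesions$components) == 0) {
    ## no lesions: distance from MV to the nearest other mesh boundary
    other <- setdiff(names(surface$boundary_loops), "MV")
    d <- vapply(other, function(nm) {
      pts <- surface$vertices[surface$boundary_loops[[nm]], , drop = FALSE]
      min(cross_dist(mv_pts, pts))
    }, numeric(1))
    channel <- min(d) / 10
    flagged <- TRUE
  } else {
    areas <- lesions$component_areas
    second <- if (length(areas) >= 2) sort(areas, decreasing = TRUE)[2] else 0
    sig <- which(areas > significance_fraction * second)
    d <- vapply(sig, function(ci) {
      vidx <- unique(as.vector(tri[lesions$components[[ci]], , drop = FALSE]))
      min(cross_dist(mv_pts, surface$vertices[vidx, , drop = FALSE]))
    }, numeric(1))
    channel <- min(d) / 10
  }
  structure(list(remaining_la_area = remaining_la,
                 remaining_fibrosis_area = remaining_fib,
                 remaining_hotspot_area = remaining_hs,
                 roof_width = roof_w,
                 min_channel_height = channel,
                 mv_distance_flagged = flagged),
            class = "lesion_metrics")
}

## minimum pairwise distances between two point sets (rows)
cross_dist <- function(a, b) {
  aa <- rowSums(a^2)
  bb <- rowSums(b^2)
  d2 <- outer(aa, bb, `+`) - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}

#' Pre-ablation imaging and electrical features
#'
#' Imaging: total LA body, pulmonary vein and fibrotic (z > 3) surface
#' areas. Electrical: mean dominant frequency and total PS hotspot area of
#' the pre-ablation simulation.
#'
#' @param patient a `virtual_patient`
#' @param preablation the pre-ablation `simulation_result`
#' @param hotspots the pre-ablation `hotspot_map`
#' @param fibrotic a fibrotic `region_set` (z > 3 segmentation)
#' @return named list: la_body_area, pv_area, fibrosis_area (cm^2),
#'   mean_df (Hz), hotspot_area (cm^2)
#' @export
imaging_electrical_features <- function(patient, preablation, hotspots,
                                        fibrotic = NULL) {
  s <- patient$surface
  if (is.null(fibrotic))
    fibrotic <- identify_fibrotic_regions(lge_z_score(patient$lge), s)
  list(la_body_area = region_area(s, "LA_body") / 100,
       pv_area = region_area(s, c("LSPV", "LIPV", "RSPV", "RIPV")) / 100,
       fibrosis_area = fibrotic$total_area,
       mean_df = dominant_frequency(preablation, s),
       hotspot_area = hotspots$total_area)
}

#' Select the optimal ablation strategy for one patient
#'
#' Best outcome category (termination > AT > AF); ties broken by the
#' smallest ablated area (the largest remaining connected area is also
#' reported). All-AF patients have no optimal strategy (global
#' non-responders).
#'
#' @param outcomes named list of `outcome_label`s, one per strategy
#' @param lesions named list of `lesion_set`s (same names)
#' @param partitions named list of `post_ablation_partition`s (same names)
#' @return list(strategy or NA, category, by_burden, by_remaining)
#' @export
select_optimal_strategy <- function(outcomes, lesions, partitions) {
  need <- STRATEGIES
  if (!all(need %in% names(outcomes)))
    stop("missing strategies: ",
         paste(setdiff(need, names(outcomes)), collapse = ", "))
  cat_rank <- vapply(outcomes[need], function(o)
    match(o$category, c("termination", "AT", "AF")), numeric(1))
  best <- min(cat_rank)
  if (best == 3)
    return(list(strategy = NA_character_, category = "AF",
                by_burden = NA_character_, by_remaining = NA_character_))
  tied <- need[cat_rank == best]
  burden <- vapply(lesions[tied], function(l) l$ablated_area, numeric(1))
  remaining <- vapply(partitions[tied], function(p)
    if (length(p$areas)) p$areas[1] else 0, numeric(1))
  by_burden <- tied[which.min(burden)]
  by_remaining <- tied[which.max(remaining)]
  list(strategy = by_burden,
       category = c("termination", "AT", "AF")[best],
       by_burden = by_burden, by_remaining = by_remaining)
}
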