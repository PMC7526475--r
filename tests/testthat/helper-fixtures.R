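# Shared fixtures, built once per test run.  Everything is generated in code
# at a deliberately small scale.

fixture_env <- new.env()

# default paroxysmal surface + LGE map (seed 7), reused across files
fx_patient <- function() {
  if (is.null(fixture_env$patient))
    fixture_env$patient <- generate_cohort(1, 0, seed = 7)[[1]]
  fixture_env$patient
}

fx_surface <- function() fx_patient()$surface

fx_tissue <- function() {
  if (is.null(fixture_env$tissue))
    fixture_env$tissue <- build_tissue(fx_surface(), fx_patient()$lge)
  fixture_env$tissue
}

# short pre-ablation AF simulation (1 s) with hotspot map, shared by the
# ablation/outcome/pipeline tests
fx_presim <- function() {
  if (is.null(fixture_env$presim)) {
    s <- fx_surface()
    init <- init_spiral_field(s)
    res <- run_simulation(s, fx_tissue(), init = init, duration = 1000)
    ph <- compute_phase(res)
    tracks <- track_ps(ph, s, res$times)
    dens <- ps_density(tracks, s)
    hot <- suppressWarnings(find_hotspots(dens, s, valid = ph$valid))
    fixture_env$presim <- list(result = res, phase = ph, tracks = tracks,
                               density = dens, hotspots = hot, init = init)
  }
  fixture_env$presim
}

# small flat patch mesh for phase-oracle tests
fx_flat_patch <- function(n = 15, h = 1) {
  strip_mesh(length_mm = (n - 1) * h, width_mm = (n - 1) * h, h = h)
}

# independent brute-force flood fill on the vertex graph (oracle for
# connected-component segmentation)
oracle_flood_fill <- function(triangles, keep) {
  n <- max(triangles)
  adj <- vector("list", n)
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  for (k in seq_len(nrow(e))) {
    a <- e[k, 1]; b <- e[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (v in which(keep)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue) > 0) {
      x <- queue[1]; queue <- queue[-1]
      for (nb in adj[[x]]) {
        if (keep[nb] && is.na(comp[nb])) {
          comp[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

# independent brute-force winding number around an arbitrary vertex loop
oracle_winding <- function(phase, loop) {
  s <- 0
  wrap <- function(x) ((x + pi) %% (2 * pi)) - pi
  for (i in seq_along(loop)) {
    j <- if (i == length(loop)) 1 else i + 1
    s <- s + wrap(phase[loop[j]] - phase[loop[i]])
  }
  round(s / (2 * pi))
}

# stub feature table with a planted deterministic rule, for classifier tests
# that do not need simulations
stub_feature_table <- function(n_anatomies, seed = 1, noise = 0,
                               rule_cutoff = 13) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_anatomies)) {
    id <- sprintf("anat_%03d", i)
    base <- list(la_body_area = rnorm(1, 102, 15),
                 pv_area = rnorm(1, 15, 3),
                 fibrosis_area = rnorm(1, 23, 6),
                 mean_df = rnorm(1, 4.9, 0.1),
                 hotspot_area = rnorm(1, 20, 5))
    for (st in afablate:::STRATEGIES) {
      rem_hs <- max(0, base$hotspot_area *
                      switch(st, all_hotspots = 0,
                             single_hotspot = runif(1, 0.3, 0.7),
                             runif(1, 0.6, 1)))
      # keep a margin around the planted decision boundary so the rule is
      # cleanly separable
      if (abs(rem_hs - rule_cutoff) < 1.5)
        rem_hs <- rule_cutoff + sign(rem_hs - rule_cutoff + 1e-9) * 1.5
      lab <- as.integer(rem_hs + rnorm(1, 0, noise) > rule_cutoff)
      rows[[length(rows) + 1]] <- data.frame(
        anatomy_id = id, strategy = st,
        la_body_area = base$la_body_area, pv_area = base$pv_area,
        fibrosis_area = base$fibrosis_area, mean_df = base$mean_df,
        hotspot_area = base$hotspot_area,
        remaining_hotspot_area = rem_hs,
        remaining_la_area = rnorm(1, 80, 10),
        remaining_fibrosis_area = rnorm(1, 25, 8),
        roof_width = max(0, rnorm(1, 2, 1)),
        min_channel_height = max(0, rnorm(1, 1.8, 0.5)),
        label = lab, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
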