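## Anisotropic monodomain reaction-diffusion on a triangulated surface with
## a phenomenological (Mitchell-Schaeffer) ionic surrogate: P1 finite-element
## Laplace-Beltrami operator with per-element conductivity tensors, explicit
## operator-split stepping in compiled code, spiral-wave initial conditions,
## pacing and conduction-velocity measurement.

## Conversion from conductivity (S/m) to voltage diffusivity (mm^2/ms):
## D = sigma / (beta * Cm) with surface-to-volume ratio beta and membrane
## capacitance Cm chosen so that the baseline longitudinal 0.4 S/m gives
## 0.3 mm^2/ms, in the usual atrial range.
KAPPA_DIFF <- 0.75

#' Surrogate ionic model parameters
#'
#' Mitchell-Schaeffer two-current kinetics on a normalized voltage
#' (0 rest, 1 peak; mapped to mV as -80 + 100 V). Defaults are the frozen
#' package tuning: with AF electrical remodeling they sustain re-entry on the
#' synthetic atrium with dominant frequencies near 5 Hz.
#'
#' @param tau_in,tau_out,tau_open,tau_close time constants (ms)
#' @param v_gate recovery-gate threshold (normalized voltage)
#' @param v_rest_mv,v_amp_mv affine map from normalized voltage to mV
#' @return list of class `ms_params`
#' @export
ms_params <- function(tau_in = 0.3, tau_out = 6, tau_open = 110,
                      tau_close = 150, v_gate = 0.13,
                      v_rest_mv = -80, v_amp_mv = 100) {
  structure(list(tau_in = tau_in, tau_out = tau_out, tau_open = tau_open,
                 tau_close = tau_close, v_gate = v_gate,
                 v_rest_mv = v_rest_mv, v_amp_mv = v_amp_mv),
            class = "ms_params")
}

## Fixed mapping from named channel-conductance multipliers to surrogate
## parameters. Sodium availability scales excitability (tau_in); the
## repolarization balance (ICaL inward vs K currents outward) scales action
## potential duration (tau_close). Exponents are a frozen design choice,
## documented in the methods vignette.
#' Per-vertex surrogate parameters from ionic multipliers
#' @param ionic base `ms_params`
#' @param mult matrix of multipliers from [apply_ionic_remodeling()]
#' @return list of per-vertex parameter vectors
#' @export
ms_params_per_vertex <- function(ionic, mult) {
  n <- nrow(mult)
  tau_close_scale <- mult[, "gCaL"]^0.45 * mult[, "gK1"]^(-0.25) *
    mult[, "gto"]^(-0.1) * mult[, "gKur"]^(-0.1) *
    mult[, "gKr"]^(-0.1) * mult[, "gKs"]^(-0.05)
  list(tau_in = rep(ionic$tau_in, n) / mult[, "gNa"],
       tau_out = rep(ionic$tau_out, n),
       tau_open = rep(ionic$tau_open, n),
       tau_close = ionic$tau_close * tau_close_scale,
       v_gate = ionic$v_gate)
}

#' Assemble the anisotropic P1 stiffness operator
#'
#' Per-element conductivity tensor sigma_l f f^T + sigma_t (I - f f^T) with
#' f the element fiber direction; natural no-flux boundaries; symmetric with
#' zero row sums. Entries are scaled to diffusivity units so that
#' -(K V) / mass is dV/dt in 1/ms.
#'
#' @param surface mesh with vertices/triangles and `fiber` per element
#' @param tissue `tissue_properties` with per-element sigma_l, sigma_t (S/m)
#' @return list(K = dgCMatrix stiffness, mass = lumped vertex areas)
#' @export
build_diffusion_operator <- function(surface, tissue) {
  v <- surface$vertices
  f <- surface$triangles
  fib <- surface$fiber
  areas <- triangle_areas(v, f)
  if (any(areas < 1e-9))
    stop("degenerate triangles (zero area): elements ",
         paste(utils::head(which(areas < 1e-9), 5), collapse = ", "))
  nrm <- triangle_normals(v, f)
  m <- nrow(f)
  ## P1 basis gradients: grad(lambda_i) = (n x e_i) / (2A), e_i opposite edge
  grads <- vector("list", 3)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  edges_opp <- list(p3 - p2, p1 - p3, p2 - p1)
  crossm <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
  for (i in 1:3) grads[[i]] <- crossm(nrm, edges_opp[[i]]) / (2 * areas)
  ## element tensor applied to gradients: D g = dl (f.g) f + dt (g - (f.g) f)
  dl <- KAPPA_DIFF * tissue$sigma_l
  dt_ <- KAPPA_DIFF * tissue$sigma_t
  Dg <- vector("list", 3)
  for (i in 1:3) {
    fg <- rowSums(fib * grads[[i]])
    Dg[[i]] <- fib * ((dl - dt_) * fg) + grads[[i]] * dt_
  }
  ii <- jj <- integer(9 * m)
  xx <- numeric(9 * m)
  k <- 0
  for (i in 1:3) for (j in 1:3) {
    idx <- k * m + seq_len(m)
    ii[idx] <- f[, i]
    jj[idx] <- f[, j]
    xx[idx] <- areas * rowSums(grads[[i]] * Dg[[j]])
    k <- k + 1
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(v), nrow(v)))
  mass <- vertex_areas(v, f)
  list(K = methods::as(K, "CsparseMatrix"), mass = mass)
}

#' Run a monodomain simulation
#'
#' Explicit operator-split stepping of the surrogate kinetics plus the
#' assembled diffusion operator; fully deterministic.
#'
#' @param surface mesh (atrial surface or strip)
#' @param tissue `tissue_properties`
#' @param ionic base `ms_params`
#' @param init `"rest"`, or a list(V, h) of normalized per-vertex states
#'   (e.g. from [init_spiral_field()] or a previous result's `state`)
#' @param duration ms
#' @param dt reaction/diffusion step (ms)
#' @param dt_output frame spacing (ms)
#' @param stim optional list(vertices, t0, duration, amp): pacing current
#'   (amp in normalized voltage per ms) applied to the given vertices
#' @param operator optional precomputed [build_diffusion_operator()] result
#' @return object of class `simulation_result`: `voltage` (mV, vertices x
#'   frames), `times` (ms), `state` (final V, h), `dt_output`, `duration`
#' @export
run_simulation <- function(surface, tissue, ionic = ms_params(),
                           init = "rest", duration = 1000, dt = 0.1,
                           dt_output = 5, stim = NULL, operator = NULL) {
  op <- if (is.null(operator)) build_diffusion_operator(surface, tissue) else operator
  nv <- nrow(surface$vertices)
  ## stability: explicit bound via Gershgorin on mass-scaled stiffness
  lam <- max(Matrix::rowSums(abs(op$K)) / op$mass)
  if (dt > 1.9 / lam)
    stop(sprintf("dt = %g ms unstable for this mesh (need dt < %.3g ms)",
                 dt, 1.9 / lam))
  pv <- ms_params_per_vertex(ionic, tissue$ionic_multipliers)
  active <- rep(TRUE, nv)
  active[tissue$inactive_vertices] <- FALSE
  if (identical(init, "rest")) {
    V0 <- numeric(nv); h0 <- rep(1, nv)
  } else {
    V0 <- init$V; h0 <- init$h
    stopifnot(length(V0) == nv, length(h0) == nv)
  }
  stim_amp <- numeric(0); stim_t0 <- 0; stim_dur <- 0
  if (!is.null(stim)) {
    stim_amp <- numeric(nv)
    stim_amp[stim$vertices] <- stim$amp
    stim_t0 <- stim$t0
    stim_dur <- stim$duration
  }
  out_every <- max(1L, as.integer(round(dt_output / dt)))
  n_steps <- as.integer(round(duration / dt))
  res <- ms_run_cpp(op$K@p, op$K@i, op$K@x, op$mass, V0, h0,
                    pv$tau_in, pv$tau_out, pv$tau_open, pv$tau_close,
                    pv$v_gate, active, dt, n_steps, out_every,
                    stim_amp, stim_t0, stim_dur)
  if (res$diverged_at >= 0)
    stop(sprintf("simulation diverged (NaN/overflow) at t = %.1f ms",
                 res$diverged_at))
  frames <- ionic$v_rest_mv + ionic$v_amp_mv * res$frames
  times <- seq(0, by = dt * out_every, length.out = ncol(frames))
  structure(list(voltage = frames, times = times,
                 dt_output = dt * out_every, duration = duration,
                 state = list(V = res$V, h = res$h),
                 active = active,
                 threshold_mv = ionic$v_rest_mv + ionic$v_amp_mv * ionic$v_gate,
                 v_rest_mv = ionic$v_rest_mv),
            class = "simulation_result")
}

#' @exportS3Method base::print
print.simulation_result <- function(x, ...) {
  cat(sprintf("Monodomain simulation: %d vertices, %.0f ms (%d frames every %g ms)\n",
              nrow(x$voltage), x$duration, ncol(x$voltage), x$dt_output))
  term <- detect_termination(x)
  cat(if (is.null(term)) "  activity persists to end of run\n"
      else sprintf("  activity terminated at %.0f ms\n", term))
  invisible(x)
}

#' Per-vertex activation time of the first beat after `after` ms
#'
#' Linear interpolation of the upstroke crossing of `threshold_mv`.
#' @param result a `simulation_result`
#' @param threshold_mv crossing level (default -40 mV)
#' @param after ignore frames before this time (ms)
#' @return per-vertex activation time in ms (NA if never activated)
#' @export
activation_times <- function(result, threshold_mv = -40, after = 0) {
  vm <- result$voltage
  keep <- result$times >= after
  vm <- vm[, keep, drop = FALSE]
  tt <- result$times[keep]
  nv <- nrow(vm)
  out <- rep(NA_real_, nv)
  above <- vm > threshold_mv
  for (v in seq_len(nv)) {
    idx <- which(above[v, ])
    if (length(idx) == 0) next
    k <- idx[1]
    if (k == 1) { out[v] <- tt[1]; next }
    v0 <- vm[v, k - 1]; v1 <- vm[v, k]
    out[v] <- tt[k - 1] + (threshold_mv - v0) / (v1 - v0) * (tt[k] - tt[k - 1])
  }
  out
}

#' Conduction velocity between two probes (mm/ms)
#'
#' Geodesic distance divided by activation-time difference; both probes must
#' be activated by the same planar beat.
#' @param result a `simulation_result`
#' @param surface the mesh the simulation ran on
#' @param probe_a,probe_b vertex indices (wave reaches a before b)
#' @export
measure_cv <- function(result, surface, probe_a, probe_b) {
  at <- activation_times(result)
  if (is.na(at[probe_a]) || is.na(at[probe_b]))
    stop("probe not activated")
  g <- mesh_graph(surface$vertices, surface$triangles)
  d <- igraph::distances(g, v = probe_a, to = probe_b)[1, 1]
  dt <- abs(at[probe_b] - at[probe_a])
  if (dt <= 0) stop("zero activation-time difference between probes")
  d / dt
}

#' Planar-wave CV on a uniform strip for a conductivity scale factor
#' @noRd
strip_cv <- function(scale = 1, sigma_l = 0.4, sigma_t = 0.1, h = 0.5,
                     ionic = ms_params(), length_mm = 40, width_mm = 10,
                     dt = 0.05) {
  strip <- strip_mesh(length_mm, width_mm, h)
  tis <- uniform_strip_tissue(strip, sigma_l, sigma_t, scale = scale)
  left <- which(strip$vertices[, 1] < 1e-9)
  ## probes on the mid row at 25% and 75% length
  midy <- width_mm / 2
  target <- function(x) which.min((strip$vertices[, 1] - x)^2 +
                                    (strip$vertices[, 2] - midy)^2)
  pa <- target(0.25 * length_mm)
  pb <- target(0.75 * length_mm)
  ## slow media need time: bound duration by twice the slowest plausible CV
  dur <- min(1500, 100 + 2 * length_mm / (0.05 * sqrt(scale)))
  res <- run_simulation(strip, tis, ionic, duration = dur, dt = dt,
                        dt_output = 0.5,
                        stim = list(vertices = left, t0 = 2, duration = 2,
                                    amp = 1))
  measure_cv(res, strip, pa, pb)
}

#' Earliest quiescence time of a simulation
#'
#' Returns the earliest time after which no vertex exceeds the activation
#' threshold for a full quiescence window, or `NULL` if activity persists to
#' the end of the run.
#'
#' @param result a `simulation_result`
#' @param threshold_mv activity threshold (default -40 mV)
#' @param window quiescence window (ms)
#' @return time in ms, or NULL
#' @export
detect_termination <- function(result, threshold_mv = -40, window = 300) {
  act <- apply(result$voltage > threshold_mv, 2, any)
  if (!any(act)) return(0)
  last <- max(which(act))
  t_last <- result$times[last]
  if (result$times[length(result$times)] - t_last >= window) t_last else NULL
}

#' Reference action-potential cycle from a paced cable
#'
#' One paced beat on a thin cable; the full state trajectory at a mid-cable
#' probe, aligned to the upstroke, used to seed spiral-wave initial states.
#'
#' @param ionic base `ms_params`
#' @param tissue_mult a single-row multiplier matrix for the tissue the
#'   spirals will run in (default: AF-remodeled LA body)
#' @param cycle_length ms
#' @return list(V, h, times, apd): normalized state sampled at 1 ms
#' @export
reference_cycle <- function(ionic = ms_params(), tissue_mult = NULL,
                            cycle_length = 250) {
  strip <- strip_mesh(30, 1.5, 0.5)
  nv <- nrow(strip$vertices)
  if (is.null(tissue_mult)) {
    z <- 0
    mult <- apply_ionic_remodeling(rep(0, nv),
                                   factor(rep("LA_body", nv),
                                          levels = c("LA_body", "LAA", "LSPV",
                                                     "LIPV", "RSPV", "RIPV")),
                                   af_remodeling = TRUE)
  } else {
    mult <- tissue_mult[rep(1, nv), , drop = FALSE]
  }
  tis <- uniform_strip_tissue(strip)
  tis$ionic_multipliers <- mult
  left <- which(strip$vertices[, 1] < 1e-9)
  res <- run_simulation(strip, tis, ionic, duration = cycle_length + 80,
                        dt = 0.05, dt_output = 1,
                        stim = list(vertices = left, t0 = 2, duration = 2,
                                    amp = 1))
  probe <- which.min((strip$vertices[, 1] - 15)^2 + strip$vertices[, 2]^2)
  ## recover h at the probe by re-integrating the local gate from V(t)
  vm <- (res$voltage[probe, ] - ionic$v_rest_mv) / ionic$v_amp_mv
  tt <- res$times
  up <- which(vm > ionic$v_gate)[1]
  if (is.na(up)) stop("reference beat failed to propagate")
  t0 <- tt[up]
  keep <- tt >= t0
  Vref <- vm[keep]
  ## integrate the gate ODE along the recorded voltage
  pv <- ms_params_per_vertex(ionic, mult[probe, , drop = FALSE])
  href <- numeric(length(Vref))
  hh <- 1
  for (i in seq_along(Vref)) {
    href[i] <- hh
    dh <- if (Vref[i] < ionic$v_gate) (1 - hh) / pv$tau_open[1] else
      -hh / pv$tau_close[1]
    hh <- hh + 1 * dh
  }
  apd <- sum(Vref > ionic$v_gate) * 1
  ## extend to cycle_length with rest recovery if the record is short
  need <- as.integer(ceiling(cycle_length)) + 1
  if (length(Vref) < need) {
    extra <- need - length(Vref)
    Vext <- numeric(extra)
    hext <- numeric(extra)
    for (i in seq_len(extra)) {
      hh <- hh + 1 * (1 - hh) / pv$tau_open[1]
      Vext[i] <- 0
      hext[i] <- hh
    }
    Vref <- c(Vref, Vext)
    href <- c(href, hext)
  }
  list(V = Vref[seq_len(need)], h = href[seq_len(need)],
       times = seq_len(need) - 1, apd = apd)
}

#' Spiral-wave initial state (four Archimedean spirals)
#'
#' Builds an activation-time field from four Archimedean spiral phase fields
#' (two on the anterior and two on the posterior wall, adjacent spirals with
#' opposite chirality) in the surface-chart disk, then sets each vertex's
#' state to the reference-cycle state at the corresponding cycle phase.
#'
#' @param surface an `atrial_surface` with surf_coord
#' @param cycle_length ms
#' @param ionic base `ms_params`
#' @param ref optional precomputed [reference_cycle()]
#' @param lambda Archimedean pitch in chart-disk units (turn spacing)
#' @return list(V, h, t_act, phase0, centers): normalized initial state, the
#'   activation-time field (ms, in [0, cycle_length)), and the analytic
#'   phase of frame 0 in (-pi, pi]
#' @export
init_spiral_field <- function(surface, cycle_length = 330,
                              ionic = ms_params(), ref = NULL,
                              lambda = 0.12) {
  if (is.null(ref)) ref <- reference_cycle(ionic, cycle_length = cycle_length)
  if (cycle_length < ref$apd + 30)
    stop("cycle_length (", cycle_length,
         " ms) is shorter than the model refractory period (~",
         round(ref$apd + 30), " ms)")
  u <- surface$surf_coord[, 1]
  v <- surface$surf_coord[, 2]
  ## chart disk: radius 1 - c2, angle 2 pi c1 (continuous across the seam)
  zr <- (1 - v) * cos(2 * pi * u)
  zi <- (1 - v) * sin(2 * pi * u)
  centers_u <- c(0.13, 0.37, 0.63, 0.87)
  charges <- c(1L, -1L, 1L, -1L)
  centers_v <- rep(0.45, 4)
  cr <- (1 - centers_v) * cos(2 * pi * centers_u)
  ci <- (1 - centers_v) * sin(2 * pi * centers_u)
  phi <- numeric(length(u))
  for (k in 1:4) {
    dr <- zr - cr[k]
    di <- zi - ci[k]
    phi <- phi + charges[k] * (atan2(di, dr) + sqrt(dr^2 + di^2) / lambda)
  }
  t_act <- (phi %% (2 * pi)) / (2 * pi) * cycle_length
  ## state at time-since-upstroke (cycle_length - t_act) mod cycle_length
  s <- (cycle_length - t_act) %% cycle_length
  idx <- pmin(length(ref$V), floor(s) + 1)
  V <- ref$V[idx]
  h <- ref$h[idx]
  phase0 <- ((-2 * pi * t_act / cycle_length + pi) %% (2 * pi)) - pi
  list(V = V, h = h, t_act = t_act, phase0 = phase0,
       centers = cbind(u = centers_u, v = centers_v, charge = charges))
}
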