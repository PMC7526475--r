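test_that("diffusion operator has zero row sums, symmetry, and matches the flat Laplacian", {
  strip <- strip_mesh(20, 20, 1)
  tis <- uniform_strip_tissue(strip, sigma_l = 0.4, sigma_t = 0.4)
  op <- build_diffusion_operator(strip, tis)
  expect_lt(max(abs(Matrix::rowSums(op$K))), 1e-10)
  expect_lt(max(abs(op$K - Matrix::t(op$K))), 1e-10)
  # isotropic operator on a quadratic field: (K u)/mass approximates
  # -D * laplacian(u) = -D * 4 for u = x^2 + y^2 on interior vertices
  D <- afablate:::KAPPA_DIFF * 0.4
  u <- strip$vertices[, 1]^2 + strip$vertices[, 2]^2
  r <- as.numeric(op$K %*% u) / op$mass
  interior <- strip$vertices[, 1] > 4 & strip$vertices[, 1] < 16 &
    strip$vertices[, 2] > 4 & strip$vertices[, 2] < 16
  expect_equal(mean(r[interior]), -4 * D, tolerance = 0.05)
})

test_that("degenerate triangles are rejected by the assembler", {
  strip <- strip_mesh(10, 5, 1)
  strip$vertices[strip$triangles[1, 2], ] <- strip$vertices[strip$triangles[1, 1], ]
  tis <- uniform_strip_tissue(strip)
  expect_error(build_diffusion_operator(strip, tis), "degenerate")
})

test_that("resting tissue stays at rest without stimulus", {
  strip <- strip_mesh(20, 5, 1)
  tis <- uniform_strip_tissue(strip)
  res <- run_simulation(strip, tis, duration = 300)
  expect_lt(max(abs(res$voltage - (-80))), 0.1)
})

test_that("simulations are deterministic and temporally converged", {
  strip <- strip_mesh(30, 5, 0.75)
  tis <- uniform_strip_tissue(strip)
  left <- which(strip$vertices[, 1] < 1e-9)
  stim <- list(vertices = left, t0 = 2, duration = 2, amp = 1)
  r1 <- run_simulation(strip, tis, duration = 120, dt = 0.1, dt_output = 1,
                       stim = stim)
  r2 <- run_simulation(strip, tis, duration = 120, dt = 0.1, dt_output = 1,
                       stim = stim)
  expect_identical(r1$voltage, r2$voltage)
  r3 <- run_simulation(strip, tis, duration = 120, dt = 0.05, dt_output = 1,
                       stim = stim)
  a1 <- activation_times(r1)
  a3 <- activation_times(r3)
  expect_lt(max(abs(a1 - a3), na.rm = TRUE), 1)
})

test_that("unstable time steps are rejected", {
  strip <- strip_mesh(10, 5, 0.25)
  tis <- uniform_strip_tissue(strip)
  expect_error(run_simulation(strip, tis, duration = 10, dt = 5), "unstable")
})

test_that("conduction is physiological, distance-linear, and anisotropic", {
  strip <- strip_mesh(40, 10, 0.5)
  tis <- uniform_strip_tissue(strip)
  left <- which(strip$vertices[, 1] < 1e-9)
  res <- run_simulation(strip, tis, duration = 150, dt = 0.05,
                        dt_output = 0.5,
                        stim = list(vertices = left, t0 = 2, duration = 2,
                                    amp = 1))
  probe <- function(x) which.min((strip$vertices[, 1] - x)^2 +
                                   (strip$vertices[, 2] - 5)^2)
  cv1 <- measure_cv(res, strip, probe(10), probe(30))
  expect_gt(cv1, 0.4)
  expect_lt(cv1, 1.2)
  # doubling probe separation: same CV within 1 percent
  cv2 <- measure_cv(res, strip, probe(15), probe(25))
  expect_lt(abs(cv1 - cv2) / cv1, 0.01)
  # transverse propagation: fibers across the strip, expect
  # CV_t / CV_l = sqrt(sigma_t / sigma_l) = 0.5 within 10 percent
  stripT <- strip_mesh(40, 10, 0.5)
  stripT$fiber <- matrix(rep(c(0, 1, 0), each = nrow(stripT$triangles)),
                         ncol = 3)
  resT <- run_simulation(stripT, uniform_strip_tissue(stripT),
                         duration = 250, dt = 0.05, dt_output = 0.5,
                         stim = list(vertices = left, t0 = 2, duration = 2,
                                     amp = 1))
  cvT <- measure_cv(resT, stripT, probe(10), probe(30))
  expect_lt(abs(cvT / cv1 - 0.5), 0.05)
  expect_error(measure_cv(res, strip, probe(10), probe(10)), "zero")
})

test_that("zero-conductivity bands block propagation", {
  strip <- strip_mesh(40, 10, 1)
  tis <- uniform_strip_tissue(strip)
  mid <- strip$vertices[strip$triangles[, 1], 1]
  band <- which(mid > 18 & mid < 23)
  tis$sigma_l[band] <- 0
  tis$sigma_t[band] <- 0
  # clamp fully-interior band vertices, as apply_lesions does
  tis$inactive_vertices <- afablate:::interior_vertices(
    strip$triangles, band, nrow(strip$vertices))
  left <- which(strip$vertices[, 1] < 1e-9)
  res <- run_simulation(strip, tis, duration = 300,
                        stim = list(vertices = left, t0 = 2, duration = 2,
                                    amp = 1))
  far <- which(strip$vertices[, 1] > 30)
  near <- which(strip$vertices[, 1] < 10)
  expect_gt(max(res$voltage[near, ]), -40)
  expect_lt(max(res$voltage[far, ]), -40)
})

test_that("termination detection reports quiescence onset", {
  # synthetic movies with planted activity patterns
  mk <- function(vm, dt = 5) structure(list(
    voltage = vm, times = seq(0, by = dt, length.out = ncol(vm)),
    dt_output = dt, duration = dt * (ncol(vm) - 1),
    active = rep(TRUE, nrow(vm))), class = "simulation_result")
  rest <- mk(matrix(-80, 5, 400))
  expect_equal(detect_termination(rest), 0)
  # quiescent from 1200 ms
  vm <- matrix(-80, 5, 400)
  vm[, seq_len(240)] <- 20
  expect_lt(abs(detect_termination(mk(vm)) - 1200), 5 + 1e-9)
  # activity to the end: no termination
  vm2 <- matrix(c(-80, 20), 5, 400)
  expect_null(detect_termination(mk(vm2)))
})

test_that("spiral initialization produces four alternating phase singularities", {
  s <- fx_surface()
  init <- fx_presim()$init
  ps <- detect_ps(init$phase0, s)
  expect_equal(nrow(ps), 4)
  expect_setequal(ps$charge, c(1, -1))
  expect_equal(sum(ps$charge), 0)
  # activation times live in [0, cycle_length)
  expect_true(all(init$t_act >= 0 & init$t_act < 330))
  # spirals alternate chirality around the chamber: order PS by chart
  # coordinate 1 of their element centroid
  u <- rowMeans(matrix(s$surf_coord[as.vector(s$triangles[ps$element, ]), 1],
                       ncol = 3))
  expect_true(all(abs(diff(ps$charge[order(u)])) == 2))
  # a cycle length below the refractory period is rejected
  expect_error(init_spiral_field(s, cycle_length = 60), "refractory")
})
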