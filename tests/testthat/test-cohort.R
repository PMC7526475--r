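test_that("generated surfaces satisfy the geometric invariants", {
  s <- fx_surface()
  nv <- nrow(s$vertices)
  ne <- nrow(mesh_edges(s$triangles)$edges)
  nf <- nrow(s$triangles)
  # sphere with 5 open disks: V - E + F = 2 - 5
  expect_equal(nv - ne + nf, -3L)
  expect_length(s$boundary_loops, 5)
  expect_named(s$boundary_loops, c("MV", "LSPV", "LIPV", "RSPV", "RIPV"))
  # single connected component
  comp <- afablate:::element_components(s$triangles, rep(TRUE, nf))
  expect_true(all(comp == 1L))
  # one label per vertex, chart within the unit square
  expect_false(anyNA(s$region_label))
  expect_true(all(s$surf_coord >= 0 & s$surf_coord <= 1))
  # each PV region touches exactly one boundary loop
  for (pv in c("LSPV", "LIPV", "RSPV", "RIPV")) {
    pv_v <- which(s$region_label == pv)
    touching <- vapply(s$boundary_loops, function(lp)
      length(intersect(lp, pv_v)) > 0, logical(1))
    expect_equal(sum(touching), 1L)
    expect_true(touching[pv])
  }
})

test_that("surface generation is deterministic and jitter-free presets are congruent", {
  p <- cohort_preset("paroxysmal")$geometry
  s1 <- generate_surface(42, p)
  s2 <- generate_surface(42, p)
  expect_identical(s1$vertices, s2$vertices)
  expect_identical(s1$fiber, s2$fiber)
  p0 <- p
  p0$jitter <- 0
  a <- generate_surface(1, p0)
  b <- generate_surface(999, p0)
  expect_equal(a$vertices, b$vertices)
  expect_identical(a$triangles, b$triangles)
})

test_that("overlapping holes raise a parameter error", {
  p <- cohort_preset("paroxysmal")$geometry
  p$holes$LSPV$theta <- p$holes$LIPV$theta
  p$holes$LSPV$phi <- p$holes$LIPV$phi
  expect_error(generate_surface(1, p), "overlap")
})

test_that("surface chart is injective on the body away from the seam", {
  s <- fx_surface()
  body <- which(s$region_label == "LA_body")
  set.seed(1)
  idx <- sample(body, 200)
  uv <- s$surf_coord[idx, ]
  d_uv <- as.matrix(stats::dist(uv))
  d_xyz <- as.matrix(stats::dist(s$vertices[idx, ]))
  h <- 2.4  # edge length scale (mm)
  clash <- d_uv < 1e-3 & d_xyz > 5 * h
  expect_false(any(clash[upper.tri(clash)]))
})

test_that("fiber fields are unit, tangent, and smoother for longer correlation lengths", {
  s <- fx_surface()
  f1 <- generate_fiber_field(s, seed = 3, corr_len = 5)
  expect_equal(sqrt(rowSums(f1^2)), rep(1, nrow(s$triangles)), tolerance = 1e-9)
  nrm <- afablate:::triangle_normals(s$vertices, s$triangles)
  expect_lt(max(abs(rowSums(f1 * nrm))), 1e-9)
  # mean angular difference between edge-adjacent triangles decreases with
  # correlation length
  e <- rbind(s$triangles[, 1:2], s$triangles[, 2:3], s$triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tid <- rep(seq_len(nrow(s$triangles)), 3)
  key <- paste(e[, 1], e[, 2])
  ord <- order(key)
  same <- key[ord][-1] == key[ord][-length(key)]
  pairs <- cbind(tid[ord][c(same, FALSE)], tid[ord][c(FALSE, same)])
  mean_angle <- function(f) {
    cosang <- abs(rowSums(f[pairs[, 1], ] * f[pairs[, 2], ]))
    mean(acos(pmin(1, cosang)))
  }
  angs <- vapply(c(5, 15, 50), function(cl)
    mean_angle(generate_fiber_field(s, seed = 3, corr_len = cl)), numeric(1))
  expect_true(all(diff(angs) < 0))
  # infinite correlation length: globally parallel up to tangent projection
  finf <- generate_fiber_field(s, seed = 3, corr_len = Inf)
  g <- colMeans(finf)
  g <- g / sqrt(sum(g^2))
  resid <- finf - nrm * rowSums(nrm * matrix(g, nrow(finf), 3, byrow = TRUE))
  # fibers should align with the projected global direction
  proj <- matrix(g, nrow(finf), 3, byrow = TRUE) -
    nrm * rowSums(nrm * matrix(g, nrow(finf), 3, byrow = TRUE))
  proj <- proj / pmax(sqrt(rowSums(proj^2)), 1e-12)
  align <- abs(rowSums(finf * proj))
  expect_gt(stats::median(align), 0.99)
})

test_that("LGE maps degenerate correctly and reject bad parameters", {
  s <- fx_surface()
  p <- cohort_preset("paroxysmal")$lge
  p$n_blobs_base <- 0L
  p$n_blobs_jitter <- 0L
  p$noise_sd <- 0
  l <- generate_lge_map(s, 1, p)
  expect_true(all(l$intensity == p$baseline))
  p$noise_sd <- -1
  expect_error(generate_lge_map(s, 1, p), "positive")
})

test_that("cohorts have the requested composition and are reproducible", {
  co <- generate_cohort(3, 2, seed = 11)
  expect_length(co, 5)
  expect_equal(sum(vapply(co, function(p) p$af_class, "") == "paroxysmal"), 3)
  expect_length(generate_cohort(0, 0, seed = 1), 0)
  co2 <- generate_cohort(3, 2, seed = 11)
  for (i in seq_along(co)) {
    expect_identical(co[[i]]$surface$vertices, co2[[i]]$surface$vertices)
    expect_identical(co[[i]]$lge$intensity, co2[[i]]$lge$intensity)
  }
})

test_that("cohort means reproduce the study calibration within one printed SD", {
  # 10-patient paroxysmal cohort: LA body area near 102.1 +/- 19.0 cm^2 and
  # fibrotic (z > 3) area near 23.2 +/- 7.89 cm^2
  co <- generate_cohort(10, 0, seed = 5)
  areas <- vapply(co, function(p) region_area(p$surface, "LA_body") / 100,
                  numeric(1))
  fib <- vapply(co, function(p)
    identify_fibrotic_regions(lge_z_score(p$lge), p$surface)$total_area,
    numeric(1))
  expect_lt(abs(mean(areas) - 102.1), 19.0)
  expect_lt(abs(mean(fib) - 23.2), 7.89)
})
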