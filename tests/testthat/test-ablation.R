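test_that("PVI encircles every vein and is contained in all other strategies", {
  s <- fx_surface()
  pre <- fx_presim()
  fib <- identify_fibrotic_regions(lge_z_score(fx_patient()$lge), s)
  plans <- plan_all_strategies(s, fib, pre$hotspots)
  pvi <- plans$pvi
  # complement of the PVI set has multiple components (closed annuli)
  part <- partition_post_ablation(s, pvi)
  expect_gte(length(part$areas), 3)
  # every PV rim is disconnected from the mitral rim
  rim_region <- function(loop) {
    e <- afablate:::elements_touching(s$triangles, s$boundary_loops[[loop]])
    unique(stats::na.omit(part$element_region[e]))
  }
  mv <- rim_region("MV")
  for (pv in c("LSPV", "LIPV", "RSPV", "RIPV"))
    expect_length(intersect(rim_region(pv), mv), 0)
  # PVI elements are a subset of every other strategy's element set
  for (st in setdiff(names(plans), "pvi"))
    expect_true(all(pvi$elements %in% plans[[st]]$elements))
  # ... so PVI leaves the most remaining tissue
  rem <- vapply(plans, function(L)
    partition_post_ablation(s, L)$areas[1], numeric(1))
  expect_true(all(rem["pvi"] >= rem))
  # monotone burden: all_X >= single_X >= pvi
  ab <- vapply(plans, function(L) L$ablated_area, numeric(1))
  expect_gte(ab["all_fibrosis"], ab["single_fibrosis"])
  expect_gte(ab["all_hotspots"], ab["single_hotspot"])
  expect_gte(ab["single_fibrosis"], ab["pvi"])
  expect_gte(ab["single_hotspot"], ab["pvi"])
  # excessive threshold errors out
  expect_error(plan_pvi(s, distance_threshold = 60), "mitral")
})

test_that("box isolation disconnects the posterior wall from the anterior wall", {
  s <- fx_surface()
  box <- plan_box(s)
  pvi <- plan_pvi(s)
  expect_gt(box$ablated_area, pvi$ablated_area)
  part <- partition_post_ablation(s, box)
  expect_gte(length(part$areas), 2)
  post_e <- afablate:::element_at_chart(s, 0.75, 0.33)
  ant_e <- afablate:::element_at_chart(s, 0.25, 0.33)
  expect_false(identical(part$element_region[post_e],
                         part$element_region[ant_e]))
  # posterior box region is smaller than the main region
  rp <- part$element_region[post_e]
  expect_gt(part$areas[1], part$areas[rp])
})

test_that("region isolation joins lesions and matches single/all semantics", {
  s <- fx_surface()
  pvi <- plan_pvi(s)
  # single planted region: select = largest and all coincide
  c1 <- which.min(abs(s$surf_coord[, 1] - 0.4) + abs(s$surf_coord[, 2] - 0.55))
  z <- rep(0, nrow(s$vertices))
  z[geodesic_distance(s, c1) < 7] <- 5
  rs <- identify_fibrotic_regions(z, s)
  expect_length(rs$regions, 1)
  a <- plan_region_isolation(s, rs, "largest", pvi)
  b <- plan_region_isolation(s, rs, "all", pvi)
  expect_identical(a$elements, b$elements)
  # empty region set returns the base with a warning
  none <- identify_fibrotic_regions(rep(0, nrow(s$vertices)), s)
  expect_warning(c0 <- plan_region_isolation(s, none, "all", pvi), "empty")
  expect_identical(c0$elements, pvi$elements)
  # no free-floating islands: every lesion component touches a boundary
  # loop, touches another component, or separates the mesh (encircles a rim)
  boundary_v <- unique(unlist(s$boundary_loops))
  for (L in list(a, plan_box(s, pvi = pvi))) {
    for (ci in seq_along(L$components)) {
      comp_v <- unique(as.vector(s$triangles[L$components[[ci]], ]))
      touches_boundary <- length(intersect(comp_v, boundary_v)) > 0
      others <- setdiff(seq_along(L$components), ci)
      touches_other <- any(vapply(others, function(oi) {
        ov <- unique(as.vector(s$triangles[L$components[[oi]], ]))
        length(intersect(comp_v, ov)) > 0
      }, logical(1)))
      separates <- length(partition_post_ablation(
        s, afablate:::new_lesion_set(s, "tmp", L$components[[ci]], 3))$areas) >= 2
      expect_true(touches_boundary || touches_other || separates)
    }
  }
})

test_that("applying lesions zeroes conductivity and disables interior vertices", {
  s <- fx_surface()
  tis <- fx_tissue()
  expect_identical(apply_lesions(tis, NULL, s), tis)
  pvi <- plan_pvi(s)
  tis2 <- apply_lesions(tis, pvi, s)
  expect_true(all(tis2$sigma_l[pvi$elements] == 0))
  expect_gt(length(tis2$inactive_vertices), 0)
  # untouched elements unchanged
  other <- setdiff(seq_along(tis$sigma_l), pvi$elements)
  expect_identical(tis2$sigma_l[other], tis$sigma_l[other])
})

test_that("post-ablation partition conserves area", {
  s <- fx_surface()
  # no lesions: one region covering the whole surface
  p0 <- partition_post_ablation(s, NULL)
  expect_length(p0$areas, 1)
  expect_equal(p0$areas[1], p0$total_area)
  for (L in list(plan_pvi(s), plan_box(s))) {
    p <- partition_post_ablation(s, L)
    expect_lt(abs(sum(p$areas) + p$ablated_area - p$total_area) /
                p$total_area, 1e-6)
  }
})

test_that("hotspot isolation removes all hotspot area from the largest region", {
  s <- fx_surface()
  pre <- fx_presim()
  expect_gt(length(pre$hotspots$regions), 0)
  L <- plan_region_isolation(s, pre$hotspots, "all")
  part <- partition_post_ablation(s, L)
  met <- compute_lesion_metrics(s, L, part, fx_tissue()$norm_lge,
                                pre$hotspots)
  expect_equal(met$remaining_hotspot_area, 0)
})
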