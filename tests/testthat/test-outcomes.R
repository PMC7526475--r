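mk_movie <- function(period_ms, n_frames = 400, dt = 5, nv = 3) {
  tt <- seq(0, by = dt, length.out = n_frames)
  vm <- matrix(rep(20 * sin(2 * pi * tt / period_ms) - 50, each = nv),
               nrow = nv, byrow = FALSE)
  structure(list(voltage = vm, times = tt, dt_output = dt,
                 duration = dt * (n_frames - 1),
                 active = rep(TRUE, nv)), class = "simulation_result")
}

test_that("dominant frequency is exact on planted periodic signals", {
  expect_equal(dominant_frequency(mk_movie(250)), 4.0, tolerance = 1e-9)
  expect_equal(dominant_frequency(mk_movie(200)), 5.0, tolerance = 1e-9)
  # two vertices at 4 and 6 Hz: arithmetic mean 5
  m4 <- mk_movie(250, nv = 1)
  m6 <- mk_movie(1000 / 6, nv = 1)
  both <- m4
  both$voltage <- rbind(m4$voltage, m6$voltage)
  both$active <- rep(TRUE, 2)
  expect_equal(dominant_frequency(both), 5.0, tolerance = 0.02)
  # all-quiescent movie: undefined
  quiet <- mk_movie(250)
  quiet$voltage[] <- -80
  expect_true(is.na(dominant_frequency(quiet)))
})

test_that("outcome classification follows the dominant-frequency rule", {
  # terminated movie
  vm <- matrix(-80, 3, 400)
  vm[, 1:40] <- 0
  term <- structure(list(voltage = vm, times = seq(0, by = 5, length.out = 400),
                         dt_output = 5, duration = 1995,
                         active = rep(TRUE, 3)), class = "simulation_result")
  o1 <- classify_outcome(term)
  expect_equal(o1$category, "termination")
  expect_true(o1$responder)
  # sustained 4 Hz: AT, responder
  o2 <- classify_outcome(mk_movie(250))
  expect_equal(o2$category, "AT")
  expect_true(o2$responder)
  # sustained 6 Hz: AF, non-responder
  o3 <- classify_outcome(mk_movie(1000 / 6))
  expect_equal(o3$category, "AF")
  expect_false(o3$responder)
  # boundary: DF exactly at threshold classifies as AT
  o4 <- classify_outcome(mk_movie(250), df_threshold = 4.0)
  expect_equal(o4$category, "AT")
})

test_that("lesion metrics carry the structural zeros and flagged edge cases", {
  s <- fx_surface()
  pre <- fx_presim()
  tis <- fx_tissue()
  # no lesions: full area, flagged MV-to-boundary distance
  p0 <- partition_post_ablation(s, NULL)
  expect_warning(
    m0 <- compute_lesion_metrics(s, NULL, p0, tis$norm_lge, pre$hotspots),
    NA)
  expect_equal(m0$remaining_la_area, p0$total_area)
  expect_true(m0$mv_distance_flagged)
  expect_gt(m0$roof_width, 0)
  # box: conducting roof width of the largest region is zero
  box <- plan_box(s)
  pbox <- partition_post_ablation(s, box)
  mbox <- compute_lesion_metrics(s, box, pbox, tis$norm_lge, pre$hotspots)
  expect_equal(mbox$roof_width, 0)
  expect_false(mbox$mv_distance_flagged)
  expect_gt(mbox$min_channel_height, 0)
})

test_that("pre-ablation imaging and electrical features are consistent", {
  pat <- fx_patient()
  pre <- fx_presim()
  fib <- identify_fibrotic_regions(lge_z_score(pat$lge), pat$surface)
  f <- imaging_electrical_features(pat, pre$result, pre$hotspots, fib)
  expect_equal(f$pv_area,
               region_area(pat$surface, c("LSPV", "LIPV", "RSPV", "RIPV")) / 100)
  expect_equal(f$fibrosis_area, fib$total_area)
  expect_equal(f$hotspot_area, pre$hotspots$total_area)
  expect_gt(f$mean_df, 3)
  expect_lt(f$mean_df, 7)
})

test_that("optimal-strategy selection ranks outcome then burden", {
  mk_out <- function(cat) structure(list(category = cat,
                                         responder = cat != "AF"),
                                    class = "outcome_label")
  mk_les <- function(a) structure(list(ablated_area = a), class = "lesion_set")
  mk_part <- function(a) structure(list(areas = a),
                                   class = "post_ablation_partition")
  sts <- afablate:::STRATEGIES
  lesions <- stats::setNames(lapply(c(10, 20, 25, 30, 22, 35), mk_les), sts)
  parts <- stats::setNames(lapply(c(90, 70, 72, 65, 75, 60), mk_part), sts)
  # termination dominates
  o <- stats::setNames(lapply(c("termination", "AT", "AF", "AF", "AT", "AF"),
                              mk_out), sts)
  sel <- select_optimal_strategy(o, lesions, parts)
  expect_equal(sel$strategy, "pvi")
  # termination elsewhere beats AT with smaller burden
  o2 <- stats::setNames(lapply(c("AF", "AT", "AF", "AF", "AF", "termination"),
                               mk_out), sts)
  expect_equal(select_optimal_strategy(o2, lesions, parts)$strategy,
               "all_hotspots")
  # ties broken by smallest ablated area; largest-remaining variant reported
  o3 <- stats::setNames(lapply(rep("AT", 6), mk_out), sts)
  sel3 <- select_optimal_strategy(o3, lesions, parts)
  expect_equal(sel3$by_burden, "pvi")
  expect_equal(sel3$by_remaining, "pvi")
  # all six AF: global non-responder
  o4 <- stats::setNames(lapply(rep("AF", 6), mk_out), sts)
  expect_true(is.na(select_optimal_strategy(o4, lesions, parts)$strategy))
  # a missing strategy is an error
  expect_error(select_optimal_strategy(o4[-1], lesions, parts), "missing")
  # never returns an AF strategy
  o5 <- stats::setNames(lapply(c("AF", "AF", "AT", "AF", "AF", "AF"), mk_out),
                        sts)
  expect_equal(select_optimal_strategy(o5, lesions, parts)$strategy,
               "single_fibrosis")
})
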