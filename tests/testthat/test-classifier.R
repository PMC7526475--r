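test_that("feature table has six rows per anatomy with responder labels", {
  # minimal synthetic patient-results structure
  mk_patient <- function(id, responder_pattern) {
    strategies <- lapply(stats::setNames(seq_along(afablate:::STRATEGIES),
                                         afablate:::STRATEGIES), function(k)
      list(metrics = list(remaining_hotspot_area = k, remaining_la_area = 80,
                          remaining_fibrosis_area = 20, roof_width = 2,
                          min_channel_height = 1.5),
           outcome = list(responder = responder_pattern[k])))
    list(id = id,
         features = list(la_body_area = 100, pv_area = 14,
                         fibrosis_area = 20, mean_df = 4.9,
                         hotspot_area = 18),
         strategies = strategies)
  }
  prs <- list(mk_patient("a", c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE)),
              mk_patient("b", rep(FALSE, 6)))
  tab <- build_feature_table(prs)
  expect_equal(nrow(tab), 12)
  expect_equal(nrow(build_feature_table(prs[1])), 6)
  # AT/termination -> 0 (responder), AF -> 1
  expect_equal(tab$label[tab$anatomy_id == "a"][1], 0L)
  expect_equal(tab$label[tab$anatomy_id == "b"][1], 1L)
  # missing strategy errors
  broken <- prs
  broken[[1]]$strategies$box <- NULL
  expect_error(build_feature_table(broken), "missing")
})

test_that("grouped split keeps anatomies intact at a 70:30 ratio", {
  tab <- stub_feature_table(50, seed = 9)
  sp <- grouped_split(tab, 0.7, seed = 2)
  expect_equal(length(unique(sp$train$anatomy_id)), 35)
  expect_equal(length(unique(sp$test$anatomy_id)), 15)
  expect_equal(nrow(sp$train), 210)
  expect_equal(nrow(sp$test), 90)
  expect_length(intersect(sp$train$anatomy_id, sp$test$anatomy_id), 0)
  sp2 <- grouped_split(tab, 0.7, seed = 2)
  expect_identical(sp$train, sp2$train)
  expect_error(grouped_split(tab[tab$anatomy_id == "anat_001", ]), "2 anatomies")
})

test_that("random forest recovers a planted deterministic rule", {
  tab <- stub_feature_table(50, seed = 3, noise = 0)
  sp <- grouped_split(tab, 0.7, seed = 3)
  rep <- train_and_evaluate(sp$train, sp$test,
                            "imaging+electrical+lesion", seed = 3)
  expect_gte(rep$accuracy, 0.95)
  # chosen hyperparameters come from the frozen grid
  g <- rf_grid()
  expect_true(any(g$n_estimators == rep$hyperparameters$n_estimators &
                    g$max_depth == rep$hyperparameters$max_depth &
                    g$min_samples_leaf == rep$hyperparameters$min_samples_leaf))
  expect_true(all(c(rep$accuracy, rep$precision, rep$recall) >= 0 &
                    c(rep$accuracy, rep$precision, rep$recall) <= 1))
})

test_that("permuted labels give chance-level accuracy", {
  tab <- stub_feature_table(30, seed = 5, noise = 0)
  # single-configuration fit keeps the null cheap; the hyperparameters are
  # the headline configuration of the frozen grid
  g1 <- data.frame(n_estimators = 50L, max_depth = 8L, min_samples_leaf = 5L)
  accs <- vapply(1:20, function(s) {
    t2 <- tab
    set.seed(1000 + s)
    t2$label <- sample(t2$label)
    sp <- grouped_split(t2, 0.7, seed = s)
    if (length(unique(sp$train$label)) < 2) return(NA_real_)
    train_and_evaluate(sp$train, sp$test, "imaging+electrical+lesion",
                       grid = g1, seed = s)$accuracy
  }, numeric(1))
  expect_gte(mean(accs, na.rm = TRUE), 0.35)
  expect_lte(mean(accs, na.rm = TRUE), 0.65)
})

test_that("single-class training data is rejected", {
  tab <- stub_feature_table(10, seed = 1)
  tab$label <- 0L
  expect_error(fit_responder_model(tab), "single class")
  expect_error(train_baselines(tab, tab), "single class")
})

test_that("nested feature sets do not lose a planted lesion-feature signal", {
  # rule on remaining_hotspot_area (a lesion feature): the lesion-feature
  # model should beat the imaging-only model in expectation over seeds
  g1 <- data.frame(n_estimators = 50L, max_depth = 8L, min_samples_leaf = 5L)
  acc <- sapply(1:10, function(s) {
    tab <- stub_feature_table(30, seed = 100 + s, noise = 0)
    sp <- grouped_split(tab, 0.7, seed = s)
    c(a = train_and_evaluate(sp$train, sp$test, "imaging", grid = g1,
                             seed = s)$accuracy,
      c = train_and_evaluate(sp$train, sp$test, "imaging+electrical+lesion",
                             grid = g1, seed = s)$accuracy)
  })
  expect_gte(mean(acc["c", ]), mean(acc["a", ]))
  # structural nesting of the feature sets
  expect_true(all(feature_columns("imaging") %in%
                    feature_columns("imaging+electrical")))
  expect_true(all(feature_columns("imaging+electrical") %in%
                    feature_columns("imaging+electrical+lesion")))
})

test_that("Shapley attributions are locally accurate and rank the planted feature first", {
  tab <- stub_feature_table(40, seed = 7, noise = 0)
  sp <- grouped_split(tab, 0.7, seed = 7)
  g1 <- data.frame(n_estimators = 50L, max_depth = 8L, min_samples_leaf = 5L)
  model <- fit_responder_model(sp$train, "imaging+electrical+lesion",
                               grid = g1, seed = 7)
  att <- feature_attribution(model, sp$test, background = sp$train,
                             n_perm = 10, n_background = 20, seed = 7)
  # local accuracy: attributions + baseline = prediction, every case
  recon <- rowSums(att$attributions) + att$baseline
  expect_lt(max(abs(recon - att$predictions)), 1e-6)
  # the planted single informative feature ranks first
  expect_equal(att$ranking[1], "remaining_hotspot_area")
  # attribution sign recovers the planted monotone direction: higher
  # remaining hotspot area pushes toward non-response
  phi <- att$attributions[, "remaining_hotspot_area"]
  x <- sp$test$remaining_hotspot_area
  expect_gt(stats::cor(phi, x), 0.5)
  # degenerate case: identical data and background give zero attributions
  one <- sp$test[1, ]
  att0 <- feature_attribution(model, one, background = one, n_perm = 3,
                              seed = 1)
  expect_lt(max(abs(att0$attributions)), 1e-12)
})

test_that("baselines recover a planted linear rule with the shared metric triple", {
  set.seed(11)
  tab <- stub_feature_table(40, seed = 11, noise = 0)
  sp <- grouped_split(tab, 0.7, seed = 11)
  reps <- train_baselines(sp$train, sp$test, "imaging+electrical+lesion",
                          seed = 11)
  # the planted threshold rule is linearly separable in one feature
  expect_gte(reps$logistic$accuracy, 0.9)
  for (r in reps) {
    expect_named(r[c("accuracy", "precision", "recall")],
                 c("accuracy", "precision", "recall"))
    expect_true(all(unlist(r[c("accuracy", "precision", "recall")]) >= 0))
  }
})
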