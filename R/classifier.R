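## Acute-ablation-response prediction: the 6-rows-per-anatomy feature table,
## anatomy-grouped 70:30 split, random-forest classifier with the frozen
## hyperparameter grid and grouped 5-fold cross-validation on balanced
## accuracy, logistic-regression and support-vector baselines, and
## permutation-Shapley feature attributions.

#' Hyperparameter grid for the random-forest classifier
#' @return data.frame over n_estimators, max_depth, min_samples_leaf
#' @export
rf_grid <- function() {
  expand.grid(n_estimators = c(10L, 20L, 50L, 70L, 80L, 100L),
              max_depth = c(4L, 8L, 16L),
              min_samples_leaf = c(5L, 10L, 20L))
}

IMAGING_FEATURES <- c("la_body_area", "pv_area", "fibrosis_area")
ELECTRICAL_FEATURES <- c("mean_df", "hotspot_area")
LESION_FEATURES <- c("remaining_hotspot_area", "remaining_la_area",
                     "remaining_fibrosis_area", "roof_width",
                     "min_channel_height")

#' Feature columns for a named feature set
#' @param feature_set "imaging", "imaging+electrical", or
#'   "imaging+electrical+lesion"
#' @export
feature_columns <- function(feature_set = c("imaging", "imaging+electrical",
                                            "imaging+electrical+lesion")) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
         "imaging" = IMAGING_FEATURES,
         "imaging+electrical" = c(IMAGING_FEATURES, ELECTRICAL_FEATURES),
         "imaging+electrical+lesion" = c(IMAGING_FEATURES,
                                         ELECTRICAL_FEATURES,
                                         LESION_FEATURES))
}

#' Build the per-(anatomy, strategy) feature table
#'
#' One row per patient per strategy: imaging and electrical features of the
#' anatomy, lesion metrics of the strategy, and the acute-responder label
#' (0 responder, 1 non-responder).
#'
#' @param patient_results list of per-patient result lists as produced by
#'   [evaluate_patient()] / [run_trial()]
#' @return data.frame with n_patients x 6 rows, ordered by (anatomy,
#'   strategy)
#' @export
build_feature_table <- function(patient_results) {
  rows <- list()
  for (pr in patient_results) {
    missing <- setdiff(STRATEGIES, names(pr$strategies))
    if (length(missing) > 0)
      stop("patient ", pr$id, " is missing strategies: ",
           paste(missing, collapse = ", "))
    for (st in STRATEGIES) {
      sr <- pr$strategies[[st]]
      rows[[length(rows) + 1]] <- data.frame(
        anatomy_id = pr$id,
        strategy = st,
        la_body_area = pr$features$la_body_area,
        pv_area = pr$features$pv_area,
        fibrosis_area = pr$features$fibrosis_area,
        mean_df = pr$features$mean_df,
        hotspot_area = pr$features$hotspot_area,
        remaining_hotspot_area = sr$metrics$remaining_hotspot_area,
        remaining_la_area = sr$metrics$remaining_la_area,
        remaining_fibrosis_area = sr$metrics$remaining_fibrosis_area,
        roof_width = sr$metrics$roof_width,
        min_channel_height = sr$metrics$min_channel_height,
        label = if (sr$outcome$responder) 0L else 1L,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (anyNA(tab)) stop("feature table contains missing values")
  tab[order(tab$anatomy_id, match(tab$strategy, STRATEGIES)), ]
}

#' Anatomy-grouped train/test split
#'
#' Splits at the anatomy level so all six strategy rows of a patient land in
#' the same set; the train set gets round(train_fraction x n) anatomies.
#'
#' @param table feature table from [build_feature_table()]
#' @param train_fraction default 0.7
#' @param seed RNG seed
#' @return list(train, test) data.frames
#' @export
grouped_split <- function(table, train_fraction = 0.7, seed = 1) {
  anat <- unique(table$anatomy_id)
  if (length(anat) < 2) stop("need at least 2 anatomies to split")
  n_train <- round(train_fraction * length(anat))
  n_train <- min(max(n_train, 1), length(anat) - 1)
  set.seed(as.integer(seed %% 2147483647))
  tr <- sample(anat, n_train)
  list(train = table[table$anatomy_id %in% tr, ],
       test = table[!(table$anatomy_id %in% tr), ])
}

## design matrix: one-hot strategy + numeric features
design_matrix <- function(table, features) {
  X <- as.matrix(table[, features, drop = FALSE])
  S <- 1 * outer(table$strategy, STRATEGIES, `==`)
  colnames(S) <- paste0("strategy_", STRATEGIES)
  cbind(S, X)
}

## anatomy-grouped k-fold assignment
grouped_folds <- function(anatomy_id, k, seed) {
  anat <- unique(anatomy_id)
  set.seed(as.integer(seed %% 2147483647))
  fold_of <- sample(rep(seq_len(k), length.out = length(anat)))
  fold_of[match(anatomy_id, anat)]
}

balanced_accuracy <- function(truth, pred) {
  lev <- sort(unique(truth))
  mean(vapply(lev, function(l) mean(pred[truth == l] == l), numeric(1)))
}

## class-balanced case weights
balance_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab[as.character(y)])
  as.numeric(w)
}

#' Fit the acute-responder random-forest model
#'
#' Grid search over the frozen hyperparameter grid by anatomy-grouped 5-fold
#' cross-validation maximizing balanced accuracy, then a final
#' class-balance-weighted fit on the full training set.
#'
#' @param train training rows of the feature table
#' @param feature_set see [feature_columns()]
#' @param grid hyperparameter grid (default [rf_grid()])
#' @param cv_folds folds for the grouped cross-validation
#' @param seed RNG seed (grid CV and final fit)
#' @return object of class `responder_model`
#' @export
fit_responder_model <- function(train,
                                feature_set = "imaging+electrical+lesion",
                                grid = rf_grid(), cv_folds = 5, seed = 1) {
  features <- feature_columns(feature_set)
  X <- design_matrix(train, features)
  y <- factor(train$label, levels = c(0, 1),
              labels = c("responder", "non_responder"))
  if (length(unique(y)) < 2)
    stop("training data contains a single class")
  folds <- grouped_folds(train$anatomy_id, cv_folds, seed)
  dat <- data.frame(X, .y = y, check.names = FALSE)
  cv_score <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    preds <- rep(NA_character_, nrow(dat))
    ok <- TRUE
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) { ok <- FALSE; break }
      m <- ranger::ranger(
        dependent.variable.name = ".y", data = dat[tr, ],
        num.trees = grid$n_estimators[gi],
        max.depth = grid$max_depth[gi],
        min.node.size = grid$min_samples_leaf[gi],
        case.weights = balance_weights(y[tr]),
        seed = as.integer(seed %% 2147483647), num.threads = 1)
      preds[!tr] <- as.character(stats::predict(m, dat[!tr, ],
                                                num.threads = 1)$predictions)
    }
    cv_score[gi] <- if (ok) balanced_accuracy(as.character(y), preds) else -Inf
  }
  best <- which.max(cv_score)
  final <- ranger::ranger(
    dependent.variable.name = ".y", data = dat,
    num.trees = grid$n_estimators[best],
    max.depth = grid$max_depth[best],
    min.node.size = grid$min_samples_leaf[best],
    case.weights = balance_weights(y),
    probability = TRUE,
    seed = as.integer(seed %% 2147483647), num.threads = 1)
  structure(list(model = final, feature_set = feature_set,
                 features = features,
                 columns = colnames(X),
                 best = grid[best, ], cv_score = cv_score[best],
                 cv_table = cbind(grid, balanced_accuracy = cv_score),
                 seed = seed),
            class = "responder_model")
}

#' @exportS3Method base::print
print.responder_model <- function(x, ...) {
  cat(sprintf("Acute-responder random forest (%s)\n", x$feature_set))
  cat(sprintf("  %d trees, max depth %d, min leaf %d (CV balanced accuracy %.3f)\n",
              x$best$n_estimators, x$best$max_depth, x$best$min_samples_leaf,
              x$cv_score))
  invisible(x)
}

#' @exportS3Method base::summary
summary.responder_model <- function(object, ...) {
  print(object)
  cat("Cross-validation grid (top 5 by balanced accuracy):\n")
  tab <- object$cv_table[order(-object$cv_table$balanced_accuracy), ]
  print(utils::head(tab, 5), row.names = FALSE)
  invisible(object)
}

#' Predict non-responder probability or class for feature-table rows
#' @param object a `responder_model`
#' @param newdata feature-table rows
#' @param type "prob" (probability of non-responder) or "class"
#' @param ... unused
#' @export
predict.responder_model <- function(object, newdata, type = c("prob", "class"),
                                    ...) {
  type <- match.arg(type)
  X <- design_matrix(newdata, object$features)
  p <- stats::predict(object$model, data.frame(X, check.names = FALSE),
                      num.threads = 1)$predictions[, "non_responder"]
  if (type == "prob") p else ifelse(p > 0.5, 1L, 0L)
}

classification_metrics <- function(truth, pred) {
  lev <- c(0L, 1L)
  support <- vapply(lev, function(l) sum(truth == l), numeric(1))
  prec <- vapply(lev, function(l) {
    d <- sum(pred == l)
    if (d == 0) 0 else sum(pred == l & truth == l) / d
  }, numeric(1))
  rec <- vapply(lev, function(l) {
    d <- sum(truth == l)
    if (d == 0) 0 else sum(pred == l & truth == l) / d
  }, numeric(1))
  w <- support / sum(support)
  list(accuracy = mean(pred == truth),
       precision = sum(w * prec),
       recall = sum(w * rec))
}

#' Train and evaluate a classifier for one feature set
#'
#' @param train,test feature-table rows
#' @inheritParams fit_responder_model
#' @return list of class `classifier_report`: feature_set, chosen
#'   hyperparameters, test accuracy/precision/recall (class-weighted
#'   averages), and the fitted `responder_model`
#' @export
train_and_evaluate <- function(train, test,
                               feature_set = "imaging+electrical+lesion",
                               grid = rf_grid(), cv_folds = 5, seed = 1) {
  if (nrow(train) == 0 || nrow(test) == 0) stop("empty train or test set")
  model <- fit_responder_model(train, feature_set, grid, cv_folds, seed)
  pred <- predict(model, test, type = "class")
  met <- classification_metrics(test$label, pred)
  structure(list(feature_set = feature_set,
                 hyperparameters = model$best,
                 accuracy = met$accuracy, precision = met$precision,
                 recall = met$recall, model = model),
            class = "classifier_report")
}

#' @exportS3Method base::print
print.classifier_report <- function(x, ...) {
  cat(sprintf("%s: accuracy %.2f, precision %.2f, recall %.2f\n",
              x$feature_set, x$accuracy, x$precision, x$recall))
  invisible(x)
}

#' Permutation-Shapley feature attributions
#'
#' Interventional Shapley values estimated by sampling feature-entry
#' permutations against a background sample. The six strategy one-hot
#' columns act as a single player. By the telescoping construction the
#' per-case attributions sum exactly to the prediction minus the mean
#' background prediction (local accuracy), at any number of permutations.
#'
#' @param model a `responder_model` (attributions on the non-responder
#'   probability)
#' @param data feature-table rows to explain
#' @param background feature-table rows for the reference distribution
#'   (default: `data`)
#' @param n_perm permutations per case
#' @param n_background background rows sampled
#' @param seed RNG seed
#' @return object of class `shap_attribution`: matrix (cases x players) of
#'   signed attributions, baseline, predictions and the importance ranking
#'   by mean absolute attribution
#' @export
feature_attribution <- function(model, data, background = data,
                                n_perm = 20, n_background = 25, seed = 1) {
  X <- design_matrix(data, model$features)
  B <- design_matrix(background, model$features)
  set.seed(as.integer(seed %% 2147483647))
  if (nrow(B) > n_background) B <- B[sample(nrow(B), n_background), , drop = FALSE]
  ## players: strategy one-hot block as one, each numeric feature its own
  players <- c(list(strategy = grep("^strategy_", colnames(X))),
               stats::setNames(as.list(match(model$features, colnames(X))),
                               model$features))
  np <- length(players)
  predfun <- function(M) stats::predict(model$model,
                                        data.frame(M, check.names = FALSE),
                                        num.threads = 1)$predictions[, "non_responder"]
  n <- nrow(X)
  phi <- matrix(0, n, np, dimnames = list(NULL, names(players)))
  baseline <- mean(predfun(B))
  for (case in seq_len(n)) {
    acc <- numeric(np)
    for (pm in seq_len(n_perm)) {
      ord <- sample(np)
      ## start from each background row, add players in permutation order
      M <- B
      prev <- predfun(M)
      for (pl in ord) {
        cols <- players[[pl]]
        M[, cols] <- matrix(X[case, cols], nrow(M), length(cols), byrow = TRUE)
        cur <- predfun(M)
        acc[pl] <- acc[pl] + mean(cur - prev)
        prev <- cur
      }
    }
    phi[case, ] <- acc / n_perm
  }
  pred <- predfun(X)
  imp <- colMeans(abs(phi))
  structure(list(attributions = phi, baseline = baseline,
                 predictions = pred,
                 ranking = names(sort(imp, decreasing = TRUE)),
                 importance = imp),
            class = "shap_attribution")
}

#' @exportS3Method base::print
print.shap_attribution <- function(x, ...) {
  cat("Shapley attributions (mean |phi|):\n")
  print(round(sort(x$importance, decreasing = TRUE), 4))
  invisible(x)
}

#' Logistic-regression and support-vector baselines
#'
#' Ridge logistic regression (regularization chosen by anatomy-grouped
#' cross-validation) and an RBF support-vector classifier (cost/gamma grid,
#' grouped CV on balanced accuracy), both class-balance weighted, evaluated
#' with the same metric triple as the random forest.
#'
#' @inheritParams train_and_evaluate
#' @return list(logistic = classifier_report, svc = classifier_report)
#' @export
train_baselines <- function(train, test,
                            feature_set = "imaging+electrical+lesion",
                            cv_folds = 5, seed = 1) {
  features <- feature_columns(feature_set)
  Xtr <- design_matrix(train, features)
  Xte <- design_matrix(test, features)
  ytr <- train$label
  if (length(unique(ytr)) < 2) stop("training data contains a single class")
  mu <- colMeans(Xtr)
  sg <- apply(Xtr, 2, stats::sd)
  sg[sg == 0] <- 1
  Ztr <- scale(Xtr, mu, sg)
  Zte <- scale(Xte, mu, sg)
  folds <- grouped_folds(train$anatomy_id, cv_folds, seed)
  w <- balance_weights(ytr)
  ## ridge logistic regression over a lambda path
  cvl <- glmnet::cv.glmnet(Ztr, ytr, family = "binomial", alpha = 0,
                           weights = w, foldid = folds,
                           type.measure = "class",
                           lambda.min.ratio = 1e-6, nlambda = 80)
  pl <- as.integer(stats::predict(cvl, Zte, s = "lambda.min",
                                  type = "class"))
  rep_lr <- structure(c(list(feature_set = feature_set,
                             hyperparameters = data.frame(lambda = cvl$lambda.min)),
                        classification_metrics(test$label, pl),
                        list(model = cvl)),
                      class = "classifier_report")
  ## RBF SVC with a small grid
  grid <- expand.grid(cost = c(0.1, 1, 10, 100),
                      gamma = c(0.25, 1, 4) / ncol(Ztr))
  yf <- factor(ytr)
  cw <- c("0" = 1 / mean(ytr == 0), "1" = 1 / mean(ytr == 1))
  score <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    preds <- rep(NA_character_, nrow(Ztr))
    for (f in sort(unique(folds))) {
      tr <- folds != f
      if (length(unique(yf[tr])) < 2) next
      m <- e1071::svm(Ztr[tr, , drop = FALSE], yf[tr],
                      kernel = "radial", cost = grid$cost[gi],
                      gamma = grid$gamma[gi], class.weights = cw,
                      scale = FALSE)
      preds[!tr] <- as.character(stats::predict(m, Ztr[!tr, , drop = FALSE]))
    }
    keep <- !is.na(preds)
    score[gi] <- balanced_accuracy(as.character(yf)[keep], preds[keep])
  }
  best <- which.max(score)
  msv <- e1071::svm(Ztr, yf, kernel = "radial", cost = grid$cost[best],
                    gamma = grid$gamma[best], class.weights = cw,
                    scale = FALSE)
  ps <- as.integer(as.character(stats::predict(msv, Zte)))
  rep_svc <- structure(c(list(feature_set = feature_set,
                              hyperparameters = grid[best, ]),
                         classification_metrics(test$label, ps),
                         list(model = msv)),
                       class = "classifier_report")
  list(logistic = rep_lr, svc = rep_svc)
}
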