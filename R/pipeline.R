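## End-to-end virtual trial: cohort -> tissue -> pre-ablation AF -> hotspot
## mapping -> six lesion sets -> post-ablation outcomes -> feature table ->
## responder classifier.

#' Trial configuration
#'
#' Desk-scale defaults: a 10-patient cohort, 2 s pre-ablation and 1.5 s
#' post-ablation windows with the surrogate ionic backend. All values are
#' serialized into the results manifest.
#'
#' @param n_paroxysmal,n_persistent cohort composition
#' @param seed master seed (cohort and classifier split)
#' @param pre_duration,post_duration simulation windows (ms)
#' @param dt,dt_output solver step and frame spacing (ms)
#' @param cycle_length spiral-initiation cycle length (ms)
#' @param smoothing_radius PS density kernel (mm)
#' @param pvi_threshold PVI junction distance (mm)
#' @param lesion_width lesion width (mm)
#' @param df_threshold AT/AF dominant-frequency boundary (Hz)
#' @param train_fraction anatomy-level train share for the classifier
#' @param cv_folds grouped CV folds
#' @param run_classifier train classifiers when the table supports it
#' @param cache_dir optional directory for per-patient result caching
#' @return list of class `trial_config`
#' @export
trial_config <- function(n_paroxysmal = 4, n_persistent = 6, seed = 1,
                         pre_duration = 2000, post_duration = 1500,
                         dt = 0.1, dt_output = 5, cycle_length = 330,
                         smoothing_radius = 5, pvi_threshold = 5,
                         lesion_width = 3, df_threshold = 4.7,
                         train_fraction = 0.7, cv_folds = 5,
                         run_classifier = TRUE, cache_dir = NULL) {
  structure(as.list(environment()), class = "trial_config")
}

#' Evaluate one virtual patient across the six ablation strategies
#'
#' Runs the pre-ablation AF simulation from the four-spiral initial state,
#' maps PS hotspots, plans the six lesion sets, restarts the simulation
#' after each ablation from the pre-ablation end state, and classifies each
#' outcome.
#'
#' @param patient a `virtual_patient`
#' @param config a `trial_config`
#' @param ionic base `ms_params`
#' @return list: id, af_class, features, hotspots, fibrotic, sustained,
#'   strategies (per strategy: lesions, outcome, partition, metrics),
#'   optimal
#' @export
evaluate_patient <- function(patient, config = trial_config(),
                             ionic = ms_params()) {
  s <- patient$surface
  tis <- build_tissue(s, patient$lge)
  fib <- identify_fibrotic_regions(lge_z_score(patient$lge), s)
  init <- init_spiral_field(s, cycle_length = config$cycle_length,
                            ionic = ionic)
  op <- build_diffusion_operator(s, tis)
  pre <- run_simulation(s, tis, ionic, init = init,
                        duration = config$pre_duration, dt = config$dt,
                        dt_output = config$dt_output, operator = op)
  sustained <- is.null(detect_termination(pre))
  ph <- compute_phase(pre)
  tracks <- track_ps(ph, s, pre$times)
  dens <- ps_density(tracks, s, config$smoothing_radius)
  hot <- suppressWarnings(find_hotspots(dens, s, k_sd = 1, valid = ph$valid))
  features <- imaging_electrical_features(patient, pre, hot, fib)
  plans <- plan_all_strategies(s, fib, hot, width = config$lesion_width,
                               pvi_threshold = config$pvi_threshold)
  lge_norm <- tis$norm_lge
  strategies <- list()
  for (st in names(plans)) {
    L <- plans[[st]]
    tis2 <- apply_lesions(tis, L, s)
    post <- run_simulation(s, tis2, ionic,
                           init = list(V = pre$state$V, h = pre$state$h),
                           duration = config$post_duration, dt = config$dt,
                           dt_output = config$dt_output)
    out <- classify_outcome(post, s, config$df_threshold)
    part <- partition_post_ablation(s, L)
    met <- suppressWarnings(
      compute_lesion_metrics(s, L, part, lge_norm, hot))
    strategies[[st]] <- list(lesions = L, outcome = out, partition = part,
                             metrics = met)
  }
  optimal <- select_optimal_strategy(
    lapply(strategies, `[[`, "outcome"),
    lapply(strategies, `[[`, "lesions"),
    lapply(strategies, `[[`, "partition"))
  list(id = patient$id, af_class = patient$af_class, features = features,
       hotspots = hot, fibrotic = fib, sustained = sustained,
       strategies = strategies, optimal = optimal)
}

#' Run the full in-silico ablation trial
#'
#' @param config a `trial_config`
#' @param progress print per-patient progress
#' @return object of class `trial_result`: patient results, feature table,
#'   per-strategy outcome tally (ordered by descending mean largest-region
#'   area), lesion-metric summary (mean and SD per strategy), the
#'   optimal-strategy distribution, classifier reports, and the config
#' @export
run_trial <- function(config = trial_config(), progress = interactive()) {
  cohort <- generate_cohort(config$n_paroxysmal, config$n_persistent,
                            config$seed)
  results <- vector("list", length(cohort))
  failed <- character(0)
  for (i in seq_along(cohort)) {
    key <- NULL
    if (!is.null(config$cache_dir)) {
      dir.create(config$cache_dir, showWarnings = FALSE, recursive = TRUE)
      key <- file.path(config$cache_dir,
                       sprintf("patient_%s_s%d_pre%d_post%d.rds",
                               cohort[[i]]$id, config$seed,
                               config$pre_duration, config$post_duration))
      if (file.exists(key)) {
        results[[i]] <- readRDS(key)
        next
      }
    }
    res <- tryCatch(evaluate_patient(cohort[[i]], config),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s: %s", cohort[[i]]$id,
                                  conditionMessage(res)))
      next
    }
    results[[i]] <- res
    if (!is.null(key)) saveRDS(res, key)
    if (progress)
      message(sprintf("[%d/%d] %s done", i, length(cohort), cohort[[i]]$id))
  }
  results <- Filter(Negate(is.null), results)
  if (length(failed) > 0)
    warning(length(failed), " patient(s) failed and were excluded:\n  ",
            paste(failed, collapse = "\n  "))
  table <- build_feature_table(results)
  ## per-strategy summaries
  largest_area <- vapply(STRATEGIES, function(st)
    mean(vapply(results, function(r) {
      a <- r$strategies[[st]]$partition$areas
      if (length(a)) a[1] else 0
    }, numeric(1))), numeric(1))
  strat_order <- STRATEGIES[order(-largest_area)]
  tally <- sapply(strat_order, function(st)
    table(factor(vapply(results, function(r)
      r$strategies[[st]]$outcome$category, character(1)),
      levels = c("AF", "AT", "termination"))))
  metric_summary <- do.call(rbind, lapply(strat_order, function(st) {
    mm <- sapply(c("remaining_la_area", "remaining_fibrosis_area",
                   "remaining_hotspot_area", "roof_width",
                   "min_channel_height"), function(mn)
      vapply(results, function(r) r$strategies[[st]]$metrics[[mn]],
             numeric(1)))
    mm <- matrix(mm, nrow = length(results))
    data.frame(strategy = st,
               metric = c("remaining_la_area", "remaining_fibrosis_area",
                          "remaining_hotspot_area", "roof_width",
                          "min_channel_height"),
               mean = colMeans(mm), sd = apply(mm, 2, stats::sd))
  }))
  optimal <- table(factor(
    vapply(results, function(r)
      if (is.na(r$optimal$strategy)) "none" else r$optimal$strategy,
      character(1)),
    levels = c(STRATEGIES, "none")))
  reports <- NULL
  if (config$run_classifier && length(unique(table$label)) == 2 &&
      length(results) >= 4) {
    sp <- grouped_split(table, config$train_fraction, config$seed)
    if (length(unique(sp$train$label)) == 2 &&
        length(unique(sp$test$label)) >= 1) {
      reports <- lapply(c("imaging", "imaging+electrical",
                          "imaging+electrical+lesion"), function(fs)
        train_and_evaluate(sp$train, sp$test, fs, seed = config$seed))
      names(reports) <- c("imaging", "imaging+electrical",
                          "imaging+electrical+lesion")
    }
  }
  structure(list(patients = results, feature_table = table,
                 outcome_tally = tally, strategy_order = strat_order,
                 mean_largest_area = largest_area[strat_order],
                 lesion_metric_summary = metric_summary,
                 optimal_distribution = optimal,
                 classifier_reports = reports,
                 failed = failed,
                 config = config), class = "trial_result")
}

#' @exportS3Method base::print
print.trial_result <- function(x, ...) {
  cat(sprintf("In-silico ablation trial: %d patients x 6 strategies\n",
              length(x$patients)))
  cat("Outcome tally (strategies ordered by mean remaining largest region):\n")
  print(x$outcome_tally)
  cat("Optimal-strategy distribution:\n")
  print(x$optimal_distribution)
  if (!is.null(x$classifier_reports)) {
    cat("Classifier reports:\n")
    for (r in x$classifier_reports) print(r)
  }
  invisible(x)
}
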