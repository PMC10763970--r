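#' The default model roster
#'
#' A single random forest, hard and soft self-voting ensembles of three
#' forests, and the four-forest self-stacking classifier, all at the tuned
#' hyperparameter defaults.
#'
#' @param master_seed seed shared by the ensemble configurations.
#' @return Named list of model specifications for [run_experiment()].
#' @export
default_model_set <- function(master_seed = 42L) {
  list(rf = learner_spec("rf"),
       `svec-h` = vote_config(criterion = "hard",
                              master_seed = master_seed),
       `svec-s` = vote_config(criterion = "soft",
                              master_seed = master_seed),
       ssc = stack_config(master_seed = master_seed))
}

#' Configure a full comparison experiment
#'
#' @param cohort a [cohort()], or `NULL` to simulate one.
#' @param preset simulation preset when `cohort` is `NULL`:
#'   `"thyroid-skew"` (the imbalanced default generator) or `"separable"`
#'   (balanced, well separated).
#' @param models named list of model specifications ([learner_spec()],
#'   [stack_config()] or [vote_config()]).
#' @param min_class_size,per_class_n balancing parameters (see
#'   [balance_cohort()]); set `balance = FALSE` to skip the balanced
#'   setting.
#' @param balance run the down-sampled setting (default TRUE).
#' @param split_ratio,split_seed held-out test split (default 0.2, i.e.
#'   80:20).
#' @param cv_k,cv_seed cross-validation folds and seed (default 10-fold).
#' @param run_cv run the cross-validation stage (default TRUE).
#' @param comparisons list of length-2 character vectors naming model pairs
#'   for the paired t-test; defaults to every model against the last one.
#' @param sim_seed seed for the simulated cohort when `cohort` is `NULL`.
#' @param out_dir directory for JSON/Markdown reports, or `NULL` to skip
#'   writing.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(cohort = NULL,
                              preset = c("thyroid-skew", "separable"),
                              models = default_model_set(),
                              min_class_size = 200L, per_class_n = 230L,
                              balance = TRUE,
                              split_ratio = 0.2, split_seed = 7L,
                              cv_k = 10L, cv_seed = 7L, run_cv = TRUE,
                              comparisons = NULL, sim_seed = 1L,
                              out_dir = NULL) {
  preset <- match.arg(preset)
  stopifnot(is.list(models), length(models) >= 1,
            !is.null(names(models)), all(nzchar(names(models))))
  if (is.null(comparisons) && length(models) > 1) {
    last <- names(models)[length(models)]
    comparisons <- lapply(setdiff(names(models), last),
                          function(a) c(a, last))
  }
  for (p in comparisons)
    if (!all(p %in% names(models)))
      stop("comparison references undefined model(s): ",
           paste(setdiff(p, names(models)), collapse = ", "), call. = FALSE)
  structure(list(cohort = cohort, preset = preset, models = models,
                 min_class_size = as.integer(min_class_size),
                 per_class_n = as.integer(per_class_n),
                 balance = isTRUE(balance),
                 split_ratio = split_ratio,
                 split_seed = as.integer(split_seed),
                 cv_k = as.integer(cv_k), cv_seed = as.integer(cv_seed),
                 run_cv = isTRUE(run_cv),
                 comparisons = comparisons,
                 sim_seed = as.integer(sim_seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Run the full comparison experiment
#'
#' For each data setting (original, and down-sampled unless balancing is
#' off) and each configured model: fit on the 80:20 training partition,
#' evaluate on the held-out partition (accuracy, per-class and macro
#' precision/recall/F1), and optionally run k-fold cross-validation on the
#' setting's full encoded data. Configured model pairs are then compared
#' with a paired t-test over each model's eight evaluation scores (accuracy
#' and three macro metrics, in both settings). When `out_dir` is set,
#' machine-readable JSON reports, a human-readable Markdown summary
#' (rounded half-up to 2 decimals at the Markdown layer only) and an
#' execution manifest are written.
#'
#' @param config an [experiment_config()].
#' @return A list (invisibly when written to disk) with `settings`
#'   (per-setting, per-model `metric_report` and `cv_result`), `ttests`,
#'   `balance_plan` and `config`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  raw <- config$cohort
  if (is.null(raw)) {
    raw <- switch(config$preset,
                  "thyroid-skew" = generate_cohort(
                    generator_config(seed = config$sim_seed)),
                  "separable" = make_separable_cohort(seed = config$sim_seed))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  settings <- list(original = stage("encode", encode_features(raw)))
  plan <- NULL
  if (config$balance) {
    bal <- stage("balance",
                 balance_cohort(raw, config$min_class_size,
                                config$per_class_n))
    plan <- bal$plan
    settings$downsampled <- stage("encode", encode_features(bal$cohort))
  }
  results <- list()
  for (sname in names(settings)) {
    em <- settings[[sname]]
    sp <- stage("split", split_train_test(em, config$split_ratio,
                                          config$split_seed, shuffle = TRUE))
    per_model <- list()
    for (mname in names(config$models)) {
      spec <- config$models[[mname]]
      fit <- stage(paste0("train:", mname), fit_model(spec, sp$train))
      pred <- stage(paste0("evaluate:", mname),
                    predict(fit, sp$test$X))
      rep <- metric_report(sp$test$y, pred, em$class_map)
      cv <- if (config$run_cv)
        stage(paste0("cv:", mname),
              kfold_cv(spec, em, config$cv_k, config$cv_seed))
      per_model[[mname]] <- list(report = rep, cv = cv)
    }
    results[[sname]] <- list(split = sp, models = per_model)
  }
  ttests <- list()
  for (pair in config$comparisons) {
    a <- pair[1]; b <- pair[2]
    sa <- model_score_vector(results, a)
    sb <- model_score_vector(results, b)
    ttests[[paste(a, "vs", b)]] <- paired_ttest(sa, sb)
  }
  bundle <- list(settings = results, ttests = ttests,
                 balance_plan = plan, config = config)
  if (!is.null(config$out_dir)) {
    write_experiment_reports(bundle, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

# the eight-score evaluation vector of one model: accuracy + three macro
# metrics, per data setting (pads with the single setting when balancing is
# off, giving four scores)
model_score_vector <- function(results, model_name) {
  unlist(lapply(results, function(s) {
    r <- s$models[[model_name]]$report
    c(r$accuracy, r$macro_precision, r$macro_recall, r$macro_f1)
  }), use.names = FALSE)
}

report_as_list <- function(rep) {
  list(accuracy = rep$accuracy,
       macro_precision = rep$macro_precision,
       macro_recall = rep$macro_recall,
       macro_f1 = rep$macro_f1,
       per_class = rep$per_class,
       confusion = rep$confusion$counts)
}

write_experiment_reports <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wj <- function(x, file)
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  md <- c("# Experiment report", "")
  for (sname in names(bundle$settings)) {
    s <- bundle$settings[[sname]]
    md <- c(md, paste0("## Setting: ", sname), "",
            "| Model | Accuracy | Macro P | Macro R | Macro F1 |",
            "|---|---|---|---|---|")
    for (mname in names(s$models)) {
      mr <- s$models[[mname]]
      wj(report_as_list(mr$report),
         sprintf("report_%s_%s.json", sname, mname))
      utils::write.csv(
        mr$report$confusion$counts,
        file.path(out_dir, sprintf("confusion_%s_%s.csv", sname, mname)))
      if (!is.null(mr$cv))
        wj(list(fold_accuracies = mr$cv$fold_accuracies,
                mean_accuracy = mr$cv$mean_accuracy, sd = mr$cv$sd,
                k = mr$cv$k, seed = mr$cv$seed),
           sprintf("cv_%s_%s.json", sname, mname))
      r <- mr$report
      md <- c(md, sprintf("| %s | %.2f | %.2f | %.2f | %.2f |", mname,
                          round_half_up(r$accuracy),
                          round_half_up(r$macro_precision),
                          round_half_up(r$macro_recall),
                          round_half_up(r$macro_f1)))
    }
    md <- c(md, "")
  }
  if (length(bundle$ttests)) {
    md <- c(md, "## Paired t-tests", "",
            "| Comparison | t | df | p | reject H0 |", "|---|---|---|---|---|")
    tts <- lapply(bundle$ttests, function(tt)
      list(t_statistic = tt$t_statistic, df = tt$df, p_value = tt$p_value,
           alpha = tt$alpha, reject_null = tt$reject_null))
    wj(tts, "ttests.json")
    for (nm in names(bundle$ttests)) {
      tt <- bundle$ttests[[nm]]
      md <- c(md, sprintf("| %s | %.3f | %d | %.4g | %s |", nm,
                          tt$t_statistic, tt$df, tt$p_value,
                          tt$reject_null))
    }
  }
  if (!is.null(bundle$balance_plan))
    wj(list(selected_classes = bundle$balance_plan$selected_classes,
            per_class_n = bundle$balance_plan$per_class_n,
            kept_indices = bundle$balance_plan$kept_indices,
            dropped_classes = bundle$balance_plan$dropped_classes),
       "balance_plan.json")
  writeLines(md, file.path(out_dir, "report.md"))
  cfg <- bundle$config
  manifest <- list(
    package_version = as.character(utils::packageVersion("selfstack")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    timestamp = format(Sys.time(), tz = "UTC"),
    preset = cfg$preset, sim_seed = cfg$sim_seed,
    split_ratio = cfg$split_ratio, split_seed = cfg$split_seed,
    cv_k = cfg$cv_k, cv_seed = cfg$cv_seed,
    models = names(cfg$models),
    min_class_size = cfg$min_class_size, per_class_n = cfg$per_class_n)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
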