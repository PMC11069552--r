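#' Configure the full prognosis pipeline
#'
#' Stage order follows the framework's flow: cohort generation (or CSV
#' input), auto-encoder imputation, golden-flower feature selection,
#' water-drop tuning of the generator-classifier coupling delta, GAN
#' training with minority augmentation, and confusion-matrix evaluation.
#' Every stage draws its seed deterministically from the global seed via
#' \code{\link{derive_seed}}.
#'
#' @param cohort a \code{\link{cohort_config}} (used when no input table is
#'   given to \code{\link{run_pipeline}}).
#' @param daem a \code{\link{daem_config}}.
#' @param gfs a \code{\link{gfs_config}} for feature selection.
#' @param colbgan a \code{\link{colbgan_config}}.
#' @param wdo an \code{\link{iwd_config}} for delta tuning.
#' @param delta_grid candidate delta values for the tuner.
#' @param tune_epochs reduced epoch count for tuning runs.
#' @param accuracy_weight,cv_folds feature-selection fitness settings.
#' @param test_fraction held-out fraction for evaluation.
#' @param stages named logical vector enabling \code{impute},
#'   \code{select}, \code{tune}, \code{augment}.
#' @param global_seed integer master seed.
#' @param output_dir optional directory for stage artifacts (CSV/JSON);
#'   nothing is written when \code{NULL}.
#' @return a list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            daem = daem_config(),
                            gfs = gfs_config(population_size = 12,
                                             iterations = 40),
                            colbgan = colbgan_config(),
                            wdo = iwd_config(n_drops = 4, max_iterations = 6),
                            delta_grid = c(0, 0.01, 0.1, 0.5, 1, 2),
                            tune_epochs = 30,
                            accuracy_weight = 0.9, cv_folds = 5,
                            test_fraction = 0.25,
                            stages = c(impute = TRUE, select = TRUE,
                                       tune = TRUE, augment = TRUE),
                            global_seed = 1L, output_dir = NULL) {
  structure(list(cohort = cohort, daem = daem, gfs = gfs, colbgan = colbgan,
                 wdo = wdo, delta_grid = delta_grid,
                 tune_epochs = tune_epochs,
                 accuracy_weight = accuracy_weight, cv_folds = cv_folds,
                 test_fraction = test_fraction, stages = stages,
                 global_seed = as.integer(global_seed),
                 output_dir = output_dir),
            class = "pipeline_config")
}

stage_on <- function(config, name) isTRUE(config$stages[[name]])

#' Run the end-to-end prognosis pipeline
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param table optional \code{\link{clinical_table}}; when \code{NULL} a
#'   synthetic cohort is generated from \code{config$cohort}.
#' @return an object of class \code{"dacl_report"}: selected features,
#'   tuned delta, test-set \code{\link{classification_metrics}} and AUC,
#'   per-stage seeds and runtimes, and the ground truth when the cohort was
#'   generated.
#' @export
run_pipeline <- function(config, table = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  gs <- config$global_seed
  timing <- list(); stamp <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    v <- expr
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    v
  }
  seeds <- list()
  truth <- NULL
  if (is.null(table)) {
    cc <- config$cohort
    cc$seed <- derive_seed(gs, "generate"); seeds$generate <- cc$seed
    gen <- stamp(generate_cohort(cc), "generate")
    table <- gen$table; truth <- gen$truth
  }
  ## split before any fitting: all maps and models come from training rows
  seeds$split <- derive_seed(gs, "split")
  sp <- stratified_split(table, config$test_fraction, seeds$split)
  train_tab <- subset_table(table, sp$train)
  test_tab <- subset_table(table, sp$test)
  ## imputation
  daem_fit <- NULL
  if (stage_on(config, "impute") &&
      any(train_tab$mask[, feature_columns(table$schema)])) {
    dc <- config$daem; dc$seed <- derive_seed(gs, "impute")
    seeds$impute <- dc$seed
    enc_train <- encode_table(train_tab)
    daem_fit <- stamp(train_daem(enc_train, dc), "impute")
    train_tab <- impute(train_tab, daem_fit)
    test_tab <- impute(test_tab, daem_fit)
  }
  enc_train <- encode_table(train_tab)
  enc_test <- encode_table(test_tab, map = enc_train$map)
  groups <- lapply(enc_train$map, function(m) m$cols)
  ## feature selection
  selected <- names(groups); sel_cols <- seq_len(ncol(enc_train$X))
  sel_fit <- NULL
  if (stage_on(config, "select")) {
    gc <- config$gfs; gc$seed <- derive_seed(gs, "select")
    seeds$select <- gc$seed
    sel_fit <- stamp(select_features(
      enc_train$X, enc_train$y, gc,
      accuracy_weight = config$accuracy_weight,
      cv_folds = config$cv_folds, groups = groups), "select")
    selected <- sel_fit$selected
    sel_cols <- sort(unlist(groups[sel_fit$mask], use.names = FALSE))
  }
  Xtr <- enc_train$X[, sel_cols, drop = FALSE]
  Xte <- enc_test$X[, sel_cols, drop = FALSE]
  ytr <- enc_train$y; yte <- enc_test$y
  ## delta tuning by water-drop search on a short training run
  delta <- config$colbgan$delta
  tune_res <- NULL
  if (stage_on(config, "tune")) {
    seeds$tune <- derive_seed(gs, "tune")
    wc <- config$wdo; wc$seed <- seeds$tune
    inner <- stratified_split(
      clinical_mini_table(ytr), 0.25, derive_seed(gs, "tune_split"))
    ev <- function(vals) {
      cfg <- config$colbgan
      cfg$delta <- vals$delta
      cfg$epochs <- config$tune_epochs
      cfg$augment_to_balance <- FALSE
      cfg$seed <- derive_seed(gs, "tune_fit")
      fit <- train_colbgan(list(X = Xtr[inner$train, , drop = FALSE],
                                y = ytr[inner$train]), cfg)
      pr <- predict(fit, Xtr[inner$test, , drop = FALSE])
      p <- pr$probabilities[cbind(seq_along(inner$test),
                                  ytr[inner$test] + 1L)]
      mean(log(pmax(p, 1e-12)))   # higher = better held-out log-likelihood
    }
    tune_res <- stamp(
      tune_loss_parameter(list(delta = config$delta_grid), ev, wc), "tune")
    delta <- tune_res$best$delta
  }
  ## final GAN training
  cb <- config$colbgan
  cb$delta <- delta
  cb$seed <- derive_seed(gs, "train"); seeds$train <- cb$seed
  if (!stage_on(config, "augment")) cb$augment_to_balance <- FALSE
  model <- stamp(train_colbgan(list(X = Xtr, y = ytr), cb), "train")
  ## evaluation
  pr <- predict(model, Xte)
  cm <- confusion(yte, pr$labels)
  metrics <- classification_metrics(cm)
  auc <- roc_auc(yte, pr$probabilities[, 2])$auc
  report <- structure(list(
    selected_features = selected,
    delta = delta,
    confusion = cm,
    metrics = metrics,
    auc = auc,
    n_train = length(ytr), n_test = length(yte),
    truth = truth,
    seeds = seeds,
    timing = timing), class = "dacl_report")
  report$model <- model
  report$daem <- daem_fit
  report$selection <- sel_fit
  report$map <- enc_train$map
  report$sel_cols <- sel_cols
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$output_dir, "report.json"))
  }
  report
}

# Tiny label-only table so the tuner can reuse the stratified splitter.
clinical_mini_table <- function(y) {
  sch <- feature_schema(list(list(name = "y", kind = "binary",
                                  levels = c("0", "1"))),
                        label_column = "y")
  clinical_table(data.frame(y = as.character(y), stringsAsFactors = FALSE),
                 sch)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the numerical content of the report (metrics, confusion counts,
#' selected features, delta, seeds) plus a separate \code{timing} block;
#' comparisons of two runs should drop \code{timing}, the only
#' non-deterministic entry.
#'
#' @param report a \code{"dacl_report"}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(report, path) {
  out <- list(
    selected_features = report$selected_features,
    delta = report$delta,
    confusion = unclass(report$confusion),
    metrics = unclass(report$metrics)[names(report$metrics)],
    auc = report$auc,
    n_train = report$n_train, n_test = report$n_test,
    seeds = report$seeds,
    truth = report$truth,
    timing = report$timing)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.dacl_report <- function(x, ...) {
  cat("DACL pipeline report\n")
  cat("  train/test:", x$n_train, "/", x$n_test, "rows\n")
  cat("  selected features:", paste(x$selected_features, collapse = ", "),
      "\n")
  cat("  tuned delta:", x$delta, "\n")
  cat(sprintf("  accuracy %.4f | sensitivity %.4f | specificity %.4f | F1 %.4f | AUC %.4f\n",
              x$metrics$accuracy, x$metrics$recall_sensitivity,
              x$metrics$specificity, x$metrics$f1, x$auc))
  if (!is.null(x$truth))
    cat(sprintf("  cohort Bayes accuracy estimate: %.4f (prevalence %.3f)\n",
                x$truth$bayes_accuracy_estimate,
                x$truth$achieved_prevalence))
  invisible(x)
}

#' @export
summary.dacl_report <- function(object, ...) {
  print(object)
  cat("  stage seeds:",
      paste(names(object$seeds), unlist(object$seeds), sep = "=",
            collapse = ", "), "\n")
  cat("  stage runtimes (s):",
      paste(names(object$timing), unlist(object$timing), sep = "=",
            collapse = ", "), "\n")
  invisible(object)
}

#' Classify new clinical records with a fitted pipeline
#'
#' Applies the frozen encoding map, imputes missing cells with the trained
#' auto-encoder (when one was fitted), restricts to the selected columns
#' and scores with the classifier head.
#'
#' @param object a \code{"dacl_report"} from \code{\link{run_pipeline}}.
#' @param newdata a \code{\link{clinical_table}} with the same schema.
#' @param ... unused.
#' @return list with \code{labels} and \code{probabilities}.
#' @export
predict.dacl_report <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "clinical_table"))
  if (!is.null(object$daem)) newdata <- impute(newdata, object$daem)
  enc <- encode_table(newdata, map = object$map)
  predict(object$model, enc$X[, object$sel_cols, drop = FALSE])
}
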