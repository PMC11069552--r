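#' Configure a synthetic clinical cohort
#'
#' The generator emulates a stroke-risk record table with a known, planted
#' sparse logistic signal. Risk factors are correlated through a shared
#' latent comorbidity factor (so that age, hypertension, heart disease,
#' glucose and BMI co-vary the way they do in real cohorts, and so that
#' reconstruction-based imputation has structure to exploit); the label is
#' drawn from a logistic model on standardized encoded features with the
#' given coefficients, and the intercept is bisection-adjusted until the
#' empirical prevalence matches \code{minority_fraction} to within 0.02.
#'
#' @param n number of rows.
#' @param schema feature schema; defaults to \code{\link{stroke_schema}}.
#' @param informative_features names of columns carrying signal; must be
#'   numeric or binary columns of the schema.
#' @param coefficients one coefficient per informative feature, on the
#'   standardized encoded scale.
#' @param intercept starting intercept before prevalence calibration.
#' @param missing_rate MCAR missingness rate applied to feature cells.
#' @param minority_fraction target prevalence of the positive class, in
#'   (0, 0.5].
#' @param latent_loading correlation loading of numeric risk factors on the
#'   shared comorbidity factor.
#' @param seed integer seed.
#' @return a list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n = 1000,
                          schema = stroke_schema(),
                          informative_features = c("age", "hypertension",
                                                   "heart_disease",
                                                   "avg_glucose", "bmi"),
                          coefficients = c(2.0, 1.5, 1.5, 2.0, 1.0),
                          intercept = 0,
                          missing_rate = 0,
                          minority_fraction = 0.5,
                          latent_loading = 0.6,
                          seed = 1L) {
  stopifnot(inherits(schema, "feature_schema"),
            length(informative_features) == length(coefficients),
            missing_rate >= 0, missing_rate < 1,
            minority_fraction > 0, minority_fraction <= 0.5)
  feats <- feature_columns(schema)
  bad <- setdiff(informative_features, feats)
  if (length(bad))
    stop("informative feature '", bad[1], "' is not a feature column")
  for (nm in informative_features)
    if (schema$kinds[[nm]] == "categorical")
      stop("informative features must be numeric or binary, not categorical ('",
           nm, "')")
  structure(list(n = n, schema = schema,
                 informative_features = informative_features,
                 coefficients = coefficients, intercept = intercept,
                 missing_rate = missing_rate,
                 minority_fraction = minority_fraction,
                 latent_loading = latent_loading, seed = as.integer(seed)),
            class = "cohort_config")
}

# Column generators for the default stroke schema. Numeric risk factors load
# on a shared latent comorbidity factor z, and lifestyle/demographic columns
# depend on age the way real cohorts do (marriage and self-employment rise
# with age, never-worked and smoking fall), so that cross-column structure is
# genuinely recoverable. Gender and residence stay independent.
draw_numeric <- function(nm, n, z, loading) {
  mix <- function(mean, sd) {
    mean + sd * (loading * z + sqrt(1 - loading^2) * stats::rnorm(n))
  }
  switch(nm,
    id = seq_len(n),
    age = pmin(95, pmax(18, mix(50, 15))),
    avg_glucose = pmax(40, mix(105, 35)),
    bmi = pmax(12, mix(28, 6)),
    mix(0, 1))
}

draw_levels <- function(nm, n, z, levels, age = NULL) {
  pick <- function(p) levels[1L + (stats::runif(n) < p)]
  a <- if (is.null(age)) rep(50, n) else age
  multinom_rows <- function(P) {
    u <- stats::runif(n)
    cum <- t(apply(P, 1, cumsum))
    levels[max.col(u <= cum, "first")]
  }
  switch(nm,
    gender = sample(levels, n, replace = TRUE),
    # comorbidity flags: latent factor plus an age gradient (probit-style)
    hypertension = pick(logistic(-1.4 + 1.0 * z + 0.045 * (a - 50))),
    heart_disease = pick(logistic(-2.2 + 1.0 * z + 0.05 * (a - 50))),
    ever_married = pick(logistic(0.10 * (a - 32))),
    residence = pick(0.5),
    work_type = {
      # Govt_job, Never_worked, Private, Self_employed
      eta <- cbind(-1.3 + 0.01 * (a - 50),
                   -2.0 - 0.10 * (a - 50),
                   0,
                   -1.0 + 0.06 * (a - 50))
      multinom_rows(exp(eta) / rowSums(exp(eta)))
    },
    smoking_status = {
      # formerly_smoked, never_smoked, smokes, unknown
      eta <- cbind(-0.8 + 0.05 * (a - 50),
                   0,
                   -0.8 - 0.04 * (a - 50),
                   -0.3 - 0.02 * (a - 50))
      multinom_rows(exp(eta) / rowSums(exp(eta)))
    },
    sample(levels, n, replace = TRUE))
}

#' Generate a synthetic cohort with a planted logistic signal
#'
#' @param config a \code{\link{cohort_config}}.
#' @return list with \code{table} (a \code{\link{clinical_table}}, with
#'   hidden truth retained when \code{missing_rate > 0}) and \code{truth}
#'   (informative features, coefficients, calibrated intercept, achieved
#'   prevalence and a Monte-Carlo Bayes accuracy estimate).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  sch <- config$schema
  res <- with_seed(config$seed, {
    n <- config$n
    z <- stats::rnorm(n)
    vals <- vector("list", length(sch$names)); names(vals) <- sch$names
    for (nm in sch$names) {
      if (nm == sch$label_column) next
      if (sch$kinds[[nm]] == "numeric")
        vals[[nm]] <- draw_numeric(nm, n, z, config$latent_loading)
    }
    for (nm in sch$names) {
      if (nm == sch$label_column || !is.null(vals[[nm]])) next
      vals[[nm]] <- draw_levels(nm, n, z, sch$levels[[nm]],
                                age = vals[["age"]])
    }
    # linear predictor on standardized encoded informative features
    lp0 <- rep(0, n)
    for (k in seq_along(config$informative_features)) {
      nm <- config$informative_features[k]
      v <- if (sch$kinds[[nm]] == "numeric") vals[[nm]]
        else as.numeric(match(vals[[nm]], sch$levels[[nm]]) - 1L)
      s <- stats::sd(v)
      if (s > 0) lp0 <- lp0 + config$coefficients[k] * (v - mean(v)) / s
    }
    u <- stats::runif(n)
    draw_prev <- function(t) mean(u < logistic(config$intercept + t + lp0))
    # bisection on an intercept shift so empirical prevalence hits target
    lo <- -30; hi <- 30; t <- 0
    if (draw_prev(lo) > config$minority_fraction ||
        draw_prev(hi) < config$minority_fraction)
      stop("unreachable prevalence given coefficients")
    for (it in seq_len(50)) {
      t <- (lo + hi) / 2
      pv <- draw_prev(t)
      if (abs(pv - config$minority_fraction) <= 0.02) break
      if (pv < config$minority_fraction) lo <- t else hi <- t
    }
    if (abs(draw_prev(t) - config$minority_fraction) > 0.02)
      stop("unreachable prevalence given coefficients (bisection budget)")
    p <- logistic(config$intercept + t + lp0)
    lab <- as.integer(u < p)
    ylv <- sch$levels[[sch$label_column]]
    vals[[sch$label_column]] <- ylv[lab + 1L]
    tab <- clinical_table(
      as.data.frame(vals[sch$names], check.names = FALSE,
                    stringsAsFactors = FALSE), sch)
    truth <- list(informative_features = config$informative_features,
                  coefficients = config$coefficients,
                  intercept = config$intercept + t,
                  achieved_prevalence = mean(lab),
                  bayes_accuracy_estimate = mean(pmax(p, 1 - p)))
    list(tab = tab, truth = truth)
  })
  tab <- res$tab
  if (config$missing_rate > 0)
    tab <- inject_missingness(tab, config$missing_rate,
                              seed = derive_seed(config$seed, "missingness"))
  list(table = tab, truth = res$truth)
}

#' Inject missing-completely-at-random gaps into a table
#'
#' Each non-label, non-id cell is independently masked with probability
#' \code{rate}. The pre-masking values are retained in a
#' \code{"hidden_truth"} attribute so imputation error against the hidden
#' cells can be scored.
#'
#' @param table a \code{\link{clinical_table}}.
#' @param rate missingness probability in [0, 1).
#' @param mechanism only \code{"MCAR"} is implemented.
#' @param seed integer seed.
#' @return a \code{\link{clinical_table}} with an updated mask.
#' @export
inject_missingness <- function(table, rate, mechanism = "MCAR", seed = 1L) {
  if (rate < 0 || rate >= 1) stop("missingness rate must be in [0, 1)")
  mechanism <- match.arg(mechanism, "MCAR")
  if (rate == 0) return(table)
  sch <- table$schema
  feats <- feature_columns(sch)
  mask <- table$mask
  with_seed(seed, {
    draw <- matrix(stats::runif(nrow(table$values) * length(feats)),
                   nrow(table$values), length(feats))
    mask[, feats] <- mask[, feats] | (draw < rate)
  })
  out <- clinical_table(table$values, sch, mask)
  attr(out, "hidden_truth") <- table$values
  out
}

#' Score imputation error against hidden truth
#'
#' Root-mean-squared error over the hidden (injected-missing) cells, on the
#' encoded [0,1] scale so numeric, binary and categorical columns are
#' commensurate — the standard way reconstruction-based imputers are
#' scored on normalized matrices. \code{imputed} may be a trained
#' \code{\link{train_daem}} model (scored by its soft completion of the
#' encoded matrix), the string \code{"column_mean"} (the observed column
#' means, the classical mean-imputation reference on this scale), or a
#' completed \code{\link{clinical_table}} (scored after re-encoding, i.e.
#' with hard category assignments).
#'
#' @param masked the table with injected missingness (carrying hidden truth).
#' @param imputed a \code{"daem"} fit, \code{"column_mean"}, or a completed
#'   \code{\link{clinical_table}}.
#' @return RMSE over hidden cells on the encoded scale.
#' @export
imputation_rmse <- function(masked, imputed) {
  truth_vals <- attr(masked, "hidden_truth")
  if (is.null(truth_vals)) stop("masked table carries no hidden truth")
  truth_tab <- clinical_table(truth_vals, masked$schema)
  enc_masked <- encode_table(masked)
  enc_truth <- encode_table(truth_tab, map = enc_masked$map)
  hidden <- enc_masked$mask
  if (!any(hidden)) stop("no hidden cells to score")
  filled <- if (inherits(imputed, "daem")) {
    complete_encoded(enc_masked, imputed)$X
  } else if (identical(imputed, "column_mean")) {
    X <- enc_masked$X
    cm <- vapply(seq_len(ncol(X)),
                 function(j) mean(X[!hidden[, j], j]), numeric(1))
    for (j in seq_len(ncol(X))) X[hidden[, j], j] <- cm[j]
    X
  } else if (inherits(imputed, "clinical_table")) {
    encode_table(imputed, map = enc_masked$map)$X
  } else stop("imputed must be a daem fit, 'column_mean', or a table")
  sqrt(mean((filled[hidden] - enc_truth$X[hidden])^2))
}

#' High-signal cohort configuration
#'
#' The default planted coefficients scaled by 1.2, which puts the cohort's
#' Bayes accuracy at about 0.93 — a sharp reference condition for
#' end-to-end classification checks: a correctly functioning pipeline
#' should approach that ceiling on held-out data.
#'
#' @param n cohort size.
#' @param missing_rate MCAR rate.
#' @param minority_fraction positive-class prevalence.
#' @param seed integer seed.
#' @return a \code{\link{cohort_config}}.
#' @export
high_signal_config <- function(n = 1200, missing_rate = 0.1,
                               minority_fraction = 0.35, seed = 1L) {
  cohort_config(n = n,
                coefficients = c(2.0, 1.5, 1.5, 2.0, 1.0) * 1.2,
                missing_rate = missing_rate,
                minority_fraction = minority_fraction, seed = seed)
}
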