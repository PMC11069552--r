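make_params <- function(omega, beta, omega_prime, beta_prime, cont_idx) {
  list(omega = omega, beta = beta, omega_prime = omega_prime,
       beta_prime = beta_prime, cont_idx = cont_idx)
}

test_that("encoder and decoder maps follow their closed forms", {
  # zero weights: sigma(0) = 0.5 on every hidden unit
  p <- make_params(matrix(0, 3, 2), c(0, 0), matrix(0, 2, 3), c(0, 0, 0),
                   c(TRUE, FALSE, TRUE))
  expect_equal(daem_encode(c(1, -2, 5), p), c(0.5, 0.5))
  # d_in 2, d_hidden 1, omega (1,1), a = (0,0) -> 0.5
  p2 <- make_params(matrix(c(1, 1), 2, 1), 0, matrix(0, 1, 2), c(0, 0),
                    c(TRUE, TRUE))
  expect_equal(daem_encode(c(0, 0), p2), 0.5)
  # monotonicity in a coordinate with positive weight
  b1 <- daem_encode(c(0.2, 0), p2); b2 <- daem_encode(c(0.9, 0), p2)
  expect_gt(b2, b1)
  # decoder zero weights: continuous coords 0, discrete 0.5
  expect_equal(daem_decode(c(0.3, 0.8), p), c(0, 0.5, 0))
  # affine doubling on continuous coordinates (bias removed)
  p3 <- make_params(matrix(0, 2, 2), c(0, 0),
                    matrix(c(1, 2, 0.5, -1), 2, 2), c(0.3, -0.2),
                    c(TRUE, TRUE))
  b <- c(0.4, 0.1)
  d1 <- daem_decode(b, p3) - p3$beta_prime
  d2 <- daem_decode(2 * b, p3) - p3$beta_prime
  expect_equal(d2, 2 * d1)
  expect_length(daem_decode(c(0.5, 0.5), p), 3)
  expect_error(daem_encode(c(1, 2), p), "structural")
  expect_error(daem_decode(c(1, 2, 3), p), "structural")
})

test_that("masked reconstruction loss mixes squared error and cross-entropy over observed cells", {
  X <- matrix(c(0.4, 0.7), 1, 2)
  cont <- c(TRUE, FALSE)
  # identical reconstruction, all observed -> 0
  expect_equal(masked_reconstruction_loss(X, X, matrix(FALSE, 1, 2), cont),
               -(0.7 * log(0.7) + 0.3 * log(0.3)) / 2, tolerance = 1e-12)
  # a single continuous cell: truth 0.4, recon 0.1 -> squared error 0.09
  expect_equal(masked_reconstruction_loss(
    matrix(0.4), matrix(0.1), matrix(FALSE), TRUE), 0.09)
  # fully masked rows contribute nothing
  X2 <- rbind(c(0.4, 0.7), c(0.9, 0.1))
  R2 <- rbind(c(0.1, 0.7), c(0.5, 0.5))
  m <- rbind(c(FALSE, TRUE), c(TRUE, TRUE))
  expect_equal(masked_reconstruction_loss(X2, R2, m, c(TRUE, TRUE)), 0.09)
  expect_error(masked_reconstruction_loss(X2, R2, !logical(4), cont),
               "zero observed")
  expect_error(masked_reconstruction_loss(X, matrix(0.1), m, cont),
               "shape")
})

test_that("training reproduces a constant column and is deterministic", {
  set.seed(5)
  sch <- numeric_schema(3)
  n <- 120
  vals <- data.frame(x01 = rep(0.7, n), x02 = runif(n), x03 = runif(n),
                     disease = sample(c("0", "1"), n, TRUE),
                     stringsAsFactors = FALSE)
  tab <- inject_missingness(clinical_table(vals, sch), 0.3, seed = 2)
  cfg <- daem_config(epochs = 200, seed = 3)
  enc <- suppressWarnings(encode_table(tab))   # constant column warning
  fit <- train_daem(enc, cfg)
  imp <- impute(tab, fit)
  miss <- tab$mask[, "x01"]
  expect_true(any(miss))
  expect_true(all(abs(imp$values$x01[miss] - 0.7) < 0.05))
  # determinism
  fit2 <- train_daem(suppressWarnings(encode_table(tab)), cfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history, fit2$history)
})

test_that("epoch-average training loss decreases overall", {
  g <- generate_cohort(cohort_config(n = 300, missing_rate = 0.2, seed = 4))
  fit <- train_daem(encode_table(g$table), daem_config(epochs = 150, seed = 4))
  tl <- fit$history$train_loss
  # start-to-end decrease, and no sustained increase beyond tolerance
  expect_lt(tl[length(tl)], tl[1])
  early <- mean(tl[1:10]); late <- mean(tl[(length(tl) - 9):length(tl)])
  expect_lt(late, early)
})

test_that("imputation preserves observed cells and completes the mask", {
  g <- generate_cohort(cohort_config(n = 300, missing_rate = 0.25, seed = 7))
  tab <- g$table
  fit <- train_daem(encode_table(tab), daem_config(epochs = 150, seed = 7))
  imp <- impute(tab, fit)
  feats <- feature_columns(tab$schema)
  expect_false(any(imp$mask[, feats]))
  for (nm in feats) {
    obs <- !tab$mask[, nm]
    expect_identical(imp$values[[nm]][obs], tab$values[[nm]][obs])
  }
  # a table with no missing cells passes through untouched
  full <- generate_cohort(cohort_config(n = 50, missing_rate = 0, seed = 1))
  expect_identical(impute(full$table, fit), full$table)
  # width mismatch is structural
  other <- random_table(numeric_schema(2), 10, 0.5, seed = 2)
  expect_error(impute(other, fit), "structural|header|schema|match")
})

test_that("auto-encoder imputation beats column means on correlated cohorts", {
  # subset of the 10-seed comparison (the full sweep runs in acceptance)
  wins <- 0
  for (s in 1:3) {
    g <- generate_cohort(cohort_config(n = 500, missing_rate = 0.2, seed = s))
    fit <- train_daem(encode_table(g$table), daem_config(seed = s))
    wins <- wins + (imputation_rmse(g$table, fit) <
                    imputation_rmse(g$table, "column_mean"))
  }
  expect_gte(wins, 2)
})

test_that("imputation error approaches the noise floor on low-rank data", {
  set.seed(11)
  n <- 400; d <- 8
  z <- rnorm(n); L <- runif(d, 0.5, 1)
  X <- 0.5 + 0.15 * outer(z, L) + matrix(rnorm(n * d, sd = 0.04), n, d)
  X[] <- pmin(1, pmax(0, as.vector(X)))
  sch <- numeric_schema(d)
  df <- as.data.frame(X); colnames(df) <- sprintf("x%02d", seq_len(d))
  df$disease <- sample(c("0", "1"), n, TRUE)
  tab <- inject_missingness(clinical_table(df, sch), 0.3, seed = 3)
  fit <- train_daem(encode_table(tab), daem_config(seed = 3))
  rd <- imputation_rmse(tab, fit)
  rm_ <- imputation_rmse(tab, "column_mean")
  expect_lt(rd, 0.75 * rm_)   # clear exploitation of the shared factor
})
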