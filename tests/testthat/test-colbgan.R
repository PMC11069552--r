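separable_set <- function(n = 600, d = 4, seed = 3) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * d, sd = 0.08), n, d) + 0.3 + 0.4 * y
  X[] <- pmin(1, pmax(0, as.vector(X)))
  list(X = X, y = y)
}

fresh_model <- function(d = 5, seed = 1) {
  set.seed(seed)
  dacl:::colbgan_init(d, colbgan_config(seed = seed))
}

test_that("condition embedding is additive in its two parts", {
  m <- fresh_model()
  set.seed(2)
  noise <- matrix(rnorm(3 * m$config$noise_dim), 3)
  g0 <- embed_condition(noise, c(0, 0, 0), m)
  g1 <- embed_condition(noise, c(1, 1, 1), m)
  expect_equal(dim(g0), c(3, m$config$embed_dim))
  # gamma_t(noise, y) - beta_t(y) = alpha_t(noise) for both labels
  expect_equal(g1 - g0,
               matrix(m$label_embed[2, ] - m$label_embed[1, ], 3,
                      m$config$embed_dim, byrow = TRUE), tolerance = 1e-12)
  # zero weights and biases give the zero vector
  mz <- m
  mz$noise_embed$layers[[1]]$W[] <- 0
  mz$noise_embed$layers[[1]]$b[] <- 0
  mz$label_embed[] <- 0
  expect_equal(embed_condition(noise, c(0, 1, 0), mz),
               matrix(0, 3, m$config$embed_dim))
  expect_error(embed_condition(noise, c(0, 2, 0), m), "label")
  expect_error(embed_condition(noise[, 1:3], c(0, 0, 0), m), "structural")
})

test_that("generated samples live in the unit hypercube with the right shape", {
  m <- fresh_model(d = 7)
  s1 <- generate_samples(c(0, 1, 1, 0), m, seed = 5)
  expect_equal(dim(s1), c(4, 7))
  expect_true(all(s1 > 0 & s1 < 1))
  expect_identical(s1, generate_samples(c(0, 1, 1, 0), m, seed = 5))
  expect_false(identical(s1, generate_samples(c(0, 1, 1, 0), m, seed = 6)))
})

test_that("discriminator value matches its closed form at reference points", {
  m <- fresh_model(d = 3)
  real <- matrix(runif(12), 4); fake <- matrix(runif(12), 4)
  # force D to output exactly 0.5 everywhere
  m0 <- m
  for (l in seq_along(m0$disc$layers)) {
    m0$disc$layers[[l]]$W[] <- 0; m0$disc$layers[[l]]$b[] <- 0
  }
  expect_equal(discriminator_value(real, fake, m0), 1.0)
  v <- discriminator_value(real, fake, m)
  expect_gt(v, 0); expect_lt(v, 2)
  expect_error(discriminator_value(real[0, , drop = FALSE], fake, m),
               "non-empty")
})

test_that("generator loss reduces to the adversarial term at delta zero", {
  m <- fresh_model(d = 3)
  fake <- matrix(runif(9), 3); labs <- c(0, 1, 0)
  l0 <- generator_loss(fake, labs, m, delta = 0)
  l1 <- generator_loss(fake, labs, m, delta = 1)
  l2 <- generator_loss(fake, labs, m, delta = 2)
  expect_gte(l1, l0)              # classifier CE is non-negative
  expect_equal(l2 - l1, l1 - l0, tolerance = 1e-10)  # linear in delta
  # a discriminator reporting "real" with certainty gives -log(1) = 0
  mh <- m
  L <- length(mh$disc$layers)
  for (l in seq_len(L)) { mh$disc$layers[[l]]$W[] <- 0
                          mh$disc$layers[[l]]$b[] <- 0 }
  mh$disc$layers[[L]]$b <- 40    # sigmoid(40) ~ 1
  expect_equal(generator_loss(fake, labs, mh, delta = 0), 0,
               tolerance = 1e-12)
})

test_that("training is deterministic, finite and fully logged", {
  dat <- separable_set(200)
  cfg <- colbgan_config(epochs = 12, seed = 4)
  f1 <- train_colbgan(dat, cfg)
  f2 <- train_colbgan(dat, cfg)
  expect_identical(f1$clf, f2$clf)
  expect_identical(f1$gen, f2$gen)
  expect_identical(f1$log, f2$log)
  expect_equal(nrow(f1$log), 12)
  expect_true(all(is.finite(f1$log$gen_loss)))
  expect_true(all(is.finite(f1$log$disc_value)))
  expect_error(train_colbgan(list(X = dat$X, y = rep(1, 200)),
                             cfg), "both classes")
})

test_that("with the classifier disabled and delta 0 training reduces to a plain cGAN", {
  dat <- separable_set(200)
  fa <- train_colbgan(dat, colbgan_config(epochs = 10, delta = 0,
                                          classifier_enabled = FALSE,
                                          augment_to_balance = FALSE,
                                          seed = 2))
  fb <- train_colbgan(dat, colbgan_config(epochs = 10, delta = 0,
                                          classifier_enabled = TRUE,
                                          augment_to_balance = FALSE,
                                          seed = 2))
  expect_equal(fa$log$gen_loss, fb$log$gen_loss, tolerance = 1e-12)
  expect_equal(fa$log$disc_value, fb$log$disc_value, tolerance = 1e-12)
  expect_identical(fa$gen, fb$gen)
})

test_that("the classifier head separates a linearly separable mixture", {
  dat <- separable_set(600)
  fit <- train_colbgan(dat, colbgan_config(epochs = 60,
                                           augment_to_balance = FALSE,
                                           seed = 1))
  pr <- predict(fit, dat$X)
  expect_gte(mean(pr$labels == dat$y), 0.95)
  expect_equal(rowSums(pr$probabilities), rep(1, 600), tolerance = 1e-6)
  # duplicated rows give identical outputs
  two <- dat$X[c(1, 1), ]
  p2 <- predict(fit, two)
  expect_identical(p2$labels[1], p2$labels[2])
  expect_equal(p2$probabilities[1, ], p2$probabilities[2, ])
  expect_error(predict(fit, dat$X[, 1:2]), "structural")
})

test_that("minority augmentation balances counts and flags synthetic rows", {
  m <- fresh_model(d = 6)
  X <- matrix(runif(600), 100, 6)
  y <- rep(c(0L, 1L), c(90, 10))
  aug <- augment_minority(list(X = X, y = y), m, seed = 2)
  expect_equal(sum(aug$y == 1), sum(aug$y == 0))
  expect_equal(sum(aug$synthetic), 80)
  expect_identical(aug$X[1:100, ], X)          # real rows untouched
  expect_identical(aug$y[1:100], y)
  # balanced input returns unchanged
  yb <- rep(c(0L, 1L), 50)
  augb <- augment_minority(list(X = X, y = yb), m, seed = 2)
  expect_identical(augb$X, X)
  expect_false(any(augb$synthetic))
})
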