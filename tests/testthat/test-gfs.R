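sphere <- function(x) sum(x^2)

test_that("population initialization fills the box uniformly and deterministically", {
  cfg <- gfs_config(population_size = 25, lower = -2, upper = 3, seed = 1)
  st1 <- with_seed_init <- local({ set.seed(1); init_population(sphere, 4, cfg) })
  expect_true(all(st1$population >= -2 & st1$population <= 3))
  expect_equal(st1$best_fitness, min(st1$fitness))
  st2 <- local({ set.seed(1); init_population(sphere, 4, cfg) })
  expect_identical(st1, st2)
  expect_error(gfs_config(lower = 1, upper = 1), "bounds")
})

test_that("flight moves annihilate at the best and respect bounds", {
  cfg <- gfs_config(lower = -1, upper = 1, step_size = 0.5, seed = 2)
  G <- c(0.3, -0.4); best <- G
  set.seed(2)
  expect_equal(pareto_flight(G, best, cfg), G)     # G == best
  expect_equal(tangent_flight(G, best, cfg), G)
  cfg0 <- cfg; cfg0$step_size <- 0
  expect_equal(pareto_flight(c(0.1, 0.9), best, cfg0), c(0.1, 0.9))
  # theta = pi/4 makes the step exactly s * (G - best)
  G2 <- c(0.5, 0.5); b2 <- c(0.1, 0.3)
  expect_equal(tangent_flight(G2, b2, cfg, theta = rep(pi / 4, 2)),
               G2 + 0.5 * (G2 - b2))
  # bounds always hold under wild draws
  set.seed(3)
  for (i in 1:50) {
    out <- tangent_flight(c(0.9, -0.9), c(-0.5, 0.2), cfg)
    expect_true(all(out >= -1 & out <= 1))
  }
})

test_that("tangent steps are heavier-tailed than Gaussian", {
  set.seed(7)
  th <- runif(1e5, -pi / 2, pi / 2)
  steps <- pmin(1e3, pmax(-1e3, tan(th)))
  kurt <- mean((steps - mean(steps))^4) / stats::var(steps)^2
  expect_gt(kurt, 3)   # Gaussian excess kurtosis benchmark
})

test_that("golden-section refinement matches closed-form minima and grid search", {
  # probes for the initial [0,1] bracket sit at 0.618 and 0.382
  probes <- c()
  f_rec <- function(x) { probes <<- c(probes, x); (x - 0.3)^2 }
  golden_section_refine(function(v) f_rec(v[1]), 0, 1, budget = 2)
  expect_equal(sort(probes[1:2]), c(1 - 0.618, 0.618), tolerance = 1e-12)
  # closed-form minimum within 1e-4
  r <- golden_section_refine(function(v) (v[1] - 0.3)^2, 0, 1, budget = 40)
  expect_lt(abs(r$x - 0.3), 1e-4)
  # symmetric objective about the midpoint
  rs <- golden_section_refine(function(v) abs(v[1] - 0.5), 0, 1, budget = 40)
  expect_lt(abs(rs$x - 0.5), 1e-3)
  # grid-search oracle on random unimodal quadratics
  set.seed(5)
  grid <- seq(0, 1, length.out = 1e4)
  for (i in 1:20) {
    tmin <- runif(1, 0.05, 0.95); a <- runif(1, 0.5, 4)
    f <- function(v) a * (v[1] - tmin)^2
    r <- golden_section_refine(f, 0, 1, budget = 40)
    gbest <- grid[which.min(a * (grid - tmin)^2)]
    expect_lt(abs(r$x - gbest), 1e-3)
  }
  expect_error(golden_section_refine(sphere, 0, 1, budget = 1), "budget")
  expect_error(golden_section_refine(sphere, c(1, 2), c(1, 2), 10), "equals")
})

test_that("the search minimizes the sphere and keeps a monotone best trace", {
  r <- gfs_optimize(sphere, 5, gfs_config(population_size = 30,
                                          iterations = 200,
                                          lower = -5, upper = 5, seed = 1))
  expect_lt(r$best_fitness, 1e-3)
  expect_true(all(diff(r$history) <= 0))
  expect_true(all(abs(r$best) <= 5))
  # one iteration can only improve on the initial population
  r1 <- gfs_optimize(sphere, 3, gfs_config(population_size = 10,
                                           iterations = 1,
                                           lower = -5, upper = 5, seed = 2))
  init <- local({ set.seed(2)
    init_population(sphere, 3, gfs_config(population_size = 10,
                                          lower = -5, upper = 5, seed = 2)) })
  expect_lte(r1$best_fitness, init$best_fitness)
  # non-finite objectives abort with the offending point
  expect_error(gfs_optimize(function(x) ifelse(x[1] > 0, Inf, sum(x^2)),
                            2, gfs_config(lower = -1, upper = 1,
                                          iterations = 2, seed = 3)),
               "non-finite")
})

test_that("feature selection recovers a single informative column", {
  for (s in 1:5) {
    cc <- cohort_config(n = 300, schema = numeric_schema(3),
                        informative_features = "x02", coefficients = 3,
                        minority_fraction = 0.5, seed = s)
    g <- generate_cohort(cc)
    enc <- encode_table(g$table)
    sel <- select_features(enc$X, enc$y,
                           gfs_config(population_size = 10, iterations = 25,
                                      seed = s))
    expect_true("x02" %in% sel$selected)
  }
})

test_that("removing sparsity pressure cannot shrink the selected subset", {
  sizes <- matrix(NA_real_, 4, 2)
  for (s in 1:4) {
    cc <- cohort_config(n = 300, schema = numeric_schema(8),
                        informative_features = c("x01", "x02"),
                        coefficients = c(2.5, 2), minority_fraction = 0.5,
                        seed = s)
    g <- generate_cohort(cc)
    enc <- encode_table(g$table)
    cfg <- gfs_config(population_size = 12, iterations = 30, seed = s)
    sizes[s, 1] <- length(select_features(enc$X, enc$y, cfg,
                                          accuracy_weight = 0.7)$selected)
    sizes[s, 2] <- length(select_features(enc$X, enc$y, cfg,
                                          accuracy_weight = 1)$selected)
  }
  expect_gte(mean(sizes[, 2]), mean(sizes[, 1]))
})

test_that("selection masks group one-hot columns with their source feature", {
  g <- generate_cohort(cohort_config(n = 400, seed = 3))
  enc <- encode_table(g$table)
  groups <- lapply(enc$map, function(m) m$cols)
  sel <- select_features(enc$X, enc$y,
                         gfs_config(population_size = 8, iterations = 15,
                                    seed = 3), groups = groups)
  expect_true(all(sel$selected %in% names(groups)))
  expect_equal(length(sel$mask), length(groups))
})
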