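#' Configure the golden flower search
#'
#' Flower-pollination population search in a box \code{[L, U]}: with the
#' switching probability a pollen takes a global tangent flight whose step
#' magnitude is drawn from a heavy-tailed Pareto law; otherwise it performs
#' local pollination — a golden-section line search along the segment to a
#' random other population member. Moves are accepted greedily, so the
#' best-so-far trace never increases.
#'
#' @param population_size number of pollens (>= 2).
#' @param iterations search iterations.
#' @param step_size global step-size factor \code{s}.
#' @param switch_probability probability of a global move.
#' @param lower,upper bound vectors (recycled to the problem dimension).
#' @param pareto_shape shape of the Pareto step-magnitude law (scale 1).
#' @param tan_clip cap on \code{|tan(theta)|} for numerical safety.
#' @param golden_budget objective evaluations per golden-section refinement.
#' @param golden_coefficient golden-section probe coefficient; 0.618 is the
#'   inverse golden ratio (an alternative printed value of 0.0618 can be set
#'   for fidelity experiments).
#' @param seed integer seed.
#' @return a list of class \code{"gfs_config"}.
#' @export
gfs_config <- function(population_size = 30, iterations = 200,
                       step_size = 0.1, switch_probability = 0.8,
                       lower = 0, upper = 1, pareto_shape = 1.5,
                       tan_clip = 1e3, golden_budget = 8,
                       golden_coefficient = 0.618, seed = 1L) {
  stopifnot(population_size >= 2, iterations >= 1,
            switch_probability >= 0, switch_probability <= 1,
            golden_budget >= 2, pareto_shape > 0)
  if (any(upper <= lower))
    stop("gfs_config: lower bounds must be strictly below upper bounds")
  structure(list(population_size = population_size, iterations = iterations,
                 step_size = step_size,
                 switch_probability = switch_probability,
                 lower = lower, upper = upper, pareto_shape = pareto_shape,
                 tan_clip = tan_clip, golden_budget = golden_budget,
                 golden_coefficient = golden_coefficient,
                 seed = as.integer(seed)),
            class = "gfs_config")
}

clip_box <- function(x, L, U) pmin(U, pmax(L, x))

# Pareto(shape, scale = 1) draws by inverse-transform sampling.
rpareto <- function(n, shape) stats::runif(n)^(-1 / shape)

#' Initialize the pollen population
#'
#' Each solution is dissipated uniformly across the search box:
#' \code{L + (U - L) * rand}.
#'
#' @param f objective (minimized).
#' @param dim problem dimension.
#' @param config a \code{\link{gfs_config}}; the caller controls the RNG.
#' @return list with \code{population} (matrix, rows = pollens),
#'   \code{fitness}, \code{best}, \code{best_fitness}.
#' @export
init_population <- function(f, dim, config) {
  L <- rep_len(config$lower, dim); U <- rep_len(config$upper, dim)
  P <- matrix(stats::runif(config$population_size * dim),
              config$population_size, dim)
  P <- sweep(sweep(P, 2, U - L, "*"), 2, L, "+")
  fit <- apply(P, 1, f)
  if (any(!is.finite(fit)))
    stop("non-finite objective at initial point ",
         paste(round(P[which(!is.finite(fit))[1], ], 4), collapse = ", "))
  b <- which.min(fit)
  list(population = P, fitness = fit, best = P[b, ], best_fitness = fit[b])
}

#' Pareto-step flight
#'
#' \code{G' = G + s * S * (G - best)} with \code{S} a componentwise
#' Pareto(shape, scale 1) draw, clipped to the box.
#'
#' @param G current solution.
#' @param best global best solution.
#' @param config a \code{\link{gfs_config}}.
#' @return moved solution.
#' @export
pareto_flight <- function(G, best, config) {
  if (length(G) != length(best)) stop("shape mismatch")
  L <- rep_len(config$lower, length(G)); U <- rep_len(config$upper, length(G))
  S <- rpareto(length(G), config$pareto_shape)
  clip_box(G + config$step_size * S * (G - best), L, U)
}

#' Tangent flight
#'
#' \code{G' = G + s * tan(theta) * (G - best)}, \code{theta} uniform on
#' \code{(-pi/2, pi/2)} per component so the tangent alternates between
#' minus and plus infinity, \code{|tan(theta)|} capped at \code{tan_clip};
#' heavy-tailed like a Levy flight, with negative draws carrying the pollen
#' toward and past the current best. \code{step} lets the caller
#' substitute an effective (e.g. Pareto-drawn) step magnitude.
#'
#' @param G current solution.
#' @param best global best solution.
#' @param config a \code{\link{gfs_config}}.
#' @param step effective step size; defaults to \code{config$step_size}.
#' @param theta optional fixed angle (for deterministic checks).
#' @return moved solution.
#' @export
tangent_flight <- function(G, best, config, step = NULL, theta = NULL) {
  if (length(G) != length(best)) stop("shape mismatch")
  L <- rep_len(config$lower, length(G)); U <- rep_len(config$upper, length(G))
  s <- step %||% config$step_size
  th <- theta %||% stats::runif(length(G), -pi / 2, pi / 2)
  tn <- pmin(config$tan_clip, pmax(-config$tan_clip, tan(th)))
  clip_box(G + s * tn * (G - best), L, U)
}

#' Golden-section line search along a segment
#'
#' Minimizes \code{f(m + t (n - m))} for \code{t} in [0, 1] by the
#' golden-section bracket update: probes at \code{a + 0.618 (b - a)} and
#' \code{b - 0.618 (b - a)}; the bracket shrinks toward the better probe and
#' the surviving probe is reused, so each shrink after the first two costs
#' one evaluation. Runs until \code{budget} evaluations are spent and
#' returns the best probed point.
#'
#' @param f objective on vectors.
#' @param m,n segment endpoints (minor and major).
#' @param budget total objective evaluations (>= 2).
#' @param coefficient probe coefficient, default 0.618.
#' @return list with \code{x} (best point), \code{value}, \code{t}.
#' @export
golden_section_refine <- function(f, m, n, budget, coefficient = 0.618) {
  if (budget < 2) stop("golden_section_refine: budget must be >= 2")
  if (isTRUE(all(m == n))) stop("golden_section_refine: m equals n")
  seg <- function(t) m + t * (n - m)
  a <- 0; b <- 1
  t1 <- a + coefficient * (b - a)   # upper probe
  t2 <- b - coefficient * (b - a)   # lower probe
  f1 <- f(seg(t1)); f2 <- f(seg(t2))
  evals <- 2L
  best_t <- if (f1 <= f2) t1 else t2
  best_f <- min(f1, f2)
  while (evals < budget) {
    if (f2 < f1) {           # minimum bracketed in [a, t1]
      b <- t1
      t1 <- t2; f1 <- f2
      t2 <- b - coefficient * (b - a)
      f2 <- f(seg(t2))
    } else {                 # minimum bracketed in [t2, b]
      a <- t2
      t2 <- t1; f2 <- f1
      t1 <- a + coefficient * (b - a)
      f1 <- f(seg(t1))
    }
    evals <- evals + 1L
    if (f1 < best_f) { best_f <- f1; best_t <- t1 }
    if (f2 < best_f) { best_f <- f2; best_t <- t2 }
  }
  list(x = seg(best_t), value = best_f, t = best_t)
}

#' Golden flower search over a box
#'
#' Per iteration, each pollen takes a global move with the switching
#' probability — a tangent flight whose effective step is the step size
#' times a Pareto draw — and otherwise a local golden-section refinement
#' along the segment to a uniformly chosen other pollen. Moves are kept only
#' if they improve the pollen's fitness (greedy acceptance).
#'
#' @param f objective to minimize; must be finite on the box.
#' @param dim problem dimension.
#' @param config a \code{\link{gfs_config}}.
#' @return list with \code{best}, \code{best_fitness}, \code{history}
#'   (best-so-far per iteration, non-increasing), \code{evaluations}.
#' @export
gfs_optimize <- function(f, dim, config = gfs_config()) {
  n_eval <- 0L
  fe <- function(x) {
    v <- f(x)
    if (!is.finite(v))
      stop("non-finite objective value at ",
           paste(round(x, 6), collapse = ", "))
    n_eval <<- n_eval + 1L
    v
  }
  with_seed(config$seed, {
    st <- init_population(fe, dim, config)
    P <- st$population; fit <- st$fitness
    best <- st$best; best_f <- st$best_fitness
    history <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      for (i in seq_len(config$population_size)) {
        if (stats::runif(1) < config$switch_probability) {
          step <- config$step_size * rpareto(1, config$pareto_shape)
          cand <- tangent_flight(P[i, ], best, config, step = step)
          cf <- fe(cand)
        } else {
          j <- sample(setdiff(seq_len(config$population_size), i), 1)
          if (all(P[i, ] == P[j, ])) next
          r <- golden_section_refine(fe, P[i, ], P[j, ],
                                     config$golden_budget,
                                     config$golden_coefficient)
          cand <- r$x; cf <- r$value
        }
        if (cf < fit[i]) { P[i, ] <- cand; fit[i] <- cf }
        if (cf < best_f) { best <- cand; best_f <- cf }
      }
      history[it] <- best_f
    }
    list(best = best, best_fitness = best_f, history = history,
         evaluations = n_eval)
  })
}

# Deterministic ridge linear classifier used by the feature-selection
# wrapper: closed-form ridge regression on 0/1 labels with an intercept,
# thresholded at 0.5. Per-fold cross-products are precomputed once so each
# candidate subset costs one small linear solve.
make_subset_scorer <- function(X, y, cv_folds, seed, lambda = 1e-2) {
  n <- nrow(X); d <- ncol(X)
  fold <- with_seed(seed, stratified_folds(y, cv_folds))
  Xa <- cbind(1, X)
  pre <- lapply(seq_len(cv_folds), function(k) {
    tr <- fold != k
    list(XtX = crossprod(Xa[tr, , drop = FALSE]),
         Xty = crossprod(Xa[tr, , drop = FALSE], y[tr]),
         test = which(!tr))
  })
  majority <- max(mean(y), 1 - mean(y))
  function(cols) {
    if (!length(cols)) return(majority)
    sel <- c(1L, cols + 1L)
    correct <- 0L
    for (k in seq_len(cv_folds)) {
      A <- pre[[k]]$XtX[sel, sel, drop = FALSE]
      diag(A)[-1] <- diag(A)[-1] + lambda
      beta <- tryCatch(solve(A, pre[[k]]$Xty[sel, ]),
                       error = function(e) NULL)
      te <- pre[[k]]$test
      pred <- if (is.null(beta)) rep(as.integer(mean(y) >= 0.5), length(te))
        else as.integer(Xa[te, sel, drop = FALSE] %*% beta >= 0.5)
      correct <- correct + sum(pred == y[te])
    }
    correct / n
  }
}

#' Wrapper feature selection by golden flower search
#'
#' Pollens live in \code{[0,1]^d}; coordinates above 0.5 select the
#' corresponding feature (an empty selection falls back to the single
#' largest coordinate). Subset fitness is
#' \code{w_a * cv_accuracy + (1 - w_a) * (1 - |S| / d)}, where the accuracy
#' is stratified k-fold cross-validation of a deterministic ridge linear
#' classifier on the selected columns; the search maximizes it by minimizing
#' its negation. Fitness values are cached per subset. When \code{groups}
#' is supplied (a list of encoded-column index vectors, one per source
#' feature), selection operates on source features and a selected feature
#' contributes all of its derived columns.
#'
#' @param X encoded feature matrix.
#' @param y 0/1 labels.
#' @param config a \code{\link{gfs_config}}; bounds are forced to [0,1].
#' @param accuracy_weight trade-off weight \code{w_a} in (0, 1].
#' @param cv_folds cross-validation folds.
#' @param groups optional list of column-index vectors per selectable
#'   feature.
#' @return list with \code{mask} (logical over selectable features),
#'   \code{selected} (names if available), \code{fitness},
#'   \code{cv_accuracy}, \code{history}.
#' @export
select_features <- function(X, y, config = gfs_config(), accuracy_weight = 0.9,
                            cv_folds = 5, groups = NULL) {
  stopifnot(accuracy_weight > 0, accuracy_weight <= 1)
  if (is.null(groups)) {
    groups <- as.list(seq_len(ncol(X)))
    names(groups) <- colnames(X)
  }
  d <- length(groups)
  scorer <- make_subset_scorer(X, y, cv_folds,
                               seed = derive_seed(config$seed, "cv_folds"))
  cache <- new.env(parent = emptyenv())
  mask_of <- function(pos) {
    sel <- pos > 0.5
    if (!any(sel)) sel[which.max(pos)] <- TRUE
    sel
  }
  objective <- function(pos) {
    sel <- mask_of(pos)
    key <- paste(which(sel), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    cols <- sort(unlist(groups[sel], use.names = FALSE))
    acc <- scorer(cols)
    fitv <- accuracy_weight * acc + (1 - accuracy_weight) * (1 - sum(sel) / d)
    cache[[key]] <- -fitv
    -fitv
  }
  cfg <- config
  cfg$lower <- 0; cfg$upper <- 1
  res <- gfs_optimize(objective, d, cfg)
  mask <- mask_of(res$best)
  cols <- sort(unlist(groups[mask], use.names = FALSE))
  list(mask = mask,
       selected = if (!is.null(names(groups))) names(groups)[mask]
                  else which(mask),
       fitness = -res$best_fitness,
       cv_accuracy = scorer(cols),
       history = -res$history)
}
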