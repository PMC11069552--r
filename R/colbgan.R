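#' Configure the collaborative bias-integrated GAN
#'
#' Three cooperating networks over encoded records in \code{[0,1]^d}: a
#' conditional generator fed by the sum of a noise embedding and a learned
#' per-class label embedding; a discriminator separating real from
#' generated records; and an auxiliary classifier that predicts the disease
#' label. Training alternates two adversarial pairings per batch —
#' generator vs discriminator, and generator vs classifier, the latter
#' weighted by the coupling parameter \code{delta} — so the generator is
#' pushed to produce records that are both realistic and correctly
#' class-conditioned, which is what makes its minority-class samples useful
#' for rebalancing.
#'
#' @param noise_dim noise vector length.
#' @param embed_dim shared embedding width.
#' @param gen_hidden,disc_hidden,clf_hidden hidden layer sizes.
#' @param delta generator-classifier coupling weight (>= 0); tuned by the
#'   water-drop search in the full pipeline.
#' @param epochs adversarial training epochs.
#' @param batch_size minibatch size.
#' @param lr_gen,lr_disc,lr_clf Adam step sizes.
#' @param augment_to_balance if \code{TRUE}, after adversarial training the
#'   classifier head is fine-tuned on the minority-augmented data.
#' @param augment_threshold augmentation is applied only when the minority
#'   fraction is below this value: rebalancing a mildly imbalanced sample
#'   with synthetic rows adds generator noise and biases the class priors
#'   for no benefit, so it is reserved for genuine imbalance.
#' @param classifier_enabled internal switch: \code{FALSE} reduces training
#'   to a plain conditional GAN (no classifier updates, no coupling term).
#' @param seed integer seed.
#' @return a list of class \code{"colbgan_config"}.
#' @export
colbgan_config <- function(noise_dim = 16, embed_dim = 32,
                           gen_hidden = c(64, 64), disc_hidden = c(64, 64),
                           clf_hidden = c(64, 64), delta = 0.1,
                           epochs = 200, batch_size = 128,
                           lr_gen = 2e-4, lr_disc = 2e-4, lr_clf = 1e-3,
                           augment_to_balance = TRUE,
                           augment_threshold = 0.3,
                           classifier_enabled = TRUE, seed = 1L) {
  stopifnot(noise_dim >= 1, embed_dim >= 1, delta >= 0, is.finite(delta),
            epochs >= 1, batch_size >= 1)
  structure(list(noise_dim = noise_dim, embed_dim = embed_dim,
                 gen_hidden = gen_hidden, disc_hidden = disc_hidden,
                 clf_hidden = clf_hidden, delta = delta, epochs = epochs,
                 batch_size = batch_size, lr_gen = lr_gen, lr_disc = lr_disc,
                 lr_clf = lr_clf, augment_to_balance = augment_to_balance,
                 augment_threshold = augment_threshold,
                 classifier_enabled = classifier_enabled,
                 seed = as.integer(seed)),
            class = "colbgan_config")
}

# Initialize all networks from the current RNG stream.
colbgan_init <- function(d, config) {
  structure(list(
    noise_embed = mlp_init(c(config$noise_dim, config$embed_dim)),
    label_embed = matrix(stats::rnorm(2 * config$embed_dim, sd = 0.1),
                         2, config$embed_dim),
    gen = mlp_init(c(config$embed_dim, config$gen_hidden, d)),
    disc = mlp_init(c(d, config$disc_hidden, 1)),
    clf = mlp_init(c(d, config$clf_hidden, 2)),
    d = d, config = config), class = "colbgan")
}

#' Conditional embedding of noise and label
#'
#' \code{alpha_t = embed(noise)}, \code{beta_t = embed(label)} (a learned
#' per-class vector), combined by addition into the contingent feature
#' vector \code{gamma_t = alpha_t + beta_t}.
#'
#' @param noise matrix of noise rows (width \code{noise_dim}) or a vector.
#' @param labels 0/1 class labels, one per row.
#' @param model a \code{"colbgan"} model.
#' @return matrix of embedded condition vectors (width \code{embed_dim}).
#' @export
embed_condition <- function(noise, labels, model) {
  G <- if (is.matrix(noise)) noise else matrix(noise, nrow = 1)
  if (ncol(G) != model$config$noise_dim)
    stop("structural error: noise width ", ncol(G))
  if (!all(labels %in% 0:1)) stop("unknown label: labels must be 0/1")
  alpha_t <- mlp_forward(model$noise_embed, G)$out
  beta_t <- model$label_embed[labels + 1L, , drop = FALSE]
  alpha_t + beta_t
}

#' Generate class-conditioned synthetic encoded records
#'
#' Noise is standard Gaussian; the generator output passes through a
#' sigmoid, so samples live in the encoded-data hypercube \code{[0,1]^d}.
#'
#' @param labels 0/1 labels of the records to generate.
#' @param model a \code{"colbgan"} model.
#' @param seed integer seed.
#' @return matrix of generated rows (width \code{d}).
#' @export
generate_samples <- function(labels, model, seed = 1L) {
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(labels) * model$config$noise_dim),
                    length(labels), model$config$noise_dim)
    gt <- embed_condition(noise, labels, model)
    logistic(mlp_forward(model$gen, gt)$out)
  })
}

#' Empirical discriminator value
#'
#' The inner value of the adversarial min-max: \code{mean(D(real)) +
#' mean(1 - D(fake))}, estimated on the given batches. 0.5-everywhere
#' discriminators score 1; a perfect discriminator scores 2.
#'
#' @param real,fake matrices of encoded rows.
#' @param model a \code{"colbgan"} model.
#' @return scalar in (0, 2).
#' @export
discriminator_value <- function(real, fake, model) {
  if (!nrow(real) || !nrow(fake)) stop("batches must be non-empty")
  dr <- logistic(mlp_forward(model$disc, real)$out)
  df <- logistic(mlp_forward(model$disc, fake)$out)
  mean(dr) + mean(1 - df)
}

#' Generator loss with classifier collaboration
#'
#' \code{CE(D(fake), 1) + delta * CE(classifier(fake), labels)}: the
#' non-saturating adversarial term pushing generated records toward "real",
#' plus the delta-weighted auxiliary classification term that couples the
#' generator to the classifier.
#'
#' @param fake generated rows.
#' @param labels the labels the rows were conditioned on.
#' @param model a \code{"colbgan"} model.
#' @param delta coupling weight.
#' @return scalar loss.
#' @export
generator_loss <- function(fake, labels, model, delta) {
  df <- logistic(mlp_forward(model$disc, fake)$out)
  adv <- bce(df, rep(1, nrow(fake)))
  if (delta == 0) return(adv)
  P <- softmax_rows(mlp_forward(model$clf, fake)$out)
  idx <- cbind(seq_len(nrow(fake)), labels + 1L)
  adv + delta * mean(-log(pmax(P[idx], 1e-12)))
}

#' Train the collaborative GAN classifier
#'
#' Per batch: (i) the discriminator ascends the adversarial value on a real
#' batch and an equal-size generated batch with uniformly drawn (arbitrary)
#' labels; (ii) the classifier descends cross-entropy on the real labelled
#' rows; (iii) the generator descends \code{\link{generator_loss}} on a
#' fresh generated batch. After adversarial training, if
#' \code{augment_to_balance} is set the classifier head is fine-tuned on
#' the minority-augmented data (reduced rate and epochs, starting from the
#' adversarially trained head). The whole procedure is deterministic given
#' the config seed.
#'
#' @param enc an \code{\link{encode_table}} result (both classes present).
#' @param config a \code{\link{colbgan_config}}.
#' @return a \code{"colbgan"} model with a \code{log} data.frame (per-epoch
#'   discriminator value, generator loss, classifier loss, minority samples
#'   generated).
#' @export
train_colbgan <- function(enc, config = colbgan_config()) {
  X <- if (inherits(enc, "encoded_matrix")) enc$X else enc$X
  y <- enc$y
  if (length(unique(y)) < 2) stop("both classes must be present")
  n <- nrow(X); d <- ncol(X)
  minority <- as.integer(names(which.min(table(y))))
  with_seed(config$seed, {
    model <- colbgan_init(d, config)
    st <- list(ne = adam_init(model$noise_embed),
               le = list(list(mW = model$label_embed * 0,
                              vW = model$label_embed * 0,
                              mb = rep(0, 1), vb = rep(0, 1))),
               gen = adam_init(model$gen), disc = adam_init(model$disc),
               clf = adam_init(model$clf))
    t_d <- 0L; t_g <- 0L; t_c <- 0L
    log <- data.frame(epoch = seq_len(config$epochs), disc_value = NA_real_,
                      gen_loss = NA_real_, clf_loss = NA_real_,
                      minority_generated = 0L)
    gen_forward <- function(m) {
      noise <- matrix(stats::rnorm(m * config$noise_dim), m,
                      config$noise_dim)
      labs <- sample(0:1, m, replace = TRUE)   # arbitrary labels
      ec <- mlp_forward(model$noise_embed, noise)
      gt <- ec$out + model$label_embed[labs + 1L, , drop = FALSE]
      gc <- mlp_forward(model$gen, gt)
      fake <- logistic(gc$out)
      list(noise = noise, labs = labs, ec = ec, gc = gc, fake = fake)
    }
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_dv <- 0; ep_gl <- 0; ep_cl <- 0; ep_min <- 0L
      for (idx in batches) {
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
        m <- length(idx)
        ## (i) discriminator step
        gf <- gen_forward(m)
        ep_min <- ep_min + sum(gf$labs == minority)
        dc_r <- mlp_forward(model$disc, Xb)
        dc_f <- mlp_forward(model$disc, gf$fake)
        pr <- logistic(dc_r$out); pf <- logistic(dc_f$out)
        ep_dv <- ep_dv + (mean(pr) + mean(1 - pf))
        # ascend value <=> descend BCE(real->1) + BCE(fake->0)
        br <- mlp_backward(model$disc, dc_r,
                           (pr - 1) / (2 * m))
        bf <- mlp_backward(model$disc, dc_f, pf / (2 * m))
        gsum <- Map(function(a, b) list(W = a$W + b$W, b = a$b + b$b),
                    br$grads, bf$grads)
        t_d <- t_d + 1L
        up <- adam_step(model$disc, gsum, st$disc, config$lr_disc, t_d)
        model$disc <- up$net; st$disc <- up$state
        ## (ii) classifier step on real labelled rows
        if (config$classifier_enabled) {
          cc <- mlp_forward(model$clf, Xb)
          P <- softmax_rows(cc$out)
          Y <- matrix(0, m, 2); Y[cbind(seq_len(m), yb + 1L)] <- 1
          ep_cl <- ep_cl + mean(-log(pmax(P[Y == 1], 1e-12)))
          bc <- mlp_backward(model$clf, cc, (P - Y) / m)
          t_c <- t_c + 1L
          up <- adam_step(model$clf, bc$grads, st$clf, config$lr_clf, t_c)
          model$clf <- up$net; st$clf <- up$state
        }
        ## (iii) generator step
        gf <- gen_forward(m)
        ep_min <- ep_min + sum(gf$labs == minority)
        dc <- mlp_forward(model$disc, gf$fake)
        p <- logistic(dc$out)
        gl <- bce(p, rep(1, m))
        dfake <- mlp_backward(model$disc, dc, (p - 1) / m)$dX
        use_clf <- config$classifier_enabled && config$delta > 0
        if (use_clf) {
          cc <- mlp_forward(model$clf, gf$fake)
          P <- softmax_rows(cc$out)
          Y <- matrix(0, m, 2); Y[cbind(seq_len(m), gf$labs + 1L)] <- 1
          gl <- gl + config$delta * mean(-log(pmax(P[Y == 1], 1e-12)))
          dfake <- dfake +
            config$delta * mlp_backward(model$clf, cc, (P - Y) / m)$dX
        }
        if (!is.finite(gl))
          stop("training aborted: non-finite generator loss at epoch ", ep)
        ep_gl <- ep_gl + gl
        dZg <- dfake * gf$fake * (1 - gf$fake)
        bg <- mlp_backward(model$gen, gf$gc, dZg)
        dGt <- bg$dX
        be <- mlp_backward(model$noise_embed, gf$ec, dGt)
        gle <- matrix(0, 2, config$embed_dim)
        for (cl in 0:1) {
          rows <- gf$labs == cl
          if (any(rows))
            gle[cl + 1L, ] <- colSums(dGt[rows, , drop = FALSE])
        }
        t_g <- t_g + 1L
        up <- adam_step(model$gen, bg$grads, st$gen, config$lr_gen, t_g)
        model$gen <- up$net; st$gen <- up$state
        up <- adam_step(model$noise_embed, be$grads, st$ne, config$lr_gen, t_g)
        model$noise_embed <- up$net; st$ne <- up$state
        # label-embedding Adam update (single parameter block)
        s <- st$le[[1]]
        s$mW <- 0.9 * s$mW + 0.1 * gle
        s$vW <- 0.999 * s$vW + 0.001 * gle^2
        model$label_embed <- model$label_embed -
          config$lr_gen * (s$mW / (1 - 0.9^t_g)) /
            (sqrt(s$vW / (1 - 0.999^t_g)) + 1e-8)
        st$le[[1]] <- s
      }
      nb <- length(batches)
      log$disc_value[ep] <- ep_dv / nb
      log$gen_loss[ep] <- ep_gl / nb
      log$clf_loss[ep] <- if (config$classifier_enabled) ep_cl / nb else NA
      log$minority_generated[ep] <- ep_min
    }
    model$log <- log
    model$minority <- minority
    minority_frac <- min(table(y)) / n
    if (config$augment_to_balance && config$classifier_enabled &&
        minority_frac < (config$augment_threshold %||% 1)) {
      # fine-tune (not refit) the head on the balanced data: the
      # adversarially trained head keeps what it learned from real rows,
      # and the balanced pass corrects the majority-class bias
      aug <- augment_minority(list(X = X, y = y), model,
                              seed = derive_seed(config$seed, "augment"))
      model$clf <- train_mlp_classifier(
        aug$X, aug$y, config$clf_hidden, config$lr_clf / 4,
        epochs = max(10L, round(config$epochs / 4)),
        batch_size = config$batch_size,
        seed = derive_seed(config$seed, "head_refit"), init = model$clf)
      model$augmented_rows <- sum(aug$synthetic)
    }
    model
  })
}

# Plain softmax MLP classifier (used to refit the head on augmented data and
# as the separable-data reference).
train_mlp_classifier <- function(X, y, hidden, lr, epochs, batch_size, seed,
                                 init = NULL) {
  n <- nrow(X)
  with_seed(seed, {
    net <- init %||% mlp_init(c(ncol(X), hidden, 2))
    state <- adam_init(net)
    t <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      for (idx in split(ord, ceiling(seq_along(ord) / batch_size))) {
        m <- length(idx)
        cc <- mlp_forward(net, X[idx, , drop = FALSE])
        P <- softmax_rows(cc$out)
        Y <- matrix(0, m, 2); Y[cbind(seq_len(m), y[idx] + 1L)] <- 1
        bc <- mlp_backward(net, cc, (P - Y) / m)
        t <- t + 1L
        up <- adam_step(net, bc$grads, state, lr, t)
        net <- up$net; state <- up$state
      }
    }
    net
  })
}

#' @export
print.colbgan <- function(x, ...) {
  cat("ColBGaN model: d =", x$d, "| delta =", x$config$delta,
      "| epochs =", x$config$epochs, "\n")
  if (!is.null(x$log))
    cat("  final disc value:",
        format(utils::tail(x$log$disc_value, 1), digits = 4),
        "| gen loss:", format(utils::tail(x$log$gen_loss, 1), digits = 4),
        "\n")
  if (!is.null(x$augmented_rows))
    cat("  minority rows synthesized for balance:", x$augmented_rows, "\n")
  invisible(x)
}

#' Balance classes by generated minority samples
#'
#' Appends generator samples of the minority class until class counts are
#' equal; real rows are left untouched and appended rows are flagged in the
#' \code{synthetic} vector. A balanced input is returned unchanged.
#'
#' @param data list with \code{X} (encoded rows) and \code{y} (0/1 labels),
#'   e.g. an \code{encoded_matrix}.
#' @param model a trained \code{"colbgan"} model.
#' @param seed integer seed.
#' @return list with \code{X}, \code{y} and logical \code{synthetic}.
#' @export
augment_minority <- function(data, model, seed = 1L) {
  X <- data$X; y <- data$y
  counts <- table(factor(y, levels = 0:1))
  deficit <- abs(counts[["1"]] - counts[["0"]])
  if (deficit == 0)
    return(list(X = X, y = y, synthetic = rep(FALSE, length(y))))
  minority <- if (counts[["1"]] < counts[["0"]]) 1L else 0L
  fake <- generate_samples(rep(minority, deficit), model, seed = seed)
  colnames(fake) <- colnames(X)
  list(X = rbind(X, fake), y = c(y, rep(minority, deficit)),
       synthetic = c(rep(FALSE, length(y)), rep(TRUE, deficit)))
}

#' Predict disease labels with the classifier head
#'
#' @param object a trained \code{"colbgan"} model.
#' @param newdata matrix of encoded rows or an \code{encoded_matrix}.
#' @param ... unused.
#' @return list with \code{labels} (0/1 arg-max) and \code{probabilities}
#'   (rows sum to 1).
#' @export
predict.colbgan <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "encoded_matrix")) newdata$X else newdata
  if (ncol(X) != object$d)
    stop("structural error: row width ", ncol(X),
         " does not match model (", object$d, ")")
  P <- softmax_rows(mlp_forward(object$clf, X)$out)
  list(labels = max.col(P, "first") - 1L, probabilities = P)
}
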