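#' Configure the deep auto-encoder imputer
#'
#' A single encoder/decoder pair: the encoder maps an encoded record through
#' a logistic-sigmoid hidden layer, and the decoder maps the hidden
#' representation back to the input space with identity outputs on
#' continuous coordinates (no nonlinear squashing, matching their Gaussian
#' treatment) and sigmoid outputs on binary/one-hot coordinates. Training
#' minimizes the reconstruction loss over observed cells only — squared
#' error on continuous coordinates, cross-entropy on discrete ones — and
#' periodically re-feeds the current reconstruction into the missing inputs.
#'
#' @param hidden_dim hidden layer width; default \code{ceiling(d_in / 2)}.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size minibatch size.
#' @param refeed_rounds how many times missing inputs are overwritten by the
#'   current reconstruction during training (>= 1).
#' @param weight_decay L2 penalty on the weights; regularizes away
#'   reconstruction pathways that do not generalize to mean-filled inputs.
#' @param val_fraction fraction of observed cells hidden from training and
#'   used to select the best epoch.
#' @param seed integer seed.
#' @return a list of class \code{"daem_config"}.
#' @export
daem_config <- function(hidden_dim = NULL, epochs = 1000, learning_rate = 1e-2,
                        batch_size = 1024, refeed_rounds = 3,
                        weight_decay = 1e-3, val_fraction = 0.2, seed = 1L) {
  stopifnot(is.null(hidden_dim) || hidden_dim >= 1, refeed_rounds >= 1,
            epochs >= 1, batch_size >= 1, learning_rate > 0, weight_decay >= 0,
            val_fraction >= 0, val_fraction < 0.5)
  structure(list(hidden_dim = hidden_dim, epochs = epochs,
                 learning_rate = learning_rate, batch_size = batch_size,
                 refeed_rounds = refeed_rounds, weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "daem_config")
}

#' Encoder map of the auto-encoder
#'
#' \code{b = sigma(omega^T a + beta)}, componentwise logistic sigmoid.
#'
#' @param a input vector (length \code{d_in}) or matrix of row vectors.
#' @param params a \code{daem_params} list with \code{omega} (d_in x
#'   d_hidden), \code{beta}, \code{omega_prime} (d_hidden x d_in),
#'   \code{beta_prime}, \code{cont_idx}.
#' @return hidden representation in (0,1)^d_hidden.
#' @export
daem_encode <- function(a, params) {
  A <- if (is.matrix(a)) a else matrix(a, nrow = 1)
  if (ncol(A) != nrow(params$omega))
    stop("structural error: input width ", ncol(A),
         " does not match encoder weights (", nrow(params$omega), ")")
  B <- logistic(sweep(A %*% params$omega, 2, params$beta, "+"))
  if (is.matrix(a)) B else as.vector(B)
}

#' Decoder map of the auto-encoder
#'
#' Pre-activation \code{z = omega'^T b + beta'}; identity on continuous
#' coordinates, logistic sigmoid on discrete coordinates.
#'
#' @param b hidden vector (length \code{d_hidden}) or matrix of row vectors.
#' @param params see \code{\link{daem_encode}}.
#' @return reconstruction of length \code{d_in}.
#' @export
daem_decode <- function(b, params) {
  B <- if (is.matrix(b)) b else matrix(b, nrow = 1)
  if (ncol(B) != nrow(params$omega_prime))
    stop("structural error: hidden width ", ncol(B),
         " does not match decoder weights (", nrow(params$omega_prime), ")")
  Z <- sweep(B %*% params$omega_prime, 2, params$beta_prime, "+")
  disc <- !params$cont_idx
  if (any(disc)) Z[, disc] <- logistic(Z[, disc])
  if (is.matrix(b)) Z else as.vector(Z)
}

#' Masked reconstruction loss
#'
#' Mean over observed (unmasked) cells of squared error on continuous
#' coordinates and binary cross-entropy on discrete coordinates. Fully
#' masked rows contribute nothing.
#'
#' @param X input matrix (encoded rows).
#' @param recon reconstruction (post-activation), same shape.
#' @param mask logical matrix, \code{TRUE} = missing (excluded).
#' @param cont_idx logical vector marking continuous columns.
#' @return scalar loss.
#' @export
masked_reconstruction_loss <- function(X, recon, mask, cont_idx) {
  if (!all(dim(X) == dim(recon))) stop("structural error: shape mismatch")
  obs <- !mask
  n_obs <- sum(obs)
  if (n_obs == 0) stop("batch has zero observed cells")
  eps <- 1e-12
  cont <- matrix(cont_idx, nrow(X), ncol(X), byrow = TRUE)
  se <- (X - recon)^2
  p <- pmin(1 - eps, pmax(eps, recon))
  ce <- -(X * log(p) + (1 - X) * log(1 - p))
  cell <- ifelse(cont, se, ce)
  sum(cell[obs]) / n_obs
}

#' Train the auto-encoder imputer
#'
#' Missing cells are initialized to observed column means; Adam minimizes
#' the masked reconstruction loss; at each re-feed boundary the missing
#' inputs are overwritten by the current reconstruction. A fixed random
#' fraction of observed cells is held out as validation: they are treated
#' as missing during training (mean-filled inputs, excluded from the loss)
#' and the reconstruction error on them — a direct estimate of imputation
#' error — is logged per epoch; the returned parameters are those of the
#' epoch with the lowest validation loss, which stops the model before it
#' starts reconstructing sample noise.
#'
#' @param enc an \code{\link{encode_table}} result.
#' @param config a \code{\link{daem_config}}.
#' @return an object of class \code{"daem"} with elements \code{params},
#'   \code{history} (per-epoch train/validation loss), \code{map},
#'   \code{col_means}, \code{config}.
#' @export
train_daem <- function(enc, config = daem_config()) {
  stopifnot(inherits(enc, "encoded_matrix"), inherits(config, "daem_config"))
  X0 <- enc$X; M <- enc$mask
  n <- nrow(X0); d <- ncol(X0)
  if (any(colSums(!M) == 0))
    stop("every column needs at least one observed cell")
  cont_idx <- continuous_cols(enc)
  h <- config$hidden_dim %||% ceiling(d / 2)
  col_means <- vapply(seq_len(d),
                      function(j) mean(X0[!M[, j], j]), numeric(1))
  with_seed(config$seed, {
    # validation holdout: a fraction of observed SOURCE cells is hidden from
    # training entirely (all derived columns of a one-hot group together,
    # exactly like a real missing cell), and the reconstruction error on
    # them estimates imputation error without within-group leakage
    groups <- lapply(enc$map, function(m) m$cols)
    src_obs <- !vapply(groups, function(g) M[, g[1]], logical(nrow(M)))
    obs_src <- which(src_obs)     # (row, source-col) pairs, column-major
    n_val <- if (config$val_fraction > 0)
      max(1L, floor(config$val_fraction * length(obs_src))) else 0L
    val_src <- if (n_val > 0) sort(sample(obs_src, n_val)) else integer(0)
    val_mask_enc <- matrix(FALSE, n, d)
    if (n_val > 0) {
      src_flag <- matrix(FALSE, n, length(groups))
      src_flag[val_src] <- TRUE
      for (k in seq_along(groups))
        val_mask_enc[src_flag[, k], groups[[k]]] <- TRUE
    }
    val_cells <- which(val_mask_enc)
    train_mask <- M | val_mask_enc  # hidden: mean-filled input, no loss
    X <- X0
    for (j in seq_len(d)) {
      fill <- train_mask[, j]
      X[fill, j] <- col_means[j]
    }
    val_mask <- !val_mask_enc
    lim1 <- sqrt(6 / (d + h)); lim2 <- sqrt(6 / (h + d))
    net <- list(layers = list(
      list(W = matrix(stats::runif(d * h, -lim1, lim1), d, h), b = rep(0, h)),
      list(W = matrix(stats::runif(h * d, -lim2, lim2), h, d), b = rep(0, d))))
    state <- adam_init(net)
    step <- 0L
    refeed_every <- max(1L, ceiling(config$epochs / config$refeed_rounds))
    history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                          val_loss = numeric(0))
    params_of <- function(net) list(
      omega = net$layers[[1]]$W, beta = net$layers[[1]]$b,
      omega_prime = net$layers[[2]]$W, beta_prime = net$layers[[2]]$b,
      cont_idx = cont_idx)
    best_val <- Inf; best_net <- net; best_epoch <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      ep_loss <- 0; ep_obs <- 0
      for (idx in batches) {
        Xb <- X[idx, , drop = FALSE]
        Mb <- train_mask[idx, , drop = FALSE]
        obs <- !Mb
        n_obs <- sum(obs)
        if (n_obs == 0) next
        H <- logistic(sweep(Xb %*% net$layers[[1]]$W, 2,
                            net$layers[[1]]$b, "+"))
        Z <- sweep(H %*% net$layers[[2]]$W, 2, net$layers[[2]]$b, "+")
        C <- Z
        disc <- !cont_idx
        if (any(disc)) C[, disc] <- logistic(Z[, disc])
        loss <- masked_reconstruction_loss(Xb, C, Mb, cont_idx)
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", ep,
               " (lr = ", config$learning_rate, ", hidden = ", h, ")")
        ep_loss <- ep_loss + loss * n_obs; ep_obs <- ep_obs + n_obs
        # gradient at decoder pre-activation over observed cells
        dZ <- matrix(0, nrow(Xb), d)
        contm <- matrix(cont_idx, nrow(Xb), d, byrow = TRUE)
        dZ[contm] <- 2 * (Z[contm] - Xb[contm])
        dZ[!contm] <- C[!contm] - Xb[!contm]
        dZ[!obs] <- 0
        dZ <- dZ / n_obs
        gW2 <- crossprod(H, dZ) + config$weight_decay * net$layers[[2]]$W
        gb2 <- colSums(dZ)
        dH <- dZ %*% t(net$layers[[2]]$W)
        dZ1 <- dH * H * (1 - H)
        gW1 <- crossprod(Xb, dZ1) + config$weight_decay * net$layers[[1]]$W
        gb1 <- colSums(dZ1)
        step <- step + 1L
        up <- adam_step(net, list(list(W = gW1, b = gb1),
                                  list(W = gW2, b = gb2)),
                        state, config$learning_rate, step)
        net <- up$net; state <- up$state
      }
      # validation loss: reconstruction error on the hidden observed cells
      pr <- params_of(net)
      Cfull <- daem_decode(daem_encode(X, pr), pr)
      # selection metric: squared error on the hidden cells (the scale
      # imputations are consumed on), regardless of the training loss mix
      vl <- if (n_val > 0) mean((Cfull[val_cells] - X0[val_cells])^2)
      else NA_real_
      history <- rbind(history, data.frame(
        epoch = ep, train_loss = ep_loss / ep_obs, val_loss = vl))
      if (n_val > 0 && vl < best_val) {
        best_val <- vl; best_net <- net; best_epoch <- ep
      }
      if (ep %% refeed_every == 0 && ep < config$epochs) {
        X[train_mask] <- Cfull[train_mask]  # re-feed hidden inputs
      }
    }
    if (n_val == 0) { best_net <- net; best_epoch <- config$epochs }
    # validation-calibrated shrinkage: per source column, regress the held-
    # out truth on the reconstruction around the column mean and clip the
    # slope to [0,1]. Columns the network cannot predict shrink to their
    # mean; columns it predicts well keep (almost) the full reconstruction.
    best_params <- params_of(best_net)
    column_blend <- rep(1, length(groups))
    names(column_blend) <- names(groups)
    if (n_val > 0) {
      Cbest <- daem_decode(daem_encode(X, best_params), best_params)
      for (k in seq_along(groups)) {
        cells <- val_mask_enc[, groups[[k]], drop = FALSE]
        if (!any(cells)) next
        tr <- X0[, groups[[k]], drop = FALSE][cells]
        mod <- Cbest[, groups[[k]], drop = FALSE][cells]
        cm <- matrix(col_means[groups[[k]]], n, length(groups[[k]]),
                     byrow = TRUE)[cells]
        den <- sum((mod - cm)^2)
        num <- sum((mod - cm) * (tr - cm))
        # slope with a one-standard-error evidence cutoff: columns whose
        # predictive signal is indistinguishable from zero shrink fully
        prod <- (mod - cm) * (tr - cm)
        se <- stats::sd(prod) * sqrt(length(prod))
        column_blend[k] <- if (den < 1e-12 || num <= se) 0
          else min(1, max(0, num / den))
      }
    }
    structure(list(params = best_params, history = history,
                   best_epoch = best_epoch, column_blend = column_blend,
                   map = enc$map, col_means = col_means,
                   cont_idx = cont_idx, config = config, d_in = d,
                   hidden_dim = h),
              class = "daem")
  })
}

#' @export
print.daem <- function(x, ...) {
  cat("Auto-encoder imputer:", x$d_in, "->", x$hidden_dim, "->", x$d_in,
      "\n  final training loss:",
      format(utils::tail(x$history$train_loss, 1), digits = 4),
      "| validation loss:",
      format(utils::tail(x$history$val_loss, 1), digits = 4), "\n")
  invisible(x)
}

#' Fill missing cells of a table with auto-encoder reconstructions
#'
#' Observed cells are never modified. Missing cells are initialized to the
#' training column means, passed through the trained auto-encoder with the
#' same number of re-feed passes as training rounds, and the final
#' reconstruction is decoded back to schema types (inverse min-max scaling,
#' 0.5 threshold for binaries, arg-max for one-hot groups).
#'
#' @param table a \code{\link{clinical_table}}.
#' @param fit a trained \code{\link{train_daem}} object.
#' @return a completed \code{\link{clinical_table}} with an all-false
#'   feature mask.
#' @export
impute <- function(table, fit) {
  stopifnot(inherits(table, "clinical_table"), inherits(fit, "daem"))
  feats <- feature_columns(table$schema)
  if (!any(table$mask[, feats])) return(table)
  enc <- encode_table(table, map = fit$map)
  comp <- complete_encoded(enc, fit)
  enc$X <- comp$X
  enc$mask[] <- FALSE
  dec <- decode_matrix(enc)
  # copy original observed cells verbatim (hard invariant)
  vals <- dec$values
  for (nm in feats) {
    obs <- !table$mask[, nm]
    vals[[nm]][obs] <- table$values[[nm]][obs]
  }
  vals[[table$schema$label_column]] <-
    table$values[[table$schema$label_column]]
  if (!is.null(table$schema$id_column))
    vals[[table$schema$id_column]] <- table$values[[table$schema$id_column]]
  mask <- matrix(FALSE, nrow(vals), length(table$schema$names),
                 dimnames = list(NULL, table$schema$names))
  if (!is.null(table$schema$id_column))
    mask[, table$schema$id_column] <- table$mask[, table$schema$id_column]
  clinical_table(vals, table$schema, mask)
}

# Soft completion of an encoded matrix: mean-fill, iterate the
# auto-encoder with re-feeding, apply the validation column gate.
complete_encoded <- function(enc, fit) {
  if (ncol(enc$X) != fit$d_in)
    stop("structural error: encoded width ", ncol(enc$X),
         " does not match trained model (", fit$d_in, ")")
  X <- enc$X; M <- enc$mask
  for (j in seq_len(ncol(X))) X[M[, j], j] <- fit$col_means[j]
  for (r in seq_len(fit$config$refeed_rounds)) {
    C <- daem_decode(daem_encode(X, fit$params), fit$params)
    X[M] <- C[M]
  }
  blend <- fit$column_blend
  if (!is.null(blend)) {
    groups <- lapply(fit$map, function(m) m$cols)
    for (k in seq_along(groups)) for (j in groups[[k]]) {
      mj <- M[, j]
      X[mj, j] <- fit$col_means[j] + blend[k] * (X[mj, j] - fit$col_means[j])
    }
  }
  list(X = X, mask = M)
}

#' Column-mean / mode baseline imputation
#'
#' The reference imputer: numeric cells get the observed column mean, binary
#' and categorical cells the observed mode.
#'
#' @param table a \code{\link{clinical_table}}.
#' @return a completed \code{\link{clinical_table}}.
#' @export
impute_column_mean <- function(table) {
  feats <- feature_columns(table$schema)
  vals <- table$values
  for (nm in feats) {
    miss <- table$mask[, nm]
    if (!any(miss)) next
    obs <- vals[[nm]][!miss]
    fill <- if (table$schema$kinds[[nm]] == "numeric") mean(obs)
      else names(sort(table(obs), decreasing = TRUE))[1]
    vals[[nm]][miss] <- fill
  }
  mask <- matrix(FALSE, nrow(vals), length(table$schema$names),
                 dimnames = list(NULL, table$schema$names))
  if (!is.null(table$schema$id_column))
    mask[, table$schema$id_column] <- table$mask[, table$schema$id_column]
  clinical_table(vals, table$schema, mask)
}
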