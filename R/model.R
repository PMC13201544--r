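# The contrastive autoencoder: four two-layer perceptrons (image encoder g1
# and decoder f1, expression encoder g2 and decoder f2 ending in softplus),
# trained jointly on a weighted sum of two reconstruction losses, an InfoNCE
# alignment loss on aggregated latents, and a cross-modal translation loss.
# Backpropagation is hand-derived and checked numerically in the tests.

#' Training configuration
#'
#' @param K contrastive batch size; each optimization step draws `K / 2`
#'   spots forming `K / 2` positive pairs (defaults: 64 for Visium, 640 for
#'   VisiumHD).
#' @param tau InfoNCE temperature (default 0.03).
#' @param weights loss weights `(image, expr, infonce, cross)`, default all 1.
#' @param epochs,lr Adam epochs and learning rate.
#' @param seed seed for the split, batching and initialization.
#' @param train_fraction fraction of spots used for training; the rest are
#'   held out for model selection on the cross-modal loss.
#' @param h latent dimension.
#' @param expr_loss `"cosine"` (default) or `"mse"` for the expression
#'   autoencoder reconstruction term.
#' @param infonce_exclude_positive keep the positive pair out of the InfoNCE
#'   denominator (default `TRUE`).
#' @return A `train_config` list.
#' @export
train_config <- function(K = 64L, tau = 0.03, weights = c(1, 1, 1, 1),
                         epochs = 500L, lr = 1e-3, seed = 1L,
                         train_fraction = 0.8, h = 128L,
                         expr_loss = c("cosine", "mse"),
                         infonce_exclude_positive = TRUE) {
  stopifnot(tau > 0, K %% 2L == 0L, all(weights >= 0), length(weights) == 4L,
            train_fraction > 0, train_fraction <= 1)
  list(K = as.integer(K), tau = tau, weights = weights,
       epochs = as.integer(epochs), lr = lr, seed = as.integer(seed),
       train_fraction = train_fraction, h = as.integer(h),
       expr_loss = match.arg(expr_loss),
       infonce_exclude_positive = isTRUE(infonce_exclude_positive))
}

# ---- parameter container -------------------------------------------------

init_params <- function(C, p, h) {
  glorot <- function(n_in, n_out)
    matrix(stats::runif(n_in * n_out, -1, 1) * sqrt(6 / (n_in + n_out)),
           n_in, n_out)
  hw <- 2L * h
  layer <- function(prefix, n_in, n_hid, n_out) {
    out <- list(glorot(n_in, n_hid), numeric(n_hid),
                glorot(n_hid, n_out), numeric(n_out))
    names(out) <- paste0(prefix, c(".W1", ".b1", ".W2", ".b2"))
    out
  }
  c(layer("g1", C, hw, h), layer("f1", h, hw, C),
    layer("g2", p, hw, h), layer("f2", h, hw, p))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

mlp_forward <- function(params, prefix, X, out_act = "linear") {
  W1 <- params[[paste0(prefix, ".W1")]]; b1 <- params[[paste0(prefix, ".b1")]]
  W2 <- params[[paste0(prefix, ".W2")]]; b2 <- params[[paste0(prefix, ".b2")]]
  H1 <- tanh(sweep(X %*% W1, 2L, b1, `+`))
  pre <- sweep(H1 %*% W2, 2L, b2, `+`)
  out <- if (out_act == "softplus") softplus(pre) else pre
  list(out = out, H1 = H1, pre = pre, X = X, prefix = prefix,
       out_act = out_act)
}

mlp_backward <- function(params, fw, dOut, grads) {
  p <- fw$prefix
  dPre <- if (fw$out_act == "softplus") dOut * stats::plogis(fw$pre) else dOut
  grads[[paste0(p, ".W2")]] <- grads[[paste0(p, ".W2")]] + crossprod(fw$H1, dPre)
  grads[[paste0(p, ".b2")]] <- grads[[paste0(p, ".b2")]] + colSums(dPre)
  dH1 <- tcrossprod(dPre, params[[paste0(p, ".W2")]]) * (1 - fw$H1^2)
  grads[[paste0(p, ".W1")]] <- grads[[paste0(p, ".W1")]] + crossprod(fw$X, dH1)
  grads[[paste0(p, ".b1")]] <- grads[[paste0(p, ".b1")]] + colSums(dH1)
  list(grads = grads, dX = tcrossprod(dH1, params[[paste0(p, ".W1")]]))
}

zero_like <- function(params) lapply(params, function(x) x * 0)

# ---- joint loss + gradients ---------------------------------------------

# X: [B*l x C] tile features of the batch, parent: spot of each tile row
# (values 1..B in the batch's local indexing), Y: [B x p].
finest_loss_grads <- function(params, X, Y, parent, config, want_grad = TRUE) {
  w <- config$weights
  grads <- if (want_grad) zero_like(params) else NULL

  fw_g1 <- mlp_forward(params, "g1", X)
  fw_f1 <- mlp_forward(params, "f1", fw_g1$out)
  img <- cosim_loss_grad(X, fw_f1$out, want_grad)

  fw_g2 <- mlp_forward(params, "g2", Y)
  fw_f2e <- mlp_forward(params, "f2", fw_g2$out, out_act = "softplus")
  expr <- if (config$expr_loss == "mse") mse_loss_grad(Y, fw_f2e$out, want_grad)
          else cosim_loss_grad(Y, fw_f2e$out, want_grad)

  U <- rowsum(fw_g1$out, group = parent, reorder = TRUE)
  nce <- infonce_loss_grad(U, fw_g2$out, config$tau,
                           config$infonce_exclude_positive,
                           want_grad = want_grad && w[3] > 0)

  fw_f2c <- mlp_forward(params, "f2", fw_g1$out, out_act = "softplus")
  P <- rowsum(fw_f2c$out, group = parent, reorder = TRUE)
  crs <- cosim_loss_grad(Y, P, want_grad)

  losses <- c(loss_image = img$loss, loss_expr = expr$loss,
              loss_infonce = nce$loss, loss_cross = crs$loss)
  total <- sum(w * losses)
  if (!want_grad)
    return(list(losses = c(losses, loss_total = total)))

  # image decoder path
  bk <- mlp_backward(params, fw_f1, w[1] * img$dB, grads)
  grads <- bk$grads; dZ <- bk$dX
  # cross path: gradient on per-spot aggregate broadcasts to member tiles
  dPred <- (w[4] * crs$dB)[parent, , drop = FALSE]
  bk <- mlp_backward(params, fw_f2c, dPred, grads)
  grads <- bk$grads; dZ <- dZ + bk$dX
  # InfoNCE path through the tile-sum aggregate
  if (w[3] > 0) dZ <- dZ + (w[3] * nce$dU)[parent, , drop = FALSE]
  bk <- mlp_backward(params, fw_g1, dZ, grads)
  grads <- bk$grads
  # expression autoencoder + InfoNCE path into g2
  bk <- mlp_backward(params, fw_f2e, w[2] * expr$dB, grads)
  grads <- bk$grads; dT <- bk$dX
  if (w[3] > 0) dT <- dT + w[3] * nce$dT
  bk <- mlp_backward(params, fw_g2, dT, grads)
  list(losses = c(losses, loss_total = total), grads = bk$grads)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- training ------------------------------------------------------------

#' Train the contrastive autoencoder
#'
#' Spots are split train/held-out by a seeded shuffle; each optimization
#' step draws `K / 2` training spots, pairing each spot's aggregated tile
#' latent with its expression latent (positives) against all cross pairs
#' (negatives). The model with the best held-out cross-modal loss is
#' returned together with a per-epoch loss log.
#'
#' @param bundle a `slide_bundle` whose counts are the training targets.
#' @param features `[n_tiles x C]` matrix from [extract_features()] covering
#'   all geometric tiles of probed spots.
#' @param tiles the `tile_set` the features were computed on.
#' @param config a [train_config()].
#' @return A `finest_model`: trained parameter set, dimensions, config, the
#'   training log (`$log`, one `LossBreakdown` row per epoch and split) and
#'   `$best_epoch`.
#' @export
train_finest <- function(bundle, features, tiles, config = train_config()) {
  df <- tiles$tiles[tiles$tiles$parent > 0, , drop = FALSE]
  ord <- order(df$parent, df$tile_id)
  df <- df[ord, , drop = FALSE]
  X <- features[ord, , drop = FALSE]
  parent <- df$parent
  l <- unique(table(parent))
  if (length(l) != 1L)
    stop("features must cover every probed-spot tile (ragged groups found)")
  Y <- bundle$counts
  n <- nrow(Y)
  stopifnot(max(parent) <= n)
  C <- ncol(X); p <- ncol(Y); h <- config$h

  set.seed(config$seed)
  perm <- sample.int(n)
  n_train <- max(2L, floor(config$train_fraction * n))
  train_spots <- sort(perm[seq_len(n_train)])
  test_spots <- sort(setdiff(perm, train_spots))

  B <- config$K %/% 2L
  if (B > n_train) {
    warning("fewer training spots (", n_train, ") than K/2 = ", B,
            "; batch size clipped")
    B <- n_train
  }

  params <- init_params(C, p, h)
  state <- list(m = zero_like(params), v = zero_like(params), t = 0L)
  tile_rows_of <- split(seq_along(parent), parent)

  batch_data <- function(spots) {
    rows <- unlist(tile_rows_of[as.character(spots)], use.names = FALSE)
    list(X = X[rows, , drop = FALSE],
         parent = match(parent[rows], spots),
         Y = Y[spots, , drop = FALSE])
  }

  log <- vector("list", config$epochs * 2L)
  best <- list(loss = Inf, params = params, epoch = 0L)
  for (epoch in seq_len(config$epochs)) {
    idx <- sample(train_spots)
    n_batch <- max(1L, floor(length(idx) / B))
    acc <- numeric(5L)
    for (b in seq_len(n_batch)) {
      spots <- idx[((b - 1L) * B + 1L):(b * B)]
      bd <- batch_data(spots)
      lg <- finest_loss_grads(params, bd$X, bd$Y, bd$parent, config)
      up <- adam_step(params, lg$grads, state, config$lr)
      params <- up$params; state <- up$state
      acc <- acc + lg$losses
    }
    acc <- acc / n_batch
    log[[2L * epoch - 1L]] <- data.frame(epoch = epoch, split = "train",
                                         t(acc))
    if (length(test_spots) >= 2L) {
      bd <- batch_data(test_spots)
      hl <- finest_loss_grads(params, bd$X, bd$Y, bd$parent, config,
                              want_grad = FALSE)$losses
      log[[2L * epoch]] <- data.frame(epoch = epoch, split = "heldout", t(hl))
      if (hl[["loss_cross"]] < best$loss)
        best <- list(loss = hl[["loss_cross"]], params = params,
                     epoch = epoch)
    }
  }
  if (!is.finite(best$loss)) best <- list(loss = NA, params = params,
                                          epoch = config$epochs)
  structure(list(params = best$params, C = C, p = p, h = h,
                 gene_names = colnames(Y), config = config,
                 log = do.call(rbind, log[!vapply(log, is.null, logical(1))]),
                 best_epoch = best$epoch,
                 train_spots = train_spots, test_spots = test_spots),
            class = "finest_model")
}

#' @export
print.finest_model <- function(x, ...) {
  cat("finest_model: C =", x$C, "-> h =", x$h, "-> p =", x$p,
      "; best held-out epoch", x$best_epoch, "\n")
  invisible(x)
}

#' Image-based expression inference for tiles
#'
#' Applies `f2(g1(feature))` row-wise; identical for geometric, between-spot
#' and nucleus tiles. The softplus output layer guarantees non-negative
#' predictions.
#'
#' @param model a `finest_model`.
#' @param features `[n_tiles x C]` feature matrix.
#' @return non-negative `[n_tiles x p]` matrix.
#' @export
infer_subspot_expression <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != model$C)
    stop("feature dimension ", ncol(features), " != model C = ", model$C)
  z <- mlp_forward(model$params, "g1", features)$out
  out <- mlp_forward(model$params, "f2", z, out_act = "softplus")$out
  colnames(out) <- model$gene_names
  out
}

#' Spot-level latent projections
#'
#' L2-normalized aggregated image latents and expression latents, the
#' quantities entering the InfoNCE loss; useful for retrieval diagnostics.
#'
#' @inheritParams train_finest
#' @param model a `finest_model`.
#' @return list with matrices `h_image` and `h_expr` (`[n_spots x h]`).
#' @export
project_spots <- function(model, features, tiles, bundle) {
  df <- tiles$tiles[tiles$tiles$parent > 0, , drop = FALSE]
  ord <- order(df$parent, df$tile_id)
  z <- mlp_forward(model$params, "g1", features[ord, , drop = FALSE])$out
  U <- rowsum(z, group = df$parent[ord], reorder = TRUE)
  T_ <- mlp_forward(model$params, "g2", bundle$counts)$out
  list(h_image = l2_normalize_rows(U)$H, h_expr = l2_normalize_rows(T_)$H)
}
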