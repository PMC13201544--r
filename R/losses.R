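# The four training losses. Public functions compute values; the *_grad
# internals also return analytic gradients (verified against numerical
# differentiation in the test suite).

#' Row-plus-column cosine similarity loss
#'
#' `(1/nrow) sum_i (1 - cos(A[i,], B[i,])) + (1/ncol) sum_j (1 - cos(A[,j],
#' B[,j]))`. A row or column with zero norm in either matrix has its cosine
#' defined as 0, i.e. contributes 1 to its term.
#'
#' @param A,B numeric matrices of identical shape.
#' @return non-negative scalar.
#' @export
cosine_row_col_loss <- function(A, B) {
  cosim_loss_grad(A, B, want_grad = FALSE)$loss
}

cosim_loss_grad <- function(A, B, want_grad = TRUE) {
  if (!all(dim(A) == dim(B))) stop("shape mismatch: A is ",
    paste(dim(A), collapse = "x"), ", B is ", paste(dim(B), collapse = "x"))
  n <- nrow(A); p <- ncol(A)
  dB <- if (want_grad) matrix(0, n, p) else NULL
  part <- function(a_sq, b_sq, dot) {
    na <- sqrt(a_sq); nb <- sqrt(b_sq)
    valid <- na > 0 & nb > 0
    cosv <- ifelse(valid, dot / (na * nb), 0)
    list(loss = mean(1 - cosv), valid = valid, na = na, nb = nb, dot = dot)
  }
  r <- part(rowSums(A^2), rowSums(B^2), rowSums(A * B))
  cl <- part(colSums(A^2), colSums(B^2), colSums(A * B))
  loss <- r$loss + cl$loss
  if (want_grad) {
    vr <- r$valid
    if (any(vr)) {
      s1 <- 1 / (r$na[vr] * r$nb[vr])
      s2 <- r$dot[vr] / (r$na[vr] * r$nb[vr]^3)
      dB[vr, ] <- dB[vr, ] - (A[vr, , drop = FALSE] * s1 -
                              B[vr, , drop = FALSE] * s2) / n
    }
    vc <- cl$valid
    if (any(vc)) {
      s1 <- 1 / (cl$na[vc] * cl$nb[vc])
      s2 <- cl$dot[vc] / (cl$na[vc] * cl$nb[vc]^3)
      dB[, vc] <- dB[, vc] - sweep(A[, vc, drop = FALSE], 2L, s1, `*`) / p +
        sweep(B[, vc, drop = FALSE], 2L, s2, `*`) / p
    }
  }
  list(loss = loss, dB = dB)
}

mse_loss_grad <- function(A, B, want_grad = TRUE) {
  d <- B - A
  list(loss = mean(d^2), dB = if (want_grad) 2 * d / length(d) else NULL)
}

#' Contrastive InfoNCE loss over matched projection pairs
#'
#' Row `k` of `H_img` and `H_expr` is a positive pair; every cross pair is
#' negative. Dot products are taken on L2-normalized rows. In the default
#' form the positive term is absent from the denominator,
#' `loss = -sum_k log( exp(s_kk / tau) / sum_{l != k} exp(s_kl / tau) )`,
#' so the value can be negative; `exclude_positive = FALSE` switches to the
#' conventional denominator that includes the positive.
#'
#' @param H_img,H_expr `[K x h]` matrices, `K >= 2`.
#' @param tau positive temperature.
#' @param exclude_positive drop the positive pair from the denominator
#'   (default `TRUE`).
#' @return scalar loss.
#' @export
infonce_loss <- function(H_img, H_expr, tau = 0.03, exclude_positive = TRUE) {
  infonce_loss_grad(H_img, H_expr, tau, exclude_positive,
                    want_grad = FALSE)$loss
}

l2_normalize_rows <- function(X) {
  n <- sqrt(rowSums(X^2))
  n[n == 0] <- 1
  list(H = X / n, norm = n)
}

# Loss + gradients with respect to the *unnormalized* inputs U (image
# aggregate) and T (expression latent); normalization is part of the map.
infonce_loss_grad <- function(U, T_, tau, exclude_positive = TRUE,
                              want_grad = TRUE) {
  K <- nrow(U)
  if (K < 2L) stop("InfoNCE needs at least 2 pairs (empty denominator)")
  if (tau <= 0) stop("temperature must be positive")
  nu <- l2_normalize_rows(U); nt <- l2_normalize_rows(T_)
  H <- nu$H; E <- nt$H
  S <- (H %*% t(E)) / tau
  W <- S
  if (exclude_positive) diag(W) <- -Inf
  mx <- apply(W, 1L, max)
  lse <- mx + log(rowSums(exp(W - mx)))
  loss <- sum(-diag(S) + lse)
  if (!want_grad) return(list(loss = loss))
  P <- exp(W - lse)                       # softmax over the denominator set
  G <- P / tau
  diag(G) <- diag(G) - 1 / tau            # d loss / d S (pre-division by tau
  dH <- G %*% E                           #   already folded into S)
  dE <- t(G) %*% H
  back_norm <- function(dh, H, norm) (dh - rowSums(dh * H) * H) / norm
  list(loss = loss,
       dU = back_norm(dH, H, nu$norm),
       dT = back_norm(dE, E, nt$norm))
}

#' Cross-modal translation loss
#'
#' Per-spot predicted expression is the sum over the spot's tiles of
#' `f2(g1(feature))`; the loss is [cosine_row_col_loss()] between the
#' measured spot expression and that aggregate.
#'
#' @param model a `finest_model`, or a plain function `(features) ->
#'   predictions` (handy for closed-form checks).
#' @param features `[n_tiles x C]` tile feature matrix.
#' @param parent spot index per feature row; every spot must contribute the
#'   same number of tiles.
#' @param Y `[n_spots x p]` measured expression, rows ordered by spot index.
#' @return non-negative scalar.
#' @export
cross_modal_loss <- function(model, features, parent, Y) {
  sizes <- table(parent)
  if (length(unique(sizes)) != 1L)
    stop("ragged tile groups: every spot must have the same number of tiles")
  pred <- if (is.function(model)) model(features)
          else infer_subspot_expression(model, features)
  P <- rowsum(pred, group = parent, reorder = TRUE)
  cosine_row_col_loss(Y, P)
}
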