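# Bivariate global and local Moran's R for ligand-receptor spatial
# co-expression. Significance uses exact first and second moments of the
# statistic under independent random relabeling (permutation) of both
# fields, with a Monte-Carlo permutation fallback; pair selection applies
# Benjamini-Hochberg FDR control across all tested pairs.

#' Gaussian k-nearest-neighbor spatial weights
#'
#' `w_ks = exp(-d_ks^2 / (2 l^2))`, retained for the `cutoff` nearest
#' neighbors of each location, symmetrized by the elementwise maximum, zero
#' diagonal.
#'
#' @param coords `[M x 2]` location coordinates.
#' @param ell kernel lengthscale, or `"auto"` for 1.2 x the median
#'   nearest-neighbor distance.
#' @param cutoff neighbors kept per location before symmetrization
#'   (default 6).
#' @param row_normalize divide each row by its sum (default `FALSE`; note
#'   this breaks symmetry).
#' @return A `spatial_weights` object wrapping a sparse `[M x M]` matrix.
#' @export
build_weights <- function(coords, ell = "auto", cutoff = 6L,
                          row_normalize = FALSE) {
  xy <- as.matrix(coords)
  M <- nrow(xy)
  if (M < 2L) stop("need at least 2 locations")
  if (all(xy[, 1] == xy[1, 1]) && all(xy[, 2] == xy[1, 2]))
    stop("all locations identical; spatial weights undefined")
  nn <- nn_distances(xy)
  if (identical(ell, "auto")) ell <- 1.2 * stats::median(nn[nn > 0])
  stopifnot(is.numeric(ell), ell > 0)
  cutoff <- min(cutoff, M - 1L)
  ii <- integer(0); jj <- integer(0); ww <- numeric(0)
  chunk <- max(1L, floor(4e6 / M))
  for (start in seq(1L, M, by = chunk)) {
    idx <- start:min(start + chunk - 1L, M)
    d2 <- outer(xy[idx, 1], xy[, 1], `-`)^2 + outer(xy[idx, 2], xy[, 2], `-`)^2
    for (r in seq_along(idx)) {
      i <- idx[r]
      di <- d2[r, ]; di[i] <- Inf
      nbr <- order(di, seq_len(M))[seq_len(cutoff)]
      ii <- c(ii, rep(i, cutoff)); jj <- c(jj, nbr)
      ww <- c(ww, exp(-di[nbr] / (2 * ell^2)))
    }
  }
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(M, M))
  Wt <- Matrix::t(W)
  W <- (W + Wt + abs(W - Wt)) / 2    # elementwise max symmetrization
  if (row_normalize) {
    rs <- Matrix::rowSums(W)
    rs[rs == 0] <- 1
    W <- W / rs
  }
  structure(list(W = W, ell = ell, cutoff = cutoff,
                 row_normalized = isTRUE(row_normalize)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat("spatial_weights:", nrow(x$W), "locations, cutoff", x$cutoff,
      ", lengthscale", signif(x$ell, 4), "\n")
  invisible(x)
}

# Exact null moments of the global statistic under independent permutation
# of both (centered, normalized) fields. Derivation: with unit-norm centered
# a, b, E[a'_k a'_k'] = 1/M on the diagonal and -1/(M(M-1)) off it, so
# Var(R) = Sw2/(M-1)^2 - (Sr+Sc)/(M(M-1)^2) + S0^2/(M^2 (M-1)^2).
global_null_var <- function(weights) {
  W <- weights$W
  M <- nrow(W)
  S0 <- sum(W)
  Sw2 <- sum(W@x^2)
  Sr <- sum(Matrix::rowSums(W)^2)
  Sc <- sum(Matrix::colSums(W)^2)
  Sw2 / (M - 1)^2 - (Sr + Sc) / (M * (M - 1)^2) + S0^2 / (M^2 * (M - 1)^2)
}

# Exact per-location null variance of R_local = sender + receiver, both
# terms built from row k of W (zero diagonal assumed).
local_null_var <- function(weights) {
  W <- weights$W
  M <- nrow(W)
  r_k <- Matrix::rowSums(W)
  q_k <- Matrix::rowSums(W^2)
  2 * (q_k - (r_k^2 - q_k) / (M - 1)) + 2 * r_k^2 / (M - 1)^2
}

#' Bivariate global Moran's R
#'
#' `R = sum_ks w_ks (L_k - mean(L)) (R_s - mean(R)) / (||L - mean(L)||
#' ||R - mean(R)||)`. The z-score uses the exact null standard deviation
#' under independent random relabeling of both fields; `p` is the
#' one-sided upper tail.
#'
#' @param L,R numeric vectors on the `M` locations (ligand and receptor).
#' @param weights a [build_weights()] object.
#' @param n_perm if positive, also compute a Monte-Carlo permutation p-value.
#' @param seed seed for the permutation draw.
#' @return list with `R_global`, `z`, `p` (and `p_perm` when requested); a
#'   zero-variance input yields `R_global = NA`, `p = 1` and `skipped =
#'   TRUE`.
#' @export
global_moran_r <- function(L, R, weights, n_perm = 0L, seed = 1L) {
  x <- L - mean(L); y <- R - mean(R)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    return(list(R_global = NA_real_, z = NA_real_, p = 1, skipped = TRUE))
  W <- weights$W
  Rg <- sum(x * as.numeric(W %*% y)) / (nx * ny)
  sd0 <- sqrt(global_null_var(weights))
  z <- Rg / sd0
  out <- list(R_global = Rg, z = z, p = stats::pnorm(z, lower.tail = FALSE),
              skipped = FALSE)
  if (n_perm > 0L) {
    set.seed(seed)
    M <- length(x)
    perm <- replicate(n_perm, {
      xp <- x[sample.int(M)]; yp <- y[sample.int(M)]
      sum(xp * as.numeric(W %*% yp)) / (nx * ny)
    })
    out$p_perm <- (1 + sum(perm >= Rg)) / (n_perm + 1)
    out$sd_perm <- stats::sd(perm)
  }
  out
}

#' Bivariate local Moran's R with sender/receiver decomposition
#'
#' `R_local_k = R_sender_k + R_receiver_k` with
#' `R_sender_k = (L_k - mean(L)) / (s_L s_R) * sum_s w_ks (R_s - mean(R))`
#' and the receiver term with roles swapped; `s` are population standard
#' deviations (divide by `M`), which makes
#' `sum_k R_local_k = 2 M R_global` exact. Per-location one-sided p-values
#' come from exact permutation-null variances.
#'
#' @inheritParams global_moran_r
#' @return list with vectors `R_sender`, `R_receiver`, `R_local`, `p_local`.
#' @export
local_moran_r <- function(L, R, weights) {
  M <- length(L)
  x <- L - mean(L); y <- R - mean(R)
  sx <- sqrt(mean(x^2)); sy <- sqrt(mean(y^2))
  if (sx == 0 || sy == 0)
    return(list(R_sender = rep(NA_real_, M), R_receiver = rep(NA_real_, M),
                R_local = rep(NA_real_, M), p_local = rep(1, M),
                skipped = TRUE))
  W <- weights$W
  sender <- x * as.numeric(W %*% y) / (sx * sy)
  receiver <- y * as.numeric(W %*% x) / (sx * sy)
  loc <- sender + receiver
  v <- local_null_var(weights)
  z <- loc / sqrt(v)
  list(R_sender = sender, R_receiver = receiver, R_local = loc,
       p_local = stats::pnorm(z, lower.tail = FALSE), skipped = FALSE)
}

#' Per-pair ligand and receptor expression vectors
#'
#' Multi-subunit complexes are aggregated over their subunit columns by the
#' arithmetic mean (or the minimum); pairs with any subunit absent from the
#' panel are dropped and reported.
#'
#' @param expr `[M x genes]` expression matrix with gene column names.
#' @param lr_db an `lr_database`.
#' @param agg `"mean"` (default) or `"min"` subunit aggregation.
#' @return list: matrices `L` and `R` (`[M x n_pairs]`), the retained
#'   `pairs` table, and `dropped` (pair labels with missing genes).
#' @export
pair_expression <- function(expr, lr_db, agg = c("mean", "min")) {
  agg <- match.arg(agg)
  genes <- colnames(expr)
  ok <- vapply(seq_len(nrow(lr_db$pairs)), function(i)
    all(lr_db$ligand_subunits[[i]] %in% genes) &&
    all(lr_db$receptor_subunits[[i]] %in% genes), logical(1))
  if (!any(ok)) stop("no LR pair has all subunits on the expression panel")
  dropped <- paste(lr_db$pairs$ligand[!ok], lr_db$pairs$receptor[!ok],
                   sep = ":")
  if (length(dropped))
    message(length(dropped), " LR pair(s) dropped for missing panel genes")
  collapse <- function(subunits) {
    cols <- expr[, subunits, drop = FALSE]
    if (agg == "mean") rowMeans(cols) else do.call(pmin, asplit(cols, 2))
  }
  keep <- which(ok)
  L <- vapply(keep, function(i) collapse(lr_db$ligand_subunits[[i]]),
              numeric(nrow(expr)))
  R <- vapply(keep, function(i) collapse(lr_db$receptor_subunits[[i]]),
              numeric(nrow(expr)))
  pairs <- lr_db$pairs[keep, , drop = FALSE]
  nm <- paste(pairs$ligand, pairs$receptor, sep = ":")
  colnames(L) <- colnames(R) <- nm
  list(L = as.matrix(L), R = as.matrix(R), pairs = pairs, dropped = dropped)
}

#' Ligand-receptor interaction discovery
#'
#' Runs the bivariate global and local Moran's R over every usable LR pair,
#' then applies [select_pairs()].
#'
#' @param expr `[M x genes]` expression on the super-resolved (or spot)
#'   locations.
#' @param coords `[M x 2]` matching coordinates (ignored when `weights`
#'   given).
#' @param lr_db an `lr_database`.
#' @param weights optional precomputed [build_weights()] object.
#' @param fdr,min_interacting,local_p see [select_pairs()].
#' @param agg subunit aggregation, see [pair_expression()].
#' @param ... further arguments to [build_weights()].
#' @return A `moran_result`: `$pairs` table (R_global, z, p, q, selected,
#'   n_interacting, eligible), `$local` matrices (R_local, R_sender,
#'   R_receiver, p_local, X_bin, X_con, all `[M x n_pairs]`), `$M`,
#'   `$weights`.
#' @export
discover_lr <- function(expr, coords = NULL, lr_db, weights = NULL,
                        fdr = 0.05, min_interacting = 3L, local_p = 0.05,
                        agg = "mean", ...) {
  if (is.null(weights)) weights <- build_weights(coords, ...)
  pe <- pair_expression(expr, lr_db, agg)
  W <- weights$W
  M <- nrow(pe$L)
  Lc <- sweep(pe$L, 2L, colMeans(pe$L))
  Rc <- sweep(pe$R, 2L, colMeans(pe$R))
  nL <- sqrt(colSums(Lc^2)); nR <- sqrt(colSums(Rc^2))
  tested <- nL > 0 & nR > 0
  WR <- as.matrix(W %*% Rc)
  WL <- as.matrix(W %*% Lc)
  Rg <- ifelse(tested, colSums(Lc * WR) / (nL * nR), NA_real_)
  sd0 <- sqrt(global_null_var(weights))
  z <- Rg / sd0
  p <- ifelse(tested, stats::pnorm(z, lower.tail = FALSE), 1)
  sL <- nL / sqrt(M); sR <- nR / sqrt(M)
  denom <- ifelse(tested, sL * sR, Inf)
  sender <- sweep(Lc * WR, 2L, denom, `/`)
  receiver <- sweep(Rc * WL, 2L, denom, `/`)
  loc <- sender + receiver
  vloc <- local_null_var(weights)
  p_local <- stats::pnorm(loc / sqrt(vloc), lower.tail = FALSE)
  p_local[, !tested] <- 1
  res <- structure(
    list(pairs = data.frame(pe$pairs,
                            pair = colnames(pe$L),
                            R_global = Rg, z = z, p = p,
                            tested = tested, row.names = NULL),
         local = list(R_sender = sender, R_receiver = receiver,
                      R_local = loc, p_local = p_local),
         dropped = pe$dropped, M = M, weights = weights),
    class = "moran_result")
  select_pairs(res, fdr = fdr, min_interacting = min_interacting,
               local_p = local_p)
}

#' Significance selection and sparse-pair filtering
#'
#' Benjamini-Hochberg step-up across all tested pairs selects `q < fdr`.
#' `X_bin` marks locations with `p_local < local_p`; pairs interacting in
#' fewer than `min_interacting` locations are flagged out of the pattern
#' analysis (kept in the table).
#'
#' @param res a `moran_result` draft.
#' @param fdr FDR level (default 0.05).
#' @param min_interacting minimum interacting locations (default 3).
#' @param local_p per-location p threshold for `X_bin` (default 0.05).
#' @return The completed `moran_result` (adds `q`, `selected`,
#'   `n_interacting`, `eligible`, `X_bin`, `X_con`).
#' @export
select_pairs <- function(res, fdr = 0.05, min_interacting = 3L,
                         local_p = 0.05) {
  stopifnot(inherits(res, "moran_result"))
  pr <- res$pairs
  pr$q <- NA_real_
  pr$q[pr$tested] <- stats::p.adjust(pr$p[pr$tested], method = "BH")
  pr$selected <- !is.na(pr$q) & pr$q < fdr
  X_bin <- (res$local$p_local < local_p) * 1L
  pr$n_interacting <- colSums(X_bin)
  pr$eligible <- pr$selected & pr$n_interacting >= min_interacting
  res$pairs <- pr
  res$local$X_bin <- X_bin
  res$local$X_con <- 1 - res$local$p_local
  res$fdr <- fdr; res$min_interacting <- min_interacting
  res$local_p <- local_p
  res
}

#' @export
print.moran_result <- function(x, ...) {
  cat("moran_result:", nrow(x$pairs), "pairs on", x$M, "locations;",
      sum(x$pairs$selected), "selected,", sum(x$pairs$eligible),
      "eligible for patterns\n")
  invisible(x)
}
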