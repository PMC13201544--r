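# Evaluation protocol: fine-resolution predictions are aggregated back to
# spots, then compared gene-by-gene with Pearson correlation and SSIM on a
# rasterized layout.

#' Aggregate tile-level expression back to spots
#'
#' Sums each spot's member tiles; tiles without a parent spot (parent -1,
#' e.g. between-spot tiles) are excluded and their count reported via a
#' message.
#'
#' @param fine `[n_tiles x genes]` matrix.
#' @param tiles the matching `tile_set`.
#' @return `[n_spots x genes]` matrix, rows ordered by spot index.
#' @export
aggregate_to_spots <- function(fine, tiles) {
  df <- if (inherits(tiles, "tile_set")) tiles$tiles else tiles
  fine <- as.matrix(fine)
  stopifnot(nrow(fine) == nrow(df))
  orphan <- df$parent < 0
  if (any(orphan))
    message(sum(orphan), " orphan tile(s) excluded from aggregation")
  rowsum(fine[!orphan, , drop = FALSE], group = df$parent[!orphan],
         reorder = TRUE)
}

#' Per-gene Pearson correlation
#'
#' @param A,B `[locations x genes]` matrices of identical shape.
#' @return numeric vector; genes with zero variance in either field are
#'   `NA` (missing, not zero).
#' @export
pcc_per_gene <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("shape mismatch")
  if (nrow(A) < 2L) stop("need at least 2 locations")
  vapply(seq_len(ncol(A)), function(j) {
    if (stats::sd(A[, j]) == 0 || stats::sd(B[, j]) == 0) return(NA_real_)
    stats::cor(A[, j], B[, j])
  }, numeric(1))
}

# Rasterize per-location values onto a regular grid inferred from the
# coordinate pitch; colliding locations are averaged, empty cells are 0.
rasterize_field <- function(values, coords, grid_spec = NULL) {
  xy <- as.matrix(coords)
  if (is.null(grid_spec)) {
    pitch_x <- stats::median(diff(sort(unique(round(xy[, 1], 6)))))
    pitch_y <- stats::median(diff(sort(unique(round(xy[, 2], 6)))))
    if (!is.finite(pitch_x) || pitch_x == 0) pitch_x <- 1
    if (!is.finite(pitch_y) || pitch_y == 0) pitch_y <- 1
    grid_spec <- list(x0 = min(xy[, 1]), y0 = min(xy[, 2]),
                      pitch_x = pitch_x, pitch_y = pitch_y)
  }
  ci <- round((xy[, 1] - grid_spec$x0) / grid_spec$pitch_x) + 1L
  ri <- round((xy[, 2] - grid_spec$y0) / grid_spec$pitch_y) + 1L
  img <- matrix(0, max(ri), max(ci))
  cnt <- matrix(0, max(ri), max(ci))
  for (i in seq_along(values)) {
    img[ri[i], ci[i]] <- img[ri[i], ci[i]] + values[i]
    cnt[ri[i], ci[i]] <- cnt[ri[i], ci[i]] + 1
  }
  img[cnt > 0] <- img[cnt > 0] / cnt[cnt > 0]
  attr(img, "grid_spec") <- grid_spec
  img
}

# Uniform-window SSIM between two equal-size images, computed over fully
# contained (valid) windows with sample covariances; matches the standard
# skimage convention for a uniform filter after boundary cropping.
ssim_uniform <- function(x, y, data_range = 1, win = 7L, K1 = 0.01,
                         K2 = 0.03) {
  stopifnot(all(dim(x) == dim(y)))
  win <- min(win, dim(x))
  if (win %% 2L == 0L) win <- win - 1L
  if (win < 1L) return(NA_real_)
  box <- function(img) {
    # valid-mode window sums via integral image
    S <- apply(apply(img, 2L, cumsum), 1L, cumsum)  # transposed cumsums
    S <- t(S)
    S <- rbind(0, cbind(0, S))
    nr <- nrow(img) - win + 1L; nc <- ncol(img) - win + 1L
    S[(1L + win):(nrow(img) + 1L), (1L + win):(ncol(img) + 1L), drop = FALSE] -
      S[1L:nr, (1L + win):(ncol(img) + 1L), drop = FALSE] -
      S[(1L + win):(nrow(img) + 1L), 1L:nc, drop = FALSE] +
      S[1L:nr, 1L:nc, drop = FALSE]
  }
  NP <- win^2
  ux <- box(x) / NP; uy <- box(y) / NP
  cov_norm <- NP / (NP - 1)
  vx <- cov_norm * (box(x * x) / NP - ux^2)
  vy <- cov_norm * (box(y * y) / NP - uy^2)
  vxy <- cov_norm * (box(x * y) / NP - ux * uy)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  s <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(s)
}

#' Per-gene structural similarity
#'
#' Each gene's values are rasterized onto a regular grid inferred from the
#' coordinate pitch (collisions averaged), min-max scaled to `[0, 1]`, and
#' compared with SSIM (`data_range = 1`, uniform 7x7 window, K1 = 0.01,
#' K2 = 0.03; the window shrinks to the largest odd size that fits small
#' images). A gene constant in either field is reported as `NA`.
#'
#' @param A,B `[locations x genes]` matrices.
#' @param coords `[locations x 2]` coordinates.
#' @param grid_spec optional list (`x0`, `y0`, `pitch_x`, `pitch_y`)
#'   overriding grid inference.
#' @return numeric vector of per-gene SSIM values.
#' @export
ssim_per_gene <- function(A, B, coords, grid_spec = NULL) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B))) stop("shape mismatch")
  vapply(seq_len(ncol(A)), function(j) {
    ia <- rasterize_field(A[, j], coords, grid_spec)
    ib <- rasterize_field(B[, j], coords, grid_spec)
    ra <- range(ia); rb <- range(ib)
    if (diff(ra) == 0 || diff(rb) == 0) return(NA_real_)
    ssim_uniform((ia - ra[1]) / diff(ra), (ib - rb[1]) / diff(rb))
  }, numeric(1))
}

#' Full evaluation report
#'
#' Aggregates fine-resolution predictions to spots and reports per-gene PCC
#' and SSIM against a spot-level ground truth.
#'
#' @param truth `[n_spots x genes]` ground-truth matrix.
#' @param fine `[n_tiles x genes]` predicted fine-resolution matrix.
#' @param tiles the `tile_set` of `fine`.
#' @param coords `[n_spots x 2]` spot coordinates for rasterization.
#' @return data.frame: `gene`, `pcc`, `ssim`.
#' @export
eval_report <- function(truth, fine, tiles, coords) {
  pred <- aggregate_to_spots(fine, tiles)
  stopifnot(nrow(pred) == nrow(truth))
  data.frame(gene = colnames(truth) %||% seq_len(ncol(truth)),
             pcc = pcc_per_gene(truth, pred),
             ssim = ssim_per_gene(truth, pred, coords))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
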