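# Final super-resolved expression: a convex blend of the image-based tile
# prediction and an inverse-distance weighted average of the nearest
# measured spots.

#' Imputation configuration
#'
#' @param kappa neighbor count for the smoothing arm (defaults: 6 for the
#'   hexagonal Visium lattice, 4 for square VisiumHD bins).
#' @param alpha blend weight on the image arm, in (0, 1); 0.5 by default.
#'   The exact endpoints 0 and 1 are admitted only with `test_mode = TRUE`
#'   (they reduce the blend to one arm and are used for limit checks).
#' @param test_mode allow `alpha` in the closed interval `[0, 1]`.
#' @return An `impute_config` list.
#' @export
impute_config <- function(kappa = 6L, alpha = 0.5, test_mode = FALSE) {
  stopifnot(kappa >= 1L)
  lo <- if (test_mode) 0 else 1e-12
  if (alpha < lo || alpha > 1 - lo)
    stop("`alpha` must lie strictly inside (0, 1)")
  list(kappa = as.integer(kappa), alpha = alpha)
}

#' k nearest measured spots of a tile center
#'
#' Euclidean distances in full-resolution pixels; ties at the kappa-th
#' distance are broken toward the lower spot index.
#'
#' @param tile_center numeric pair (x, y).
#' @param spot_coords `[n x 2]` matrix or the `spot_coords` data.frame of a
#'   bundle.
#' @param kappa neighbor count; clipped with a warning when fewer spots
#'   exist.
#' @return list with integer `index` and numeric `dist`, both length kappa.
#' @export
knn_spots <- function(tile_center, spot_coords, kappa) {
  xy <- if (is.data.frame(spot_coords)) cbind(spot_coords$x, spot_coords$y)
        else as.matrix(spot_coords)
  if (kappa > nrow(xy)) {
    warning("kappa = ", kappa, " clipped to ", nrow(xy), " available spots")
    kappa <- nrow(xy)
  }
  d <- sqrt((xy[, 1] - tile_center[1])^2 + (xy[, 2] - tile_center[2])^2)
  ord <- order(d, seq_along(d))[seq_len(kappa)]
  list(index = ord, dist = d[ord])
}

#' Inverse-distance weights
#'
#' `w_s = d_s^-1 / sum(d^-1)`. If any distance is exactly zero, the first
#' zero-distance neighbor takes weight 1 and all others 0.
#'
#' @param distances non-negative distances.
#' @return weights summing to 1.
#' @export
idw_weights <- function(distances) {
  if (!length(distances)) stop("empty distance list")
  if (any(distances == 0)) {
    w <- numeric(length(distances))
    w[which(distances == 0)[1]] <- 1
    return(w)
  }
  inv <- 1 / distances
  inv / sum(inv)
}

#' Blend image predictions with neighborhood smoothing
#'
#' For every tile, `out = alpha * prediction + (1 - alpha) * IDW average of
#' the kappa nearest measured spots' expression`; applied identically to
#' within-spot, between-spot and nucleus tiles. Measured expression must be
#' on the same scale (same transform) as the predictions.
#'
#' @param predictions `[n_tiles x p]` matrix from
#'   [infer_subspot_expression()].
#' @param tiles the matching `tile_set` (provides tile centers).
#' @param bundle the `slide_bundle` providing measured spot expression and
#'   coordinates on the same gene panel.
#' @param config an [impute_config()].
#' @return `[n_tiles x p]` imputed matrix.
#' @export
impute_tiles <- function(predictions, tiles, bundle, config = impute_config()) {
  df <- if (inherits(tiles, "tile_set")) tiles$tiles else tiles
  predictions <- as.matrix(predictions)
  if (nrow(predictions) != nrow(df))
    stop("predictions (", nrow(predictions), " rows) not aligned to tiles (",
         nrow(df), ")")
  if (ncol(predictions) != ncol(bundle$counts) ||
      (!is.null(colnames(predictions)) &&
       !identical(colnames(predictions), colnames(bundle$counts))))
    stop("gene panel mismatch between predictions and measured expression")
  Y <- bundle$counts
  sm <- smooth_expression(cbind(df$center_x, df$center_y), bundle, config)
  out <- config$alpha * predictions + (1 - config$alpha) * sm
  dimnames(out) <- dimnames(predictions)
  out
}

# IDW smoothing of measured spot expression onto arbitrary target centers.
smooth_expression <- function(centers, bundle, config) {
  xy <- cbind(bundle$spot_coords$x, bundle$spot_coords$y)
  Y <- bundle$counts
  kappa <- min(config$kappa, nrow(xy))
  if (kappa < config$kappa)
    warning("kappa clipped to ", kappa, " available spots")
  out <- matrix(0, nrow(centers), ncol(Y))
  # chunked pairwise distances keep memory bounded on large tile sets
  chunk <- max(1L, floor(2e6 / nrow(xy)))
  for (start in seq(1L, nrow(centers), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(centers))
    d2 <- outer(centers[idx, 1], xy[, 1], `-`)^2 +
          outer(centers[idx, 2], xy[, 2], `-`)^2
    for (i in seq_along(idx)) {
      ord <- order(d2[i, ], seq_len(ncol(d2)))[seq_len(kappa)]
      w <- idw_weights(sqrt(d2[i, ord]))
      out[idx[i], ] <- w %*% Y[ord, , drop = FALSE]
    }
  }
  out
}
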