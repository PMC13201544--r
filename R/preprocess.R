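#' Restrict a bundle to the ligand-receptor gene panel
#'
#' Keeps the genes of the LR database (plus any `extra_genes`) that are
#' present in the bundle, and drops genes detected (nonzero) in fewer than
#' `min_spots` spots. Gene order of the bundle is preserved.
#'
#' @param bundle a `slide_bundle`.
#' @param lr_db an `lr_database`; defaults to the one attached to the bundle.
#' @param extra_genes additional gene symbols to retain (e.g. highly
#'   variable genes).
#' @param min_spots minimum number of spots a gene must be detected in
#'   (default 10).
#' @return The filtered `slide_bundle`.
#' @export
select_genes <- function(bundle, lr_db = bundle$lr_db, extra_genes = character(0),
                         min_spots = 10L) {
  stopifnot(inherits(bundle, "slide_bundle"))
  if (is.null(lr_db)) stop("no LR database supplied or attached to the bundle")
  if (min_spots < 1L) stop("`min_spots` must be >= 1")
  wanted <- union(lr_db$lr_gene_set, extra_genes)
  keep <- bundle$gene_names %in% wanted
  n_detect <- colSums(bundle$counts > 0)
  keep <- keep & n_detect >= min_spots
  if (!any(keep))
    stop("no genes retained; relax `min_spots` or extend the gene panel")
  out <- bundle
  out$counts <- bundle$counts[, keep, drop = FALSE]
  out$gene_names <- bundle$gene_names[keep]
  out$lr_db <- lr_db
  out
}

#' Library-size normalization and log transform
#'
#' With `normalize = TRUE`, each spot is scaled so its total count is
#' 10,000 and then transformed as `log(value + 1)`; with the default
#' `normalize = FALSE` counts pass through unchanged (the model consumes raw
#' counts by default). All-zero spots are left all-zero with a warning.
#'
#' @param bundle a `slide_bundle`.
#' @param normalize logical flag.
#' @return The transformed `slide_bundle`; `$normalized` records the choice.
#' @export
preprocess_counts <- function(bundle, normalize = FALSE) {
  stopifnot(inherits(bundle, "slide_bundle"))
  out <- bundle
  if (normalize) {
    tot <- rowSums(bundle$counts)
    zero <- tot == 0
    if (any(zero))
      warning(sum(zero), " all-zero spot(s) left untouched by normalization")
    scale <- ifelse(zero, 0, 1e4 / tot)
    out$counts <- log1p(bundle$counts * scale)
  }
  out$normalized <- isTRUE(normalize)
  out
}

#' Even-odd point-in-polygon membership, boundary inclusive
#'
#' @param px,py point coordinates.
#' @param poly matrix or data.frame of polygon vertices (columns x, y).
#' @return logical vector.
#' @keywords internal
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)[, 1:2, drop = FALSE]
  nv <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:nv, 1)]; ye <- ys[c(2:nv, 1)]
  inside <- logical(length(px))
  on_edge <- logical(length(px))
  for (e in seq_len(nv)) {
    x1 <- xs[e]; y1 <- ys[e]; x2 <- xe[e]; y2 <- ye[e]
    # boundary test: point on segment (collinear and within bbox)
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    on_seg <- abs(cross) < 1e-9 * (1 + abs(x2 - x1) + abs(y2 - y1)) &
      px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    # even-odd ray cast to +x
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Crop a bundle to a region of interest polygon
#'
#' Keeps spots whose centers fall inside the polygon (even-odd rule,
#' boundary counts as inside), crops the image to the polygon's bounding
#' box, and re-offsets spot coordinates to the cropped frame.
#'
#' @param bundle a `slide_bundle`.
#' @param polygon matrix/data.frame of >= 3 vertices (x, y) in
#'   full-resolution pixels, or a CSV path with columns x, y.
#' @return The cropped `slide_bundle`; `$roi_offset` holds the (x, y) shift
#'   applied to coordinates.
#' @export
crop_roi <- function(bundle, polygon) {
  stopifnot(inherits(bundle, "slide_bundle"))
  if (is.character(polygon)) polygon <- utils::read.csv(polygon)
  polygon <- as.matrix(as.data.frame(polygon)[, 1:2])
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  keep <- point_in_polygon(bundle$spot_coords$x, bundle$spot_coords$y, polygon)
  if (!any(keep))
    stop("no spots inside the polygon (x range [",
         min(polygon[, 1]), ", ", max(polygon[, 1]), "], y range [",
         min(polygon[, 2]), ", ", max(polygon[, 2]), "])")
  H <- dim(bundle$image)[1]; W <- dim(bundle$image)[2]
  x0 <- max(0L, floor(min(polygon[, 1]))); x1 <- min(W - 1L, ceiling(max(polygon[, 1])))
  y0 <- max(0L, floor(min(polygon[, 2]))); y1 <- min(H - 1L, ceiling(max(polygon[, 2])))
  out <- bundle
  out$image <- bundle$image[(y0 + 1L):(y1 + 1L), (x0 + 1L):(x1 + 1L), , drop = FALSE]
  out$spot_coords <- bundle$spot_coords[keep, , drop = FALSE]
  out$spot_coords$x <- out$spot_coords$x - x0
  out$spot_coords$y <- out$spot_coords$y - y0
  out$counts <- bundle$counts[keep, , drop = FALSE]
  out$spot_ids <- bundle$spot_ids[keep]
  out$roi_offset <- c(x = x0, y = y0)
  out
}
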