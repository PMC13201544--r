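# Pixel bookkeeping: spot patches, tile grids, between-spot centers and
# nuclei-centered tiles. Convention throughout: 0-based pixel coordinates,
# (x = column, y = row), half-open windows [a, b).

tile_set <- function(df, tile_size_px, counts = list()) {
  need <- c("tile_id", "kind", "parent", "row0", "col0", "size",
            "center_x", "center_y")
  stopifnot(all(need %in% names(df)))
  structure(list(tiles = df[, need], tile_size_px = tile_size_px,
                 counts = counts), class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  cat("tile_set:", nrow(x$tiles), "tiles of", x$tile_size_px, "px (",
      paste(names(table(x$tiles$kind)), table(x$tiles$kind), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Extract a square image patch window around every spot
#'
#' The window for a spot at `(x, y)` is the half-open pixel box
#' `[y - patch_px/2, y + patch_px/2) x [x - patch_px/2, x + patch_px/2)`.
#' Spots closer than `patch_px / 2` to the image border are excluded with a
#' warning; if no spot survives this is a hard error.
#'
#' @param bundle a `slide_bundle`, or any object with `$image` and
#'   `$spot_coords`.
#' @param patch_px even patch side length in pixels (default 112).
#' @param centers optional data.frame (x, y, parent) overriding the bundle's
#'   spot centers, e.g. the augmented list from [generate_between_spots()].
#' @return data.frame with one row per retained center: `parent` (spot index
#'   or -1 for between-spot centers), `row0`, `col0`, `patch_px`,
#'   `center_x`, `center_y`.
#' @export
extract_patches <- function(bundle, patch_px = 112L, centers = NULL) {
  if (patch_px %% 2L != 0L) stop("`patch_px` must be even")
  if (is.null(centers)) {
    centers <- data.frame(x = bundle$spot_coords$x, y = bundle$spot_coords$y,
                          parent = seq_len(nrow(bundle$spot_coords)))
  }
  H <- dim(bundle$image)[1]; W <- dim(bundle$image)[2]
  half <- patch_px / 2
  row0 <- round(centers$y - half); col0 <- round(centers$x - half)
  ok <- row0 >= 0 & col0 >= 0 & row0 + patch_px <= H & col0 + patch_px <= W
  if (!any(ok)) stop("every spot center is within ", half, " px of the border")
  if (any(!ok))
    warning(sum(!ok), " spot(s) closer than ", half,
            " px to the image border excluded")
  data.frame(parent = centers$parent[ok], row0 = row0[ok], col0 = col0[ok],
             patch_px = patch_px,
             center_x = col0[ok] + half, center_y = row0[ok] + half)
}

#' Split one patch window into a grid of tiles
#'
#' Tiles are emitted in row-major order; the 1-based tile `(i, j)` occupies
#' rows `[(i-1) t, i t)` and columns `[(j-1) t, j t)` within the patch,
#' where `t = patch_px / grid`.
#'
#' @param patch one row of the data.frame returned by [extract_patches()].
#' @param grid tiles per side (default 8, i.e. 64 tiles from a 112-px patch).
#' @return data.frame of `grid^2` tile rows.
#' @export
tile_patch <- function(patch, grid = 8L) {
  patch_px <- patch$patch_px[1]
  if (patch_px %% grid != 0L)
    stop("patch of ", patch_px, " px not divisible into a ", grid, "-grid")
  t <- patch_px / grid
  ij <- expand.grid(j = seq_len(grid), i = seq_len(grid))  # row-major
  row0 <- patch$row0[1] + (ij$i - 1L) * t
  col0 <- patch$col0[1] + (ij$j - 1L) * t
  data.frame(kind = "geometric", parent = patch$parent[1],
             row0 = row0, col0 = col0, size = t,
             center_x = col0 + t / 2, center_y = row0 + t / 2)
}

#' Build the full geometric tile set of a slide
#'
#' Convenience wrapper: patch extraction around every (optionally augmented)
#' spot center followed by grid tiling of every patch.
#'
#' @inheritParams extract_patches
#' @inheritParams tile_patch
#' @return A `tile_set` whose `$counts` records `n` (probed spots), `l`
#'   (tiles per spot), `m` (centers incl. between-spots) and `M = m * l`.
#' @export
tile_slide <- function(bundle, patch_px = 112L, grid = 8L, centers = NULL) {
  patches <- extract_patches(bundle, patch_px, centers)
  tiles <- do.call(rbind, lapply(seq_len(nrow(patches)), function(i)
    tile_patch(patches[i, , drop = FALSE], grid)))
  tiles$tile_id <- seq_len(nrow(tiles))
  m <- nrow(patches)
  tile_set(tiles, tile_size_px = patch_px / grid,
           counts = list(n = sum(patches$parent > 0), l = grid^2,
                         m = m, M = m * grid^2))
}

#' Augment probed spots with between-spot gap centers
#'
#' Pseudo spot centers are placed in the unmeasured gaps so the imputed
#' expression covers the tissue continuously. For a hexagonal (Visium)
#' lattice the gap centers are the midpoints between lattice neighbors
#' (the Voronoi cell face centers); for a square lattice (VisiumHD,
#' generic) they are the 4-neighbor edge midpoints plus the cell corners
#' (midpoints of diagonal neighbor pairs). Candidates are deduplicated and
#' those outside the convex hull of the probed spots are dropped. On a
#' large interior lattice this yields close to 4 centers per probed spot.
#'
#' @param bundle a `slide_bundle` (its `platform_tag` selects the lattice).
#' @return data.frame of `m` centers: `x`, `y`, `kind`
#'   (`"within"`/`"between"`), `parent` (spot index, or -1 for between).
#' @export
generate_between_spots <- function(bundle) {
  xy <- cbind(bundle$spot_coords$x, bundle$spot_coords$y)
  n <- nrow(xy)
  within <- data.frame(x = xy[, 1], y = xy[, 2], kind = "within",
                       parent = seq_len(n))
  if (n == 1L) return(within)
  if (n >= 3L) {
    v1 <- xy[2, ] - xy[1, ]
    cross <- (xy[, 1] - xy[1, 1]) * v1[2] - (xy[, 2] - xy[1, 2]) * v1[1]
    span <- max(abs(xy)) + 1
    if (all(abs(cross) < 1e-9 * span^2))
      stop("degenerate layout: all spot centers are collinear")
  }
  pitch <- stats::median(nn_distances(xy))
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  cand <- NULL
  pair_mid <- function(max_d, min_d = 0) {
    idx <- which(d > min_d & d <= max_d, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    if (!nrow(idx)) return(NULL)
    (xy[idx[, 1], , drop = FALSE] + xy[idx[, 2], , drop = FALSE]) / 2
  }
  if (bundle$platform_tag == "visium") {
    cand <- pair_mid(1.3 * pitch)
  } else {
    cand <- rbind(pair_mid(1.3 * pitch),                       # edge midpoints
                  pair_mid(1.3 * sqrt(2) * pitch, 1.3 * pitch)) # cell corners
  }
  if (!is.null(cand) && nrow(cand)) {
    key <- paste(round(cand[, 1] / pitch, 6), round(cand[, 2] / pitch, 6))
    cand <- cand[!duplicated(key), , drop = FALSE]
    if (n >= 3L) {
      hull <- xy[grDevices::chull(xy), , drop = FALSE]
      keep <- point_in_polygon(cand[, 1], cand[, 2], hull)
      cand <- cand[keep, , drop = FALSE]
    }
  }
  if (is.null(cand) || !nrow(cand)) return(within)
  rbind(within,
        data.frame(x = cand[, 1], y = cand[, 2], kind = "between",
                   parent = -1L))
}

#' Nucleus-centered tiles
#'
#' One tile of side `tile_px` is centered on every nucleus coordinate;
#' centers within `tile_px / 2` of the image border are excluded with a
#' warning. Every retained nucleus is assigned to its nearest spot center
#' (ties broken toward the lower spot index) for per-spot bookkeeping.
#'
#' @param bundle a `slide_bundle`.
#' @param nuclei_centers data.frame or matrix of (x, y) in full-resolution
#'   pixels, or a CSV path with columns x, y.
#' @param tile_px tile side length (default 14).
#' @return A `tile_set` of kind `"nucleus"`; `$counts$M_hat` is the retained
#'   nucleus count and `$counts$M_hat_k` the per-spot tallies.
#' @export
nuclei_tiles <- function(bundle, nuclei_centers, tile_px = 14L) {
  if (is.character(nuclei_centers)) nuclei_centers <- utils::read.csv(nuclei_centers)
  nc <- as.matrix(as.data.frame(nuclei_centers)[, 1:2])
  if (!nrow(nc)) stop("empty nuclei center list")
  H <- dim(bundle$image)[1]; W <- dim(bundle$image)[2]
  half <- tile_px / 2
  row0 <- round(nc[, 2] - half); col0 <- round(nc[, 1] - half)
  ok <- row0 >= 0 & col0 >= 0 & row0 + tile_px <= H & col0 + tile_px <= W
  if (any(!ok))
    warning(sum(!ok), " nucleus center(s) within ", half,
            " px of the border excluded")
  if (!any(ok)) stop("no nucleus tile fits inside the image")
  nc <- nc[ok, , drop = FALSE]; row0 <- row0[ok]; col0 <- col0[ok]
  sxy <- cbind(bundle$spot_coords$x, bundle$spot_coords$y)
  # nearest spot; which.min returns the first (lowest-index) minimizer
  parent <- vapply(seq_len(nrow(nc)), function(i)
    which.min((sxy[, 1] - nc[i, 1])^2 + (sxy[, 2] - nc[i, 2])^2), integer(1))
  M_hat_k <- tabulate(parent, nbins = nrow(sxy))
  df <- data.frame(tile_id = seq_len(nrow(nc)), kind = "nucleus",
                   parent = parent, row0 = row0, col0 = col0, size = tile_px,
                   center_x = col0 + half, center_y = row0 + half)
  tile_set(df, tile_size_px = tile_px,
           counts = list(M_hat = nrow(nc), M_hat_k = M_hat_k))
}

#' Serialize / load a tile set as TSV
#' @param tiles a `tile_set`.
#' @param path TSV path.
#' @return `path` (write) or a `tile_set` (read).
#' @export
write_tiles <- function(tiles, path) {
  utils::write.table(tiles$tiles, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tiles
#' @export
read_tiles <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  tile_set(df, tile_size_px = df$size[1])
}

#' Crop tile pixel windows out of an image
#' @param image RGB array.
#' @param tiles a `tile_set` or tile data.frame.
#' @return list of `[size x size x 3]` arrays, one per tile.
#' @export
tile_pixels <- function(image, tiles) {
  df <- if (inherits(tiles, "tile_set")) tiles$tiles else tiles
  lapply(seq_len(nrow(df)), function(i) {
    r <- df$row0[i]; c <- df$col0[i]; s <- df$size[i]
    image[(r + 1L):(r + s), (c + 1L):(c + s), , drop = FALSE]
  })
}
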