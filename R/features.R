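# Tile -> embedding. The extractor is pluggable: heavyweight foundation-model
# profiles declare their contract (embedding dim, tile size) and are loaded
# as plugins, while the built-in stub is a deterministic, dependency-free
# featurizer so the whole downstream pipeline is testable offline.

#' Declare a tile feature extractor profile
#'
#' @param profile `"stub"`, `"virchow2"` or `"vit256"`. The foundation-model
#'   profiles declare the published embedding dimensions (1280 and 384) and
#'   tile sizes (14 and 16 px); their `fn` must be supplied by a plugin. The
#'   stub is self-contained.
#' @param embed_dim embedding dimension for the stub (>= 8, default 32).
#' @param seed seed fixing the stub's random projection.
#' @param tile_px expected tile side for the stub (default 14).
#' @param fn optional plugin function `(pixels) -> numeric[C]` for the
#'   foundation-model profiles.
#' @return A `feature_extractor` with fields `name`, `dim`, `tile_px`, `fn`.
#' @export
feature_extractor <- function(profile = c("stub", "virchow2", "vit256"),
                              embed_dim = 32L, seed = 1L, tile_px = 14L,
                              fn = NULL) {
  profile <- match.arg(profile)
  ex <- switch(profile,
    stub = {
      if (embed_dim < 8L) stop("stub embedding dimension must be >= 8")
      list(name = "stub", dim = as.integer(embed_dim), tile_px = tile_px,
           fn = function(px) stub_extractor(px, embed_dim, seed))
    },
    virchow2 = list(name = "virchow2", dim = 1280L, tile_px = 14L, fn = fn),
    vit256 = list(name = "vit256", dim = 384L, tile_px = 16L, fn = fn))
  structure(ex, class = "feature_extractor")
}

#' Deterministic stub tile featurizer
#'
#' Embedding layout: per-channel means (3), per-channel variances (3),
#' low-order 2-D moments of the mean-centered grayscale intensity (5:
#' first moments, second moments and the cross moment on coordinates
#' normalized to `[-0.5, 0.5]`), then a seeded fixed random projection of
#' the flattened mean-centered tile filling the remaining dimensions. The
#' map is deterministic given `(pixels, C, seed)` and Lipschitz in the
#' pixel values; shifting all pixels by a constant changes only the three
#' channel-mean coordinates.
#'
#' @param pixels `[t x t x 3]` array.
#' @param C output dimension (>= 8).
#' @param seed integer fixing the projection matrix.
#' @return numeric vector of length `C`.
#' @export
stub_extractor <- function(pixels, C, seed = 1L) {
  stopifnot(C >= 8L)
  ch_mean <- apply(pixels, 3L, mean)
  ch_var <- apply(pixels, 3L, function(v) mean((v - mean(v))^2))
  g <- (pixels[, , 1] + pixels[, , 2] + pixels[, , 3]) / 3
  w <- g - mean(g)
  nr <- nrow(g); nc <- ncol(g)
  r <- (row(g) - (nr + 1) / 2) / nr
  cc <- (col(g) - (nc + 1) / 2) / nc
  mom <- c(mean(w * r), mean(w * cc), mean(w * r^2), mean(w * cc^2),
           mean(w * r * cc))
  head_block <- c(ch_mean, ch_var, mom)
  n_proj <- C - length(head_block)
  if (n_proj > 0) {
    flat <- as.numeric(pixels) - mean(pixels)
    P <- projection_matrix(length(flat), n_proj, seed)
    c(head_block, as.numeric(crossprod(P, flat)) / sqrt(length(flat)))
  } else {
    head_block[seq_len(C)]
  }
}

# Fixed seeded projection, cached per (n_in, n_out, seed) for speed.
proj_cache <- new.env(parent = emptyenv())
projection_matrix <- function(n_in, n_out, seed) {
  key <- paste(n_in, n_out, seed, sep = "_")
  if (is.null(proj_cache[[key]])) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    proj_cache[[key]] <- matrix(stats::rnorm(n_in * n_out), n_in, n_out)
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
  }
  proj_cache[[key]]
}

#' Embed every tile of a tile set
#'
#' @param tiles a `tile_set`.
#' @param image the RGB raster the tile windows index into.
#' @param extractor a `feature_extractor`.
#' @return `[n_tiles x C]` numeric matrix; rows are a pure function of the
#'   tile pixels. Attribute `tile_index` maps rows back to `tiles$tiles`.
#' @export
extract_features <- function(tiles, image, extractor) {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (is.null(extractor$fn))
    stop("extractor profile '", extractor$name,
         "' has no plugin function attached; use the stub or supply `fn`")
  df <- tiles$tiles
  if (any(df$size != extractor$tile_px))
    stop("tile size ", unique(df$size)[1], " px does not match the '",
         extractor$name, "' contract of ", extractor$tile_px, " px")
  px <- tile_pixels(image, tiles)
  out <- t(vapply(px, extractor$fn, numeric(extractor$dim)))
  if (any(!is.finite(out))) stop("non-finite feature values produced")
  attr(out, "tile_index") <- df$tile_id
  out
}
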