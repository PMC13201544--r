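# Shared fixtures, built once per test session. The default slide and the
# trained model are the most expensive objects; memoising them keeps the
# suite fast while every test still consumes generator output.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- force(expr)
  fixture_env[[name]]
}

# small slide: fast geometry / io tests
small_slide <- function() memo("small", {
  make_slide(slide_config(n_rows = 8L, n_cols = 8L, n_cells = 400L),
             seed = 101L)
})

# the default study-condition fixture (20x20 spots, 5 planted pairs)
default_slide <- function() memo("default", {
  make_slide(slide_config(), seed = 11L)
})

default_features <- function() memo("default_feats", {
  s <- default_slide()
  ex <- feature_extractor("stub", embed_dim = 32L, seed = 5L,
                          tile_px = s$tiles$tile_size_px)
  extract_features(s$tiles, s$bundle$image, ex)
})

# one trained model shared by the model / imputation / metrics tests
trained_model <- function() memo("model", {
  s <- default_slide()
  train_finest(s$bundle, default_features(), s$tiles,
               train_config(K = 64L, h = 32L, epochs = 120L, lr = 2e-3,
                            seed = 2L))
})

# deterministic two-blob pattern fixture: G pairs active on opposite halves
two_blob_fixture <- function(M_side = 20L, G = 40L, noise = 0.3,
                             seed = 9L) {
  set.seed(seed)
  co <- as.matrix(expand.grid(x = seq_len(M_side) * 10,
                              y = seq_len(M_side) * 10))
  left <- co[, "x"] < stats::median(co[, "x"])
  grp <- rep(1:2, each = G / 2)
  X <- t(vapply(seq_len(G), function(g)
    (if (grp[g] == 1) left else !left) + stats::rnorm(nrow(co), sd = noise),
    numeric(nrow(co))))
  list(X = X, coords = co, groups = grp)
}

# spatial weights on a jittered grid, reused by the statistics tests
grid_weights <- function(M = 200L, seed = 3L, cutoff = 6L) {
  set.seed(seed)
  co <- matrix(stats::runif(2L * M, 0, 10), M)
  list(coords = co, weights = build_weights(co, cutoff = cutoff))
}

# naive double-loop oracles for the Moran statistics
naive_global_moran <- function(L, R, W) {
  x <- L - mean(L); y <- R - mean(R)
  s <- 0
  for (k in seq_along(L)) for (t in seq_along(L)) s <- s + W[k, t] * x[k] * y[t]
  s / (sqrt(sum(x^2)) * sqrt(sum(y^2)))
}

naive_local_moran <- function(L, R, W) {
  x <- L - mean(L); y <- R - mean(R)
  sx <- sqrt(mean(x^2)); sy <- sqrt(mean(y^2))
  M <- length(L)
  sen <- rec <- numeric(M)
  for (k in seq_len(M)) {
    sen[k] <- x[k] * sum(W[k, ] * y) / (sx * sy)
    rec[k] <- y[k] * sum(W[k, ] * x) / (sx * sy)
  }
  list(sender = sen, receiver = rec, local = sen + rec)
}

# minimal tile set for toy training runs (l tiles per spot, no pixels)
make_toy_tiles <- function(n, l) {
  structure(list(
    tiles = data.frame(tile_id = seq_len(n * l), kind = "geometric",
                       parent = rep(seq_len(n), each = l), row0 = 0,
                       col0 = 0, size = 14, center_x = 0, center_y = 0),
    tile_size_px = 14, counts = list(n = n, l = l, m = n, M = n * l)),
    class = "tile_set")
}

# one-tile bundle for the hand-worked imputation example: neighbors at
# distances 1 and 2 carrying values 2 and 4
toy_impute_setup <- function() {
  img <- array(100, c(60, 60, 3))
  b <- slide_bundle(img,
                    data.frame(spot_id = c("a", "b"), x = c(31, 32),
                               y = c(30, 30)),
                    rbind(2, 4), gene_names = "g1", spot_diameter_px = 5,
                    platform_tag = "generic")
  tiles <- data.frame(tile_id = 1L, kind = "geometric", parent = 1L,
                      row0 = 0, col0 = 0, size = 14, center_x = 30,
                      center_y = 30)
  list(bundle = b, tiles = tiles)
}

# hand-rolled spatial_weights wrapper around an explicit dense matrix
manual_weights <- function(W) {
  structure(list(W = Matrix::Matrix(W, sparse = TRUE), ell = NA,
                 cutoff = NA, row_normalized = FALSE),
            class = "spatial_weights")
}
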