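test_that("spatial weights follow the Gaussian kernel contract", {
  # two points at distance ell * sqrt(2 ln 2): off-diagonal weight 0.5
  ell <- 3
  d <- ell * sqrt(2 * log(2))
  w <- build_weights(rbind(c(0, 0), c(d, 0)), ell = ell, cutoff = 1L)
  expect_equal(as.numeric(w$W[1, 2]), 0.5)
  expect_equal(as.numeric(w$W[2, 1]), 0.5)
  expect_equal(as.numeric(Matrix::diag(w$W)), c(0, 0))
  # weight tends to 1 as distance tends to 0 (duplicates allowed)
  w2 <- build_weights(rbind(c(0, 0), c(1e-8, 0), c(5, 5)), ell = 1,
                      cutoff = 1L)
  expect_equal(as.numeric(w2$W[1, 2]), 1, tolerance = 1e-10)
  expect_error(build_weights(rbind(c(1, 1), c(1, 1))), "identical")
  # 5-point line, cutoff 1: interior points keep their single nearest
  co <- cbind(c(0, 1, 2.1, 3.3, 4.6), 0)
  w3 <- build_weights(co, ell = 1, cutoff = 1L)
  pre_sym_nbrs <- vapply(1:5, function(i) {
    d <- abs(co[, 1] - co[i, 1]); d[i] <- Inf; which.min(d)
  }, integer(1))
  for (i in 2:4) expect_true(w3$W[i, pre_sym_nbrs[i]] > 0)
  # symmetry before row normalization
  expect_equal(as.matrix(w3$W), t(as.matrix(w3$W)))
  wr <- build_weights(co, ell = 1, cutoff = 2L, row_normalize = TRUE)
  expect_equal(unname(Matrix::rowSums(wr$W)), rep(1, 5))
})

test_that("vectorized Moran statistics equal the naive double loop", {
  set.seed(42)
  max_g <- max_l <- max_id <- 0
  for (i in 1:25) {
    M <- sample(10:50, 1)
    co <- matrix(runif(2 * M, 0, 10), M)
    w <- build_weights(co, cutoff = 4L)
    L <- rnorm(M); R <- rnorm(M)
    g <- global_moran_r(L, R, w)
    lo <- local_moran_r(L, R, w)
    Wd <- as.matrix(w$W)
    max_g <- max(max_g, abs(g$R_global - naive_global_moran(L, R, Wd)))
    nl <- naive_local_moran(L, R, Wd)
    max_l <- max(max_l, max(abs(lo$R_local - nl$local)),
                 max(abs(lo$R_sender - nl$sender)))
    max_id <- max(max_id, abs(sum(lo$R_local) - 2 * M * g$R_global))
  }
  expect_lt(max_g, 1e-10)
  expect_lt(max_l, 1e-10)
  expect_lt(max_id, 1e-8)
})

test_that("hand-worked toys and degenerate cases behave as stated", {
  # 2-point swap matrix with L = R = (1, -1): R_global = -1
  w <- manual_weights(rbind(c(0, 1), c(1, 0)))
  expect_equal(global_moran_r(c(1, -1), c(1, -1), w)$R_global, -1)
  # identical smooth gradients with nearest-neighbor weights: positive R
  co <- cbind(1:20, 0)
  wg <- build_weights(co, ell = 1.5, cutoff = 2L)
  grad <- seq(0, 1, length.out = 20)
  expect_gt(global_moran_r(grad, grad, wg)$R_global, 0)
  # zero-variance input is skipped with p = 1
  g0 <- global_moran_r(rep(2, 20), grad, wg)
  expect_true(g0$skipped); expect_equal(g0$p, 1)
  l0 <- local_moran_r(rep(2, 20), grad, wg)
  expect_true(l0$skipped)
  # location at the field mean has zero sender statistic
  L <- c(0, 1, 2); R <- c(5, 1, 3)
  wl <- manual_weights(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_equal(local_moran_r(L, R, wl)$R_sender[2], 0)  # L_2 == mean(L)
})

test_that("R_global is invariant to positive affine rescaling", {
  gw <- grid_weights(M = 60L)
  set.seed(2)
  L <- rnorm(60); R <- rnorm(60)
  base <- global_moran_r(L, R, gw$weights)$R_global
  expect_equal(global_moran_r(3.7 * L + 11, R, gw$weights)$R_global, base,
               tolerance = 1e-12)
  expect_equal(global_moran_r(L, 0.02 * R - 5, gw$weights)$R_global, base,
               tolerance = 1e-12)
})

test_that("analytic p-values agree with a permutation oracle", {
  gw <- grid_weights(M = 200L)
  set.seed(10)
  agree <- vapply(1:40, function(i) {
    L <- rnorm(200); R <- rnorm(200)
    g <- global_moran_r(L, R, gw$weights, n_perm = 10000L, seed = i)
    abs(g$p - g$p_perm) <= 0.02
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("pair expression averages subunits and drops incomplete pairs", {
  expr <- cbind(WNT3 = c(1, 2, 3), FZD9 = c(2, 2, 2), LRP6 = c(0, 4, 2))
  db <- lr_database(data.frame(
    ligand = c("WNT3", "WNT3", "MISSING"),
    receptor = c("FZD9_LRP6", "FZD9", "FZD9"),
    pathway = "WNT"))
  expect_message(pe <- pair_expression(expr, db), "dropped")
  expect_equal(unname(pe$R[, "WNT3:FZD9_LRP6"]), c(1, 3, 2))
  expect_equal(unname(pe$R[, "WNT3:FZD9"]), c(2, 2, 2))  # single subunit
  expect_equal(pe$dropped, "MISSING:FZD9")
  # min aggregation by flag
  pe2 <- suppressMessages(pair_expression(expr, db, agg = "min"))
  expect_equal(unname(pe2$R[, "WNT3:FZD9_LRP6"]), c(0, 2, 2))
  expect_error(pair_expression(expr[, 1, drop = FALSE], db), "no LR pair")
})

test_that("BH selection and the sparse-pair filter follow the step-up rule", {
  # BH by hand: p = (.01, .02, .04, .8) at FDR .05 selects the first two
  M <- 30L
  co <- cbind(seq_len(M), 0)
  res <- structure(list(
    pairs = data.frame(ligand = paste0("L", 1:4),
                       receptor = paste0("R", 1:4), pathway = "PW",
                       pair = paste0("L", 1:4, ":R", 1:4),
                       R_global = 0.1, z = 1,
                       p = c(0.01, 0.02, 0.04, 0.8),
                       tested = TRUE),
    local = list(p_local = matrix(c(rep(0.01, M), rep(0.5, M),
                                    rep(0.01, 2), rep(0.5, M - 2),
                                    rep(0.5, M)), M, 4)),
    M = M, weights = NULL), class = "moran_result")
  out <- select_pairs(res, fdr = 0.05, min_interacting = 3L)
  expect_equal(out$pairs$selected, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(out$pairs$q >= out$pairs$p))
  # X_bin thresholds p_local and n_interacting counts it
  expect_equal(out$pairs$n_interacting, c(M, 0L, 2L, 0L))
  # pair with 2 interacting locations is flagged out of pattern analysis
  expect_false(out$pairs$eligible[3])
  expect_equal(out$local$X_con, 1 - res$local$p_local)
  # all p = 1 selects nothing
  res$pairs$p <- rep(1, 4)
  expect_false(any(select_pairs(res)$pairs$selected))
})

test_that("discover_lr ties the pieces together on a planted slide", {
  s <- make_slide(slide_config(render_image = FALSE), seed = 21L)
  b <- suppressWarnings(preprocess_counts(s$bundle, normalize = TRUE))
  res <- discover_lr(b$counts, cbind(b$spot_coords$x, b$spot_coords$y),
                     s$lr_db)
  expect_s3_class(res, "moran_result")
  expect_equal(nrow(res$pairs), 15L)
  planted <- res$pairs$pair %in% s$truth$planted$pair
  # planted pairs dominate the ranking
  expect_gt(mean(res$pairs$R_global[planted]),
            mean(res$pairs$R_global[!planted]))
  expect_true(all(dim(res$local$X_bin) == c(res$M, 15L)))
})
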