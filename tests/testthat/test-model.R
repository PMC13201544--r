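test_that("cosine row-column loss matches hand-computed values", {
  set.seed(1)
  A <- matrix(rnorm(12), 3, 4)
  expect_equal(cosine_row_col_loss(A, A), 0)
  expect_equal(cosine_row_col_loss(A, -A), 4)   # rows 2 + columns 2
  A2 <- rbind(c(1, 0), c(0, 1))
  B2 <- rbind(c(0, 1), c(1, 0))
  # all four cosines are 0: mean row term 1 + mean column term 1
  expect_equal(cosine_row_col_loss(A2, B2), 2)
  expect_error(cosine_row_col_loss(A, A[, 1:2]), "shape mismatch")
  # zero-norm rows and columns contribute 1 each by convention
  expect_equal(cosine_row_col_loss(rbind(c(1, 1)), rbind(c(0, 0))), 2)
})

test_that("InfoNCE matches its closed forms", {
  # identical unit rows: every ratio exp(1/tau) / ((K-1) exp(1/tau))
  for (K in c(3L, 4L, 8L)) {
    H <- matrix(rep(c(1, 0, 0), each = K), K, 3)
    expect_equal(infonce_loss(H, H, tau = 0.03), K * log(K - 1))
  }
  # K = 2, positive dot equal to negative dot: ratio 1, loss 0
  I2 <- diag(2)
  E2 <- matrix(1 / sqrt(2), 2, 2)   # both rows see pos dot == neg dot
  expect_equal(infonce_loss(I2, E2, tau = 0.1), 0)
  # K = 2 with pos - neg = tau * ln 2 for both rows: loss -2 ln 2
  tau <- 0.03
  a <- 0.6; cc <- 0.6 - tau * log(2); b <- 0.2; d <- 0.2 + tau * log(2)
  I3 <- rbind(c(1, 0, 0), c(0, 1, 0))
  E3 <- rbind(c(a, b, sqrt(1 - a^2 - b^2)),
              c(cc, d, sqrt(1 - cc^2 - d^2)))
  expect_equal(infonce_loss(I3, E3, tau = tau), -2 * log(2))
  expect_error(infonce_loss(I2[1, , drop = FALSE], E2[1, , drop = FALSE]),
               "at least 2")
  # the standard denominator includes the positive and is always >= 0 here
  expect_gt(infonce_loss(diag(4), diag(4), tau = 1,
                         exclude_positive = FALSE), 0)
})

test_that("cross-modal loss evaluates the aggregated translation", {
  Y <- rbind(c(2, 4), c(6, 2))
  feats <- matrix(1, 8, 3)
  parent <- rep(1:2, each = 4)
  # prediction equal to Y_k / l for every tile: loss 0
  perfect <- function(f) (Y / 4)[rep(1:2, each = 4), ]
  expect_equal(cross_modal_loss(perfect, feats, parent, Y), 0)
  # single spot, orthogonal 2-gene prediction: row 1 + two zero-norm columns
  Y1 <- rbind(c(1, 0))
  ortho <- function(f) matrix(c(0, 0, 0, 0, 0.25, 0.25, 0.25, 0.25), 4, 2)
  expect_equal(cross_modal_loss(ortho, feats[1:4, ], rep(1L, 4), Y1), 2)
  # zero-prediction model: loss 2 by the zero-norm convention
  zero <- function(f) matrix(0, nrow(f), 2)
  expect_equal(cross_modal_loss(zero, feats[1:4, ], rep(1L, 4), Y1), 2)
  expect_error(cross_modal_loss(zero, feats[1:7, ], parent[1:7], Y),
               "ragged")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(1)
  B <- 4L; l <- 4L; C <- 7L; p <- 5L; h <- 3L
  X <- matrix(abs(rnorm(B * l * C)), B * l, C)
  Y <- matrix(abs(rnorm(B * p)), B, p)
  parent <- rep(seq_len(B), each = l)
  for (cfg in list(train_config(K = 8L, h = h, tau = 0.05),
                   train_config(K = 8L, h = h, tau = 0.05,
                                expr_loss = "mse"),
                   train_config(K = 8L, h = h, tau = 0.05,
                                infonce_exclude_positive = FALSE))) {
    params <- finespot:::init_params(C, p, h)
    lg <- finespot:::finest_loss_grads(params, X, Y, parent, cfg)
    maxrel <- 0
    for (nm in names(params)) {
      idx <- sample(length(params[[nm]]), min(4L, length(params[[nm]])))
      for (ii in idx) {
        eps <- 1e-5
        pp <- params; pp[[nm]][ii] <- pp[[nm]][ii] + eps
        lp <- finespot:::finest_loss_grads(pp, X, Y, parent, cfg,
                                           want_grad = FALSE)$losses[["loss_total"]]
        pp[[nm]][ii] <- pp[[nm]][ii] - 2 * eps
        lm <- finespot:::finest_loss_grads(pp, X, Y, parent, cfg,
                                           want_grad = FALSE)$losses[["loss_total"]]
        num <- (lp - lm) / (2 * eps)
        ana <- lg$grads[[nm]][ii]
        maxrel <- max(maxrel, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
      }
    }
    expect_lt(maxrel, 1e-4)
  }
})

test_that("loss breakdown is linear in the weights", {
  set.seed(3)
  X <- matrix(abs(rnorm(32)), 8, 4)
  Y <- matrix(abs(rnorm(10)), 2, 5)
  parent <- rep(1:2, each = 4)
  params <- finespot:::init_params(4L, 5L, 3L)
  l1 <- finespot:::finest_loss_grads(params, X, Y, parent,
          train_config(K = 4L, h = 3L, weights = c(1, 1, 1, 1)),
          want_grad = FALSE)$losses
  l2 <- finespot:::finest_loss_grads(params, X, Y, parent,
          train_config(K = 4L, h = 3L, weights = c(1, 1, 1, 2)),
          want_grad = FALSE)$losses
  expect_equal(l1[["loss_total"]],
               sum(l1[c("loss_image", "loss_expr", "loss_infonce",
                        "loss_cross")]),
               tolerance = 1e-6)
  expect_equal(l2[["loss_total"]] - l1[["loss_total"]], l1[["loss_cross"]])
  # w3 = 0 removes the only tau-dependent term
  la <- finespot:::finest_loss_grads(params, X, Y, parent,
          train_config(K = 4L, h = 3L, weights = c(1, 1, 0, 1), tau = 0.03),
          want_grad = FALSE)$losses
  lb <- finespot:::finest_loss_grads(params, X, Y, parent,
          train_config(K = 4L, h = 3L, weights = c(1, 1, 0, 1), tau = 7),
          want_grad = FALSE)$losses
  expect_equal(la[["loss_total"]], lb[["loss_total"]])
})

test_that("training is deterministic under a fixed seed", {
  set.seed(5)
  n <- 20L; l <- 4L; C <- 6L; p <- 8L
  X <- matrix(abs(rnorm(n * l * C)), n * l, C)
  Y <- matrix(abs(rnorm(n * p)), n, p)
  tiles <- make_toy_tiles(n, l)
  cfg <- train_config(K = 8L, h = 4L, epochs = 5L, seed = 42L)
  m1 <- train_finest(list(counts = Y), X, tiles, cfg)
  m2 <- train_finest(list(counts = Y), X, tiles, cfg)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
})

test_that("expression autoencoder recovers low-rank structure", {
  set.seed(3)
  n <- 80L; p <- 20L
  Y <- matrix(abs(rnorm(n * 2)), n) %*% t(matrix(abs(rnorm(p * 2)), p))
  tiles <- make_toy_tiles(n, 4L)
  X <- matrix(rnorm(n * 4L * 8L), n * 4L, 8L)
  cfg <- train_config(K = 32L, h = 4L, weights = c(0, 1, 0, 0),
                      epochs = 300L, lr = 3e-3, seed = 3L,
                      train_fraction = 1)
  mdl <- train_finest(list(counts = Y), X, tiles, cfg)
  final <- utils::tail(subset(mdl$log, split == "train"), 1L)
  expect_lt(final$loss_expr, 0.05)
})

test_that("training improves held-out cross-modal translation", {
  mdl <- trained_model()
  hl <- subset(mdl$log, split == "heldout")
  expect_lt(utils::tail(hl$loss_cross, 1L), hl$loss_cross[1L])
  expect_lt(min(hl$loss_cross), hl$loss_cross[1L])
})

test_that("inference is pure, non-negative and dimension-checked", {
  mdl <- trained_model()
  f <- default_features()
  pred <- infer_subspot_expression(mdl, f[1:10, ])
  expect_true(all(pred >= 0))
  expect_equal(pred[1, ], infer_subspot_expression(mdl, f[c(1, 1), ])[2, ])
  expect_error(infer_subspot_expression(mdl, f[, 1:5]), "dimension")
})

test_that("a converged toy model reconstructs spot expression by tile sums", {
  set.seed(8)
  n <- 30L; l <- 4L; p <- 10L; C <- 8L
  U <- matrix(abs(rnorm(n * 2)), n)
  V <- matrix(abs(rnorm(p * 2)), p)
  Y <- U %*% t(V)
  A <- matrix(rnorm(2L * C, sd = 0.7), 2L, C)
  Xsp <- U %*% A
  X <- Xsp[rep(seq_len(n), each = l), ] +
    matrix(rnorm(n * l * C, sd = 0.02), n * l, C)
  tiles <- make_toy_tiles(n, l)
  cfg <- train_config(K = 16L, h = 4L, epochs = 400L, lr = 3e-3, seed = 4L,
                      train_fraction = 1)
  mdl <- train_finest(list(counts = Y), X, tiles, cfg)
  P <- rowsum(infer_subspot_expression(mdl, X), rep(seq_len(n), each = l))
  cosims <- vapply(seq_len(n), function(k)
    sum(Y[k, ] * P[k, ]) / sqrt(sum(Y[k, ]^2) * sum(P[k, ]^2)), numeric(1))
  expect_true(all(cosims >= 0.9))
})

test_that("held-out retrieval beats chance on 32-candidate panels", {
  mdl <- trained_model()
  s <- default_slide()
  pr <- project_spots(mdl, default_features(), s$tiles, s$bundle)
  test <- mdl$test_spots
  set.seed(6)
  hits <- vapply(test, function(k) {
    panel <- c(k, sample(setdiff(seq_len(nrow(pr$h_expr)), k), 31L))
    sims <- as.numeric(pr$h_image[k, ] %*% t(pr$h_expr[panel, ]))
    which.max(sims) == 1L
  }, logical(1))
  rate <- mean(hits)
  expect_gt(rate, 3 / 32)
  bt <- stats::binom.test(sum(hits), length(hits), p = 1 / 32,
                          alternative = "greater")
  expect_lt(bt$p.value, 0.01)
})

test_that("batch clipping warns when spots are scarce", {
  set.seed(9)
  n <- 6L
  X <- matrix(abs(rnorm(n * 4L * 5L)), n * 4L, 5L)
  Y <- matrix(abs(rnorm(n * 6L)), n, 6L)
  tiles <- make_toy_tiles(n, 4L)
  expect_warning(
    train_finest(list(counts = Y), X, tiles,
                 train_config(K = 64L, h = 3L, epochs = 2L,
                              train_fraction = 1)),
    "clipped")
})
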