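# Communication-pattern discovery: significant LR pairs are clustered into a
# small number of smooth spatial surfaces by EM on a mixture of
# Gaussian-process pattern means (squared-exponential kernel). The sparse
# variant approximates the covariance block-diagonally over spatially
# contiguous groups of locations, dropping the per-iteration solve cost from
# O(M^3) to O(M * group_size^2).

#' Assemble the pattern-clustering input matrix
#'
#' Rows are the eligible pairs (selected by FDR and passing the
#' sparse-pair filter); `binary` mode uses the 0/1 local-significance
#' matrix, `continuous` mode uses `1 - p_local`.
#'
#' @param res a completed `moran_result`.
#' @param mode `"binary"` or `"continuous"`.
#' @return `[eligible pairs x M]` matrix with pair rownames.
#' @export
build_pattern_input <- function(res, mode = c("binary", "continuous")) {
  mode <- match.arg(mode)
  stopifnot(inherits(res, "moran_result"), !is.null(res$local$X_bin))
  keep <- res$pairs$eligible
  if (!any(keep)) stop("no eligible pairs for pattern analysis")
  X <- if (mode == "binary") res$local$X_bin else res$local$X_con
  out <- t(X[, keep, drop = FALSE])
  rownames(out) <- res$pairs$pair[keep]
  out
}

se_kernel_block <- function(xy, lengthscale, noise_floor, rank_cap = NULL) {
  D2 <- as.matrix(stats::dist(xy))^2
  K0 <- exp(-D2 / (2 * lengthscale^2))
  if (!is.null(rank_cap) && is.finite(rank_cap) && rank_cap < nrow(K0)) {
    eg <- eigen(K0, symmetric = TRUE)
    d <- pmax(eg$values[seq_len(rank_cap)], 0)
    K0 <- eg$vectors[, seq_len(rank_cap), drop = FALSE] %*%
      (d * t(eg$vectors[, seq_len(rank_cap), drop = FALSE]))
  }
  K <- K0 + diag(noise_floor, nrow(K0))
  ch <- chol(K)
  list(Kinv = chol2inv(ch), logdet = 2 * sum(log(diag(ch))))
}

aeh_engine <- function(X, coords, n_patterns, lengthscale, blocks,
                       noise_floor, rank_cap, seed, max_iter, tol) {
  G <- nrow(X); M <- ncol(X)
  stopifnot(M == nrow(coords), n_patterns >= 1L)
  if (identical(lengthscale, "auto"))
    lengthscale <- 2 * stats::median(nn_distances(coords))
  kern <- lapply(blocks, function(ix)
    se_kernel_block(coords[ix, , drop = FALSE], lengthscale, noise_floor,
                    rank_cap))
  prior_const <- -0.5 * sum(vapply(kern, `[[`, numeric(1), "logdet")) -
    M / 2 * log(2 * pi)

  set.seed(seed)
  resp <- matrix(0, G, n_patterns)
  if (n_patterns == 1L) {
    resp[, 1] <- 1
  } else {
    km <- tryCatch(
      stats::kmeans(X, centers = n_patterns, nstart = 5L, iter.max = 50L),
      error = function(e) list(cluster = rep(seq_len(n_patterns), length.out = G)))
    resp[cbind(seq_len(G), km$cluster)] <- 1
  }

  s2 <- max(stats::var(as.numeric(X)), 1e-6)
  pi_c <- rep(1 / n_patterns, n_patterns)
  mu <- matrix(0, M, n_patterns)
  trace <- numeric(0)
  obj_prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # M-step: GP-posterior pattern means, then noise and mixture weights
    N_c <- colSums(resp)
    pi_c <- pmax(N_c, 1e-12) / G
    B <- crossprod(resp, X)                         # [patterns x M]
    for (cc in seq_len(n_patterns)) {
      for (bi in seq_along(blocks)) {
        ix <- blocks[[bi]]
        A <- kern[[bi]]$Kinv
        diag(A) <- diag(A) + N_c[cc] / s2
        mu[ix, cc] <- solve(A, B[cc, ix] / s2)
      }
    }
    rss <- 0
    for (cc in seq_len(n_patterns)) {
      d <- sweep(X, 2L, mu[, cc])
      rss <- rss + sum(resp[, cc] * rowSums(d^2))
    }
    s2 <- max(rss / (G * M), 1e-12)

    # E-step + penalized objective (MAP-EM; non-decreasing by construction)
    logd <- matrix(0, G, n_patterns)
    for (cc in seq_len(n_patterns)) {
      d <- sweep(X, 2L, mu[, cc])
      logd[, cc] <- -M / 2 * log(2 * pi * s2) - rowSums(d^2) / (2 * s2) +
        log(pi_c[cc])
    }
    mx <- apply(logd, 1L, max)
    lse <- mx + log(rowSums(exp(logd - mx)))
    resp <- exp(logd - lse)
    prior <- prior_const * n_patterns
    for (cc in seq_len(n_patterns))
      for (bi in seq_along(blocks)) {
        ix <- blocks[[bi]]
        prior <- prior -
          0.5 * sum(mu[ix, cc] * (kern[[bi]]$Kinv %*% mu[ix, cc]))
      }
    obj <- sum(lse) + prior
    trace <- c(trace, obj)
    if (iter > 1L && abs(obj - obj_prev) < tol) { converged <- TRUE; break }
    obj_prev <- obj
  }

  labels <- max.col(resp, ties.method = "first")
  structure(list(n_patterns = n_patterns, labels = labels,
                 responsibilities = resp, pattern_means = mu,
                 lengthscale = lengthscale, noise_floor = noise_floor,
                 s2 = s2, pi = pi_c, log_lik = trace, converged = converged,
                 blocks = blocks,
                 solve_ops = sum(lengths(blocks)^2)),
            class = "pattern_model")
}

#' @export
print.pattern_model <- function(x, ...) {
  cat("pattern_model:", x$n_patterns, "patterns over",
      nrow(x$pattern_means), "locations;", length(x$log_lik),
      "EM iterations", if (x$converged) "(converged)" else "(max iter)", "\n")
  invisible(x)
}

#' Full automatic-expression-histology clustering
#'
#' EM on a mixture of `n_patterns` Gaussian-process pattern surfaces with a
#' squared-exponential kernel `K(d) = exp(-d^2 / (2 lengthscale^2)) +
#' noise_floor I` over all `M` locations (dense covariance; guarded to
#' `M <= 5000`). Responsibilities are initialized by seeded k-means on the
#' input rows; convergence at an objective change below `tol` or `max_iter`
#' iterations.
#'
#' @param X `[pairs x M]` input from [build_pattern_input()].
#' @param coords `[M x 2]` location coordinates.
#' @param n_patterns number of patterns.
#' @param lengthscale kernel lengthscale, or `"auto"` (2 x median
#'   nearest-neighbor distance).
#' @param seed seed for initialization.
#' @param noise_floor kernel jitter (default 1e-5).
#' @param rank_cap optional low-rank cap on the kernel (default none).
#' @param max_iter,tol EM controls.
#' @return A `pattern_model` with labels, responsibilities, `[M x
#'   n_patterns]` pattern-mean surfaces and the objective trace.
#' @export
fit_aeh_full <- function(X, coords, n_patterns, lengthscale = "auto",
                         seed = 1L, noise_floor = 1e-5, rank_cap = NULL,
                         max_iter = 200L, tol = 1e-5) {
  coords <- as.matrix(coords)
  if (ncol(X) > 5000L)
    stop("M = ", ncol(X), " exceeds the dense-covariance guard (5000); ",
         "use fit_aeh_sparse()")
  aeh_engine(X, coords, n_patterns, lengthscale,
             blocks = list(seq_len(ncol(X))), noise_floor, rank_cap, seed,
             max_iter, tol)
}

#' Block-sparse automatic-expression-histology clustering
#'
#' Identical EM to [fit_aeh_full()] but the GP covariance is approximated
#' block-diagonally over spatially contiguous groups of about `group_size`
#' locations (seeded k-means on the coordinates), making the per-iteration
#' solve cost `O(M * group_size^2)`. With `group_size = ncol(X)` the single
#' block reproduces the full model exactly.
#'
#' @inheritParams fit_aeh_full
#' @param group_size target locations per covariance block (default 16).
#' @param rank_cap low-rank cap on each block's kernel (default 30; never
#'   binds at the default `group_size`).
#' @return A `pattern_model`.
#' @export
fit_aeh_sparse <- function(X, coords, n_patterns, group_size = 16L,
                           lengthscale = "auto", seed = 1L,
                           noise_floor = 1e-5, rank_cap = 30L,
                           max_iter = 200L, tol = 1e-5) {
  coords <- as.matrix(coords)
  M <- ncol(X)
  if (group_size > M) stop("group_size exceeds the number of locations")
  n_blocks <- max(1L, round(M / group_size))
  if (n_blocks == 1L) {
    blocks <- list(seq_len(M))
  } else {
    set.seed(seed)
    km <- stats::kmeans(coords, centers = n_blocks, nstart = 3L,
                        iter.max = 100L)
    blocks <- split(seq_len(M), km$cluster)
  }
  aeh_engine(X, coords, n_patterns, lengthscale, blocks, noise_floor,
             rank_cap, seed, max_iter, tol)
}
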