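# Interpretation of discovered interactions: pathway enrichment, signaling
# network extraction, cell-type co-localization and per-pattern abundance.

#' Fisher's exact pathway enrichment of selected LR pairs
#'
#' For every pathway, a 2x2 table over the universe (query-and-pathway,
#' query-only, pathway-only, neither) is tested one-sided (upper tail,
#' hypergeometric). The universe defaults to all tested pairs rather than
#' the full database, so the test conditions on the gene panel.
#'
#' @param query character vector of pair labels (`"LIG:REC"`), a subset of
#'   the universe.
#' @param lr_db an `lr_database` providing the pair-to-pathway map.
#' @param universe character vector of all tested pair labels.
#' @param adjust apply Benjamini-Hochberg to the enrichment p-values
#'   (default `FALSE`; the raw p is the conventional report).
#' @return data.frame sorted by p: `pathway`, `pairs_in_query`,
#'   `pairs_in_pathway`, `query_size`, `universe_size`, `fraction`, `p`
#'   (and `q` when `adjust`).
#' @export
pathway_enrichment <- function(query, lr_db, universe, adjust = FALSE) {
  if (!length(query)) stop("empty query set")
  if (!all(query %in% universe))
    stop("query must be a subset of the universe")
  universe <- unique(universe)
  query <- unique(query)
  lab <- paste(lr_db$pairs$ligand, lr_db$pairs$receptor, sep = ":")
  path_of <- split(lab, lr_db$pairs$pathway)
  N <- length(universe); nq <- length(query)
  rows <- lapply(names(path_of), function(pw) {
    in_path <- intersect(path_of[[pw]], universe)
    Kp <- length(in_path)
    if (Kp == 0L) return(NULL)
    a <- length(intersect(query, in_path))
    p <- stats::phyper(a - 1, Kp, N - Kp, nq, lower.tail = FALSE)
    data.frame(pathway = pw, pairs_in_query = a, pairs_in_pathway = Kp,
               query_size = nq, universe_size = N, fraction = a / Kp, p = p)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$pathway), , drop = FALSE]
}

#' Extract the L-R-TF-TG signaling network of a pattern
#'
#' Chain construction: the pattern's LR pairs give the L->R layer; their
#' receptors (complexes matched by full name or by subunit) seed R->TF
#' edges from the receptor-TF table; the resulting TFs seed TF->TG edges.
#' A receptor absent from the R-TF table still contributes its L->R edge.
#'
#' @param pattern_pairs data.frame with columns `ligand`, `receptor` (one
#'   row per LR pair in the pattern).
#' @param rtf_table data.frame with columns `receptor`, `tf` and optional
#'   `score`.
#' @param tftg_table data.frame with columns `tf`, `target`.
#' @param min_rtf_score optional lower bound on the R-TF association score.
#' @return A `network_module`: `$edges` (columns `from`, `to`, `type` in
#'   {L->R, R->TF, TF->TG}, `score`) and `$nodes` (name, role).
#' @export
extract_lr_tf_tg <- function(pattern_pairs, rtf_table, tftg_table,
                             min_rtf_score = NULL) {
  need_cols <- function(df, cols, what)
    for (cl in cols) if (!cl %in% names(df))
      stop("malformed ", what, " table: missing column '", cl, "'")
  need_cols(pattern_pairs, c("ligand", "receptor"), "pattern pair")
  need_cols(rtf_table, c("receptor", "tf"), "R-TF")
  need_cols(tftg_table, c("tf", "target"), "TF-TG")
  pp <- unique(pattern_pairs[, c("ligand", "receptor")])
  lr <- data.frame(from = pp$ligand, to = pp$receptor, type = "L->R",
                   score = NA_real_)
  rec_keys <- unique(c(pp$receptor,
                       unlist(strsplit(pp$receptor, "_", fixed = TRUE))))
  rt <- rtf_table[rtf_table$receptor %in% rec_keys, , drop = FALSE]
  if (!is.null(min_rtf_score) && "score" %in% names(rt))
    rt <- rt[rt$score >= min_rtf_score, , drop = FALSE]
  rtf <- if (nrow(rt))
    data.frame(from = rt$receptor, to = rt$tf, type = "R->TF",
               score = if ("score" %in% names(rt)) rt$score else NA_real_)
  else NULL
  tfs <- unique(if (!is.null(rtf)) rtf$to else character(0))
  tg <- tftg_table[tftg_table$tf %in% tfs, , drop = FALSE]
  tftg <- if (nrow(tg))
    data.frame(from = tg$tf, to = tg$target, type = "TF->TG",
               score = NA_real_)
  else NULL
  edges <- unique(rbind(lr, rtf, tftg))
  rownames(edges) <- NULL
  role <- c(stats::setNames(rep("ligand", length(unique(pp$ligand))),
                            unique(pp$ligand)),
            stats::setNames(rep("receptor", length(unique(pp$receptor))),
                            unique(pp$receptor)),
            stats::setNames(rep("tf", length(tfs)), tfs),
            stats::setNames(rep("target", length(unique(tg$target))),
                            unique(tg$target)))
  role <- role[!duplicated(names(role))]
  structure(list(edges = edges,
                 nodes = data.frame(name = names(role), role = unname(role),
                                    row.names = NULL)),
            class = "network_module")
}

#' @export
print.network_module <- function(x, ...) {
  cat("network_module:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      paste(names(table(x$edges$type)), table(x$edges$type), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Write a network module as SIF
#' @param module a `network_module`.
#' @param path output path.
#' @export
write_sif <- function(module, path) {
  utils::write.table(module$edges[, c("from", "type", "to")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Cell-type spatial co-localization
#'
#' Bivariate global Moran's R for every unordered pair of cell-type
#' abundance fields; self-pairs are reported but flagged.
#'
#' @param abundance `[locations x cell types]` non-negative matrix.
#' @param weights a [build_weights()] object on the same locations.
#' @return data.frame: `type_a`, `type_b`, `R_global`, `z`, `p`, `self`.
#'   Zero-variance types are excluded with a message.
#' @export
colocalization <- function(abundance, weights) {
  abundance <- as.matrix(abundance)
  if (ncol(abundance) < 2L) stop("need at least 2 cell types")
  if (is.null(colnames(abundance)))
    colnames(abundance) <- paste0("type", seq_len(ncol(abundance)))
  v <- apply(abundance, 2L, stats::var)
  if (any(v == 0)) {
    message("excluding zero-variance type(s): ",
            paste(colnames(abundance)[v == 0], collapse = ", "))
    abundance <- abundance[, v > 0, drop = FALSE]
  }
  tt <- colnames(abundance)
  combs <- expand.grid(a = seq_along(tt), b = seq_along(tt))
  combs <- combs[combs$a <= combs$b, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combs)), function(i) {
    a <- combs$a[i]; b <- combs$b[i]
    g <- global_moran_r(abundance[, a], abundance[, b], weights)
    data.frame(type_a = tt[a], type_b = tt[b], R_global = g$R_global,
               z = g$z, p = g$p, self = a == b)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cell-type abundance within each communication pattern
#'
#' Each pattern's mean surface (clipped at zero and normalized over
#' locations) weights the per-location cell-type abundances; the weighted
#' type totals are normalized to proportions per pattern.
#'
#' @param pattern_model a `pattern_model`.
#' @param celltype_by_location `[locations x types]` non-negative matrix.
#' @return `[types x patterns]` matrix of proportions (columns sum to 1).
#' @export
cell_abundance_per_pattern <- function(pattern_model, celltype_by_location) {
  A <- as.matrix(celltype_by_location)
  if (any(A < 0)) stop("cell-type abundances must be non-negative")
  mu <- pattern_model$pattern_means
  if (nrow(A) != nrow(mu))
    stop("location count mismatch: ", nrow(A), " vs ", nrow(mu))
  out <- vapply(seq_len(ncol(mu)), function(cc) {
    w <- pmax(mu[, cc], 0)
    if (sum(w) == 0) w <- rep(1, length(w))
    w <- w / sum(w)
    tot <- as.numeric(crossprod(A, w))
    tot / sum(tot)
  }, numeric(ncol(A)))
  dimnames(out) <- list(colnames(A), paste0("pattern", seq_len(ncol(mu))))
  out
}
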