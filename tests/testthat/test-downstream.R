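test_that("enrichment p equals the hypergeometric closed form", {
  # worked 2x2 example: pathway of 5 fully inside a query of 10 from 20
  db <- lr_database(data.frame(
    ligand = paste0("L", 1:20), receptor = paste0("R", 1:20),
    pathway = rep(c("PWa", "PWother"), c(5, 15))))
  universe <- paste0("L", 1:20, ":R", 1:20)
  query <- universe[1:10]                       # contains all 5 of PWa
  et <- pathway_enrichment(query, db, universe)
  expect_equal(et$p[et$pathway == "PWa"], 3003 / 184756)
  expect_equal(et$fraction[et$pathway == "PWa"], 1)
  # query == pathway == universe: no enrichment possible
  db1 <- lr_database(data.frame(ligand = "L1", receptor = "R1",
                                pathway = "PW"))
  expect_equal(pathway_enrichment("L1:R1", db1, "L1:R1")$p, 1)
  # disjoint query and pathway: upper-tail p = 1
  q2 <- universe[6:10]
  expect_equal(
    pathway_enrichment(q2, db, universe)$p[
      pathway_enrichment(q2, db, universe)$pathway == "PWa"], 1)
  expect_error(pathway_enrichment(character(0), db, universe), "empty")
  expect_error(pathway_enrichment("X:Y", db, universe), "subset")
})

test_that("Fisher p matches an explicit choose-sum over swept margins", {
  # oracle: direct hypergeometric tail sum from binomial coefficients
  tail_sum <- function(a, K, N, n) {
    js <- a:min(K, n)
    sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
  }
  worst <- 0
  for (N in c(5L, 11L, 23L, 37L, 50L)) {
    for (K in seq(1L, N, by = 2L)) {
      for (n in seq(1L, N, by = 3L)) {
        for (a in max(0L, K + n - N):min(K, n)) {
          p_pkg <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
          worst <- max(worst, abs(p_pkg - tail_sum(a, K, N, n)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("enrichment is monotone in query membership", {
  db <- lr_database(data.frame(
    ligand = paste0("L", 1:20), receptor = paste0("R", 1:20),
    pathway = rep(c("PWa", "PWb"), each = 10)))
  universe <- paste0("L", 1:20, ":R", 1:20)
  q <- universe[c(1:3, 11:14)]
  p0 <- pathway_enrichment(q, db, universe)
  p1 <- pathway_enrichment(c(q, universe[4]), db, universe)  # +1 PWa member
  expect_lte(p1$p[p1$pathway == "PWa"], p0$p[p0$pathway == "PWa"])
})

test_that("network extraction builds the L-R-TF-TG chain", {
  rtf <- data.frame(receptor = c("R1", "R9"), tf = c("TF1", "TFX"),
                    score = c(0.8, 0.2))
  tftg <- data.frame(tf = c("TF1", "TFZ"), target = c("G1", "GZ"))
  nm <- extract_lr_tf_tg(data.frame(ligand = "L1", receptor = "R1"),
                         rtf, tftg)
  expect_equal(nrow(nm$edges), 3L)
  expect_setequal(nm$edges$type, c("L->R", "R->TF", "TF->TG"))
  # receptor absent from the R-TF table: only the L->R layer
  nm2 <- extract_lr_tf_tg(data.frame(ligand = "L2", receptor = "R2"),
                          rtf, tftg)
  expect_equal(nm2$edges$type, "L->R")
  # shared receptor deduplicates the TF layer; edge count by hand
  pp <- data.frame(ligand = c("La", "Lb"), receptor = c("R1", "R1"))
  rtf5 <- data.frame(receptor = c("R1", "R1", "R2", "R1", "R2"),
                     tf = c("TF1", "TF2", "TF3", "TF1", "TF1"),
                     score = 1:5 / 5)
  tftg5 <- data.frame(tf = c("TF1", "TF2", "TF9"),
                      target = c("G1", "G2", "G9"))
  nm3 <- extract_lr_tf_tg(pp, rtf5, tftg5)
  # 2 L->R + 2 unique R->TF (TF1 dup dropped... scores differ so rows kept)
  expect_equal(sum(nm3$edges$type == "L->R"), 2L)
  expect_equal(length(unique(nm3$edges$to[nm3$edges$type == "R->TF"])), 2L)
  expect_equal(sum(nm3$edges$type == "TF->TG"), 2L)
  # order independence
  nm4 <- extract_lr_tf_tg(pp[2:1, ], rtf5[sample(5), ], tftg5[3:1, ])
  expect_setequal(paste(nm3$edges$from, nm3$edges$to, nm3$edges$type),
                  paste(nm4$edges$from, nm4$edges$to, nm4$edges$type))
  expect_error(extract_lr_tf_tg(pp, data.frame(r = 1), tftg5),
               "missing column")
})

test_that("co-localization reflects spatial arrangement of cell types", {
  co <- as.matrix(expand.grid(x = seq_len(10) * 5, y = seq_len(10) * 5))
  w <- build_weights(co, cutoff = 4L)
  left <- as.numeric(co[, 1] < 26)
  set.seed(3)
  ab <- cbind(A = left + runif(100, 0, 0.01),
              B = left + runif(100, 0, 0.01),
              C = 1 - left + runif(100, 0, 0.01))
  cl <- colocalization(ab, w)
  get <- function(a, b) cl$R_global[cl$type_a == a & cl$type_b == b]
  # duplicated field behaves like the self pair
  expect_equal(get("A", "B"), get("A", "A"), tolerance = 0.01)
  # disjoint halves anticorrelate
  expect_lt(get("A", "C"), 0)
  expect_true(all(cl$self == (cl$type_a == cl$type_b)))
  # zero-variance types are excluded
  expect_message(colocalization(cbind(ab, D = rep(1, 100)), w), "zero-var")
  # independent abundances are rarely significant
  co2 <- as.matrix(expand.grid(x = seq_len(20) * 5, y = seq_len(10) * 5))
  w2 <- build_weights(co2, cutoff = 4L)
  set.seed(4)
  ps <- replicate(60, {
    ab0 <- cbind(runif(200), runif(200))
    colocalization(ab0, w2)$p[2]   # the single cross pair
  })
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("pattern cell abundance weights locations by the surface", {
  types <- cbind(A = c(1, 0, 2, 0), B = c(0, 1, 0, 3))
  pm1 <- list(pattern_means = cbind(rep(1, 4)))
  out <- cell_abundance_per_pattern(pm1, types)
  expect_equal(unname(out[, 1]), c(3, 4) / 7)   # global proportions
  # mass entirely on pure-type-A locations
  pm2 <- list(pattern_means = cbind(c(1, 0, 1, 0)))
  expect_equal(unname(cell_abundance_per_pattern(pm2, types)[, 1]), c(1, 0))
  # two-pattern worked example
  pm3 <- list(pattern_means = cbind(c(2, 2, 0, 0), c(0, 0, 1, 1)))
  out3 <- cell_abundance_per_pattern(pm3, types)
  expect_equal(unname(out3[, 1]), c(0.5, 0.5))        # rows 1-2 equally
  expect_equal(unname(out3[, 2]), c(2, 3) / 5)        # rows 3-4 equally
  expect_equal(unname(colSums(out3)), c(1, 1))
  expect_error(cell_abundance_per_pattern(pm1, -types), "non-negative")
})
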