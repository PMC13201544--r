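# Seeded generator of complete synthetic slides with known sub-spot truth.
# The rendering scale is fixed at 1 px = 0.5 synthetic um, so the default
# 14-px tile is about the size of one cell (7 um). Cell types occupy smooth
# density territories and carry type-specific marker expression and hue, so
# image features hold real signal for the model; ligand/receptor genes are
# spatially flat except where a planted pair boosts both genes inside its
# hotspot regions, giving the spatial statistics a known positive set and a
# known null set.

#' Synthetic slide configuration
#'
#' @param n_rows,n_cols spot lattice shape (default 20 x 20).
#' @param platform `"visium"` (hexagonal lattice) or `"generic"` /
#'   `"visiumhd"` (square).
#' @param pitch_px center-to-center spot pitch in pixels (default 64, i.e.
#'   32 synthetic um).
#' @param patch_px,grid patch side and tile grid used for the ground-truth
#'   tiling (defaults 56 px / 4, i.e. cell-sized 14-px tiles).
#' @param n_types number of cell types (default 3).
#' @param n_genes total genes: `2 * n_lr_pairs` ligand/receptor genes, the
#'   rest type markers (default 60).
#' @param n_lr_pairs LR pairs emitted in the database (default 15).
#' @param n_planted pairs with planted spatial co-expression (default 5).
#' @param n_cells target cell count (default 1500).
#' @param noise_sd per-cell log-normal expression jitter (default 0.3).
#' @param hotspot_boost rate multiplier inside a planted pair's hotspots
#'   (default 6, a strong focal upregulation).
#' @param hotspot_radius hotspot radius in pixels (default 3 x pitch; each
#'   planted pair gets two hotspots covering roughly 15% of the tissue).
#' @param mean_expr base per-cell per-gene rate scale (default 1).
#' @param render_image render the RGB raster (default `TRUE`; switching it
#'   off leaves a tiny blank image for expression-only studies).
#' @return A `slide_config` list.
#' @export
slide_config <- function(n_rows = 20L, n_cols = 20L, platform = "visium",
                         pitch_px = 64, patch_px = 56L, grid = 4L,
                         n_types = 3L, n_genes = 60L, n_lr_pairs = 15L,
                         n_planted = 5L, n_cells = 1500L, noise_sd = 0.3,
                         hotspot_boost = 6, hotspot_radius = 3 * pitch_px,
                         mean_expr = 1, render_image = TRUE) {
  stopifnot(n_rows >= 4L, n_cols >= 4L, n_types >= 2L, n_genes >= 10L,
            n_planted <= n_lr_pairs, 2L * n_lr_pairs < n_genes)
  as.list(environment())
}

hex_lattice <- function(cfg, margin) {
  r <- rep(seq_len(cfg$n_rows) - 1L, each = cfg$n_cols)
  cc <- rep(seq_len(cfg$n_cols) - 1L, cfg$n_rows)
  if (cfg$platform == "visium") {
    x <- margin + cc * cfg$pitch_px + (r %% 2L) * cfg$pitch_px / 2
    y <- margin + r * cfg$pitch_px * sqrt(3) / 2
  } else {
    x <- margin + cc * cfg$pitch_px
    y <- margin + r * cfg$pitch_px
  }
  data.frame(spot_id = sprintf("s%04d", seq_along(x)), x = x, y = y)
}

render_cells <- function(H, W, cells, type_cols, rng_noise = 6) {
  img <- array(0, c(H, W, 3))
  img[, , 1] <- 236; img[, , 2] <- 222; img[, , 3] <- 228  # eosin background
  img <- img + array(stats::runif(H * W * 3, -rng_noise, rng_noise),
                     c(H, W, 3))
  rad <- 8L; sigma <- 3
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]; cy <- cells$y[i]
    r0 <- max(1L, round(cy) - rad); r1 <- min(H, round(cy) + rad)
    c0 <- max(1L, round(cx) - rad); c1 <- min(W, round(cx) + rad)
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; ccx <- c0:c1
    w <- exp(-(outer((rr - 1 - cy)^2, (ccx - 1 - cx)^2, `+`)) / (2 * sigma^2))
    col <- type_cols[cells$type[i], ]
    for (ch in 1:3)
      img[rr, ccx, ch] <- img[rr, ccx, ch] * (1 - w) + col[ch] * w
  }
  pmin(pmax(img, 0), 255)
}

make_slide_impl <- function(config, seed, planted, shuffle_types) {
  cfg <- config
  set.seed(seed)
  margin <- cfg$patch_px
  coords <- hex_lattice(cfg, margin)
  H <- ceiling(max(coords$y) + margin)
  W <- ceiling(max(coords$x) + margin)

  # --- cell positions and types ------------------------------------------
  n_cells <- cfg$n_cells
  cx <- stats::runif(n_cells, min(coords$x) - cfg$pitch_px / 2,
                     max(coords$x) + cfg$pitch_px / 2)
  cy <- stats::runif(n_cells, min(coords$y) - cfg$pitch_px / 2,
                     max(coords$y) + cfg$pitch_px / 2)
  n_types <- cfg$n_types
  anchors <- lapply(seq_len(n_types), function(t)
    cbind(stats::runif(2L, min(coords$x), max(coords$x)),
          stats::runif(2L, min(coords$y), max(coords$y))))
  bw <- 4 * cfg$pitch_px
  dens <- vapply(seq_len(n_types), function(t) {
    a <- anchors[[t]]
    rowSums(vapply(seq_len(nrow(a)), function(k)
      exp(-((cx - a[k, 1])^2 + (cy - a[k, 2])^2) / (2 * bw^2)),
      numeric(n_cells))) + 0.08
  }, numeric(n_cells))
  type <- if (shuffle_types) {
    sample.int(n_types, n_cells, replace = TRUE)
  } else {
    apply(dens, 1L, function(p) sample.int(n_types, 1L, prob = p))
  }
  cells <- data.frame(x = cx, y = cy, type = type)

  # --- gene panel ---------------------------------------------------------
  n_lr <- cfg$n_lr_pairs
  lig_genes <- sprintf("LG%02d", seq_len(n_lr))
  rec_genes <- sprintf("RC%02d", seq_len(n_lr))
  n_marker <- cfg$n_genes - 2L * n_lr
  mk_genes <- sprintf("MK%02d", seq_len(n_marker))
  genes <- c(mk_genes, lig_genes, rec_genes)
  # type-specific marker means; LR genes flat across types
  mean_mat <- matrix(0, n_types, cfg$n_genes, dimnames = list(NULL, genes))
  mean_mat[, mk_genes] <- cfg$mean_expr *
    exp(matrix(stats::rnorm(n_types * n_marker, sd = 1), n_types))
  lr_base <- cfg$mean_expr * exp(stats::rnorm(2L * n_lr, sd = 0.4))
  mean_mat[, c(lig_genes, rec_genes)] <- rep(lr_base, each = n_types)

  # --- planted hotspots ----------------------------------------------------
  planted_tab <- NULL
  boost <- matrix(1, n_cells, cfg$n_genes, dimnames = list(NULL, genes))
  if (planted > 0L) {
    # hotspot centers stay a radius away from the tissue edge when the
    # slide is large enough; small slides fall back to the full extent
    place_range <- function(v) {
      lo <- min(v) + cfg$hotspot_radius; hi <- max(v) - cfg$hotspot_radius
      if (lo >= hi) c(min(v), max(v)) else c(lo, hi)
    }
    rx <- place_range(coords$x); ry <- place_range(coords$y)
    rows <- lapply(seq_len(planted), function(i) {
      hx <- stats::runif(2L, rx[1], rx[2])
      hy <- stats::runif(2L, ry[1], ry[2])
      inside <- rep(FALSE, n_cells)
      for (k in 1:2)
        inside <- inside |
          ((cx - hx[k])^2 + (cy - hy[k])^2 < cfg$hotspot_radius^2)
      boost[inside, c(lig_genes[i], rec_genes[i])] <<- cfg$hotspot_boost
      data.frame(pair = paste(lig_genes[i], rec_genes[i], sep = ":"),
                 ligand = lig_genes[i], receptor = rec_genes[i],
                 hx1 = hx[1], hy1 = hy[1], hx2 = hx[2], hy2 = hy[2],
                 radius = cfg$hotspot_radius, effect = cfg$hotspot_boost)
    })
    planted_tab <- do.call(rbind, rows)
  }

  # --- per-cell expression rates ------------------------------------------
  jitter <- exp(matrix(stats::rnorm(n_cells * cfg$n_genes, sd = cfg$noise_sd),
                       n_cells))
  cell_expr <- mean_mat[cells$type, , drop = FALSE] * jitter * boost

  # --- image ----------------------------------------------------------------
  type_cols <- cbind(
    130 + 90 * cos(2 * pi * (seq_len(n_types) - 1) / n_types),
    90 + 50 * sin(2 * pi * (seq_len(n_types) - 1) / n_types),
    150 + 70 * cos(2 * pi * (seq_len(n_types) - 1) / n_types + 1))
  img <- if (cfg$render_image) render_cells(H, W, cells, type_cols)
         else {
           blank <- array(200, c(H, W, 3))
           blank
         }

  # --- tiling and ground truth --------------------------------------------
  bundle0 <- slide_bundle(img, coords,
                          matrix(0L, nrow(coords), cfg$n_genes,
                                 dimnames = list(coords$spot_id, genes)),
                          gene_names = genes,
                          spot_diameter_px = cfg$patch_px,
                          platform_tag = if (cfg$platform == "visium")
                            "visium" else "generic")
  tiles <- tile_slide(bundle0, patch_px = cfg$patch_px, grid = cfg$grid)
  df <- tiles$tiles
  # assign cells to the tile of their nearest spot's patch
  sxy <- cbind(coords$x, coords$y)
  nearest <- vapply(seq_len(n_cells), function(i)
    which.min((sxy[, 1] - cx[i])^2 + (sxy[, 2] - cy[i])^2), integer(1))
  t_px <- cfg$patch_px / cfg$grid
  half <- cfg$patch_px / 2
  ti <- floor((cy - (sxy[nearest, 2] - half)) / t_px)
  tj <- floor((cx - (sxy[nearest, 1] - half)) / t_px)
  in_patch <- ti >= 0 & ti < cfg$grid & tj >= 0 & tj < cfg$grid
  # row-major tile index within the parent's block of grid^2 rows
  tile_of_cell <- ifelse(in_patch,
                         (nearest - 1L) * cfg$grid^2 + ti * cfg$grid + tj + 1L,
                         NA_integer_)
  tile_truth <- matrix(0, nrow(df), cfg$n_genes,
                       dimnames = list(NULL, genes))
  has_tile <- which(!is.na(tile_of_cell))
  if (length(has_tile)) {
    agg <- rowsum(cell_expr[has_tile, , drop = FALSE],
                  group = tile_of_cell[has_tile])
    tile_truth[as.integer(rownames(agg)), ] <- agg
  }
  spot_rate <- rowsum(tile_truth, group = df$parent, reorder = TRUE)
  counts <- matrix(stats::rpois(length(spot_rate), lambda = spot_rate),
                   nrow(spot_rate), dimnames = dimnames(spot_rate))

  # --- LR database, pathways, edge tables ---------------------------------
  pathways <- paste0("PW", ((seq_len(n_lr) - 1L) %% 4L) + 1L)
  if (planted > 0L) pathways[seq_len(planted)] <- "PW1"
  lr_db <- lr_database(data.frame(ligand = lig_genes, receptor = rec_genes,
                                  pathway = pathways))
  tfs <- sprintf("TF%02d", seq_len(n_lr))
  rtf_table <- data.frame(receptor = rep(rec_genes, each = 2L),
                          tf = c(rbind(tfs, tfs[c(2:n_lr, 1L)])),
                          score = round(stats::runif(2L * n_lr), 3))
  tftg_table <- data.frame(tf = rep(tfs, each = 2L),
                           target = sprintf("TG%02d", seq_len(2L * n_lr)))

  bundle <- slide_bundle(img, coords, counts, gene_names = genes,
                         spot_diameter_px = cfg$patch_px,
                         platform_tag = bundle0$platform_tag, lr_db = lr_db)
  type_frac <- prop.table(
    table(factor(nearest, levels = seq_len(nrow(coords))),
          factor(cells$type, levels = seq_len(n_types))), margin = 1L)
  type_frac[is.na(type_frac)] <- 0

  list(bundle = bundle, tiles = tiles, lr_db = lr_db,
       nuclei_centers = cells[, c("x", "y")],
       rtf_table = rtf_table, tftg_table = tftg_table,
       truth = list(cell_centers = cells[, c("x", "y")],
                    cell_types = cells$type, cell_expr = cell_expr,
                    tile_truth = tile_truth, spot_rate = spot_rate,
                    planted = planted_tab,
                    spot_type_fractions = unclass(as.matrix(type_frac)),
                    config = cfg, seed = seed))
}

#' Generate a complete synthetic slide with known truth
#'
#' Emits everything the pipeline consumes: a `slide_bundle` (image, spot
#' coordinates, Poisson counts, LR database), the ground-truth tile set and
#' tile-level expression, nuclei centers (the cell centers), cell types and
#' R-TF / TF-TG edge tables. All outputs are reproducible from
#' `(config, seed)`. For every spot, the truth tile expression sums exactly
#' to the pre-noise spot rate.
#'
#' @param config a [slide_config()].
#' @param seed integer seed.
#' @return list with `bundle`, `tiles`, `lr_db`, `nuclei_centers`,
#'   `rtf_table`, `tftg_table` and `truth` (cell centers/types/expression,
#'   `tile_truth`, `spot_rate`, the planted-pair table, per-spot type
#'   fractions).
#' @export
make_slide <- function(config = slide_config(), seed = 1L) {
  make_slide_impl(config, seed, planted = config$n_planted,
                  shuffle_types = FALSE)
}

#' Generate a matched null slide
#'
#' Identical pipeline with hotspots removed and cell types spatially
#' shuffled; used for calibration studies.
#'
#' @inheritParams make_slide
#' @export
make_null_slide <- function(config = slide_config(), seed = 1L) {
  make_slide_impl(config, seed, planted = 0L, shuffle_types = TRUE)
}

#' Write the synthetic fixture in the on-disk formats the readers consume
#'
#' @param slide output of [make_slide()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_slide_fixture <- function(slide, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bundle(slide$bundle, dir)
  utils::write.csv(slide$nuclei_centers, file.path(dir, "nuclei.csv"),
                   row.names = FALSE)
  utils::write.csv(slide$rtf_table, file.path(dir, "rtf.csv"),
                   row.names = FALSE)
  utils::write.csv(slide$tftg_table, file.path(dir, "tftg.csv"),
                   row.names = FALSE)
  write_tiles(slide$tiles, file.path(dir, "tiles.tsv"))
  invisible(dir)
}
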