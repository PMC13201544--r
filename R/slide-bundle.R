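#' Assemble a slide bundle
#'
#' A `slide_bundle` is the unit every pipeline stage consumes: the RGB
#' histology raster, spot center coordinates in full-resolution pixels, the
#' spot-by-gene count matrix and the ligand-receptor database.
#'
#' @param image numeric array `[H x W x 3]`, channel values in `[0, 255]`.
#' @param spot_coords data.frame with columns `spot_id`, `x`, `y`
#'   (`x` = pixel column, `y` = pixel row, 0-based origin at the top-left).
#' @param counts non-negative matrix `[n_spots x n_genes]`; row order must
#'   match `spot_coords`.
#' @param gene_names character vector of gene symbols (one per column).
#' @param spot_diameter_px positive scalar, spot diameter in pixels.
#' @param platform_tag one of `"visium"` (hexagonal lattice), `"visiumhd"`
#'   or `"generic"` (square lattice).
#' @param lr_db optional `lr_database` attached for downstream stages.
#'
#' @return An object of class `slide_bundle`.
#' @export
slide_bundle <- function(image, spot_coords, counts, gene_names = colnames(counts),
                         spot_diameter_px, platform_tag = c("visium", "visiumhd", "generic"),
                         lr_db = NULL) {
  platform_tag <- match.arg(platform_tag)
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("`image` must be an [H x W x 3] RGB array")
  counts <- as.matrix(counts)
  if (!is.data.frame(spot_coords) || !all(c("spot_id", "x", "y") %in% names(spot_coords)))
    stop("`spot_coords` needs columns spot_id, x, y")
  if (nrow(spot_coords) != nrow(counts))
    stop("coordinate rows (", nrow(spot_coords), ") != count rows (", nrow(counts), ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.numeric(spot_diameter_px) || spot_diameter_px <= 0)
    stop("`spot_diameter_px` must be positive")
  H <- dim(image)[1]; W <- dim(image)[2]
  if (any(spot_coords$x < 0 | spot_coords$x >= W | spot_coords$y < 0 | spot_coords$y >= H))
    stop("spot coordinates fall outside the image bounds [", H, " x ", W, "]")
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(ncol(counts)))
  colnames(counts) <- gene_names
  rownames(counts) <- spot_coords$spot_id
  structure(
    list(image = image, spot_coords = spot_coords, counts = counts,
         gene_names = gene_names, spot_ids = as.character(spot_coords$spot_id),
         spot_diameter_px = spot_diameter_px, platform_tag = platform_tag,
         lr_db = lr_db),
    class = "slide_bundle")
}

#' @export
print.slide_bundle <- function(x, ...) {
  cat("slide_bundle:", nrow(x$counts), "spots x", ncol(x$counts), "genes;",
      "image", dim(x$image)[1], "x", dim(x$image)[2], "px;",
      "platform", x$platform_tag, "\n")
  invisible(x)
}

#' @export
dim.slide_bundle <- function(x) dim(x$counts)

#' Parse a ligand-receptor database table
#'
#' Reads a CellChatDB-style export with columns `ligand`, `receptor`,
#' `pathway`. Multi-subunit complexes are encoded by joining gene symbols
#' with `"_"` (e.g. `FZD9_LRP6`).
#'
#' @param x path to a CSV file, or a data.frame with those columns.
#' @return An `lr_database`: the pair table plus parsed subunit lists and the
#'   union of all subunit gene symbols (`lr_gene_set`).
#' @export
lr_database <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop("LR database file not found: ", x)
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "pathway")
  if (!all(need %in% names(df)))
    stop("LR database must have columns ", paste(need, collapse = ", "))
  lig_sub <- strsplit(df$ligand, "_", fixed = TRUE)
  rec_sub <- strsplit(df$receptor, "_", fixed = TRUE)
  if (any(lengths(lig_sub) == 0L) || any(lengths(rec_sub) == 0L))
    stop("empty ligand or receptor subunit list in LR database")
  structure(
    list(pairs = df[, need], ligand_subunits = lig_sub, receptor_subunits = rec_sub,
         lr_gene_set = unique(c(unlist(lig_sub), unlist(rec_sub)))),
    class = "lr_database")
}

#' @export
print.lr_database <- function(x, ...) {
  cat("lr_database:", nrow(x$pairs), "pairs,", length(x$lr_gene_set), "genes,",
      length(unique(x$pairs$pathway)), "pathways\n")
  invisible(x)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

read_counts_file <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    genes_path <- file.path(dirname(path), "genes.tsv")
    spots_path <- file.path(dirname(path), "spots.tsv")
    if (file.exists(genes_path))
      colnames(m) <- utils::read.table(genes_path, stringsAsFactors = FALSE)[[1]]
    if (file.exists(spots_path))
      rownames(m) <- utils::read.table(spots_path, stringsAsFactors = FALSE)[[1]]
    m
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                            check.names = FALSE)
    as.matrix(df)
  }
}

#' Load a slide bundle from disk
#'
#' @param counts_path dense TSV (spots x genes, first column = spot id) or a
#'   Matrix Market `.mtx` with `genes.tsv` / `spots.tsv` sidecars.
#' @param coords_path TSV with columns `spot_id`, `x`, `y` in full-resolution
#'   pixels.
#' @param image_path RGB PNG or TIFF.
#' @param lr_db_path optional LR database CSV (`ligand,receptor,pathway`).
#' @param platform_tag,spot_diameter_px see [slide_bundle()].
#'
#' @details Spot order follows the coordinate file. Duplicated gene symbols
#'   keep their first occurrence (with a warning). Spot identifiers present
#'   in one file but not the other raise a consistency error listing the
#'   offenders.
#' @return A validated `slide_bundle`.
#' @export
load_slide <- function(counts_path, coords_path, image_path, lr_db_path = NULL,
                       platform_tag = "visium", spot_diameter_px = NULL) {
  for (p in c(counts_path, coords_path, image_path))
    if (!file.exists(p)) stop("input file not found: ", p)
  counts <- read_counts_file(counts_path)
  coords <- utils::read.table(coords_path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(coords)))
    stop("coords file must have columns spot_id, x, y: ", coords_path)
  coords$spot_id <- as.character(coords$spot_id)
  miss_in_counts <- setdiff(coords$spot_id, rownames(counts))
  miss_in_coords <- setdiff(rownames(counts), coords$spot_id)
  if (length(miss_in_counts) || length(miss_in_coords))
    stop("spot id mismatch between counts and coords; missing in counts: [",
         paste(utils::head(miss_in_counts, 5), collapse = ", "),
         "]; missing in coords: [",
         paste(utils::head(miss_in_coords, 5), collapse = ", "), "]")
  counts <- counts[coords$spot_id, , drop = FALSE]
  if (anyDuplicated(colnames(counts))) {
    warning("duplicate gene names in counts; keeping first occurrence")
    counts <- counts[, !duplicated(colnames(counts)), drop = FALSE]
  }
  img <- read_image_file(image_path)
  lr_db <- if (!is.null(lr_db_path)) lr_database(lr_db_path) else NULL
  if (is.null(spot_diameter_px)) {
    d <- nn_distances(coords[, c("x", "y")])
    spot_diameter_px <- stats::median(d) * 0.55
  }
  slide_bundle(img, coords[, c("spot_id", "x", "y")], counts,
               gene_names = colnames(counts),
               spot_diameter_px = spot_diameter_px,
               platform_tag = platform_tag, lr_db = lr_db)
}

#' Write / read a slide bundle snapshot directory
#'
#' Plain-text checkpoint of the expression side of a bundle (counts TSV,
#' coords TSV, gene list); the image is stored as PNG.
#' @param bundle a `slide_bundle`.
#' @param dir snapshot directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    data.frame(spot_id = bundle$spot_ids, bundle$counts, check.names = FALSE),
    file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$spot_coords, file.path(dir, "coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$gene_names, file.path(dir, "genes.txt"))
  png::writePNG(bundle$image / 255, file.path(dir, "image.png"))
  meta <- list(spot_diameter_px = bundle$spot_diameter_px,
               platform_tag = bundle$platform_tag)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  if (!is.null(bundle$lr_db))
    utils::write.csv(bundle$lr_db$pairs, file.path(dir, "lr_db.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  lr_path <- file.path(dir, "lr_db.csv")
  load_slide(file.path(dir, "counts.tsv"), file.path(dir, "coords.tsv"),
             file.path(dir, "image.png"),
             lr_db_path = if (file.exists(lr_path)) lr_path else NULL,
             platform_tag = meta$platform_tag,
             spot_diameter_px = meta$spot_diameter_px)
}

# Nearest-neighbor distance of every point to any other point.
nn_distances <- function(xy) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 2L) return(numeric(0))
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  apply(d, 1L, min)
}
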