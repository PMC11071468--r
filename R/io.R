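# Readers for platform transcript-table dialects and writers for the
# standard downstream formats (MatrixMarket counts, CSV metadata, GeoJSON
# boundaries).

#' Transcript-table column dialects
#'
#' Column-name maps, unassigned sentinels and negative-control name patterns
#' for the common imaging spatial transcriptomics platforms.  Coordinates
#' must be micrometres; `coord_scale` converts pixel dialects (CosMx global
#' pixel coordinates default to 0.12028 um per px).
#'
#' @param name one of `"generic"`, `"xenium"`, `"merscope"`, `"cosmx"`, or
#'   `"custom"` (supply the remaining arguments yourself).
#' @param gene,x,y,z,cell,quality source column names (`z`, `cell`,
#'   `quality` may be absent from the file).
#' @param unassigned values of the cell column meaning "no nucleus".
#' @param negative_patterns regular expressions matching control probes;
#'   matching rows are dropped on read.
#' @param coord_scale multiplier applied to x/y/z on read.
#' @return a `dialect_spec` list.
#' @export
dialect_spec <- function(name = "generic", gene = "gene", x = "x", y = "y",
                         z = "z", cell = "nucleus", quality = NULL,
                         unassigned = c("", "-1", "0", "UNASSIGNED", "NA"),
                         negative_patterns = character(0),
                         coord_scale = 1) {
  preset <- switch(name,
    generic = list(),
    xenium = list(gene = "feature_name", x = "x_location", y = "y_location",
                  z = "z_location", cell = "cell_id", quality = "qv",
                  unassigned = c("UNASSIGNED", "-1", ""),
                  negative_patterns = c("^NegControlProbe", "^NegControlCodeword",
                                        "^BLANK_", "^UnassignedCodeword",
                                        "^DeprecatedCodeword", "^antisense")),
    merscope = list(gene = "gene", x = "global_x", y = "global_y",
                    z = "global_z", cell = "cell_id",
                    unassigned = c("-1", "0", ""),
                    negative_patterns = c("^Blank-")),
    cosmx = list(gene = "target", x = "x_global_px", y = "y_global_px",
                 z = "z", cell = "cell_ID",
                 unassigned = c("0", ""),
                 negative_patterns = c("^NegPrb", "^Negative", "^SystemControl",
                                       "^FalseCode"),
                 coord_scale = 0.12028),
    custom = list(),
    stop("unknown dialect: ", name)
  )
  spec <- list(name = name, gene = gene, x = x, y = y, z = z, cell = cell,
               quality = quality, unassigned = unassigned,
               negative_patterns = negative_patterns,
               coord_scale = coord_scale)
  spec[names(preset)] <- preset
  structure(spec, class = "dialect_spec")
}

#' Read a transcript table
#'
#' Reads a delimited transcript table in one of the platform dialects,
#' mapping columns to the internal layout (`gene`, `x`, `y`, `z`,
#' `nucleus`, optional `qv`), dropping negative-control rows and rows below
#' the quality threshold, and filling a missing z with 0.
#'
#' @param path file path (any delimited format data.table::fread accepts).
#' @param dialect a [dialect_spec()] or dialect name.
#' @param quality_threshold optional minimum quality score; rows below it
#'   are dropped (no default threshold is applied).
#' @return a `transcript_table` data frame with attributes
#'   `n_negative_dropped` and `n_quality_dropped`.
#' @export
read_transcripts <- function(path, dialect = "generic",
                             quality_threshold = NULL) {
  if (is.character(dialect)) dialect <- dialect_spec(dialect)
  dt <- data.table::fread(path, data.table = FALSE)
  need <- c(gene = dialect$gene, x = dialect$x, y = dialect$y)
  miss <- setdiff(unname(need), names(dt))
  if (length(miss))
    stop("missing mapped column(s): ", paste(miss, collapse = ", "))
  out <- data.frame(gene = as.character(dt[[dialect$gene]]),
                    x = as.numeric(dt[[dialect$x]]) * dialect$coord_scale,
                    y = as.numeric(dt[[dialect$y]]) * dialect$coord_scale,
                    stringsAsFactors = FALSE)
  out$z <- if (!is.null(dialect$z) && dialect$z %in% names(dt))
    as.numeric(dt[[dialect$z]]) * dialect$coord_scale else 0
  if (!is.null(dialect$cell) && dialect$cell %in% names(dt)) {
    cell <- as.character(dt[[dialect$cell]])
    cell[cell %in% dialect$unassigned | is.na(cell)] <- NA
    out$nucleus <- cell
  } else out$nucleus <- NA_character_
  if (!is.null(dialect$quality) && dialect$quality %in% names(dt))
    out$qv <- as.numeric(dt[[dialect$quality]])

  n_neg <- 0L
  if (length(dialect$negative_patterns)) {
    pat <- paste(dialect$negative_patterns, collapse = "|")
    neg <- grepl(pat, out$gene)
    n_neg <- sum(neg)
    if (n_neg) out <- out[!neg, , drop = FALSE]
  }
  n_q <- 0L
  if (!is.null(quality_threshold) && !is.null(out$qv)) {
    low <- out$qv < quality_threshold
    n_q <- sum(low)
    if (n_q) out <- out[!low, , drop = FALSE]
  }
  rownames(out) <- NULL
  if (!all(is.finite(out$x)) || !all(is.finite(out$y)) || !all(is.finite(out$z)))
    stop("non-finite coordinates after parsing")
  attr(out, "n_negative_dropped") <- n_neg
  attr(out, "n_quality_dropped") <- n_q
  attr(out, "dialect") <- dialect$name
  class(out) <- c("transcript_table", "data.frame")
  out
}

#' Write the cell-by-gene count matrix
#'
#' Sparse MatrixMarket triplet file (genes as rows) with gene and cell
#' barcode sidecar files.  The matrix sum equals the number of assigned
#' transcripts of retained cells.
#'
#' @param result a `segmentation_result`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_count_matrix <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  X <- Matrix::Matrix(result$counts, sparse = TRUE)
  mtx <- file.path(dir, "counts.mtx")
  Matrix::writeMM(X, mtx)
  genes <- file.path(dir, "genes.tsv")
  cells <- file.path(dir, "barcodes.tsv")
  writeLines(rownames(result$counts), genes)
  writeLines(colnames(result$counts), cells)
  invisible(c(mtx, genes, cells))
}

#' Write cell metadata, boundary polygons and repositioned transcripts
#'
#' Cell metadata CSV (centroid, volume, component, transcript total), a
#' GeoJSON FeatureCollection of per-cell per-layer boundary polygons
#' (closed rings, coordinates in um), and a transcript CSV of observed and
#' inferred positions with assignments.
#'
#' @param result a `segmentation_result`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_cell_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- file.path(dir, "cells.csv")
  utils::write.csv(result$cell_meta, meta, row.names = FALSE)

  features <- lapply(result$polygons, function(p) {
    ring <- rbind(p$ring, p$ring[1, , drop = FALSE])  # close the ring
    list(type = "Feature",
         properties = list(cell = p$cell, layer = p$layer,
                           area_um2 = p$area_um2),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) unname(ring[i, ])))))
  })
  gj <- file.path(dir, "boundaries.geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       gj, auto_unbox = TRUE, digits = NA)

  tr <- file.path(dir, "transcripts.csv")
  utils::write.csv(result$transcripts, tr, row.names = FALSE)
  invisible(c(meta, gj, tr))
}

#' Write the voxel label raster
#'
#' Debug export: one CSV row per voxel with its center coordinates (um) and
#' cell label (0 = unassigned).
#'
#' @param lattice a `voxel_lattice`.
#' @param path output CSV path.
#' @export
write_voxel_raster <- function(lattice, path) {
  d <- lattice$dims
  ix <- rep(seq_len(d[1]) - 1L, times = d[2] * d[3])
  iy <- rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3])
  iz <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  df <- data.frame(
    x = lattice$origin[1] + (ix + 0.5) * lattice$voxel_size[1],
    y = lattice$origin[2] + (iy + 0.5) * lattice$voxel_size[2],
    z = lattice$origin[3] + (iz + 0.5) * lattice$voxel_size[3],
    cell = as.integer(lattice$state))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
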