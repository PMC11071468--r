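# Voxel-lattice geometry and cell-state bookkeeping.
#
# Conventions: voxel indices are 0-based triplets (ix, iy, iz); voxel i spans
# the half-open box [origin + i * voxel_size, origin + (i + 1) * voxel_size);
# all coordinates are in micrometres.  Lattice state is an integer array with
# 0 meaning unassigned and 1..n a cell id.

#' Build an empty voxel lattice covering a set of transcripts
#'
#' The lattice bounding box covers all transcript positions.  The x/y voxel
#' edge lengths are taken from `voxel_size`; the z axis is split into exactly
#' `z_layers` layers spanning the z-coordinate range (flat data with no z
#' extent gets a nominal 1 um thickness so voxel volumes stay finite).
#'
#' @param transcripts a data frame with numeric columns `x`, `y`, `z` (um).
#' @param voxel_size numeric of length 2 or 3: in-plane voxel edge (um);
#'   a third element is used as the nominal z thickness for flat data.
#' @param z_layers number of z layers.
#' @return a `voxel_lattice`: list with `origin`, `voxel_size`, `dims`,
#'   `state` (3-d integer array, 0 = unassigned).
#' @export
build_lattice <- function(transcripts, voxel_size, z_layers = 1L) {
  stopifnot(nrow(transcripts) > 0, all(voxel_size > 0), z_layers >= 1)
  pos <- as.matrix(transcripts[, c("x", "y", "z")])
  if (!all(is.finite(pos))) stop("non-finite transcript coordinates")
  lo <- apply(pos, 2, min)
  hi <- apply(pos, 2, max)
  vx <- voxel_size[1]
  vy <- voxel_size[2]
  nx <- max(1L, as.integer(ceiling((hi[1] - lo[1]) / vx - 1e-9)))
  ny <- max(1L, as.integer(ceiling((hi[2] - lo[2]) / vy - 1e-9)))
  zspan <- hi[3] - lo[3]
  if (zspan <= 0) zspan <- if (length(voxel_size) >= 3) voxel_size[3] else 1
  vz <- zspan / z_layers
  dims <- c(nx, ny, as.integer(z_layers))
  structure(list(
    origin = unname(lo),
    voxel_size = c(vx, vy, vz),
    dims = dims,
    state = array(0L, dim = dims)
  ), class = "voxel_lattice")
}

#' @export
print.voxel_lattice <- function(x, ...) {
  cat(sprintf("<voxel_lattice> %d x %d x %d voxels of %.3g x %.3g x %.3g um, %d assigned\n",
              x$dims[1], x$dims[2], x$dims[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              sum(x$state > 0L)))
  invisible(x)
}

#' Voxel containing a point
#'
#' Half-open interval convention per axis; points exactly on the upper
#' bounding-box face map to the last voxel.  Points outside the bounding box
#' are an error.
#'
#' @param lattice a `voxel_lattice`.
#' @param point numeric of length 3, or an n x 3 matrix.
#' @return 0-based voxel index triplet(s): integer vector, or n x 3 matrix.
#' @export
voxel_of <- function(lattice, point) {
  p <- if (is.matrix(point)) point else matrix(point, ncol = 3)
  idx <- floor(sweep(sweep(p, 2, lattice$origin), 2, lattice$voxel_size, "/"))
  hi <- lattice$origin + lattice$dims * lattice$voxel_size
  out_lo <- sweep(p, 2, lattice$origin, "<")
  out_hi <- sweep(p, 2, hi, ">")
  if (any(out_lo) || any(out_hi)) stop("point outside lattice bounding box")
  # upper-face points land one past the end under floor(); clamp them back
  idx <- pmin(idx, matrix(lattice$dims - 1L, nrow(idx), 3, byrow = TRUE))
  storage.mode(idx) <- "integer"
  if (!is.matrix(point)) idx[1, ] else idx
}

# 0-based linear voxel index from 0-based triplets
.lin_index <- function(lattice, ijk) {
  if (!is.matrix(ijk)) ijk <- matrix(ijk, ncol = 3)
  as.integer(ijk[, 1] + lattice$dims[1] * (ijk[, 2] + lattice$dims[2] * ijk[, 3]))
}

.transcript_voxels <- function(lattice, transcripts) {
  .lin_index(lattice, voxel_of(lattice, as.matrix(transcripts[, c("x", "y", "z")])))
}

#' Moore neighborhood of a voxel
#'
#' All in-bounds voxels differing by at most one step on every axis
#' (up to 26 in 3-d, 8 in a single-layer lattice).
#'
#' @param lattice a `voxel_lattice`.
#' @param j 0-based voxel index triplet.
#' @return matrix of 0-based neighbor triplets, one per row.
#' @export
moore_neighbors <- function(lattice, j) {
  stopifnot(length(j) == 3, all(j >= 0), all(j < lattice$dims))
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  d <- d[rowSums(d != 0) > 0, , drop = FALSE]
  nb <- sweep(d, 2, as.numeric(j), "+")
  keep <- nb[, 1] >= 0 & nb[, 1] < lattice$dims[1] &
          nb[, 2] >= 0 & nb[, 2] < lattice$dims[2] &
          nb[, 3] >= 0 & nb[, 3] < lattice$dims[3]
  m <- nb[keep, , drop = FALSE]
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}

#' Local articulation test
#'
#' TRUE iff changing the state of voxel `j` alters the number of
#' Moore-connected components of the voxels with state `label` restricted to
#' j's Moore neighborhood plus j itself.  Proposals flipping such voxels are
#' pre-rejected by the sampler: removing an articulation voxel would split
#' (or locally annihilate) a cell, an irreversible move that would break
#' detailed balance.
#'
#' @param lattice a `voxel_lattice`.
#' @param j 0-based voxel index triplet.
#' @param label a positive cell id.
#' @export
is_local_articulation <- function(lattice, j, label) {
  .is_articulation_cpp(as.integer(lattice$state), lattice$dims,
                       .lin_index(lattice, j), as.integer(label))
}

#' Cell-state tallies from a lattice
#'
#' Per-cell voxel counts, per-layer volumes and raw perimeter tallies
#' (in-plane Moore-neighbor mismatch counts), and volumes in um^3.
#'
#' @param lattice a `voxel_lattice`.
#' @param n number of cells (defaults to the largest label present).
#' @return a `cell_state` list.
#' @export
cell_state <- function(lattice, n = max(lattice$state)) {
  n <- max(1L, as.integer(n))
  tal <- .layer_tallies_cpp(as.integer(lattice$state), lattice$dims, n)
  bvol <- prod(lattice$voxel_size)
  vox <- rowSums(tal$layer_volume)
  structure(list(
    n = n,
    cell_voxels = vox,
    layer_volume = tal$layer_volume,
    layer_perimeter_raw = tal$layer_perimeter_raw,
    volume_um3 = vox * bvol,
    voxel_size = lattice$voxel_size
  ), class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("<cell_state> %d cells, %d assigned voxels, median volume %.1f um^3\n",
              x$n, sum(x$cell_voxels), median(x$volume_um3[x$cell_voxels > 0])))
  invisible(x)
}

#' Initialize lattice state from nuclear transcript labels
#'
#' Each voxel holding at least one nuclear-labeled transcript is assigned the
#' label with the plurality of its nuclear transcripts.  Ties are broken by
#' the larger count of that label's transcripts in the voxel's Moore
#' neighborhood, then by the smaller label id.  If a label's voxels are
#' disconnected, only its largest Moore-connected component is kept, so every
#' cell starts non-empty and connected.
#'
#' @param lattice a `voxel_lattice`.
#' @param transcripts data frame with `x`, `y`, `z` and a `nucleus` column
#'   (cell label, with `NA` or 0 meaning unlabeled).
#' @return list with the filled `lattice`, the `cells` tallies, and
#'   `cell_ids` mapping internal ids 1..n to the original labels.
#' @export
initialize_from_nuclei <- function(lattice, transcripts) {
  nuc <- transcripts$nucleus
  lab <- !is.na(nuc) & nuc != 0
  if (!any(lab)) stop("no nuclear-labeled transcripts")
  ids <- sort(unique(nuc[lab]))
  n <- length(ids)
  labint <- match(nuc[lab], ids)
  vox <- .transcript_voxels(lattice, transcripts[lab, , drop = FALSE])

  dt <- data.table::data.table(vox = vox, lab = labint)
  cnt <- dt[, .N, by = .(vox, lab)]
  data.table::setorder(cnt, vox, -N, lab)
  top <- cnt[, .SD[N == max(N)], by = vox]
  ntie <- top[, .N, by = vox]
  winners <- top[vox %in% ntie[N == 1L, vox]][, .SD[1L], by = vox]

  tievox <- ntie[N > 1L, vox]
  if (length(tievox)) {
    # neighborhood support: labeled transcripts of each tied label in the
    # Moore neighborhood of the tied voxel
    counts_by_vox <- cnt
    tie_rows <- top[vox %in% tievox]
    support <- vapply(seq_len(nrow(tie_rows)), function(r) {
      v <- tie_rows$vox[r]; l <- tie_rows$lab[r]
      ijk <- c(v %% lattice$dims[1],
               (v %/% lattice$dims[1]) %% lattice$dims[2],
               v %/% (lattice$dims[1] * lattice$dims[2]))
      nb <- .lin_index(lattice, moore_neighbors(lattice, ijk))
      sum(counts_by_vox[vox %in% nb & lab == l, N])
    }, numeric(1))
    tie_rows[, supp := support]
    data.table::setorder(tie_rows, vox, -supp, lab)
    winners <- rbind(winners[, .(vox, lab, N)], tie_rows[, .SD[1L], by = vox][, .(vox, lab, N)])
  }

  st <- lattice$state
  st[winners$vox + 1L] <- winners$lab
  st <- array(.largest_component_filter_cpp(as.integer(st), lattice$dims, n),
              dim = lattice$dims)
  lattice$state <- st
  list(lattice = lattice, cells = cell_state(lattice, n), cell_ids = ids)
}

#' Perimeter of one cell layer
#'
#' The perceived perimeter of cell `c` on z-layer `z`: the number of in-plane
#' Moore neighbors outside the cell, summed over the cell's voxels in that
#' layer, scaled by the calibration constant `xi` and the in-plane voxel edge
#' length.  Returns 0 if the cell does not occupy the layer.
#'
#' @param cells a `cell_state`.
#' @param c cell id.
#' @param z 0-based layer index.
#' @param xi perceived-perimeter scaling constant (see [calibrate_xi()]).
#' @return perimeter in um (times `xi`'s dimensionless calibration).
#' @export
layer_perimeter <- function(cells, c, z, xi = calibrate_xi()) {
  raw <- cells$layer_perimeter_raw[c, z + 1L]
  xi * raw * sqrt(cells$voxel_size[1] * cells$voxel_size[2])
}

#' Perimeter-to-volume constraint check
#'
#' TRUE iff the layer perimeter is at most `b_factor` times the perimeter of
#' a disk of the same area: perimeter <= b 2 sqrt(pi area).  Empty layers
#' pass vacuously.
#'
#' @inheritParams layer_perimeter
#' @param b_factor bound multiplier (default 1.3).
#' @export
perimeter_bound_ok <- function(cells, c, z, b_factor = 1.3, xi = calibrate_xi()) {
  nvox <- cells$layer_volume[c, z + 1L]
  if (nvox == 0) return(TRUE)
  area <- nvox * cells$voxel_size[1] * cells$voxel_size[2]
  layer_perimeter(cells, c, z, xi) <= b_factor * 2 * sqrt(pi * area)
}

#' Calibrate the perceived-perimeter constant
#'
#' The raw mismatch tally is proportional to the true (smoothed) boundary
#' length.  The constant is fitted once by rasterizing disks over a range of
#' radii and regressing the true circumference 2 pi r on the raw tally
#' (through the origin).  The fit is cached for the session.
#'
#' @param radii disk radii in voxels.
#' @return the dimensionless scaling constant xi.
#' @export
calibrate_xi <- function(radii = c(10, 20, 40, 60, 80, 100)) {
  key <- paste0("xi_", paste(radii, collapse = "_"))
  if (!is.null(.voxseg_env[[key]])) return(.voxseg_env[[key]])
  raw <- vapply(radii, function(r) .disk_raw_perimeter(r), numeric(1))
  xi <- sum(2 * pi * radii * raw) / sum(raw^2)
  .voxseg_env[[key]] <- xi
  xi
}

# raw in-plane mismatch tally of a rasterized disk of radius r voxels
.disk_raw_perimeter <- function(r) {
  n <- as.integer(2 * r + 5)
  cx <- (n + 1) / 2
  xs <- matrix(seq_len(n), n, n)
  mask <- (xs - cx)^2 + (t(xs) - cx)^2 <= r^2
  st <- array(ifelse(mask, 1L, 0L), dim = c(n, n, 1L))
  tal <- .layer_tallies_cpp(as.integer(st), c(n, n, 1L), 1L)
  as.numeric(tal$layer_perimeter_raw[1, 1])
}

#' Double the lattice resolution
#'
#' Splits each voxel into sub-voxels (2 per axis; 8 when `split_z`), copying
#' its state to the children.  The spatial region of every cell, and hence
#' its volume in um^3, is unchanged; tallies are recomputed at the new
#' resolution.  Flat single-layer data is doubled in-plane only
#' (`split_z = FALSE`), since there is no z extent to subdivide.
#'
#' @param lattice a `voxel_lattice`.
#' @param cells a `cell_state` (used for its cell count).
#' @param split_z also split the z axis (default TRUE).
#' @return list with the refined `lattice` and recomputed `cells`.
#' @export
double_resolution <- function(lattice, cells, split_z = TRUE) {
  d <- lattice$dims
  zf <- if (split_z) 2L else 1L
  ix <- rep(seq_len(d[1]), each = 2)
  iy <- rep(seq_len(d[2]), each = 2)
  iz <- if (split_z) rep(seq_len(d[3]), each = 2) else seq_len(d[3])
  st <- lattice$state[ix, iy, iz, drop = FALSE]
  lattice$dims <- c(2L * d[1], 2L * d[2], zf * d[3])
  lattice$voxel_size <- lattice$voxel_size / c(2, 2, zf)
  lattice$state <- array(st, dim = lattice$dims)
  list(lattice = lattice, cells = cell_state(lattice, cells$n))
}

#' Checkerboard proposal phases
#'
#' Partitions the lattice into square bins of `bin_size` voxels in-plane and
#' cycles four phases over the bin sub-quadrants, so that simultaneous
#' proposals within one phase are separated by at least one bin and cannot
#' touch the same cell when bins exceed the cell diameter.
#'
#' @param lattice a `voxel_lattice`.
#' @param bin_size bin edge in voxels (>= 2).
#' @return a `checkerboard_schedule`: `bin_size` plus a per-voxel phase array
#'   with values 0..3.
#' @export
checkerboard_phases <- function(lattice, bin_size) {
  stopifnot(bin_size >= 2)
  d <- lattice$dims
  px <- ((seq_len(d[1]) - 1) %/% bin_size) %% 2
  py <- ((seq_len(d[2]) - 1) %/% bin_size) %% 2
  ph <- outer(px, 2 * py, "+")
  structure(list(bin_size = as.integer(bin_size),
                 phase = array(ph, dim = d)),
            class = "checkerboard_schedule")
}

#' Enumerate the mismatch edge pool
#'
#' All ordered von-Neumann-adjacent voxel pairs with differing states: the
#' support of the sampler's flip proposals.
#'
#' @param lattice a `voxel_lattice`.
#' @return 2-column matrix of 0-based linear voxel indices (from, to).
#' @export
edge_pool <- function(lattice) {
  .edge_pool_cpp(as.integer(lattice$state), lattice$dims)
}

#' Audit cached cell-state tallies and connectivity
#'
#' Recomputes voxel counts, layer volumes and perimeters from scratch and
#' verifies the partition invariant and Moore-connectivity of every cell.
#'
#' @param lattice a `voxel_lattice`.
#' @param cells the cached `cell_state` to check.
#' @return TRUE invisibly if all checks pass, otherwise an error.
#' @export
audit_cell_state <- function(lattice, cells) {
  ref <- cell_state(lattice, cells$n)
  stopifnot(
    identical(unname(ref$cell_voxels), unname(cells$cell_voxels)),
    identical(unname(ref$layer_volume), unname(cells$layer_volume)),
    identical(unname(ref$layer_perimeter_raw), unname(cells$layer_perimeter_raw)),
    sum(cells$cell_voxels) + sum(lattice$state == 0L) == prod(lattice$dims)
  )
  comp <- .cell_component_counts_cpp(as.integer(lattice$state), lattice$dims, cells$n)
  if (any(comp[cells$cell_voxels > 0] != 1L))
    stop("disconnected cell detected")
  invisible(TRUE)
}
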