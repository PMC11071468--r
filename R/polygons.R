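# Boundary polygon tracing from voxel rasters.
#
# Each boundary unit edge of a cell's in-plane mask is oriented with the
# cell interior on its left; following edges (preferring the sharpest right
# turn at pinch vertices) yields closed rings whose signed (shoelace) area
# is positive for exterior rings.  The exterior ring's area equals the voxel
# count times the voxel area exactly, minus any holes.

# trace rings of a 0/1 mask given as integer matrix (nx x ny);
# returns list of k x 2 matrices of vertex coordinates in voxel units
.trace_mask_rings <- function(mask) {
  nx <- nrow(mask); ny <- ncol(mask)
  inm <- function(x, y) x >= 1 && x <= nx && y >= 1 && y <= ny && mask[x, y] > 0
  # directed edges: from-vertex and direction code 0:+x 1:+y 2:-x 3:-y,
  # vertex (vx, vy) in 0..nx x 0..ny
  from <- integer(0); dir <- integer(0)
  vkey <- function(x, y) x + (nx + 1L) * y
  for (x in seq_len(nx)) for (y in seq_len(ny)) {
    if (mask[x, y] <= 0) next
    x0 <- x - 1L; y0 <- y - 1L
    if (!inm(x, y - 1L)) { from <- c(from, vkey(x0, y0)); dir <- c(dir, 0L) }
    if (!inm(x + 1L, y)) { from <- c(from, vkey(x0 + 1L, y0)); dir <- c(dir, 1L) }
    if (!inm(x, y + 1L)) { from <- c(from, vkey(x0 + 1L, y0 + 1L)); dir <- c(dir, 2L) }
    if (!inm(x - 1L, y)) { from <- c(from, vkey(x0, y0 + 1L)); dir <- c(dir, 3L) }
  }
  if (!length(from)) return(list())
  dx <- c(1L, 0L, -1L, 0L); dy <- c(0L, 1L, 0L, -1L)
  used <- logical(length(from))
  # edges grouped by start vertex
  ord <- order(from)
  starts <- from[ord]
  grp_begin <- c(1L, which(diff(starts) != 0) + 1L)
  grp_key <- starts[grp_begin]
  lookup <- function(v) {
    i <- findInterval(v, grp_key)
    if (i == 0 || grp_key[i] != v) return(integer(0))
    j <- grp_begin[i]
    jend <- if (i < length(grp_begin)) grp_begin[i + 1L] - 1L else length(ord)
    ord[j:jend]
  }
  rings <- list()
  for (e0 in seq_along(from)) {
    if (used[e0]) next
    ring_v <- from[e0]
    e <- e0
    repeat {
      used[e] <- TRUE
      v <- from[e]
      vx <- v %% (nx + 1L); vy <- v %/% (nx + 1L)
      nxt_v <- vkey(vx + dx[dir[e] + 1L], vy + dy[dir[e] + 1L])
      ring_v <- c(ring_v, nxt_v)
      if (nxt_v == from[e0]) break
      cand <- lookup(nxt_v)
      cand <- cand[!used[cand]]
      if (!length(cand)) break  # should not happen on a valid mask
      if (length(cand) > 1L) {
        # pinch vertex (diagonally touching voxels): prefer the left turn so
        # the exterior of a Moore-connected mask stays a single ring
        turn <- (dir[cand] - dir[e]) %% 4L
        # left turn = 1, straight = 0, right = 3 under this encoding
        pref <- order(match(turn, c(1L, 0L, 3L)))
        cand <- cand[pref]
      }
      e <- cand[1L]
    }
    vx <- ring_v %% (nx + 1L); vy <- ring_v %/% (nx + 1L)
    rings[[length(rings) + 1L]] <- cbind(vx, vy)
  }
  rings
}

.ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

#' Trace cell boundary polygons
#'
#' For each retained cell and occupied z-layer, traces the exterior boundary
#' ring of the cell's voxel mask and scales it to micrometres.  Rings are
#' closed (first vertex repeated last) and counter-clockwise.
#'
#' @param lattice a `voxel_lattice`.
#' @param cell_ids internal cell ids to trace.
#' @param labels output labels for the cells (defaults to the ids).
#' @return data frame-less list of polygons: each element has `cell`,
#'   `layer` (0-based), and `ring` (k x 2 matrix of x, y in um).
#' @export
trace_cell_polygons <- function(lattice, cell_ids, labels = as.character(cell_ids)) {
  out <- list()
  d <- lattice$dims
  for (i in seq_along(cell_ids)) {
    c_id <- cell_ids[i]
    for (z in seq_len(d[3])) {
      sl <- lattice$state[, , z, drop = FALSE]
      dim(sl) <- d[1:2]
      mask <- (sl == c_id) + 0L
      if (!any(mask > 0)) next
      rings <- .trace_mask_rings(mask)
      if (!length(rings)) next
      areas <- vapply(rings, .ring_area, numeric(1))
      ext <- rings[[which.max(areas)]]
      ring_um <- cbind(lattice$origin[1] + ext[, 1] * lattice$voxel_size[1],
                       lattice$origin[2] + ext[, 2] * lattice$voxel_size[2])
      colnames(ring_um) <- c("x", "y")
      out[[length(out) + 1L]] <- list(cell = labels[i], layer = z - 1L,
                                      ring = ring_um,
                                      area_um2 = max(areas) *
                                        lattice$voxel_size[1] * lattice$voxel_size[2])
    }
  }
  out
}
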