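# Metropolis-Hastings segmentation engine: configuration, boundary sweeps,
# the multi-resolution schedule, transcript repositioning, and finalization.

#' Sampler configuration
#'
#' @param b_factor perimeter bound multiplier (1.3: a layer's perimeter may
#'   exceed that of an equal-area disk by at most 30 percent).
#' @param bubble_prob probability a flip proposal writes the unassigned
#'   state instead of copying its source voxel (0.05), keeping inter-cell
#'   bubble formation and popping mutually reversible.
#' @param p_nuc nuclear prior retention probability (0.8).
#' @param reposition transcript-repositioning settings: `rho`, `sigma_a`,
#'   `sigma_b` of the Normal-mixture diffusion prior (um), the symmetric
#'   proposal sd `proposal_sd` (xy, z; um), and `every_n_sweeps` (0 disables
#'   repositioning).
#' @param schedule data frame of stages with columns `voxel_xy` (um,
#'   strictly halving), `z_layers`, and `sweeps`; the default starts at 4 um
#'   single-layer voxels and halves twice to 1 um, stacking z layers 1, 2, 4.
#' @param sweeps_per_stage used to build the default schedule.
#' @param bin_size checkerboard bin edge in voxels (0 = plain sequential
#'   proposals over the whole pool).
#' @param components mixture components k.
#' @param prior a [prior_config()] (built from `components` by default).
#' @param gibbs_warmup parameter-only sweeps before boundary sampling.
#' @param min_cell_transcripts cells below this total are dropped at
#'   finalization (10).
#' @param xi perceived-perimeter constant; calibrated from rasterized disks
#'   by default.
#' @param seed RNG seed (all randomness flows through R's RNG).
#' @return a `sampler_config` list.
#' @export
sampler_config <- function(b_factor = 1.3, bubble_prob = 0.05, p_nuc = 0.8,
                           reposition = list(rho = 0.2, sigma_a = 4,
                                             sigma_b = 0.5,
                                             proposal_sd = c(1, 0.5),
                                             every_n_sweeps = 5L),
                           schedule = NULL, sweeps_per_stage = 200L,
                           bin_size = 0L, components = 10L, prior = NULL,
                           gibbs_warmup = 20L, min_cell_transcripts = 10L,
                           xi = NULL, seed = 1L) {
  if (is.null(schedule))
    schedule <- data.frame(voxel_xy = c(4, 2, 1), z_layers = c(1L, 2L, 4L),
                           sweeps = sweeps_per_stage)
  stopifnot(bubble_prob > 0, bubble_prob < 1, p_nuc > 0, p_nuc < 1,
            b_factor > 0, nrow(schedule) >= 1,
            all(diff(schedule$voxel_xy) < 0))
  if (nrow(schedule) > 1)
    stopifnot(all(abs(schedule$voxel_xy[-1] * 2 - schedule$voxel_xy[-nrow(schedule)]) < 1e-9))
  if (is.null(prior)) prior <- prior_config(k = components)
  if (is.null(xi)) xi <- calibrate_xi()
  structure(list(b_factor = b_factor, bubble_prob = bubble_prob,
                 p_nuc = p_nuc, reposition = reposition,
                 schedule = schedule, bin_size = as.integer(bin_size),
                 components = as.integer(components), prior = prior,
                 gibbs_warmup = as.integer(gibbs_warmup),
                 min_cell_transcripts = as.integer(min_cell_transcripts),
                 xi = xi, seed = as.integer(seed)),
            class = "sampler_config")
}

#' Run boundary-flip proposals
#'
#' Low-level driver for the Metropolis-Hastings voxel-flip chain.  Proposals
#' draw a mismatched von-Neumann edge uniformly from the pool, write either
#' the source state (copy) or the unassigned state (bubble) into the target
#' voxel, pre-reject moves that would annihilate a cell, break local
#' connectivity, or violate the perimeter bound, and otherwise accept with
#' the Metropolis-Hastings ratio including the exact proposal-density
#' correction.
#'
#' @param lattice a `voxel_lattice`.
#' @param cells the matching `cell_state`.
#' @param params a `model_params`.
#' @param tvox 0-based linear voxel index per transcript.
#' @param gene 1-based gene index per transcript.
#' @param nuclear 1-based nuclear label per transcript (0 = none).
#' @param cfg a [sampler_config()].
#' @param n_proposals number of proposals to make.
#' @param use_qratio,use_articulation,check_perimeter safeguard switches
#'   (disabling the first two breaks detailed balance; exposed for negative
#'   controls and diagnostics).
#' @param use_volume_prior include the per-component log-normal volume
#'   prior in the acceptance ratio.
#' @param record_states tally visited states (tiny enumerable lattices only).
#' @return list with updated `lattice`, `cells`, acceptance and conflict
#'   counts, and (optionally) the state-visit tallies.
#' @export
run_boundary_sweeps <- function(lattice, cells, params, tvox, gene, nuclear,
                                cfg, n_proposals,
                                use_qratio = TRUE, use_articulation = TRUE,
                                check_perimeter = TRUE,
                                use_volume_prior = TRUE,
                                record_states = FALSE) {
  res <- .run_sweeps_cpp(
    as.integer(lattice$state), lattice$dims, lattice$voxel_size,
    cells$n, as.integer(tvox), as.integer(gene) - 1L, as.integer(nuclear),
    params$tau, params$tau_bg, as.integer(params$z),
    params$mu_vol, params$prec_vol, use_volume_prior,
    cfg$p_nuc, cfg$bubble_prob, cfg$b_factor, cfg$xi,
    as.integer(n_proposals), cfg$bin_size,
    max(1L, as.integer(n_proposals / 4L)),
    use_qratio, use_articulation, check_perimeter, record_states)
  if (res$conflicts > 0)
    warning(sprintf("%d same-phase proposals touched the same cell; consider a larger bin_size",
                    res$conflicts))
  lattice$state <- array(res$state, dim = lattice$dims)
  cells$cell_voxels <- rowSums(res$layer_volume)
  cells$layer_volume <- res$layer_volume
  cells$layer_perimeter_raw <- res$layer_perimeter_raw
  cells$volume_um3 <- cells$cell_voxels * prod(lattice$voxel_size)
  list(lattice = lattice, cells = cells, accepted = res$accepted,
       proposed = res$proposed, conflicts = res$conflicts,
       visits = res$visits)
}

#' Segment cells from a transcript table
#'
#' The full pipeline: builds a coarse lattice over the transcripts, seeds
#' cells from the nuclear labels, alternates Metropolis-Hastings boundary
#' sweeps with Gibbs parameter sweeps and (optionally) transcript
#' repositioning, doubling the lattice resolution between schedule stages,
#' and finalizes counts, metadata and boundary polygons.  Deterministic for
#' a fixed config and seed.
#'
#' @param transcripts a `transcript_table` (see [read_transcripts()]) or
#'   data frame with columns `gene`, `x`, `y`, `z`, `nucleus`.
#' @param config a [sampler_config()].
#' @param verbose print per-stage acceptance summaries.
#' @return a `segmentation_result`; see [finalize_segmentation()].
#' @export
segment_cells <- function(transcripts, config = sampler_config(),
                          verbose = FALSE) {
  set.seed(config$seed)
  tt <- as.data.frame(transcripts)
  stopifnot(all(c("gene", "x", "y", "z") %in% names(tt)))
  if (is.null(tt$nucleus)) stop("transcripts need a 'nucleus' label column")
  gene_f <- factor(tt$gene)
  gene <- as.integer(gene_f)
  m <- nlevels(gene_f)
  flat <- diff(range(tt$z)) == 0

  sched <- config$schedule
  if (flat) sched$z_layers <- 1L

  lattice <- build_lattice(tt, voxel_size = rep(sched$voxel_xy[1], 2),
                           z_layers = sched$z_layers[1])
  init <- initialize_from_nuclei(lattice, tt)
  lattice <- init$lattice
  cells <- init$cells
  cell_ids <- init$cell_ids
  n <- cells$n
  nuclear <- match(tt$nucleus, cell_ids)
  nuclear[is.na(nuclear)] <- 0L

  pos <- as.matrix(tt[, c("x", "y", "z")])
  obs <- pos
  tvox <- .transcript_voxels(lattice, tt)
  total_volume <- prod(lattice$dims) * prod(lattice$voxel_size)

  params <- init_model_params(m, n, config$prior,
                              volumes = cells$volume_um3)
  volumes <- pmax(cells$volume_um3, prod(lattice$voxel_size))
  counts <- tally_counts(gene, lattice$state[tvox + 1L], m, n)
  for (i in seq_len(config$gibbs_warmup))
    params <- gibbs_sweep(counts, volumes, params, total_volume, config$prior)

  rep_cfg <- config$reposition
  for (s in seq_len(nrow(sched))) {
    if (s > 1) {
      refined <- double_resolution(lattice, cells,
                                   split_z = sched$z_layers[s] > sched$z_layers[s - 1])
      lattice <- refined$lattice
      cells <- refined$cells
      tvox <- .lin_index(lattice, voxel_of(lattice, pos))
    }
    acc <- 0
    for (sw in seq_len(sched$sweeps[s])) {
      pool_n <- nrow(edge_pool(lattice))
      if (pool_n == 0) break
      step <- run_boundary_sweeps(lattice, cells, params, tvox, gene,
                                  nuclear, config, pool_n)
      lattice <- step$lattice
      cells <- step$cells
      acc <- acc + step$accepted
      volumes <- pmax(cells$volume_um3, prod(lattice$voxel_size))
      counts <- tally_counts(gene, lattice$state[tvox + 1L], m, n)
      params <- gibbs_sweep(counts, volumes, params, total_volume,
                            config$prior)
      if (rep_cfg$every_n_sweeps > 0 && sw %% rep_cfg$every_n_sweeps == 0) {
        rp <- .reposition_sweep_cpp(pos, obs, as.integer(gene) - 1L,
                                    as.integer(tvox),
                                    as.integer(lattice$state), lattice$dims,
                                    lattice$origin, lattice$voxel_size,
                                    params$tau, params$tau_bg,
                                    rep_cfg$rho, rep_cfg$sigma_a,
                                    rep_cfg$sigma_b,
                                    rep_cfg$proposal_sd[1],
                                    if (flat) 0 else rep_cfg$proposal_sd[2])
        pos <- rp$pos
        tvox <- rp$tvox
        counts <- tally_counts(gene, lattice$state[tvox + 1L], m, n)
      }
    }
    if (verbose)
      message(sprintf("stage %d (%.3g um): %d cells, %.1f%% acceptance",
                      s, lattice$voxel_size[1], n,
                      100 * acc / max(1, sum(sched$sweeps[s] * pool_n))))
  }

  finalize_segmentation(lattice, cells, params, config,
                        gene = gene, gene_levels = levels(gene_f),
                        tvox = tvox, obs = obs, pos = pos,
                        cell_ids = cell_ids)
}

#' Finalize a segmentation
#'
#' Builds the cell-by-gene count matrix from the final voxel states and
#' transcript positions, drops cells with fewer than
#' `config$min_cell_transcripts` transcripts (their transcripts are flagged
#' `filtered`), computes transcript-weighted centroids, and traces per-layer
#' boundary polygons from the voxel raster.
#'
#' @param lattice,cells final lattice and tallies.
#' @param params final model parameters.
#' @param config the [sampler_config()] used.
#' @param gene 1-based gene index per transcript; `gene_levels` the
#'   vocabulary.
#' @param tvox per-transcript 0-based voxel index.
#' @param obs,pos observed and inferred transcript positions (M x 3, um).
#' @param cell_ids original nucleus labels for internal ids 1..n.
#' @return a `segmentation_result` list: `assignments` (per transcript:
#'   internal cell id, 0 = background), `status` (assigned / background /
#'   filtered), `counts` (genes x retained cells), `X_bg`, `cell_meta`,
#'   `polygons`, `transcripts` (observed and inferred positions), `params`.
#' @export
finalize_segmentation <- function(lattice, cells, params, config, gene,
                                  gene_levels, tvox, obs, pos, cell_ids) {
  m <- length(gene_levels)
  n <- cells$n
  assign_all <- lattice$state[tvox + 1L]
  totals <- tabulate(assign_all[assign_all > 0L], nbins = n)
  retained <- which(totals >= config$min_cell_transcripts &
                      cells$cell_voxels > 0)
  status <- ifelse(assign_all == 0L, "background",
                   ifelse(assign_all %in% retained, "assigned", "filtered"))
  cnt <- tally_counts(gene, ifelse(status == "assigned", assign_all, 0L), m, n)
  X <- cnt$X[, retained, drop = FALSE]
  rownames(X) <- gene_levels
  colnames(X) <- as.character(cell_ids[retained])
  X_bg <- tabulate(gene[status == "background"], nbins = m)

  centroid <- matrix(NA_real_, length(retained), 3)
  for (i in seq_along(retained)) {
    sel <- assign_all == retained[i] & status == "assigned"
    centroid[i, ] <- colMeans(pos[sel, , drop = FALSE])
  }
  cell_meta <- data.frame(
    cell = as.character(cell_ids[retained]),
    x = centroid[, 1], y = centroid[, 2], z = centroid[, 3],
    volume_um3 = cells$volume_um3[retained],
    component = params$z[retained],
    transcripts = totals[retained],
    stringsAsFactors = FALSE)

  polys <- trace_cell_polygons(lattice, retained,
                               labels = as.character(cell_ids[retained]))

  structure(list(
    assignments = assign_all, status = status,
    counts = X, X_bg = X_bg, M = length(gene),
    cell_meta = cell_meta, polygons = polys,
    transcripts = data.frame(gene = gene_levels[gene],
                             x = obs[, 1], y = obs[, 2], z = obs[, 3],
                             inferred_x = pos[, 1], inferred_y = pos[, 2],
                             inferred_z = pos[, 3],
                             cell = ifelse(status == "assigned",
                                           as.character(cell_ids[assign_all]),
                                           ""),
                             status = status, stringsAsFactors = FALSE),
    retained = retained, cell_ids = cell_ids, params = params,
    lattice = lattice, cells = cells
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d cells (%d retained), %d transcripts: %d assigned, %d background, %d filtered\n",
              x$cells$n, nrow(x$cell_meta), x$M,
              sum(x$status == "assigned"), sum(x$status == "background"),
              sum(x$status == "filtered")))
  invisible(x)
}
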