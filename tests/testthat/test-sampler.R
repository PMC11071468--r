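# Metropolis-Hastings engine: invariants, determinism, repositioning,
# finalization and polygon tracing.

# a mid-run segmentation state to exercise the engine on
engine_fixture <- function(seed = 33) {
  tis <- small_tissue(seed = seed)
  tt <- tis$transcripts
  gene_f <- factor(tt$gene)
  lat <- build_lattice(tt, c(2, 2), z_layers = 1)
  ini <- initialize_from_nuclei(lat, tt)
  nuclear <- match(tt$nucleus, ini$cell_ids)
  nuclear[is.na(nuclear)] <- 0L
  params <- init_model_params(nlevels(gene_f), ini$cells$n,
                              prior_config(k = 3),
                              volumes = ini$cells$volume_um3)
  params$tau <- matrix(rgamma(length(params$tau), 2, 20),
                       nrow(params$tau), ncol(params$tau))
  params$tau_bg <- rep(1e-4, nrow(params$tau))
  list(lattice = ini$lattice, cells = ini$cells, params = params,
       tvox = voxseg:::.transcript_voxels(ini$lattice, tt),
       gene = as.integer(gene_f), nuclear = nuclear,
       cfg = sampler_config(components = 3, seed = seed))
}

test_that("accepted flips preserve partition, connectivity and cached tallies", {
  set.seed(34)
  fx <- engine_fixture()
  out <- run_boundary_sweeps(fx$lattice, fx$cells, fx$params, fx$tvox,
                             fx$gene, fx$nuclear, fx$cfg, 40000)
  expect_gt(out$accepted, 1000)  # the audit must cover real flips
  # cache coherence + partition + Moore connectivity, from scratch
  expect_true(audit_cell_state(out$lattice, out$cells))
})

test_that("no accepted state violates the perimeter bound", {
  set.seed(35)
  fx <- engine_fixture(seed = 35)
  out <- run_boundary_sweeps(fx$lattice, fx$cells, fx$params, fx$tvox,
                             fx$gene, fx$nuclear, fx$cfg, 30000)
  cs <- out$cells
  ok <- TRUE
  for (c in seq_len(cs$n)) for (z in seq_len(fx$lattice$dims[3]) - 1L)
    ok <- ok && perimeter_bound_ok(cs, c, z, b_factor = fx$cfg$b_factor,
                                   xi = fx$cfg$xi)
  expect_true(ok)
})

test_that("annihilation is prohibited: cells never vanish", {
  set.seed(36)
  fx <- engine_fixture(seed = 36)
  out <- run_boundary_sweeps(fx$lattice, fx$cells, fx$params, fx$tvox,
                             fx$gene, fx$nuclear, fx$cfg, 50000)
  expect_true(all(out$cells$cell_voxels >= 1))
})

test_that("checkerboard phases detect same-cell conflicts in undersized bins", {
  set.seed(37)
  fx <- engine_fixture(seed = 37)
  cfg <- fx$cfg
  cfg$bin_size <- 2L  # far below cell diameter: conflicts expected
  expect_warning(
    run_boundary_sweeps(fx$lattice, fx$cells, fx$params, fx$tvox, fx$gene,
                        fx$nuclear, cfg, 20000),
    "same-phase")
})

test_that("checkerboard run stays valid and covers the lattice", {
  set.seed(38)
  fx <- engine_fixture(seed = 38)
  cfg <- fx$cfg
  cfg$bin_size <- 24L  # ~48 um bins at 2 um voxels: well above cell size
  out <- suppressWarnings(
    run_boundary_sweeps(fx$lattice, fx$cells, fx$params, fx$tvox, fx$gene,
                        fx$nuclear, cfg, 40000))
  expect_gt(out$accepted, 500)
  expect_true(audit_cell_state(out$lattice, out$cells))
})

test_that("repositioning leaves the diffusion prior invariant for free transcripts", {
  # uniform rates everywhere: acceptance depends only on the mixture prior.
  # Starting the latent positions from the Normal mixture itself, the sweep
  # must preserve that law (stationarity); a wrong acceptance ratio drifts
  # the sample away from it.
  set.seed(39)
  M <- 6000
  obs <- cbind(runif(M, 40, 60), runif(M, 40, 60), 0)
  wide <- runif(M) < 0.2
  sd0 <- ifelse(wide, 4, 0.5)
  pos <- obs + cbind(rnorm(M, 0, sd0), rnorm(M, 0, sd0), 0)
  lat <- build_lattice(data.frame(gene = "a", x = c(0, 100), y = c(0, 100),
                                  z = 0), c(4, 4))
  st <- as.integer(lat$state)
  tau <- matrix(0.05, 1, 1)
  for (i in 1:40) {
    rp <- voxseg:::.reposition_sweep_cpp(pos, obs, rep(0L, M), rep(0L, M),
                                         st, lat$dims, lat$origin,
                                         lat$voxel_size, tau, 0.05,
                                         0.2, 4, 0.5, 1.0, 0)
    pos <- rp$pos
  }
  dx <- pos[, 1] - obs[, 1]
  mix_cdf <- function(x) 0.2 * pnorm(x, 0, 4) + 0.8 * pnorm(x, 0, 0.5)
  ks <- suppressWarnings(stats::ks.test(dx, mix_cdf))
  expect_gt(ks$p.value, 0.01)
  # and the variance stays at the mixture moment
  expect_equal(var(dx), 0.2 * 16 + 0.8 * 0.25,
               tolerance = 0.15)
})

test_that("zero displacement proposals are always accepted", {
  M <- 50
  obs <- cbind(runif(M, 10, 30), runif(M, 10, 30), 0)
  lat <- build_lattice(data.frame(gene = "a", x = c(0, 40), y = c(0, 40),
                                  z = 0), c(4, 4))
  rp <- voxseg:::.reposition_sweep_cpp(obs, obs, rep(0L, M), rep(0L, M),
                                       as.integer(lat$state), lat$dims,
                                       lat$origin, lat$voxel_size,
                                       matrix(1, 1, 1), 0.1,
                                       0.2, 4, 0.5, 0, 0)
  expect_equal(rp$accepted, M)
  expect_equal(rp$pos, obs)
})

test_that("segmentation is deterministic given the seed and conserves transcripts", {
  tis <- small_tissue(seed = 40)
  cfg <- sampler_config(components = 3, seed = 9, gibbs_warmup = 5,
                        schedule = data.frame(voxel_xy = 4, z_layers = 1L,
                                              sweeps = 25L))
  r1 <- segment_cells(tis$transcripts, cfg)
  r2 <- segment_cells(tis$transcripts, cfg)
  expect_identical(r1$assignments, r2$assignments)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$transcripts$inferred_x, r2$transcripts$inferred_x)
  # conservation: assigned + background + filtered = M
  expect_equal(sum(r1$status == "assigned") + sum(r1$status == "background") +
                 sum(r1$status == "filtered"), r1$M)
  expect_equal(sum(r1$counts) + sum(r1$X_bg) +
                 sum(r1$status == "filtered"), r1$M)
})

test_that("finalization drops cells below the 10-transcript threshold", {
  # two cells: 9 transcripts in one, 10 in the other
  st <- array(0L, dim = c(6, 1, 1))
  st[1:3, 1, 1] <- 1L
  st[4:6, 1, 1] <- 2L
  lat <- lattice_with_state(st, voxel_size = c(1, 1, 1))
  cells <- cell_state(lat, 2)
  params <- init_model_params(1, 2, prior_config(k = 1))
  cfg <- sampler_config(components = 1)
  gene <- rep(1L, 19)
  tvox <- c(rep(0L, 9), rep(3L, 10))
  pos <- cbind(c(rep(0.5, 9), rep(3.5, 10)), 0.5, 0.5)
  res <- finalize_segmentation(lat, cells, params, cfg, gene,
                               gene_levels = "g", tvox = tvox,
                               obs = pos, pos = pos, cell_ids = c(101L, 102L))
  expect_equal(nrow(res$cell_meta), 1L)
  expect_equal(res$cell_meta$cell, "102")
  expect_equal(sum(res$status == "filtered"), 9L)
  expect_equal(sum(res$counts), 10)
  # boundary case: exactly 10 is retained
  expect_equal(res$cell_meta$transcripts, 10)
})

test_that("traced polygons are closed rings with exact raster area", {
  set.seed(41)
  # an irregular but connected blob
  st <- array(0L, dim = c(12, 12, 1))
  blob <- matrix(c(3,3, 4,3, 5,3, 5,4, 5,5, 4,5, 6,4, 7,4, 7,5, 6,3),
                 ncol = 2, byrow = TRUE)
  for (r in seq_len(nrow(blob))) st[blob[r, 1], blob[r, 2], 1] <- 1L
  lat <- lattice_with_state(st)
  polys <- trace_cell_polygons(lat, 1L)
  expect_length(polys, 1)
  ring <- polys[[1]]$ring
  expect_equal(ring[1, ], ring[nrow(ring), ])  # closed
  expect_equal(polys[[1]]$area_um2, nrow(blob))  # shoelace = voxel count
  # a plain rectangle
  st2 <- array(0L, dim = c(8, 8, 1)); st2[2:5, 3:6, 1] <- 1L
  polys2 <- trace_cell_polygons(lattice_with_state(st2), 1L)
  expect_equal(polys2[[1]]$area_um2, 16)
  expect_equal(nrow(polys2[[1]]$ring), 17)  # 16 unit edges + closure
})
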