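# Voxel-grid geometry, cell bookkeeping, connectivity and perimeter
# predicates.

test_that("build_lattice covers the bounding box with the requested geometry", {
  tt <- data.frame(gene = "a", x = c(0, 40), y = c(0, 40), z = c(0, 0))
  lat <- build_lattice(tt, voxel_size = c(4, 4), z_layers = 1)
  expect_equal(lat$dims, c(10L, 10L, 1L))
  expect_true(all(lat$state == 0L))

  single <- build_lattice(data.frame(gene = "a", x = 3, y = 7, z = 1),
                          voxel_size = c(4, 4))
  expect_equal(single$dims, c(1L, 1L, 1L))
  expect_equal(voxel_of(single, c(3, 7, 1)), c(0L, 0L, 0L))

  expect_error(build_lattice(tt[0, ], c(4, 4)))
  expect_error(build_lattice(data.frame(gene = "a", x = NaN, y = 0, z = 0),
                             c(4, 4)))
})

test_that("voxel_of matches the half-open floor formula on random clouds", {
  cloud <- random_cloud(1000, seed = 11)
  lat <- build_lattice(cloud, voxel_size = c(3.7, 2.1, 5), z_layers = 2)
  idx <- voxel_of(lat, as.matrix(cloud[, c("x", "y", "z")]))
  # containment
  expect_true(all(idx >= 0))
  expect_true(all(sweep(idx, 2, lat$dims, "<")))
  # brute-force formula with clamping at the max edge
  ref <- floor(sweep(sweep(as.matrix(cloud[, c("x", "y", "z")]), 2,
                           lat$origin), 2, lat$voxel_size, "/"))
  ref <- pmin(ref, matrix(lat$dims - 1, nrow(ref), 3, byrow = TRUE))
  expect_equal(unname(idx), unname(ref), ignore_attr = TRUE)
  # half-open convention on an interior boundary
  lat1 <- build_lattice(data.frame(gene = "a", x = c(0, 4), y = c(0, 4),
                                   z = 0), c(1, 1))
  expect_equal(voxel_of(lat1, c(1.0, 0.5, 0))[1], 1L)
  expect_error(voxel_of(lat1, c(9, 0, 0)))
})

test_that("moore_neighbors counts interior, corner and single-layer cases", {
  lat <- lattice_with_state(array(0L, dim = c(3, 3, 3)))
  expect_equal(nrow(moore_neighbors(lat, c(1, 1, 1))), 26)
  expect_equal(nrow(moore_neighbors(lat, c(0, 0, 0))), 7)
  flat <- lattice_with_state(array(0L, dim = c(5, 5, 1)))
  expect_lte(nrow(moore_neighbors(flat, c(2, 2, 0))), 8)
})

test_that("is_local_articulation agrees with a flood-fill oracle", {
  set.seed(42)
  mismatch <- 0L
  for (rep in 1:2000) {
    state <- array(sample(0:2, 27, replace = TRUE, prob = c(0.3, 0.5, 0.2)),
                   dim = c(3, 3, 3))
    lat <- lattice_with_state(state)
    j <- c(1L, 1L, 1L)
    got <- is_local_articulation(lat, j, 1L)
    want <- articulation_oracle(state, j, 1L)
    if (got != want) mismatch <- mismatch + 1L
  }
  expect_identical(mismatch, 0L)
})

test_that("articulation test handles the stated edge cases", {
  # only one same-label Moore neighbor: not an articulation point
  st <- array(0L, dim = c(3, 3, 1))
  st[2, 2, 1] <- 1L
  st[1, 1, 1] <- 1L
  lat <- lattice_with_state(st)
  expect_false(is_local_articulation(lat, c(1, 1, 0), 1L))
  # j bridges two opposite corners: articulation
  st2 <- array(0L, dim = c(3, 3, 1))
  st2[1, 1, 1] <- 1L
  st2[2, 2, 1] <- 1L
  st2[3, 3, 1] <- 1L
  lat2 <- lattice_with_state(st2)
  expect_true(is_local_articulation(lat2, c(1, 1, 0), 1L))
})

test_that("layer perimeter tallies match hand counts", {
  mk <- function(fill) {
    st <- array(0L, dim = c(6, 6, 1))
    for (r in seq_len(nrow(fill))) st[fill[r, 1], fill[r, 2], 1] <- 1L
    cell_state(lattice_with_state(st), 1)
  }
  # single interior voxel: all 8 in-plane neighbors mismatch
  expect_equal(mk(cbind(3, 3))$layer_perimeter_raw[1, 1], 8L)
  expect_equal(layer_perimeter(mk(cbind(3, 3)), 1, 0, xi = 1), 8)
  # 2x2 block: 5 of 8 outside for each voxel
  sq <- as.matrix(expand.grid(3:4, 3:4))
  expect_equal(mk(sq)$layer_perimeter_raw[1, 1], 20L)
  # 1x3 row: ends 7 each, middle 6
  row3 <- cbind(2:4, 3)
  expect_equal(mk(row3)$layer_perimeter_raw[1, 1], 20L)
})

test_that("perimeter bound matches the disk arithmetic and accepts disks", {
  # |V| = 100 with 1 um^2 voxels: bound = 1.3 * 2 * sqrt(100 pi)
  st <- array(0L, dim = c(30, 30, 1))
  st[1:10, 1:10, 1] <- 1L
  cs <- cell_state(lattice_with_state(st), 1)
  expect_equal(1.3 * 2 * sqrt(pi * 100), 46.08, tolerance = 1e-3)
  expect_true(perimeter_bound_ok(cs, 1, 0, b_factor = 1.3))
  # empty layer is vacuously fine even with a zero bound
  cs0 <- cell_state(lattice_with_state(array(0L, dim = c(3, 3, 2))), 1)
  expect_true(perimeter_bound_ok(cs0, 1, 1, b_factor = 0))
  # a rasterized disk satisfies the bound with the calibrated constant
  r <- 20
  n <- 2 * r + 5
  xs <- matrix(seq_len(n), n, n)
  disk <- (xs - (n + 1) / 2)^2 + (t(xs) - (n + 1) / 2)^2 <= r^2
  csd <- cell_state(lattice_with_state(array(disk + 0L, dim = c(n, n, 1))), 1)
  expect_true(perimeter_bound_ok(csd, 1, 0, b_factor = 1.3))
})

test_that("xi calibration reproduces disk circumference within 5% at all radii", {
  xi <- calibrate_xi()
  for (r in c(10, 25, 50, 100)) {
    raw <- voxseg:::.disk_raw_perimeter(r)
    expect_lt(abs(xi * raw - 2 * pi * r) / (2 * pi * r), 0.05)
  }
})

test_that("initialize_from_nuclei assigns plurality labels and prunes", {
  # one voxel with three transcripts of one label
  tt <- data.frame(gene = "a", x = c(1.1, 1.5, 1.9), y = 1.5, z = 0,
                   nucleus = 7L)
  lat <- build_lattice(data.frame(gene = "a", x = c(0, 8), y = c(0, 8), z = 0),
                       c(1, 1))
  ini <- initialize_from_nuclei(lat, rbind(tt, data.frame(gene = "a", x = 7,
                                                          y = 7, z = 0,
                                                          nucleus = NA)))
  expect_equal(sum(ini$lattice$state > 0), 1L)
  expect_equal(ini$lattice$state[2, 2, 1], 1L)  # label 7 -> internal id 1
  expect_equal(ini$cell_ids, 7L)

  # tie broken by larger neighborhood support
  tt2 <- data.frame(gene = "a",
                    x = c(1.2, 1.8, 1.4, 1.6, 2.5, 3.5),
                    y = c(1.5, 1.5, 1.5, 1.5, 1.5, 1.5), z = 0,
                    nucleus = c(1L, 1L, 2L, 2L, 1L, 1L))
  lat2 <- build_lattice(data.frame(gene = "a", x = c(0, 8), y = c(0, 8), z = 0),
                        c(1, 1))
  ini2 <- initialize_from_nuclei(lat2, tt2)
  expect_equal(ini2$lattice$state[2, 2, 1], 1L)  # label 1 wins the tie

  # random labeled cloud: voxel tally equals labeled-voxel count minus pruning
  set.seed(5)
  cl <- random_cloud(400, hi = c(30, 30, 4), seed = 5)
  cl$nucleus <- sample(c(NA, 1:6), 400, replace = TRUE)
  lat3 <- build_lattice(cl, c(2, 2), z_layers = 2)
  ini3 <- initialize_from_nuclei(lat3, cl)
  vox_lab <- unique(voxseg:::.transcript_voxels(lat3, cl[!is.na(cl$nucleus), ]))
  expect_lte(sum(ini3$cells$cell_voxels), length(vox_lab))
  expect_true(all(ini3$cells$cell_voxels > 0))
  expect_true(audit_cell_state(ini3$lattice, ini3$cells))
  expect_error(initialize_from_nuclei(lat3, transform(cl, nucleus = NA)))
})

test_that("double_resolution preserves regions, volumes and counts", {
  set.seed(8)
  cl <- random_cloud(300, hi = c(16, 16, 4), seed = 8)
  cl$nucleus <- sample(c(NA, 1:3), 300, replace = TRUE)
  lat <- build_lattice(cl, c(4, 4), z_layers = 1)
  ini <- initialize_from_nuclei(lat, cl)
  vol_before <- ini$cells$volume_um3
  tv_before <- voxseg:::.transcript_voxels(ini$lattice, cl)
  assign_before <- ini$lattice$state[tv_before + 1L]

  ref <- double_resolution(ini$lattice, ini$cells, split_z = TRUE)
  expect_equal(ref$lattice$dims, ini$lattice$dims * 2L)
  expect_equal(ref$cells$cell_voxels, ini$cells$cell_voxels * 8)
  expect_equal(ref$cells$volume_um3, vol_before)
  # per-transcript assignments (hence X_gc) unchanged
  tv_after <- voxseg:::.transcript_voxels(ref$lattice, cl)
  expect_equal(ref$lattice$state[tv_after + 1L], assign_before)
  expect_true(audit_cell_state(ref$lattice, ref$cells))
})

test_that("checkerboard phases partition the lattice in a 2-periodic pattern", {
  lat <- lattice_with_state(array(0L, dim = c(4, 4, 1)))
  sch <- checkerboard_phases(lat, 2)
  expect_equal(sort(unique(as.integer(sch$phase))), 0:3)
  expect_equal(as.integer(table(sch$phase)), rep(4L, 4))
  big <- lattice_with_state(array(0L, dim = c(12, 12, 2)))
  schb <- checkerboard_phases(big, 3)
  expect_equal(length(schb$phase), prod(big$dims))
  expect_error(checkerboard_phases(big, 1))
})

test_that("edge pool membership equals a full mismatch rescan", {
  set.seed(13)
  st <- array(sample(0:3, 5 * 4 * 2, replace = TRUE), dim = c(5, 4, 2))
  lat <- lattice_with_state(st)
  pool <- edge_pool(lat)
  # brute-force rescan over ordered von Neumann pairs
  ref <- list()
  d <- dim(st)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    for (delta in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                       c(0, 0, 1), c(0, 0, -1))) {
      q <- c(x, y, z) + delta
      if (any(q < 1) || any(q > d)) next
      if (st[x, y, z] != st[q[1], q[2], q[3]]) {
        a <- (x - 1) + d[1] * ((y - 1) + d[2] * (z - 1))
        b <- (q[1] - 1) + d[1] * ((q[2] - 1) + d[2] * (q[3] - 1))
        ref[[length(ref) + 1]] <- c(a, b)
      }
    }
  }
  ref <- do.call(rbind, ref)
  expect_equal(nrow(pool), nrow(ref))
  key <- function(m) sort(m[, 1] * prod(d) + m[, 2])
  expect_equal(key(pool), key(ref))
})
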