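# Shared fixtures, all built in code.

# uniform random transcript cloud over a box
random_cloud <- function(n, lo = c(0, 0, 0), hi = c(40, 40, 8), seed = 1) {
  set.seed(seed)
  data.frame(gene = sample(c("a", "b", "c"), n, replace = TRUE),
             x = runif(n, lo[1], hi[1]),
             y = runif(n, lo[2], hi[2]),
             z = runif(n, lo[3], hi[3]))
}

# a lattice with a given state array
lattice_with_state <- function(state, voxel_size = c(1, 1, 1),
                               origin = c(0, 0, 0)) {
  structure(list(origin = origin, voxel_size = voxel_size,
                 dims = dim(state), state = state),
            class = "voxel_lattice")
}

# flood-fill component count oracle over an arbitrary voxel set
# (Moore adjacency), independent of the package's C++ path
flood_fill_components <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(0L)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      a <- queue[[1]]
      queue <- queue[-1]
      adj <- which(comp == 0L &
                     abs(coords[, 1] - coords[a, 1]) <= 1 &
                     abs(coords[, 2] - coords[a, 2]) <= 1 &
                     abs(coords[, 3] - coords[a, 3]) <= 1)
      comp[adj] <- cur
      queue <- c(queue, adj)
    }
  }
  cur
}

# brute-force articulation oracle: does flipping voxel j change the number
# of Moore components of `label` within Moore(j) + j?
articulation_oracle <- function(state, j, label) {
  d <- dim(state)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- sweep(nb, 2, j, "+")
  keep <- nb[, 1] >= 0 & nb[, 1] < d[1] & nb[, 2] >= 0 & nb[, 2] < d[2] &
    nb[, 3] >= 0 & nb[, 3] < d[3]
  nb <- nb[keep, , drop = FALSE]
  vals <- state[nb + 1L]
  centre <- apply(nb, 1, function(r) all(r == j))
  members_without <- nb[vals == label & !centre, , drop = FALSE]
  with_j <- rbind(members_without, j)
  flood_fill_components(members_without) != flood_fill_components(with_j)
}

# tiny deterministic tissue for pipeline tests
small_tissue <- function(seed = 3, n_cells = 12, domain = 110) {
  generate_tissue(synthetic_config(n_cells = n_cells, domain_um = domain,
                                   seed = seed))
}
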