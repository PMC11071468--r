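# Segmentation quality metrics: the spurious co-expression benchmark and
# absorbing random-walk proximity on Delaunay cell-neighborhood graphs.

#' Censored log-proportions transform
#'
#' Divides each cell's count vector by its total, floors the proportions at
#' 1e-4, and takes the natural log.  The standard preprocessing before
#' building expression neighbor graphs on these data.
#'
#' @param counts genes x cells count matrix; every cell total must be > 0.
#' @param floor lower bound on proportions.
#' @return transformed matrix, same shape; all entries <= 0.
#' @export
censored_log_proportions <- function(counts, floor = 1e-4) {
  tot <- colSums(counts)
  if (any(tot <= 0)) stop("zero-total cell in counts")
  log(pmax(sweep(counts, 2, tot, "/"), floor))
}

#' Conditional co-expression matrix
#'
#' C[i, j] = |P_i intersect P_j| / |P_j| where P_i is the set of cells with
#' at least one count of gene i.  C[j, j] = 1 for any expressed gene; genes
#' expressed nowhere give C[., j] = 0 and are flagged.
#'
#' @param counts genes x cells count matrix.
#' @return gene x gene matrix with attribute `empty_genes` (indices with
#'   empty P_j).
#' @export
conditional_coexpression <- function(counts) {
  B <- (counts >= 1) + 0
  N <- B %*% t(B)             # N[i, j] = |P_i intersect P_j|
  nj <- diag(N)
  C <- sweep(N, 2, pmax(nj, 1), "/")
  C[, nj == 0] <- 0
  attr(C, "empty_genes") <- which(nj == 0)
  C
}

#' Identify spuriously co-expressed gene pairs
#'
#' Pairs whose conditional co-expression inflates at least `fold_threshold`
#' fold when nuclear boundaries are (deliberately badly) expanded:
#' log2(C'[i, j] / C[i, j]) >= log2(fold_threshold).  Pairs with zero
#' nuclear co-expression are excluded (undefined ratio) and reported in the
#' `zero_pairs` attribute.
#'
#' @param C_nuclear,C_expanded conditional co-expression matrices over the
#'   same gene vocabulary (nuclear and expanded segmentation).
#' @param fold_threshold fold-change threshold (1.5).
#' @return data frame of pairs (i, j, C_nuclear, C_expanded, log2_ratio).
#' @export
find_spurious_pairs <- function(C_nuclear, C_expanded, fold_threshold = 1.5) {
  stopifnot(identical(dim(C_nuclear), dim(C_expanded)))
  m <- nrow(C_nuclear)
  off <- which(row(C_nuclear) != col(C_nuclear))
  zero <- off[C_nuclear[off] == 0 & C_expanded[off] > 0]
  ok <- off[C_nuclear[off] > 0]
  lr <- log2(C_expanded[ok] / C_nuclear[ok])
  sel <- ok[lr >= log2(fold_threshold)]
  out <- data.frame(i = row(C_nuclear)[sel], j = col(C_nuclear)[sel],
                    C_nuclear = C_nuclear[sel], C_expanded = C_expanded[sel],
                    log2_ratio = log2(C_expanded[sel] / C_nuclear[sel]))
  attr(out, "zero_pairs") <- cbind(i = row(C_nuclear)[zero],
                                   j = col(C_nuclear)[zero])
  out
}

#' Down-sample counts to a fixed per-cell total
#'
#' Keeps only cells with at least `total` transcripts and redraws each
#' retained cell's vector from Multinomial(total, observed proportions), so
#' every output cell has exactly `total` counts but matches the observed
#' proportions in expectation.  Guards the co-expression benchmark against
#' being cheated by assigning fewer transcripts or predicting too many
#' cells.
#'
#' @param counts genes x cells count matrix.
#' @param total target per-cell total (50).
#' @return genes x cells matrix over the retained cells, every column
#'   summing to exactly `total`.
#' @export
downsample_counts <- function(counts, total = 50L) {
  keep <- colSums(counts) >= total
  X <- counts[, keep, drop = FALSE]
  out <- apply(X, 2, function(v) rmultinom(1, total, v / sum(v))[, 1])
  out <- matrix(out, nrow = nrow(counts),
                dimnames = list(rownames(counts), colnames(X)))
  out
}

#' Relative spurious co-expression scores
#'
#' For each spurious pair, the ratio of the method's conditional
#' co-expression to the nuclear segmentation's.  Both count sets are
#' expected to be down-sampled (see [downsample_counts()]) so totals are
#' comparable.  Pairs with zero nuclear co-expression are excluded and
#' counted in `n_excluded`.
#'
#' @param method_counts,nuclear_counts genes x cells matrices (down-sampled).
#' @param spurious_pairs data frame with columns `i`, `j` (from
#'   [find_spurious_pairs()]).
#' @return list with `scores` (per-pair ratio), `quantiles`, `n_excluded`.
#' @export
relative_spurious_score <- function(method_counts, nuclear_counts,
                                    spurious_pairs) {
  if (nrow(spurious_pairs) == 0) stop("empty spurious-pair list")
  Cm <- conditional_coexpression(method_counts)
  Cn <- conditional_coexpression(nuclear_counts)
  ij <- cbind(spurious_pairs$i, spurious_pairs$j)
  num <- Cm[ij]; den <- Cn[ij]
  ok <- den > 0
  scores <- num[ok] / den[ok]
  list(scores = scores,
       quantiles = quantile(scores, c(0.25, 0.5, 0.75), names = TRUE),
       n_excluded = sum(!ok))
}

#' Delaunay cell-neighborhood graph with absorbing states
#'
#' Builds the Delaunay triangulation of the cell centroids (x, y), assigns
#' uniform transition probability to each transient cell's outgoing edges,
#' and deletes edges outgoing from absorbing cells (those of
#' `absorbing_type`).  Degenerate point sets are perturbed by a
#' deterministic 1e-9 jitter.
#'
#' @param centroids n x 2 matrix (or data frame) of cell positions.
#' @param types per-cell type labels.
#' @param absorbing_type the type treated as absorbing (e.g. tumor).
#' @return a `proximity_graph`: adjacency list, transient/absorbing index
#'   sets, and the sparse transient-to-transient transition matrix `Q`.
#' @export
delaunay_graph <- function(centroids, types, absorbing_type) {
  xy <- as.matrix(centroids)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  stopifnot(n >= 3, length(types) == n)
  jit <- ((seq_len(n) * 2654435761) %% 1000) * 1e-12
  tri <- deldir::deldir(xy[, 1] + jit, xy[, 2] + rev(jit))
  ed <- tri$delsgs[, c("ind1", "ind2")]
  adj <- vector("list", n)
  for (r in seq_len(nrow(ed))) {
    a <- ed[r, 1]; b <- ed[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj <- lapply(adj, function(v) sort(unique(v)))
  g <- proximity_graph(adj, types, absorbing_type)
  g$centroids <- xy
  g
}

#' Build a proximity graph from an adjacency list
#'
#' General constructor behind [delaunay_graph()]: any undirected
#' neighborhood structure works (k-nearest-neighbor graphs, hand-built
#' chains).  Transient cells get uniform probability over all their
#' neighbors; absorbing cells keep incoming edges only.
#'
#' @param adjacency list of integer neighbor vectors, one per cell.
#' @param types per-cell type labels.
#' @param absorbing_type the absorbing type.
#' @return a `proximity_graph` with the sparse transient-to-transient
#'   transition matrix `Q`.
#' @export
proximity_graph <- function(adjacency, types, absorbing_type) {
  n <- length(adjacency)
  stopifnot(length(types) == n)
  absorbing <- which(types == absorbing_type)
  transient <- setdiff(seq_len(n), absorbing)
  # sparse Q over transient nodes (uniform over all neighbors, including
  # absorbing ones; columns into absorbing states belong to R, not Q)
  ti <- match(seq_len(n), transient)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (a in transient) {
    nb <- adjacency[[a]]
    if (!length(nb)) next
    p <- 1 / length(nb)
    tn <- nb[!is.na(ti[nb])]
    ii <- c(ii, rep(ti[a], length(tn)))
    jj <- c(jj, ti[tn])
    xx <- c(xx, rep(p, length(tn)))
  }
  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(length(transient), length(transient)))
  structure(list(n = n, adjacency = adjacency, types = types,
                 absorbing = absorbing, transient = transient, Q = Q),
            class = "proximity_graph")
}

#' Expected hitting time to absorption
#'
#' Solves the sparse linear system (I - Q) t = 1 for the expected number of
#' random-walk steps from each transient cell until an absorbing cell is
#' reached.  Transient cells with no path to an absorbing cell get Inf.
#'
#' @param graph a `proximity_graph`.
#' @return numeric vector over all cells: 0 for absorbing cells, the
#'   expected hitting time for transient ones (Inf if unreachable).
#' @export
expected_hitting_time <- function(graph) {
  n <- graph$n
  t_all <- numeric(n)
  if (!length(graph$transient)) return(t_all)
  if (!length(graph$absorbing)) return(replace(t_all, graph$transient, Inf))
  # reachability to absorption along transient out-edges (fixpoint over the
  # reversed graph; absorbing nodes need not list their own neighbors)
  reach <- logical(n)
  reach[graph$absorbing] <- TRUE
  repeat {
    grew <- FALSE
    for (a in graph$transient) {
      if (!reach[a] && any(reach[graph$adjacency[[a]]])) {
        reach[a] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  tr <- graph$transient
  sub <- which(reach[tr])          # positions within the transient set
  t_tr <- rep(Inf, length(tr))
  if (length(sub)) {
    Q <- graph$Q[sub, sub, drop = FALSE]
    A <- Matrix::Diagonal(length(sub)) - Q
    t_tr[sub] <- as.numeric(Matrix::solve(A, rep(1, length(sub))))
  }
  t_all[tr] <- t_tr
  t_all
}

#' Normalized expected hitting time
#'
#' Removes the influence of local cell-type composition: each transient cell
#' is first sent on a k-step random walk (shuffling it within its local
#' neighborhood), the hitting time at the walk's endpoint is averaged over
#' repeats as a background, and the relative score t_i / background_i is
#' returned.  It is about 1 under random spatial organization of the same
#' cells, below 1 for types genuinely closer to the absorbing type than
#' their neighborhood composition implies.
#'
#' With the default `absorbing_walks = "avoid"`, background walks move over
#' non-absorbing cells only, so the shuffle repositions the cell among its
#' transient neighbors.  `"terminate"` lets walks step onto absorbing cells
#' and end there with remaining hitting time 0; note that choice makes the
#' background systematically smaller than t (by the expected number of
#' absorbed steps), so relative scores are then biased above 1.
#'
#' @param graph a `proximity_graph`.
#' @param k_steps walk length (10).
#' @param repeats walks averaged per cell (100).
#' @param absorbing_walks background-walk treatment of absorbing cells.
#' @return data frame over transient cells: `cell`, `t`, `t_background`,
#'   `relative`.
#' @export
normalized_hitting_time <- function(graph, k_steps = 10L, repeats = 100L,
                                    absorbing_walks = c("avoid", "terminate")) {
  stopifnot(k_steps >= 0, repeats >= 1)
  absorbing_walks <- match.arg(absorbing_walks)
  t_all <- expected_hitting_time(graph)
  tr <- graph$transient
  is_abs <- logical(graph$n)
  is_abs[graph$absorbing] <- TRUE
  adj <- graph$adjacency
  if (absorbing_walks == "avoid")
    adj <- lapply(adj, function(v) v[!is_abs[v]])
  deg <- lengths(adj)
  # CSR adjacency for vectorized stepping
  off <- c(0L, cumsum(deg))
  flat <- unlist(adj, use.names = FALSE)

  bg <- numeric(length(tr))
  for (r in seq_len(repeats)) {
    cur <- tr
    if (k_steps > 0) {
      for (s in seq_len(k_steps)) {
        active <- !is_abs[cur] & deg[cur] > 0
        if (!any(active)) break
        a <- which(active)
        pick <- off[cur[a]] + 1L + as.integer(floor(runif(length(a)) * deg[cur[a]]))
        cur[a] <- flat[pick]
      }
    }
    bg <- bg + t_all[cur]
  }
  bg <- bg / repeats
  data.frame(cell = tr, t = t_all[tr], t_background = bg,
             relative = t_all[tr] / bg)
}
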