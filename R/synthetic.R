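# Synthetic spatial-transcriptomics tissue with known ground truth, built
# from the model's own generative assumptions: compact cells rasterized from
# a radius-clipped Voronoi partition of Poisson-disk-sampled centers,
# per-component Gamma expression rates, uniform-within-cell Poisson
# transcript placement, uniform background noise, and Normal-mixture
# positional diffusion.

#' Synthetic tissue configuration
#'
#' Defaults emulate a small, sparse patch of an imaging-based panel run:
#' 50 cells of ~8 um radius in a 200 x 200 um field, 30 genes in 3
#' components with 10 strong marker genes each (mean in-cell rates 0.1 and
#' 0.005 transcripts/um^3 for markers and non-markers, giving roughly 220
#' transcripts per cell), background at 5e-3 transcripts/um^3 (~2% of
#' transcripts), and the diffusion mixture rho = 0.2, sigma_a = 4,
#' sigma_b = 0.5 um.
#'
#' @param n_cells,m_genes,k_components tissue dimensions.
#' @param domain_um field edge length (square, flat z).
#' @param mean_radius_um mean cell radius.
#' @param sdlog_volume log-scale sd of per-cell areas.
#' @param marker_genes_per_component strong genes per component.
#' @param alpha_marker,beta_marker,alpha_other,beta_other Gamma shape/rate
#'   of in-cell expression rates (transcripts/um^3).
#' @param background_rate uniform noise rate (transcripts/um^3).
#' @param diffusion list with `rho`, `sigma_a`, `sigma_b` (um).
#' @param nuclear_fraction fraction of each cell's area treated as nucleus;
#'   transcripts generated inside it carry the nuclear label.
#' @param seed RNG seed.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_cells = 50L, m_genes = 30L, k_components = 3L,
                             domain_um = 200, mean_radius_um = 8,
                             sdlog_volume = 0.25,
                             marker_genes_per_component = 10L,
                             alpha_marker = 2, beta_marker = 20,
                             alpha_other = 0.5, beta_other = 100,
                             background_rate = 5e-3,
                             diffusion = list(rho = 0.2, sigma_a = 4,
                                              sigma_b = 0.5),
                             nuclear_fraction = 0.35, seed = 1L) {
  stopifnot(n_cells >= 1, m_genes >= 1, k_components >= 1, domain_um > 0,
            mean_radius_um > 0, nuclear_fraction > 0, nuclear_fraction <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

# Poisson-disk (dart-throwing) center placement
.poisson_disk <- function(n, domain, min_dist, max_tries = 2000L * n) {
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("infeasible packing: too many cells for the domain")
    p <- runif(2, 0, domain)
    if (placed == 0L ||
        min(sqrt((pts[seq_len(placed), 1] - p[1])^2 +
                 (pts[seq_len(placed), 2] - p[2])^2)) >= min_dist) {
      placed <- placed + 1L
      pts[placed, ] <- p
    }
  }
  pts
}

#' Generate synthetic tissue with ground truth
#'
#' Cells are compact contiguous regions: the Voronoi partition of
#' Poisson-disk-sampled centers, clipped to per-cell radii drawn from the
#' log-normal area model and rasterized at 1 um.  Per-cell expression rates
#' are Gamma draws from the cell's component; transcript counts are Poisson
#' in the cell's area with uniform placement; background transcripts are
#' uniform over the domain.  Transcripts generated within the nuclear disk
#' of their cell carry the nuclear label, emulating a nuclear segmentation
#' input.  Deterministic given the config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `transcripts` (a `transcript_table`-shaped data frame:
#'   gene, x, y, z, nucleus) and `truth` (per-transcript true cell labels
#'   and positions, the rasterized label mask, true tau, z, volumes).
#' @export
generate_tissue <- function(cfg = synthetic_config()) {
  set.seed(cfg$seed)
  n <- cfg$n_cells; m <- cfg$m_genes; k <- cfg$k_components
  centers <- .poisson_disk(n, cfg$domain_um, 2 * cfg$mean_radius_um)

  mean_area <- pi * cfg$mean_radius_um^2
  areas <- exp(rnorm(n, log(mean_area), cfg$sdlog_volume))
  radii <- sqrt(areas / pi)
  z_true <- sample.int(k, n, replace = TRUE)

  # component rate parameters: block markers
  alpha <- matrix(cfg$alpha_other, m, k)
  beta <- matrix(cfg$beta_other, m, k)
  nmark <- min(cfg$marker_genes_per_component, floor(m / k))
  for (t in seq_len(k)) {
    idx <- ((t - 1) * nmark + 1):(t * nmark)
    alpha[idx, t] <- cfg$alpha_marker
    beta[idx, t] <- cfg$beta_marker
  }
  tau <- matrix(rgamma(m * n, shape = alpha[, z_true], rate = beta[, z_true]),
                m, n)

  # rasterize: 1 um grid, nearest center within its clipped radius
  g <- floor(cfg$domain_um)
  gx <- rep(seq_len(g) - 0.5, times = g)
  gy <- rep(seq_len(g) - 0.5, each = g)
  lab <- integer(g * g)
  best <- rep(Inf, g * g)
  for (c_i in seq_len(n)) {
    d2 <- (gx - centers[c_i, 1])^2 + (gy - centers[c_i, 2])^2
    hit <- d2 <= radii[c_i]^2 & d2 < best
    lab[hit] <- c_i
    best[hit] <- d2[hit]
  }
  vox_of_cell <- split(seq_len(g * g), factor(lab, levels = seq_len(n)))
  nu <- lengths(vox_of_cell)  # um^2 x 1 um nominal thickness = um^3
  if (any(nu == 0)) stop("a cell rasterized to zero area; enlarge the domain")

  # transcripts: Poisson counts per gene and cell, uniform within the region
  lam <- sweep(tau, 2, nu, "*")
  X <- matrix(rpois(m * n, lam), m, n)
  per_cell <- colSums(X)
  cell_lab <- rep(seq_len(n), per_cell)
  gene_lab <- unlist(lapply(seq_len(n), function(c_i) rep(seq_len(m), X[, c_i])),
                     use.names = FALSE)
  vox_pick <- unlist(lapply(seq_len(n), function(c_i) {
    v <- vox_of_cell[[c_i]]
    v[sample.int(length(v), per_cell[c_i], replace = TRUE)]
  }), use.names = FALSE)
  px <- gx[vox_pick] + runif(length(vox_pick), -0.5, 0.5)
  py <- gy[vox_pick] + runif(length(vox_pick), -0.5, 0.5)

  n_bg <- rpois(1, cfg$background_rate * cfg$domain_um^2)  # 1 um thickness
  bx <- runif(n_bg, 0, cfg$domain_um)
  by <- runif(n_bg, 0, cfg$domain_um)
  bg_gene <- sample.int(m, n_bg, replace = TRUE)

  gene_all <- c(gene_lab, bg_gene)
  x_all <- c(px, bx)
  y_all <- c(py, by)
  cell_all <- c(cell_lab, rep(0L, n_bg))

  # nuclear labels: transcripts inside the nuclear disk of their own cell
  r_nuc <- radii * sqrt(cfg$nuclear_fraction)
  d_cen <- sqrt((x_all - centers[pmax(cell_all, 1L), 1])^2 +
                (y_all - centers[pmax(cell_all, 1L), 2])^2)
  nucleus <- ifelse(cell_all > 0L & d_cen <= r_nuc[pmax(cell_all, 1L)],
                    cell_all, NA_integer_)

  transcripts <- data.frame(gene = sprintf("g%02d", gene_all),
                            x = x_all, y = y_all, z = 0,
                            nucleus = nucleus, stringsAsFactors = FALSE)
  truth <- list(cell = cell_all,
                true_x = x_all, true_y = y_all,
                centers = centers, radii = radii, areas_raster = nu,
                label_mask = matrix(lab, g, g),
                tau = tau, z = z_true, alpha = alpha, beta = beta,
                gene = gene_all, m = m, n = n)
  list(transcripts = transcripts, truth = truth)
}

#' Apply positional diffusion to a synthetic tissue
#'
#' Displaces every observed transcript position by a draw from the
#' Normal mixture rho N(0, sigma_a^2 I) + (1 - rho) N(0, sigma_b^2 I),
#' emulating RNA leakage and positional error; the truth keeps the
#' undiffused positions.
#'
#' @param tissue output of [generate_tissue()].
#' @param diffusion list with `rho`, `sigma_a`, `sigma_b` (defaults from
#'   the tissue's config are not retained; pass explicitly to vary).
#' @return the tissue with displaced `transcripts$x`, `$y`.
#' @export
diffuse_transcripts <- function(tissue, diffusion = list(rho = 0.2,
                                                         sigma_a = 4,
                                                         sigma_b = 0.5)) {
  M <- nrow(tissue$transcripts)
  wide <- runif(M) < diffusion$rho
  sd_vec <- ifelse(wide, diffusion$sigma_a, diffusion$sigma_b)
  tissue$transcripts$x <- tissue$transcripts$x + rnorm(M, 0, sd_vec)
  tissue$transcripts$y <- tissue$transcripts$y + rnorm(M, 0, sd_vec)
  tissue
}

#' Score a segmentation against ground truth
#'
#' Matches each true cell to the predicted cell sharing the most
#' transcripts (greedy one-to-one by overlap), then reports: the fraction
#' of non-background transcripts assigned to their true cell's match;
#' background precision/recall; the predicted/true cell-count ratio; and
#' the per-matched-cell Pearson correlation of count vectors.
#'
#' @param result a `segmentation_result`.
#' @param truth the `truth` element of [generate_tissue()].
#' @return list of summary statistics.
#' @export
evaluate_segmentation <- function(result, truth) {
  stopifnot(length(result$assignments) == length(truth$cell))
  pred <- ifelse(result$status == "assigned", result$assignments, 0L)
  true <- truth$cell
  nb_true <- true > 0L

  # greedy one-to-one matching by transcript overlap
  ov <- table(true[nb_true & pred > 0L], pred[nb_true & pred > 0L])
  match_of <- rep(NA_integer_, truth$n)
  if (length(ov)) {
    df <- data.frame(ti = as.integer(rownames(ov))[row(ov)],
                     pi = as.integer(colnames(ov))[col(ov)],
                     n = as.integer(ov))
    df <- df[df$n > 0, ]
    df <- df[order(-df$n), ]
    used_p <- logical(max(df$pi))
    for (r in seq_len(nrow(df))) {
      if (is.na(match_of[df$ti[r]]) && !used_p[df$pi[r]]) {
        match_of[df$ti[r]] <- df$pi[r]
        used_p[df$pi[r]] <- TRUE
      }
    }
  }
  correct <- nb_true & !is.na(match_of[pmax(true, 1L)]) &
    pred == match_of[pmax(true, 1L)]
  accuracy <- sum(correct) / sum(nb_true)

  bg_recall <- if (any(!nb_true)) sum(pred == 0L & !nb_true) / sum(!nb_true) else NA
  bg_precision <- if (any(pred == 0L)) sum(pred == 0L & !nb_true) / sum(pred == 0L) else NA
  n_pred <- nrow(result$cell_meta)
  n_true_retained <- length(unique(true[nb_true]))

  # count-vector correlation over matched cells
  cors <- c()
  m <- truth$m
  for (ti in which(!is.na(match_of))) {
    tv <- tabulate(truth$gene[true == ti], nbins = m)
    pj <- match(as.character(result$cell_ids[match_of[ti]]),
                colnames(result$counts))
    if (is.na(pj)) next
    pv <- result$counts[, pj]
    if (sd(tv) > 0 && sd(pv) > 0) cors <- c(cors, cor(tv, pv))
  }

  list(accuracy = accuracy,
       background_recall = bg_recall,
       background_precision = bg_precision,
       cell_count_ratio = n_pred / n_true_retained,
       count_correlation = if (length(cors)) median(cors) else NA,
       n_matched = sum(!is.na(match_of)))
}

#' Fit the expression model with boundaries held fixed
#'
#' Runs the Gibbs parameter sweeps alone (no boundary sampling) on a fixed
#' count matrix and volumes, returning posterior means after burn-in.  Used
#' for parameter-recovery checks and for inspecting expression parameters
#' under a known segmentation.
#'
#' @param counts list from [tally_counts()] (or any list with `X`, `X_bg`).
#' @param volumes per-cell volumes (um^3).
#' @param total_volume total observed volume (um^3).
#' @param prior a [prior_config()].
#' @param n_sweeps,burnin Gibbs sweeps and discarded burn-in.
#' @param include_volume_in_z weight component draws by the volume model.
#' @return list with posterior means `tau`, `alpha`, `beta`, the modal
#'   component assignment `z`, mixing weights `pi`, and the final
#'   `params`.
#' @export
fit_expression_model <- function(counts, volumes, total_volume, prior,
                                 n_sweeps = 300L, burnin = 100L,
                                 include_volume_in_z = FALSE) {
  m <- nrow(counts$X); n <- ncol(counts$X)
  params <- init_model_params(m, n, prior, volumes = volumes)
  tau_acc <- matrix(0, m, n)
  alpha_acc <- matrix(0, m, prior$k)
  beta_acc <- matrix(0, m, prior$k)
  z_votes <- matrix(0L, n, prior$k)
  kept <- 0L
  for (s in seq_len(n_sweeps)) {
    params <- gibbs_sweep(counts, volumes, params, total_volume, prior,
                          include_volume_in_z = include_volume_in_z)
    if (s > burnin) {
      kept <- kept + 1L
      tau_acc <- tau_acc + params$tau
      alpha_acc <- alpha_acc + params$alpha
      beta_acc <- beta_acc + exp(-params$phi)
      z_votes[cbind(seq_len(n), params$z)] <- z_votes[cbind(seq_len(n), params$z)] + 1L
    }
  }
  list(tau = tau_acc / kept, alpha = alpha_acc / kept,
       beta = beta_acc / kept,
       z = max.col(z_votes), pi = params$pi, params = params)
}
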