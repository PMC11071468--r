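# Hierarchical Gamma-Poisson expression model, cell-volume model, nuclear
# prior, and the Gibbs updates for all model parameters.
#
# Counts are held genes x cells throughout (matching the MatrixMarket
# orientation the writers use).  tau[g, c] is the Poisson rate of gene g in
# cell c in transcripts per um^3; tau_bg[g] the spatially constant background
# rate.  Component parameters alpha[g, t] and phi[g, t] = -log beta[g, t]
# give the negative-binomial marginal X_gc ~ NB(alpha, nu_c / (nu_c + beta)).

#' Hyperparameter configuration for the expression and volume models
#'
#' Defaults are weakly informative implementation defaults (the model is
#' insensitive to them at realistic transcript counts): unit-scale Gamma
#' priors on rates and shapes, a unit-precision Normal prior on -log beta,
#' a log-normal volume prior centred on 200 um^3, and a flat Dirichlet on
#' the component weights.
#'
#' @param k number of mixture components.
#' @param e0bg,f0bg Gamma shape/rate hyperparameters of the background rate.
#' @param e0,f0 Gamma shape/rate hyperparameters for alpha and h.
#' @param gamma precision of the Normal prior on phi = -log beta.
#' @param p_nuc prior probability that a nuclear transcript stays with its
#'   nucleus (0.8 by default).
#' @param mu0,sigma0 Normal prior mean/variance for the per-component
#'   log-volume mean.
#' @param alpha0,beta0 Gamma prior shape/rate for the per-component
#'   log-volume precision.
#' @param dirichlet_conc Dirichlet concentration for the component weights.
#' @return a `prior_config` list.
#' @export
prior_config <- function(k = 10L, e0bg = 1, f0bg = 1, e0 = 1, f0 = 1,
                         gamma = 1, p_nuc = 0.8,
                         mu0 = log(200), sigma0 = 1, alpha0 = 1, beta0 = 1,
                         dirichlet_conc = 1) {
  stopifnot(k >= 1, e0bg > 0, f0bg > 0, e0 > 0, f0 > 0, gamma > 0,
            p_nuc > 0, p_nuc < 1, sigma0 > 0, alpha0 > 0, beta0 > 0,
            dirichlet_conc > 0)
  structure(list(k = as.integer(k), e0bg = e0bg, f0bg = f0bg, e0 = e0,
                 f0 = f0, gamma = gamma, p_nuc = p_nuc, mu0 = mu0,
                 sigma0 = sigma0, alpha0 = alpha0, beta0 = beta0,
                 dirichlet_conc = dirichlet_conc),
            class = "prior_config")
}

#' Initialize model parameters
#'
#' @param m gene count.
#' @param n cell count.
#' @param prior a [prior_config()].
#' @param volumes optional initial cell volumes (um^3), used to seed the
#'   volume model means.
#' @return a `model_params` list holding tau (m x n), tau_bg (m),
#'   alpha/phi (m x k), h, pi (k), z (n), mu_vol/prec_vol (k).
#' @export
init_model_params <- function(m, n, prior, volumes = NULL) {
  k <- prior$k
  mu0 <- if (!is.null(volumes) && any(volumes > 0)) {
    mean(log(volumes[volumes > 0]))
  } else prior$mu0
  structure(list(
    m = as.integer(m), n = as.integer(n), k = k,
    tau = matrix(0.01, m, n),
    tau_bg = rep(1e-5, m),
    alpha = matrix(1, m, k),
    phi = matrix(0, m, k),
    h = 1,
    pi = rep(1 / k, k),
    z = rep(seq_len(k), length.out = n),
    mu_vol = rep(mu0, k),
    prec_vol = rep(4, k)
  ), class = "model_params")
}

#' Tally transcript counts by gene and cell
#'
#' Builds the genes x cells count matrix X and the background count vector
#' from per-transcript cell assignments (0 = background).
#'
#' @param gene integer gene index per transcript (1..m).
#' @param assignment integer cell id per transcript (0 = background).
#' @param m,n gene and cell counts.
#' @return list with `X` (m x n), `X_bg` (m), and the total `M`.
#' @export
tally_counts <- function(gene, assignment, m, n) {
  keep <- assignment > 0L
  X <- matrix(0L, m, n)
  if (any(keep)) {
    tab <- table(factor(gene[keep], levels = seq_len(m)),
                 factor(assignment[keep], levels = seq_len(n)))
    X <- matrix(as.integer(tab), m, n)
  }
  X_bg <- as.integer(table(factor(gene[!keep], levels = seq_len(m))))
  list(X = X, X_bg = X_bg, M = length(gene))
}

#' Poisson point-process log-likelihood
#'
#' The full data log-likelihood: exposure terms -nu_c (tau_bg + tau_gc) for
#' every gene and cell, background exposure -tau_bg nu_0 of the unassigned
#' volume, and a point term log(tau_bg + tau_{g, cell}) per transcript
#' (tau of the unassigned state is 0).
#'
#' @param counts a list as from [tally_counts()]; only used for dimensions
#'   and conservation checking.
#' @param params a `model_params`.
#' @param volumes cell volumes nu_c in um^3.
#' @param total_volume total lattice volume in um^3.
#' @param gene,assignment per-transcript gene index and cell assignment
#'   (0 = background).
#' @return the log-likelihood (finite for strictly positive rates).
#' @export
log_likelihood <- function(counts, params, volumes, total_volume,
                           gene, assignment) {
  stopifnot(length(volumes) == params$n, total_volume >= sum(volumes))
  expo <- -sum(outer(rep(1, params$m), volumes) * sweep(params$tau, 1, params$tau_bg, "+"))
  expo <- expo - sum(params$tau_bg) * (total_volume - sum(volumes))
  rate_at <- params$tau_bg[gene] +
    ifelse(assignment > 0L, params$tau[cbind(gene, pmax(assignment, 1L))], 0)
  if (any(rate_at <= 0)) stop("zero rate at a transcript location")
  expo + sum(log(rate_at))
}

#' Incremental log-likelihood change for a boundary flip
#'
#' The change in [log_likelihood()] when one voxel moves from cell `old_cell`
#' to `new_cell` (either may be 0 = unassigned): exposure changes for the two
#' affected cells plus point-term changes for the transcripts in the flipped
#' voxel.  Matches full recomputation to floating-point accuracy.
#'
#' @param params a `model_params`.
#' @param voxel_volume volume of one voxel (um^3).
#' @param old_cell,new_cell cell ids (0 = unassigned).
#' @param genes_in_voxel integer gene indices of the transcripts in the
#'   flipped voxel (possibly empty).
#' @return the log-likelihood difference.
#' @export
delta_log_likelihood <- function(params, voxel_volume, old_cell, new_cell,
                                 genes_in_voxel = integer(0)) {
  s_old <- if (old_cell > 0) sum(params$tau[, old_cell]) else 0
  s_new <- if (new_cell > 0) sum(params$tau[, new_cell]) else 0
  d <- voxel_volume * (s_old - s_new)
  if (length(genes_in_voxel)) {
    rn <- params$tau_bg[genes_in_voxel] +
      (if (new_cell > 0) params$tau[genes_in_voxel, new_cell] else 0)
    ro <- params$tau_bg[genes_in_voxel] +
      (if (old_cell > 0) params$tau[genes_in_voxel, old_cell] else 0)
    d <- d + sum(log(rn) - log(ro))
  }
  d
}

#' Log-normal volume prior log-density
#'
#' Per-component log-normal density of a cell's volume, parameterized by the
#' component's log-volume mean and precision.
#'
#' @param v volume in um^3 (> 0).
#' @param mu log-volume mean.
#' @param prec log-volume precision.
#' @export
volume_log_prior <- function(v, mu, prec) {
  stopifnot(all(v > 0))
  -log(v) + 0.5 * log(prec) - 0.5 * log(2 * pi) - 0.5 * prec * (log(v) - mu)^2
}

#' Nuclear prior log-ratio for reassigning one transcript
#'
#' The prior puts mass `p_nuc` on a nuclear transcript keeping its nuclear
#' label and spreads `1 - p_nuc` flatly over any other assignment, so the
#' ratio between two non-matching assignments is 1.  Unlabeled transcripts
#' contribute 0.  Antisymmetric under swapping old and new.
#'
#' @param old_cell,new_cell assignments (0 = background).
#' @param nuclear_label the transcript's nuclear label (0 or NA = none).
#' @param p_nuc prior retention probability.
#' @export
nuclear_log_prior_ratio <- function(old_cell, new_cell, nuclear_label,
                                    p_nuc = 0.8) {
  if (is.na(nuclear_label) || nuclear_label == 0) return(0)
  p <- function(a) if (a == nuclear_label) p_nuc else 1 - p_nuc
  log(p(new_cell)) - log(p(old_cell))
}

# negative-binomial marginal log-pmf matrix helper:
# sum_g log NB(X_gc; alpha_gt, nu_c / (nu_c + beta_gt)) for all cells x comps
.nb_loglik_by_component <- function(X, volumes, alpha, phi) {
  m <- nrow(X); n <- ncol(X); k <- ncol(alpha)
  beta <- exp(-phi)
  out <- matrix(0, n, k)
  for (t in seq_len(k)) {
    a <- alpha[, t]
    # prob parameter of dnbinom is P(failure stops) = beta / (nu + beta)
    pr <- outer(beta[, t], volumes, function(b, v) b / (v + b))
    ll <- dnbinom(X, size = a, prob = pr, log = TRUE)
    out[, t] <- colSums(ll)
  }
  out
}

#' Gibbs update of component assignments
#'
#' Draws z_c with P(z_c = t) proportional to pi_t times the product over
#' genes of the negative-binomial marginal NB(X_gc; alpha_gt,
#' nu_c / (nu_c + beta_gt)), computed in log space.  Optionally includes the
#' per-component log-normal volume density.
#'
#' @param counts list from [tally_counts()].
#' @param volumes cell volumes (um^3).
#' @param params a `model_params`.
#' @param include_volume also weight components by the volume model.
#' @return `params` with a fresh `z`.
#' @export
sample_component_assignments <- function(counts, volumes, params,
                                         include_volume = FALSE) {
  if (params$k == 1L) {
    params$z <- rep(1L, params$n)
    return(params)
  }
  lw <- .nb_loglik_by_component(counts$X, volumes, params$alpha, params$phi)
  lw <- sweep(lw, 2, log(params$pi), "+")
  if (include_volume) {
    for (t in seq_len(params$k))
      lw[, t] <- lw[, t] +
        volume_log_prior(volumes, params$mu_vol[t], params$prec_vol[t])
  }
  mx <- apply(lw, 1, max)
  if (any(!is.finite(mx))) stop("all-zero component weights for some cell")
  w <- exp(lw - mx)
  w <- w / rowSums(w)
  u <- runif(params$n)
  params$z <- as.integer(1L + rowSums(t(apply(w, 1, cumsum)) < u))
  params$z <- pmin(params$z, params$k)
  params
}

#' Gibbs update of Poisson rates
#'
#' Conjugate Gamma updates: tau_gc ~ Gamma(alpha + X_gc, rate beta + nu_c)
#' with the component parameters of cell c, and tau_bg,g ~ Gamma(e0bg +
#' background count, rate f0bg + total volume) -- the background is exposed
#' over the whole lattice.
#'
#' @inheritParams sample_component_assignments
#' @param total_volume total lattice volume (um^3).
#' @param prior a [prior_config()].
#' @return `params` with fresh `tau` and `tau_bg`.
#' @export
sample_rates <- function(counts, volumes, params, total_volume, prior) {
  stopifnot(all(volumes > 0))
  beta <- exp(-params$phi)
  a <- params$alpha[, params$z, drop = FALSE] + counts$X
  r <- sweep(beta[, params$z, drop = FALSE], 2, volumes, "+")
  params$tau <- matrix(rgamma(length(a), shape = a, rate = r),
                       params$m, params$n)
  params$tau_bg <- rgamma(params$m, shape = prior$e0bg + counts$X_bg,
                          rate = prior$f0bg + total_volume)
  params
}

#' Chinese-restaurant-table draw
#'
#' l = sum of n Bernoulli(r / (r + i - 1)) successes; the auxiliary count
#' that makes the negative-binomial shape update conjugate.
#'
#' @param n non-negative integer counts (vectorized).
#' @param r positive rate(s), recycled.
#' @return integer draws with 0 <= l <= n (l >= 1 whenever n >= 1).
#' @export
sample_crt <- function(n, r) {
  .crt_sample_cpp(as.integer(n), as.numeric(r))
}

#' Gibbs update of the shape parameters alpha and the hyper-rate h
#'
#' Draws CRT counts l_gc ~ CRT(X_gc, alpha_{g, z_c}), then
#' alpha_gt ~ Gamma(e0 + sum l_gc, rate h - sum log(beta / (nu_c + beta)))
#' over the cells of component t, then h ~ Gamma(e0 + m k, rate f0 +
#' sum alpha).  The alpha rate is always > h > 0 since every log term is
#' negative.
#'
#' @inheritParams sample_rates
#' @return `params` with fresh `alpha` and `h`, plus the CRT table in
#'   attribute `"crt"`.
#' @export
sample_alpha_and_h <- function(counts, volumes, params, prior) {
  m <- params$m; k <- params$k
  beta <- exp(-params$phi)
  alpha_by_cell <- params$alpha[, params$z, drop = FALSE]
  ell <- matrix(sample_crt(counts$X, alpha_by_cell), m, params$n)
  lograt <- log(sweep(beta[, params$z, drop = FALSE], 2, volumes,
                      function(b, v) b / (v + b)))  # log(beta/(nu+beta)) < 0
  shp <- matrix(prior$e0, m, k)
  rte <- matrix(params$h, m, k)
  for (t in seq_len(k)) {
    ct <- which(params$z == t)
    if (length(ct)) {
      shp[, t] <- shp[, t] + rowSums(ell[, ct, drop = FALSE])
      rte[, t] <- rte[, t] - rowSums(lograt[, ct, drop = FALSE])
    }
  }
  params$alpha <- matrix(rgamma(m * k, shape = shp, rate = rte), m, k)
  params$h <- rgamma(1, shape = prior$e0 + m * k,
                     rate = prior$f0 + sum(params$alpha))
  attr(params, "crt") <- ell
  params
}

#' Polya-Gamma draw
#'
#' Samples PG(b, c), the auxiliary variable that makes the phi = -log beta
#' update conjugate Normal.  Uses a truncated sum-of-Gammas representation
#' with a deterministic tail-mean correction for b < 30 and a moment-matched
#' Normal for larger shapes (mean and variance exact in closed form).
#'
#' @param b positive shape(s).
#' @param c tilt parameter(s).
#' @param trunc number of series terms.
#' @return strictly positive draws, vectorized over the longer of b and c.
#' @export
sample_polya_gamma <- function(b, c = 0, trunc = 200L) {
  .pg_sample_cpp(as.numeric(b), as.numeric(c), as.integer(trunc))
}

#' Gibbs update of phi = -log beta
#'
#' Draws omega_gc ~ PG(X_gc + alpha_{g,z_c}, log nu_c + phi_{g,z_c}), then
#' phi_gt ~ Normal(mu*, var*) with var* = 1 / (gamma + sum omega) and
#' mu* = var* sum[(X_gc - alpha_gt)/2 - omega_gc log nu_c] over the cells of
#' component t (the canonical Polya-Gamma negative-binomial update).
#'
#' @inheritParams sample_rates
#' @param pg_trunc series truncation for the PG draws.
#' @return `params` with fresh `phi`.
#' @export
sample_beta <- function(counts, volumes, params, prior, pg_trunc = 100L) {
  m <- params$m; k <- params$k
  alpha_by_cell <- params$alpha[, params$z, drop = FALSE]
  bpar <- counts$X + alpha_by_cell
  cpar <- sweep(params$phi[, params$z, drop = FALSE], 2, log(volumes), "+")
  omega <- matrix(sample_polya_gamma(bpar, cpar, pg_trunc), m, params$n)
  prec <- matrix(prior$gamma, m, k)
  rhs <- matrix(0, m, k)
  logv <- log(volumes)
  kappa <- (counts$X - alpha_by_cell) / 2
  for (t in seq_len(k)) {
    ct <- which(params$z == t)
    if (length(ct)) {
      prec[, t] <- prec[, t] + rowSums(omega[, ct, drop = FALSE])
      rhs[, t] <- rhs[, t] + rowSums(
        kappa[, ct, drop = FALSE] -
          sweep(omega[, ct, drop = FALSE], 2, logv[ct], "*"))
    }
  }
  params$phi <- matrix(rnorm(m * k, mean = rhs / prec, sd = sqrt(1 / prec)),
                       m, k)
  params
}

#' Gibbs update of the volume model and component weights
#'
#' Per component: conjugate Normal update of the log-volume mean given its
#' member cells, Gamma update of the log-volume precision, and a
#' Dirichlet(conc + occupancy) draw of pi.  Empty components draw from their
#' priors.
#'
#' @inheritParams sample_rates
#' @return `params` with fresh `mu_vol`, `prec_vol`, `pi`.
#' @export
sample_volume_params <- function(volumes, params, prior) {
  stopifnot(all(volumes > 0))
  lv <- log(volumes)
  occ <- integer(params$k)
  for (t in seq_len(params$k)) {
    ct <- which(params$z == t)
    occ[t] <- length(ct)
    lam <- params$prec_vol[t]
    post_prec <- 1 / prior$sigma0 + occ[t] * lam
    post_mean <- (prior$mu0 / prior$sigma0 + lam * sum(lv[ct])) / post_prec
    params$mu_vol[t] <- rnorm(1, post_mean, sqrt(1 / post_prec))
    ss <- sum((lv[ct] - params$mu_vol[t])^2)
    params$prec_vol[t] <- rgamma(1, shape = prior$alpha0 + occ[t] / 2,
                                 rate = prior$beta0 + ss / 2)
  }
  g <- rgamma(params$k, shape = prior$dirichlet_conc + occ, rate = 1)
  params$pi <- g / sum(g)
  params
}

#' One full Gibbs sweep over all model parameters
#'
#' Updates, in order: component assignments z, rates tau and tau_bg, shapes
#' alpha and hyper-rate h, scales beta (via phi), and the volume model and
#' component weights pi.
#'
#' @inheritParams sample_rates
#' @param include_volume_in_z weight z draws by the volume model.
#' @param resample_pi update pi (set FALSE to keep it fixed uniform).
#' @return updated `params`.
#' @export
gibbs_sweep <- function(counts, volumes, params, total_volume, prior,
                        include_volume_in_z = TRUE, resample_pi = TRUE) {
  if (params$k > 1L)
    params <- sample_component_assignments(counts, volumes, params,
                                           include_volume = include_volume_in_z)
  params <- sample_rates(counts, volumes, params, total_volume, prior)
  params <- sample_alpha_and_h(counts, volumes, params, prior)
  params <- sample_beta(counts, volumes, params, prior)
  pi_old <- params$pi
  params <- sample_volume_params(volumes, params, prior)
  if (!resample_pi) params$pi <- pi_old
  params
}
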