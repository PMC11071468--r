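# Expression model: likelihood, priors, and every Gibbs update, checked
# against independent closed forms, enumeration and moment oracles.

make_params <- function(m, n, k = 1, tau = NULL, tau_bg = NULL) {
  p <- init_model_params(m, n, prior_config(k = k))
  if (!is.null(tau)) p$tau <- tau
  if (!is.null(tau_bg)) p$tau_bg <- tau_bg
  p
}

test_that("log-likelihood equals term-by-term brute-force summation", {
  set.seed(21)
  m <- 3; n <- 2
  tau <- matrix(rgamma(m * n, 2, 4), m, n)
  tbg <- rep(0.01, m)
  p <- make_params(m, n, tau = tau, tau_bg = tbg)
  vols <- c(5, 9)
  vtot <- 30
  gene <- c(1L, 2L, 2L, 3L, 1L)
  assign <- c(1L, 1L, 2L, 0L, 2L)
  cnt <- tally_counts(gene, assign, m, n)
  got <- log_likelihood(cnt, p, vols, vtot, gene, assign)

  # independent brute force, straight from the model definition
  want <- 0
  for (g in 1:m) for (c in 1:n) want <- want - vols[c] * (tbg[g] + tau[g, c])
  want <- want - sum(tbg) * (vtot - sum(vols))
  for (j in seq_along(gene)) {
    r <- tbg[gene[j]] + if (assign[j] > 0) tau[gene[j], assign[j]] else 0
    want <- want + log(r)
  }
  expect_equal(got, want, tolerance = 1e-12)

  # with no transcripts only exposure terms remain
  cnt0 <- tally_counts(integer(0), integer(0), m, n)
  base <- log_likelihood(cnt0, p, vols, vtot, integer(0), integer(0))
  expect_equal(base, -sum(outer(rep(1, m), vols) * sweep(tau, 1, tbg, "+")) -
                 sum(tbg) * (vtot - sum(vols)))
  # one transcript adds exactly its point term
  one <- log_likelihood(tally_counts(2L, 1L, m, n), p, vols, vtot, 2L, 1L)
  expect_equal(one - base, log(tbg[2] + tau[2, 1]))
})

test_that("incremental delta matches full recomputation and is antisymmetric", {
  set.seed(22)
  m <- 4; n <- 3
  tau <- matrix(rgamma(m * n, 2, 2), m, n)
  p <- make_params(m, n, tau = tau, tau_bg = rep(0.02, m))
  bvol <- 2.5
  vtot <- 500
  M <- 60
  gene <- sample.int(m, M, replace = TRUE)
  voxel_cell <- sample(0:n, 20, replace = TRUE)      # 20 voxels
  tvox <- sample.int(20, M, replace = TRUE)
  worst <- 0
  for (rep in 1:1000) {
    j <- sample.int(20, 1)
    old_c <- voxel_cell[j]
    new_c <- sample(setdiff(0:n, old_c), 1)
    vols <- bvol * tabulate(voxel_cell[voxel_cell > 0], nbins = n) + 1
    assign <- ifelse(voxel_cell[tvox] > 0, voxel_cell[tvox], 0L)
    ll_before <- log_likelihood(tally_counts(gene, assign, m, n), p, vols,
                                vtot, gene, assign)
    vc2 <- voxel_cell; vc2[j] <- new_c
    vols2 <- bvol * tabulate(vc2[vc2 > 0], nbins = n) + 1
    assign2 <- ifelse(vc2[tvox] > 0, vc2[tvox], 0L)
    ll_after <- log_likelihood(tally_counts(gene, assign2, m, n), p, vols2,
                               vtot, gene, assign2)
    d <- delta_log_likelihood(p, bvol, old_c, new_c,
                              genes_in_voxel = gene[tvox == j])
    worst <- max(worst, abs(d - (ll_after - ll_before)))
    # antisymmetry: reverting sums to zero
    d_back <- delta_log_likelihood(p, bvol, new_c, old_c,
                                   genes_in_voxel = gene[tvox == j])
    expect_lt(abs(d + d_back), 1e-10)
    voxel_cell <- vc2
  }
  expect_lt(worst, 1e-8)
})

test_that("volume prior is a proper density with the stated closed form", {
  mu <- log(150); prec <- 2.5
  # closed form at v = exp(mu)
  expect_equal(volume_log_prior(exp(mu), mu, prec),
               -mu + 0.5 * log(prec) - 0.5 * log(2 * pi))
  # integrates to ~1
  grid <- exp(seq(mu - 6 / sqrt(prec), mu + 6 / sqrt(prec), length.out = 4000))
  dens <- exp(volume_log_prior(grid, mu, prec))
  integral <- sum(diff(grid) * (dens[-1] + dens[-length(dens)]) / 2)
  expect_equal(integral, 1, tolerance = 1e-3)
  expect_error(volume_log_prior(-1, mu, prec))
})

test_that("nuclear prior ratio follows the retention model and is antisymmetric", {
  expect_equal(nuclear_log_prior_ratio(1, 2, 0), 0)
  expect_equal(nuclear_log_prior_ratio(1, 2, NA), 0)
  # moving a transcript off its nucleus with the default retention 0.8
  expect_equal(nuclear_log_prior_ratio(3, 1, 3, p_nuc = 0.8), log(0.2 / 0.8))
  expect_equal(nuclear_log_prior_ratio(1, 3, 3, p_nuc = 0.8),
               -nuclear_log_prior_ratio(3, 1, 3, p_nuc = 0.8))
  # between two non-matching assignments the ratio is flat
  expect_equal(nuclear_log_prior_ratio(1, 2, 3), 0)
})

test_that("component assignment draws match the enumerated posterior", {
  set.seed(23)
  m <- 2; n <- 3; k <- 2
  prior <- prior_config(k = k)
  p <- init_model_params(m, n, prior)
  p$alpha <- matrix(c(2, 0.5, 0.5, 2), m, k)
  p$phi <- matrix(c(-log(4), -log(50), -log(50), -log(4)), m, k)
  p$pi <- c(0.3, 0.7)
  vols <- c(3, 5, 8)
  X <- matrix(c(4L, 0L, 1L, 1L, 0L, 6L), m, n)
  cnt <- list(X = X, X_bg = c(0L, 0L))

  # exact posterior by enumeration
  beta <- exp(-p$phi)
  post <- matrix(0, n, k)
  for (c in 1:n) for (t in 1:k) {
    lp <- log(p$pi[t])
    for (g in 1:m)
      lp <- lp + dnbinom(X[g, c], size = p$alpha[g, t],
                         prob = beta[g, t] / (vols[c] + beta[g, t]), log = TRUE)
    post[c, t] <- lp
  }
  post <- exp(post - apply(post, 1, max))
  post <- post / rowSums(post)

  draws <- matrix(0L, n, k)
  for (r in 1:20000) {
    p2 <- sample_component_assignments(cnt, vols, p)
    draws[cbind(1:n, p2$z)] <- draws[cbind(1:n, p2$z)] + 1L
  }
  freq <- draws / 20000
  se <- sqrt(post * (1 - post) / 20000)
  expect_true(all(abs(freq - post) <= 3 * se + 1e-3))

  # identical components with uniform pi: probability one half
  p$alpha <- matrix(1, m, k); p$phi <- matrix(0, m, k); p$pi <- c(0.5, 0.5)
  z1 <- replicate(4000, sample_component_assignments(cnt, vols, p)$z[1])
  expect_equal(mean(z1 == 1), 0.5, tolerance = 0.03)

  # k = 1 is degenerate
  p1 <- init_model_params(m, n, prior_config(k = 1))
  expect_true(all(sample_component_assignments(cnt, vols, p1)$z == 1L))
})

test_that("rate updates have the conjugate Gamma posterior moments", {
  set.seed(24)
  prior <- prior_config(k = 1)
  m <- 1; n <- 1
  p <- init_model_params(m, n, prior)
  p$alpha <- matrix(2, 1, 1)
  p$phi <- matrix(-log(3), 1, 1)  # beta = 3
  vols <- 7
  X <- matrix(5L, 1, 1)
  cnt <- list(X = X, X_bg = 4L)
  draws <- replicate(60000, sample_rates(cnt, vols, p, 100, prior)$tau[1, 1])
  want_mean <- (2 + 5) / (3 + 7)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - want_mean), 3 * se)
  # background: Gamma(e0bg + X_bg, f0bg + total volume)
  bg <- replicate(60000, sample_rates(cnt, vols, p, 100, prior)$tau_bg[1])
  expect_lt(abs(mean(bg) - (1 + 4) / (1 + 100)), 3 * sd(bg) / sqrt(length(bg)))
  # X = 0 draws from the exposure-only prior Gamma(alpha, beta + nu)
  cnt0 <- list(X = matrix(0L, 1, 1), X_bg = 0L)
  d0 <- replicate(60000, sample_rates(cnt0, vols, p, 100, prior)$tau[1, 1])
  expect_lt(abs(mean(d0) - 2 / 10), 3 * sd(d0) / sqrt(length(d0)))
})

test_that("CRT draws match the digamma closed-form mean", {
  expect_identical(sample_crt(0L, 2), 0L)
  expect_true(all(sample_crt(rep(1L, 50), 0.7) == 1L))
  set.seed(25)
  for (case in list(c(5, 2), c(20, 0.5), c(100, 3))) {
    n_i <- case[1]; r_i <- case[2]
    draws <- sample_crt(rep.int(as.integer(n_i), 50000), r_i)
    want <- r_i * (digamma(r_i + n_i) - digamma(r_i))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - want), 3 * se)
    expect_true(all(draws >= 1 & draws <= n_i))
  }
  expect_error(sample_crt(-1L, 1))
})

test_that("Polya-Gamma draws match closed-form moments and monotonicity", {
  set.seed(26)
  pg_mean <- function(b, c) if (abs(c) < 1e-8) b / 4 else b / (2 * c) * tanh(c / 2)
  cases <- list(c(1, 0), c(2, 1), c(0.5, 1), c(5, 2), c(40, 1))
  for (bc in cases) {
    draws <- sample_polya_gamma(rep(bc[1], 50000), bc[2])
    expect_true(all(draws > 0))
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - pg_mean(bc[1], bc[2])), 3 * se + 2e-4)
  }
  # mean decreases in |c| at fixed b
  ms <- vapply(c(0, 1, 2, 4), function(cc)
    mean(sample_polya_gamma(rep(1, 30000), cc)), numeric(1))
  expect_true(all(diff(ms) < 0))
})

test_that("empty components draw alpha and phi from their priors", {
  set.seed(27)
  prior <- prior_config(k = 2, gamma = 1)
  m <- 2; n <- 4
  p <- init_model_params(m, n, prior)
  p$z <- rep(1L, n)  # component 2 empty
  vols <- rep(5, n)
  cnt <- list(X = matrix(2L, m, n), X_bg = rep(0L, m))
  a2 <- replicate(3000, sample_alpha_and_h(cnt, vols, p, prior)$alpha[1, 2])
  # prior Gamma(e0 = 1, rate h = 1): mean 1, var 1
  expect_equal(mean(a2), 1, tolerance = 0.1)
  ph2 <- replicate(3000, sample_beta(cnt, vols, p, prior)$phi[1, 2])
  expect_equal(mean(ph2), 0, tolerance = 0.1)
  expect_equal(sd(ph2), 1, tolerance = 0.1)
})

test_that("one-cell zero-count alpha update uses the stated rate", {
  # with one cell and X = 0: l = 0, rate = h + log((nu + beta) / beta)
  prior <- prior_config(k = 1)
  p <- init_model_params(1, 1, prior)
  p$h <- 2
  p$phi <- matrix(-log(4), 1, 1)  # beta = 4
  vols <- 6
  cnt <- list(X = matrix(0L, 1, 1), X_bg = 0L)
  set.seed(28)
  draws <- replicate(40000, sample_alpha_and_h(cnt, vols, p, prior)$alpha[1, 1])
  want_rate <- 2 + log((6 + 4) / 4)
  # posterior is Gamma(e0 = 1, want_rate): mean 1 / want_rate
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 1 / want_rate), 3 * se)
})

test_that("volume-model updates concentrate and pi has the Dirichlet mean", {
  set.seed(29)
  prior <- prior_config(k = 2)
  n <- 60
  p <- init_model_params(2, n, prior)
  p$z <- rep(1L, n)
  v <- rep(exp(5.3), n)  # identical log-volumes
  mus <- replicate(2000, sample_volume_params(v, p, prior)$mu_vol[1])
  expect_equal(mean(mus), 5.3, tolerance = 0.05)
  pis <- replicate(4000, sample_volume_params(v, p, prior)$pi[1])
  expect_equal(mean(pis), (1 + 60) / (2 + 60), tolerance = 0.02)
})

test_that("Poisson-Gamma counts match the negative binomial marginal", {
  set.seed(30)
  alpha <- 2; beta <- 5; nu <- 10
  n_draw <- 100000
  tau <- rgamma(n_draw, alpha, rate = beta)
  X <- rpois(n_draw, nu * tau)
  cap <- 25
  obs <- tabulate(pmin(X, cap) + 1L, nbins = cap + 1L)
  pr <- dnbinom(0:(cap - 1), size = alpha, prob = beta / (nu + beta))
  pr <- c(pr, 1 - sum(pr))
  chi <- suppressWarnings(stats::chisq.test(obs, p = pr))
  expect_gt(chi$p.value, 0.01)
})

test_that("count tallies conserve the transcript total", {
  set.seed(31)
  gene <- sample.int(5, 200, replace = TRUE)
  assign <- sample(0:3, 200, replace = TRUE)
  cnt <- tally_counts(gene, assign, 5, 3)
  expect_equal(sum(cnt$X) + sum(cnt$X_bg), 200)
})
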