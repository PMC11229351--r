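# Independent oracles and small fixture builders used across the suite.

# beta-binomial log pmf by numerical integration of Binomial(n, q) against
# the Beta(a, b) mixing density
bb_logpmf_quadrature <- function(y, n, p, phi) {
  s <- (1 - phi) / phi
  val <- stats::integrate(function(q) dbinom(y, n, q) *
                            stats::dbeta(q, p * s, (1 - p) * s),
                          0, 1, rel.tol = 1e-12, abs.tol = 0)$value
  log(val)
}

# Benjamini-Hochberg step-up, written directly from the definition:
# q_(i) = min_{j >= i} p_(j) * m / j
bh_reference <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- p[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

# multi-start grid + Nelder-Mead maximizer of the gene log-likelihood,
# independent of the trust-region path
oracle_max_loglik <- function(design, phi, n_starts = 8, seed = 1) {
  set.seed(seed)
  nll <- function(b) {
    v <- loglik_grad_hess(b, phi, design, what = "loglik")$loglik
    if (!is.finite(v)) 1e10 else -v
  }
  starts <- c(list(rep(0, design$P)),
              lapply(seq_len(n_starts), function(i) rnorm(design$P, 0, 1.5)))
  best <- -Inf
  for (b0 in starts) {
    o <- stats::optim(b0, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    o <- stats::optim(o$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
    if (-o$value > best) best <- -o$value
  }
  best
}

# direct thin-plate interpolation solve on tiny instances: radial kernel +
# affine polynomial, with the standard orthogonality side conditions
tps_interpolate_direct <- function(coords, z) {
  S <- nrow(coords)
  r2 <- as.matrix(dist(coords))^2
  E <- ifelse(r2 == 0, 0, 0.5 * r2 * log(r2))
  Tm <- cbind(1, coords)
  A <- rbind(cbind(E, Tm), cbind(t(Tm), matrix(0, 3, 3)))
  sol <- solve(A, c(z, rep(0, 3)))
  unname(drop(E %*% sol[1:S] + Tm %*% sol[S + 1:3]))
}

# small random spatial dataset with one gene sampled from a known smooth
# truth (single aggregate cell type)
make_small_dataset <- function(S = 300, umi = 2000, phi = 0.1,
                               coef_scale = 1.5, seed = 1, K = 1,
                               layout = "uniform") {
  land <- sim_landscape(max(S, 100), K, layout, seed = seed)
  basis <- tps_basis(land$coords, k = 5)
  truth <- sim_truth(land, basis = basis, coef_scale = coef_scale,
                     phi = phi, seed = seed + 1)
  counts <- sim_counts(truth, total_umi = umi, seed = seed + 2)
  list(landscape = land, basis = basis, truth = truth, counts = counts)
}

# random small mixture design for derivative checks
random_design <- function(S = 60, K = 2, L = 3, nmax = 8, seed = 1,
                          share_spline = FALSE) {
  set.seed(seed)
  n <- sample(1:nmax, S, replace = TRUE)
  W <- matrix(stats::rgamma(S * K, 1), S, K)
  W <- W / rowSums(W)
  colnames(W) <- paste0("ct", seq_len(K))
  wdf <- cell_type_weights(cbind(data.frame(spot_id = as.character(1:S)),
                                 as.data.frame(W)))
  alpha <- compute_alpha(wdf)
  G <- if (L > 0) matrix(rnorm(S * L), S, L) else NULL
  eta <- matrix(rnorm(S * K, 0, 1), S, K)
  p <- rowSums(alpha$A * stats::plogis(eta))
  y <- rbinom(S, n, p)
  gene_design(y, n, alpha = alpha, covariates = G,
              share_spline = share_spline, ct_floor = 0.1)
}

# long-format toy counts table on a 3x3 grid of spots
toy_counts <- function() {
  coords <- data.frame(spot_id = paste0("s", 1:9),
                       x = rep(1:3, 3), y = rep(1:3, each = 3))
  long <- data.frame(
    spot_id = c("s1", "s1", "s2", "s3", "s5", "s7", "s9"),
    gene = c("g1", "g2", "g1", "g2", "g1", "g2", "g1"),
    maternal_count = c(2, 1, 0, 4, 3, 2, 1),
    paternal_count = c(3, 0, 2, 1, 0, 2, 1))
  as_allelic_counts(long, coords, sample_id = "toy")
}
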