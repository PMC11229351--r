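test_that("log pmf handles the uniform case, binomial limit and masses", {
  # phi = 1/3 at p = 1/2 gives Beta(1, 1): discrete uniform on 0..n
  expect_equal(bb_logpmf(2, 4, 0.5, 1 / 3), log(1 / 5))
  expect_equal(bb_logpmf(0:4, 4, 0.5, 1 / 3), rep(log(1 / 5), 5))
  # phi = 0 is the exact binomial
  expect_equal(bb_logpmf(3, 10, 0.37, 0), dbinom(3, 10, 0.37, log = TRUE))
  # degenerate means are point masses
  expect_equal(bb_logpmf(0, 5, 0, 0.2), 0)
  expect_equal(bb_logpmf(1, 5, 0, 0.2), -Inf)
  expect_equal(bb_logpmf(5, 5, 1, 0.2), 0)
  expect_error(bb_logpmf(6, 5, 0.5, 0.2), "y <= n")
  expect_error(bb_logpmf(2, 5, 0.5, 1), "phi")
})

test_that("pmf normalizes and is reflection symmetric", {
  for (n in c(1, 7, 23, 50)) {
    for (p in c(0.1, 0.5, 0.93)) {
      for (phi in c(0, 0.01, 0.3, 0.8)) {
        expect_equal(sum(exp(bb_logpmf(0:n, n, p, phi))), 1,
                     tolerance = 1e-10)
      }
    }
  }
  set.seed(8)
  for (i in 1:25) {
    n <- sample(1:40, 1); y <- sample(0:n, 1)
    p <- runif(1, 0.05, 0.95); phi <- runif(1, 0, 0.9)
    expect_equal(bb_logpmf(y, n, p, phi), bb_logpmf(n - y, n, 1 - p, phi))
  }
})

test_that("log pmf matches the quadrature oracle to 1e-10", {
  expect_equal(bb_logpmf(5, 17, 0.3, 0.2),
               bb_logpmf_quadrature(5, 17, 0.3, 0.2), tolerance = 1e-10)
  set.seed(9)
  for (i in 1:20) {
    n <- sample(2:30, 1); y <- sample(0:n, 1)
    p <- runif(1, 0.1, 0.9); phi <- runif(1, 0.05, 0.7)
    expect_equal(bb_logpmf(y, n, p, phi), bb_logpmf_quadrature(y, n, p, phi),
                 tolerance = 1e-10)
  }
})

test_that("mixture mean matches a naive per-spot loop", {
  set.seed(10)
  d <- random_design(S = 50, K = 3, L = 4, seed = 10)
  beta <- rnorm(d$P, 0, 0.7)
  p <- mixture_mean(beta, d)
  # naive loop over spots and cell types
  p_loop <- numeric(length(d$y))
  for (i in seq_along(d$y)) {
    acc <- 0
    for (k in seq_len(d$K)) {
      eta <- sum(d$X[i, d$xcols[[k]]] * beta[d$bcols[[k]]])
      acc <- acc + d$A[i, k] * plogis(min(max(eta, -15), 15))
    }
    p_loop[i] <- acc
  }
  expect_equal(p, p_loop, tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
  # K = 1 intercept-only at beta = 0 is one half everywhere
  d1 <- gene_design(y = c(1, 2), n = c(3, 4))
  expect_equal(mixture_mean(0, d1), c(0.5, 0.5))
  # saturated expits recover the mixture weights
  w <- cell_type_weights(data.frame(spot_id = "s1", a = 0.25, b = 0.75))
  d2 <- gene_design(y = 1, n = 4, alpha = compute_alpha(w), ct_floor = 0)
  expect_equal(unname(mixture_mean(c(15, -15), d2)), 0.25,
               tolerance = 1e-5)
  expect_error(mixture_mean(c(1, 2, 3), d1), "length")
})

test_that("analytic derivatives match finite differences", {
  set.seed(11)
  for (case in 1:12) {
    K <- sample(1:3, 1); L <- sample(0:4, 1)
    share <- sample(c(TRUE, FALSE), 1)
    d <- random_design(S = sample(30:80, 1), K = K, L = L,
                       seed = 100 + case, share_spline = share)
    phi <- runif(1, 0, 0.5)
    beta <- rnorm(d$P, 0, 0.6)
    ev <- loglik_grad_hess(beta, phi, d)
    h <- 1e-5
    fd_g <- vapply(seq_len(d$P), function(i) {
      e <- rep(0, d$P); e[i] <- h
      (loglik_grad_hess(beta + e, phi, d, "loglik")$loglik -
         loglik_grad_hess(beta - e, phi, d, "loglik")$loglik) / (2 * h)
    }, numeric(1))
    expect_lt(max(abs(ev$gradient - fd_g) / pmax(abs(fd_g), 1)), 1e-5)
    fd_H <- vapply(seq_len(d$P), function(i) {
      e <- rep(0, d$P); e[i] <- h
      (loglik_grad_hess(beta + e, phi, d)$gradient -
         loglik_grad_hess(beta - e, phi, d)$gradient) / (2 * h)
    }, numeric(d$P))
    expect_lt(max(abs(ev$hessian - fd_H) / pmax(abs(fd_H), 1)), 1e-4)
    expect_lt(max(abs(ev$hessian - t(ev$hessian))), 1e-10)
  }
})

test_that("likelihood is invariant to permuting cell-type labels", {
  set.seed(12)
  d <- random_design(S = 60, K = 3, L = 2, seed = 12)
  beta <- rnorm(d$P, 0, 0.5)
  ll <- loglik_grad_hess(beta, 0.2, d, "loglik")$loglik
  perm <- c(3, 1, 2)
  d2 <- d
  d2$A <- d$A[, perm]
  # permute the per-cell-type parameter blocks the same way
  beta2 <- unlist(lapply(perm, function(k) beta[d$bcols[[k]]]))
  expect_equal(loglik_grad_hess(beta2, 0.2, d2, "loglik")$loglik, ll)
})

test_that("overdispersion is recovered, flagged flat, and near zero when binomial", {
  set.seed(13)
  S <- 2000
  n <- rpois(S, 6) + 1
  # truth phi = 0.3 at p = 0.55
  s <- (1 - 0.3) / 0.3
  q <- rbeta(S, 0.55 * s, 0.45 * s)
  y <- rbinom(S, n, q)
  d <- gene_design(y, n)
  fit <- fit_gene(d)
  expect_lt(abs(fit$phi - 0.3), 0.05)
  # likelihood flat in phi when every spot has n = 1
  d1 <- gene_design(y = rbinom(500, 1, 0.5), n = rep(1, 500))
  ph <- estimate_phi(0, d1)
  expect_true(ph$flat)
  # binomially generated data drive the estimate to the lower bound
  yb <- rbinom(1500, 8, 0.5)
  db <- gene_design(yb, rep(8, 1500))
  fitb <- fit_gene(db)
  expect_lt(fitb$phi, 0.02)
})

test_that("intercept-only MLE solves the weighted moment condition", {
  # for K = 1, fixed phi, the score in the intercept is a positive
  # multiple of sum(y) - p sum(n); cross-check against a grid search
  set.seed(14)
  y <- rbinom(40, 7, 0.3); n <- rep(7, 40)
  d <- gene_design(y, n)
  for (phi in c(0, 0.25)) {
    fit <- fit_gene(d, phi = phi)
    grid <- seq(-3, 3, by = 1e-4)
    ll <- vapply(grid, function(b)
      sum(bb_logpmf(d$y, d$n, plogis(b), phi)), numeric(1))
    expect_equal(unname(fit$beta[1]), grid[which.max(ll)], tolerance = 1e-3)
    if (phi == 0) {
      expect_equal(unname(plogis(fit$beta[1])), sum(y) / sum(n),
                   tolerance = 1e-8)
    }
  }
})
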