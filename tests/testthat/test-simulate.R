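test_that("landscapes are deterministic and structured as requested", {
  l1 <- sim_landscape(200, 2, "bands", seed = 36)
  l2 <- sim_landscape(200, 2, "bands", seed = 36)
  expect_identical(l1$weights, l2$weights)
  expect_identical(l1$coords, l2$coords)
  # bands: left half dominated by type 1, right half by type 2
  W <- as.matrix(l1$weights[, c("ct1", "ct2")])
  left <- l1$coords$x < 0.4
  right <- l1$coords$x > 0.6
  expect_gt(mean(W[left, 1]), 0.9)
  expect_gt(mean(W[right, 2]), 0.9)
  # uniform: equal weights everywhere
  lu <- sim_landscape(150, 3, "uniform", seed = 37)
  expect_true(all(abs(as.matrix(lu$weights[, -1]) - 1 / 3) < 1e-12))
  expect_error(sim_landscape(50, 2), "at least 100")
})

test_that("truth surfaces respect the null and probability bounds", {
  land <- sim_landscape(300, 2, "blobs", seed = 38)
  t0 <- sim_truth(land, coef_scale = 0, seed = 39)
  expect_equal(t0$p_true, rep(0.5, 300))
  t1 <- sim_truth(land, coef_scale = 2, seed = 40)
  expect_true(all(t1$p_true >= 0 & t1$p_true <= 1))
  expect_gt(sd(t1$p_true), 0.01)
  # identical coefficients in every cell type: mixture independent of W
  t2 <- sim_truth(land, coef_scale = 1.5, ase_cell_type = "all",
                  seed = 41)
  basis <- t2$basis
  direct <- plogis(pmin(pmax(drop(cbind(1, basis$B) %*%
                                    t2$beta_ct[, 1]), -15), 15))
  expect_equal(t2$p_true, unname(direct))
})

test_that("count sampling conserves totals and respects the truth", {
  land <- sim_landscape(400, 2, "blobs", seed = 42)
  truth <- sim_truth(land, coef_scale = 1, phi = 0, seed = 43)
  cnt <- sim_counts(truth, total_umi = 2537, seed = 44)
  expect_equal(sum(cnt$N@x), 2537)
  expect_s3_class(cnt, "allelic_counts")  # validator runs in-construction
  expect_identical(sim_counts(truth, 2537, seed = 44)$Y, cnt$Y)
  # binomial sampling: pooled fraction approaches the N-weighted truth
  big <- sim_counts(truth, 1e5, seed = 45)
  n <- as.numeric(big$N[, 1])
  pooled <- sum(big$Y[, 1]) / sum(n)
  expected <- sum(n * truth$p_true) / sum(n)
  expect_equal(pooled, expected, tolerance = 0.01)
})

test_that("overdispersed sampling inflates the per-spot variance", {
  set.seed(46)
  land <- sim_landscape(150, 1, "uniform", seed = 46)
  truth <- sim_truth(land, coef_scale = 0, phi = 0.3, seed = 47)
  n_fixed <- 20
  draws_bb <- replicate(400, {
    s <- (1 - 0.3) / 0.3
    rbinom(1, n_fixed, rbeta(1, 0.5 * s, 0.5 * s))
  })
  v_bin <- n_fixed * 0.25
  # one-sided check: beta-binomial variance clearly exceeds binomial
  expect_gt(var(draws_bb), v_bin * (1 + (n_fixed - 1) * 0.3) * 0.7)
  # and the full sampler at phi = 0.3 shows excess over phi = 0
  c0 <- sim_counts(truth, 5e4, phi = 0, seed = 48)
  c3 <- sim_counts(truth, 5e4, phi = 0.3, seed = 49)
  f0 <- as.numeric(c0$Y[, 1]) / pmax(as.numeric(c0$N[, 1]), 1)
  f3 <- as.numeric(c3$Y[, 1]) / pmax(as.numeric(c3$N[, 1]), 1)
  expect_gt(var(f3), var(f0) * 2)
})

test_that("perfect and constant fits evaluate as expected", {
  land <- sim_landscape(300, 2, "blobs", seed = 50)
  basis <- tps_basis(land$coords, k = 5)
  truth <- sim_truth(land, basis = basis, coef_scale = 1.5, seed = 51)
  cnt <- sim_counts(truth, 3000, seed = 52)
  a <- allelemix:::reorder_alpha(truth$alpha, rownames(cnt$Y))
  d <- gene_design(as.numeric(cnt$Y[, 1]), as.numeric(cnt$N[, 1]),
                   alpha = a, covariates = basis$B, share_spline = FALSE,
                   spot_ids = rownames(cnt$Y))
  mock <- fit_gene(d, phi = 0.1,
                   control = fit_control(max_iter = 1,
                                         max_alternations = 1))
  mock$beta[] <- as.vector(truth$beta_ct)
  ev <- evaluate_fit(mock, truth)
  expect_equal(ev$pearson_r, 1, tolerance = 1e-9)
  expect_equal(ev$rmse_beta, 0)
  # constant fit: correlation undefined, flagged
  mock$beta[] <- 0
  ev0 <- evaluate_fit(mock, truth)
  expect_true(ev0$constant_fit)
  expect_true(is.na(ev0$pearson_r))
})

test_that("simulation grids are reproducible and track overdispersion", {
  g1 <- run_simulation_grid(S = 300, umi_bins = list(c(500, 1000)),
                            phi_values = c(0.05, 0.5), replicates = 6,
                            seed = 53)
  g2 <- run_simulation_grid(S = 300, umi_bins = list(c(500, 1000)),
                            phi_values = c(0.05, 0.5), replicates = 6,
                            seed = 53)
  expect_identical(g1, g2)
  expect_true(all(!is.na(g1$pearson_r)))
  # recovery degrades (stochastically) with the true overdispersion
  expect_gt(median(g1$pearson_r[g1$phi_true == 0.05]),
            median(g1$pearson_r[g1$phi_true == 0.5]))
})
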