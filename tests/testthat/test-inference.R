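# small spatial dataset with several genes at chosen per-gene maternal
# probabilities (constant in space), n ~ Poisson per spot
biased_dataset <- function(p_by_gene, S = 400, mean_n = 4, seed = 1,
                           phi = 0) {
  set.seed(seed)
  coords <- data.frame(spot_id = paste0("s", 1:S),
                       x = runif(S), y = runif(S))
  G <- length(p_by_gene)
  N <- matrix(rpois(S * G, mean_n), S, G,
              dimnames = list(coords$spot_id, names(p_by_gene)))
  Y <- N * 0
  for (j in 1:G) {
    p <- p_by_gene[j]
    if (phi > 0) {
      s <- (1 - phi) / phi
      q <- rbeta(S, p * s, (1 - p) * s)
    } else q <- rep(p, S)
    Y[, j] <- rbinom(S, N[, j], q)
  }
  allelic_counts(Y, N, coords)
}

test_that("BH adjustment matches the step-up reference implementation", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  set.seed(22)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))
    expect_lt(max(abs(adjust_fdr(p) - bh_reference(p))), 1e-12)
    expect_true(all(adjust_fdr(p) >= p))
  }
  expect_warning(q <- adjust_fdr(c(0.1, NaN)), "NaN")
  expect_true(is.nan(q[2]))
})

test_that("overall bias test finds direction only past the 0.6/0.4 bounds", {
  cnt <- biased_dataset(c(gM = 0.75, gNull = 0.5, gP = 0.2,
                          gNear = 0.55),
                        S = 500, mean_n = 6, seed = 23)
  res <- test_overall_bias(cnt, min_nonzero = 50)
  res <- res[order(res$gene), ]
  r <- split(res, res$gene)
  expect_equal(r$gM$direction, "maternal")
  expect_lt(r$gM$q_value, 0.01)
  expect_gt(r$gM$p_hat, 0.6)
  expect_equal(r$gP$direction, "paternal")
  # significant but inside the direction bounds: no call
  expect_lt(r$gNear$q_value, 0.01)
  expect_equal(r$gNear$direction, "none")
  # null gene: no signal
  expect_gt(r$gNull$p_value, 0.01)
  expect_equal(r$gNull$direction, "none")
})

test_that("within-cell-type bias localizes to the biased cell type", {
  set.seed(24)
  S <- 700
  land <- sim_landscape(S, 2, "bands", seed = 24)
  W <- as.matrix(land$weights[, c("ct1", "ct2")])
  p_ct <- c(0.9, 0.5)
  p_spot <- drop(W %*% p_ct)
  N <- matrix(rpois(S, 5), S, 1,
              dimnames = list(land$weights$spot_id, "g1"))
  Y <- matrix(rbinom(S, N, p_spot), S, 1, dimnames = dimnames(N))
  cnt <- allelic_counts(Y, N, land$coords)
  res <- test_within_ct_bias(cnt, land$weights, min_nonzero = 50)
  r1 <- res[res$cell_type == "ct1", ]
  r2 <- res[res$cell_type == "ct2", ]
  expect_equal(r1$direction, "maternal")
  expect_lt(r1$q_value, 0.01)
  expect_equal(r2$direction, "none")
  expect_equal(r2$p_hat, 0.5, tolerance = 0.07)
})

test_that("single-cell-type within-ct test reduces to the overall test", {
  cnt <- biased_dataset(c(g1 = 0.7, g2 = 0.5), S = 300, seed = 25)
  w <- cell_type_weights(data.frame(spot_id = paste0("s", 1:300),
                                    only = 1))
  res_w <- test_within_ct_bias(cnt, w, min_nonzero = 50)
  res_o <- test_overall_bias(cnt, min_nonzero = 50)
  expect_equal(res_w$estimate, res_o$estimate, tolerance = 1e-8)
  expect_equal(res_w$p_value, res_o$p_value, tolerance = 1e-8)
})

test_that("spatial LRT floors at zero for identical fits and detects strong
          patterns", {
  f <- list(loglik = -100, warnings = character(), converged = TRUE,
            phi = 0.1)
  row <- allelemix:::lrt_row("g", "overall_spatial", f, f, df = 4)
  expect_equal(row$statistic, 0)
  expect_equal(row$p_value, 1)
  # numerically negative statistic floors with a note
  f2 <- list(loglik = -100.001, warnings = character(), converged = TRUE,
             phi = 0.1)
  row2 <- allelemix:::lrt_row("g", "overall_spatial", f2, f, df = 4)
  expect_equal(row2$statistic, 0)
  expect_match(row2$note, "floored")

  # strong smooth surface at high UMI: overwhelming evidence
  ds <- make_small_dataset(S = 600, umi = 5000, phi = 0.05,
                           coef_scale = 2, seed = 26)
  res <- test_overall_spatial(ds$counts, basis = ds$basis,
                              min_nonzero = 50)
  expect_lt(res$p_value, 1e-6)
})

test_that("within-cell-type spatial LRT flags the cell type with the
          pattern", {
  set.seed(27)
  land <- sim_landscape(1200, 2, "bands", seed = 27)
  basis <- tps_basis(land$coords, k = 5)
  truth <- sim_truth(land, basis = basis, coef_scale = 2,
                     ase_cell_type = 1, phi = 0.05, seed = 28)
  cnt <- sim_counts(truth, 20000, seed = 29)
  # shared-spline variant: one test per gene
  res_sh <- test_within_ct_spatial(cnt, land$weights, min_nonzero = 50,
                                   basis = basis, spline = "shared")
  expect_equal(nrow(res_sh), 1)
  expect_lt(res_sh$p_value, 1e-6)
  expect_equal(res_sh$df, 4L)
  # cell-type-specific variant: the patterned cell type drives the signal
  res_sp <- test_within_ct_spatial(cnt, land$weights, min_nonzero = 50,
                                   basis = basis, spline = "specific")
  p1 <- res_sp$p_value[res_sp$cell_type == "ct1"]
  p2 <- res_sp$p_value[res_sp$cell_type == "ct2"]
  expect_lt(p1, 1e-6)
  expect_gt(p2, p1)
})

test_that("classification honors multi-membership and exclusivity", {
  res <- tibble::tibble(
    gene = c("gA", "gA", "gB", "gC"),
    category = c("overall_bias", "overall_spatial", "overall_bias",
                 "overall_bias"),
    q_value = c(0.001, 0.005, 0.5, 0.002),
    direction = c("maternal", "none", "none", "none"))
  cls <- classify_genes(res)
  gA <- cls[cls$gene == "gA", ]
  expect_true(gA$overall_maternal && gA$overall_spatial)
  expect_false(gA$no_significant_ase)
  # gB nothing significant -> exclusively unclassified
  gB <- cls[cls$gene == "gB", ]
  expect_true(gB$no_significant_ase)
  expect_false(any(unlist(gB[, 2:7])))
  # gC significant but directionless: not counted as biased
  gC <- cls[cls$gene == "gC", ]
  expect_true(gC$no_significant_ase)
  summ <- category_summary(cls, chromosome_map = data.frame(
    gene = c("gA", "gB", "gC"), chromosome = c("X", "2", "3")))
  expect_equal(summ$n_genes[summ$category == "No significant ASE"], 2L)
  expect_equal(summ$n_x[summ$category == "Overall maternal bias"], 1L)
})

test_that("direction calls never violate the probability bounds", {
  cnt <- biased_dataset(setNames(runif(12, 0.3, 0.7),
                                 paste0("g", 1:12)),
                        S = 350, mean_n = 5, seed = 30, phi = 0.1)
  res <- test_overall_bias(cnt, min_nonzero = 50)
  expect_false(any(res$direction == "maternal" & res$p_hat <= 0.6))
  expect_false(any(res$direction == "paternal" & res$p_hat >= 0.4))
  expect_false(any(res$direction != "none" & res$q_value >= 0.01))
})
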