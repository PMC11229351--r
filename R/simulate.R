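#' Synthetic cell-type landscape
#'
#' Generates spot positions uniform on the unit square and a spatially
#' structured cell-type weight matrix. `"blobs"` (clustered fields from a
#' softmax of random Gaussian bumps) emulates the spatially clustered cell
#' types of real tissue; `"bands"` gives sharp vertical domains; and
#' `"uniform"` gives equal weights everywhere.
#'
#' @param S Number of spots (at least 100).
#' @param K Number of cell types.
#' @param layout `"blobs"`, `"bands"` or `"uniform"`.
#' @param seed Integer seed; identical seeds give identical landscapes.
#' @return List with `coords` (tibble `spot_id`, `x`, `y`) and `weights`
#'   (a [cell_type_weights()] tibble).
#' @export
sim_landscape <- function(S, K, layout = c("blobs", "bands", "uniform"),
                          seed = 1) {
  layout <- match.arg(layout)
  if (S < 100) abort("need at least 100 spots")
  set.seed(seed)
  coords <- tibble(spot_id = sprintf("s%05d", seq_len(S)),
                   x = runif(S), y = runif(S))
  X <- cbind(coords$x, coords$y)
  score <- switch(layout,
    uniform = matrix(0, S, K),
    bands = {
      centers <- (seq_len(K) - 0.5) / K
      -10 * abs(outer(coords$x, centers, "-")) * K
    },
    blobs = {
      sapply(seq_len(K), function(k) {
        nb <- 3
        cx <- runif(nb); cy <- runif(nb); a <- rnorm(nb, 0, 2)
        f <- numeric(S)
        for (b in seq_len(nb)) {
          f <- f + a[b] * exp(-((X[, 1] - cx[b])^2 +
                                  (X[, 2] - cy[b])^2) / (2 * 0.25^2))
        }
        2 * f
      })
    })
  W <- exp(score - apply(score, 1, max))
  W <- W / rowSums(W)
  colnames(W) <- paste0("ct", seq_len(K))
  weights <- cell_type_weights(cbind(tibble(spot_id = coords$spot_id),
                                     as_tibble(as.data.frame(W))))
  list(coords = coords, weights = weights)
}

#' Ground-truth spatial allelic surface
#'
#' Draws a random smooth maternal-probability surface as a linear
#' combination of thin-plate spline basis functions on the logit scale:
#' the designated cell type receives intercept and spline coefficients
#' drawn from `N(0, coef_scale^2)`; other cell types sit at the balanced
#' probability (all coefficients zero). `coef_scale = 0` gives the global
#' null surface `p = 0.5`.
#'
#' @param landscape A [sim_landscape()] result.
#' @param basis A [tps_basis()] on the landscape coordinates; `NULL`
#'   builds one with `k`.
#' @param k Spline degrees of freedom of the truth surface.
#' @param coef_scale Standard deviation of the coefficients (logit scale).
#' @param ase_cell_type Index or label of the cell type carrying the ASE
#'   pattern, or `"all"` for the same coefficients in every cell type.
#' @param rates Optional [expression_rates()] for the simulated gene;
#'   `NULL` for uniform rates (mixture shares equal the weights).
#' @param phi True overdispersion carried into [sim_counts()].
#' @param seed Integer seed.
#' @return A `sim_truth` object: coordinates, weights, mixture shares
#'   `A`, per-cell-type coefficients `beta` (design layout,
#'   cell-type-specific), `p_true`, `phi`, the basis, and the seed.
#' @export
sim_truth <- function(landscape, basis = NULL, k = 5, coef_scale = 1.5,
                      ase_cell_type = 1, rates = NULL, phi = 0.1,
                      seed = 1) {
  coords <- landscape$coords
  weights <- landscape$weights
  cts <- setdiff(names(weights), "spot_id")
  K <- length(cts)
  if (is.null(basis)) basis <- tps_basis(coords, k = k)
  L <- basis$L
  set.seed(seed)
  beta_ct <- matrix(0, L + 1, K, dimnames = list(NULL, cts))
  targets <- if (identical(ase_cell_type, "all")) seq_len(K) else {
    if (is.character(ase_cell_type)) match(ase_cell_type, cts)
    else as.integer(ase_cell_type)
  }
  if (anyNA(targets)) abort("unknown ase_cell_type")
  draw <- rnorm(L + 1, 0, coef_scale)
  for (k_i in targets) beta_ct[, k_i] <- draw
  alpha <- compute_alpha(weights, rates, gene = "sim_gene")
  eta <- cbind(1, basis$B) %*% beta_ct
  p_true <- unname(rowSums(alpha$A * expit(clip_eta(eta))))
  structure(list(coords = coords, weights = weights, alpha = alpha,
                 rates = rates, basis = basis, beta_ct = beta_ct,
                 p_true = p_true, phi = phi, ase_cell_type = targets,
                 seed = seed),
            class = "sim_truth")
}

#' Sample allele-resolved counts from a truth surface
#'
#' Allocates the gene's total UMI over spots by a multinomial with
#' probabilities proportional to the spot expression intensity
#' `sum_k w[i,k] mu[j,k]`, then draws maternal counts per spot from the
#' beta-binomial at the true probability and overdispersion (`phi = 0`
#' draws exact binomials).
#'
#' @param truth A [sim_truth()] object.
#' @param total_umi Total allele-resolved UMI for the gene.
#' @param phi Overdispersion; defaults to the truth's value.
#' @param seed Integer seed.
#' @return An [allelic_counts()] object with the single gene `sim_gene`.
#' @export
sim_counts <- function(truth, total_umi, phi = NULL, seed = 1) {
  phi <- phi %||% truth$phi
  if (total_umi < 1) abort("total_umi must be at least 1")
  if (phi < 0 || phi >= 1) abort("phi must lie in [0, 1)")
  set.seed(seed)
  W <- weights_matrix(truth$weights)
  intensity <- if (is.null(truth$rates)) {
    rowSums(W)  # uniform rates
  } else {
    r <- expression_rates(truth$rates)
    r <- r[r$gene == "sim_gene", ]
    mu <- setNames(r$rate, r$cell_type)[colnames(W)]
    drop(W %*% mu)
  }
  S <- nrow(W)
  N <- drop(rmultinom(1, size = total_umi, prob = intensity / sum(intensity)))
  Y <- integer(S)
  nz <- which(N > 0)
  if (phi == 0) {
    Y[nz] <- rbinom(length(nz), N[nz], truth$p_true[nz])
  } else {
    s <- (1 - phi) / phi
    q <- rbeta(length(nz), truth$p_true[nz] * s,
               (1 - truth$p_true[nz]) * s)
    Y[nz] <- rbinom(length(nz), N[nz], q)
  }
  spots <- truth$coords$spot_id
  Ym <- sparseMatrix(i = which(Y > 0), j = rep(1L, sum(Y > 0)),
                     x = as.numeric(Y[Y > 0]), dims = c(S, 1L),
                     dimnames = list(spots, "sim_gene"))
  Nm <- sparseMatrix(i = which(N > 0), j = rep(1L, sum(N > 0)),
                     x = as.numeric(N[N > 0]), dims = c(S, 1L),
                     dimnames = list(spots, "sim_gene"))
  allelic_counts(Ym, Nm, truth$coords, sample_id = "simulation")
}

#' Compare a fit against the simulation truth
#'
#' Pearson correlation between estimated and true maternal probabilities
#' at the fitted spot locations, and the root-mean-squared error of the
#' logit-scale coefficients (aligned by cell type and basis column; only
#' defined when the fitted design matches the truth layout).
#'
#' @param fit A [fit_gene()] result.
#' @param truth The [sim_truth()] the data came from.
#' @return Tibble `pearson_r`, `rmse_beta`, `constant_fit` flag.
#' @export
evaluate_fit <- function(fit, truth) {
  design <- fit$design
  p_hat <- mixture_mean(fit$beta, design)
  idx <- match(design$spot_ids, truth$coords$spot_id)
  p_tr <- truth$p_true[idx]
  constant <- stats::sd(p_hat) < 1e-12
  r <- if (constant) NA_real_ else cor(p_hat, p_tr)
  rmse <- NA_real_
  if (!design$share_spline && design$L == nrow(truth$beta_ct) - 1 &&
        setequal(design$cell_types, colnames(truth$beta_ct))) {
    bt <- as.vector(truth$beta_ct[, design$cell_types, drop = FALSE])
    if (length(bt) == design$P) {
      rmse <- sqrt(mean((fit$beta - bt)^2))
    }
  }
  tibble(pearson_r = r, rmse_beta = rmse, constant_fit = constant)
}

#' Run a factorial simulation grid
#'
#' Generates a landscape once per layout, then for every combination of
#' UMI bin, overdispersion value and replicate: draws a truth surface,
#' samples counts (total UMI uniform within the bin), fits the
#' non-parametric mixture model with cell-type-specific spline
#' coefficients, and records recovery metrics. Per-replicate seeds are
#' derived from the master seed, so the grid is reproducible and each
#' replicate independent.
#'
#' @param S,K,layout Landscape parameters, see [sim_landscape()].
#' @param umi_bins List of `c(lo, hi)` total-UMI ranges.
#' @param phi_values True overdispersion values.
#' @param replicates Replicates per condition.
#' @param k Spline degrees of freedom (truth and fit).
#' @param coef_scale Truth coefficient scale, see [sim_truth()].
#' @param ase_cell_type Cell type carrying the pattern.
#' @param seed Master seed.
#' @param control See [fit_control()].
#' @return Tidy tibble: one row per replicate with condition factors,
#'   `pearson_r`, `rmse_beta`, `converged` and `error`.
#' @export
run_simulation_grid <- function(S = 2000, K = 2, layout = "blobs",
                                umi_bins = list(c(100, 500), c(500, 1000),
                                                c(1000, 10000)),
                                phi_values = 0.1, replicates = 20, k = 5,
                                coef_scale = 1.5, ase_cell_type = 1,
                                seed = 1, control = fit_control()) {
  land <- sim_landscape(S, K, layout, seed = seed)
  basis <- tps_basis(land$coords, k = k)
  set.seed(seed)
  max_seed <- 2^31 - 1
  rows <- list()
  for (b in seq_along(umi_bins)) {
    for (phi in phi_values) {
      for (rep_i in seq_len(replicates)) {
        child <- (seed * 7919 + b * 104729 + round(phi * 1e4) * 1299709 +
                    rep_i * 15485863) %% max_seed
        res <- simulate_one(land, basis, umi_bins[[b]], phi, coef_scale,
                            ase_cell_type, child, control)
        res$umi_bin <- paste(umi_bins[[b]], collapse = "-")
        res$phi_true <- phi
        res$replicate <- rep_i
        rows[[length(rows) + 1]] <- res
      }
    }
  }
  dplyr::bind_rows(rows)
}

simulate_one <- function(land, basis, umi_range, phi, coef_scale,
                         ase_cell_type, child_seed, control) {
  tryCatch({
    truth <- sim_truth(land, basis = basis, coef_scale = coef_scale,
                       ase_cell_type = ase_cell_type, phi = phi,
                       seed = child_seed)
    set.seed(child_seed + 1)
    umi <- round(runif(1, umi_range[1], umi_range[2]))
    counts <- sim_counts(truth, total_umi = umi, seed = child_seed + 2)
    alpha <- reorder_alpha(truth$alpha, rownames(counts$Y))
    d <- gene_design(as.numeric(counts$Y[, 1]),
                     as.numeric(counts$N[, 1]), alpha = alpha,
                     covariates = basis$B, share_spline = FALSE,
                     gene_id = "sim_gene",
                     spot_ids = rownames(counts$Y))
    fit <- fit_gene(d, control = control)
    ev <- evaluate_fit(fit, truth)
    ev$total_umi <- umi
    ev$phi_hat <- fit$phi
    ev$converged <- fit$converged
    ev$error <- NA_character_
    ev
  }, error = function(e) {
    tibble(pearson_r = NA_real_, rmse_beta = NA_real_,
           constant_fit = NA, total_umi = NA_real_, phi_hat = NA_real_,
           converged = FALSE, error = conditionMessage(e))
  })
}
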