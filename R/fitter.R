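#' Fitting control parameters
#'
#' Trust-region and alternation constants for [fit_gene()]. The strategy
#' is fixed (second-order trust region with adaptive radius); these
#' constants are engineering defaults.
#'
#' @param max_iter Maximum Newton iterations per coefficient step.
#' @param tol_ll Absolute log-likelihood change declaring convergence.
#' @param tol_grad Gradient-norm convergence threshold.
#' @param delta_init,delta_max Initial and maximum trust-region radius.
#' @param accept_ratio Minimum actual/predicted improvement ratio to
#'   accept a step.
#' @param shrink_threshold,grow_threshold Ratio thresholds below/above
#'   which the radius is shrunk/grown.
#' @param shrink,grow Radius multipliers.
#' @param max_alternations Maximum coefficient/overdispersion alternations.
#' @param phi_bounds Search interval for the overdispersion.
#' @return List of control values.
#' @export
fit_control <- function(max_iter = 200, tol_ll = 1e-8, tol_grad = 1e-6,
                        delta_init = 1, delta_max = 1e3,
                        accept_ratio = 0.1, shrink_threshold = 0.25,
                        grow_threshold = 0.75, shrink = 0.5, grow = 2,
                        max_alternations = 50,
                        phi_bounds = c(1e-6, 1 - 1e-6)) {
  as.list(environment())
}

# exact trust-region subproblem for minimizing g's + s'Bs/2, ||s|| <= Delta,
# via eigendecomposition of B (P is small)
solve_trust_region <- function(g, B, Delta) {
  eg <- eigen(B, symmetric = TRUE)
  lam <- eg$values
  Q <- eg$vectors
  gt <- drop(crossprod(Q, g))
  if (lam[length(lam)] > 1e-10) {
    s <- -drop(Q %*% (gt / lam))
    if (sqrt(sum(s^2)) <= Delta) return(s)
  }
  step_norm <- function(l) sqrt(sum((gt / (lam + l))^2))
  l_lo <- max(0, -lam[length(lam)]) + 1e-12
  if (step_norm(l_lo) <= Delta) {
    # hard case: boundary multiplier leaves the step short; pad along the
    # most negative eigen-direction to reach the boundary
    s <- -drop(Q %*% (gt / (lam + l_lo)))
    resid <- Delta^2 - sum(s^2)
    if (resid > 0) s <- s + sqrt(resid) * Q[, length(lam)]
    return(s)
  }
  l_hi <- l_lo + 1
  while (step_norm(l_hi) > Delta) l_hi <- l_hi * 2
  for (it in 1:100) {
    l_mid <- (l_lo + l_hi) / 2
    if (step_norm(l_mid) > Delta) l_lo <- l_mid else l_hi <- l_mid
  }
  -drop(Q %*% (gt / (lam + l_hi)))
}

# trust-region Newton ascent of the log-likelihood in beta at fixed phi
tr_newton <- function(beta, phi, design, control) {
  ev <- loglik_grad_hess(beta, phi, design)
  if (!is.finite(ev$loglik)) abort("non-finite likelihood at initialization")
  Delta <- control$delta_init
  n_iter <- 0L
  n_clipped <- ev$n_clipped
  for (iter in seq_len(control$max_iter)) {
    n_iter <- iter
    gnorm <- sqrt(sum(ev$gradient^2))
    if (gnorm < control$tol_grad) break
    s <- solve_trust_region(-ev$gradient, -ev$hessian, Delta)
    pred <- sum(ev$gradient * s) + 0.5 * drop(crossprod(s, ev$hessian %*% s))
    if (!is.finite(pred) || pred <= 0) {
      Delta <- Delta * control$shrink
      if (Delta < 1e-13) break
      next
    }
    cand <- loglik_grad_hess(beta + s, phi, design, what = "loglik")
    rho <- (cand$loglik - ev$loglik) / pred
    if (is.finite(rho) && rho > control$accept_ratio) {
      beta <- beta + s
      delta_ll <- cand$loglik - ev$loglik
      stopifnot(delta_ll >= 0)  # accepted steps never decrease the loglik
      ev <- loglik_grad_hess(beta, phi, design)
      n_clipped <- max(n_clipped, ev$n_clipped)
      if (abs(delta_ll) < control$tol_ll) break
    }
    if (!is.finite(rho) || rho < control$shrink_threshold) {
      Delta <- Delta * control$shrink
    } else if (rho > control$grow_threshold &&
                 sqrt(sum(s^2)) >= 0.99 * Delta) {
      Delta <- min(Delta * control$grow, control$delta_max)
    }
    if (Delta < 1e-13) break
  }
  list(beta = beta, loglik = ev$loglik, gradient = ev$gradient,
       hessian = ev$hessian, n_iter = n_iter,
       gradient_norm = sqrt(sum(ev$gradient^2)), n_clipped = n_clipped)
}

# method-of-moments warm start for the overdispersion
phi_moments <- function(design, bounds) {
  p0 <- sum(design$y) / sum(design$n)
  p0 <- min(max(p0, 1e-6), 1 - 1e-6)
  n <- design$n
  v <- (design$y - n * p0)^2
  num <- sum(v) - sum(n * p0 * (1 - p0))
  den <- sum(n * p0 * (1 - p0) * (n - 1))
  phi <- if (den > 0) num / den else bounds[1]
  min(max(phi, bounds[1]), bounds[2])
}

#' Maximum-likelihood fit for one gene
#'
#' Second-order trust-region Newton ascent in the coefficients, alternated
#' with bounded scalar maximization of the overdispersion, until the joint
#' log-likelihood stabilizes. Quadratic subproblems are solved exactly
#' within the current radius; the radius shrinks when a step's actual
#' improvement falls short of its quadratic prediction and grows when the
#' prediction is reliable. Non-concave regions are handled by the exact
#' subproblem (no line search needed). The coefficient covariance is the
#' inverse observed information at the optimum (ridge-regularized if
#' necessary, recorded in `warnings`).
#'
#' @param design A [gene_design()] object.
#' @param phi Fixed overdispersion value, or `NULL` to estimate it.
#' @param control See [fit_control()].
#' @return A `gene_fit` object: `beta` (named), `phi`, `loglik`,
#'   `cov_beta`, `converged`, `n_iterations`, `gradient_norm`, `warnings`,
#'   plus the design.
#' @export
fit_gene <- function(design, phi = NULL, control = fit_control()) {
  if (length(design$y) < design$P) {
    abort(paste0("gene ", design$gene_id, ": ", design$P,
                 " parameters exceed ", length(design$y), " usable spots"))
  }
  warnings <- character()
  if (length(design$dropped_cell_types)) {
    warnings <- c(warnings, paste0("dropped cell types: ",
                                   paste(design$dropped_cell_types,
                                         collapse = ", ")))
  }
  fix_phi <- !is.null(phi)
  if (!fix_phi) phi <- phi_moments(design, control$phi_bounds)
  beta <- rep(0, design$P)
  ll_prev <- -Inf
  converged <- FALSE
  total_iter <- 0L
  phi_boundary <- FALSE
  res <- NULL
  for (alt in seq_len(control$max_alternations)) {
    res <- tr_newton(beta, phi, design, control)
    beta <- res$beta
    total_iter <- total_iter + res$n_iter
    ll <- res$loglik
    if (!fix_phi) {
      ph <- estimate_phi(beta, design, bounds = control$phi_bounds)
      phi <- ph$phi
      ll <- ph$loglik
      phi_boundary <- ph$boundary
      if (ph$flat) warnings <- c(warnings,
                                 "likelihood flat in phi (unidentifiable)")
    }
    if (abs(ll - ll_prev) < control$tol_ll || fix_phi) {
      converged <- res$gradient_norm < control$tol_grad ||
        abs(ll - ll_prev) < control$tol_ll
      if (fix_phi) converged <- res$gradient_norm < control$tol_grad ||
          res$n_iter < control$max_iter
      ll_prev <- ll
      break
    }
    ll_prev <- ll
  }
  if (res$n_clipped > 0) {
    warnings <- c(warnings, paste0("linear predictor clipped at ",
                                   res$n_clipped,
                                   " spots (possible separation)"))
  }
  if (phi_boundary) warnings <- c(warnings, "phi at search boundary")
  # final derivatives at (beta, phi)
  final <- loglik_grad_hess(beta, phi, design)
  cv <- safe_covariance(-final$hessian)
  if (cv$ridge > 0) {
    warnings <- c(warnings, paste0("covariance ridge ",
                                   formatC(cv$ridge, format = "e",
                                           digits = 1)))
  }
  structure(list(gene_id = design$gene_id, beta = setNames(beta,
                                                           design$par_names),
                 phi = phi, loglik = final$loglik, cov_beta = cv$cov,
                 converged = converged, n_iterations = total_iter,
                 gradient_norm = sqrt(sum(final$gradient^2)),
                 warnings = warnings, design = design),
            class = "gene_fit")
}

# invert the observed information, escalating a ridge until positive
# definite (mixtures of expits are non-concave in general)
safe_covariance <- function(info) {
  ridge <- 0
  for (m in 0:40) {
    r <- if (m == 0) 0 else 1e-8 * 2^(m - 1)
    ok <- tryCatch({
      ch <- chol(info + r * diag(nrow(info)))
      cov <- chol2inv(ch)
      TRUE
    }, error = function(e) FALSE)
    if (ok) {
      ridge <- r
      dimnames(cov) <- list(rownames(info), colnames(info))
      return(list(cov = cov, ridge = ridge))
    }
  }
  list(cov = matrix(NA_real_, nrow(info), ncol(info)), ridge = NA_real_)
}

#' @export
print.gene_fit <- function(x, ...) {
  cat("<gene_fit>", x$gene_id, ": loglik =", format(x$loglik),
      ", phi =", format(x$phi, digits = 4),
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' Fit every gene in a dataset
#'
#' Independent per-gene maximum-likelihood fits; results do not depend on
#' ordering or worker count. Per-gene failures are captured in the result
#' table, not fatal.
#'
#' @param counts An [allelic_counts()] object.
#' @param weights Optional [cell_type_weights()]; `NULL` collapses all
#'   cell types.
#' @param rates Optional [expression_rates()]; `NULL` uses uniform rates.
#' @param genes Genes to fit; defaults to [filter_genes_overall()].
#' @param covariates Optional S x L covariate matrix aligned to spots
#'   (e.g. `tps_basis(counts$coords, k)$B`).
#' @param share_spline Share covariate coefficients across cell types?
#' @param phi Fixed overdispersion or `NULL` to estimate per gene.
#' @param min_nonzero Filter threshold when `genes` is `NULL`.
#' @param control See [fit_control()].
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return Tibble with one row per gene: estimates summary columns and the
#'   full `gene_fit` in a list-column `fit`.
#' @export
fit_all <- function(counts, weights = NULL, rates = NULL, genes = NULL,
                    covariates = NULL, share_spline = TRUE, phi = NULL,
                    min_nonzero = 128, control = fit_control(),
                    workers = 1) {
  if (is.null(genes)) genes <- filter_genes_overall(counts, min_nonzero)
  if (!length(genes)) {
    warn("empty gene list; returning empty result")
    return(tibble(gene = character(), loglik = double(), phi = double(),
                  converged = logical(), error = character(),
                  fit = list()))
  }
  W <- if (!is.null(weights)) cell_type_weights(weights)
  one <- function(g) {
    tryCatch({
      alpha <- if (!is.null(W)) {
        al <- compute_alpha(W, rates, gene = g)
        reorder_alpha(al, rownames(counts$Y))
      }
      d <- gene_design(y = as.numeric(counts$Y[, g]),
                       n = as.numeric(counts$N[, g]),
                       alpha = alpha, covariates = covariates,
                       share_spline = share_spline, gene_id = g,
                       spot_ids = rownames(counts$Y))
      fit <- fit_gene(d, phi = phi, control = control)
      tibble(gene = g, loglik = fit$loglik, phi = fit$phi,
             converged = fit$converged, error = NA_character_,
             fit = list(fit))
    }, error = function(e) {
      tibble(gene = g, loglik = NA_real_, phi = NA_real_,
             converged = FALSE, error = conditionMessage(e), fit = list(NULL))
    })
  }
  res <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(genes, one, mc.cores = workers)
  } else {
    lapply(genes, one)
  }
  dplyr::bind_rows(res)
}

# align a mixture_weights object to a spot ordering
reorder_alpha <- function(alpha, spot_ids) {
  idx <- match(spot_ids, alpha$spot_ids)
  if (anyNA(idx)) abort("weights are missing some count spots")
  alpha$A <- alpha$A[idx, , drop = FALSE]
  alpha$valid <- alpha$valid[idx]
  alpha$spot_ids <- spot_ids
  alpha
}
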