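#' Beta-binomial log probability mass in mean/overdispersion form
#'
#' The beta-binomial distribution parameterized by its mean probability `p`
#' and an overdispersion `phi` in `[0, 1)`, corresponding to a
#' `Beta(a, b)` mixing distribution with `a = p (1 - phi) / phi` and
#' `b = (1 - p) (1 - phi) / phi`. `phi = 0` evaluates the exact binomial
#' limit; `p` equal to 0 or 1 is handled as a point mass at `y = 0` or
#' `y = n` by continuity.
#'
#' @param y Number of maternal counts, `0 <= y <= n` (vectorized).
#' @param n Total allele-resolved counts.
#' @param p Mean maternal probability in `[0, 1]`.
#' @param phi Overdispersion in `[0, 1)`.
#' @return Log probability mass, recycled to common length.
#' @export
bb_logpmf <- function(y, n, p, phi) {
  ll <- cbind(y, n, p, phi)  # recycle
  y <- ll[, 1]; n <- ll[, 2]; p <- ll[, 3]; phi <- ll[, 4]
  if (any(y < 0) || any(y > n)) abort("need 0 <= y <= n")
  if (any(phi < 0) || any(phi >= 1)) abort("phi must lie in [0, 1)")
  if (any(p < 0) || any(p > 1)) abort("p must lie in [0, 1]")
  out <- numeric(length(y))

  pm <- p <= 0 | p >= 1
  if (any(pm)) {
    out[pm] <- ifelse((p[pm] <= 0 & y[pm] == 0) |
                        (p[pm] >= 1 & y[pm] == n[pm]), 0, -Inf)
  }
  bin <- !pm & phi == 0
  if (any(bin)) out[bin] <- dbinom(y[bin], n[bin], p[bin], log = TRUE)
  bb <- !pm & phi > 0
  if (any(bb)) {
    s <- (1 - phi[bb]) / phi[bb]
    a <- p[bb] * s
    b <- (1 - p[bb]) * s
    out[bb] <- lchoose(n[bb], y[bb]) + lbeta(y[bb] + a, n[bb] - y[bb] + b) -
      lbeta(a, b)
  }
  out
}

# first and second derivatives of the beta-binomial log pmf w.r.t. p
bb_dp <- function(y, n, p, phi) {
  if (phi == 0) {
    list(g = y / p - (n - y) / (1 - p),
         h = -y / p^2 - (n - y) / (1 - p)^2)
  } else {
    s <- (1 - phi) / phi
    a <- s * p
    b <- s * (1 - p)
    list(g = s * (digamma(y + a) - digamma(a) -
                    digamma(n - y + b) + digamma(b)),
         h = s^2 * (trigamma(y + a) - trigamma(a) +
                      trigamma(n - y + b) - trigamma(b)))
  }
}

#' Per-gene design for the mixture beta-binomial model
#'
#' Assembles the usable-spot data for one gene: maternal/total counts,
#' mixture shares, and covariates. Usable spots have `n > 0` and a valid
#' mixture row. Cell types whose total share over usable spots falls below
#' `ct_floor` are dropped (their intercepts would be unidentifiable) and
#' remaining shares renormalized.
#'
#' The parameter vector is laid out as one `(intercept, L covariates)`
#' block per cell type when `share_spline = FALSE` (length `K (L + 1)`),
#' or as `K` intercepts followed by `L` shared covariate coefficients
#' (length `K + L`) when `share_spline = TRUE`.
#'
#' @param y,n Maternal and total counts per spot (equal length).
#' @param alpha A [compute_alpha()] object, or `NULL` for a single
#'   aggregate cell type.
#' @param covariates S x L covariate matrix (e.g. a spline design), or
#'   `NULL` for intercept-only.
#' @param share_spline Share covariate coefficients across cell types?
#' @param spline_cell_types When `share_spline = FALSE`, the cell types
#'   that receive covariate blocks (`NULL` = all); others are
#'   intercept-only, which is how nested per-cell-type null models are
#'   expressed.
#' @param ct_floor Minimum total mixture share for a cell type to be kept.
#' @param gene_id Label carried into fits.
#' @param spot_ids Optional spot identifiers.
#' @return A `gene_design` object.
#' @export
gene_design <- function(y, n, alpha = NULL, covariates = NULL,
                        share_spline = TRUE, spline_cell_types = NULL,
                        ct_floor = 1.0, gene_id = "gene",
                        spot_ids = NULL) {
  y <- as.numeric(y); n <- as.numeric(n)
  stopifnot(length(y) == length(n))
  if (any(y < 0) || any(y > n)) abort("need 0 <= y <= n")
  S0 <- length(y)
  if (is.null(spot_ids)) spot_ids <- as.character(seq_len(S0))
  if (is.null(alpha)) {
    A0 <- matrix(1, S0, 1, dimnames = list(NULL, "all"))
    valid <- rep(TRUE, S0)
  } else {
    A0 <- alpha$A
    valid <- alpha$valid
    if (nrow(A0) != S0) abort("alpha and counts disagree in spot count")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != S0) abort("covariates and counts disagree")
  }
  usable <- n > 0 & valid
  if (!any(usable)) abort("no usable spots (n > 0 with valid mixture row)")

  A <- A0[usable, , drop = FALSE]
  dropped_ct <- character()
  repeat {
    share <- colSums(A)
    low <- share < ct_floor
    if (!any(low) || sum(!low) == 0) break
    dropped_ct <- c(dropped_ct, colnames(A)[low])
    A <- A[, !low, drop = FALSE]
    rs <- rowSums(A)
    keep_rows <- rs > 0
    A <- A / ifelse(rs > 0, rs, 1)
    if (!all(keep_rows)) {
      idx <- which(usable)
      usable[idx[!keep_rows]] <- FALSE
      A <- A[keep_rows, , drop = FALSE]
    }
  }
  if (ncol(A) == 0) abort("all cell types dropped by the share floor")

  K <- ncol(A)
  G <- if (is.null(covariates)) {
    matrix(0, sum(usable), 0)
  } else {
    covariates[usable, , drop = FALSE]
  }
  L <- ncol(G)
  cov_names <- colnames(G) %||% if (L) paste0("g", 1:L) else character()
  share_spline <- isTRUE(share_spline) && L > 0 && K > 1
  X <- cbind(`(Intercept)` = 1, G)
  cts <- colnames(A)
  # per-cell-type maps: bcols picks this type's entries of beta, xcols the
  # matching columns of X
  if (share_spline) {
    bcols <- lapply(seq_len(K), function(k) c(k, K + seq_len(L)))
    xcols <- rep(list(seq_len(L + 1)), K)
    P <- K + L
    par_names <- c(paste0("b0[", cts, "]"), cov_names)
  } else {
    mask <- if (is.null(spline_cell_types)) rep(TRUE, K) else
      cts %in% spline_cell_types
    mask <- mask & L > 0
    sizes <- 1L + ifelse(mask, L, 0L)
    off <- cumsum(c(0L, sizes[-K]))
    bcols <- lapply(seq_len(K), function(k) off[k] + seq_len(sizes[k]))
    xcols <- lapply(seq_len(K), function(k) seq_len(sizes[k]))
    P <- sum(sizes)
    par_names <- unlist(lapply(seq_len(K), function(k) {
      nm <- c("b0", if (mask[k]) cov_names)
      if (K == 1) nm else paste0(nm, "[", cts[k], "]")
    }))
  }
  structure(list(gene_id = gene_id, y = y[usable], n = n[usable],
                 A = A, X = X, K = K, L = L, P = P,
                 share_spline = share_spline,
                 bcols = bcols, xcols = xcols,
                 par_names = par_names,
                 cell_types = cts, dropped_cell_types = dropped_ct,
                 spot_ids = spot_ids[usable], usable = usable),
            class = "gene_design")
}

#' @export
print.gene_design <- function(x, ...) {
  cat("<gene_design>", x$gene_id, ":", length(x$y), "usable spots, K =",
      x$K, ", L =", x$L, ",", x$P, "parameters",
      if (x$share_spline) "(shared covariates)" else "", "\n")
  invisible(x)
}

# linear predictors per cell type, S x K (unclipped)
design_eta <- function(beta, design) {
  eta <- matrix(0, nrow(design$X), design$K)
  for (k in seq_len(design$K)) {
    eta[, k] <- design$X[, design$xcols[[k]], drop = FALSE] %*%
      beta[design$bcols[[k]]]
  }
  eta
}

#' Mixture-of-expit mean maternal probability
#'
#' `p_i = sum_k alpha[i,k] expit(eta[i,k])` with the linear predictor
#' clipped to `[-15, 15]` for stability under complete separation.
#'
#' @param beta Parameter vector matching the design layout.
#' @param design A [gene_design()] object.
#' @return Probability vector over usable spots.
#' @export
mixture_mean <- function(beta, design) {
  if (length(beta) != design$P) {
    abort(paste0("beta has length ", length(beta), ", design expects ",
                 design$P))
  }
  eta <- clip_eta(design_eta(beta, design))
  unname(rowSums(design$A * expit(eta)))
}

#' Gene log-likelihood with analytic gradient and Hessian
#'
#' Sum over usable spots of the beta-binomial log pmf at the mixture mean,
#' with exact first and second derivatives in `beta` obtained by the chain
#' rule through the mixture (digamma/trigamma terms for the derivative in
#' `p`).
#'
#' @param beta Parameter vector.
#' @param phi Overdispersion in `[0, 1)`.
#' @param design A [gene_design()] object.
#' @param what `"loglik"` for the value only, `"all"` for value, gradient
#'   and Hessian.
#' @return For `"all"`, a list `loglik`, `gradient` (length P), `hessian`
#'   (P x P, symmetric), `n_clipped` (spots with clipped predictors).
#' @export
loglik_grad_hess <- function(beta, phi, design, what = c("all", "loglik")) {
  what <- match.arg(what)
  if (length(beta) != design$P) abort("parameter length mismatch")
  eta_raw <- design_eta(beta, design)
  eta <- clip_eta(eta_raw)
  n_clipped <- sum(rowSums(abs(eta_raw) > ETA_CLIP) > 0)
  sig <- expit(eta)
  p <- rowSums(design$A * sig)
  ll <- sum(bb_logpmf(design$y, design$n, p, phi))
  if (what == "loglik") return(list(loglik = ll, n_clipped = n_clipped))
  if (!is.finite(ll)) {
    bad <- which(!is.finite(bb_logpmf(design$y, design$n, p, phi)))
    abort(paste0("non-finite log-likelihood at spots ",
                 paste(head(bad, 3), collapse = ", ")))
  }

  d <- bb_dp(design$y, design$n, p, phi)
  sp <- design$A * sig * (1 - sig)         # S x K: dp/deta_k
  spp <- sp * (1 - 2 * sig)                # S x K: d2p/deta_k^2
  K <- design$K; P <- design$P
  X <- design$X
  U <- matrix(0, nrow(X), P)
  H2 <- matrix(0, P, P)
  for (k in seq_len(K)) {
    bi <- design$bcols[[k]]
    Xk <- X[, design$xcols[[k]], drop = FALSE]
    U[, bi] <- U[, bi] + sp[, k] * Xk
    w2 <- d$g * spp[, k]
    H2[bi, bi] <- H2[bi, bi] + crossprod(Xk, Xk * w2)
  }
  gradient <- drop(crossprod(U, d$g))
  hessian <- crossprod(U, U * d$h) + H2
  hessian <- (hessian + t(hessian)) / 2
  names(gradient) <- design$par_names
  list(loglik = ll, gradient = gradient, hessian = hessian,
       n_clipped = n_clipped)
}

#' Estimate overdispersion with coefficients held fixed
#'
#' Bounded scalar maximization of the gene log-likelihood over `phi`.
#' Deterministic for fixed inputs; boundary solutions and likelihoods flat
#' in `phi` (e.g. every spot with `n = 1`) are flagged.
#'
#' @param beta Parameter vector.
#' @param design A [gene_design()] object.
#' @param bounds Search interval for `phi`.
#' @return List with `phi`, `loglik`, `boundary` flag and `flat` flag.
#' @export
estimate_phi <- function(beta, design, bounds = c(1e-6, 1 - 1e-6)) {
  p <- mixture_mean(beta, design)
  f <- function(phi) sum(bb_logpmf(design$y, design$n, p, phi))
  opt <- optimize(f, interval = bounds, maximum = TRUE, tol = 1e-8)
  phi <- opt$maximum
  ll <- opt$objective
  f_lo <- f(bounds[1]); f_hi <- f(bounds[2])
  # flatness judged relative to the data scale (log-gamma rounding at the
  # extreme shape values keeps the ends from agreeing to machine precision)
  tol_flat <- 1e-8 * max(1, sum(design$n))
  flat <- abs(ll - f_lo) < tol_flat && abs(ll - f_hi) < tol_flat
  if (f_lo >= ll) { phi <- bounds[1]; ll <- f_lo }
  if (f_hi > ll) { phi <- bounds[2]; ll <- f_hi }
  boundary <- phi <= bounds[1] + 1e-5 || phi >= bounds[2] - 1e-5
  list(phi = phi, loglik = ll, boundary = boundary, flat = flat)
}
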