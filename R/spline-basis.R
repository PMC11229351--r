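#' Thin-plate regression spline basis in 2D
#'
#' Builds a low-rank unpenalized thin-plate regression spline basis from 2D
#' coordinates: the radial kernel `r^2 log r` evaluated on pairwise
#' distances is rank-reduced to its leading eigen-directions, the linear
#' null space (x, y) is appended, and the constant direction is absorbed by
#' a sum-to-zero constraint since the model supplies its own intercept.
#' The result is `L = k - 1` centered covariate columns usable both as
#' model covariates and for out-of-sample surface prediction.
#'
#' Coordinates are internally standardized (centered, scaled by
#' root-mean-square distance from the centroid) for numerical conditioning;
#' the constants are stored so evaluation at new coordinates is
#' transparent. Eigenvector sign is fixed by forcing the
#' largest-magnitude component positive, making construction deterministic.
#' For large point sets the kernel eigenproblem is solved on a
#' deterministic space-covering subset of `max_knots` spots.
#'
#' @param coords Numeric S x 2 matrix (or data frame with `x`, `y`) of
#'   spot positions.
#' @param k Basis dimension (degrees of freedom), `k >= 3`. Use `k = 5`
#'   for hypothesis testing and `k = 15` for high-resolution
#'   visualization surfaces.
#' @param max_knots Maximum number of knots used for the kernel
#'   eigendecomposition.
#' @return A `tps_basis` object with the design matrix `B` (S x (k-1),
#'   columns summing to zero over the training spots) and everything
#'   needed by [evaluate_basis()].
#' @export
tps_basis <- function(coords, k = 5, max_knots = 600) {
  X <- coords_matrix(coords)
  S <- nrow(X)
  if (k < 3) abort("k must be at least 3")
  if (S < k) abort(paste0("need at least k = ", k, " spots; lower k"))
  if (any(!is.finite(X))) abort("coordinates must be finite")

  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(mean(rowSums(Xc^2)))
  if (scale <= 0) abort("degenerate coordinate geometry: all spots coincide")
  Z <- Xc / scale
  if (qr(cbind(1, Z))$rank < 3 && k > 3) {
    abort("degenerate coordinate geometry: spots are collinear")
  }

  m <- k - 3L  # number of kernel eigen-directions beyond the linear space
  if (m > 0) {
    knots <- Z[knot_index(Z, max_knots), , drop = FALSE]
    E <- tps_kernel(knots, knots)
    eg <- eigen(E, symmetric = TRUE)
    ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(m)]
    U <- eg$vectors[, ord, drop = FALSE]
    # deterministic sign convention
    for (jj in seq_len(ncol(U))) {
      piv <- which.max(abs(U[, jj]))
      if (U[piv, jj] < 0) U[, jj] <- -U[, jj]
    }
  } else {
    knots <- Z[integer(0), , drop = FALSE]
    U <- matrix(0, 0, 0)
  }

  basis <- structure(list(k = as.integer(k), L = as.integer(k - 1),
                          center = center, scale = scale,
                          knots = knots, U = U,
                          col_means = NULL, col_scales = NULL, B = NULL,
                          training_coords_digest = coords_digest(X)),
                     class = "tps_basis")
  Braw <- basis_columns(basis, Z)
  basis$col_means <- colMeans(Braw)
  Bc <- sweep(Braw, 2, basis$col_means)
  # unit-variance columns over the training spots: coefficients then live
  # on a common logit scale and the optimizer sees a well-conditioned
  # design; undone transparently at evaluation
  sds <- apply(Bc, 2, stats::sd)
  sds[sds < 1e-12] <- 1
  basis$col_scales <- sds
  basis$B <- sweep(Bc, 2, sds, "/")
  colnames(basis$B) <- paste0("tps", seq_len(basis$L))
  basis
}

coords_matrix <- function(coords) {
  if (is.data.frame(coords)) {
    if (all(c("x", "y") %in% names(coords))) {
      coords <- cbind(coords$x, coords$y)
    } else {
      coords <- as.matrix(coords[, 1:2])
    }
  }
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2) abort("coords must have two columns")
  coords
}

coords_digest <- function(X) {
  v <- c(nrow(X), colSums(X), colSums(X^2), sum(X[, 1] * X[, 2]))
  paste(formatC(v, digits = 12, format = "g"), collapse = "|")
}

# deterministic space-covering subset: stratify on x then thin evenly
knot_index <- function(Z, max_knots) {
  S <- nrow(Z)
  if (S <= max_knots) return(seq_len(S))
  ord <- order(Z[, 1], Z[, 2])
  ord[round(seq(1, S, length.out = max_knots))]
}

# eta(r) = r^2 log r, zero at r = 0
tps_kernel <- function(A, B) {
  r2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  r2[r2 < 1e-300] <- 1e-300
  0.5 * r2 * log(r2)
}

# uncentered basis columns at standardized coordinates
basis_columns <- function(basis, Z) {
  cols <- Z  # linear null space
  if (ncol(basis$U) > 0) {
    cols <- cbind(cols, tps_kernel(Z, basis$knots) %*% basis$U)
  }
  cols
}

#' Evaluate a thin-plate basis at new coordinates
#'
#' Applies the stored standardization, kernel directions and centering
#' constants, so that evaluation at the training coordinates reproduces the
#' stored design matrix exactly.
#'
#' @param basis A [tps_basis()] object.
#' @param new_coords Numeric M x 2 matrix or data frame with `x`, `y`.
#' @return M x L numeric matrix.
#' @export
evaluate_basis <- function(basis, new_coords) {
  X <- coords_matrix(new_coords)
  Z <- sweep(X, 2, basis$center) / basis$scale
  B <- sweep(basis_columns(basis, Z), 2, basis$col_means)
  B <- sweep(B, 2, basis$col_scales, "/")
  colnames(B) <- paste0("tps", seq_len(basis$L))
  B
}

#' @export
print.tps_basis <- function(x, ...) {
  cat("<tps_basis> k =", x$k, "->", x$L, "centered columns;",
      nrow(x$B), "training spots,", nrow(x$knots), "knots\n")
  invisible(x)
}
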