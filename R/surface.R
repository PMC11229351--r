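#' Predict a maternal-probability surface with confidence intervals
#'
#' Evaluates a fitted model's maternal allele probability over a grid of
#' 2D locations. For a single requested cell type the linear predictor is
#' `eta(x) = b0[k] + B(x) b[k]`; the `"overall"` surface weights the
#' per-cell-type expits by the spot-averaged mixture shares. Pointwise
#' variance comes from the delta method through the coefficient
#' covariance; intervals are formed on the logit scale and mapped through
#' the inverse logit, so they respect `[0, 1]` by construction.
#'
#' By default the grid is masked to locations near observed spots
#' (distance below `mask_radius`), so surfaces take the shape of the
#' tissue rather than extrapolating into empty space.
#'
#' @param fit A [fit_gene()] result whose design used `basis` columns.
#' @param basis The [tps_basis()] the fit's covariates came from.
#' @param grid M x 2 matrix / data frame of locations, or `NULL` to build
#'   an `n_grid` x `n_grid` lattice over the bounding box of the training
#'   spots.
#' @param coords Training spot coordinates (needed for grid construction
#'   and masking when `grid` is `NULL`).
#' @param n_grid Lattice resolution per axis.
#' @param level Confidence level for the pointwise intervals.
#' @param cell_type Cell-type label, or `"overall"`.
#' @param mask_radius Mask distance; `NULL` disables masking for an
#'   explicit `grid`, and defaults to 2x the median nearest-neighbour
#'   spacing for a constructed lattice.
#' @return An `ase_surface` tibble: `x`, `y`, `p_hat`, `ci_lower`,
#'   `ci_upper`, `se_eta`, with the level and basis df as attributes.
#' @export
predict_surface <- function(fit, basis, grid = NULL, coords = NULL,
                            n_grid = 60, level = 0.95,
                            cell_type = "overall", mask_radius = NULL) {
  design <- fit$design
  if (is.null(grid)) {
    if (is.null(coords)) abort("supply grid or coords")
    Xc <- coords_matrix(coords)
    gx <- seq(min(Xc[, 1]), max(Xc[, 1]), length.out = n_grid)
    gy <- seq(min(Xc[, 2]), max(Xc[, 2]), length.out = n_grid)
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    if (is.null(mask_radius)) {
      mask_radius <- 2 * median_nn_distance(Xc)
    }
  } else {
    grid <- coords_matrix(grid)
  }
  if (!is.null(mask_radius) && !is.null(coords)) {
    keep <- min_dist_to(grid, coords_matrix(coords)) <= mask_radius
    grid <- grid[keep, , drop = FALSE]
  }
  M <- nrow(grid)
  if (!M) abort("empty prediction grid after masking")
  B <- if (design$L > 0) evaluate_basis(basis, grid) else
    matrix(0, M, 0)
  if (design$L > 0 && ncol(B) != design$L) {
    abort("basis does not match the fit's covariate dimension")
  }

  z <- -stats::qnorm((1 - level) / 2)
  if (!identical(cell_type, "overall")) {
    k <- match(cell_type, design$cell_types)
    if (is.na(k)) abort(paste0("cell type '", cell_type,
                               "' not in the fit"))
    # rows of the prediction design in this cell type's coordinates
    Xg <- cbind(1, B)[, design$xcols[[k]], drop = FALSE]
    full <- matrix(0, M, design$P)
    full[, design$bcols[[k]]] <- Xg
    eta <- drop(full %*% fit$beta)
    var_eta <- rowSums((full %*% fit$cov_beta) * full)
    se <- sqrt(pmax(var_eta, 0))
    p_hat <- expit(eta)
    lo <- expit(eta - z * se)
    hi <- expit(eta + z * se)
  } else {
    abar <- colMeans(design$A)
    eta_k <- matrix(0, M, design$K)
    J <- matrix(0, M, design$P)  # dp/dbeta
    for (k in seq_len(design$K)) {
      Xg <- cbind(1, B)[, design$xcols[[k]], drop = FALSE]
      eta_k[, k] <- clip_eta(drop(Xg %*% fit$beta[design$bcols[[k]]]))
      sgk <- expit(eta_k[, k])
      J[, design$bcols[[k]]] <- J[, design$bcols[[k]]] +
        abar[k] * sgk * (1 - sgk) * Xg
    }
    p_hat <- drop(expit(eta_k) %*% abar)
    var_p <- rowSums((J %*% fit$cov_beta) * J)
    se_p <- sqrt(pmax(var_p, 0))
    pc <- pmin(pmax(p_hat, 1e-8), 1 - 1e-8)
    se <- se_p / (pc * (1 - pc))  # logit-scale se by the delta method
    eta <- stats::qlogis(pc)
    lo <- expit(eta - z * se)
    hi <- expit(eta + z * se)
  }
  out <- tibble(x = grid[, 1], y = grid[, 2], p_hat = p_hat,
                ci_lower = pmin(lo, p_hat), ci_upper = pmax(hi, p_hat),
                se_eta = se)
  attr(out, "level") <- level
  attr(out, "k_used") <- basis$k
  attr(out, "source_fit") <- fit$gene_id
  attr(out, "cell_type") <- cell_type
  class(out) <- c("ase_surface", class(out))
  out
}

median_nn_distance <- function(X) {
  n <- nrow(X)
  sub <- if (n > 2000) X[seq(1, n, length.out = 2000), , drop = FALSE] else X
  D <- as.matrix(dist(sub))
  diag(D) <- Inf
  stats::median(apply(D, 1, min))
}

min_dist_to <- function(A, B) {
  # chunked to keep memory bounded
  out <- numeric(nrow(A))
  bs <- 2000L
  for (s in seq(1, nrow(A), by = bs)) {
    idx <- s:min(s + bs - 1L, nrow(A))
    d2 <- outer(rowSums(A[idx, , drop = FALSE]^2), rowSums(B^2), "+") -
      2 * tcrossprod(A[idx, , drop = FALSE], B)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}

#' Profile a surface along a line segment
#'
#' Evaluates [predict_surface()] at evenly spaced points along a segment
#' and returns an arc-length-parameterized profile with its confidence
#' band, as used for cross-sections through X-inactivation domains.
#'
#' @inheritParams predict_surface
#' @param point Numeric length-2 start of the segment.
#' @param direction Numeric length-2 direction (normalized internally).
#' @param length Segment length in coordinate units.
#' @param n_points Number of evaluation points.
#' @return Tibble `arc_length`, `x`, `y`, `p_hat`, `ci_lower`, `ci_upper`.
#' @export
cross_section <- function(fit, basis, point, direction, length,
                          n_points = 100, level = 0.95,
                          cell_type = "overall") {
  nrm <- sqrt(sum(direction^2))
  if (!is.finite(nrm) || nrm == 0 || length <= 0) {
    abort("zero-length segment or degenerate direction")
  }
  u <- direction / nrm
  t <- seq(0, length, length.out = n_points)
  pts <- cbind(point[1] + t * u[1], point[2] + t * u[2])
  surf <- predict_surface(fit, basis, grid = pts, level = level,
                          cell_type = cell_type, mask_radius = NULL)
  out <- tibble(arc_length = t, x = surf$x, y = surf$y,
                p_hat = surf$p_hat, ci_lower = surf$ci_lower,
                ci_upper = surf$ci_upper)
  attr(out, "level") <- level
  out
}

#' Raw per-spot maternal fractions
#'
#' The model-free view used beside fitted surfaces: per spot with
#' non-zero total counts, the observed maternal fraction and the total
#' count (for point sizing).
#'
#' @param counts An [allelic_counts()] object.
#' @param gene Gene identifier.
#' @return Tibble `spot_id`, `x`, `y`, `fraction`, `total`.
#' @export
raw_fraction_map <- function(counts, gene) {
  df <- gene_counts(counts, gene)
  df <- df[df$total > 0, ]
  tibble(spot_id = df$spot_id, x = df$x, y = df$y,
         fraction = df$maternal / df$total, total = df$total)
}

#' Plot a fitted allelic surface
#'
#' Diverging red (maternal) / blue (paternal) map centred at the balanced
#' probability 0.5.
#'
#' @param object An `ase_surface` tibble from [predict_surface()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ase_surface
#' @export
autoplot.ase_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       fill = .data$p_hat)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "blue",
                                  mid = "white", high = "red",
                                  limits = c(0, 1),
                                  name = "maternal\nprobability") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = attr(object, "source_fit"),
                  subtitle = paste0("cell type: ",
                                    attr(object, "cell_type"))) +
    ggplot2::theme_minimal()
}

#' Plot raw maternal fractions per spot
#'
#' @param fractions Output of [raw_fraction_map()].
#' @return A ggplot object.
#' @export
plot_fraction_map <- function(fractions) {
  ggplot2::ggplot(fractions, ggplot2::aes(.data$x, .data$y,
                                          colour = .data$fraction,
                                          size = .data$total)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(midpoint = 0.5, low = "blue",
                                    mid = "white", high = "red",
                                    limits = c(0, 1),
                                    name = "maternal\nfraction") +
    ggplot2::scale_size_area(max_size = 3, name = "total UMI") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Plot a cross-section profile with its confidence band
#'
#' @param profile Output of [cross_section()].
#' @return A ggplot object.
#' @export
plot_cross_section <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$arc_length, .data$p_hat)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "distance along section",
                  y = "maternal allele probability") +
    ggplot2::theme_minimal()
}
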