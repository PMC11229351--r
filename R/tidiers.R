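#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a per-gene fit
#'
#' One row per coefficient with its standard error and Wald statistics.
#'
#' @param x A [fit_gene()] result.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `std.error`, `statistic`, `p.value`.
#' @method tidy gene_fit
#' @export
tidy.gene_fit <- function(x, ...) {
  se <- sqrt(pmax(diag(x$cov_beta), 0))
  est <- unname(x$beta)
  tibble(term = names(x$beta), estimate = est, std.error = se,
         statistic = est / se, p.value = wald_p(est, se))
}

#' One-row fit summary
#'
#' @param x A [fit_gene()] result.
#' @param ... Unused.
#' @return Tibble with likelihood, overdispersion and convergence record.
#' @method glance gene_fit
#' @export
glance.gene_fit <- function(x, ...) {
  tibble(gene = x$gene_id, loglik = x$loglik, phi = x$phi,
         n_parameters = length(x$beta), n_spots = length(x$design$y),
         converged = x$converged, n_iterations = x$n_iterations,
         gradient_norm = x$gradient_norm,
         n_warnings = length(x$warnings))
}

#' Export fit coefficients for a table of fits
#'
#' @param fits Output of [fit_all()].
#' @return Tibble with one row per gene x coefficient.
#' @export
tidy_fits <- function(fits) {
  ok <- !vapply(fits$fit, is.null, logical(1))
  dplyr::bind_rows(lapply(fits$fit[ok], function(f) {
    out <- tidy(f)
    out$gene <- f$gene_id
    out[, c("gene", setdiff(names(out), "gene"))]
  }))
}

#' Plot simulation-grid recovery results
#'
#' Boxplots of the per-replicate correlation between estimated and true
#' surfaces, grouped by total-UMI bin.
#'
#' @param results Output of [run_simulation_grid()].
#' @return A ggplot object.
#' @export
plot_simulation_results <- function(results) {
  results$umi_bin <- factor(results$umi_bin,
                            levels = unique(results$umi_bin))
  ggplot2::ggplot(results, ggplot2::aes(.data$umi_bin, .data$pearson_r)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::labs(x = "total UMI bin",
                  y = "correlation with true surface") +
    ggplot2::theme_minimal()
}
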