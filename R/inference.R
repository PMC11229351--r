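#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, applied separately per test family. `NaN`
#' p-values propagate to `NaN` adjusted values with a warning.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @return Vector of adjusted (q) values.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.nan(p_values))) warn("NaN p-values propagated to q-values")
  ok <- !is.na(p_values)
  q <- p_values
  q[ok] <- p.adjust(p_values[ok], method = "BH")
  q
}

# direction call: maternal/paternal only when significant AND the
# estimated probability clears the corresponding bound
call_direction <- function(p_hat, q, q_cutoff = 0.01,
                           bounds = c(0.4, 0.6)) {
  dplyr::case_when(
    is.na(q) | is.na(p_hat) ~ "none",
    q < q_cutoff & p_hat > bounds[2] ~ "maternal",
    q < q_cutoff & p_hat < bounds[1] ~ "paternal",
    .default = "none")
}

result_row <- function(gene, category, cell_type = NA_character_,
                       estimate = NA_real_, statistic = NA_real_,
                       df = NA_integer_, p_value = NA_real_,
                       p_hat = NA_real_, converged = NA, phi = NA_real_,
                       note = NA_character_) {
  tibble(gene = gene, category = category, cell_type = cell_type,
         estimate = unname(estimate), statistic = unname(statistic),
         df = as.integer(df), p_value = unname(p_value),
         p_hat = unname(p_hat), converged = converged,
         phi = phi, note = note)
}

finalize_family <- function(res, q_cutoff, bounds, directional = TRUE) {
  if (!nrow(res)) {
    res$q_value <- double()
    res$direction <- character()
    return(res)
  }
  grp <- if (all(is.na(res$cell_type))) "category" else
    c("category", "cell_type")
  res <- dplyr::group_by(res, dplyr::across(dplyr::all_of(grp)))
  res <- dplyr::mutate(res, q_value = adjust_fdr(.data$p_value))
  res <- dplyr::ungroup(res)
  res$direction <- if (directional) {
    call_direction(res$p_hat, res$q_value, q_cutoff, bounds)
  } else "none"
  res
}

wald_p <- function(est, se) 2 * pnorm(-abs(est / se))

#' Test for overall allelic bias
#'
#' Fits the intercept-only beta-binomial model (cell type and space
#' ignored) per gene and Wald-tests the intercept against zero. A
#' significant gene is called maternal only when the estimated maternal
#' probability exceeds 0.6 and paternal only when it falls below 0.4.
#'
#' @param counts An [allelic_counts()] object.
#' @param genes Genes to test; defaults to [filter_genes_overall()].
#' @param min_nonzero Filter threshold when `genes` is `NULL`.
#' @param q_cutoff Significance threshold on the adjusted p-value.
#' @param direction_bounds Lower/upper probability bounds for calling
#'   paternal/maternal direction.
#' @param phi Fixed overdispersion, or `NULL` to estimate per gene.
#' @param control See [fit_control()].
#' @return Tibble of test results (one row per gene) with `q_value` and
#'   `direction` computed within the family.
#' @export
test_overall_bias <- function(counts, genes = NULL, min_nonzero = 128,
                              q_cutoff = 0.01,
                              direction_bounds = c(0.4, 0.6), phi = NULL,
                              control = fit_control()) {
  if (is.null(genes)) genes <- filter_genes_overall(counts, min_nonzero)
  rows <- lapply(genes, function(g) {
    tryCatch({
      d <- gene_design(as.numeric(counts$Y[, g]),
                       as.numeric(counts$N[, g]), gene_id = g,
                       spot_ids = rownames(counts$Y))
      fit <- fit_gene(d, phi = phi, control = control)
      se <- sqrt(fit$cov_beta[1, 1])
      result_row(g, "overall_bias", estimate = fit$beta[1],
                 statistic = fit$beta[1] / se, df = 1L,
                 p_value = wald_p(fit$beta[1], se),
                 p_hat = expit(fit$beta[1]), converged = fit$converged,
                 phi = fit$phi,
                 note = paste(fit$warnings, collapse = "; "))
    }, error = function(e) {
      result_row(g, "overall_bias", note = conditionMessage(e))
    })
  })
  finalize_family(dplyr::bind_rows(rows), q_cutoff, direction_bounds)
}

#' Test for within-cell-type allelic bias
#'
#' Fits the mixture intercept model
#' `p_i = sum_k alpha[i,k] expit(b0[k])` per gene and Wald-tests each
#' retained cell type's intercept, with the same 0.6/0.4 direction rule
#' applied to `expit(b0[k])`. Results are reported for (gene, cell type)
#' pairs passing the within-cell-type filter; adjustment is per cell type.
#'
#' @inheritParams test_overall_bias
#' @param weights [cell_type_weights()] tibble.
#' @param rates Optional [expression_rates()]; `NULL` for uniform rates.
#' @param presence_threshold See [filter_genes_within_celltype()].
#' @return Tibble of test results, one row per gene x cell type.
#' @export
test_within_ct_bias <- function(counts, weights, rates = NULL,
                                genes = NULL, min_nonzero = 128,
                                presence_threshold = 0.5, q_cutoff = 0.01,
                                direction_bounds = c(0.4, 0.6), phi = NULL,
                                control = fit_control()) {
  keep <- filter_genes_within_celltype(counts, weights, min_nonzero,
                                       presence_threshold)
  if (is.null(genes)) genes <- unique(unlist(keep))
  W <- cell_type_weights(weights)
  rows <- lapply(genes, function(g) {
    cts_wanted <- names(keep)[vapply(keep, function(v) g %in% v, logical(1))]
    if (!length(cts_wanted)) return(NULL)
    tryCatch({
      alpha <- reorder_alpha(compute_alpha(W, rates, gene = g),
                             rownames(counts$Y))
      d <- gene_design(as.numeric(counts$Y[, g]),
                       as.numeric(counts$N[, g]), alpha = alpha,
                       gene_id = g, spot_ids = rownames(counts$Y))
      fit <- fit_gene(d, phi = phi, control = control)
      cts <- intersect(cts_wanted, d$cell_types)
      dplyr::bind_rows(lapply(cts, function(ct) {
        i <- match(ct, d$cell_types)
        se <- sqrt(fit$cov_beta[i, i])
        result_row(g, "within_ct_bias", cell_type = ct,
                   estimate = fit$beta[i], statistic = fit$beta[i] / se,
                   df = 1L, p_value = wald_p(fit$beta[i], se),
                   p_hat = expit(fit$beta[i]), converged = fit$converged,
                   phi = fit$phi,
                   note = paste(fit$warnings, collapse = "; "))
      }))
    }, error = function(e) {
      result_row(g, "within_ct_bias", note = conditionMessage(e))
    })
  })
  finalize_family(dplyr::bind_rows(rows), q_cutoff, direction_bounds)
}

# likelihood ratio test of a full against a nested null fit
lrt_row <- function(gene, category, fit_full, fit_null, df,
                    cell_type = NA_character_) {
  stat <- 2 * (fit_full$loglik - fit_null$loglik)
  note <- paste(c(fit_full$warnings, fit_null$warnings), collapse = "; ")
  if (stat < 0) {
    # numerically non-nested decrease: floor at zero
    stat <- 0
    note <- paste(note, "LRT statistic floored at 0", sep = "; ")
  }
  result_row(gene, category, cell_type = cell_type, statistic = stat,
             df = as.integer(df),
             p_value = pchisq(stat, df = df, lower.tail = FALSE),
             p_hat = NA_real_,
             converged = fit_full$converged && fit_null$converged,
             phi = fit_full$phi, note = note)
}

#' Test for an overall spatial allelic pattern
#'
#' Likelihood ratio test of the spline model
#' `logit(p_i) = b0 + B(x_i) b` against the intercept-only model, cell
#' types ignored, with the overdispersion re-estimated in each model. The
#' statistic refers to a chi-square with `L = k - 1` degrees of freedom.
#'
#' @inheritParams test_overall_bias
#' @param basis A [tps_basis()] built on the dataset coordinates, or
#'   `NULL` to build one with `k`.
#' @param k Spline degrees of freedom used when `basis` is `NULL`.
#' @return Tibble of test results, one row per gene.
#' @export
test_overall_spatial <- function(counts, genes = NULL, basis = NULL, k = 5,
                                 min_nonzero = 128, q_cutoff = 0.01,
                                 phi = NULL, control = fit_control()) {
  if (is.null(genes)) genes <- filter_genes_overall(counts, min_nonzero)
  if (is.null(basis)) basis <- tps_basis(counts$coords, k = k)
  B <- basis$B
  rows <- lapply(genes, function(g) {
    tryCatch({
      y <- as.numeric(counts$Y[, g]); n <- as.numeric(counts$N[, g])
      d0 <- gene_design(y, n, gene_id = g, spot_ids = rownames(counts$Y))
      d1 <- gene_design(y, n, covariates = B, gene_id = g,
                        spot_ids = rownames(counts$Y))
      f0 <- fit_gene(d0, phi = phi, control = control)
      f1 <- fit_gene(d1, phi = phi, control = control)
      lrt_row(g, "overall_spatial", f1, f0, df = basis$L)
    }, error = function(e) {
      result_row(g, "overall_spatial", note = conditionMessage(e))
    })
  })
  finalize_family(dplyr::bind_rows(rows), q_cutoff, directional = FALSE)
}

#' Test for a within-cell-type spatial allelic pattern
#'
#' Fits the full mixture model with cell-type intercepts and spline terms
#' inside the expit and likelihood-ratio-tests it against the
#' within-cell-type intercept model. With `spline = "shared"` (default)
#' the spline coefficients are shared across cell types and a single test
#' with `L` degrees of freedom is reported per gene; with
#' `spline = "specific"` each cell type carries its own spline block and
#' is tested separately (df `L` each) by refitting without that block.
#'
#' @inheritParams test_within_ct_bias
#' @param basis A [tps_basis()], or `NULL` to build one with `k`.
#' @param k Spline degrees of freedom.
#' @param spline `"shared"` or `"specific"` spline coefficients.
#' @return Tibble of test results.
#' @export
test_within_ct_spatial <- function(counts, weights, rates = NULL,
                                   genes = NULL, basis = NULL, k = 5,
                                   spline = c("shared", "specific"),
                                   min_nonzero = 128,
                                   presence_threshold = 0.5,
                                   q_cutoff = 0.01, phi = NULL,
                                   control = fit_control()) {
  spline <- match.arg(spline)
  keep <- filter_genes_within_celltype(counts, weights, min_nonzero,
                                       presence_threshold)
  if (is.null(genes)) genes <- unique(unlist(keep))
  if (is.null(basis)) basis <- tps_basis(counts$coords, k = k)
  B <- basis$B
  W <- cell_type_weights(weights)
  rows <- lapply(genes, function(g) {
    tryCatch({
      alpha <- reorder_alpha(compute_alpha(W, rates, gene = g),
                             rownames(counts$Y))
      y <- as.numeric(counts$Y[, g]); n <- as.numeric(counts$N[, g])
      d0 <- gene_design(y, n, alpha = alpha, gene_id = g,
                        spot_ids = rownames(counts$Y))
      f0 <- fit_gene(d0, phi = phi, control = control)
      if (spline == "shared") {
        d1 <- gene_design(y, n, alpha = alpha, covariates = B,
                          share_spline = TRUE, gene_id = g,
                          spot_ids = rownames(counts$Y))
        f1 <- fit_gene(d1, phi = phi, control = control)
        lrt_row(g, "within_ct_spatial", f1, f0, df = basis$L)
      } else {
        d1 <- gene_design(y, n, alpha = alpha, covariates = B,
                          share_spline = FALSE, gene_id = g,
                          spot_ids = rownames(counts$Y))
        f1 <- fit_gene(d1, phi = phi, control = control)
        cts_wanted <- intersect(
          names(keep)[vapply(keep, function(v) g %in% v, logical(1))],
          d1$cell_types)
        dplyr::bind_rows(lapply(cts_wanted, function(ct) {
          # null: full model with cell type ct restricted to intercept-only
          fr <- fit_restricted_ct(y, n, alpha, B, ct,
                                  rownames(counts$Y), phi, control)
          lrt_row(g, "within_ct_spatial", f1, fr, df = basis$L,
                  cell_type = ct)
        }))
      }
    }, error = function(e) {
      result_row(g, "within_ct_spatial", note = conditionMessage(e))
    })
  })
  finalize_family(dplyr::bind_rows(rows), q_cutoff, directional = FALSE)
}

# cell-type-specific-spline model with one cell type's spline block fixed
# at zero (that cell type reduced to intercept-only)
fit_restricted_ct <- function(y, n, alpha, B, ct, spot_ids, phi, control) {
  d <- gene_design(y, n, alpha = alpha, covariates = B,
                   share_spline = FALSE,
                   spline_cell_types = setdiff(alpha$cell_types, ct),
                   spot_ids = spot_ids)
  fit_gene(d, phi = phi, control = control)
}

#' Aggregate per-gene classification across test batteries
#'
#' Joins all test results into the per-gene seven-way taxonomy: no
#' significant ASE (exclusive); overall maternal / paternal bias;
#' within-cell-type maternal / paternal bias; overall spatial pattern;
#' within-cell-type spatial pattern. Genes may belong to several
#' non-exclusive categories.
#'
#' @param results Tibble binding rows of the four test batteries.
#' @param q_cutoff Significance threshold.
#' @return Per-gene tibble of logical membership columns.
#' @export
classify_genes <- function(results, q_cutoff = 0.01) {
  genes <- unique(results$gene)
  sig <- function(cat, dir = NULL) {
    r <- results[results$category == cat & !is.na(results$q_value) &
                   results$q_value < q_cutoff, ]
    if (!is.null(dir)) r <- r[r$direction == dir, ]
    genes %in% unique(r$gene)
  }
  out <- tibble(
    gene = genes,
    overall_maternal = sig("overall_bias", "maternal"),
    overall_paternal = sig("overall_bias", "paternal"),
    within_ct_maternal = sig("within_ct_bias", "maternal"),
    within_ct_paternal = sig("within_ct_bias", "paternal"),
    overall_spatial = sig("overall_spatial"),
    within_ct_spatial = sig("within_ct_spatial"))
  out$no_significant_ase <- !Reduce(`|`, out[, -1])
  out
}

#' Category summary table
#'
#' Row-per-category gene counts in the order used for reporting, with an
#' optional autosome / X-chromosome split.
#'
#' @param classification Output of [classify_genes()].
#' @param chromosome_map Optional tibble `gene`, `chromosome` (X-linked
#'   genes labelled `"X"`).
#' @return Tibble `category`, `n_genes` (and `n_autosomal`, `n_x` when a
#'   map is given).
#' @export
category_summary <- function(classification, chromosome_map = NULL) {
  cats <- c(no_significant_ase = "No significant ASE",
            overall_maternal = "Overall maternal bias",
            overall_paternal = "Overall paternal bias",
            within_ct_maternal = "Within cell type maternal bias",
            within_ct_paternal = "Within cell type paternal bias",
            overall_spatial = "Overall spatial pattern",
            within_ct_spatial = "Within cell type spatial pattern")
  out <- tibble(category = unname(cats),
                n_genes = vapply(names(cats), function(cc)
                  sum(classification[[cc]]), integer(1),
                  USE.NAMES = FALSE))
  if (!is.null(chromosome_map)) {
    isx <- classification$gene %in%
      chromosome_map$gene[chromosome_map$chromosome == "X"]
    out$n_autosomal <- vapply(names(cats), function(cc)
      sum(classification[[cc]] & !isx), integer(1), USE.NAMES = FALSE)
    out$n_x <- vapply(names(cats), function(cc)
      sum(classification[[cc]] & isx), integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Run the full hypothesis-testing suite
#'
#' Convenience wrapper running the requested test batteries and returning
#' the bound result table; each battery is corrected separately.
#'
#' @inheritParams test_within_ct_spatial
#' @param categories Subset of the four batteries to run.
#' @return Tibble of all test results.
#' @export
ase_tests <- function(counts, weights = NULL, rates = NULL,
                      categories = c("overall_bias", "within_ct_bias",
                                     "overall_spatial",
                                     "within_ct_spatial"),
                      k = 5, min_nonzero = 128, presence_threshold = 0.5,
                      q_cutoff = 0.01, direction_bounds = c(0.4, 0.6),
                      phi = NULL, control = fit_control()) {
  categories <- match.arg(categories, several.ok = TRUE)
  need_w <- intersect(categories, c("within_ct_bias", "within_ct_spatial"))
  if (length(need_w) && is.null(weights)) {
    abort(paste0("cell-type weights required for: ",
                 paste(need_w, collapse = ", ")))
  }
  basis <- if (any(grepl("spatial", categories)))
    tps_basis(counts$coords, k = k)
  out <- list()
  if ("overall_bias" %in% categories) {
    out$ob <- test_overall_bias(counts, min_nonzero = min_nonzero,
                                q_cutoff = q_cutoff,
                                direction_bounds = direction_bounds,
                                phi = phi, control = control)
  }
  if ("within_ct_bias" %in% categories) {
    out$wb <- test_within_ct_bias(counts, weights, rates,
                                  min_nonzero = min_nonzero,
                                  presence_threshold = presence_threshold,
                                  q_cutoff = q_cutoff,
                                  direction_bounds = direction_bounds,
                                  phi = phi, control = control)
  }
  if ("overall_spatial" %in% categories) {
    out$os <- test_overall_spatial(counts, basis = basis,
                                   min_nonzero = min_nonzero,
                                   q_cutoff = q_cutoff, phi = phi,
                                   control = control)
  }
  if ("within_ct_spatial" %in% categories) {
    out$ws <- test_within_ct_spatial(counts, weights, rates,
                                     basis = basis,
                                     min_nonzero = min_nonzero,
                                     presence_threshold = presence_threshold,
                                     q_cutoff = q_cutoff, phi = phi,
                                     control = control)
  }
  dplyr::bind_rows(out)
}
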