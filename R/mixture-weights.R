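#' Validate and normalize cell-type deconvolution weights
#'
#' Cell-type proportions per spot as produced by an upstream deconvolution
#' tool. Rows are renormalized to sum to 1 on load (proportions from
#' doublet-mode output often sum slightly off 1).
#'
#' @param df Data frame with a `spot_id` column plus one numeric column per
#'   cell type.
#' @param normalize Renormalize rows to sum to 1 (default). When `FALSE`,
#'   rows must already sum to 1 within `1e-6`.
#' @return A tibble of the same shape with normalized rows.
#' @export
cell_type_weights <- function(df, normalize = TRUE) {
  df <- as_tibble(df)
  if (!"spot_id" %in% names(df)) abort("weights need a spot_id column")
  if (anyDuplicated(df$spot_id)) abort("duplicate spot_id in weights")
  ct <- setdiff(names(df), "spot_id")
  if (!length(ct)) abort("weights need at least one cell-type column")
  W <- as.matrix(df[, ct])
  if (any(!is.finite(W)) || any(W < 0)) {
    abort("cell-type weights must be finite and non-negative")
  }
  rs <- rowSums(W)
  if (any(rs <= 0)) abort("some spots have all-zero cell-type weights")
  if (normalize) {
    W <- W / rs
  } else if (any(abs(rs - 1) > 1e-6)) {
    abort("weight rows do not sum to 1 (set normalize = TRUE)")
  }
  out <- as_tibble(as.data.frame(W))
  out$spot_id <- as.character(df$spot_id)
  out[, c("spot_id", ct)]
}

# tibble -> matrix, aligned (and restricted) to spot_ids when given
weights_matrix <- function(weights, spot_ids = NULL) {
  weights <- cell_type_weights(weights)
  ct <- setdiff(names(weights), "spot_id")
  W <- as.matrix(weights[, ct])
  rownames(W) <- weights$spot_id
  if (!is.null(spot_ids)) {
    common <- intersect(spot_ids, rownames(W))
    if (!length(common)) abort("no spots shared between counts and weights")
    W <- W[common, , drop = FALSE]
  }
  W
}

#' Cell-type-specific expression rates
#'
#' Expected expression rate of each gene in each cell type, as estimated by
#' an upstream cell-type-specific DE tool. Rates can be constant per cell
#' type (no `spot_id` column) or spatially varying (one row per spot).
#'
#' @param df Data frame with columns `gene`, `cell_type`, `rate` and
#'   optionally `spot_id`.
#' @return Validated tibble.
#' @export
expression_rates <- function(df) {
  df <- as_tibble(df)
  req <- c("gene", "cell_type", "rate")
  if (!all(req %in% names(df))) {
    abort("rates need gene, cell_type and rate columns")
  }
  if (any(!is.finite(df$rate)) || any(df$rate < 0)) {
    abort("expression rates must be finite and non-negative")
  }
  zero <- dplyr::group_by(df, .data$gene)
  zero <- dplyr::summarise(zero, all0 = all(.data$rate == 0))
  if (any(zero$all0)) {
    abort(paste0("genes with all-zero rates across cell types: ",
                 paste(head(zero$gene[zero$all0], 3), collapse = ", ")))
  }
  df
}

#' Uniform fallback rates
#'
#' All rates equal to 1, so the mixture shares reduce to the deconvolution
#' weights. Used when no upstream DE estimates are supplied; fitting with
#' uniform rates when true rates differ biases cell-type attribution.
#'
#' @param gene_ids,cell_types Identifier vectors.
#' @return An [expression_rates()] tibble.
#' @export
default_rates <- function(gene_ids, cell_types) {
  expression_rates(tidyr::expand_grid(gene = gene_ids,
                                      cell_type = cell_types, rate = 1))
}

#' Per-gene cell-type mixture shares
#'
#' The share of gene `j`'s transcripts at spot `i` attributable to cell
#' type `k`: `alpha[i,k] = w[i,k] * mu[j,k] / sum_k w[i,k] * mu[j,k]`,
#' combining deconvolution proportions `w` with expression rates `mu`.
#' Spots with a zero denominator (the gene is not expressed by any cell
#' type present) are marked invalid and excluded from likelihoods, where
#' the conditional maternal probability is undefined.
#'
#' @param weights [cell_type_weights()] tibble.
#' @param rates [expression_rates()] tibble; `NULL` for uniform rates.
#' @param gene Gene identifier to extract rates for.
#' @return A `mixture_weights` object: `gene_id`, `spot_ids`, `cell_types`,
#'   share matrix `A` (rows of valid spots sum to 1) and `valid` mask.
#' @export
compute_alpha <- function(weights, rates = NULL, gene = "gene") {
  W <- weights_matrix(weights)
  cts <- colnames(W)
  if (is.null(rates)) rates <- default_rates(gene, cts)
  rates <- expression_rates(rates)
  r <- rates[rates$gene == gene, ]
  if (!nrow(r)) abort(paste0("no rates for gene '", gene, "'"))
  if (!setequal(unique(r$cell_type), cts)) {
    abort("cell-type labels of weights and rates disagree")
  }
  if ("spot_id" %in% names(r) && !all(is.na(r$spot_id))) {
    Mu <- matrix(0, nrow(W), length(cts),
                 dimnames = list(rownames(W), cts))
    idx <- cbind(match(as.character(r$spot_id), rownames(W)),
                 match(r$cell_type, cts))
    ok <- !is.na(idx[, 1])
    Mu[idx[ok, , drop = FALSE]] <- r$rate[ok]
  } else {
    mu <- setNames(r$rate, r$cell_type)[cts]
    Mu <- matrix(mu, nrow(W), length(cts), byrow = TRUE,
                 dimnames = list(rownames(W), cts))
  }
  num <- W * Mu
  den <- rowSums(num)
  valid <- den > 0
  A <- num
  A[valid, ] <- num[valid, , drop = FALSE] / den[valid]
  A[!valid, ] <- 0
  structure(list(gene_id = gene, spot_ids = rownames(W), cell_types = cts,
                 A = A, valid = valid),
            class = "mixture_weights")
}

#' @export
print.mixture_weights <- function(x, ...) {
  cat("<mixture_weights>", x$gene_id, ":", length(x$spot_ids), "spots x",
      length(x$cell_types), "cell types;", sum(!x$valid), "invalid spots\n")
  invisible(x)
}
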