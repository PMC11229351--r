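#' Allele-resolved spatial count container
#'
#' Holds maternal (`Y`) and total (`N`) allele-resolved UMI counts per spot
#' and gene together with 2D spot coordinates. Counts are stored as sparse
#' matrices (spots in rows, genes in columns). The container enforces the
#' core data invariants: `0 <= Y <= N` entrywise, unique spot and gene
#' identifiers, and finite coordinates.
#'
#' @param maternal Sparse or dense non-negative integer matrix of maternal
#'   allele counts, spots x genes, with row and column names.
#' @param total Matrix of total allele-resolved counts, same shape and
#'   dimnames as `maternal`.
#' @param coords Data frame with columns `spot_id`, `x`, `y` covering every
#'   row of the count matrices.
#' @param sample_id Label for the sample/puck.
#'
#' @return An object of class `allelic_counts` with elements `Y`, `N`
#'   (`dgCMatrix`), `coords` (tibble, ordered as the matrix rows) and
#'   `sample_id`.
#' @export
allelic_counts <- function(maternal, total, coords, sample_id = "sample") {
  Y <- as(as(as(maternal, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  N <- as(as(as(total, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(Y)) || is.null(colnames(Y))) {
    abort("count matrices must carry spot (row) and gene (column) names")
  }
  if (!identical(dim(Y), dim(N)) || !identical(dimnames(Y), dimnames(N))) {
    abort("maternal and total matrices must share dimensions and dimnames")
  }
  if (ncol(Y) == 0L) abort("no genes supplied (empty gene column set)")
  if (anyDuplicated(rownames(Y))) abort("duplicate spot identifiers")
  if (anyDuplicated(colnames(Y))) abort("duplicate gene identifiers")

  coords <- as_tibble(coords)
  req <- c("spot_id", "x", "y")
  if (!all(req %in% names(coords))) {
    abort("coords must have columns spot_id, x, y")
  }
  coords <- coords[, req]
  if (anyDuplicated(coords$spot_id)) abort("duplicate spot_id in coords")
  missing_xy <- setdiff(rownames(Y), coords$spot_id)
  if (length(missing_xy)) {
    abort(paste0("coords missing for ", length(missing_xy), " spots, e.g. ",
                 paste(head(missing_xy, 3), collapse = ", ")))
  }
  coords <- coords[match(rownames(Y), coords$spot_id), ]
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y))) {
    abort("coordinates must be finite")
  }

  validate_counts_pair(Y, N)
  structure(list(Y = Y, N = N, coords = coords, sample_id = sample_id),
            class = "allelic_counts")
}

validate_counts_pair <- function(Y, N) {
  if (any(Y@x < 0) || any(N@x < 0)) abort("negative counts are not allowed")
  D <- N - Y
  bad <- which(D@x < -1e-9)
  if (length(bad)) {
    ij <- which(as.matrix(D) < -1e-9, arr.ind = TRUE)
    ex <- paste0(rownames(D)[ij[, 1]], "/", colnames(D)[ij[, 2]])
    abort(paste0("maternal count exceeds total at ", length(ex),
                 " entries, e.g. ", paste(head(ex, 3), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.allelic_counts <- function(x, ...) {
  cat("<allelic_counts> sample:", x$sample_id, "\n")
  cat("  ", nrow(x$Y), "spots x", ncol(x$Y), "genes;",
      sum(x$N@x), "allele-resolved UMIs (", sum(x$Y@x), "maternal )\n")
  invisible(x)
}

#' @export
dim.allelic_counts <- function(x) dim(x$Y)

#' Build the count container from a long-format table
#'
#' Accepts the human-writable exchange dialect: one row per (spot, gene)
#' with maternal and paternal counts; the total is their sum by definition.
#'
#' @param long Data frame with columns `spot_id`, `gene`, `maternal_count`,
#'   and either `paternal_count` or `total_count`.
#' @param coords Data frame with `spot_id`, `x`, `y`.
#' @param sample_id Sample label.
#' @return An [allelic_counts()] object.
#' @export
as_allelic_counts <- function(long, coords, sample_id = "sample") {
  long <- as_tibble(long)
  if (!all(c("spot_id", "gene", "maternal_count") %in% names(long))) {
    abort("long table needs spot_id, gene, maternal_count columns")
  }
  if ("paternal_count" %in% names(long)) {
    total <- long$maternal_count + long$paternal_count
  } else if ("total_count" %in% names(long)) {
    total <- long$total_count
  } else {
    abort("long table needs paternal_count or total_count")
  }
  coords <- as_tibble(coords)
  spots <- unique(as.character(coords$spot_id))  # zero-count spots are real
  genes <- unique(as.character(long$gene))
  if (length(genes) == 0L) abort("no genes supplied (empty gene column set)")
  orphan <- setdiff(unique(as.character(long$spot_id)), spots)
  if (length(orphan)) {
    abort(paste0(length(orphan), " spots in the count table lack",
                 " coordinates, e.g. ", paste(head(orphan, 3),
                                              collapse = ", ")))
  }
  i <- match(as.character(long$spot_id), spots)
  j <- match(as.character(long$gene), genes)
  Y <- sparseMatrix(i = i, j = j, x = as.numeric(long$maternal_count),
                    dims = c(length(spots), length(genes)),
                    dimnames = list(spots, genes))
  N <- sparseMatrix(i = i, j = j, x = as.numeric(total),
                    dims = c(length(spots), length(genes)),
                    dimnames = list(spots, genes))
  allelic_counts(Y, N, coords, sample_id = sample_id)
}

#' Read allele-resolved counts from disk
#'
#' Two dialects are supported: (a) a pair of Matrix Market (`.mtx`) sparse
#' matrices with one-identifier-per-line sidecar files for spots and genes,
#' or (b) a single long-format CSV/TSV with columns `spot_id`, `gene`,
#' `maternal_count`, `paternal_count`. Spots are aligned by intersection
#' across sources; dropped identifiers are reported, never zero-filled.
#'
#' @param maternal_source Path to the maternal `.mtx` file, or the long CSV.
#' @param total_source Path to the total `.mtx` file; `NULL` for the long
#'   dialect.
#' @param coords_source Path to a CSV/TSV with `spot_id`, `x`, `y`.
#' @param spots_file,genes_file Sidecar identifier files (mtx dialect).
#' @param sample_id Sample label.
#' @return An [allelic_counts()] object.
#' @export
read_allelic_counts <- function(maternal_source, total_source = NULL,
                                coords_source, spots_file = NULL,
                                genes_file = NULL, sample_id = "sample") {
  coords <- readr::read_delim(coords_source, delim = delim_of(coords_source),
                              show_col_types = FALSE)
  if (grepl("\\.mtx$", maternal_source)) {
    if (is.null(total_source) || is.null(spots_file) || is.null(genes_file)) {
      abort("mtx dialect needs total_source, spots_file and genes_file")
    }
    spots <- readr::read_lines(spots_file)
    genes <- readr::read_lines(genes_file)
    Y <- as(readMM(maternal_source), "CsparseMatrix")
    N <- as(readMM(total_source), "CsparseMatrix")
    if (nrow(Y) != length(spots) || ncol(Y) != length(genes)) {
      abort("mtx dimensions do not match sidecar identifier files")
    }
    dimnames(Y) <- dimnames(N) <- list(spots, genes)
    keep <- intersect(spots, coords$spot_id)
    dropped <- length(spots) - length(keep)
    if (dropped > 0) {
      inform(paste0("dropping ", dropped, " spots absent from coords"))
    }
    if (!length(keep)) abort("no spots shared between counts and coords")
    allelic_counts(Y[keep, , drop = FALSE], N[keep, , drop = FALSE],
                   coords[coords$spot_id %in% keep, ], sample_id = sample_id)
  } else {
    long <- readr::read_delim(maternal_source,
                              delim = delim_of(maternal_source),
                              show_col_types = FALSE)
    keep <- intersect(unique(long$spot_id), coords$spot_id)
    dropped <- length(unique(long$spot_id)) - length(keep)
    if (dropped > 0) {
      inform(paste0("dropping ", dropped, " spots absent from coords"))
    }
    if (!length(keep)) abort("no spots shared between counts and coords")
    as_allelic_counts(long[long$spot_id %in% keep, ],
                      coords[coords$spot_id %in% keep, ],
                      sample_id = sample_id)
  }
}

delim_of <- function(path) if (grepl("\\.tsv$", path)) "\t" else ","

#' Write a count container as an MTX bundle
#'
#' Writes `maternal.mtx`, `total.mtx`, `spots.tsv`, `genes.tsv` and
#' `coords.csv` into `dir`; the bundle round-trips through
#' [read_allelic_counts()] exactly.
#'
#' @param x An [allelic_counts()] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_allelic_counts <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMM(x$Y, file.path(dir, "maternal.mtx"))
  writeMM(x$N, file.path(dir, "total.mtx"))
  readr::write_lines(rownames(x$Y), file.path(dir, "spots.tsv"))
  readr::write_lines(colnames(x$Y), file.path(dir, "genes.tsv"))
  readr::write_csv(x$coords, file.path(dir, "coords.csv"))
  invisible(dir)
}

#' Filter genes by overall spot support
#'
#' Retains genes observed (total count > 0) in at least `min_nonzero`
#' spots. The default of 128 spots reflects the count depth below which 2D
#' surface estimates become too variable to interpret.
#'
#' @param counts An [allelic_counts()] object.
#' @param min_nonzero Minimum number of spots with non-zero total counts.
#' @return Character vector of retained gene identifiers.
#' @export
filter_genes_overall <- function(counts, min_nonzero = 128) {
  stopifnot(min_nonzero >= 1)
  nz <- Matrix::colSums(counts$N > 0)
  names(nz)[nz >= min_nonzero]
}

#' Filter genes by spot support within each cell type
#'
#' A spot counts toward cell type `k` when its deconvolution weight for `k`
#' is at least `presence_threshold`. Per cell type, genes need
#' `min_nonzero` such spots with non-zero total counts.
#'
#' @param counts An [allelic_counts()] object.
#' @param weights Cell-type weights, see [cell_type_weights()].
#' @param min_nonzero Minimum supporting spots per gene per cell type.
#' @param presence_threshold Weight at or above which a spot is considered
#'   to contain the cell type; 0.5 corresponds to majority assignment in
#'   doublet-mode deconvolution output.
#' @return Named list mapping cell type to retained gene identifiers.
#' @export
filter_genes_within_celltype <- function(counts, weights, min_nonzero = 128,
                                         presence_threshold = 0.5) {
  W <- weights_matrix(weights, spot_ids = rownames(counts$N))
  out <- lapply(colnames(W), function(k) {
    present <- rownames(W)[W[, k] >= presence_threshold]
    sub <- counts$N[present, , drop = FALSE]
    nz <- Matrix::colSums(sub > 0)
    names(nz)[nz >= min_nonzero]
  })
  setNames(out, colnames(W))
}

#' Merge genes into a single pseudo-gene
#'
#' Sums maternal and total counts per spot over a retained gene set. Used
#' e.g. to merge all X-chromosome genes (excluding Xist) into one
#' high-coverage profile of the X-inactivation landscape.
#'
#' @param counts An [allelic_counts()] object.
#' @param gene_set Genes to merge.
#' @param exclude Genes removed from `gene_set` before merging.
#' @param name Identifier given to the pseudo-gene.
#' @return An [allelic_counts()] object with a single gene column.
#' @export
merge_genes <- function(counts, gene_set, exclude = character(),
                        name = "merged") {
  keep <- setdiff(intersect(gene_set, colnames(counts$Y)), exclude)
  if (!length(keep)) abort("no genes left to merge after exclusions")
  Y <- Matrix::rowSums(counts$Y[, keep, drop = FALSE])
  N <- Matrix::rowSums(counts$N[, keep, drop = FALSE])
  Ym <- sparseMatrix(i = which(Y > 0), j = rep(1L, sum(Y > 0)), x = Y[Y > 0],
                     dims = c(length(Y), 1L),
                     dimnames = list(rownames(counts$Y), name))
  Nm <- sparseMatrix(i = which(N > 0), j = rep(1L, sum(N > 0)), x = N[N > 0],
                     dims = c(length(N), 1L),
                     dimnames = list(rownames(counts$Y), name))
  allelic_counts(Ym, Nm, counts$coords, sample_id = counts$sample_id)
}

#' Extract one gene's counts as a tibble
#'
#' @param counts An [allelic_counts()] object.
#' @param gene Gene identifier.
#' @return Tibble with `spot_id`, `x`, `y`, `maternal`, `total`.
#' @export
gene_counts <- function(counts, gene) {
  if (!gene %in% colnames(counts$Y)) {
    abort(paste0("gene '", gene, "' not present"))
  }
  tibble(spot_id = rownames(counts$Y),
         x = counts$coords$x, y = counts$coords$y,
         maternal = as.numeric(counts$Y[, gene]),
         total = as.numeric(counts$N[, gene]))
}
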