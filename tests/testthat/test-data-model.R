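test_that("long-format construction sums alleles and validates", {
  cnt <- toy_counts()
  expect_equal(as.numeric(cnt$Y["s1", "g1"]), 2)
  expect_equal(as.numeric(cnt$N["s1", "g1"]), 5)  # maternal + paternal
  expect_equal(as.numeric(cnt$N["s5", "g1"]), 3)
  expect_equal(dim(cnt), c(9L, 2L))

  bad <- data.frame(spot_id = "s1", gene = "g1",
                    maternal_count = 5, total_count = 3)
  coords <- data.frame(spot_id = "s1", x = 0, y = 0)
  expect_error(as_allelic_counts(bad, coords), "exceeds total")
  empty <- data.frame(spot_id = character(), gene = character(),
                      maternal_count = numeric(),
                      paternal_count = numeric())
  expect_error(as_allelic_counts(empty, coords), "no genes")
})

test_that("validation rejects Y > N on random sparse matrices", {
  set.seed(42)
  for (rep_i in 1:10) {
    S <- 20; G <- 6
    N <- matrix(rbinom(S * G, 6, 0.3), S, G,
                dimnames = list(paste0("s", 1:S), paste0("g", 1:G)))
    Y <- matrix(rbinom(S * G, N, 0.5), S, G, dimnames = dimnames(N))
    coords <- data.frame(spot_id = rownames(N), x = runif(S), y = runif(S))
    expect_s3_class(allelic_counts(Y, N, coords), "allelic_counts")
    ij <- which(N > 0, arr.ind = TRUE)[1, ]
    Ybad <- Y
    Ybad[ij[1], ij[2]] <- N[ij[1], ij[2]] + 1
    expect_error(allelic_counts(Ybad, N, coords), "exceeds total")
  }
})

test_that("MTX bundle round-trips simulator output exactly", {
  ds <- make_small_dataset(S = 150, umi = 800, seed = 7)
  dir <- withr::local_tempdir()
  write_allelic_counts(ds$counts, dir)
  back <- read_allelic_counts(file.path(dir, "maternal.mtx"),
                              file.path(dir, "total.mtx"),
                              file.path(dir, "coords.csv"),
                              spots_file = file.path(dir, "spots.tsv"),
                              genes_file = file.path(dir, "genes.tsv"))
  expect_equal(as.matrix(back$Y), as.matrix(ds$counts$Y))
  expect_equal(as.matrix(back$N), as.matrix(ds$counts$N))
  expect_equal(back$coords$x, ds$counts$coords$x)
  expect_equal(back$coords$y, ds$counts$coords$y)
})

test_that("overall gene filter applies the spot-support threshold strictly", {
  set.seed(3)
  S <- 300
  nz <- c(g_at = 128, g_below = 127, g_tiny = 1)
  N <- matrix(0, S, 3, dimnames = list(paste0("s", 1:S), names(nz)))
  for (j in 1:3) N[sample(S, nz[j]), j] <- rpois(nz[j], 2) + 1
  Y <- N * 0
  coords <- data.frame(spot_id = rownames(N), x = runif(S), y = runif(S))
  cnt <- allelic_counts(Y, N, coords)

  kept <- filter_genes_overall(cnt, min_nonzero = 128)
  expect_true("g_at" %in% kept)
  expect_false("g_below" %in% kept)
  expect_setequal(filter_genes_overall(cnt, min_nonzero = 1),
                  c("g_at", "g_below", "g_tiny"))
  # monotone in the threshold
  for (thr in c(2, 50, 129, 200)) {
    expect_true(all(filter_genes_overall(cnt, thr) %in%
                      filter_genes_overall(cnt, thr - 1)))
  }
})

test_that("within-cell-type filter counts only presence-weighted spots", {
  set.seed(4)
  S <- 400
  N <- matrix(0, S, 1, dimnames = list(paste0("s", 1:S), "g1"))
  expressed <- sample(S, 200)
  N[expressed, 1] <- 1
  coords <- data.frame(spot_id = rownames(N), x = runif(S), y = runif(S))
  cnt <- allelic_counts(N * 0, N, coords)
  # 130 of the expressed spots contain ctA, the rest ctB
  wA <- rep(0.1, S)
  wA[expressed[1:130]] <- 0.9
  w <- cell_type_weights(data.frame(spot_id = rownames(N),
                                    ctA = wA, ctB = 1 - wA))
  keep <- filter_genes_within_celltype(cnt, w, min_nonzero = 128,
                                       presence_threshold = 0.5)
  expect_true("g1" %in% keep$ctA)
  expect_false("g1" %in% keep$ctB)
  # threshold 0 reduces to the overall filter for every cell type
  keep0 <- filter_genes_within_celltype(cnt, w, min_nonzero = 128,
                                        presence_threshold = 0)
  overall <- filter_genes_overall(cnt, 128)
  expect_equal(keep0$ctA, overall)
  expect_equal(keep0$ctB, overall)
})

test_that("gene merging is additive, conservative and handles exclusions", {
  cnt <- toy_counts()
  merged <- merge_genes(cnt, c("g1", "g2"), name = "chrX")
  expect_equal(as.numeric(merged$Y["s1", "chrX"]),
               as.numeric(cnt$Y["s1", "g1"] + cnt$Y["s1", "g2"]))
  expect_equal(sum(merged$Y@x), sum(cnt$Y@x))
  expect_equal(sum(merged$N@x), sum(cnt$N@x))
  expect_equal(merged$coords, cnt$coords)

  # excluding one gene mirrors the merged X-minus-Xist construction
  only_g1 <- merge_genes(cnt, c("g1", "g2"), exclude = "g2")
  expect_equal(as.numeric(only_g1$Y[, 1]), as.numeric(cnt$Y[, "g1"]))
  expect_equal(as.numeric(only_g1$N[, 1]), as.numeric(cnt$N[, "g1"]))
  expect_error(merge_genes(cnt, "g1", exclude = "g1"), "no genes left")
})
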