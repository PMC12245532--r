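small_sc <- function(seed = 1, ...) {
  simulate_singlecell_counts(
    n_genes = 60, cell_types = c("Cardiomyocyte", "Fibroblast",
                                 "Endothelial"),
    donors = default_donors(4, 4, 3, seed = seed),
    cells_per_donor_type = 15, seed = seed, ...)
}

test_that("pseudobulk aggregation sums exactly and conserves counts", {
  sc <- small_sc(2)
  pb <- aggregate_pseudobulk(sc$counts, sc$cells, sc$donors)
  expect_equal(sum(pb$counts), sum(sc$counts))
  expect_equal(unname(colSums(pb$counts)), pb$profiles$lib_size)
  # hand-check one profile
  d1 <- sc$cells$cell_id[sc$cells$donor_id == "don01" &
                           sc$cells$cell_type == "Fibroblast"]
  want <- Matrix::rowSums(sc$counts[, d1])
  got <- pb$counts[, pb$profiles$profile_id == "don01_Fibroblast"]
  expect_equal(got, want)
  # one cell per profile equals the raw counts
  one <- sc
  one$cells <- sc$cells[1:3, ]
  one$counts <- sc$counts[, 1:3]
  pb1 <- aggregate_pseudobulk(one$counts, one$cells, one$donors)
  expect_equal(unname(pb1$counts),
               unname(as.matrix(one$counts)[, order(one$cells$donor_id)]),
               ignore_attr = TRUE)
  bad <- sc$cells
  bad$donor_id[1] <- "ghost"
  expect_error(aggregate_pseudobulk(sc$counts, bad, sc$donors),
               "unknown donor")
})

test_that("TMM factors behave like pure-depth corrections", {
  sc <- small_sc(3)
  pb <- aggregate_pseudobulk(sc$counts, sc$cells, sc$donors)
  f <- tmm_factors(pb)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # identical profiles: all factors 1
  set.seed(1)
  base <- rpois(100, 20)
  m <- cbind(base, base, base, base)
  expect_equal(unname(tmm_factors(m)), rep(1, 4), tolerance = 1e-12)
  m <- matrix(rpois(400, 20), 100, 4)    # near-identical Poisson profiles
  # doubling depth only: factor stays 1 after library-size scaling
  # (all M-values between the two profiles are exactly 0)
  m2 <- cbind(base, 2L * base)
  f2 <- tmm_factors(m2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-12)
  # all-zero profiles are dropped with a warning
  m3 <- cbind(m, 0)
  expect_warning(f3 <- tmm_factors(m3), "all-zero")
  expect_length(f3, 4)
})

test_that("log-CPM applies the documented pseudocount formula", {
  m <- matrix(c(0, 10, 100, 5, 20, 75), 3, 2)
  colnames(m) <- c("a", "b")
  f <- setNames(c(1, 1), c("a", "b"))
  lc <- log_cpm(m, f)
  want <- log2((m[1, 1] + 0.25) / (110 + 0.5) * 1e6)
  expect_equal(lc[1, 1], want)
  expect_true(all(is.finite(lc)))
  # monotone in the count at fixed library size
  expect_true(all(diff(lc[, 1]) > 0))
  # doubling count and library barely moves values once counts dominate
  # the pseudocount: |delta| <~ (p/2)/(c ln 2) plus a library-size term
  m3 <- matrix(c(5, 10, 200, 1000, 8, 20, 300, 900), 4, 2,
               dimnames = list(NULL, c("a", "b")))
  lc3 <- log_cpm(m3, f)
  lc6 <- log_cpm(2 * m3, f)
  expect_lt(max(abs(lc6[m3 >= 200] - lc3[m3 >= 200])), 1e-3)
  expect_lt(max(abs(lc6[m3 >= 10] - lc3[m3 >= 10])), 0.02)
})

test_that("the rank AUC equals exhaustive pair counting", {
  expect_equal(auc_single_gene(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               1)
  expect_equal(auc_single_gene(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(auc_single_gene(c(2, 1, 3), c(TRUE, FALSE, FALSE)), 0.5)
  expect_true(is.na(auc_single_gene(1:3, rep(TRUE, 3))))
  for (s in 1:25) {
    set.seed(s)
    n <- sample(5:50, 1)
    x <- sample(0:5, n, replace = TRUE)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(lab) || !any(lab)) next
    pairs <- outer(x[lab], x[!lab], function(a, b)
      (a > b) + 0.5 * (a == b))
    expect_equal(auc_single_gene(x, lab), mean(pairs))
  }
})

test_that("the Gini coefficient matches closed forms and is exchangeable", {
  expect_equal(gini(c(1, 1, 1, 1)), 0)
  expect_equal(gini(c(1, 0, 0, 0)), 0.75)
  set.seed(4)
  v <- rgamma(9, 2)
  expect_equal(gini(v), gini(sample(v)))
  expect_true(gini(v) >= 0 && gini(v) <= 1 - 1 / 9)
  expect_true(is.na(gini(c(0, 0))))
})

test_that("cell-type enrichment requires all three criteria", {
  enr <- data.frame(gene = c("G0001", "G0002", "G0003"),
                    cell_type = "Cardiomyocyte", fold = c(8, 8, 2))
  sc <- small_sc(5, enriched_genes = enr)
  pb <- aggregate_pseudobulk(sc$counts, sc$cells, sc$donors)
  en <- celltype_enrichment(pb, sc$counts, sc$cells)
  cm <- en[en$cell_type == "Cardiomyocyte", ]
  expect_true(cm$enriched[cm$gene == "G0001"])
  expect_true(cm$enriched[cm$gene == "G0002"])
  # fold 2 fails criterion (1)
  expect_false(cm$enriched[cm$gene == "G0003"])
  # planted folds are recovered approximately in pseudobulk
  expect_gt(cm$fold_one_vs_rest[cm$gene == "G0001"], 4)
  # enrichment flags are invariant to uniform depth rescaling
  pb2 <- pb
  pb2$counts <- pb$counts * 3L
  pb2$profiles$lib_size <- colSums(pb2$counts)
  en2 <- celltype_enrichment(pb2, sc$counts * 3L, sc$cells)
  expect_identical(en$enriched, en2$enriched)
})

test_that("low-fraction genes are not called enriched", {
  # fold 8 but expressed in few nuclei: high dropout via tiny base mean
  sc <- small_sc(6)
  pb <- aggregate_pseudobulk(sc$counts, sc$cells, sc$donors)
  en <- celltype_enrichment(pb, sc$counts, sc$cells,
                            fraction_threshold = 0.25)
  frac_fail <- en$fraction_nuclei < 0.25
  expect_false(any(en$enriched[frac_fail]))
})

test_that("fold-1 genes pass no enrichment filter in expectation", {
  sc <- small_sc(7)     # no planted genes at all
  pb <- aggregate_pseudobulk(sc$counts, sc$cells, sc$donors)
  en <- celltype_enrichment(pb, sc$counts, sc$cells)
  expect_equal(sum(en$enriched), 0)
})

test_that("differential expression recovers planted fold changes", {
  de <- data.frame(gene = c("G0005", "G0006"),
                   cell_type = "Cardiomyocyte", condition = "DCM",
                   fold = c(2, 1.4))
  sc <- simulate_singlecell_counts(
    n_genes = 80, cell_types = c("Cardiomyocyte", "Fibroblast"),
    donors = default_donors(), cells_per_donor_type = 25,
    de_genes = de, seed = 8)
  pb <- aggregate_pseudobulk(sc$counts, sc$cells, sc$donors)
  res <- de_disease_vs_control(pb, "DCM")
  cm <- res[res$cell_type == "Cardiomyocyte", ]
  expect_true(cm$pass[cm$gene == "G0005"])
  expect_gt(cm$log2fc[cm$gene == "G0005"], log2(1.5))
  # fold 1.4 misses the 50% rule regardless of p
  expect_false(cm$pass[cm$gene == "G0006"])
  # no effect in the other cell type
  fb <- res[res$cell_type == "Fibroblast", ]
  expect_false(any(fb$pass[fb$gene %in% de$gene]))
  # expected log2FC of a declared 1.5-fold contrast
  expect_equal(log2(1.5), 0.585, tolerance = 1e-3)
})

test_that("arms below the donor minimum are marked not testable", {
  sc <- simulate_singlecell_counts(
    n_genes = 30, cell_types = "Cardiomyocyte",
    donors = default_donors(4, 2, 0), cells_per_donor_type = 10,
    seed = 9)
  pb <- aggregate_pseudobulk(sc$counts, sc$cells, sc$donors)
  res <- de_disease_vs_control(pb, "DCM")
  expect_true(all(!res$testable))
})

test_that("condition/sex confounding raises a named error", {
  donors <- data.frame(donor_id = sprintf("d%02d", 1:8),
                       condition = rep(c("NF", "DCM"), each = 4),
                       age = 50, sex = rep(c("F", "M"), each = 4))
  sc <- simulate_singlecell_counts(n_genes = 30,
                                   cell_types = "Cardiomyocyte",
                                   donors = donors,
                                   cells_per_donor_type = 10, seed = 10)
  pb <- aggregate_pseudobulk(sc$counts, sc$cells, sc$donors)
  expect_error(de_disease_vs_control(pb, "DCM"), "collinear with sex")
})

test_that("single-cell data round-trip through Matrix Market files", {
  sc <- small_sc(11)
  pre <- file.path(withr::local_tempdir(), "sc")
  write_singlecell(sc, pre)
  back <- read_singlecell(pre)
  expect_equal(as.matrix(back$counts), as.matrix(sc$counts),
               ignore_attr = TRUE)
  expect_equal(back$cells, sc$cells)
  expect_equal(back$donors, sc$donors)
})
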