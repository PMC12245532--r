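test_that("truth spec validates its internal references", {
  tr <- tiny_truth(seed = 5)
  expect_s3_class(tr, "truth_spec")
  expect_true(all(tr$cis_effects$protein_id %in% tr$proteins$protein_id))
  # cis causal variants fall inside the +/- 1 Mb gene window
  ci <- merge(tr$cis_effects, tr$variants, by = "variant_id")
  ci <- merge(ci, tr$proteins, by = "protein_id",
              suffixes = c("", ".g"))
  expect_true(all(ci$chrom == ci$chrom.g))
  expect_true(all(ci$pos >= ci$start - 1e6 & ci$pos <= ci$stop + 1e6))
})

test_that("marginal-effect expectation equals R times the joint effects", {
  # matrix-product oracle: a causal variant's r = 0.8 neighbor shows an
  # expected marginal effect of 0.8 x beta at near-infinite sample size
  anc <- data.frame(ancestry = "EUR", n_exposure = 1e10, n_outcome = 1e10,
                    ld_seed = 11L, ld_decay = 0.8)
  tr <- tiny_truth(ancestries = anc, seed = 2)
  ld <- truth_ld_blocks(tr, "EUR", jitter = 0)
  p1 <- tr$proteins$protein_id[1]
  ss <- simulate_marginal_stats(tr, p1, ld, seed = 9)
  bj <- protmr:::joint_effects(tr, p1)
  for (b in ld) {
    mu <- drop(b$R %*% bj[b$variant_ids])
    got <- ss$beta[match(b$variant_ids, ss$variant_id)]
    expect_equal(got, mu, tolerance = 1e-3, ignore_attr = TRUE)
  }
  causal <- tr$cis_effects[tr$cis_effects$protein_id == p1, ]
  v <- causal$variant_id[1]
  blk <- ld[[tr$variants$block_id[match(v, tr$variants$variant_id)]]]
  i <- match(v, blk$variant_ids)
  nb <- blk$variant_ids[i + 1]
  expect_equal(blk$R[i, i + 1], 0.8, tolerance = 1e-12)
  other <- setdiff(causal$variant_id, v)
  leak <- sum(blk$R[match(other, blk$variant_ids), i + 1] *
                bj[other], na.rm = TRUE)
  expect_equal(ss$beta[match(nb, ss$variant_id)],
               0.8 * bj[v] + leak, tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("single causal variant with identity LD leaks nowhere", {
  anc <- data.frame(ancestry = "EUR", n_exposure = 1e10, n_outcome = 1e10,
                    ld_seed = 3L, ld_decay = 0)
  tr <- tiny_truth(ancestries = anc, n_causal_cis = 1, seed = 4)
  ld <- truth_ld_blocks(tr, "EUR", jitter = 0)
  p1 <- tr$proteins$protein_id[1]
  ss <- simulate_marginal_stats(tr, p1, ld, seed = 1)
  bj <- protmr:::joint_effects(tr, p1)
  nonzero <- names(bj)[bj != 0]
  got <- ss$beta[match(names(bj), ss$variant_id)]
  expect_true(all(abs(got[bj == 0]) < 1e-3))
  expect_equal(got[bj != 0], unname(bj[nonzero]), tolerance = 1e-3)
})

test_that("sampling is reproducible and seed-sensitive", {
  tr <- tiny_truth(seed = 8)
  ld <- cache_ld_chol(truth_ld_blocks(tr, "EUR"))
  a <- simulate_marginal_stats(tr, "P001", ld, seed = 21)
  b <- simulate_marginal_stats(tr, "P001", ld, seed = 21)
  expect_identical(a, b)
  d <- simulate_marginal_stats(tr, "P001", ld, seed = 22)
  expect_false(identical(a$beta, d$beta))
})

test_that("unknown traits and uncovered causal variants are errors", {
  tr <- tiny_truth(seed = 8)
  ld <- truth_ld_blocks(tr, "EUR")
  expect_error(simulate_marginal_stats(tr, "NOPE", ld, seed = 1),
               "not declared")
  expect_error(simulate_marginal_stats(tr, "P001", ld[-1], seed = 1),
               "not covered")
})

test_that("allele-flip fraction preserves the underlying association", {
  tr <- tiny_truth(seed = 8)
  ld <- cache_ld_chol(truth_ld_blocks(tr, "EUR"))
  plain <- simulate_marginal_stats(tr, "P001", ld, seed = 5)
  flip <- simulate_marginal_stats(tr, "P001", ld, seed = 5,
                                  flip_fraction = 0.5)
  flipped <- flip$beta != plain$beta
  expect_gt(sum(flipped), 0)
  expect_equal(flip$beta[flipped], -plain$beta[flipped])
  expect_equal(flip$eaf[flipped], 1 - plain$eaf[flipped])
  expect_equal(flip$effect_allele[flipped], plain$other_allele[flipped])
})

test_that("overlapping-sample simulation injects error correlation", {
  # all true effects zero, so the beta vectors are pure sampling noise
  tr <- tiny_truth(seed = 8, n_causal_forward = 0, n_biomarkers = 0,
                   cis_beta_range = c(0, 0), disease_beta = 0,
                   trans_beta = 0)
  ld <- cache_ld_chol(truth_ld_blocks(tr, "EUR"))
  cors <- vapply(1:40, function(s) {
    ov <- simulate_overlapping_stats(tr, "P001", "D01", ld,
                                     n_exposure = 5000, n_outcome = 5000,
                                     overlap_r = 0.8, seed = s)
    cor(ov$exposure$beta, ov$outcome$beta)
  }, numeric(1))
  expect_gt(mean(cors), 0.5)
  ind <- vapply(1:40, function(s) {
    ov <- simulate_overlapping_stats(tr, "P001", "D01", ld,
                                     n_exposure = 5000, n_outcome = 5000,
                                     overlap_r = 0, seed = s + 100)
    cor(ov$exposure$beta, ov$outcome$beta)
  }, numeric(1))
  expect_lt(abs(mean(ind)), 0.15)
})

test_that("truth specs round-trip through YAML", {
  tr <- tiny_truth(seed = 12, n_pleiotropy = 1)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_truth_yaml(tr, path)
  back <- read_truth_yaml(path)
  for (f in c("proteins", "diseases", "forward_effects",
              "reverse_effects", "cis_effects", "disease_effects",
              "pleiotropy", "variants", "blocks")) {
    expect_equal(back[[f]], tr[[f]], tolerance = 1e-12)
  }
  expect_equal(back$replication_n, tr$replication_n)
})

test_that("ancestries carry distinct LD and sample sizes", {
  tr <- tiny_truth(seed = 14)
  eur <- truth_ld_blocks(tr, "EUR")
  eas <- truth_ld_blocks(tr, "EAS")
  expect_identical(names(eur), names(eas))
  expect_false(isTRUE(all.equal(eur[[1]]$R, eas[[1]]$R)))
  ss <- simulate_marginal_stats(tr, "P001", cache_ld_chol(eas), seed = 3,
                                ancestry = "EAS")
  expect_equal(unique(ss$n),
               tr$ancestries$n_exposure[tr$ancestries$ancestry == "EAS"])
  expect_identical(attr(ss, "ancestry"), "EAS")
  expect_error(truth_ld_blocks(tr, "AFR"), "unknown ancestry")
})
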