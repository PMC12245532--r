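# independent greedy-clumping oracle: plain double loop over p-sorted rows
oracle_clump <- function(ss, R, r2, window_bp) {
  ord <- order(ss$pvalue, ss$variant_id)
  kept <- character()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      j <- match(k, ss$variant_id)
      if (ss$chrom[i] != ss$chrom[j]) next
      if (abs(ss$pos[i] - ss$pos[j]) > window_bp) next
      if (R[ss$variant_id[i], k]^2 >= r2) ok <- FALSE
    }
    if (ok) kept <- c(kept, ss$variant_id[i])
  }
  kept
}

as_block <- function(R) {
  structure(list(variant_ids = rownames(R), R = R), class = "ld_block")
}

test_that("clumping reproduces the worked three-variant example", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- sqrt(0.5)
  R[1, 3] <- R[3, 1] <- sqrt(0.05)
  R[2, 3] <- R[3, 2] <- sqrt(0.05)
  dimnames(R) <- list(paste0("v", 1:3), paste0("v", 1:3))
  ss <- make_sumstats(paste0("v", 1:3), beta = c(7, 6.5, 6), se = 1)
  ss$pvalue <- c(1e-10, 1e-9, 1e-8)
  out <- clump(ss, list(as_block(R)))
  expect_identical(out, c("v1", "v3"))
})

test_that("mutually independent significant variants are all kept", {
  ss <- make_sumstats(paste0("v", 1:4), beta = 7:10, se = 1)
  blocks <- simulate_ld_blocks(1, 4, decay = 0, seed = 1,
                               variant_ids = list(paste0("v", 1:4)))
  expect_setequal(clump(ss, blocks), paste0("v", 1:4))
  weak <- make_sumstats(paste0("v", 1:4), beta = rep(1, 4), se = 1)
  expect_identical(clump(weak, blocks), character())
})

test_that("clumping matches the exhaustive greedy oracle on toy sets", {
  for (s in 1:20) {
    set.seed(s)
    m <- sample(4:10, 1)
    blk <- simulate_ld_blocks(1, m, decay = runif(1, 0.2, 0.9),
                              seed = s, jitter = 0.1,
                              variant_ids = list(paste0("v", 1:m)))[[1]]
    ss <- make_sumstats(paste0("v", 1:m), beta = runif(m, 5.6, 9),
                        se = 1, pos = sort(sample(1:5e5, m)))
    got <- clump(ss, list(blk), r2_threshold = 0.3)
    want <- oracle_clump(ss, blk$R, 0.3, 5e5)
    expect_setequal(got, want)
    # invariant: no retained pair within the window at r2 >= threshold
    for (a in got) for (b in got) {
      if (a == b) next
      if (abs(ss$pos[match(a, ss$variant_id)] -
                ss$pos[match(b, ss$variant_id)]) > 5e5) next
      expect_lt(blk$R[a, b]^2, 0.3)
    }
  }
})

test_that("significant variants missing from the LD panel are dropped", {
  ss <- make_sumstats(c("v1", "vX"), beta = c(8, 9), se = 1)
  blocks <- simulate_ld_blocks(1, 1, decay = 0, seed = 1,
                               variant_ids = list("v1"))
  expect_warning(out <- clump(ss, blocks), "absent from the LD panel")
  expect_identical(out, "v1")
  expect_error(clump(ss, blocks, missing_ld = "fail"), "missing from LD")
})

test_that("cis/trans classification uses the 1 Mb flank exactly", {
  gene <- data.frame(chrom = "1", start = 1e6, stop = 1.01e6)
  expect_identical(classify_cis_trans("1", 1.5e6, gene), "cis")
  expect_identical(classify_cis_trans("1", 2.01e6, gene), "cis")   # edge
  expect_identical(classify_cis_trans("1", 2.010001e6, gene), "trans")
  expect_identical(classify_cis_trans("2", 1.5e6, gene), "trans")
  expect_identical(classify_cis_trans("1", 0, gene), "cis")
})

test_that("proxy search respects thresholds and tie-breaks", {
  # one-factor structure (PSD by construction): r13 = r14 = 0.9 exactly
  l <- c(1, 0.6, 0.9, 0.9)
  R <- outer(l, l)
  diag(R) <- 1
  dimnames(R) <- list(paste0("v", 1:4), paste0("v", 1:4))
  ex <- make_sumstats(paste0("v", 1:4), beta = c(8, 7, 6.5, 7.5), se = 1,
                      pos = c(1e5, 2e5, 3e5, 4e5))
  oy <- make_sumstats(paste0("v", 2:4), beta = c(1, 1, 1), se = 1,
                      pos = c(2e5, 3e5, 4e5))
  pr <- find_proxy("v1", oy, ex, list(as_block(R)))
  # v3/v4 share (near) the top r2; v4 has the smaller exposure p
  expect_identical(pr$variant_id, "v4")
  # below the r2 cutoff: nothing
  expect_null(find_proxy("v1", oy, ex, list(as_block(R)), r2_min = 0.95))
  # insufficient exposure significance: nothing
  weak <- ex; weak$pvalue <- rep(1e-4, 4)
  expect_null(find_proxy("v1", oy, weak, list(as_block(R))))
})

test_that("cis-only instruments are a subset of cis-plus-trans", {
  tr <- tiny_truth(seed = 31)
  ld <- cache_ld_chol(truth_ld_blocks(tr, "EUR"))
  genes <- genes_of(tr)
  ex <- simulate_marginal_stats(tr, "P001", ld, seed = 1)
  oy <- simulate_marginal_stats(tr, "D01", ld, seed = 2)
  g <- genes[genes$protein_id == "P001", ]
  cis <- build_instrument_set(ex, oy, g, "cis_only", ld)
  both <- build_instrument_set(ex, oy, g, "cis_plus_trans", ld)
  expect_true(all(cis$members$variant_id %in% both$members$variant_id))
  expect_true(all(cis$members$cis_trans == "cis"))
})

test_that("proxies carry the index exposure effect and LD sign", {
  blk <- simulate_ld_blocks(1, 3, decay = 0.9, seed = 2,
                            variant_ids = list(paste0("v", 1:3)))
  ex <- make_sumstats(paste0("v", 1:3), beta = c(0.4, 0.38, 0.1),
                      se = 0.02, pos = c(1e5, 1.1e5, 1.2e5))
  # index v1 absent from the outcome; proxy v2 available
  oy <- make_sumstats(c("v2", "v3"), beta = c(0.12, 0.01), se = 0.05,
                      pos = c(1.1e5, 1.2e5))
  iv <- build_instrument_set(ex, oy, gene = NULL, mode = "cis_plus_trans",
                             ld = blk)
  pm <- iv$members[iv$members$role == "proxy", ]
  expect_equal(pm$proxy_of, "v1")
  expect_equal(pm$variant_id, "v2")
  pp <- iv$pairs[iv$pairs$variant_id == "v2", ]
  expect_equal(pp$beta_exposure, 0.4)        # mapped back to the index
  expect_equal(pp$beta_outcome, 0.12)        # positive LD sign
})

test_that("untestable exposures yield empty, flagged sets", {
  blk <- simulate_ld_blocks(1, 2, decay = 0, seed = 2,
                            variant_ids = list(c("v1", "v2")))
  ex <- make_sumstats(c("v1", "v2"), beta = c(0.01, 0.02), se = 0.02)
  oy <- make_sumstats(c("v1", "v2"), beta = c(0, 0), se = 0.05)
  iv <- build_instrument_set(ex, oy, gene = NULL, ld = blk)
  expect_false(iv$testable)
  expect_equal(nrow(iv$members), 0)
})
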