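# Instrument construction: LD clumping, cis/trans classification, proxy
# substitution, and assembly of harmonized instrument sets.

default_iv_params <- function(params = list()) {
  def <- list(p_threshold = 5e-8, r2_clump = 0.1, window_kb = 500,
              r2_proxy = 0.7, palindromic_maf = 0.42)
  def[names(params)] <- params
  def
}

#' Greedy LD clumping
#'
#' Selects independent lead variants: genome-wide-significant variants are
#' sorted by ascending p-value and accepted greedily whenever their squared
#' correlation with every already-accepted variant within `window_kb` is
#' below `r2_threshold`.  Variants on different chromosomes, in different
#' LD blocks, or farther apart than the window are treated as independent.
#'
#' @param sumstats a `sumstats` object.
#' @param ld list of `ld_block` objects covering the significant variants.
#' @param p_threshold significance threshold (default 5e-8).
#' @param r2_threshold clumping r-squared threshold (default 0.1).
#' @param window_kb window around lead variants in kilobases (default 500).
#' @param missing_ld `"drop"` (default, with a warning) or `"fail"` for
#'   significant variants absent from the LD panel.
#' @param idx optional precomputed LD index (internal use, avoids
#'   rebuilding the variant lookup on repeated calls).
#' @return character vector of retained lead variant ids, ordered by p.
#' @export
clump <- function(sumstats, ld, p_threshold = 5e-8, r2_threshold = 0.1,
                  window_kb = 500, missing_ld = c("drop", "fail"),
                  idx = NULL) {
  missing_ld <- match.arg(missing_ld)
  sig <- sumstats[sumstats$pvalue < p_threshold, , drop = FALSE]
  if (!nrow(sig)) return(character())
  if (is.null(idx)) idx <- ld_index(ld)
  absent <- setdiff(sig$variant_id, idx$variant_id)
  if (length(absent)) {
    if (missing_ld == "fail") {
      stop2("significant variants missing from LD panel: ",
            paste(head(absent, 5), collapse = ", "))
    }
    warning("clump: dropping ", length(absent),
            " significant variant(s) absent from the LD panel",
            call. = FALSE)
    sig <- sig[!sig$variant_id %in% absent, , drop = FALSE]
  }
  sig <- sig[order(sig$pvalue, sig$variant_id), , drop = FALSE]
  accepted <- integer()
  for (i in seq_len(nrow(sig))) {
    ok <- TRUE
    for (a in accepted) {
      if (sig$chrom[i] != sig$chrom[a]) next
      if (abs(sig$pos[i] - sig$pos[a]) > window_kb * 1000) next
      r <- ld_r(ld, idx, sig$variant_id[i], sig$variant_id[a])
      if (!is.na(r) && r^2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  sig$variant_id[accepted]
}

#' Classify variants as cis or trans pQTLs
#'
#' A variant is cis to a protein-coding gene if it lies on the same
#' chromosome within `window` bp (default 1 Mb) on either side of the
#' gene's start and stop codons; otherwise trans.
#'
#' @param chrom,pos variant coordinates (vectorized).
#' @param gene one-row data.frame with `chrom`, `start`, `stop`
#'   (1-based inclusive).
#' @param window flank size in bp.
#' @return character vector of `"cis"` / `"trans"`.
#' @export
classify_cis_trans <- function(chrom, pos, gene, window = 1e6) {
  stopifnot(nrow(gene) == 1)
  ifelse(as.character(chrom) == as.character(gene$chrom) &
           pos >= gene$start - window & pos <= gene$stop + window,
         "cis", "trans")
}

#' Find the best proxy for an index variant missing from the outcome study
#'
#' Candidates must be present in both studies, significant for the exposure
#' at `p_threshold`, within `window_kb` of the index, and in LD
#' r-squared > `r2_min` with it.  The candidate with the highest r-squared
#' wins; ties break to the smaller exposure p-value, then the
#' lexicographically smaller id.
#'
#' @param index_variant variant id absent from the outcome set.
#' @param outcome,exposure `sumstats` objects.
#' @param ld list of `ld_block` objects.
#' @param r2_min minimum r-squared with the index (default 0.7).
#' @param window_kb search window in kb (default 500).
#' @param p_threshold exposure significance threshold (default 5e-8).
#' @return list with `variant_id` and `r` (signed LD correlation), or
#'   `NULL` when no candidate qualifies.
#' @export
find_proxy <- function(index_variant, outcome, exposure, ld,
                       r2_min = 0.7, window_kb = 500, p_threshold = 5e-8) {
  idx <- ld_index(ld)
  i <- match(index_variant, idx$variant_id)
  ei <- match(index_variant, exposure$variant_id)
  if (is.na(i) || is.na(ei)) return(NULL)
  block <- ld[[idx$block[i]]]
  cand <- setdiff(block$variant_ids, index_variant)
  cand <- cand[cand %in% outcome$variant_id & cand %in% exposure$variant_id]
  if (!length(cand)) return(NULL)
  ec <- match(cand, exposure$variant_id)
  within <- abs(exposure$pos[ec] - exposure$pos[ei]) <= window_kb * 1000
  signif <- exposure$pvalue[ec] < p_threshold
  r <- block$R[match(cand, block$variant_ids),
               match(index_variant, block$variant_ids)]
  ok <- within & signif & r^2 > r2_min
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; r <- r[ok]; pv <- exposure$pvalue[ec][ok]
  ord <- order(-r^2, pv, cand)
  list(variant_id = cand[ord[1]], r = r[ord[1]])
}

#' Build a harmonized instrument set for one exposure/outcome pair
#'
#' Pipeline: clump the exposure -> classify cis/trans against the encoding
#' gene -> (cis_only: keep cis) -> substitute proxies for index variants
#' absent from the outcome -> harmonize alleles.  Proxies carry the index
#' variant's exposure effect; their outcome effect is sign-aligned by the
#' sign of the index-proxy LD correlation.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param gene one-row gene annotation for the exposure protein, or `NULL`
#'   (e.g. disease exposures in reverse MR; members are then unclassified).
#' @param mode `"cis_only"` or `"cis_plus_trans"`.
#' @param ld list of `ld_block` objects (the exposure ancestry's panel).
#' @param params named list overriding `p_threshold`, `r2_clump`,
#'   `window_kb`, `r2_proxy`, `palindromic_maf`.
#' @param leads optional precomputed clumped lead-variant ids for this
#'   exposure (skips re-clumping when looping over outcomes).
#' @return an `instrument_set`: list with `exposure_id`, `outcome_id`,
#'   `members` (variant_id, role, proxy_of, cis_trans), `pairs` (harmonized
#'   effect pairs, one per member), `selection_params`, and `testable`
#'   (FALSE when no instrument survives).
#' @export
build_instrument_set <- function(exposure, outcome, gene = NULL,
                                 mode = c("cis_plus_trans", "cis_only"),
                                 ld, params = list(), leads = NULL) {
  mode <- match.arg(mode)
  p <- default_iv_params(params)
  if (is.null(leads)) {
    leads <- clump(exposure, ld, p_threshold = p$p_threshold,
                   r2_threshold = p$r2_clump, window_kb = p$window_kb)
  }
  empty <- function() {
    structure(list(
      exposure_id = attr(exposure, "trait_id"),
      outcome_id = attr(outcome, "trait_id"),
      members = data.frame(variant_id = character(), role = character(),
                           proxy_of = character(), cis_trans = character(),
                           stringsAsFactors = FALSE),
      pairs = data.frame(), selection_params = p, testable = FALSE
    ), class = "instrument_set")
  }
  if (!length(leads)) return(empty())

  epos <- match(leads, exposure$variant_id)
  ct <- if (is.null(gene)) rep(NA_character_, length(leads)) else {
    classify_cis_trans(exposure$chrom[epos], exposure$pos[epos], gene)
  }
  if (mode == "cis_only" && !is.null(gene)) {
    keep <- ct == "cis"
    leads <- leads[keep]; ct <- ct[keep]
  }
  if (!length(leads)) return(empty())

  members <- data.frame(variant_id = leads, role = "index",
                        proxy_of = NA_character_, cis_trans = ct,
                        ld_sign = 1, stringsAsFactors = FALSE)
  need_proxy <- !members$variant_id %in% outcome$variant_id
  for (k in which(need_proxy)) {
    pr <- find_proxy(members$variant_id[k], outcome, exposure, ld,
                     r2_min = p$r2_proxy, window_kb = p$window_kb,
                     p_threshold = p$p_threshold)
    if (is.null(pr)) {
      members$role[k] <- "drop"
    } else {
      members$proxy_of[k] <- members$variant_id[k]
      members$variant_id[k] <- pr$variant_id
      members$role[k] <- "proxy"
      members$ld_sign[k] <- sign(pr$r)
    }
  }
  members <- members[members$role != "drop", , drop = FALSE]
  if (!nrow(members)) return(empty())

  pairs <- harmonize(exposure, outcome, members$variant_id,
                     palindromic_maf = p$palindromic_maf)
  m <- match(pairs$variant_id, members$variant_id)
  pairs$role <- members$role[m]
  pairs$proxy_of <- members$proxy_of[m]
  pairs$cis_trans <- members$cis_trans[m]
  # proxies: map back the index variant's exposure effect, sign-align the
  # outcome effect by the LD correlation's sign
  is_proxy <- pairs$role == "proxy"
  if (any(is_proxy)) {
    ix <- match(pairs$proxy_of[is_proxy], exposure$variant_id)
    pairs$beta_exposure[is_proxy] <- exposure$beta[ix]
    pairs$se_exposure[is_proxy] <- exposure$se[ix]
    pairs$eaf_exposure[is_proxy] <- exposure$eaf[ix]
    pairs$beta_outcome[is_proxy] <- pairs$beta_outcome[is_proxy] *
      members$ld_sign[m][is_proxy]
  }
  members <- members[members$variant_id %in% pairs$variant_id, , drop = FALSE]
  structure(list(
    exposure_id = attr(exposure, "trait_id"),
    outcome_id = attr(outcome, "trait_id"),
    members = members, pairs = pairs, selection_params = p,
    testable = nrow(pairs) > 0
  ), class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", x$exposure_id, "->", x$outcome_id, "\n")
  cat(" ", nrow(x$members), "member(s):",
      sum(x$members$cis_trans == "cis", na.rm = TRUE), "cis,",
      sum(x$members$cis_trans == "trans", na.rm = TRUE), "trans,",
      sum(x$members$role == "proxy"), "proxy;",
      if (x$testable) "testable" else "NOT testable", "\n")
  invisible(x)
}
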