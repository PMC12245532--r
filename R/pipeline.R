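# Orchestration: per-direction MR across exposure/outcome panels,
# multiplicity control, replication, target/biomarker overlap, and the
# phenome-wide scan.

#' Run MR for every exposure x outcome pair in one direction
#'
#' For each pair: instrument construction ([build_instrument_set()]) ->
#' estimators ([mr_fit()]) -> optional RSS-outlier sensitivity.  Pairs with
#' zero surviving instruments are recorded as not testable and excluded
#' from multiplicity denominators.
#'
#' @param exposures,outcomes named lists of `sumstats` objects.
#' @param ld LD blocks for the exposure panel's ancestry.
#' @param genes gene annotation data.frame (see
#'   [read_gene_annotations()]); looked up by the exposure's trait id for
#'   forward (protein-exposure) runs, ignored when no row matches.
#' @param direction `"forward"` (protein -> disease) or `"reverse"`.
#' @param iv_mode `"cis_plus_trans"` or `"cis_only"` (forward only).
#' @param ancestry label recorded on the records.
#' @param methods estimator subset passed to [mr_fit()].
#' @param params instrument-selection overrides, see
#'   [build_instrument_set()].
#' @param seed integer seed (bootstrap estimators, sensitivity).
#' @param sensitivity run [presso()] per significant-sized set (>= 4 IVs)
#'   and record its outlier count and global p.
#' @param n_boot bootstrap replicates for median/mode estimators.
#' @return data.frame of association records (class
#'   `association_records`), one row per tested pair, with per-method
#'   `beta_*`, `se_*`, `p_*` columns and `p_primary` (IVW).
#' @export
run_direction <- function(exposures, outcomes, ld, genes = NULL,
                          direction = c("forward", "reverse"),
                          iv_mode = c("cis_plus_trans", "cis_only"),
                          ancestry = "EUR", methods = "ivw",
                          params = list(), seed = 1, sensitivity = FALSE,
                          n_boot = 1000) {
  direction <- match.arg(direction)
  iv_mode <- match.arg(iv_mode)
  rows <- list()
  idx <- ld_index(ld)
  p <- default_iv_params(params)
  for (ex in exposures) {
    eid <- attr(ex, "trait_id")
    gene <- NULL
    if (!is.null(genes)) {
      gm <- genes[genes$protein_id == eid, , drop = FALSE]
      if (nrow(gm) == 1) gene <- gm
    }
    leads <- clump(ex, ld, p_threshold = p$p_threshold,
                   r2_threshold = p$r2_clump, window_kb = p$window_kb,
                   idx = idx)
    for (oy in outcomes) {
      oid <- attr(oy, "trait_id")
      iv <- build_instrument_set(ex, oy, gene = gene, mode = iv_mode,
                                 ld = ld, params = params, leads = leads)
      rec <- data.frame(
        exposure_id = eid, outcome_id = oid, direction = direction,
        ancestry = ancestry, iv_mode = iv_mode,
        n_iv = nrow(iv$members), testable = iv$testable,
        stringsAsFactors = FALSE
      )
      if (iv$testable) {
        fit <- mr_fit(iv, methods = methods,
                      seed = child_seed(seed, paste(eid, oid)),
                      n_boot = n_boot)
        for (m in names(fit$estimates)) {
          e <- fit$estimates[[m]]
          rec[[paste0("beta_", m)]] <- e$beta
          rec[[paste0("se_", m)]] <- e$se
          rec[[paste0("p_", m)]] <- e$pvalue
          if (m == "egger") {
            rec$egger_intercept <- e$intercept
            rec$egger_intercept_p <- e$intercept_p
          }
        }
        rec$p_primary <- fit$estimates$ivw$pvalue %||% NA_real_
        rec$beta_primary <- fit$estimates$ivw$beta %||% NA_real_
        if (sensitivity && nrow(iv$pairs) >= 4) {
          pr <- presso(iv$pairs, n_sim = 200,
                       seed = child_seed(seed, paste("pr", eid, oid)))
          rec$presso_global_p <- pr$global_p
          rec$presso_n_outliers <- length(pr$outliers_removed)
          rec$beta_presso_corrected <- pr$corrected_estimate$beta
        }
      } else {
        rec$p_primary <- NA_real_
        rec$beta_primary <- NA_real_
      }
      rows[[length(rows) + 1]] <- rec
    }
  }
  out <- rbind_fill(rows)
  class(out) <- c("association_records", "data.frame")
  out
}

# rbind data.frames with unequal column sets, filling with NA
rbind_fill <- function(lst) {
  allcols <- unique(unlist(lapply(lst, names)))
  lst <- lapply(lst, function(d) {
    for (cn in setdiff(allcols, names(d))) d[[cn]] <- NA
    d[, allcols, drop = FALSE]
  })
  out <- do.call(rbind, lst)
  rownames(out) <- NULL
  out
}

#' Multiplicity control over association records
#'
#' Families are the testable records within each
#' `(direction, iv_mode, ancestry)` stratum; the family size `m` is
#' recorded per row.  Bonferroni flags `p_primary < alpha / m`;
#' Benjamini-Hochberg uses the standard step-up rule.
#'
#' @param records an `association_records` data.frame.
#' @param alpha family-wise / FDR level (default 0.05).
#' @return the records with `m_family`, `significant_bonferroni` and
#'   `significant_fdr` columns.
#' @export
adjust_multiplicity <- function(records, alpha = 0.05) {
  if (!nrow(records)) return(records)
  key <- interaction(records$direction, records$iv_mode, records$ancestry,
                     drop = TRUE)
  records$m_family <- NA_integer_
  records$significant_bonferroni <- FALSE
  records$significant_fdr <- FALSE
  for (g in levels(key)) {
    sel <- which(key == g & records$testable & !is.na(records$p_primary))
    m <- length(sel)
    if (!m) next
    records$m_family[key == g] <- m
    p <- records$p_primary[sel]
    records$significant_bonferroni[sel] <- p < alpha / m
    records$significant_fdr[sel] <- p.adjust(p, "BH") < alpha
  }
  records
}

#' Replicate discovery hits in a second pQTL panel
#'
#' Re-runs the same MR for each discovery-significant record using
#' instruments rebuilt from the replication exposure panel.  Flags:
#' nominal `p < 0.05`, Benjamini-Hochberg and Bonferroni over the
#' replication family, and sign consistency of the primary-method
#' estimate.  Exposures missing from the replication panel get NA flags
#' (not assessable).
#'
#' @param discovery records from [run_direction()] +
#'   [adjust_multiplicity()]; only rows with `significant_bonferroni`
#'   (or `significant` per `select`) are replicated.
#' @param replication_exposures named list of `sumstats` from the
#'   replication panel.
#' @param outcomes named list of outcome `sumstats`.
#' @param ld LD blocks for the replication panel.
#' @param genes gene annotations.
#' @param select flag column defining the discovery-significant family.
#' @param alpha significance level (default 0.05).
#' @inheritParams run_direction
#' @return the selected records with `beta_replication`, `p_replication`,
#'   `replicated_p05`, `replicated_fdr`, `replicated_bonferroni`,
#'   `direction_consistent`.
#' @export
replicate_mr <- function(discovery, replication_exposures, outcomes, ld,
                         genes = NULL, select = "significant_bonferroni",
                         alpha = 0.05, methods = "ivw", params = list(),
                         seed = 1) {
  hits <- discovery[isTRUE_vec(discovery[[select]]), , drop = FALSE]
  if (!nrow(hits)) return(hits)
  hits$beta_replication <- NA_real_
  hits$p_replication <- NA_real_
  rep_ids <- vapply(replication_exposures, attr, "", "trait_id")
  for (i in seq_len(nrow(hits))) {
    eid <- hits$exposure_id[i]
    j <- match(eid, rep_ids)
    if (is.na(j)) next
    ex <- replication_exposures[[j]]
    oy <- outcomes[[match(hits$outcome_id[i],
                          vapply(outcomes, attr, "", "trait_id"))]]
    gene <- NULL
    if (!is.null(genes)) {
      gm <- genes[genes$protein_id == eid, , drop = FALSE]
      if (nrow(gm) == 1) gene <- gm
    }
    iv <- build_instrument_set(ex, oy, gene = gene,
                               mode = hits$iv_mode[i], ld = ld,
                               params = params)
    if (!iv$testable) next
    fit <- mr_fit(iv, methods = methods,
                  seed = child_seed(seed, paste("rep", eid)))
    hits$beta_replication[i] <- fit$estimates$ivw$beta
    hits$p_replication[i] <- fit$estimates$ivw$pvalue
  }
  assessed <- !is.na(hits$p_replication)
  hits$replicated_p05 <- ifelse(assessed, hits$p_replication < 0.05, NA)
  hits$replicated_fdr <- NA
  hits$replicated_bonferroni <- NA
  if (any(assessed)) {
    p <- hits$p_replication[assessed]
    hits$replicated_fdr[assessed] <- p.adjust(p, "BH") < alpha
    hits$replicated_bonferroni[assessed] <- p < alpha / length(p)
  }
  hits$direction_consistent <- ifelse(
    assessed, sign(hits$beta_replication) == sign(hits$beta_primary), NA)
  hits
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Proteins that are both targets and biomarkers
#'
#' Intersects proteins significant in the forward direction (targets) with
#' proteins significant as outcomes of the reverse direction (biomarkers).
#'
#' @param forward_records,reverse_records adjusted association records.
#' @param select flag column defining significance.
#' @return data.frame with `protein_id`, `forward_outcomes`,
#'   `reverse_exposures` (comma-separated).
#' @export
overlap_targets_biomarkers <- function(forward_records, reverse_records,
                                       select = "significant_bonferroni") {
  fw <- forward_records[isTRUE_vec(forward_records[[select]]), ,
                        drop = FALSE]
  rv <- reverse_records[isTRUE_vec(reverse_records[[select]]), ,
                        drop = FALSE]
  shared <- sort(intersect(fw$exposure_id, rv$outcome_id))
  data.frame(
    protein_id = shared,
    forward_outcomes = vapply(shared, function(p) {
      paste(sort(unique(fw$outcome_id[fw$exposure_id == p])),
            collapse = ",")
    }, ""),
    reverse_exposures = vapply(shared, function(p) {
      paste(sort(unique(rv$exposure_id[rv$outcome_id == p])),
            collapse = ",")
    }, ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Phenome-wide MR scan
#'
#' Runs MR for each significant protein against a phenotype panel
#' (disease phenotypes require >= `min_cases` cases; quantitative
#' biomarker and medication phenotypes are exempt) and assembles dense
#' z- and p-matrices with significance flags.
#'
#' @param proteins named list of protein `sumstats` (the significant set).
#' @param phenotypes named list of phenotype `sumstats`.
#' @param phenotype_meta data.frame with `phenotype_id`, `category`,
#'   `kind`, `n_cases`.
#' @param ld LD blocks for the exposure panel.
#' @param genes gene annotations.
#' @param min_cases case-count filter for disease phenotypes (default 50).
#' @param direction MR direction for the scan cells (default forward:
#'   protein exposure, phenotype outcome); run again with `"reverse"` for
#'   the bidirectional scan.
#' @param adjust `"bh"` or `"bonferroni"` across all testable cells.
#' @param alpha significance level.
#' @inheritParams run_direction
#' @return object of class `phewas_matrix`: list with matrices `z`, `p`,
#'   `sig` (protein x phenotype; NA = not testable), `meta` (the filtered
#'   panel), and `records`.
#' @export
phewas_scan <- function(proteins, phenotypes, phenotype_meta, ld,
                        genes = NULL, min_cases = 50,
                        direction = c("forward", "reverse"),
                        iv_mode = "cis_plus_trans", adjust = "bh",
                        alpha = 0.05, params = list(), seed = 1) {
  direction <- match.arg(direction)
  meta <- phenotype_meta
  is_disease <- meta$kind == "disease"
  keep <- !is_disease | (!is.na(meta$n_cases) & meta$n_cases >= min_cases)
  meta <- meta[keep, , drop = FALSE]
  pheno_ids <- vapply(phenotypes, attr, "", "trait_id")
  phenotypes <- phenotypes[pheno_ids %in% meta$phenotype_id]
  if (direction == "forward") {
    records <- run_direction(proteins, phenotypes, ld = ld, genes = genes,
                             direction = "forward", iv_mode = iv_mode,
                             methods = "ivw", params = params, seed = seed)
  } else {
    records <- run_direction(phenotypes, proteins, ld = ld, genes = NULL,
                             direction = "reverse", iv_mode = iv_mode,
                             methods = "ivw", params = params, seed = seed)
    # reorient so rows are proteins, columns phenotypes
    tmp <- records$exposure_id
    records$exposure_id <- records$outcome_id
    records$outcome_id <- tmp
  }
  prot_ids <- sort(unique(records$exposure_id))
  ph_ids <- meta$phenotype_id
  z <- p <- matrix(NA_real_, length(prot_ids), length(ph_ids),
                   dimnames = list(prot_ids, ph_ids))
  ok <- records$testable & !is.na(records$p_primary)
  idx <- cbind(match(records$exposure_id, prot_ids),
               match(records$outcome_id, ph_ids))
  z[idx[ok, , drop = FALSE]] <-
    (records$beta_ivw / records$se_ivw)[ok]
  p[idx[ok, , drop = FALSE]] <- records$p_primary[ok]
  sig <- matrix(NA, nrow(z), ncol(z), dimnames = dimnames(z))
  pv <- p[!is.na(p)]
  if (length(pv)) {
    flags <- if (adjust == "bh") p.adjust(pv, "BH") < alpha
             else pv < alpha / length(pv)
    sig[!is.na(p)] <- flags
  }
  structure(list(z = z, p = p, sig = sig, meta = meta, records = records),
            class = "phewas_matrix")
}

#' Classify phenome-scan specificity per protein
#'
#' @param phewas a `phewas_matrix`.
#' @param thresholds pleiotropy count thresholds (default 20, 15, 10, 5).
#' @return data.frame per protein: significant-disease and category
#'   counts, `specific_one_disease`, `specific_one_category`, and a
#'   logical `pleiotropic_at_<k>` column per threshold; proteins with no
#'   significant cell are labeled `unclassified`.
#' @export
classify_specificity <- function(phewas, thresholds = c(20, 15, 10, 5)) {
  sig <- phewas$sig
  cats <- phewas$meta$category[match(colnames(sig),
                                     phewas$meta$phenotype_id)]
  out <- data.frame(protein_id = rownames(sig),
                    n_significant = NA_integer_,
                    n_categories = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sig))) {
    s <- which(!is.na(sig[i, ]) & sig[i, ])
    out$n_significant[i] <- length(s)
    out$n_categories[i] <- length(unique(cats[s]))
  }
  out$class <- ifelse(out$n_significant == 0, "unclassified",
               ifelse(out$n_significant == 1, "specific_one_disease",
               ifelse(out$n_categories == 1, "specific_one_category",
                      "pleiotropic")))
  out$specific_one_disease <- out$n_significant == 1
  out$specific_one_category <- out$n_significant >= 1 &
    out$n_categories == 1
  for (k in sort(thresholds)) {
    out[[paste0("pleiotropic_at_", k)]] <- out$n_significant >= k
  }
  out
}
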