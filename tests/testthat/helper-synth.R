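# shared fixtures built in code

make_pairs <- function(bx, by, sx = 0.01, sy = 0.05,
                       ids = paste0("v", seq_along(bx))) {
  data.frame(variant_id = ids,
             beta_exposure = bx, se_exposure = rep_len(sx, length(bx)),
             beta_outcome = by, se_outcome = rep_len(sy, length(bx)),
             stringsAsFactors = FALSE)
}

make_sumstats <- function(ids, beta, se, chrom = "1",
                          pos = seq_along(ids) * 1e4,
                          ea = "A", oa = "C", eaf = 0.3,
                          n = 10000, trait_id = "T", kind = "protein") {
  as_sumstats(data.frame(
    variant_id = ids, chrom = chrom, pos = pos,
    effect_allele = rep_len(ea, length(ids)),
    other_allele = rep_len(oa, length(ids)),
    eaf = rep_len(eaf, length(ids)), beta = beta,
    se = rep_len(se, length(ids)),
    pvalue = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n,
    stringsAsFactors = FALSE
  ), trait_id = trait_id, trait_kind = kind, ancestry = "EUR")
}

tiny_truth <- function(...) {
  defaults <- list(n_proteins = 3, n_diseases = 2, n_causal_forward = 1,
                   n_biomarkers = 1, cis_block_size = 12, n_causal_cis = 4,
                   disease_block_size = 12, n_causal_disease = 4,
                   n_trans_hubs = 1, trans_block_size = 6)
  args <- utils::modifyList(defaults, list(...))
  do.call(synth_truth, args)
}

# one-region colocalization fixture: shared -> the disease signal runs
# through the protein's single causal cis variant; distinct -> the disease
# signal sits on a different (non-causal) cis-window variant
coloc_truth <- function(shared, seed, decay = 0.6) {
  anc <- data.frame(ancestry = "EUR", n_exposure = 34557,
                    n_outcome = 2e5, ld_seed = 7L, ld_decay = decay)
  synth_truth(n_proteins = 1, n_diseases = 1, n_causal_forward = 1,
              gamma = if (shared) 0.5 else 0,
              n_biomarkers = 0, cis_block_size = 30, n_causal_cis = 1,
              n_trans_hubs = 0, n_pleiotropy = if (shared) 0 else 1,
              pleiotropy_on = "noncausal_cis", pleiotropy_beta = 0.3,
              ancestries = anc, seed = seed)
}

coloc_region <- function(truth, seed, ld = NULL) {
  if (is.null(ld)) ld <- cache_ld_chol(truth_ld_blocks(truth, "EUR",
                                                       jitter = 0))
  region <- truth$variants$variant_id[truth$variants$block_id ==
                                        "P001_cis"]
  prot <- simulate_marginal_stats(truth, "P001", ld, seed = seed)
  dis <- simulate_marginal_stats(truth, "D01", ld, seed = seed + 1000)
  list(prot = prot[prot$variant_id %in% region, ],
       dis = dis[dis$variant_id %in% region, ])
}

genes_of <- function(truth) {
  data.frame(gene_id = truth$proteins$gene_id,
             protein_id = truth$proteins$protein_id,
             chrom = truth$proteins$chrom, start = truth$proteins$start,
             stop = truth$proteins$stop, stringsAsFactors = FALSE)
}
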