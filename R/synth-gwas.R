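# Ground-truth causal structures and summary-statistics sampling.
#
# The generator plants a per-protein cis architecture (causal variants within
# +/- 1 Mb of the encoding gene), shared trans hubs, per-disease liability
# loci (the reverse-MR instruments), protein -> disease effects gamma on the
# log-odds scale, disease -> protein effects delta, and optional variants
# with direct disease effects that bypass the protein (horizontal
# pleiotropy).  Summary statistics are sampled directly in marginal-effect
# space: within each LD block, beta_hat ~ MVN(R %*% beta_joint, R / n).

NON_PALINDROMIC <- list(c("A", "C"), c("A", "G"), c("C", "T"), c("G", "T"))

#' Construct a synthetic ground-truth causal structure
#'
#' Builds a `truth_spec`: proteins with gene intervals and cis/trans pQTL
#' architecture, diseases with categories and case counts, protein->disease
#' causal effects (`gamma`, log-odds per SD of protein), disease->protein
#' effects (`delta`), optional direct-pleiotropy variants, and per-ancestry
#' study sizes.  Defaults emulate the structure of a proteome-wide
#' bidirectional MR study (discovery pQTL cohort of ~34.6k Europeans, disease
#' GWAS meta-analysis of ~449k, a 1225-sample replication panel, an East
#' Asian branch) with the number of proteins reduced to desk scale.
#'
#' @param n_proteins,n_diseases panel sizes.
#' @param n_causal_forward number of proteins with a nonzero `gamma`.
#' @param gamma causal effect(s) of protein on disease liability; recycled.
#' @param n_biomarkers number of proteins affected by a disease (`delta`).
#' @param delta disease->protein effect(s); recycled.
#' @param n_dual number of proteins given both a forward and a reverse
#'   effect (drawn from the causal set).
#' @param cis_block_size,n_causal_cis variants per cis LD block and causal
#'   cis variants per protein.
#' @param cis_beta_range range of |cis effect| (SD of protein per allele).
#' @param n_trans_hubs,trans_block_size,trans_targets,trans_beta shared
#'   trans-hub blocks, their size, proteins affected per hub, |effect|.
#' @param disease_block_size,n_causal_disease,disease_beta per-disease
#'   liability locus block size, causal count and |log-odds effect|.
#' @param n_pleiotropy number of protein cis variants also given a direct
#'   disease effect of size `pleiotropy_beta` (bypassing the protein).
#' @param pleiotropy_beta direct log-odds effect of pleiotropic variants.
#' @param pleiotropy_on `"causal_cis"` plants the direct effects on causal
#'   cis pQTLs (instrument-invalidating pleiotropy); `"noncausal_cis"` on
#'   non-causal cis-window variants (distinct causal variants for
#'   colocalization).
#' @param ancestries data.frame with columns ancestry, n_exposure,
#'   n_outcome, ld_seed, ld_decay.
#' @param replication_n sample size of the second (replication) pQTL panel.
#' @param n_categories number of disease-category labels to cycle over.
#' @param seed integer seed controlling the randomized layout.
#' @return object of class `truth_spec`.
#' @export
synth_truth <- function(n_proteins = 50, n_diseases = 19,
                        n_causal_forward = 5, gamma = 0.035,
                        n_biomarkers = 2, delta = 0.12, n_dual = 0,
                        cis_block_size = 27, n_causal_cis = 9,
                        cis_beta_range = c(0.28, 0.32),
                        n_trans_hubs = 3, trans_block_size = 10,
                        trans_targets = 3, trans_beta = 0.15,
                        disease_block_size = 36, n_causal_disease = 12,
                        disease_beta = 0.08,
                        n_pleiotropy = 0, pleiotropy_beta = 0.3,
                        pleiotropy_on = c("causal_cis", "noncausal_cis"),
                        ancestries = default_ancestries(),
                        replication_n = 1225,
                        n_categories = 5, seed = 1) {
  pleiotropy_on <- match.arg(pleiotropy_on)
  stopifnot(n_proteins >= 1, n_diseases >= 1,
            n_causal_forward <= n_proteins, n_biomarkers <= n_proteins,
            n_causal_cis <= cis_block_size,
            n_causal_disease <= disease_block_size,
            all(ancestries$n_exposure > 0), all(ancestries$n_outcome > 0),
            replication_n > 0)
  set.seed(as.integer(seed))

  pid <- sprintf("P%03d", seq_len(n_proteins))
  did <- sprintf("D%02d", seq_len(n_diseases))
  chroms <- as.character(rep_len(1:22, n_proteins))
  start <- 1e6 + (seq_len(n_proteins) - 1) %/% 22 * 6e6 +
    ((seq_len(n_proteins) - 1) %% 22) * 0  # one gene per chrom per tier
  proteins <- data.frame(
    protein_id = pid, gene_id = sprintf("GENE%03d", seq_len(n_proteins)),
    chrom = chroms, start = start, stop = start + 1e4,
    stringsAsFactors = FALSE
  )
  categories <- sprintf("category_%d",
                        rep_len(seq_len(n_categories), n_diseases))
  diseases <- data.frame(
    disease_id = did, category = categories, kind = "disease",
    n_cases = pmax(50L, as.integer(round(runif(n_diseases, 500, 20000)))),
    stringsAsFactors = FALSE
  )

  blocks <- data.frame(block_id = character(), size = integer(),
                       kind = character(), stringsAsFactors = FALSE)
  variants <- list()
  add_block <- function(block_id, kind, chrom, pos, prefix) {
    size <- length(pos)
    al <- NON_PALINDROMIC[sample.int(4, size, replace = TRUE)]
    variants[[length(variants) + 1]] <<- data.frame(
      variant_id = sprintf("%s_v%02d", prefix, seq_len(size)),
      chrom = chrom, pos = as.integer(round(pos)), block_id = block_id,
      effect_allele = vapply(al, `[`, "", 2),
      other_allele = vapply(al, `[`, "", 1),
      eaf = runif(size, 0.05, 0.95), stringsAsFactors = FALSE
    )
    blocks <<- rbind(blocks, data.frame(block_id = block_id, size = size,
                                        kind = kind))
  }

  # one cis block per protein, spanning the core of the +/- 1 Mb window
  for (i in seq_len(n_proteins)) {
    pos <- seq(proteins$start[i] - 5e5, proteins$stop[i] + 5e5,
               length.out = cis_block_size)
    add_block(paste0(pid[i], "_cis"), "cis", proteins$chrom[i], pos,
              paste0(pid[i], "_cis"))
  }
  # trans hubs, far from every gene interval
  for (h in seq_len(n_trans_hubs)) {
    pos <- seq(2.5e8 + h * 1e6, by = 5e4, length.out = trans_block_size)
    add_block(sprintf("hub%d", h), "trans", as.character(h), pos,
              sprintf("hub%d", h))
  }
  # one liability-locus block per disease, far from genes and hubs
  for (j in seq_len(n_diseases)) {
    pos <- seq(1.5e8 + j * 2e6, by = 5e4, length.out = disease_block_size)
    add_block(paste0(did[j], "_loc"), "disease",
              as.character(rep_len(1:22, n_diseases)[j]), pos,
              paste0(did[j], "_loc"))
  }
  variants <- do.call(rbind, variants)

  draw_beta <- function(k, lo, hi) {
    runif(k, lo, hi) * sample(c(-1, 1), k, replace = TRUE)
  }
  # causal cis variants are spread evenly through the block so their
  # marginal effects stay close to the joint effects (limited LD overlap)
  cis_idx <- unique(round(seq(2, cis_block_size - 1,
                              length.out = n_causal_cis)))
  cis_effects <- do.call(rbind, lapply(seq_len(n_proteins), function(i) {
    v <- variants$variant_id[variants$block_id == paste0(pid[i], "_cis")]
    data.frame(variant_id = v[cis_idx],
               protein_id = pid[i],
               beta = draw_beta(length(cis_idx), cis_beta_range[1],
                                cis_beta_range[2]),
               stringsAsFactors = FALSE)
  }))
  trans_effects <- if (n_trans_hubs > 0) {
    do.call(rbind, lapply(seq_len(n_trans_hubs), function(h) {
      v <- variants$variant_id[variants$block_id == sprintf("hub%d", h)]
      targets <- sample(pid, min(trans_targets, n_proteins))
      do.call(rbind, lapply(targets, function(p) {
        data.frame(variant_id = sample(v, 1), protein_id = p,
                   beta = draw_beta(1, 0.5 * trans_beta, 1.5 * trans_beta),
                   stringsAsFactors = FALSE)
      }))
    }))
  } else {
    data.frame(variant_id = character(), protein_id = character(),
               beta = numeric(), stringsAsFactors = FALSE)
  }
  loc_idx <- unique(round(seq(2, disease_block_size - 1,
                              length.out = n_causal_disease)))
  disease_effects <- do.call(rbind, lapply(seq_len(n_diseases), function(j) {
    v <- variants$variant_id[variants$block_id == paste0(did[j], "_loc")]
    data.frame(variant_id = v[loc_idx],
               disease_id = did[j],
               beta = draw_beta(length(loc_idx), 0.9375 * disease_beta,
                                1.0625 * disease_beta),
               stringsAsFactors = FALSE)
  }))

  causal <- if (n_causal_forward > 0) sample(pid, n_causal_forward)
            else character()
  forward_effects <- data.frame(
    protein_id = causal,
    disease_id = sample(did, n_causal_forward, replace = TRUE),
    gamma = rep_len(gamma, n_causal_forward), stringsAsFactors = FALSE
  )
  bm_pool <- setdiff(pid, causal)
  n_dual <- min(n_dual, length(causal), n_biomarkers)
  biomarkers <- c(if (n_dual > 0) sample(causal, n_dual),
                  if (n_biomarkers - n_dual > 0)
                    sample(bm_pool, n_biomarkers - n_dual))
  reverse_effects <- data.frame(
    disease_id = sample(did, n_biomarkers, replace = TRUE),
    protein_id = biomarkers,
    delta = rep_len(delta, max(n_biomarkers, 1))[seq_len(n_biomarkers)],
    stringsAsFactors = FALSE
  )

  pleiotropy <- data.frame(variant_id = character(),
                           disease_id = character(), beta = numeric(),
                           stringsAsFactors = FALSE)
  if (n_pleiotropy > 0) {
    pool <- if (pleiotropy_on == "causal_cis") cis_effects$variant_id
            else setdiff(variants$variant_id[
              variants$block_id %in% paste0(pid, "_cis")],
              cis_effects$variant_id)
    pv <- sample(pool, n_pleiotropy)
    pleiotropy <- data.frame(
      variant_id = pv,
      disease_id = sample(did, n_pleiotropy, replace = TRUE),
      beta = rep_len(pleiotropy_beta, n_pleiotropy),
      stringsAsFactors = FALSE
    )
  }

  validate_truth_spec(structure(list(
    proteins = proteins, diseases = diseases,
    forward_effects = forward_effects, reverse_effects = reverse_effects,
    cis_effects = cis_effects, trans_effects = trans_effects,
    disease_effects = disease_effects, pleiotropy = pleiotropy,
    variants = variants, blocks = blocks,
    ancestries = ancestries, replication_n = replication_n, seed = seed
  ), class = "truth_spec"))
}

#' @rdname synth_truth
#' @export
default_ancestries <- function() {
  data.frame(
    ancestry = c("EUR", "EAS"),
    n_exposure = c(34557, 2783),
    n_outcome = c(50000, 30000),
    ld_seed = c(101L, 202L),
    ld_decay = c(0.3, 0.25),
    stringsAsFactors = FALSE
  )
}

validate_truth_spec <- function(truth) {
  with(truth, {
    stopifnot(all(cis_effects$protein_id %in% proteins$protein_id),
              all(trans_effects$protein_id %in% proteins$protein_id),
              all(forward_effects$protein_id %in% proteins$protein_id),
              all(forward_effects$disease_id %in% diseases$disease_id),
              all(reverse_effects$protein_id %in% proteins$protein_id),
              all(reverse_effects$disease_id %in% diseases$disease_id),
              all(pleiotropy$disease_id %in% diseases$disease_id),
              all(ancestries$n_exposure > 0), all(ancestries$n_outcome > 0),
              replication_n > 0)
    # cis variants must fall inside the +/- 1 Mb window of the owning gene
    ci <- merge(cis_effects, variants, by = "variant_id")
    ci <- merge(ci, proteins, by = "protein_id",
                suffixes = c("", ".gene"))
    stopifnot(all(ci$chrom == ci$chrom.gene),
              all(ci$pos >= ci$start - 1e6 & ci$pos <= ci$stop + 1e6))
  })
  truth
}

#' @export
print.truth_spec <- function(x, ...) {
  cat("Synthetic truth:", nrow(x$proteins), "proteins,",
      nrow(x$diseases), "diseases,", nrow(x$variants), "variants in",
      nrow(x$blocks), "LD blocks\n")
  cat("  forward effects:", nrow(x$forward_effects),
      "| reverse effects:", nrow(x$reverse_effects),
      "| pleiotropic variants:", nrow(x$pleiotropy), "\n")
  cat("  ancestries:", paste(x$ancestries$ancestry, collapse = ", "),
      "| replication n =", x$replication_n, "\n")
  invisible(x)
}

#' LD blocks matching a truth spec
#'
#' Simulates one LD block per block declared in the truth, with the
#' ancestry's decay rate and seed, so distinct ancestries get distinct LD.
#'
#' @param truth a `truth_spec`.
#' @param ancestry ancestry label present in `truth$ancestries`.
#' @param jitter off-diagonal jitter passed to [simulate_ld_blocks()].
#' @return named list of `ld_block` objects (by block id).
#' @export
truth_ld_blocks <- function(truth, ancestry = "EUR", jitter = 0.03) {
  a <- truth$ancestries[truth$ancestries$ancestry == ancestry, ]
  if (nrow(a) != 1) stop2("unknown ancestry: ", ancestry)
  set.seed(a$ld_seed)
  out <- lapply(seq_len(nrow(truth$blocks)), function(k) {
    size <- truth$blocks$size[k]
    R <- ar1_matrix(size, a$ld_decay)
    if (jitter > 0 && size > 1) {
      E <- matrix(rnorm(size^2, sd = jitter), size)
      E <- (E + t(E)) / 2
      diag(E) <- 0
      R <- project_psd(pmin(pmax(R + E, -1), 1))
      diag(R) <- 1
    }
    ids <- truth$variants$variant_id[
      truth$variants$block_id == truth$blocks$block_id[k]]
    new_ld_block(ids, R)
  })
  names(out) <- truth$blocks$block_id
  out
}

# joint (conditional) true effect of every variant on one trait
joint_effects <- function(truth, trait_id) {
  v <- truth$variants$variant_id
  beta <- setNames(numeric(length(v)), v)
  if (trait_id %in% truth$proteins$protein_id) {
    ce <- truth$cis_effects[truth$cis_effects$protein_id == trait_id, ]
    te <- truth$trans_effects[truth$trans_effects$protein_id == trait_id, ]
    beta[ce$variant_id] <- beta[ce$variant_id] + ce$beta
    beta[te$variant_id] <- beta[te$variant_id] + te$beta
    re <- truth$reverse_effects[truth$reverse_effects$protein_id == trait_id, ]
    for (r in seq_len(nrow(re))) {
      de <- truth$disease_effects[
        truth$disease_effects$disease_id == re$disease_id[r], ]
      beta[de$variant_id] <- beta[de$variant_id] + re$delta[r] * de$beta
    }
  } else if (trait_id %in% truth$diseases$disease_id) {
    de <- truth$disease_effects[truth$disease_effects$disease_id == trait_id, ]
    beta[de$variant_id] <- beta[de$variant_id] + de$beta
    fe <- truth$forward_effects[truth$forward_effects$disease_id == trait_id, ]
    for (r in seq_len(nrow(fe))) {
      pe <- rbind(
        truth$cis_effects[truth$cis_effects$protein_id == fe$protein_id[r],
                          c("variant_id", "beta")],
        truth$trans_effects[truth$trans_effects$protein_id ==
                              fe$protein_id[r], c("variant_id", "beta")]
      )
      beta[pe$variant_id] <- beta[pe$variant_id] + fe$gamma[r] * pe$beta
    }
    pl <- truth$pleiotropy[truth$pleiotropy$disease_id == trait_id, ]
    beta[pl$variant_id] <- beta[pl$variant_id] + pl$beta
  } else {
    stop2("trait '", trait_id, "' is not declared in the truth spec")
  }
  beta
}

block_chol <- function(block) {
  ch <- attr(block, "chol")
  if (is.null(ch)) ch <- chol(block$R + diag(1e-10, nrow(block$R)))
  ch
}

#' Cache Cholesky factors on LD blocks
#'
#' Precomputes and attaches the upper-triangular Cholesky factor of each
#' block so repeated summary-statistic sampling avoids refactorization.
#'
#' @param ld_blocks list of `ld_block` objects.
#' @return the same list with a `chol` attribute on each block.
#' @export
cache_ld_chol <- function(ld_blocks) {
  lapply(ld_blocks, function(b) {
    attr(b, "chol") <- chol(b$R + diag(1e-10, nrow(b$R)))
    b
  })
}

#' Sample marginal GWAS summary statistics for one trait
#'
#' Within each LD block the marginal-effect estimate is sampled as
#' \eqn{\hat\beta \sim \mathrm{MVN}(R\beta_{joint},\ R/n)} with
#' \eqn{se = 1/\sqrt n}; the trait is treated as variance-standardized.
#' Disease traits accumulate their own liability loci, the protein-mediated
#' effects \eqn{\sum_p \gamma_p \beta_p}, and any direct pleiotropic
#' effects; protein traits accumulate cis + trans effects plus
#' \eqn{\sum_d \delta_d \beta_d} from reverse causation.
#'
#' @param truth a `truth_spec`.
#' @param trait_id a declared protein or disease id.
#' @param ld_blocks blocks from [truth_ld_blocks()] (optionally
#'   [cache_ld_chol()]-ed).
#' @param n GWAS sample size; defaults to the ancestry's exposure size for
#'   proteins and outcome size for diseases.
#' @param seed integer seed; sampling is deterministic given
#'   `(truth, seed)`.
#' @param flip_fraction fraction of variants reported on the opposite
#'   allele (beta negated, alleles swapped, EAF complemented) to exercise
#'   harmonization.
#' @param ancestry ancestry label used for default sample sizes.
#' @return a `sumstats` data.frame (see [read_sumstats()] for the schema).
#' @export
simulate_marginal_stats <- function(truth, trait_id, ld_blocks, n = NULL,
                                    seed, flip_fraction = 0,
                                    ancestry = "EUR") {
  beta_joint <- joint_effects(truth, trait_id)  # errors on unknown trait
  if (is.null(n)) {
    a <- truth$ancestries[truth$ancestries$ancestry == ancestry, ]
    if (nrow(a) != 1) stop2("unknown ancestry: ", ancestry)
    n <- if (trait_id %in% truth$proteins$protein_id) a$n_exposure
         else a$n_outcome
  }
  kind <- if (trait_id %in% truth$proteins$protein_id) "protein"
          else truth$diseases$kind[truth$diseases$disease_id == trait_id]
  covered <- unlist(lapply(ld_blocks, `[[`, "variant_ids"),
                    use.names = FALSE)
  missing <- setdiff(names(beta_joint)[beta_joint != 0], covered)
  if (length(missing)) {
    stop2("causal variants not covered by any LD block: ",
          paste(head(missing, 5), collapse = ", "))
  }

  set.seed(as.integer(seed))
  se <- 1 / sqrt(n)
  ids <- unlist(lapply(ld_blocks, `[[`, "variant_ids"), use.names = FALSE)
  bh <- unlist(lapply(ld_blocks, function(b) {
    bj <- beta_joint[b$variant_ids]
    bj[is.na(bj)] <- 0
    mu <- drop(b$R %*% bj)
    mu + drop(crossprod(block_chol(b), rnorm(length(mu)))) * se
  }), use.names = FALSE)
  vi <- match(ids, truth$variants$variant_id)
  out <- data.frame(
    variant_id = ids,
    chrom = truth$variants$chrom[vi], pos = truth$variants$pos[vi],
    effect_allele = truth$variants$effect_allele[vi],
    other_allele = truth$variants$other_allele[vi],
    eaf = truth$variants$eaf[vi],
    beta = bh, se = se, stringsAsFactors = FALSE
  )
  out$pvalue <- z_pvalue(out$beta, out$se)
  out$n <- n

  if (flip_fraction > 0) {
    fl <- runif(nrow(out)) < flip_fraction
    tmp <- out$effect_allele[fl]
    out$effect_allele[fl] <- out$other_allele[fl]
    out$other_allele[fl] <- tmp
    out$beta[fl] <- -out$beta[fl]
    out$eaf[fl] <- 1 - out$eaf[fl]
  }
  as_sumstats(out, trait_id = trait_id, trait_kind = kind,
              ancestry = ancestry)
}

#' Sample exposure/outcome statistics with overlapping samples
#'
#' Draws the two traits' estimates with a shared per-variant noise
#' component of correlation `overlap_r`, emulating participant overlap
#' between the exposure and outcome studies (off by default elsewhere).
#'
#' @inheritParams simulate_marginal_stats
#' @param exposure_id,outcome_id declared trait ids.
#' @param n_exposure,n_outcome sample sizes.
#' @param overlap_r correlation of the sampling errors, in `[0, 1]`.
#' @return list with elements `exposure` and `outcome` (`sumstats`).
#' @export
simulate_overlapping_stats <- function(truth, exposure_id, outcome_id,
                                       ld_blocks, n_exposure, n_outcome,
                                       overlap_r = 0, seed) {
  stopifnot(overlap_r >= 0, overlap_r <= 1)
  bx <- joint_effects(truth, exposure_id)
  by <- joint_effects(truth, outcome_id)
  set.seed(as.integer(seed))
  sample_one <- function(b, bj, n, z) {
    mu <- drop(b$R %*% bj[b$variant_ids])
    mu + drop(crossprod(block_chol(b), z)) / sqrt(n)
  }
  make <- function(trait_id, est, n, kind) {
    out <- merge(truth$variants[, c("variant_id", "chrom", "pos",
                                    "effect_allele", "other_allele", "eaf")],
                 est, by = "variant_id", sort = FALSE)
    out$se <- 1 / sqrt(n)
    out$pvalue <- z_pvalue(out$beta, out$se)
    out$n <- n
    as_sumstats(out, trait_id = trait_id, trait_kind = kind,
                ancestry = truth$ancestries$ancestry[1])
  }
  ex <- list(); oy <- list()
  for (b in ld_blocks) {
    m <- length(b$variant_ids)
    z1 <- rnorm(m)
    z2 <- overlap_r * z1 + sqrt(1 - overlap_r^2) * rnorm(m)
    ex[[length(ex) + 1]] <- data.frame(
      variant_id = b$variant_ids,
      beta = sample_one(b, bx, n_exposure, z1), stringsAsFactors = FALSE)
    oy[[length(oy) + 1]] <- data.frame(
      variant_id = b$variant_ids,
      beta = sample_one(b, by, n_outcome, z2), stringsAsFactors = FALSE)
  }
  list(
    exposure = make(exposure_id, do.call(rbind, ex), n_exposure, "protein"),
    outcome = make(outcome_id, do.call(rbind, oy), n_outcome, "disease")
  )
}

#' Write / read a truth spec as YAML
#'
#' @param truth a `truth_spec`.
#' @param path file path.
#' @return `read_truth_yaml` returns the reconstructed `truth_spec`.
#' @export
write_truth_yaml <- function(truth, path) {
  obj <- lapply(unclass(truth), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  })
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_truth_yaml
#' @export
read_truth_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  dfs <- c("proteins", "diseases", "forward_effects", "reverse_effects",
           "cis_effects", "trans_effects", "disease_effects", "pleiotropy",
           "variants", "blocks", "ancestries")
  for (d in dfs) {
    cols <- lapply(obj[[d]], function(col) {
      v <- unlist(col)
      if (is.null(v)) character() else v
    })
    obj[[d]] <- as.data.frame(cols, stringsAsFactors = FALSE)
  }
  validate_truth_spec(structure(obj, class = "truth_spec"))
}
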