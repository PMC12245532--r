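# Synthetic single-nucleus counts with planted cell-type-enriched and
# disease-DE genes, emulating a left-ventricular snRNA-seq cohort
# (non-failing vs dilated/hypertrophic cardiomyopathy donors) at desk
# scale.

#' Default synthetic donor table
#'
#' Three arms mirroring a left-ventricular cohort of 16 non-failing, 11
#' dilated-cardiomyopathy and 15 hypertrophic-cardiomyopathy donors, with
#' ages and sexes balanced across arms.
#'
#' @param n_nf,n_dcm,n_hcm donors per arm.
#' @param seed integer seed for ages/sexes.
#' @return data.frame with donor_id, condition, age, sex.
#' @export
default_donors <- function(n_nf = 16, n_dcm = 11, n_hcm = 15, seed = 1) {
  set.seed(as.integer(seed))
  n <- n_nf + n_dcm + n_hcm
  data.frame(
    donor_id = sprintf("don%02d", seq_len(n)),
    condition = rep(c("NF", "DCM", "HCM"), c(n_nf, n_dcm, n_hcm)),
    age = as.integer(round(runif(n, 35, 70))),
    sex = rep_len(c("F", "M"), n),
    stringsAsFactors = FALSE
  )
}

#' Simulate single-nucleus counts with planted structure
#'
#' Negative-binomial counts per nucleus.  A gene's mean in a nucleus is
#' `base_mean x enrichment fold (if the nucleus' cell type is the gene's
#' declared target) x DE fold (if the nucleus' donor carries the declared
#' condition and the nucleus is of the declared cell type) x a per
#' (gene, donor) lognormal biological factor`.  Enriched genes therefore
#' show at least the declared fold in pseudobulk expectation, and DE genes
#' the declared fold between conditions within their cell type.
#'
#' @param n_genes total genes (planted genes are drawn from these).
#' @param cell_types character vector of cell-type labels.
#' @param donors data.frame as from [default_donors()].
#' @param cells_per_donor_type nuclei per donor per cell type.
#' @param enriched_genes data.frame `gene`, `cell_type`, `fold`
#'   (fold > 0; 1 = no enrichment).
#' @param de_genes data.frame `gene`, `cell_type`, `condition`, `fold`.
#' @param base_mean_meanlog,base_mean_sdlog lognormal parameters of the
#'   per-gene baseline mean counts per nucleus.
#' @param dispersion negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param donor_sd lognormal SD of the per-(gene, donor) biological
#'   factor.
#' @param seed integer seed; output is deterministic given it.
#' @return list with `counts` (sparse genes x cells Matrix), `genes`,
#'   `cells` (cell_id, cell_type, donor_id), `donors`.
#' @export
simulate_singlecell_counts <- function(n_genes = 200,
                                       cell_types = c("Cardiomyocyte",
                                                      "Fibroblast",
                                                      "Endothelial",
                                                      "Macrophage"),
                                       donors = default_donors(),
                                       cells_per_donor_type = 30,
                                       enriched_genes = NULL,
                                       de_genes = NULL,
                                       base_mean_meanlog = log(1.5),
                                       base_mean_sdlog = 0.8,
                                       dispersion = 2, donor_sd = 0.15,
                                       seed = 1) {
  if (!is.null(enriched_genes) && any(enriched_genes$fold <= 0)) {
    stop2("enrichment fold must be > 0")
  }
  if (!is.null(de_genes) && any(de_genes$fold <= 0)) {
    stop2("DE fold must be > 0")
  }
  set.seed(as.integer(seed))
  genes <- sprintf("G%04d", seq_len(n_genes))
  base <- stats::rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog)

  cells <- expand.grid(donor_id = donors$donor_id, cell_type = cell_types,
                       nucleus = seq_len(cells_per_donor_type),
                       stringsAsFactors = FALSE)
  cells$cell_id <- sprintf("c%05d", seq_len(nrow(cells)))
  cells <- cells[, c("cell_id", "cell_type", "donor_id")]
  cond <- donors$condition[match(cells$donor_id, donors$donor_id)]

  # per (gene, donor) biological factor
  dfac <- matrix(stats::rlnorm(n_genes * nrow(donors),
                               -donor_sd^2 / 2, donor_sd),
                 n_genes, nrow(donors),
                 dimnames = list(genes, donors$donor_id))

  # per (gene, cell type) enrichment fold
  efold <- matrix(1, n_genes, length(cell_types),
                  dimnames = list(genes, cell_types))
  for (i in seq_len(NROW(enriched_genes))) {
    efold[enriched_genes$gene[i], enriched_genes$cell_type[i]] <-
      enriched_genes$fold[i]
  }
  # per (gene, cell type, condition) DE fold
  dfold <- array(1, c(n_genes, length(cell_types), 3),
                 dimnames = list(genes, cell_types, c("NF", "DCM", "HCM")))
  for (i in seq_len(NROW(de_genes))) {
    dfold[de_genes$gene[i], de_genes$cell_type[i],
          de_genes$condition[i]] <- de_genes$fold[i]
  }

  counts <- matrix(0L, n_genes, nrow(cells),
                   dimnames = list(genes, cells$cell_id))
  for (j in seq_len(nrow(cells))) {
    mu <- base * efold[, cells$cell_type[j]] *
      dfold[, cells$cell_type[j], cond[j]] * dfac[, cells$donor_id[j]]
    counts[, j] <- rnbinom(n_genes, size = dispersion, mu = mu)
  }
  list(counts = Matrix::Matrix(counts, sparse = TRUE),
       genes = data.frame(gene_id = genes, stringsAsFactors = FALSE),
       cells = cells, donors = donors)
}

#' Write / read single-cell data as Matrix Market + TSV sidecars
#'
#' Files: `<prefix>.mtx`, `<prefix>.genes.tsv`, `<prefix>.cells.tsv`
#' (cell_id, cell_type, donor_id), `<prefix>.donors.tsv`
#' (donor_id, condition, age, sex).
#'
#' @param sc list as returned by [simulate_singlecell_counts()].
#' @param prefix path prefix.
#' @return `read_singlecell` returns the same list structure.
#' @export
write_singlecell <- function(sc, prefix) {
  Matrix::writeMM(methods::as(sc$counts, "CsparseMatrix"),
                  paste0(prefix, ".mtx"))
  write.table(sc$genes, paste0(prefix, ".genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sc$cells, paste0(prefix, ".cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sc$donors, paste0(prefix, ".donors.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_singlecell
#' @export
read_singlecell <- function(prefix) {
  counts <- Matrix::readMM(paste0(prefix, ".mtx"))
  genes <- read.delim(paste0(prefix, ".genes.tsv"),
                      stringsAsFactors = FALSE)
  cells <- read.delim(paste0(prefix, ".cells.tsv"),
                      stringsAsFactors = FALSE)
  donors <- read.delim(paste0(prefix, ".donors.tsv"),
                       stringsAsFactors = FALSE)
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  list(counts = counts, genes = genes, cells = cells, donors = donors)
}
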