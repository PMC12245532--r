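# Pseudobulk construction, TMM/log2-CPM normalization, cell-type
# enrichment, and cardiomyopathy-vs-control differential expression.

#' Aggregate nuclei into pseudobulk profiles
#'
#' Sums gene counts by (donor, cell type).  Profiles with zero nuclei are
#' omitted.  Nuclei-level summaries needed downstream (fraction of nuclei
#' expressing and mean nuclei expression per gene and cell type) are
#' computed here and attached.
#'
#' @param counts genes x cells matrix (sparse or dense) with dimnames.
#' @param cells data.frame `cell_id`, `cell_type`, `donor_id`.
#' @param donors data.frame `donor_id`, `condition`, `age`, `sex`.
#' @return object of class `pseudobulk`: list with `counts` (genes x
#'   profiles, integer), `profiles` (profile metadata incl. `lib_size`),
#'   `nuclei_fraction` and `nuclei_mean` (genes x cell-type matrices),
#'   `n_nuclei` (per cell type).
#' @export
aggregate_pseudobulk <- function(counts, cells, donors) {
  stopifnot(ncol(counts) == nrow(cells))
  if (any(!cells$donor_id %in% donors$donor_id)) {
    stop2("cell(s) reference unknown donor: ",
          paste(head(setdiff(cells$donor_id, donors$donor_id), 3),
                collapse = ", "))
  }
  if (anyNA(cells$cell_type)) stop2("cell(s) with missing cell type")
  grp <- interaction(cells$donor_id, cells$cell_type, sep = "||",
                     drop = TRUE)
  ind <- Matrix::sparseMatrix(i = seq_len(nrow(cells)),
                              j = as.integer(grp), x = 1,
                              dims = c(nrow(cells), nlevels(grp)))
  pb <- as.matrix(counts %*% ind)
  parts <- do.call(rbind, strsplit(levels(grp), "||", fixed = TRUE))
  profiles <- data.frame(
    profile_id = paste(parts[, 1], parts[, 2], sep = "_"),
    donor_id = parts[, 1], cell_type = parts[, 2],
    stringsAsFactors = FALSE
  )
  profiles <- cbind(profiles,
                    donors[match(profiles$donor_id, donors$donor_id),
                           c("condition", "age", "sex")])
  rownames(profiles) <- NULL
  colnames(pb) <- profiles$profile_id
  profiles$lib_size <- colSums(pb)
  profiles$n_nuclei <- as.integer(table(grp)[levels(grp)])

  types <- sort(unique(cells$cell_type))
  nf <- nm <- matrix(NA_real_, nrow(counts), length(types),
                     dimnames = list(rownames(counts), types))
  nn <- setNames(integer(length(types)), types)
  for (t in types) {
    sel <- which(cells$cell_type == t)
    nn[t] <- length(sel)
    sub <- counts[, sel, drop = FALSE]
    nf[, t] <- Matrix::rowSums(sub > 0) / length(sel)
    nm[, t] <- Matrix::rowMeans(sub)
  }
  structure(list(counts = pb, profiles = profiles,
                 nuclei_fraction = nf, nuclei_mean = nm, n_nuclei = nn),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat("Pseudobulk:", nrow(x$counts), "genes x", ncol(x$counts),
      "profiles (", length(unique(x$profiles$donor_id)), "donors,",
      length(unique(x$profiles$cell_type)), "cell types )\n")
  invisible(x)
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Per-profile scaling factors from the TMM method (doubly trimmed
#' weighted mean of log-ratios against the profile whose upper-quartile
#' count fraction is closest to the mean), computed by
#' `edgeR::calcNormFactors` and rescaled to geometric mean 1.  All-zero
#' profiles are dropped with a warning.
#'
#' @param pb a `pseudobulk` object (or genes x profiles count matrix).
#' @param trim_m log-ratio (M) trim fraction (default 0.3).
#' @param trim_a absolute-intensity (A) trim fraction (default 0.05).
#' @return named numeric vector of factors, one per (nonzero) profile.
#' @export
tmm_factors <- function(pb, trim_m = 0.3, trim_a = 0.05) {
  m <- if (inherits(pb, "pseudobulk")) pb$counts else as.matrix(pb)
  nz <- colSums(m) > 0
  if (any(!nz)) {
    warning("dropping ", sum(!nz), " all-zero profile(s)", call. = FALSE)
    m <- m[, nz, drop = FALSE]
  }
  if (ncol(m) < 2) stop2("TMM needs >= 2 profiles with nonzero counts")
  f <- edgeR::calcNormFactors(m, method = "TMM", logratioTrim = trim_m,
                              sumTrim = trim_a)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

#' log2 counts per million
#'
#' `log2((count + pseudocount) / (lib_size x factor + 2 x pseudocount)
#' x 1e6)`, applied uniformly; the pseudocount guards zero counts.
#'
#' @param pb a `pseudobulk` object or count matrix.
#' @param factors normalization factors from [tmm_factors()] (default:
#'   computed); profiles without a factor are dropped.
#' @param pseudocount additive constant (default 0.25).
#' @param log take log2 (default TRUE; FALSE returns linear CPM).
#' @return real matrix, genes x profiles.
#' @export
log_cpm <- function(pb, factors = NULL, pseudocount = 0.25, log = TRUE) {
  m <- if (inherits(pb, "pseudobulk")) pb$counts else as.matrix(pb)
  if (is.null(factors)) factors <- tmm_factors(m)
  m <- m[, names(factors), drop = FALSE]
  lib <- colSums(m) * factors
  cpm <- sweep(m + pseudocount, 2, lib + 2 * pseudocount, "/") * 1e6
  if (log) log2(cpm) else cpm
}

#' Rank-based single-gene AUC
#'
#' Area under the ROC curve of a single gene's expression for predicting
#' membership of one class, computed from the Mann-Whitney statistic with
#' midrank tie handling.
#'
#' @param expr numeric expression values.
#' @param in_class logical, same length: TRUE for the positive class.
#' @return AUC in `[0, 1]`; NA when either class is empty.
#' @export
auc_single_gene <- function(expr, in_class) {
  n1 <- sum(in_class)
  n0 <- sum(!in_class)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(expr)                            # midranks
  (sum(r[in_class]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Gini coefficient
#'
#' Standard sorted-value formula
#' `sum((2i - n - 1) x_(i)) / (n sum(x))`; lies in `[0, 1 - 1/n]` for
#' non-negative input.
#'
#' @param values non-negative numeric vector.
#' @return the coefficient; NA when all values are zero.
#' @export
gini <- function(values) {
  stopifnot(all(values >= 0))
  n <- length(values)
  s <- sum(values)
  if (s == 0) return(NA_real_)
  x <- sort(values)
  sum((2 * seq_len(n) - n - 1) * x) / (n * s)
}

#' Cell-type enrichment of gene expression
#'
#' A gene is enriched in a cell type when (1) its mean normalized
#' expression is more than `fold_threshold` (4) times higher than in the
#' other cell types with BH-adjusted one-vs-rest p-value below
#' `fdr_threshold` (0.01), (2) at least `fraction_threshold` (25%) of the
#' type's nuclei express it, and (3) the single-gene nucleus classifier
#' achieves AUC above `auc_threshold` (0.6).  The one-vs-rest test is a
#' Welch t-test on profile-level log2-CPM.  For display, enriched genes
#' are ordered by the cell type of highest average nuclei expression and
#' then by the mean of the Gini coefficients of (average nuclei
#' expression, fraction expressing) across types, descending.
#'
#' @param pb a `pseudobulk` object.
#' @param counts,cells the nucleus-level matrix and metadata used to build
#'   `pb` (for the AUC criterion).
#' @param factors TMM factors (default: computed from `pb`).
#' @param fold_threshold,fdr_threshold,fraction_threshold,auc_threshold
#'   the enrichment criteria.
#' @return data.frame of class `celltype_enrichment`: one row per
#'   (gene, cell_type) with `fold_one_vs_rest`, `pvalue`, `fdr`,
#'   `fraction_nuclei`, `auc`, `enriched`, `gini`, `ordering_key`.
#' @export
celltype_enrichment <- function(pb, counts, cells, factors = NULL,
                                fold_threshold = 4, fdr_threshold = 0.01,
                                fraction_threshold = 0.25,
                                auc_threshold = 0.6) {
  types <- sort(unique(pb$profiles$cell_type))
  if (length(types) < 2) stop2("need >= 2 cell types")
  if (is.null(factors)) factors <- tmm_factors(pb)
  lc <- log_cpm(pb, factors)
  cpm <- log_cpm(pb, factors, log = FALSE)
  prof_type <- pb$profiles$cell_type[match(colnames(lc),
                                           pb$profiles$profile_id)]
  genes <- rownames(pb$counts)

  # nuclei-level AUC: rank each gene once, then group rank sums
  type_of_cell <- cells$cell_type
  rk <- t(apply(as.matrix(counts), 1, rank))
  n_cells <- ncol(counts)

  rows <- list()
  for (t in types) {
    in_t <- prof_type == t
    fold <- rowMeans(cpm[, in_t, drop = FALSE]) /
      rowMeans(cpm[, !in_t, drop = FALSE])
    pv <- rep(NA_real_, length(genes))
    if (sum(in_t) >= 2 && sum(!in_t) >= 2) {
      x <- lc[, in_t, drop = FALSE]
      y <- lc[, !in_t, drop = FALSE]
      nx <- ncol(x); ny <- ncol(y)
      mx <- rowMeans(x); my <- rowMeans(y)
      vx <- apply(x, 1, var); vy <- apply(y, 1, var)
      sdm <- sqrt(vx / nx + vy / ny)
      tt <- (mx - my) / sdm
      df <- (vx / nx + vy / ny)^2 /
        ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
      pv <- 2 * pt(-abs(tt), df)
      pv[sdm == 0] <- ifelse(mx[sdm == 0] == my[sdm == 0], 1, NA)
    }
    n1 <- sum(type_of_cell == t)
    n0 <- n_cells - n1
    auc <- (rowSums(rk[, type_of_cell == t, drop = FALSE]) -
              n1 * (n1 + 1) / 2) / (n1 * n0)
    rows[[t]] <- data.frame(
      gene = genes, cell_type = t, fold_one_vs_rest = fold,
      pvalue = pv, fraction_nuclei = pb$nuclei_fraction[, t],
      auc = auc, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- p.adjust(out$pvalue, "BH")
  out$enriched <- !is.na(out$fdr) &
    out$fold_one_vs_rest > fold_threshold & out$fdr < fdr_threshold &
    out$fraction_nuclei >= fraction_threshold & out$auc > auc_threshold

  # display ordering: top cell type by mean nuclei expression, then mean
  # Gini of (average nuclei expression, fraction expressing), descending
  gmean <- apply(pb$nuclei_mean, 1, function(v) {
    if (all(v == 0)) NA_real_ else gini(v)
  })
  gfrac <- apply(pb$nuclei_fraction, 1, function(v) {
    if (all(v == 0)) NA_real_ else gini(v)
  })
  gscore <- (gmean + gfrac) / 2
  top_type <- types[max.col(pb$nuclei_mean, ties.method = "first")]
  out$gini <- gscore[out$gene]
  out$ordering_key <- order(order(match(top_type[match(out$gene, genes)],
                                        types), -out$gini))
  class(out) <- c("celltype_enrichment", "data.frame")
  out
}

#' Differential expression: cardiomyopathy vs non-failing hearts
#'
#' Per cell type, fits the limma-voom pipeline on pseudobulk counts:
#' TMM-normalized, mean-variance weighted linear model of expression on
#' disease group adjusted for age and sex.  A gene passes when its
#' expression is at least 50% higher in the cardiomyopathy arm
#' (log2FC >= log2(1.5)) with BH-adjusted p < 0.01 within the cell type.
#' Cell types with fewer than `min_donors` donors per arm are marked not
#' testable; a design in which condition is collinear with sex (or age)
#' raises an error naming the collinearity.
#'
#' @param pb a `pseudobulk` object.
#' @param contrast `"DCM"` or `"HCM"` (vs the control condition).
#' @param control control condition label (default `"NF"`).
#' @param fc_threshold fold-change rule (default 1.5).
#' @param fdr_threshold BH threshold (default 0.01).
#' @param min_donors minimum donors per arm per cell type (default 3).
#' @return data.frame: per (gene, cell_type) `log2fc`, `pvalue`, `fdr`,
#'   `pass`, `testable`.
#' @export
de_disease_vs_control <- function(pb, contrast = c("DCM", "HCM"),
                                  control = "NF", fc_threshold = 1.5,
                                  fdr_threshold = 0.01, min_donors = 3) {
  contrast <- match.arg(contrast)
  types <- sort(unique(pb$profiles$cell_type))
  rows <- list()
  for (t in types) {
    sel <- pb$profiles$cell_type == t &
      pb$profiles$condition %in% c(contrast, control) &
      pb$profiles$lib_size > 0
    meta <- pb$profiles[sel, , drop = FALSE]
    n_case <- length(unique(meta$donor_id[meta$condition == contrast]))
    n_ctrl <- length(unique(meta$donor_id[meta$condition == control]))
    base <- data.frame(gene = rownames(pb$counts), cell_type = t,
                       contrast = paste0(contrast, "_vs_", control),
                       log2fc = NA_real_, pvalue = NA_real_,
                       fdr = NA_real_, pass = NA, testable = FALSE,
                       stringsAsFactors = FALSE)
    if (n_case < min_donors || n_ctrl < min_donors) {
      rows[[t]] <- base
      next
    }
    grp <- factor(meta$condition, levels = c(control, contrast))
    sex <- factor(meta$sex)
    design <- if (nlevels(sex) > 1) {
      stats::model.matrix(~ grp + meta$age + sex)
    } else {
      stats::model.matrix(~ grp + meta$age)
    }
    if (qr(design)$rank < ncol(design)) {
      if (nlevels(sex) > 1 &&
          all(table(grp, sex) %in% c(0, table(grp)))) {
        stop2("confounded design in cell type '", t,
              "': condition is collinear with sex")
      }
      stop2("confounded design in cell type '", t,
            "': covariates are collinear with condition")
    }
    y <- edgeR::DGEList(pb$counts[, meta$profile_id, drop = FALSE])
    y <- edgeR::calcNormFactors(y, method = "TMM")
    v <- limma::voom(y, design)
    fit <- limma::eBayes(limma::lmFit(v, design))
    tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
    base$log2fc <- tt$logFC
    base$pvalue <- tt$P.Value
    base$fdr <- p.adjust(tt$P.Value, "BH")
    base$pass <- base$log2fc >= log2(fc_threshold) &
      base$fdr < fdr_threshold
    base$testable <- TRUE
    rows[[t]] <- base
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
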