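# Over-representation of a protein functional group in a disease category.

#' Upper-tail hypergeometric enrichment p-value
#'
#' \deqn{P(X \ge k) = 1 - \sum_{i=0}^{k-1}
#'   \binom{M}{i}\binom{N-M}{n-i} / \binom{N}{n}}
#' where, for a protein functional group G and disease category D:
#' `N` = (total diseases across categories) x |G|, `M` = (diseases in D)
#' x |G|, `n` = significant signals in G across categories, `k` =
#' significant signals in G within D.  `k = 0` gives P = 1.
#'
#' @param k,n,M,N hypergeometric counts as above.
#' @return the upper-tail probability.
#' @export
hyper_enrichment_p <- function(k, n, M, N) {
  stopifnot(length(k) == length(n), length(n) == length(M),
            length(M) == length(N))
  if (any(M > N | n > N | k > pmin(n, M) | k < 0)) {
    stop2("inconsistent counts: need k <= min(n, M), M <= N, n <= N")
  }
  phyper(k - 1, M, N - M, n, lower.tail = FALSE)
}

#' Functional-group x disease-category over-representation scan
#'
#' Computes the hypergeometric enrichment p-value for every (protein
#' functional group, disease category) combination from a phenome-scan
#' significance table, Bonferroni-corrected for the total number of groups
#' times categories.
#'
#' @param phewas a `phewas_matrix` (see [phewas_scan()]).
#' @param groups data.frame mapping `protein_id` to `group_id`.
#' @param alpha significance level before Bonferroni correction.
#' @return data.frame of class `enrichment_results`: one row per
#'   (group_id, category_id) with `N`, `M`, `n`, `k`, `pvalue`,
#'   `significant`.
#' @export
enrichment_test <- function(phewas, groups, alpha = 0.05) {
  sig <- phewas$sig
  meta <- phewas$meta
  cats <- sort(unique(meta$category))
  gids <- sort(unique(groups$group_id))
  n_dis_total <- nrow(meta)
  rows <- list()
  for (g in gids) {
    members <- intersect(groups$protein_id[groups$group_id == g],
                         rownames(sig))
    if (!length(members)) next
    sub <- sig[members, , drop = FALSE]
    hit <- !is.na(sub) & sub
    n_sig_total <- sum(hit)
    for (d in cats) {
      in_cat <- meta$phenotype_id[meta$category == d]
      N <- n_dis_total * length(members)
      M <- length(in_cat) * length(members)
      k <- sum(hit[, colnames(sub) %in% in_cat, drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(
        group_id = g, category_id = d, N = N, M = M, n = n_sig_total,
        k = k, pvalue = hyper_enrichment_p(k, n_sig_total, M, N),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  m <- nrow(out)
  out$significant <- out$pvalue < alpha / m
  class(out) <- c("enrichment_results", "data.frame")
  out
}
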