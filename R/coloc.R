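# Multi-trait colocalization from Wakefield approximate Bayes factors.
#
# Simplified, fully specified multi-trait algorithm: per-variant log-ABFs
# per trait are combined into (a) per-trait regional association evidence,
# (b) the shared-single-causal-variant configuration (first trait at prior
# p1 per variant, every further trait at the conditional colocalization
# prior), and (c) all-causal-but-distinct configurations.  When the
# regional or alignment posterior fails its threshold, the trait whose
# removal maximizes the remaining cluster's alignment is split off and the
# remainder is re-evaluated (divisive, deterministic).

#' Wakefield approximate log Bayes factor
#'
#' `log ABF = 0.5 log(se^2/(se^2+W^2)) + 0.5 z^2 W^2/(se^2+W^2)` with
#' `z = beta/se`, comparing a normal effect prior N(0, W^2) against the
#' point null.
#'
#' @param beta,se effect estimate and standard error (vectorized).
#' @param W prior standard deviation of the true effect (default 0.15 for
#'   quantitative traits; 0.2 is conventional for binary log-odds).
#' @return log Bayes factor(s).
#' @export
wakefield_abf <- function(beta, se, W = 0.15) {
  stopifnot(all(se > 0), W > 0)
  z <- beta / se
  r <- W^2 / (se^2 + W^2)
  0.5 * log(1 - r) + 0.5 * z^2 * r
}

# log-sum-exp
lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# evidence terms for one trait set (list of labf vectors on a shared index)
coloc_evidence <- function(labf, p1, p_cond) {
  t_n <- length(labf)
  m <- length(labf[[1]])
  per_trait <- vapply(labf, function(v) lse(v) + log(p1), numeric(1))
  # shared single causal variant: first trait p1, others conditional prior
  shared_terms <- Reduce(`+`, labf) + log(p1) + (t_n - 1) * log(p_cond)
  log_shared <- lse(shared_terms)
  # all causal at distinct variants: product of per-trait sums minus the
  # same-variant overlap (both at per-variant prior p1)
  log_prod <- sum(per_trait)
  log_same_p1 <- lse(Reduce(`+`, labf)) + t_n * log(p1)
  dd <- exp(log_prod - max(log_prod, log_same_p1)) -
    exp(log_same_p1 - max(log_prod, log_same_p1))
  log_distinct <- if (dd <= 0) -Inf else log(dd) + max(log_prod,
                                                       log_same_p1)
  # some-but-not-all causal: sum over nonempty proper subsets
  subset_terms <- -Inf
  if (t_n > 1) {
    combs <- unlist(lapply(seq_len(t_n - 1), function(s) {
      asplit(utils::combn(t_n, s), 2)
    }), recursive = FALSE)
    subset_terms <- lse(vapply(combs, function(u) {
      sum(per_trait[u])
    }, numeric(1)))
  }
  list(log_null = 0, log_subset = subset_terms,
       log_shared = log_shared, log_distinct = log_distinct,
       shared_terms = shared_terms)
}

#' Multi-trait colocalization
#'
#' @param trait_stats named list of `sumstats`, each restricted to the
#'   same region (>= 2 traits; regions with < 10 shared variants trigger a
#'   warning).
#' @param p1 per-variant prior probability that a trait has a causal
#'   variant (default 1e-4).
#' @param conditional conditional colocalization prior for each trait
#'   beyond the first in the shared configuration (default 0.02; the
#'   conventional sweep is 0.005, 0.01, 0.02, see
#'   [coloc_sensitivity()]).
#' @param regional_threshold,alignment_threshold cluster acceptance
#'   thresholds (convention: swept over 0.6-0.9 in steps of 0.1).
#' @param W named or scalar prior SD passed to [wakefield_abf()]; a vector
#'   is matched to traits by name.
#' @return a list (class `coloc_result`) of clusters; each cluster has
#'   `traits`, `regional_prob`, `alignment_prob`, `posterior_prob`
#'   (regional x alignment: probability of one shared causal variant
#'   across the cluster), `candidate_variant`, and `passed`.  Singleton
#'   leaves report only their trait.
#' @export
multitrait_coloc <- function(trait_stats, p1 = 1e-4, conditional = 0.02,
                             regional_threshold = 0.8,
                             alignment_threshold = 0.8, W = 0.15) {
  stopifnot(length(trait_stats) >= 2)
  ids <- Reduce(intersect, lapply(trait_stats, `[[`, "variant_id"))
  if (!length(ids)) stop2("no shared variants across traits")
  if (length(ids) < 10) {
    warning("coloc region has < 10 shared variants; results unstable",
            call. = FALSE)
  }
  tn <- names(trait_stats) %||%
    vapply(trait_stats, attr, "", "trait_id")
  if (is.null(names(W))) W <- setNames(rep_len(W, length(tn)), tn)
  labf <- lapply(seq_along(trait_stats), function(t) {
    s <- trait_stats[[t]]
    i <- match(ids, s$variant_id)
    wakefield_abf(s$beta[i], s$se[i], W = unname(W[tn[t]]))
  })
  names(labf) <- tn

  evaluate <- function(members) {
    ev <- coloc_evidence(labf[members], p1, conditional)
    logs <- c(ev$log_null, ev$log_subset, ev$log_shared, ev$log_distinct)
    denom <- lse(logs[is.finite(logs)])
    regional <- exp(lse(c(ev$log_shared, ev$log_distinct)) - denom)
    align_den <- lse(c(ev$log_shared, ev$log_distinct))
    alignment <- exp(ev$log_shared - align_den)
    best <- which.max(ev$shared_terms)
    list(regional_prob = regional, alignment_prob = alignment,
         posterior_prob = regional * alignment,
         candidate_variant = ids[best])
  }

  clusters <- list()
  recurse <- function(members) {
    if (length(members) == 1) {
      clusters[[length(clusters) + 1]] <<- list(
        traits = members, regional_prob = NA_real_,
        alignment_prob = NA_real_, posterior_prob = NA_real_,
        candidate_variant = NA_character_, passed = FALSE)
      return(invisible())
    }
    e <- evaluate(members)
    if (e$regional_prob >= regional_threshold &&
        e$alignment_prob >= alignment_threshold) {
      clusters[[length(clusters) + 1]] <<- c(list(traits = members),
                                             e, list(passed = TRUE))
      return(invisible())
    }
    if (length(members) == 2) {
      clusters[[length(clusters) + 1]] <<- c(list(traits = members),
                                             e, list(passed = FALSE))
      return(invisible())
    }
    # drop the trait whose removal maximizes the remaining alignment;
    # ties break to the first trait in the (stable) member order
    gains <- vapply(seq_along(members), function(d) {
      evaluate(members[-d])$alignment_prob
    }, numeric(1))
    d <- which.max(gains)
    recurse(members[d])
    recurse(members[-d])
  }
  recurse(tn)
  structure(clusters, class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("Multi-trait colocalization:", length(x), "cluster(s)\n")
  for (cl in x) {
    cat("  [", paste(cl$traits, collapse = ", "), "] ", sep = "")
    if (is.na(cl$posterior_prob)) {
      cat("singleton\n")
    } else {
      cat(sprintf(
        "regional %.3f, alignment %.3f, posterior %.3f at %s%s\n",
        cl$regional_prob, cl$alignment_prob, cl$posterior_prob,
        cl$candidate_variant, if (cl$passed) "" else " (not passed)"))
    }
  }
  invisible(x)
}

#' Sweep colocalization priors and thresholds
#'
#' Re-runs [multitrait_coloc()] over the conventional grid of conditional
#' priors (0.005, 0.01, 0.02) and regional/alignment thresholds (0.6 to
#' 0.9 by 0.1) and tabulates the top cluster per setting.
#'
#' @inheritParams multitrait_coloc
#' @param conditional_priors,thresholds grids to sweep.
#' @return data.frame, one row per (conditional prior, threshold) setting.
#' @export
coloc_sensitivity <- function(trait_stats, p1 = 1e-4,
                              conditional_priors = c(0.005, 0.01, 0.02),
                              thresholds = seq(0.6, 0.9, by = 0.1),
                              W = 0.15) {
  rows <- list()
  for (pc in conditional_priors) {
    for (th in thresholds) {
      res <- multitrait_coloc(trait_stats, p1 = p1, conditional = pc,
                              regional_threshold = th,
                              alignment_threshold = th, W = W)
      sizes <- vapply(res, function(cl) length(cl$traits), 1L)
      top <- res[[which.max(sizes)]]
      rows[[length(rows) + 1]] <- data.frame(
        conditional_prior = pc, threshold = th,
        top_cluster = paste(top$traits, collapse = ","),
        posterior_prob = top$posterior_prob,
        candidate_variant = top$candidate_variant,
        passed = top$passed, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
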