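# Pleiotropy sensitivity analyses: RSS-simulation outlier detection
# (MR-PRESSO style), HEIDI-style ratio-heterogeneity filtering, and
# multivariable MR on z-scores.

#' Residual-sum-of-squares pleiotropy outlier test
#'
#' Compares the observed weighted residual sum of squares of leave-one-out
#' IVW predictions against a null distribution obtained by parametric
#' simulation of the outcome effects under the leave-one-out fitted model
#' with the reported outcome noise.  Instruments whose per-IV term is
#' significant after Bonferroni correction over the number of IVs are
#' removed and the IVW estimate recomputed; a distortion test compares the
#' corrected-vs-raw shift against removals of random subsets of the same
#' size.
#'
#' @param pairs harmonized effect pairs (>= 4 rows).
#' @param n_sim null simulations (default 1000); p-values are floored at
#'   `1/(n_sim+1)`.
#' @param outlier_alpha per-IV significance level before Bonferroni
#'   correction over `n_iv` (default 0.05).
#' @param seed integer seed (mandatory).
#' @return object of class `presso_result` with fields
#'   `global_rss_observed`, `global_p`, `per_iv_outlier_p`,
#'   `outliers_removed`, `raw_estimate`, `corrected_estimate`,
#'   `distortion_p`, `estimable`.
#' @export
presso <- function(pairs, n_sim = 1000, outlier_alpha = 0.05, seed) {
  pairs <- check_pairs(pairs)
  k <- nrow(pairs)
  if (k < 4) {
    return(structure(list(estimable = FALSE,
                          note = "needs >= 4 instruments"),
                     class = "presso_result"))
  }
  bx <- pairs$beta_exposure; by <- pairs$beta_outcome
  sy <- pairs$se_outcome
  w <- 1 / sy^2
  Sxx <- sum(w * bx^2)
  Sxy <- sum(w * bx * by)
  b_loo <- (Sxy - w * bx * by) / (Sxx - w * bx^2)
  t_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(t_obs)

  set.seed(child_seed(seed, "presso"))
  mu <- b_loo * bx
  By <- matrix(rnorm(k * n_sim, mean = mu, sd = sy), nrow = k)
  Sxy_s <- colSums((w * bx) * By)
  num <- sweep(-(w * bx) * By, 2, Sxy_s, "+")
  B_loo <- num / (Sxx - w * bx^2)
  Tsim <- w * (By - B_loo * bx)^2
  rss_sim <- colSums(Tsim)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  per_iv_p <- (1 + rowSums(Tsim >= t_obs)) / (n_sim + 1)
  names(per_iv_p) <- pairs$variant_id %||% as.character(seq_len(k))
  out_idx <- which(per_iv_p < outlier_alpha / k)

  raw <- mr_ivw(pairs)
  corrected <- raw
  distortion_p <- NA_real_
  if (length(out_idx) > 0 && length(out_idx) < k - 1) {
    corrected <- mr_ivw(pairs[-out_idx, , drop = FALSE])
    d_obs <- corrected$beta - raw$beta
    q <- length(out_idx)
    # distortion null: IVW slopes after removing random subsets of size q
    d_sim <- vapply(seq_len(n_sim), function(s) {
      drop_s <- sample.int(k, q)
      (Sxy - sum((w * bx * by)[drop_s])) /
        (Sxx - sum((w * bx^2)[drop_s])) - raw$beta
    }, numeric(1))
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }
  structure(list(
    global_rss_observed = rss_obs, global_p = global_p,
    per_iv_outlier_p = per_iv_p,
    outliers_removed = names(per_iv_p)[out_idx],
    raw_estimate = raw, corrected_estimate = corrected,
    distortion_p = distortion_p, estimable = TRUE
  ), class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  if (!x$estimable) {
    cat("RSS outlier test: not estimable (", x$note, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("RSS outlier test: observed RSS = %.4g, global p = %.3g\n",
              x$global_rss_observed, x$global_p))
  cat("  outliers removed:",
      if (length(x$outliers_removed)) paste(x$outliers_removed,
                                            collapse = ", ") else "none",
      "\n")
  if (!is.na(x$distortion_p)) {
    cat(sprintf("  distortion p = %.3g\n", x$distortion_p))
  }
  invisible(x)
}

#' HEIDI-style heterogeneity filter
#'
#' Uses the instrument with the smallest exposure p-value as the reference
#' and tests, for every other instrument, whether its Wald ratio deviates
#' from the reference ratio (difference variance by the delta method on
#' both traits, instruments treated as independent).  Instruments with
#' two-sided `p < heidi_alpha` are removed; the pass is repeated once.
#' The reference instrument is never removed.
#'
#' @param pairs harmonized effect pairs (>= 3 rows).
#' @param heidi_alpha removal threshold (default 0.01).
#' @return list with `pairs` (filtered), `removed` (variant ids),
#'   `reference` (variant id of the reference instrument).
#' @export
heidi_filter <- function(pairs, heidi_alpha = 0.01) {
  pairs <- check_pairs(pairs)
  if (nrow(pairs) < 3) {
    return(list(pairs = pairs, removed = character(),
                reference = NA_character_))
  }
  ids <- pairs$variant_id %||% as.character(seq_len(nrow(pairs)))
  zx <- abs(pairs$beta_exposure / pairs$se_exposure)
  ref <- which.max(zx)           # smallest exposure p
  ratio <- pairs$beta_outcome / pairs$beta_exposure
  var_ratio <- pairs$se_outcome^2 / pairs$beta_exposure^2 +
    pairs$beta_outcome^2 * pairs$se_exposure^2 / pairs$beta_exposure^4
  keep <- rep(TRUE, nrow(pairs))
  removed <- character()
  for (pass in 1:2) {
    test <- which(keep & seq_along(keep) != ref)
    d <- ratio[test] - ratio[ref]
    v <- var_ratio[test] + var_ratio[ref]
    p <- 2 * pnorm(-abs(d) / sqrt(v))
    drop <- test[p < heidi_alpha]
    if (!length(drop)) break
    keep[drop] <- FALSE
    removed <- c(removed, ids[drop])
  }
  list(pairs = pairs[keep, , drop = FALSE], removed = removed,
       reference = ids[ref])
}

#' Multivariable MR on z-scores
#'
#' Weighted least squares of outcome z-scores on the matrix of exposure
#' z-scores without intercept, for variants pre-clumped at a strict
#' threshold (r-squared < 0.01 within 500 kb) and associated with at least
#' one exposure protein.  Because z-scores carry unit sampling variance,
#' the coefficient covariance is `(X'X)^{-1}`; p-values are two-sided
#' normal.
#'
#' @param z_exposures numeric matrix, variants x proteins, with column
#'   names.
#' @param z_outcome numeric vector of outcome z-scores, one per variant.
#' @return object of class `mvmr_result`: data.frame with per-exposure
#'   `beta`, `se`, `pvalue`, plus attributes `n_variants` and `exposures`.
#' @export
mvmr_fit <- function(z_exposures, z_outcome) {
  X <- as.matrix(z_exposures)
  y <- as.numeric(z_outcome)
  stopifnot(nrow(X) == length(y))
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop2("duplicated exposure names")
  if (nrow(X) < ncol(X)) stop2("fewer variants than exposures")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_col <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]][1]
    cc <- abs(stats::cor(X))
    diag(cc) <- 0
    partner <- colnames(X)[which.max(cc[drop_col, ])]
    stop2("rank-deficient design: exposure '", drop_col,
          "' is collinear with '", partner, "'")
  }
  XtX <- crossprod(X)
  beta <- drop(solve(XtX, crossprod(X, y)))
  cv <- solve(XtX)                # unit-variance z-score noise
  se <- sqrt(diag(cv))
  out <- data.frame(exposure = colnames(X), beta = beta, se = se,
                    pvalue = z_pvalue(beta, se), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_variants = nrow(X), exposures = colnames(X),
            class = c("mvmr_result", "data.frame"))
}
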