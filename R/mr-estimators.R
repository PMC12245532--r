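# Two-sample MR estimators on harmonized effect pairs.
#
# Notation: per instrument j, (bx_j, sx_j) is the exposure association,
# (by_j, sy_j) the outcome association; wald ratio r_j = by_j / bx_j.
# Instruments are assumed independent (post-clumping).

new_mr_estimate <- function(method, beta = NA_real_, se = NA_real_,
                            pvalue = NA_real_, n_iv = 0L,
                            intercept = NA_real_, intercept_se = NA_real_,
                            intercept_p = NA_real_, Q = NA_real_,
                            se_fixed = NA_real_, pvalue_fixed = NA_real_,
                            variant = NA_character_, estimable = TRUE,
                            note = NA_character_) {
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 n_iv = as.integer(n_iv), intercept = intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p,
                 Q = Q, se_fixed = se_fixed, pvalue_fixed = pvalue_fixed,
                 variant = variant, estimable = estimable, note = note),
            class = "mr_estimate")
}

not_estimable <- function(method, note) {
  new_mr_estimate(method, estimable = FALSE, note = note)
}

#' @export
print.mr_estimate <- function(x, ...) {
  if (!x$estimable) {
    cat(sprintf("%s: not estimable (%s)\n", x$method, x$note))
    return(invisible(x))
  }
  cat(sprintf("%s: beta = %.4g (se %.4g), p = %.3g, nIV = %d\n",
              x$method, x$beta, x$se, x$pvalue, x$n_iv))
  if (!is.na(x$intercept)) {
    cat(sprintf("  intercept = %.4g (se %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

check_pairs <- function(pairs) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop2("pairs missing columns: ",
                          paste(miss, collapse = ", "))
  pairs
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = by / bx`, `se = sy / |bx|` (first-order delta method, exposure
#' uncertainty ignored), two-sided normal p-value.
#'
#' @param pair one-row data.frame of harmonized effects.
#' @return an `mr_estimate`.
#' @export
wald_ratio <- function(pair) {
  pair <- check_pairs(pair)
  stopifnot(nrow(pair) == 1)
  if (pair$beta_exposure == 0) {
    stop2("wald_ratio undefined: exposure effect is exactly 0")
  }
  beta <- pair$beta_outcome / pair$beta_exposure
  se <- pair$se_outcome / abs(pair$beta_exposure)
  new_mr_estimate("wald", beta = beta, se = se,
                  pvalue = z_pvalue(beta, se), n_iv = 1L,
                  variant = pair$variant_id %||% NA_character_)
}

#' Inverse-variance-weighted MR
#'
#' Weighted zero-intercept regression of outcome on exposure effects with
#' weights `1/sy^2`: `beta = sum(w bx by) / sum(w bx^2)`, fixed-effect
#' `se = (sum(w bx^2))^{-1/2}`.  Cochran's Q is reported; with
#' `random_effects = "auto"` (the default) the standard error is inflated
#' by `sqrt(Q/(n-1))` when that exceeds 1 (multiplicative random effects).
#' The fixed-effect se and p are always carried alongside in `se_fixed` /
#' `pvalue_fixed` so either variant can be reported.
#'
#' @param pairs harmonized effect pairs (>= 1 row; one row delegates to
#'   [wald_ratio()]).
#' @param random_effects `"auto"`, `"fixed"`, or `"random"`.
#' @return an `mr_estimate`.
#' @export
mr_ivw <- function(pairs, random_effects = c("auto", "fixed", "random")) {
  random_effects <- match.arg(random_effects)
  pairs <- check_pairs(pairs)
  k <- nrow(pairs)
  if (k == 0) return(not_estimable("ivw", "no instruments"))
  if (k == 1) {
    est <- wald_ratio(pairs)
    est$method <- "ivw"
    est$se_fixed <- est$se
    est$pvalue_fixed <- est$pvalue
    return(est)
  }
  bx <- pairs$beta_exposure; by <- pairs$beta_outcome
  w <- 1 / pairs$se_outcome^2
  if (all(bx == 0)) stop2("ivw undefined: all exposure effects are 0")
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_f <- 1 / sqrt(sum(w * bx^2))
  Q <- sum(w * (by - beta * bx)^2)
  phi <- Q / (k - 1)
  infl <- if (random_effects == "fixed") 1 else sqrt(max(phi, 1))
  se <- se_f * infl
  new_mr_estimate("ivw", beta = beta, se = se,
                  pvalue = z_pvalue(beta, se), n_iv = k, Q = Q,
                  se_fixed = se_f, pvalue_fixed = z_pvalue(beta, se_f))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with an unconstrained
#' intercept (weights `1/sy^2`), after orienting every exposure effect
#' non-negative.  The slope is the causal estimate; the intercept estimate,
#' SE and p-value form the directional-pleiotropy balance test.  Inference
#' uses the t distribution with `n_iv - 2` degrees of freedom and the
#' regression residual scale.
#'
#' @param pairs harmonized effect pairs (>= 3 rows).
#' @return an `mr_estimate`; fewer than 3 pairs yields a not-estimable
#'   marker (recorded, not raised).
#' @export
mr_egger <- function(pairs) {
  pairs <- check_pairs(pairs)
  k <- nrow(pairs)
  if (k < 3) return(not_estimable("egger", "needs >= 3 instruments"))
  flip <- sign(pairs$beta_exposure)
  flip[flip == 0] <- 1
  bx <- pairs$beta_exposure * flip
  by <- pairs$beta_outcome * flip
  w <- 1 / pairs$se_outcome^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  cf <- solve(XtWX, crossprod(X, w * by))
  resid <- by - X %*% cf
  Q <- sum(w * resid^2)
  sigma2 <- Q / (k - 2)
  cv <- solve(XtWX) * sigma2
  se <- sqrt(diag(cv))
  cf <- unname(drop(cf))
  se <- unname(se)
  tstat <- cf / se
  pv <- 2 * pt(-abs(tstat), df = k - 2)
  new_mr_estimate("egger", beta = cf[2], se = se[2], pvalue = pv[2],
                  n_iv = k, intercept = cf[1], intercept_se = se[1],
                  intercept_p = pv[1], Q = Q)
}

# interpolated weighted median of ratios r with weights w
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  k <- length(r)
  if (s[k] < 0.5) return(r[k])
  j <- max(which(s < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median MR
#'
#' The causal estimate is the weighted median of the per-instrument Wald
#' ratios with weights `bx^2 / sy^2` (the inverse variance of each ratio),
#' linearly interpolated where the standardized cumulative weight crosses
#' 0.5.  It is consistent when instruments carrying at least half the
#' weight are valid.  The standard error comes from a parametric bootstrap
#' resampling `(bx, by)` from their reported normal errors.
#'
#' @param pairs harmonized effect pairs (>= 3 rows).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap (mandatory).
#' @return an `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed) {
  pairs <- check_pairs(pairs)
  k <- nrow(pairs)
  if (k < 3) return(not_estimable("weighted_median",
                                  "needs >= 3 instruments"))
  r <- pairs$beta_outcome / pairs$beta_exposure
  w <- pairs$beta_exposure^2 / pairs$se_outcome^2
  beta <- weighted_median_point(r, w)
  set.seed(child_seed(seed, "wmedian"))
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(k, pairs$beta_exposure, pairs$se_exposure)
    by <- rnorm(k, pairs$beta_outcome, pairs$se_outcome)
    weighted_median_point(by / bx, bx^2 / pairs$se_outcome^2)
  }, numeric(1))
  se <- sd(boot)
  new_mr_estimate("weighted_median", beta = beta, se = se,
                  pvalue = z_pvalue(beta, se), n_iv = k)
}

# weighted normal-kernel density argmax over a fixed grid
mode_point <- function(r, w, phi = 1, grid_n = 512) {
  w <- w / sum(w)
  disp <- c(sd(r), mad(r))
  disp <- disp[disp > 0]
  if (!length(disp)) return(r[1])          # all ratios identical
  h <- phi * 0.9 * min(disp) * length(r)^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = grid_n)
  dens <- vapply(grid, function(x) sum(w * dnorm(x, r, h)), numeric(1))
  grid[which.max(dens)]                     # which.max: first (smallest) tie
}

#' Weighted-mode MR
#'
#' The causal estimate is the mode of the weighted kernel density of the
#' Wald ratios (normal kernel; bandwidth `phi` times the modified Silverman
#' rule `0.9 min(sd, mad) k^{-1/5}`), evaluated on a 512-point grid
#' spanning the ratios plus/minus three bandwidths.  Weights as in
#' [mr_weighted_median()]; bootstrap standard error.
#'
#' @param pairs harmonized effect pairs (>= 3 rows).
#' @param phi bandwidth inflation factor (default 1).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed (mandatory).
#' @return an `mr_estimate`.
#' @export
mr_weighted_mode <- function(pairs, phi = 1, n_boot = 1000, seed) {
  pairs <- check_pairs(pairs)
  k <- nrow(pairs)
  if (k < 3) return(not_estimable("weighted_mode",
                                  "needs >= 3 instruments"))
  r <- pairs$beta_outcome / pairs$beta_exposure
  w <- pairs$beta_exposure^2 / pairs$se_outcome^2
  beta <- mode_point(r, w, phi)
  set.seed(child_seed(seed, "wmode"))
  boot <- vapply(seq_len(n_boot), function(i) {
    bx <- rnorm(k, pairs$beta_exposure, pairs$se_exposure)
    by <- rnorm(k, pairs$beta_outcome, pairs$se_outcome)
    mode_point(by / bx, bx^2 / pairs$se_outcome^2, phi)
  }, numeric(1))
  se <- sd(boot)
  new_mr_estimate("weighted_mode", beta = beta, se = se,
                  pvalue = z_pvalue(beta, se), n_iv = k)
}
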