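#' Fit a set of two-sample MR estimators
#'
#' The unified model interface: runs the requested estimators on one set of
#' harmonized instrument pairs and returns a classed fit with print,
#' summary, coef, confint and plot methods.
#'
#' @param pairs harmonized effect pairs (from [harmonize()] or
#'   [build_instrument_set()]`$pairs`), or an `instrument_set`.
#' @param methods subset of `c("ivw", "egger", "weighted_median",
#'   "weighted_mode")`; a single pair always falls back to the Wald ratio
#'   via the ivw path.
#' @param seed integer seed for the bootstrap-based estimators.
#' @param n_boot bootstrap replicates for median/mode (default 1000).
#' @param random_effects IVW variant, see [mr_ivw()].
#' @param phi weighted-mode bandwidth factor.
#' @param exposure_id,outcome_id labels carried into the output.
#' @return object of class `mr_fit`: list with `estimates` (named list of
#'   `mr_estimate`), `pairs`, and the labels.
#' @export
mr_fit <- function(pairs,
                   methods = c("ivw", "egger", "weighted_median",
                               "weighted_mode"),
                   seed = 1, n_boot = 1000,
                   random_effects = c("auto", "fixed", "random"),
                   phi = 1, exposure_id = NULL, outcome_id = NULL) {
  random_effects <- match.arg(random_effects)
  if (inherits(pairs, "instrument_set")) {
    exposure_id <- exposure_id %||% pairs$exposure_id
    outcome_id <- outcome_id %||% pairs$outcome_id
    pairs <- pairs$pairs
  }
  methods <- match.arg(methods, several.ok = TRUE)
  pairs <- check_pairs(pairs)
  est <- list()
  for (m in methods) {
    est[[m]] <- switch(
      m,
      ivw = mr_ivw(pairs, random_effects = random_effects),
      egger = mr_egger(pairs),
      weighted_median = mr_weighted_median(pairs, n_boot = n_boot,
                                           seed = seed),
      weighted_mode = mr_weighted_mode(pairs, phi = phi, n_boot = n_boot,
                                       seed = seed)
    )
  }
  structure(list(estimates = est, pairs = pairs,
                 exposure_id = exposure_id, outcome_id = outcome_id),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  hdr <- paste0("Two-sample MR",
                if (!is.null(x$exposure_id))
                  paste0(": ", x$exposure_id, " -> ", x$outcome_id))
  cat(hdr, " (", nrow(x$pairs), " instruments)\n", sep = "")
  for (e in x$estimates) print(e)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, conf_level = 0.95, ...) {
  tab <- as.data.frame(object)
  z <- qnorm(1 - (1 - conf_level) / 2)
  tab$or <- exp(tab$beta)
  tab$or_lo <- exp(tab$beta - z * tab$se)
  tab$or_hi <- exp(tab$beta + z * tab$se)
  structure(list(table = tab, exposure_id = object$exposure_id,
                 outcome_id = object$outcome_id,
                 conf_level = conf_level),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat("Two-sample MR summary")
  if (!is.null(x$exposure_id)) {
    cat(":", x$exposure_id, "->", x$outcome_id)
  }
  cat("\nOdds ratios per 1-SD increment of the exposure (",
      100 * x$conf_level, "% CI):\n", sep = "")
  t <- x$table
  for (i in seq_len(nrow(t))) {
    if (!t$estimable[i]) {
      cat(sprintf("  %-16s not estimable\n", t$method[i]))
    } else {
      cat(sprintf("  %-16s OR %.3f (%.3f-%.3f), p = %.3g, nIV = %d\n",
                  t$method[i], t$or[i], t$or_lo[i], t$or_hi[i],
                  t$pvalue[i], t$n_iv[i]))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  do.call(rbind, lapply(x$estimates, function(e) {
    data.frame(method = e$method, beta = e$beta, se = e$se,
               pvalue = e$pvalue, n_iv = e$n_iv, intercept = e$intercept,
               intercept_se = e$intercept_se, intercept_p = e$intercept_p,
               Q = e$Q, estimable = e$estimable,
               stringsAsFactors = FALSE)
  }))
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  out <- t(vapply(object$estimates, function(e) {
    c(e$beta - z * e$se, e$beta + z * e$se)
  }, numeric(2)))
  colnames(out) <- sprintf("%g %%", 100 * c((1 - level) / 2,
                                            1 - (1 - level) / 2))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
plot.mr_fit <- function(x, ...) {
  p <- x$pairs
  plot(p$beta_exposure, p$beta_outcome,
       xlab = "SNP effect on exposure", ylab = "SNP effect on outcome",
       pch = 19, ...)
  graphics::segments(p$beta_exposure, p$beta_outcome - 1.96 * p$se_outcome,
                     p$beta_exposure, p$beta_outcome + 1.96 * p$se_outcome,
                     col = "grey60")
  if (!is.null(x$estimates$ivw) && x$estimates$ivw$estimable) {
    graphics::abline(0, x$estimates$ivw$beta, col = "steelblue", lwd = 2)
  }
  e <- x$estimates$egger
  if (!is.null(e) && e$estimable) {
    graphics::abline(e$intercept, e$beta, col = "firebrick", lty = 2)
  }
  invisible(x)
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  e <- object$estimates[[method]]
  if (is.null(e) || !e$estimable) stop2("no estimable '", method, "' fit")
  p <- object$pairs
  bx <- p$beta_exposure
  by <- p$beta_outcome
  int <- 0
  if (!is.na(e$intercept)) {   # Egger fits on non-negatively oriented bx
    flip <- sign(bx)
    flip[flip == 0] <- 1
    bx <- bx * flip
    by <- by * flip
    int <- e$intercept
  }
  (by - int - e$beta * bx) / p$se_outcome
}
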