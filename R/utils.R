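#' @keywords internal
"_PACKAGE"

#' @importFrom stats pnorm pt qnorm rnorm rbinom runif rgamma dnorm density
#'   lm coef p.adjust phyper setNames complete.cases sd mad median quantile
#'   rnbinom t.test var aggregate
#' @importFrom utils read.delim write.table head
#' @importFrom methods as
#' @importFrom graphics abline segments
NULL

# two-sided normal p-value from an effect and its SE, guarded against se = 0
z_pvalue <- function(beta, se) {
  p <- 2 * pnorm(-abs(beta / se))
  pmax(p, .Machine$double.xmin)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

# symmetrize and clip eigenvalues so a correlation-like matrix is PSD
project_psd <- function(R, tol = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -tol) return(R)
  v <- pmax(e$values, 0)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

# derive a reproducible child seed from a base seed and a label
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(paste0(label)) * seq_along(utf8ToInt(paste0(label))))
  # keep headroom below .Machine$integer.max so callers can add offsets
  (as.integer(seed) * 1009L + (h %% 1000003L)) %% 2100000000L
}
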