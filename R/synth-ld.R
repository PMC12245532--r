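# Synthetic LD blocks: AR(1)-style correlation with optional jitter,
# re-projected to the PSD cone so downstream Cholesky sampling is safe.

ar1_matrix <- function(size, decay) {
  idx <- seq_len(size)
  decay^abs(outer(idx, idx, "-"))
}

new_ld_block <- function(variant_ids, R, tol = 1e-8) {
  stopifnot(length(variant_ids) == nrow(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > tol) stop2("LD matrix is not symmetric")
  if (max(abs(diag(R) - 1)) > tol) stop2("LD matrix diagonal is not 1")
  if (any(R < -1 - tol | R > 1 + tol)) stop2("LD entries outside [-1, 1]")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol) {
    stop2("LD matrix is not positive semi-definite (min eigenvalue ",
          format(min(ev)), ")")
  }
  dimnames(R) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), R = R),
            class = "ld_block")
}

#' Simulate synthetic LD blocks
#'
#' Generates square variant-correlation blocks with exponential decay
#' \eqn{r(i,j) = \mathrm{decay}^{|i-j|}}, optionally perturbed by symmetric
#' jitter and re-projected onto the positive semi-definite cone (with the
#' unit diagonal restored).  `decay = 0` yields independent variants,
#' `decay = 1` perfect LD.
#'
#' @param n_blocks number of blocks.
#' @param block_size variants per block.
#' @param decay correlation decay rate per index step, in `[0, 1]`.
#' @param seed integer seed; the output is deterministic given it.
#' @param jitter standard deviation of symmetric noise added to the
#'   off-diagonal entries before re-projection (0 = exact AR structure).
#' @param variant_ids optional list (length `n_blocks`) of character vectors
#'   naming the variants of each block; defaults to `b<k>_v<i>`.
#' @return list of `ld_block` objects, each with `$variant_ids` and `$R`.
#' @export
simulate_ld_blocks <- function(n_blocks, block_size, decay, seed,
                               jitter = 0, variant_ids = NULL) {
  stopifnot(n_blocks >= 1, block_size >= 1, decay >= 0, decay <= 1,
            jitter >= 0)
  if (!is.null(variant_ids)) stopifnot(length(variant_ids) == n_blocks)
  set.seed(as.integer(seed))
  lapply(seq_len(n_blocks), function(b) {
    R <- ar1_matrix(block_size, decay)
    if (jitter > 0 && block_size > 1) {
      E <- matrix(rnorm(block_size^2, sd = jitter), block_size)
      E <- (E + t(E)) / 2
      diag(E) <- 0
      R <- pmin(pmax(R + E, -1), 1)
      diag(R) <- 1
      R <- project_psd(R)
    }
    ids <- if (is.null(variant_ids)) {
      sprintf("b%d_v%d", b, seq_len(block_size))
    } else variant_ids[[b]]
    new_ld_block(ids, R)
  })
}

# lookup table: variant id -> (block index, position within block)
ld_index <- function(ld_blocks) {
  ids <- unlist(lapply(ld_blocks, `[[`, "variant_ids"), use.names = FALSE)
  if (anyDuplicated(ids)) stop2("duplicate variant ids across LD blocks")
  data.frame(
    variant_id = ids,
    block = rep(seq_along(ld_blocks),
                vapply(ld_blocks, function(b) length(b$variant_ids), 1L)),
    within = unlist(lapply(ld_blocks,
                           function(b) seq_along(b$variant_ids)),
                    use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

# pairwise r for two variants; 0 if they live in different blocks
ld_r <- function(ld_blocks, idx, v1, v2) {
  i <- match(v1, idx$variant_id)
  j <- match(v2, idx$variant_id)
  if (is.na(i) || is.na(j)) return(NA_real_)
  if (idx$block[i] != idx$block[j]) return(0)
  ld_blocks[[idx$block[i]]]$R[idx$within[i], idx$within[j]]
}

#' Write / read LD blocks as plain-text matrices
#'
#' Each block `k` becomes `<prefix>_block<k>.tsv` (dense numeric matrix) and
#' `<prefix>_block<k>.variants.tsv` (one variant id per line).
#'
#' @param ld_blocks list of `ld_block` objects.
#' @param prefix file path prefix.
#' @return `write_ld_blocks` the file prefix, invisibly; `read_ld_blocks`
#'   a list of `ld_block` objects.
#' @export
write_ld_blocks <- function(ld_blocks, prefix) {
  for (k in seq_along(ld_blocks)) {
    b <- ld_blocks[[k]]
    write.table(b$R, sprintf("%s_block%d.tsv", prefix, k),
                sep = "\t", row.names = FALSE, col.names = FALSE)
    writeLines(b$variant_ids, sprintf("%s_block%d.variants.tsv", prefix, k))
  }
  invisible(prefix)
}

#' @rdname write_ld_blocks
#' @export
read_ld_blocks <- function(prefix) {
  files <- Sys.glob(sprintf("%s_block*.variants.tsv", prefix))
  if (!length(files)) stop2("no LD block files found at prefix ", prefix)
  ord <- order(as.integer(sub(".*_block(\\d+)\\.variants\\.tsv$", "\\1",
                              files)))
  lapply(files[ord], function(f) {
    ids <- readLines(f)
    R <- as.matrix(read.delim(sub("\\.variants\\.tsv$", ".tsv", f),
                              header = FALSE))
    dimnames(R) <- NULL
    new_ld_block(ids, R)
  })
}
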