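# Shared format layer: summary-statistics tables, gene annotations, and
# exposure/outcome allele harmonization.

SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' Summary-statistics container
#'
#' A `sumstats` object is a data.frame with columns `variant_id`, `chrom`,
#' `pos` (1-based), `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#' `pvalue`, `n`, plus attributes `trait_id`, `trait_kind`
#' (protein/disease/quantitative_biomarker/medication) and `ancestry`.
#'
#' @param x data.frame with the schema columns.
#' @param trait_id,trait_kind,ancestry trait metadata.
#' @return a validated `sumstats` data.frame.
#' @export
as_sumstats <- function(x, trait_id = NA_character_,
                        trait_kind = NA_character_,
                        ancestry = NA_character_) {
  miss <- setdiff(SUMSTATS_COLS, names(x))
  if (length(miss)) stop2("missing columns: ", paste(miss, collapse = ", "))
  x <- as.data.frame(x)[, SUMSTATS_COLS]
  x$chrom <- as.character(x$chrom)
  if (anyDuplicated(x$variant_id)) {
    stop2("duplicate variant ids: ",
          paste(head(unique(x$variant_id[duplicated(x$variant_id)]), 3),
                collapse = ", "))
  }
  if (any(x$se <= 0, na.rm = TRUE)) stop2("se must be > 0")
  if (any(x$eaf <= 0 | x$eaf >= 1, na.rm = TRUE)) {
    stop2("eaf must lie strictly in (0, 1)")
  }
  if (any(x$pvalue <= 0 | x$pvalue > 1, na.rm = TRUE)) {
    stop2("pvalue must lie in (0, 1]")
  }
  rownames(x) <- NULL
  structure(x, trait_id = trait_id, trait_kind = trait_kind,
            ancestry = ancestry,
            class = c("sumstats", "data.frame"))
}

#' Read / write GWAS summary statistics
#'
#' Tab-separated files with exactly the schema header (see
#' [as_sumstats()]).  Rows with missing beta or se are dropped with a
#' message; unknown columns or duplicated variant ids are errors.
#'
#' @param path file path.
#' @param trait_id,trait_kind,ancestry metadata attached to the result
#'   (defaults recovered from a `# trait:` comment line if present).
#' @return a `sumstats` data.frame.
#' @export
read_sumstats <- function(path, trait_id = NA_character_,
                          trait_kind = NA_character_,
                          ancestry = NA_character_) {
  if (!file.exists(path)) stop2("file not found: ", path)
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    meta <- strsplit(sub("^#\\s*trait:\\s*", "", first), "\t")[[1]]
    if (length(meta) == 3) {
      if (is.na(trait_id)) trait_id <- meta[1]
      if (is.na(trait_kind)) trait_kind <- meta[2]
      if (is.na(ancestry)) ancestry <- meta[3]
    }
  }
  x <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                  colClasses = c(chrom = "character"))
  extra <- setdiff(names(x), SUMSTATS_COLS)
  if (length(extra)) {
    stop2("unknown columns in ", path, ": ", paste(extra, collapse = ", "),
          " (expected header: ", paste(SUMSTATS_COLS, collapse = ", "), ")")
  }
  miss <- setdiff(SUMSTATS_COLS, names(x))
  if (length(miss)) stop2("missing columns: ", paste(miss, collapse = ", "))
  bad <- !complete.cases(x[, c("beta", "se")]) |
    (!is.na(x$se) & x$se <= 0)
  if (any(bad)) {
    message("read_sumstats: dropped ", sum(bad),
            " row(s) with missing/invalid beta or se")
    x <- x[!bad, , drop = FALSE]
  }
  as_sumstats(x, trait_id = trait_id, trait_kind = trait_kind,
              ancestry = ancestry)
}

#' @rdname read_sumstats
#' @param x a `sumstats` object.
#' @export
write_sumstats <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trait:\t%s\t%s\t%s", attr(x, "trait_id"),
                     attr(x, "trait_kind"), attr(x, "ancestry")), con)
  suppressWarnings(write.table(as.data.frame(x), con, sep = "\t",
                               quote = FALSE, row.names = FALSE))
  invisible(path)
}

#' Read gene annotations
#'
#' Accepts BED (0-based half-open; columns chrom, start, stop, name, and
#' optionally a protein id in column 5) or a native TSV with 1-based
#' inclusive coordinates and header
#' `gene_id, protein_id, chrom, start, stop`.  BED coordinates are
#' converted to 1-based inclusive on read.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"bed"`, or `"tsv"`.
#' @return data.frame with columns gene_id, protein_id, chrom, start, stop.
#' @export
read_gene_annotations <- function(path, format = c("auto", "bed", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  }
  if (format == "bed") {
    x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(x) < 4) stop2("BED file needs >= 4 columns")
    out <- data.frame(
      gene_id = as.character(x[[4]]),
      protein_id = if (ncol(x) >= 5) as.character(x[[5]])
                   else as.character(x[[4]]),
      chrom = as.character(x[[1]]),
      start = as.integer(x[[2]]) + 1L,   # 0-based -> 1-based
      stop = as.integer(x[[3]]),         # half-open end == 1-based stop
      stringsAsFactors = FALSE
    )
  } else {
    out <- read.delim(path, stringsAsFactors = FALSE,
                      colClasses = c(chrom = "character"))
    need <- c("gene_id", "protein_id", "chrom", "start", "stop")
    miss <- setdiff(need, names(out))
    if (length(miss)) stop2("missing columns: ", paste(miss, collapse = ", "))
    out <- out[, need]
  }
  if (any(out$start > out$stop)) stop2("gene interval with start > stop")
  if (any(!nzchar(out$chrom))) stop2("empty chrom in gene annotation")
  out
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  !is.na(comp[a1]) & comp[a1] == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome's effects to the exposure's effect allele.  When the
#' outcome reports the swapped allele pair, the outcome beta is negated and
#' its EAF complemented (`flipped = TRUE`).  Palindromic variants (A/T,
#' C/G) whose minor-allele frequency exceeds `palindromic_maf` are dropped
#' as strand-ambiguous; incompatible allele pairs are dropped with a reason
#' code.  Strand is assumed forward in both studies; set
#' `infer_strand = TRUE` to rescue incompatible pairs whose
#' strand-complemented alleles match and whose frequencies agree.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param variant_ids variants to harmonize (default: intersection).
#' @param palindromic_maf MAF above which palindromic variants are dropped.
#' @param infer_strand attempt frequency-based strand inference.
#' @return data.frame of harmonized pairs (columns `variant_id`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure`, `eaf_outcome`, `flipped`, `palindromic`), with an
#'   attribute `dropped` recording removed variants and reasons.
#' @export
harmonize <- function(exposure, outcome, variant_ids = NULL,
                      palindromic_maf = 0.42, infer_strand = FALSE) {
  if (is.null(variant_ids)) {
    variant_ids <- intersect(exposure$variant_id, outcome$variant_id)
  }
  ex <- exposure[match(variant_ids, exposure$variant_id), ]
  oy <- outcome[match(variant_ids, outcome$variant_id), ]
  if (anyNA(ex$variant_id) || anyNA(oy$variant_id)) {
    stop2("requested variants missing from exposure or outcome")
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  n <- length(variant_ids)
  keep <- rep(TRUE, n)
  flipped <- rep(FALSE, n)
  reason <- rep(NA_character_, n)
  beta_o <- oy$beta
  eaf_o <- oy$eaf
  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  same <- oy$effect_allele == ex$effect_allele &
    oy$other_allele == ex$other_allele
  swap <- oy$effect_allele == ex$other_allele &
    oy$other_allele == ex$effect_allele
  beta_o[swap] <- -beta_o[swap]
  eaf_o[swap] <- 1 - eaf_o[swap]
  flipped[swap] <- TRUE

  other <- !(same | swap)
  if (any(other) && infer_strand) {
    flp_e <- unname(comp[oy$effect_allele])
    flp_o <- unname(comp[oy$other_allele])
    s_same <- other & flp_e == ex$effect_allele & flp_o == ex$other_allele
    s_swap <- other & flp_e == ex$other_allele & flp_o == ex$effect_allele
    freq_ok <- abs(eaf_o - ex$eaf) < abs((1 - eaf_o) - ex$eaf)
    beta_o[s_swap] <- -beta_o[s_swap]
    eaf_o[s_swap] <- 1 - eaf_o[s_swap]
    flipped[s_swap] <- TRUE
    rescued <- (s_same & freq_ok) | (s_swap & !freq_ok)
    other <- other & !rescued
  }
  keep[other] <- FALSE
  reason[other] <- "incompatible_alleles"

  maf <- pmin(ex$eaf, 1 - ex$eaf)
  ambig <- pal & maf > palindromic_maf
  keep[keep & ambig] <- FALSE
  reason[is.na(reason) & ambig] <- "palindromic_ambiguous"

  out <- data.frame(
    variant_id = variant_ids,
    beta_exposure = ex$beta, se_exposure = ex$se,
    beta_outcome = beta_o, se_outcome = oy$se,
    eaf_exposure = ex$eaf, eaf_outcome = eaf_o,
    flipped = flipped, palindromic = pal,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- data.frame(
    variant_id = variant_ids[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  out
}
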