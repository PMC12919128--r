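# Rule-based screens for rare loss-of-function signatures: severe expression
# downregulation in candidate ALS genes, allele-balance imbalance at
# heterozygous sites, and carrier-unique splice junctions near rare variants.

#' IQR-based severe downregulation screen
#'
#' For each candidate gene, computes the robust score
#' `(value - median) / IQR` per sample and flags samples scoring below `-k`
#' (default 3 interquartile ranges below the cohort median).  Values are
#' expected to be batch-corrected upstream.
#'
#' @param expression numeric gene x sample matrix (rownames = genes).
#' @param genes candidate genes to screen; defaults to all rows.
#' @param k IQR multiplier (default 3).
#' @return Data frame: gene, sample, value, score, flagged.  Genes with zero
#'   IQR or absent from the matrix are skipped with a warning.
#' @export
iqr_outliers <- function(expression, genes = NULL, k = 3) {
  stopifnot(is.matrix(expression))
  if (ncol(expression) < 8) stop("need at least 8 samples per gene")
  if (is.null(genes)) genes <- rownames(expression)
  absent <- setdiff(genes, rownames(expression))
  if (length(absent) > 0) {
    warning("candidate gene(s) absent from matrix, skipped: ",
            paste(absent, collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  out <- list()
  for (g in genes) {
    x <- expression[g, ]
    med <- stats::median(x)
    iqr <- stats::IQR(x)
    if (iqr == 0) {
      warning("gene ", g, " has zero IQR, skipped")
      next
    }
    score <- (x - med) / iqr
    out[[g]] <- data.frame(gene = g, sample = colnames(expression),
                           value = unname(x), score = unname(score),
                           flagged = unname(score < -k),
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), sample = character(0),
                      value = numeric(0), score = numeric(0),
                      flagged = logical(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pooled allele-balance imbalance test
#'
#' Pools reference/alternate read counts across heterozygous sites of one
#' sample x gene and tests the pooled alternate fraction against the
#' balanced expectation 0.5 with a two-sided exact binomial test.  Strong
#' imbalance suggests allele-specific silencing of one copy.
#'
#' @param ref_counts reference-allele read counts, one per site.
#' @param alt_counts alternate-allele read counts, one per site.
#' @return A list: `ref`, `alt`, `total`, `fraction` (pooled alt fraction),
#'   `imbalance` (|fraction - 0.5|), `p`.
#' @examples
#' allele_balance(10, 0)$p  # 2 * 0.5^10
#' @export
allele_balance <- function(ref_counts, alt_counts) {
  stopifnot(length(ref_counts) == length(alt_counts))
  if (any(ref_counts < 0) || any(alt_counts < 0)) stop("negative read counts")
  ref <- sum(ref_counts); alt <- sum(alt_counts)
  total <- ref + alt
  if (total == 0) stop("zero total reads: allele balance undefined")
  bt <- stats::binom.test(alt, total, p = 0.5)
  list(ref = ref, alt = alt, total = total, fraction = alt / total,
       imbalance = abs(alt / total - 0.5), p = bt$p.value)
}

#' Rank samples by allele-balance imbalance
#'
#' Applies [allele_balance()] per (sample, gene) group of an allele-count
#' table and ranks by imbalance (descending), breaking ties by p-value.
#'
#' @param allele_counts data frame with columns `sample`, `gene`, `ref`,
#'   `alt` (one row per heterozygous site).
#' @return Data frame sorted by rank: sample, gene, n_sites, ref, alt,
#'   fraction, imbalance, p, rank.
#' @export
ase_ranking <- function(allele_counts) {
  stopifnot(all(c("sample", "gene", "ref", "alt") %in% names(allele_counts)))
  key <- interaction(allele_counts$sample, allele_counts$gene, drop = TRUE)
  rows <- lapply(split(allele_counts, key), function(d) {
    ab <- allele_balance(d$ref, d$alt)
    data.frame(sample = d$sample[1], gene = d$gene[1], n_sites = nrow(d),
               ref = ab$ref, alt = ab$alt, fraction = ab$fraction,
               imbalance = ab$imbalance, p = ab$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$imbalance, res$p), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Detect carrier-unique splice junctions near rare variants
#'
#' Flags junctions supported by at least `min_count` reads in exactly one
#' sample and fewer than `noise_count` reads in every other sample, then
#' joins each flagged junction to rare variants carried uniquely by that
#' sample within `window` bp of either splice site.  This is the automated
#' counterpart of checking that a cryptic splicing event is unique to the
#' candidate carrier across the whole cohort.
#'
#' @param junctions junction x sample count matrix with rownames of the form
#'   `"chrom:start-end"` (0-based half-open intron coordinates).
#' @param min_count minimum supporting reads in the carrier (default 5).
#' @param noise_count strict upper bound for all other samples (default 2,
#'   tolerating stray mismapped reads).
#' @param variants optional rare-variant table: `sample`, `chrom`, `pos`
#'   (0-based), `id`.
#' @param window linkage window in bp around either splice site.
#' @return Data frame: junction, chrom, start, end, carrier, count,
#'   max_other, variants (comma-separated ids, "" if none).
#' @export
unique_junctions <- function(junctions, min_count = 5, noise_count = 2,
                             variants = NULL, window = 100) {
  stopifnot(is.matrix(junctions), min_count > noise_count, noise_count >= 0)
  coord <- regmatches(rownames(junctions),
                      regexec("^(.+):([0-9]+)-([0-9]+)$", rownames(junctions)))
  out <- list()
  for (r in seq_len(nrow(junctions))) {
    v <- junctions[r, ]
    top <- which.max(v)
    others <- v[-top]
    if (v[top] >= min_count && all(others < noise_count) &&
        sum(v >= min_count) == 1) {
      cc <- coord[[r]]
      chrom <- if (length(cc) == 4) cc[2] else NA_character_
      start <- if (length(cc) == 4) as.numeric(cc[3]) else NA_real_
      end   <- if (length(cc) == 4) as.numeric(cc[4]) else NA_real_
      carrier <- colnames(junctions)[top]
      linked <- ""
      if (!is.null(variants) && !is.na(start)) {
        # variants carried by exactly one sample, and that sample is the carrier
        vcount <- table(variants$id)
        uniq <- names(vcount)[vcount == 1]
        cand <- variants[variants$id %in% uniq & variants$sample == carrier &
                           variants$chrom == chrom, , drop = FALSE]
        near <- abs(cand$pos - start) <= window | abs(cand$pos - end) <= window
        if (any(near)) linked <- paste(cand$id[near], collapse = ",")
      }
      out[[length(out) + 1]] <- data.frame(
        junction = rownames(junctions)[r], chrom = chrom, start = start,
        end = end, carrier = carrier, count = unname(v[top]),
        max_other = if (length(others)) max(others) else 0,
        variants = linked, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(junction = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      carrier = character(0), count = numeric(0),
                      max_other = numeric(0), variants = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
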