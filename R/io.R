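# Readers and writers for the formats the pipeline touches.  Genomic
# coordinates are 0-based half-open internally; BED is native and VCF
# positions are converted from 1-based at the file boundary.

#' Read unphased genotypes for selected SNPs from a VCF
#'
#' Extracts the genotype at each requested biallelic SNP (matched by ID) and
#' decodes it to an unordered allele pair; phase separators are ignored and
#' missing genotypes become `NA`.
#'
#' @param path path to a VCF file.
#' @param snp_ids SNP identifiers that must be present.
#' @return Data frame with a `sample` column and one column per SNP holding
#'   sorted `"X/Y"` allele strings (or `NA`), plus attribute `positions`
#'   (0-based) for the records used.
#' @export
read_genotypes <- function(path, snp_ids = c("rs2492816", "rs13691", "rs113860022")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  hit <- match(snp_ids, fix[, "ID"])
  if (anyNA(hit)) {
    stop("SNP not found in VCF: ", paste(snp_ids[is.na(hit)], collapse = ", "))
  }
  multi <- grepl(",", fix[hit, "ALT"], fixed = TRUE)
  if (any(multi)) {
    stop("multiallelic record(s) for: ", paste(snp_ids[multi], collapse = ", "))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (j in seq_along(snp_ids)) {
    i <- hit[j]
    alleles <- c(fix[i, "REF"], fix[i, "ALT"])
    raw <- gt[i, ]
    decoded <- vapply(strsplit(ifelse(is.na(raw), "./.", raw), "[/|]"), function(a) {
      if (length(a) != 2 || any(a == ".")) return(NA_character_)
      letters <- alleles[as.integer(a) + 1]
      if (anyNA(letters)) return(NA_character_)
      paste(sort(letters), collapse = "/")
    }, character(1))
    out[[snp_ids[j]]] <- unname(decoded)
  }
  attr(out, "positions") <- stats::setNames(as.integer(fix[hit, "POS"]) - 1L, snp_ids)
  out
}

#' Read a clinical survival table
#'
#' Expects tab-separated columns `sample`, `status`, `hre`, `survival_months`,
#' `onset_site`.  Rows with missing or non-positive survival are dropped with
#' a logged count; an onset-site filter is applied when given.
#'
#' @param path path to a TSV file.
#' @param onset_sites retain only these onset sites (`NULL` keeps all).
#' @return Data frame of survival records; duplicated patient ids are a hard
#'   error.
#' @export
read_clinical <- function(path, onset_sites = c("limb", "bulbar")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "status", "hre", "survival_months", "onset_site")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols) > 0) {
    stop("clinical table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(d$sample)) {
    stop("duplicated patient id(s): ",
         paste(unique(d$sample[duplicated(d$sample)]), collapse = ", "))
  }
  bad <- is.na(d$survival_months) | d$survival_months <= 0
  if (any(bad)) {
    message(sum(bad), " record(s) dropped for missing or non-positive survival")
    d <- d[!bad, , drop = FALSE]
  }
  if (!is.null(onset_sites)) {
    drop <- !d$onset_site %in% onset_sites
    if (any(drop)) {
      message(sum(drop), " record(s) dropped by onset-site filter")
      d <- d[!drop, , drop = FALSE]
    }
  }
  d$hre <- as.logical(d$hre)
  rownames(d) <- NULL
  d
}

#' Read longitudinal ALSFRS-R visits
#'
#' @param path TSV with columns `sample`, `month`, `score`.
#' @return Data frame of visits.
#' @export
read_visits <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "month", "score") %in% names(d)))
  d
}

#' Read a genes-by-samples expression matrix
#'
#' @param path TSV with gene ids in the first column and one column per
#'   sample.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Read a junction-by-sample count matrix
#'
#' @param path TSV with junction ids (`chrom:start-end`) in the first column.
#' @return Numeric matrix with junction rownames.
#' @export
read_junction_counts <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Read per-site allele read counts
#'
#' @param path TSV with columns `sample`, `gene`, `site`, `ref`, `alt`.
#' @return Data frame of allele counts.
#' @export
read_allele_counts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "gene", "ref", "alt") %in% names(d)))
  d
}

#' Read a BED peak set
#'
#' @param path BED file of peak intervals.
#' @return Data frame: chrom, start, end (0-based half-open), peak_id.
#' @export
read_peaks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm)) {
    nm <- sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(gr)),
                  GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr))
  }
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             peak_id = nm, stringsAsFactors = FALSE)
}

#' Read per-sample ATAC read 5' ends from BED
#'
#' Each record is a single-base interval holding the 5' end of one read in
#' genome coordinates, with the sample id in the name field and the read
#' strand in the strand field; apply [shift_cuts()] to obtain Tn5 insertion
#' coordinates.
#'
#' @param path BED6 file.
#' @return Data frame: sample, chrom, pos (0-based), strand.
#' @export
read_cut_events <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(sample = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             pos = GenomicRanges::start(gr) - 1L,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a result table as TSV at full precision
#'
#' Numeric columns are serialized with 17 significant digits so that writing
#' and re-reading preserves values exactly.
#'
#' @param d data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(d, path) {
  fmt <- d
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) fmt[[j]] <- formatC(fmt[[j]], digits = 17, format = "g")
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# ---- writing synthetic cohorts to disk --------------------------------------

#' Write a simulated cohort in the dialects the pipeline reads
#'
#' Emits `genotypes.vcf` (synthetic positions on chr9), `clinical.tsv`,
#' `visits.tsv`, `expression.tsv`, `junctions.tsv`, `allele_counts.tsv`,
#' `variants.tsv`, `covariates.tsv`, `peaks.bed` and `cuts.bed` (read 5'
#' ends, i.e. the inverse of the +5/-4 shift applied to the simulated
#' insertion coordinates), so the pipeline consumes synthetic data through
#' the same readers as real data.
#'
#' @param cohort a `sim_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- cohort$samples

  # genotypes: minimal synthetic VCFv4.2 (positions are placeholders)
  snps <- data.frame(id = c("rs2492816", "rs13691", "rs113860022"),
                     pos0 = c(27573000L, 27573500L, 27574000L),
                     ref = c("G", "G", "C"), alt = c("A", "A", "G"),
                     stringsAsFactors = FALSE)
  gt_code <- function(dose) c("0/0", "0/1", "1/1")[dose + 1]
  header <- c("##fileformat=VCFv4.2",
              "##source=c9wta synthetic cohort generator",
              "##contig=<ID=chr9>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", s$sample), collapse = "\t"))
  body <- vapply(seq_len(nrow(snps)), function(k) {
    dose <- s[[paste0("dose_", snps$id[k])]]
    paste(c("chr9", snps$pos0[k] + 1L, snps$id[k], snps$ref[k], snps$alt[k],
            ".", "PASS", ".", "GT", gt_code(dose)), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), file.path(dir, "genotypes.vcf"))

  if (!is.null(cohort$clinical)) {
    write_result_table(cohort$clinical, file.path(dir, "clinical.tsv"))
  }
  if (!is.null(cohort$visits)) {
    write_result_table(cohort$visits, file.path(dir, "visits.tsv"))
  }
  if (!is.null(cohort$expression)) {
    ex <- data.frame(gene = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
    write_result_table(ex, file.path(dir, "expression.tsv"))
  }
  if (!is.null(cohort$junctions)) {
    jx <- data.frame(junction = rownames(cohort$junctions),
                     cohort$junctions, check.names = FALSE)
    write_result_table(jx, file.path(dir, "junctions.tsv"))
  }
  if (!is.null(cohort$allele_counts)) {
    write_result_table(cohort$allele_counts, file.path(dir, "allele_counts.tsv"))
  }
  if (!is.null(cohort$variants)) {
    write_result_table(cohort$variants, file.path(dir, "variants.tsv"))
  }
  if (!is.null(cohort$covariates)) {
    cv <- data.frame(sample = rownames(cohort$covariates), cohort$covariates)
    write_result_table(cv, file.path(dir, "covariates.tsv"))
  }
  if (!is.null(cohort$peaks)) {
    gr <- GenomicRanges::GRanges(
      cohort$peaks$chrom,
      IRanges::IRanges(start = cohort$peaks$start + 1, end = cohort$peaks$end),
      name = cohort$peaks$peak_id)
    rtracklayer::export(gr, file.path(dir, "peaks.bed"), format = "BED")
  }
  if (!is.null(cohort$cuts)) {
    # invert the +5/-4 shift to store read 5' ends
    p5 <- cohort$cuts$pos - ifelse(cohort$cuts$strand == "+", 5L, -4L)
    gr <- GenomicRanges::GRanges(cohort$cuts$chrom,
                                 IRanges::IRanges(start = p5 + 1, width = 1),
                                 strand = cohort$cuts$strand,
                                 name = cohort$cuts$sample,
                                 score = 0L)
    rtracklayer::export(gr, file.path(dir, "cuts.bed"), format = "BED")
  }
  invisible(dir)
}

#' Load a cohort directory written by [write_cohort()]
#'
#' @param dir directory path.
#' @param onset_sites onset-site filter passed to [read_clinical()].
#' @return A list of tables in the layout [run_pipeline()] expects.
#' @export
load_cohort_dir <- function(dir, onset_sites = c("limb", "bulbar")) {
  path <- function(f) file.path(dir, f)
  tables <- list(genotypes = read_genotypes(path("genotypes.vcf")))
  if (file.exists(path("clinical.tsv"))) {
    tables$clinical <- read_clinical(path("clinical.tsv"), onset_sites)
  }
  if (file.exists(path("visits.tsv"))) tables$visits <- read_visits(path("visits.tsv"))
  if (file.exists(path("expression.tsv"))) {
    tables$expression <- read_expression_matrix(path("expression.tsv"))
  }
  if (file.exists(path("junctions.tsv"))) {
    tables$junctions <- read_junction_counts(path("junctions.tsv"))
  }
  if (file.exists(path("allele_counts.tsv"))) {
    tables$allele_counts <- read_allele_counts(path("allele_counts.tsv"))
  }
  if (file.exists(path("variants.tsv"))) {
    tables$variants <- utils::read.delim(path("variants.tsv"), stringsAsFactors = FALSE)
  }
  if (file.exists(path("covariates.tsv"))) {
    cv <- utils::read.delim(path("covariates.tsv"), stringsAsFactors = FALSE)
    rownames(cv) <- cv$sample
    tables$covariates <- cv[, setdiff(names(cv), "sample"), drop = FALSE]
  }
  if (file.exists(path("peaks.bed"))) tables$peaks <- read_peaks(path("peaks.bed"))
  if (file.exists(path("cuts.bed"))) tables$cuts <- read_cut_events(path("cuts.bed"))
  tables
}
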