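#' Default pipeline configuration
#'
#' Central container for the constants the modifier analysis depends on: the
#' three C9orf72 regulatory SNPs with their ref/alt alleles, the haplotype the
#' hexanucleotide repeat expansion (HRE) travels on, trimming fraction,
#' ALSFRS-R anchors/threshold, the footprint-test covariates, and the outlier
#' screen parameters.
#'
#' Alleles follow dbSNP orientation with the alt allele chosen so that the
#' reported per-allele expression slopes apply to alt dosage: rs2492816 G>A
#' (+), rs13691 G>A (-), rs113860022 C>G (-).  The HRE haplotype is
#' rs2492816-A / rs13691-G / rs113860022-C, i.e. the C9-high background.
#'
#' @param ... named overrides for any default entry.
#' @return A list of class `c9wta_config`.
#' @examples
#' cfg <- default_config(trim_frac = 0.1)
#' cfg$snps
#' @export
default_config <- function(...) {
  cfg <- list(
    snps = data.frame(
      id  = c("rs2492816", "rs13691", "rs113860022"),
      ref = c("G", "G", "C"),
      alt = c("A", "A", "G"),
      stringsAsFactors = FALSE
    ),
    # allele carried by the expanded (mutant) chromosome at each SNP, in
    # snps$id order: the C9-high background
    hre_haplotype    = c("A", "G", "C"),
    trim_frac        = 0.05,
    alsfrs_threshold = 24,
    scan_range       = 3:45,
    onset_sites      = c("limb", "bulbar"),
    outlier_k        = 3,
    outlier_genes    = c("NEK1", "OPTN", "TBK1", "SETX", "SPG11", "ATP13A2"),
    junction_min_count   = 5,
    junction_noise_count = 2,
    junction_window      = 100,
    footprint_covariates = c("sex", "frip"),
    missing_hap_eps  = 0.005,
    em_tol           = 1e-8,
    em_max_iter      = 10000L,
    seed             = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "c9wta_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a list as returned by [default_config()].
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.data.frame(cfg$snps) || nrow(cfg$snps) != 3 ||
      !all(c("id", "ref", "alt") %in% names(cfg$snps))) {
    stop("config 'snps' must be a 3-row data frame with id/ref/alt columns")
  }
  if (cfg$trim_frac < 0 || cfg$trim_frac >= 0.5) {
    stop("trim_frac must lie in [0, 0.5)")
  }
  if (cfg$alsfrs_threshold < 0 || cfg$alsfrs_threshold > 48) {
    stop("alsfrs_threshold must lie within [0, 48]")
  }
  if (length(cfg$hre_haplotype) != 3) {
    stop("hre_haplotype must give one allele per SNP")
  }
  ok <- cfg$hre_haplotype == cfg$snps$ref | cfg$hre_haplotype == cfg$snps$alt
  if (!all(ok)) {
    stop("hre_haplotype alleles must be drawn from each SNP's ref/alt set")
  }
  invisible(cfg)
}

#' Read a configuration from a YAML file
#'
#' Entries present in the file override the defaults of [default_config()];
#' the `snps` entry, if given, must be a list of three records with
#' `id`/`ref`/`alt` fields.
#'
#' @param path path to a YAML file.
#' @return A validated `c9wta_config` list.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$snps)) {
    raw$snps <- do.call(rbind, lapply(raw$snps, function(s) {
      data.frame(id = s$id, ref = s$ref, alt = s$alt, stringsAsFactors = FALSE)
    }))
  }
  do.call(default_config, raw)
}
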