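# ---- founder haplotype bookkeeping ------------------------------------------

#' Founder haplotypes of the C9orf72 regulatory locus
#'
#' The four ancestral allele combinations over rs2492816 / rs13691 /
#' rs113860022 observed in the population, coded by increasing wild-type
#' allele (WTA) C9orf72 expression: 0 = C9-super-low (G,A,G), 1 = C9-low
#' (G,A,C), 2 = C9-medium (G,G,C), 3 = C9-high (A,G,C).  The rs2492816-A /
#' rs13691-A combination is absent from the population, and the repeat
#' expansion travels on the C9-high background.
#'
#' @return A data frame with columns `haplotype` (three-letter allele string),
#'   `code` (integer 0-3) and `label`.
#' @examples
#' founder_haplotypes()
#' @export
founder_haplotypes <- function() {
  data.frame(
    haplotype = c("GAG", "GAC", "GGC", "AGC"),
    code      = 0:3,
    label     = c("C9-super-low", "C9-low", "C9-medium", "C9-high"),
    stringsAsFactors = FALSE
  )
}

# normalize an unphased genotype string to sorted "X/Y" form; NA passes through
norm_geno <- function(g) {
  ifelse(is.na(g) | g == "", NA_character_, vapply(strsplit(g, "[/|]"), function(a) {
    if (length(a) != 2 || any(a %in% c(".", ""))) return(NA_character_)
    paste(sort(a), collapse = "/")
  }, character(1)))
}

# allele pair of a normalized genotype string
geno_alleles <- function(g) strsplit(g, "/", fixed = TRUE)[[1]]

# enumerate the full haplotype space (cartesian product of per-SNP alleles);
# returns a character matrix, one haplotype per row
hap_space <- function(alleles) {
  grid <- expand.grid(rev(alleles), stringsAsFactors = FALSE)[, length(alleles):1, drop = FALSE]
  m <- as.matrix(grid)
  rownames(m) <- apply(m, 1, paste, collapse = "")
  colnames(m) <- NULL
  m
}

# ordered haplotype-index pairs compatible with one unphased multi-SNP
# genotype (character vector of normalized "X/Y" strings, one per SNP)
compatible_pairs <- function(genos, haps) {
  pairs <- expand.grid(i = seq_len(nrow(haps)), j = seq_len(nrow(haps)))
  keep <- rep(TRUE, nrow(pairs))
  for (k in seq_along(genos)) {
    want <- genos[k]
    got <- paste(pmin(haps[pairs$i, k], haps[pairs$j, k]),
                 pmax(haps[pairs$i, k], haps[pairs$j, k]), sep = "/")
    # genotype strings are sorted, so direct comparison works
    keep <- keep & (got == want)
  }
  pairs[keep, , drop = FALSE]
}

# coerce a genotype table (data.frame or matrix, columns named by SNP id)
# to a normalized character matrix restricted to `snps`
as_geno_matrix <- function(genotypes, snps) {
  missing_cols <- setdiff(snps, colnames(genotypes))
  if (length(missing_cols) > 0) {
    stop("genotype table lacks SNP column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.data.frame(genotypes)) genotypes <- as.matrix(genotypes[, snps, drop = FALSE])
  g <- genotypes[, snps, drop = FALSE]
  g[] <- norm_geno(g)
  g
}

# ---- EM frequency estimation ------------------------------------------------

#' Estimate founder-haplotype frequencies by EM from unphased genotypes
#'
#' Standard two- (or three-) locus haplotype-frequency EM: each
#' phase-ambiguous genotype is split across its compatible ordered haplotype
#' pairs in proportion to the current frequency product (E-step), and the
#' expected haplotype counts are renormalized (M-step).  Samples missing a
#' genotype at any selected SNP are excluded.
#'
#' @param genotypes data frame or character matrix of unphased genotype
#'   strings ("G/A"; phase separators `|` are accepted and ignored), columns
#'   named by SNP id.
#' @param snps character vector of 2 or 3 SNP ids selecting the loci.
#' @param alleles optional named list giving the two alleles per SNP; inferred
#'   from the data when `NULL`.
#' @param tol convergence tolerance on the maximum frequency change.
#' @param max_iter iteration cap.
#' @return An object of class `hap_freq`: list with `freq` (named frequency
#'   vector over the haplotype space), `loglik` (trace, one value per
#'   iteration), `iterations`, `converged`, `n_used`, `snps`.
#' @examples
#' g <- data.frame(rs2492816 = c("G/G", "G/A"), rs13691 = c("A/A", "A/G"))
#' em_haplotype_frequencies(g, c("rs2492816", "rs13691"))
#' @export
em_haplotype_frequencies <- function(genotypes, snps = c("rs2492816", "rs13691"),
                                     alleles = NULL, tol = 1e-8, max_iter = 10000L) {
  stopifnot(length(snps) %in% c(2L, 3L), tol > 0)
  g <- as_geno_matrix(genotypes, snps)
  complete <- stats::complete.cases(g)
  g <- g[complete, , drop = FALSE]
  if (nrow(g) == 0) stop("no complete genotypes at the selected SNPs")

  if (is.null(alleles)) {
    alleles <- lapply(seq_along(snps), function(k) {
      sort(unique(unlist(strsplit(g[, k], "/", fixed = TRUE))))
    })
    names(alleles) <- snps
  }
  alleles <- lapply(alleles, unique)
  if (any(vapply(alleles, length, 1L) > 2)) stop("more than two alleles at a selected SNP")

  haps <- hap_space(alleles)
  nh <- nrow(haps)

  # collapse samples into unique genotype classes
  key <- apply(g, 1, paste, collapse = ";")
  classes <- table(key)
  class_genos <- strsplit(names(classes), ";", fixed = TRUE)
  class_pairs <- lapply(class_genos, compatible_pairs, haps = haps)
  if (any(vapply(class_pairs, nrow, 1L) == 0)) {
    stop("genotype incompatible with the declared allele space")
  }
  n_class <- as.numeric(classes)
  n <- sum(n_class)

  # initialize at the product of marginal allele frequencies
  f <- rep(1, nh)
  for (k in seq_along(snps)) {
    obs <- unlist(strsplit(g[, k], "/", fixed = TRUE))
    marg <- table(factor(obs, levels = alleles[[k]])) / length(obs)
    f <- f * as.numeric(marg[haps[, k]])
  }
  f <- f / sum(f)

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(nh)
    ll <- 0
    for (c in seq_along(n_class)) {
      pr <- class_pairs[[c]]
      w <- f[pr$i] * f[pr$j]
      tot <- sum(w)
      ll <- ll + n_class[c] * log(tot)
      w <- w / tot * n_class[c]
      counts <- counts + vapply(seq_len(nh), function(h) {
        sum(w[pr$i == h]) + sum(w[pr$j == h])
      }, numeric(1))
    }
    loglik <- c(loglik, ll)
    f_new <- counts / (2 * n)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  if (length(loglik) > 1 && any(diff(loglik) < -1e-8)) {
    stop("internal error: EM log-likelihood decreased")
  }
  names(f) <- rownames(haps)
  structure(list(freq = f, loglik = loglik, iterations = iter,
                 converged = converged, n_used = n, snps = snps,
                 alleles = alleles),
            class = "hap_freq")
}

#' @export
print.hap_freq <- function(x, ...) {
  cat("Haplotype frequencies over", paste(x$snps, collapse = "/"),
      sprintf("(n = %d, %d EM iterations, %s)\n", x$n_used, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(round(x$freq, 4))
  invisible(x)
}

#' Report haplotypes absent from the population
#'
#' Returns the haplotype labels whose estimated frequency falls below `eps`.
#' With the package defaults this flags the missing rs2492816-A / rs13691-A
#' combination, the signature of the historical bottleneck at the locus.
#'
#' @param freqs a `hap_freq` object from [em_haplotype_frequencies()].
#' @param eps frequency threshold; the default 0.005 sits below the rare
#'   rs113860022-G allele frequency (0.011) but above sampling noise at
#'   cohort scale.
#' @return Character vector of haplotype labels with frequency `< eps`.
#' @export
detect_missing_haplotype <- function(freqs, eps = 0.005) {
  stopifnot(inherits(freqs, "hap_freq"))
  names(freqs$freq)[freqs$freq < eps]
}

#' Check nesting of the rare rs113860022-G allele inside the C9-low haplotype
#'
#' For every carrier of rs113860022-G, tests whether the unphased three-SNP
#' genotype is compatible with the G allele residing on a rs2492816-G /
#' rs13691-A (C9-low) background, i.e. whether the carrier's genotype admits
#' at least one phasing in which every G-carrying haplotype is (G, A, G).
#'
#' @param genotypes genotype table (columns named by SNP id).
#' @param snps the three SNP ids, in rs2492816/rs13691/rs113860022 order.
#' @param rare_allele the rare allele at the third SNP (default "G").
#' @return A list with `n_carriers`, `n_compatible`, `n_incompatible`, and a
#'   per-carrier data frame `carriers`.
#' @export
test_rare_allele_nesting <- function(genotypes,
                                     snps = c("rs2492816", "rs13691", "rs113860022"),
                                     rare_allele = "G") {
  g <- as_geno_matrix(genotypes, snps)
  complete <- stats::complete.cases(g)
  g3 <- g[complete, , drop = FALSE]
  carries <- grepl(rare_allele, g3[, 3], fixed = TRUE)
  idx <- which(carries)
  if (length(idx) == 0) {
    return(list(n_carriers = 0L, n_compatible = 0L, n_incompatible = 0L,
                carriers = data.frame(row = integer(0), compatible = logical(0)),
                message = "no carriers"))
  }
  alleles <- lapply(1:3, function(k) sort(unique(unlist(strsplit(g3[, k], "/", fixed = TRUE)))))
  alleles[[3]] <- sort(unique(c(alleles[[3]], rare_allele)))
  haps <- hap_space(alleles)
  compat <- vapply(idx, function(i) {
    pr <- compatible_pairs(g3[i, ], haps)
    any(vapply(seq_len(nrow(pr)), function(r) {
      pair <- haps[c(pr$i[r], pr$j[r]), , drop = FALSE]
      on_g <- pair[, 3] == rare_allele
      all(pair[on_g, 1] == "G" & pair[on_g, 2] == "A")
    }, logical(1)))
  }, logical(1))
  list(n_carriers = length(idx),
       n_compatible = sum(compat),
       n_incompatible = sum(!compat),
       carriers = data.frame(row = which(complete)[idx], compatible = compat))
}

# ---- WTA subgroup assignment ------------------------------------------------

#' Assign the wild-type-allele (WTA) subgroup of an HRE carrier
#'
#' For a repeat-expansion carrier, one chromosome is the mutant-HRE haplotype
#' (rs2492816-A, rs13691-G, rs113860022-C).  Subtracting those alleles from
#' the unphased genotype triple leaves the wild-type allele's haplotype,
#' which must be one of the four founder haplotypes; its ordinal code (0 =
#' C9-super-low ... 3 = C9-high, ordered by increasing WTA C9orf72
#' expression) is returned.
#'
#' @param triple character vector of the three unphased genotypes in
#'   rs2492816 / rs13691 / rs113860022 order, e.g. `c("G/A", "A/G", "G/C")`.
#' @param hre_carrier must be `TRUE`; subgroups are defined only for carriers.
#' @param hre_haplotype alleles on the expanded chromosome, in SNP order.
#' @return A list with `code` (integer 0-3), `wta` (three-letter haplotype)
#'   and `label`.
#' @examples
#' assign_wta_subgroup(c("G/A", "A/G", "G/C"))$code  # 0, C9-super-low WTA
#' assign_wta_subgroup(c("A/A", "G/G", "C/C"))$code  # 3, C9-high WTA
#' @export
assign_wta_subgroup <- function(triple, hre_carrier = TRUE,
                                hre_haplotype = c("A", "G", "C")) {
  if (!isTRUE(hre_carrier)) {
    stop("WTA subgroups are defined only for HRE carriers")
  }
  triple <- norm_geno(triple)
  if (length(triple) != 3 || anyNA(triple)) {
    stop("a complete genotype triple is required")
  }
  snp_names <- c("rs2492816", "rs13691", "rs113860022")
  residual <- character(3)
  for (k in 1:3) {
    pair <- geno_alleles(triple[k])
    hit <- match(hre_haplotype[k], pair)
    if (is.na(hit)) {
      stop(sprintf("HRE-incompatible genotype at %s: no %s allele in %s",
                   snp_names[k], hre_haplotype[k], triple[k]))
    }
    residual[k] <- pair[-hit]
  }
  wta <- paste(residual, collapse = "")
  founders <- founder_haplotypes()
  row <- match(wta, founders$haplotype)
  if (is.na(row)) {
    stop(sprintf("non-founder WTA haplotype: %s", wta))
  }
  list(code = founders$code[row], wta = wta, label = founders$label[row])
}

#' WTA subgroup table for a cohort of HRE carriers
#'
#' Applies [assign_wta_subgroup()] across samples; incompatible or incomplete
#' triples yield `NA` codes with the failure recorded in `note`.
#'
#' @param genotypes genotype table with columns named by the three SNP ids and
#'   row-identifying column `sample` (or rownames).
#' @param hre_carrier logical vector (recycled) flagging carriers.
#' @param snps SNP ids in locus order.
#' @param hre_haplotype alleles of the expanded chromosome.
#' @return Data frame: sample, code, wta, label, note.
#' @export
wta_subgroup_table <- function(genotypes, hre_carrier = TRUE,
                               snps = c("rs2492816", "rs13691", "rs113860022"),
                               hre_haplotype = c("A", "G", "C")) {
  samples <- if ("sample" %in% names(genotypes)) genotypes$sample else rownames(genotypes)
  g <- as_geno_matrix(genotypes, snps)
  hre_carrier <- rep_len(hre_carrier, nrow(g))
  out <- data.frame(sample = samples, code = NA_integer_, wta = NA_character_,
                    label = NA_character_, note = "", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(g))) {
    if (!hre_carrier[i]) { out$note[i] <- "not an HRE carrier"; next }
    res <- tryCatch(assign_wta_subgroup(g[i, ], TRUE, hre_haplotype),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      out$note[i] <- res
    } else {
      out$code[i]  <- res$code
      out$wta[i]   <- res$wta
      out$label[i] <- res$label
    }
  }
  out
}

# ---- marginal dosage effects ------------------------------------------------

#' Marginal per-allele (dosage) effect by linear regression
#'
#' Ordinary least squares of a quantitative trait on alt-allele dosage
#' (0/1/2), optionally adjusted for covariates; the workhorse behind the
#' per-SNP expression slopes.
#'
#' @param y numeric response (e.g. batch-corrected expression).
#' @param dose numeric alt-allele dosage per sample.
#' @param covariates optional data frame of additional regressors.
#' @return An `effect_estimate` list: estimate (slope per alt allele),
#'   se, p, n, transform, plus `sigma` (residual sd).
#' @examples
#' dosage_effect(c(0, 2, 4), c(0, 1, 2))$estimate  # exactly 2
#' @export
dosage_effect <- function(y, dose, covariates = NULL) {
  keep <- !is.na(y) & !is.na(dose)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]; dose <- dose[keep]
  if (length(y) < 3) stop("need at least 3 complete samples")
  if (length(unique(dose)) < 2) stop("constant dose: dosage effect undefined")
  dat <- data.frame(y = y, dose = dose)
  if (!is.null(covariates)) dat <- cbind(dat, covariates[keep, , drop = FALSE])
  fit <- stats::lm(y ~ ., data = dat)
  sm <- summary(fit)$coefficients
  effect_estimate(estimate = sm["dose", 1], se = sm["dose", 2],
                  p = sm["dose", 4], n = length(y), transform = "identity",
                  sigma = summary(fit)$sigma)
}

# shared constructor for regression/test summaries
effect_estimate <- function(estimate, se, p, n, transform = "identity", ...) {
  structure(list(estimate = estimate, se = se, p = p, n = n,
                 transform = transform, ...),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("estimate %.4g (SE %.3g), p = %.3g, n = %d [%s scale]\n",
              x$estimate, x$se, x$p, x$n, x$transform))
  invisible(x)
}
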