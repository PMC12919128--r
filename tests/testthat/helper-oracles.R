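# Independent oracles and small fixture builders, written without reusing the
# package's internal machinery so they can disagree with it.

# draw n unphased two-SNP genotypes from known haplotype frequencies
draw_genotypes_2snp <- function(freqs, n) {
  haps <- names(freqs)
  h1 <- sample(haps, n, replace = TRUE, prob = freqs)
  h2 <- sample(haps, n, replace = TRUE, prob = freqs)
  sort_pair <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "/")
  data.frame(
    rs2492816 = sort_pair(substr(h1, 1, 1), substr(h2, 1, 1)),
    rs13691   = sort_pair(substr(h1, 2, 2), substr(h2, 2, 2)),
    stringsAsFactors = FALSE)
}

# brute-force likelihood grid over the 3-simplex (4 haplotype frequencies)
# for two-SNP unphased genotype data; returns argmax and max log-likelihood
grid_likelihood_oracle <- function(genotypes, hap_order, step = 0.005) {
  # compatible ordered haplotype pairs per genotype class, by enumeration
  alleles <- function(h, k) substr(h, k, k)
  classes <- table(paste(genotypes[, 1], genotypes[, 2]))
  class_pairs <- lapply(names(classes), function(key) {
    gs <- strsplit(strsplit(key, " ")[[1]], "/")
    pairs <- expand.grid(i = seq_along(hap_order), j = seq_along(hap_order))
    ok <- mapply(function(i, j) {
      all(vapply(1:2, function(k) {
        setequal_multiset <- identical(
          sort(c(alleles(hap_order[i], k), alleles(hap_order[j], k))),
          sort(gs[[k]]))
        setequal_multiset
      }, logical(1)))
    }, pairs$i, pairs$j)
    pairs[ok, , drop = FALSE]
  })
  sq <- seq(0, 1, by = step)
  grid <- expand.grid(f1 = sq, f2 = sq, f3 = sq)
  grid <- grid[rowSums(grid) <= 1 + 1e-12, , drop = FALSE]
  F <- cbind(as.matrix(grid), 1 - rowSums(grid))
  F[F[, 4] < 0, 4] <- 0
  ll <- numeric(nrow(F))
  for (c in seq_along(class_pairs)) {
    pr <- class_pairs[[c]]
    P <- numeric(nrow(F))
    for (r in seq_len(nrow(pr))) P <- P + F[, pr$i[r]] * F[, pr$j[r]]
    ll <- ll + as.numeric(classes[c]) * log(P)
  }
  best <- which.max(ll)
  list(freq = stats::setNames(F[best, ], hap_order), loglik = ll[best])
}

# brute-force WTA assignment: enumerate phase-consistent haplotype pairs
# restricted to founders + the HRE haplotype, require one chromosome to be
# the HRE haplotype, and demand a unique wild-type residual
wta_oracle <- function(triple) {
  founders <- c(GAG = 0L, GAC = 1L, GGC = 2L, AGC = 3L)
  hre <- "AGC"
  haps <- names(founders)
  gs <- strsplit(triple, "/")
  consistent <- function(h1, h2) {
    all(vapply(1:3, function(k) {
      identical(sort(c(substr(h1, k, k), substr(h2, k, k))), sort(gs[[k]]))
    }, logical(1)))
  }
  wtas <- character(0)
  for (h1 in haps) for (h2 in haps) {
    if (h1 == hre && consistent(h1, h2)) wtas <- c(wtas, h2)
  }
  wtas <- unique(wtas)
  if (length(wtas) != 1) return(NA_integer_)   # incompatible or ambiguous
  founders[[wtas]]
}

# all 27 unphased genotype triples over the locus allele sets
all_triples <- function() {
  g1 <- c("G/G", "A/G", "A/A")
  g2 <- c("A/A", "A/G", "G/G")
  g3 <- c("C/C", "C/G", "G/G")
  expand.grid(rs2492816 = g1, rs13691 = g2, rs113860022 = g3,
              stringsAsFactors = FALSE)
}

# minimal VCF fixture writer for reader tests
write_test_vcf <- function(path, rows, samples) {
  header <- c("##fileformat=VCFv4.2", "##contig=<ID=chr9>",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, rows), path)
}
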