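test_that("EM reduces to direct counting when phase is unambiguous", {
  # all samples homozygous at both SNPs: a single haplotype
  g <- data.frame(rs2492816 = rep("G/G", 5), rs13691 = rep("A/A", 5))
  hf <- em_haplotype_frequencies(g, alleles = list(c("G", "A"), c("A", "G")))
  expect_equal(unname(hf$freq["GA"]), 1)
  expect_equal(sum(hf$freq), 1)
  expect_true(all(hf$freq[setdiff(names(hf$freq), "GA")] == 0))

  # no double heterozygote anywhere: every sample phases uniquely, so EM
  # must equal enumeration-based haplotype counting exactly
  g <- data.frame(
    rs2492816 = c("G/G", "A/G", "A/A", "G/G", "A/G"),
    rs13691   = c("A/G", "G/G", "A/G", "A/A", "A/A"))
  hf <- em_haplotype_frequencies(g)
  # haplotypes by hand: GA+GG, AG+GG, AA+AG, GA+GA, AA+GA
  counted <- table(factor(c("GA", "GG", "AG", "GG", "AA", "AG", "GA", "GA",
                            "AA", "GA"),
                          levels = names(hf$freq))) / 10
  expect_equal(hf$freq, c(counted)[names(hf$freq)], tolerance = 1e-9)
})

test_that("EM recovers simulated haplotype frequencies and matches the grid oracle", {
  set.seed(11)
  truth <- c(GA = 0.21, GG = 0.37, AG = 0.41, AA = 0.01)
  g <- draw_genotypes_2snp(truth, 10000)
  hf <- em_haplotype_frequencies(g)
  expect_true(hf$converged)
  expect_lt(max(abs(hf$freq[names(truth)] - truth)), 0.015)

  sub <- g[sample(nrow(g), 200), ]
  hf_sub <- em_haplotype_frequencies(sub)
  oracle <- grid_likelihood_oracle(sub, names(hf_sub$freq), step = 0.005)
  # EM optimizes over the continuum; allow slack of the EM stopping rule
  expect_gte(utils::tail(hf_sub$loglik, 1), unname(oracle$loglik) - 1e-4)
  expect_lt(max(abs(hf_sub$freq - oracle$freq[names(hf_sub$freq)])), 0.01)
})

test_that("a single double-heterozygote is a documented stationary tie", {
  g <- data.frame(rs2492816 = "A/G", rs13691 = "A/G")
  hf <- em_haplotype_frequencies(g)
  expect_equal(unname(hf$freq), rep(0.25, 4))
  expect_true(hf$converged)
})

test_that("EM log-likelihood is monotone over random datasets", {
  set.seed(202)
  for (rep in 1:10) {
    f <- as.numeric(stats::rgamma(4, 1))
    f <- f / sum(f)
    g <- draw_genotypes_2snp(stats::setNames(f, c("GA", "GG", "AG", "AA")), 150)
    hf <- em_haplotype_frequencies(g, tol = 1e-10)
    expect_true(all(diff(hf$loglik) >= -1e-8))
    expect_equal(sum(hf$freq), 1, tolerance = 1e-9)
    expect_true(all(hf$freq >= 0))
  }
})

test_that("EM input guards fire", {
  g <- data.frame(rs2492816 = NA_character_, rs13691 = "A/G")
  expect_error(em_haplotype_frequencies(g), "no complete genotypes")
  expect_error(em_haplotype_frequencies(data.frame(x = "A/G"), snps = c("a", "b")),
               "lacks SNP")
})

test_that("missing-haplotype detection applies the eps threshold", {
  hf <- structure(list(freq = c(GA = 0.21, GG = 0.37, AG = 0.419, AA = 0.001)),
                  class = "hap_freq")
  expect_equal(detect_missing_haplotype(hf), "AA")
  uniform <- structure(list(freq = c(GA = .25, GG = .25, AG = .25, AA = .25)),
                       class = "hap_freq")
  expect_equal(detect_missing_haplotype(uniform), character(0))
  expect_equal(detect_missing_haplotype(hf, eps = 0), character(0))
})

test_that("rare-allele nesting classifies carriers against the C9-low background", {
  g <- data.frame(rs2492816 = c("A/G", "A/A", "G/G"),
                  rs13691   = c("A/G", "G/G", "A/A"),
                  rs113860022 = c("C/G", "C/G", "G/G"))
  rep <- test_rare_allele_nesting(g)
  expect_equal(rep$n_carriers, 3L)
  # sample 1: G can sit on (G,A); sample 2 has no G/A alleles at SNPs 1-2
  expect_true(rep$carriers$compatible[1])
  expect_false(rep$carriers$compatible[2])
  expect_true(rep$carriers$compatible[3])
  none <- test_rare_allele_nesting(
    data.frame(rs2492816 = "G/G", rs13691 = "A/A", rs113860022 = "C/C"))
  expect_equal(none$n_carriers, 0L)
  expect_equal(none$message, "no carriers")
})

test_that("WTA subgroup assignment reproduces the published encoding", {
  expect_equal(assign_wta_subgroup(c("G/A", "A/G", "G/C"))$code, 0L)
  expect_equal(assign_wta_subgroup(c("G/A", "A/G", "C/C"))$code, 1L)
  expect_equal(assign_wta_subgroup(c("G/A", "G/G", "C/C"))$code, 2L)
  expect_equal(assign_wta_subgroup(c("A/A", "G/G", "C/C"))$code, 3L)
  expect_equal(assign_wta_subgroup(c("G/A", "A/G", "G/C"))$label, "C9-super-low")
  expect_error(assign_wta_subgroup(c("G/G", "A/G", "C/C")), "HRE-incompatible")
  expect_error(assign_wta_subgroup(c("A/A", "A/G", "G/G")), "HRE-incompatible")
  expect_error(assign_wta_subgroup(c("A/A", "A/G", "C/C")), "non-founder")
  expect_error(assign_wta_subgroup(c("G/A", "A/G", "C/C"), hre_carrier = FALSE),
               "only for HRE carriers")
})

test_that("WTA assignment agrees with brute-force phase enumeration on all triples", {
  triples <- all_triples()
  for (r in seq_len(nrow(triples))) {
    tri <- unlist(triples[r, ])
    expected <- wta_oracle(tri)
    got <- tryCatch(assign_wta_subgroup(tri)$code, error = function(e) NA_integer_)
    expect_identical(got, expected,
                     label = sprintf("triple %s", paste(tri, collapse = " ")))
  }
})

test_that("subgroup table records per-sample failures instead of aborting", {
  g <- data.frame(sample = c("a", "b", "c"),
                  rs2492816 = c("G/A", "G/G", "A/A"),
                  rs13691 = c("A/G", "A/G", "G/G"),
                  rs113860022 = c("G/C", "C/C", "C/C"))
  tab <- wta_subgroup_table(g, hre_carrier = c(TRUE, TRUE, FALSE))
  expect_equal(tab$code, c(0L, NA_integer_, NA_integer_))
  expect_match(tab$note[2], "HRE-incompatible")
  expect_match(tab$note[3], "not an HRE carrier")
})

test_that("dosage regression: exact fits, guards, and planted-slope recovery", {
  fit <- suppressWarnings(dosage_effect(c(0, 2, 4), c(0, 1, 2)))
  expect_equal(fit$estimate, 2)
  expect_equal(fit$sigma, 0)
  expect_error(dosage_effect(c(1, 2, 3), c(1, 1, 1)), "constant dose")
  expect_error(dosage_effect(c(1, 2), c(0, 1)), "at least 3")

  set.seed(33)
  hits <- 0L
  for (s in 1:40) {
    dose <- stats::rbinom(1000, 2, 0.41)
    y <- 0.086 * dose + stats::rnorm(1000, 0, 0.15)
    est <- dosage_effect(y, dose)
    if (abs(est$estimate - 0.086) <= 2 * est$se) hits <- hits + 1L
  }
  expect_gte(hits, 36L)  # within 2 SE in at least 90% of seeds
})

test_that("dosage regression p-values are calibrated under the null", {
  set.seed(44)
  p <- replicate(1000, {
    dose <- stats::rbinom(200, 2, 0.41)
    dosage_effect(stats::rnorm(200), dose)$p
  })
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})
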