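make_reads <- function(sample, pos, strand, chrom = "chr1") {
  data.frame(sample = sample, chrom = chrom, pos = pos, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("Tn5 shift moves plus strand +5 and minus strand -4", {
  expect_equal(shift_cuts(make_reads("s1", 100, "+"))$pos, 105)
  expect_equal(shift_cuts(make_reads("s1", 200, "-"))$pos, 196)
  expect_error(shift_cuts(make_reads("s1", 50, ".")), "unknown strand")
})

test_that("tabulation counts per base, honors half-open peaks, conserves cuts", {
  peaks <- data.frame(chrom = "chr1", start = 100, end = 110, peak_id = "pk")
  cuts <- make_reads("s1", c(103, 103, 103, 109, 110), "+")  # 110 = end, outside
  bm <- tabulate_cuts(cuts, peaks)
  expect_equal(dim(bm$counts), c(10L, 1L))
  expect_equal(unname(bm$counts["pk:3", "s1"]), 3L)
  expect_equal(unname(bm$counts["pk:9", "s1"]), 1L)
  expect_equal(sum(bm$counts), 4)     # the boundary cut is excluded
  expect_equal(unname(bm$peak_totals["pk", "s1"]), 4L)

  empty <- tabulate_cuts(cuts[0, ], peaks, samples = c("s1", "s2"))
  expect_equal(dim(empty$counts), c(10L, 2L))
  expect_true(all(empty$counts == 0))
})

test_that("overlapping peaks are merged with a warning", {
  peaks <- data.frame(chrom = "chr1", start = c(100, 105), end = c(110, 120))
  expect_warning(bm <- tabulate_cuts(make_reads("s1", 107, "+"), peaks),
                 "merged")
  expect_equal(nrow(bm$counts), 20L)  # one merged 100-120 peak
})

test_that("cut conservation holds for random cut sets", {
  set.seed(31)
  peaks <- data.frame(chrom = "chr1", start = c(0, 500), end = c(100, 650))
  for (rep in 1:5) {
    n <- 500
    cuts <- make_reads(sample(c("a", "b", "c"), n, TRUE),
                       sample(0:800, n, TRUE),
                       sample(c("+", "-"), n, TRUE))
    bm <- tabulate_cuts(cuts, peaks)
    in_peak <- (cuts$pos >= 0 & cuts$pos < 100) |
      (cuts$pos >= 500 & cuts$pos < 650)
    expect_equal(sum(bm$counts), sum(in_peak))
  }
})

test_that("genotype profiles normalize per sample then average", {
  peaks <- data.frame(chrom = "chr1", start = 0, end = 50, peak_id = "p")
  # 50 cuts total, 5 of them at base 10
  cuts_s1 <- make_reads("s1", c(rep(10, 5), rep(20, 45)), "+")
  bm <- tabulate_cuts(cuts_s1, peaks)
  prof <- genotype_profiles(bm, c(s1 = 0))
  expect_equal(prof$frequency[prof$offset == 10], 0.1)
  expect_equal(sum(prof$frequency), 1, tolerance = 1e-9)

  # two identical samples: average equals either sample's profile
  cuts2 <- rbind(cuts_s1, transform(cuts_s1, sample = "s2"))
  bm2 <- tabulate_cuts(cuts2, peaks)
  prof2 <- genotype_profiles(bm2, c(s1 = 0, s2 = 0))
  expect_equal(prof2$frequency, prof$frequency)
})

test_that("profiles are invariant to uniform per-sample depth scaling", {
  peaks <- data.frame(chrom = "chr1", start = 0, end = 20, peak_id = "p")
  base_pos <- c(rep(3, 4), rep(7, 6), rep(15, 10))
  shallow <- make_reads("s1", base_pos, "+")
  deep <- make_reads("s2", rep(base_pos, 3), "+")   # 3x depth, same shape
  bm <- tabulate_cuts(rbind(shallow, deep), peaks)
  prof <- genotype_profiles(bm, c(s1 = 0, s2 = 1))
  p0 <- prof$frequency[prof$genotype == 0]
  p1 <- prof$frequency[prof$genotype == 1]
  expect_equal(p0, p1, tolerance = 1e-12)
})

test_that("stacking filters rows with mean strictly below one", {
  counts <- rbind(r1 = rep(2L, 10), r2 = c(rep(1L, 9), 0L), r3 = rep(1L, 10))
  # r2 mean 0.9 removed; r3 mean exactly 1.0 kept (strict inequality)
  bm <- structure(list(counts = counts,
                       rows = data.frame(peak_id = "p", chrom = "c",
                                         pos = 1:3, offset = 0:2,
                                         row.names = rownames(counts)),
                       peak_totals = matrix(colSums(counts), 1,
                                            dimnames = list("p", paste0("s", 1:10))),
                       samples = paste0("s", 1:10),
                       peaks = data.frame(chrom = "c", start = 0, end = 3,
                                          peak_id = "p")),
                  class = "base_matrix")
  colnames(bm$counts) <- paste0("s", 1:10)
  expect_message(filt <- stack_and_filter(bm), "1 low-count")
  expect_equal(rownames(filt$counts), c("r1", "r3"))
  bm_other <- bm
  bm_other$samples <- paste0("x", 1:10)
  expect_error(suppressMessages(stack_and_filter(list(bm, bm_other))), "differ")
})

test_that("per-base dose test finds planted bases and respects guards", {
  set.seed(41)
  n <- 120
  dose <- stats::rbinom(n, 2, 0.41)
  n_null <- 200
  counts <- matrix(stats::rnbinom(n_null * n, size = 10, mu = 5), n_null, n)
  planted <- 1:10
  for (r in planted) {
    counts[r, ] <- stats::rnbinom(n, size = 10, mu = 5 * 2^dose)
  }
  rownames(counts) <- paste0("b", seq_len(n_null))
  colnames(counts) <- paste0("s", seq_len(n))
  bm <- structure(list(counts = counts,
                       rows = data.frame(peak_id = "p", chrom = "c",
                                         pos = seq_len(n_null),
                                         offset = seq_len(n_null) - 1),
                       peak_totals = matrix(colSums(counts), 1,
                                            dimnames = list("p", colnames(counts))),
                       samples = colnames(counts),
                       peaks = data.frame(chrom = "c", start = 0, end = n_null,
                                          peak_id = "p")),
                  class = "base_matrix")
  res <- per_base_dose_test(bm, stats::setNames(dose, colnames(counts)))
  top10 <- order(res$padj)[1:10]
  expect_gte(length(intersect(top10, planted)), 8)
  expect_true(all(res$log2fc[planted] > 0))      # planted direction recovered
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
  expect_error(per_base_dose_test(bm, stats::setNames(rep(1, n), colnames(counts))),
               "constant dose")
})
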