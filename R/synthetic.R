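# Synthetic cohort generator.  Emulates the statistical structure the
# modifier analysis assumes -- founder haplotypes with the (A,A) combination
# absent and the rare promoter allele nested in the C9-low background,
# HRE co-inheritance with the C9-high haplotype, additive per-allele
# expression effects, log-scale survival ordered by WTA subgroup,
# piecewise-linear ALSFRS-R decline, negative-binomial per-base Tn5 cut
# counts with a genotype-dependent planted footprint, and planted
# low-expression outliers / carrier-unique junctions -- so that every
# downstream estimator has a known ground truth.

#' Default generator parameters
#'
#' Haplotype frequencies are allocated so the marginal alt-allele frequencies
#' match the population values 0.41 (rs2492816-A), 0.22 (rs13691-A) and
#' 0.011 (rs113860022-G) under the constraints that the (A,A) two-SNP
#' combination is absent and the rare G allele occurs only on the C9-low
#' (G,A) background: f(GAG) = 0.011, f(GAC) = 0.209, f(GGC) = 0.37,
#' f(AGC) = 0.41.  Expression effects default to the reported per-allele
#' slopes (+0.086, -0.081, -0.16).  Survival is log-normal with a per-code
#' log10 effect, and non-carriers matched on genotype live longer by a
#' per-code month difference interpolating the reported 18 (code 0) to 8
#' (code 3) month gaps.
#'
#' @param ... named overrides for any default entry.
#' @return A list of class `c9wta_params`.
#' @export
default_params <- function(...) {
  p <- list(
    hap_freq = c(GAG = 0.011, GAC = 0.209, GGC = 0.37, AGC = 0.41),
    hre_haplotype = "AGC",
    hre_prevalence = 0.1,          # among ALS cases
    # expression model (batch-corrected scale); effects per alt allele
    expr_baseline = 1.0,
    expr_effects = c(rs2492816 = 0.086, rs13691 = -0.081, rs113860022 = -0.16),
    expr_hre_shift = -0.3,
    expr_sd = 0.15,
    # survival model: carriers log10(months) = b0 + b1 * code + N(0, sd);
    # genotype-matched non-carriers live longer by delta months (per code)
    surv_log10_baseline = log10(30),
    surv_log10_per_code = 0.04,
    surv_sd_log10 = 0.2,
    surv_delta_months = c(18, 14.7, 11.3, 8),
    # ALSFRS-R visits
    visit_spacing = 3,
    alsfrs_sd = 2,
    # per-base Tn5 cut model over one designated promoter peak
    peak = list(chrom = "chr9", start = 1000L, end = 1200L),
    footprint_interval = c(1090L, 1110L),   # 0-based half-open, absolute
    cut_mu = 5,
    cut_size = 10,                 # NB size (1/dispersion)
    cut_depth_sd = 0.3,            # log-normal per-sample depth factor
    footprint_log2fc = -0.5,       # per rs2492816-A allele, inside footprint
    # plants for the outlier screens
    outlier_plants = data.frame(gene = c("NEK1", "TBK1"), depth = c(4, 4),
                                stringsAsFactors = FALSE),
    junction_plant = list(junction = "chr12:64840000-64840500", count = 25,
                          variant_id = "var_cryptic_synth", variant_offset = 40),
    ase_plant = TRUE,              # one sample with fully silenced alt allele
    n_background_genes = 20,
    n_background_junctions = 15
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown) > 0) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  p[names(dots)] <- dots
  if (any(p$hap_freq < 0) || abs(sum(p$hap_freq) - 1) > 1e-9) {
    stop("haplotype frequencies must be non-negative and sum to 1")
  }
  class(p) <- "c9wta_params"
  p
}

hap_code <- function(h) founder_haplotypes()$code[match(h, founder_haplotypes()$haplotype)]

# mean survival months of a carrier at (possibly fractional) code c
carrier_mean_months <- function(p, code) {
  halfvar <- p$surv_sd_log10^2 * log(10) / 2
  10^(p$surv_log10_baseline + p$surv_log10_per_code * code + halfvar)
}

delta_months_at <- function(p, code) {
  stats::approx(x = 0:3, y = p$surv_delta_months, xout = code, rule = 2)$y
}

# draw log-normal months with a given mean on the months scale
rlnorm10_mean <- function(n, mean_months, sd_log10) {
  halfvar <- sd_log10^2 * log(10) / 2
  10^(stats::rnorm(n, log10(mean_months) - halfvar, sd_log10))
}

#' Simulate a C9-ALS modifier cohort
#'
#' Draws haplotype pairs (non-carriers: two i.i.d. founder haplotypes;
#' HRE carriers: one chromosome fixed at the C9-high/HRE background plus one
#' founder draw), derives unphased genotype triples, and generates the
#' downstream data layers requested in `with`.
#'
#' @param params a `c9wta_params` list from [default_params()].
#' @param n_cases number of ALS cases.
#' @param n_controls number of non-ALS controls.
#' @param with character subset of
#'   `c("expression", "clinical", "visits", "cuts", "junctions", "allele_counts")`
#'   selecting which data layers to generate (genotypes are always
#'   generated).
#' @param seed optional integer seed; identical seed and arguments give an
#'   identical cohort.
#' @return A `sim_cohort` list: `samples` (per-sample truth: haplotypes,
#'   carrier flag, genotype triple, doses, code), plus the requested layers
#'   (`expression`, `clinical`, `visits`, `cuts`, `covariates`, `peaks`,
#'   `junctions`, `allele_counts`, `variants`) and a `truth` list of every
#'   planted parameter.
#' @export
simulate_cohort <- function(params = default_params(), n_cases = 200,
                            n_controls = 50,
                            with = c("expression", "clinical", "visits",
                                     "cuts", "junctions", "allele_counts"),
                            seed = NULL) {
  stopifnot(n_cases > 0, n_controls >= 0)
  if (!is.null(seed)) set.seed(seed)
  p <- params
  haps <- names(p$hap_freq)
  n <- n_cases + n_controls
  id <- sprintf("S%05d", seq_len(n))
  status <- rep(c("ALS", "control"), c(n_cases, n_controls))
  hre <- c(stats::rbinom(n_cases, 1, p$hre_prevalence) == 1, rep(FALSE, n_controls))

  hap1 <- sample(haps, n, replace = TRUE, prob = p$hap_freq)
  hap1[hre] <- p$hre_haplotype
  hap2 <- sample(haps, n, replace = TRUE, prob = p$hap_freq)

  snps <- c("rs2492816", "rs13691", "rs113860022")
  alt <- c(rs2492816 = "A", rs13691 = "A", rs113860022 = "G")
  triple <- matrix(NA_character_, n, 3, dimnames = list(id, snps))
  dose <- matrix(0L, n, 3, dimnames = list(id, snps))
  for (k in 1:3) {
    a1 <- substr(hap1, k, k); a2 <- substr(hap2, k, k)
    triple[, k] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    dose[, k] <- (a1 == alt[k]) + (a2 == alt[k])
  }
  code <- ifelse(hre, hap_code(hap2), NA_integer_)

  samples <- data.frame(sample = id, status = status, hre = hre,
                        hap1 = hap1, hap2 = hap2,
                        rs2492816 = triple[, 1], rs13691 = triple[, 2],
                        rs113860022 = triple[, 3],
                        dose_rs2492816 = dose[, 1], dose_rs13691 = dose[, 2],
                        dose_rs113860022 = dose[, 3],
                        code = code, stringsAsFactors = FALSE)
  cohort <- list(params = p, samples = samples,
                 truth = list(hap_freq = p$hap_freq,
                              expr_effects = p$expr_effects,
                              survival_effect_per_code = p$surv_log10_per_code,
                              survival_delta_months = p$surv_delta_months,
                              footprint_log2fc = p$footprint_log2fc,
                              footprint_interval = p$footprint_interval))

  if ("expression" %in% with) {
    c9 <- p$expr_baseline + as.vector(dose %*% p$expr_effects) +
      ifelse(hre, p$expr_hre_shift, 0) + stats::rnorm(n, 0, p$expr_sd)
    genes <- c("C9orf72", "NEK1", "OPTN", "TBK1", "SETX", "SPG11", "ATP13A2",
               sprintf("GENE%02d", seq_len(p$n_background_genes)))
    expr <- matrix(NA_real_, length(genes), n, dimnames = list(genes, id))
    expr["C9orf72", ] <- c9
    for (g in genes[-1]) {
      expr[g, ] <- stats::rnorm(1, 10, 2) + stats::rnorm(n, 0, 1)
    }
    plants <- p$outlier_plants
    planted <- NULL
    if (!is.null(plants) && nrow(plants) > 0) {
      target <- sample(id[status == "ALS"], nrow(plants))
      for (r in seq_len(nrow(plants))) {
        g <- plants$gene[r]
        med <- stats::median(expr[g, ]); iqr <- stats::IQR(expr[g, ])
        expr[g, target[r]] <- med - plants$depth[r] * iqr
      }
      planted <- data.frame(gene = plants$gene, sample = target,
                            depth = plants$depth, stringsAsFactors = FALSE)
    }
    cohort$expression <- expr
    cohort$truth$outlier_plants <- planted
  }

  if ("clinical" %in% with) {
    surv <- rep(NA_real_, n)
    cstar <- rep(NA_real_, n)
    ci <- which(status == "ALS")
    for (i in ci) {
      if (hre[i]) {
        surv[i] <- 10^(stats::rnorm(1, p$surv_log10_baseline +
                                      p$surv_log10_per_code * code[i],
                                    p$surv_sd_log10))
      } else {
        # genotype-matched mean: if one chromosome is the HRE background,
        # this genotype also occurs in carriers with code = other haplotype
        cs <- if (hap1[i] == p$hre_haplotype) hap_code(hap2[i])
              else if (hap2[i] == p$hre_haplotype) hap_code(hap1[i])
              else (hap_code(hap1[i]) + hap_code(hap2[i])) / 2
        cstar[i] <- cs
        mean_m <- carrier_mean_months(p, cs) + delta_months_at(p, cs)
        surv[i] <- rlnorm10_mean(1, mean_m, p$surv_sd_log10)
      }
    }
    onset <- sample(c("limb", "bulbar", "respiratory"), n_cases,
                    replace = TRUE, prob = c(0.6, 0.3, 0.1))
    cohort$clinical <- data.frame(
      sample = id[ci],
      status = ifelse(hre[ci], "C9-ALS", "non-C9-ALS"),
      hre = hre[ci], survival_months = surv[ci], onset_site = onset,
      stringsAsFactors = FALSE)
  }

  if ("visits" %in% with) {
    if (is.null(cohort$clinical)) stop("visits require the clinical layer")
    vis <- list()
    for (r in seq_len(nrow(cohort$clinical))) {
      s <- cohort$clinical$survival_months[r]
      times <- seq(p$visit_spacing, s, by = p$visit_spacing)
      times <- times[times < s]
      if (length(times) == 0) next
      score <- pmin(48, pmax(0, 48 * (1 - times / s) +
                               stats::rnorm(length(times), 0, p$alsfrs_sd)))
      vis[[r]] <- data.frame(sample = cohort$clinical$sample[r],
                             month = times, score = score,
                             stringsAsFactors = FALSE)
    }
    cohort$visits <- if (length(vis)) do.call(rbind, vis) else
      data.frame(sample = character(0), month = numeric(0), score = numeric(0))
    rownames(cohort$visits) <- NULL
  }

  if ("cuts" %in% with) {
    pk <- p$peak
    width <- pk$end - pk$start
    pos_all <- pk$start + seq_len(width) - 1L
    in_fp <- pos_all >= p$footprint_interval[1] & pos_all < p$footprint_interval[2]
    depth <- exp(stats::rnorm(n, 0, p$cut_depth_sd))
    events <- list()
    for (i in seq_len(n)) {
      mu <- p$cut_mu * depth[i] *
        ifelse(in_fp, 2^(p$footprint_log2fc * dose[i, 1]), 1)
      k <- stats::rnbinom(width, size = p$cut_size, mu = mu)
      if (sum(k) == 0) next
      pos <- rep(pos_all, k)
      events[[i]] <- data.frame(sample = id[i], chrom = pk$chrom, pos = pos,
                                strand = sample(c("+", "-"), length(pos),
                                                replace = TRUE),
                                stringsAsFactors = FALSE)
    }
    cohort$cuts <- do.call(rbind, events)
    rownames(cohort$cuts) <- NULL
    cohort$peaks <- data.frame(chrom = pk$chrom, start = pk$start,
                               end = pk$end, peak_id = "promoter_peak",
                               stringsAsFactors = FALSE)
    cohort$covariates <- data.frame(
      row.names = id,
      sex = sample(c("F", "M"), n, replace = TRUE),
      frip = stats::runif(n, 0.2, 0.6))
  }

  if ("junctions" %in% with) {
    nj <- p$n_background_junctions
    jnames <- sprintf("chr12:%d-%d", 64800000 + (seq_len(nj) - 1) * 2000,
                      64800000 + (seq_len(nj) - 1) * 2000 + 500)
    jx <- matrix(stats::rpois(nj * n, 10), nj, n, dimnames = list(jnames, id))
    jp <- p$junction_plant
    if (!is.null(jp)) {
      carrier <- sample(id[status == "ALS"], 1)
      row <- stats::rbinom(n, 1, 0.05)         # stray noise reads, all < 2
      row[id == carrier] <- jp$count
      jx <- rbind(jx, matrix(row, 1, n, dimnames = list(jp$junction, id)))
      jstart <- as.numeric(sub("^.+:([0-9]+)-.*$", "\\1", jp$junction))
      jchrom <- sub(":.*$", "", jp$junction)
      cohort$variants <- data.frame(
        sample = c(carrier, sample(id, 3)),
        chrom = c(jchrom, rep("chr1", 3)),
        pos = c(jstart + jp$variant_offset, c(1e6, 2e6, 3e6)),
        id = c(jp$variant_id, sprintf("var_decoy_%d", 1:3)),
        stringsAsFactors = FALSE)
      cohort$truth$junction_plant <- data.frame(
        junction = jp$junction, carrier = carrier, variant = jp$variant_id,
        stringsAsFactors = FALSE)
    }
    cohort$junctions <- jx
  }

  if ("allele_counts" %in% with) {
    subset <- sample(id, min(10, n))
    ac <- do.call(rbind, lapply(subset, function(s) {
      data.frame(sample = s, gene = "SETX", site = 1:4,
                 ref = stats::rbinom(4, 20, 0.5), stringsAsFactors = FALSE)
    }))
    ac$alt <- 20 - ac$ref
    if (isTRUE(p$ase_plant)) {
      imb <- sample(setdiff(id, subset), 1)
      ac <- rbind(ac, data.frame(sample = imb, gene = "SETX", site = 1:4,
                                 ref = c(20, 20, 20, 20), alt = c(0, 0, 0, 0)))
      cohort$truth$ase_plant <- imb
    }
    cohort$allele_counts <- ac
  }

  class(cohort) <- "sim_cohort"
  cohort
}

#' Simulate genotype-matched carrier and non-carrier survival groups
#'
#' Direct draws from the generator's survival model for one WTA subgroup
#' code: carrier months are log-normal with log10 mean
#' `b0 + b1 * code`, and genotype-matched non-carriers are log-normal with
#' mean months larger by the planted per-code difference.  Used to study the
#' within-genotype difference estimator at controlled group sizes (the
#' super-low genotype is too rare for natural cohorts of tractable size).
#'
#' @param params a `c9wta_params` list.
#' @param code WTA subgroup code (0-3).
#' @param n_c9,n_non group sizes.
#' @return List with numeric vectors `c9` and `non_c9` (months).
#' @export
simulate_survival_groups <- function(params, code, n_c9, n_non) {
  p <- params
  c9 <- 10^(stats::rnorm(n_c9, p$surv_log10_baseline +
                           p$surv_log10_per_code * code, p$surv_sd_log10))
  mean_non <- carrier_mean_months(p, code) + delta_months_at(p, code)
  non <- rlnorm10_mean(n_non, mean_non, p$surv_sd_log10)
  list(c9 = c9, non_c9 = non)
}

#' Tabulate every planted parameter of a simulated cohort
#'
#' @param cohort a `sim_cohort`.
#' @return Data frame: parameter, value (character), estimator (the
#'   downstream stage expected to recover it).
#' @export
truth_report <- function(cohort) {
  stopifnot(inherits(cohort, "sim_cohort"))
  tr <- cohort$truth
  rows <- list(
    data.frame(parameter = paste0("hap_freq_", names(tr$hap_freq)),
               value = as.character(tr$hap_freq), estimator = "em_haplotype_frequencies"),
    data.frame(parameter = paste0("expr_effect_", names(tr$expr_effects)),
               value = as.character(tr$expr_effects), estimator = "dosage_effect"),
    data.frame(parameter = "survival_effect_per_code",
               value = as.character(tr$survival_effect_per_code),
               estimator = "subgroup_survival_model"),
    data.frame(parameter = paste0("survival_delta_months_code", 0:3),
               value = as.character(tr$survival_delta_months),
               estimator = "within_genotype_difference"),
    data.frame(parameter = "footprint_log2fc",
               value = as.character(tr$footprint_log2fc),
               estimator = "per_base_dose_test")
  )
  if (!is.null(tr$outlier_plants)) {
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0("outlier_", tr$outlier_plants$gene),
      value = tr$outlier_plants$sample, estimator = "iqr_outliers")
  }
  if (!is.null(tr$junction_plant)) {
    rows[[length(rows) + 1]] <- data.frame(
      parameter = paste0("junction_", tr$junction_plant$junction),
      value = tr$junction_plant$carrier, estimator = "unique_junctions")
  }
  if (!is.null(tr$ase_plant)) {
    rows[[length(rows) + 1]] <- data.frame(
      parameter = "ase_imbalanced_sample", value = tr$ase_plant,
      estimator = "ase_ranking")
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
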