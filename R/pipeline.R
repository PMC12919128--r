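# End-to-end orchestration of the modifier analysis.

# warn when sample identifiers disagree across loaded tables
check_sample_consistency <- function(tables) {
  sets <- list()
  if (!is.null(tables$genotypes)) sets$genotypes <- tables$genotypes$sample
  if (!is.null(tables$clinical)) sets$clinical <- tables$clinical$sample
  if (!is.null(tables$expression)) sets$expression <- colnames(tables$expression)
  if (!is.null(tables$junctions)) sets$junctions <- colnames(tables$junctions)
  if (length(sets) < 2) return(invisible(NULL))
  common <- Reduce(intersect, sets)
  message("sample intersection across ", length(sets), " tables: ",
          length(common), " samples")
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], sets$genotypes)
    if (!is.null(tables$genotypes) && length(extra) > 0) {
      warning(length(extra), " sample(s) in ", nm, " absent from genotypes")
    }
  }
  invisible(common)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full wild-type-allele modifier pipeline
#'
#' Executes every analysis stage on the supplied cohort tables and writes one
#' TSV per result to `out_dir`: founder-haplotype frequencies, per-sample WTA
#' subgroup assignments, the trimmed log10-survival regression, per-genotype
#' carrier vs non-carrier t-tests, per-patient ALSFRS-R times to threshold,
#' the threshold robustness scan, per-base footprint dose tests, and the
#' outlier screen calls (plus allele-balance ranking, junction events,
#' footprint profiles, and a run log).  Identical configuration and inputs
#' produce byte-identical outputs.
#'
#' @param config a `c9wta_config` from [default_config()].
#' @param tables named list of input tables (see [load_cohort_dir()]):
#'   `genotypes` required; `clinical`, `visits`, `expression`, `junctions`,
#'   `allele_counts`, `variants`, `covariates`, `peaks`, `cuts` optional --
#'   stages without inputs are skipped.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the named list of result data frames.
#' @export
run_pipeline <- function(config, tables, out_dir) {
  validate_config(config)
  set.seed(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("c9wta pipeline, seed %d", config$seed))
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  results <- list()
  snps <- config$snps$id
  check_sample_consistency(tables)

  # --- haplotype stage -------------------------------------------------------
  results$haplotype_frequencies <- run_stage("haplotypes", {
    if (is.null(tables$genotypes) || nrow(tables$genotypes) == 0) {
      stop("empty genotype table")
    }
    hf2 <- em_haplotype_frequencies(
      tables$genotypes, snps[1:2],
      alleles = list(c(config$snps$ref[1], config$snps$alt[1]),
                     c(config$snps$ref[2], config$snps$alt[2])),
      tol = config$em_tol, max_iter = config$em_max_iter)
    missing_hap <- detect_missing_haplotype(hf2, config$missing_hap_eps)
    nest <- test_rare_allele_nesting(tables$genotypes, snps)
    note("EM converged in %d iterations, loglik %.4f", hf2$iterations,
         utils::tail(hf2$loglik, 1))
    note("missing haplotypes (< %g): %s", config$missing_hap_eps,
         paste(missing_hap, collapse = ",") )
    note("rare-allele nesting: %d/%d carriers compatible with C9-low background",
         nest$n_compatible, nest$n_carriers)
    data.frame(haplotype = names(hf2$freq), frequency = unname(hf2$freq),
               missing = names(hf2$freq) %in% missing_hap,
               stringsAsFactors = FALSE)
  })

  # --- subgroup stage --------------------------------------------------------
  hre_flags <- NULL
  if (!is.null(tables$clinical)) {
    hre_flags <- stats::setNames(tables$clinical$hre, tables$clinical$sample)
  }
  results$subgroups <- run_stage("subgroups", {
    flags <- if (is.null(hre_flags)) FALSE else {
      f <- hre_flags[tables$genotypes$sample]
      f[is.na(f)] <- FALSE
      f
    }
    wta_subgroup_table(tables$genotypes, flags, snps, config$hre_haplotype)
  })

  # --- survival stage --------------------------------------------------------
  if (!is.null(tables$clinical)) {
    surv <- run_stage("survival", {
      cl <- tables$clinical
      cl <- cl[cl$onset_site %in% config$onset_sites &
                 !is.na(cl$survival_months) & cl$survival_months > 0, ]
      code <- results$subgroups$code[match(cl$sample, results$subgroups$sample)]
      carriers <- which(cl$hre & !is.na(code))
      keep <- carriers[trim_extremes(cl$survival_months[carriers],
                                     config$trim_frac)]
      note("survival: %d C9-ALS retained after %.0f%% trimming (of %d)",
           length(keep), 100 * config$trim_frac, length(carriers))
      model <- subgroup_survival_model(cl$survival_months[keep], code[keep])
      gmat <- as_geno_matrix(tables$genotypes, snps)
      gt_all <- apply(gmat, 1, paste, collapse = ";")
      gt <- gt_all[match(cl$sample, tables$genotypes$sample)]
      diffs <- genotype_survival_differences(cl$survival_months, gt, cl$hre)
      list(model = data.frame(term = "code", estimate = model$estimate,
                              se = model$se, p = model$p, n = model$n,
                              transform = model$transform),
           diffs = diffs)
    })
    results$survival_model <- surv$model
    results$survival_differences <- surv$diffs
  }

  # --- ALSFRS-R stage --------------------------------------------------------
  if (!is.null(tables$visits) && !is.null(tables$clinical)) {
    als <- run_stage("alsfrs", {
      cl <- tables$clinical
      code <- results$subgroups$code[match(cl$sample, results$subgroups$sample)]
      use <- which(cl$hre & !is.na(code))
      series <- lapply(use, function(i) {
        v <- tables$visits[tables$visits$sample == cl$sample[i], ]
        build_anchored_series(v$month, v$score,
                              death_month = cl$survival_months[i],
                              id = cl$sample[i])
      })
      codes <- code[use]
      tt <- threshold_table(series, config$alsfrs_threshold, config$trim_frac)
      tt$code <- codes[match(tt$id, cl$sample[use])]
      scan <- threshold_scan(series, codes, config$scan_range, config$trim_frac)
      note("ALSFRS-R: %d carriers with trajectories; %d retained at t_%d",
           length(series), nrow(tt), config$alsfrs_threshold)
      list(tt = tt, scan = scan)
    })
    results$time_to_threshold <- als$tt
    results$threshold_scan <- als$scan
  }

  # --- footprint stage -------------------------------------------------------
  if (!is.null(tables$cuts) && !is.null(tables$peaks)) {
    fp <- run_stage("footprint", {
      cuts <- shift_cuts(tables$cuts)
      dose <- geno_dose(tables$genotypes, snps[1],
                        alt = config$snps$alt[1])
      dose <- dose[!is.na(dose)]
      bm <- tabulate_cuts(cuts, tables$peaks,
                          samples = intersect(sort(unique(cuts$sample)),
                                              names(dose)))
      filtered <- stack_and_filter(bm)
      covar <- tables$covariates
      if (!is.null(covar)) {
        covar <- covar[, intersect(config$footprint_covariates, names(covar)),
                       drop = FALSE]
      }
      tests <- per_base_dose_test(filtered, dose, covar)
      profiles <- genotype_profiles(bm, dose)
      note("footprint: %d bases tested (%d removed), %d samples",
           nrow(filtered$counts), filtered$n_removed, length(bm$samples))
      list(tests = tests, profiles = profiles)
    })
    results$footprint_tests <- fp$tests
    results$footprint_profiles <- fp$profiles
  }

  # --- outlier stage ---------------------------------------------------------
  if (!is.null(tables$expression)) {
    results$outlier_calls <- run_stage("outliers", {
      calls <- iqr_outliers(tables$expression,
                            intersect(config$outlier_genes,
                                      rownames(tables$expression)),
                            k = config$outlier_k)
      note("outliers: %d flagged of %d gene-sample scores",
           sum(calls$flagged), nrow(calls))
      calls
    })
  }
  if (!is.null(tables$allele_counts)) {
    results$ase_ranking <- run_stage("allele_balance",
                                     ase_ranking(tables$allele_counts))
  }
  if (!is.null(tables$junctions)) {
    results$junction_events <- run_stage("junctions", {
      unique_junctions(tables$junctions,
                       min_count = config$junction_min_count,
                       noise_count = config$junction_noise_count,
                       variants = tables$variants,
                       window = config$junction_window)
    })
  }

  for (nm in names(results)) {
    write_result_table(results[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
  }
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(results)
}

# alt-allele dosage vector (named by sample) for one SNP of a genotype table
geno_dose <- function(genotypes, snp, alt) {
  g <- as_geno_matrix(genotypes, snp)[, 1]
  dose <- vapply(strsplit(g, "/", fixed = TRUE),
                 function(a) as.numeric(sum(a == alt)), numeric(1))
  dose[is.na(g)] <- NA_real_
  samples <- if ("sample" %in% names(genotypes)) genotypes$sample else rownames(genotypes)
  stats::setNames(dose, samples)
}
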