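# Survival (disease-duration) statistics for the C9-ALS subgroup analysis.
# Durations are fully observed months from onset to death; no censoring model.

#' Symmetrically trim extreme values
#'
#' Removes the `ceiling(frac * n)` largest and smallest values, agnostic of
#' any grouping, and returns the indices retained.  Ties at a trim boundary
#' are broken by original position: the earlier element is removed first
#' (stable sort).
#'
#' @param values numeric vector.
#' @param frac trimming fraction in `[0, 0.5)` per tail (default 0.05).
#' @return Integer vector of retained indices, in original order.
#' @examples
#' trim_extremes(1:20)  # drops 1 and 20
#' @export
trim_extremes <- function(values, frac = 0.05) {
  stopifnot(is.numeric(values), frac >= 0, frac < 0.5)
  if (anyNA(values)) stop("values must not contain NA; filter upstream")
  n <- length(values)
  k <- ceiling(frac * n)
  ord <- order(values)              # stable: ties keep original order
  drop <- if (k > 0) c(ord[seq_len(k)], ord[n + 1 - seq_len(k)]) else integer(0)
  retained <- sort(setdiff(seq_len(n), drop))
  if (length(retained) < 3) stop("fewer than 3 values retained after trimming")
  retained
}

#' Log10-survival regression on the ordinal WTA subgroup code
#'
#' Fits ordinary least squares of `log10(survival months)` on the integer
#' subgroup code (0 = C9-super-low ... 3 = C9-high); the log transform
#' addresses the right-skew of duration residuals.  Trimming of extreme
#' durations is expected to have been applied upstream (see
#' [trim_extremes()]).
#'
#' @param survival_months positive durations, one per patient.
#' @param code integer subgroup codes.
#' @return An `effect_estimate` with the slope in log10-months per code step.
#' @export
subgroup_survival_model <- function(survival_months, code) {
  keep <- !is.na(survival_months) & !is.na(code)
  s <- survival_months[keep]; code <- code[keep]
  if (any(s <= 0)) stop("survival months must be positive")
  if (length(unique(code)) < 2) stop("need at least 2 distinct subgroup codes")
  y <- log10(s)
  if (stats::var(y) == 0) {
    # all durations equal: slope 0 by construction, no evidence either way
    return(effect_estimate(estimate = 0, se = 0, p = 1, n = length(y),
                           transform = "log10"))
  }
  fit <- stats::lm(y ~ code)
  sm <- summary(fit)$coefficients
  effect_estimate(estimate = sm["code", 1], se = sm["code", 2],
                  p = sm["code", 4], n = length(y), transform = "log10")
}

#' Carrier vs non-carrier survival difference within a shared genotype
#'
#' Welch two-sample t-test comparing mean survival (months) of C9-ALS
#' patients against non-C9-ALS patients carrying the same unphased three-SNP
#' genotype.  The estimate is `mean(c9) - mean(non_c9)`, negative when
#' carriers die sooner.
#'
#' @param c9 survival months of the repeat-expansion carriers.
#' @param non_c9 survival months of genotype-matched non-carriers.
#' @return An `effect_estimate` (months scale) with Welch SE and two-sided p.
#' @examples
#' within_genotype_difference(c(30, 34, 38), c(40, 44, 48))
#' @export
within_genotype_difference <- function(c9, non_c9) {
  c9 <- c9[!is.na(c9)]; non_c9 <- non_c9[!is.na(non_c9)]
  if (length(c9) < 2 || length(non_c9) < 2) {
    stop("each group needs at least 2 observations (variance undefined below)")
  }
  diff <- mean(c9) - mean(non_c9)
  if (stats::var(c9) == 0 && stats::var(non_c9) == 0) {
    # degenerate: identical constants carry no evidence
    return(effect_estimate(estimate = diff, se = 0,
                           p = if (diff == 0) 1 else 0,
                           n = length(c9) + length(non_c9), transform = "months"))
  }
  tt <- stats::t.test(c9, non_c9, var.equal = FALSE)
  effect_estimate(estimate = diff, se = tt$stderr, p = tt$p.value,
                  n = length(c9) + length(non_c9), transform = "months",
                  t = unname(tt$statistic), df = unname(tt$parameter))
}

#' Per-genotype survival differences across a cohort
#'
#' Groups patients by their full unphased three-SNP genotype string and runs
#' [within_genotype_difference()] wherever both the carrier and non-carrier
#' group have at least `min_n` patients.
#'
#' @param survival_months durations (months).
#' @param genotype character genotype label per patient (e.g. "G/A;A/G;G/C").
#' @param hre_carrier logical carrier flag per patient.
#' @param min_n minimum group size (default 2).
#' @return Data frame: genotype, n_c9, n_nonc9, difference, se, p.
#' @export
genotype_survival_differences <- function(survival_months, genotype, hre_carrier,
                                          min_n = 2) {
  keep <- !is.na(survival_months) & !is.na(genotype) & !is.na(hre_carrier)
  survival_months <- survival_months[keep]
  genotype <- genotype[keep]; hre_carrier <- hre_carrier[keep]
  out <- list()
  for (gt in unique(genotype)) {
    c9  <- survival_months[genotype == gt & hre_carrier]
    non <- survival_months[genotype == gt & !hre_carrier]
    if (length(c9) < min_n || length(non) < min_n) next
    est <- within_genotype_difference(c9, non)
    out[[gt]] <- data.frame(genotype = gt, n_c9 = length(c9),
                            n_nonc9 = length(non), difference = est$estimate,
                            se = est$se, p = est$p, stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(genotype = character(0), n_c9 = integer(0),
                      n_nonc9 = integer(0), difference = numeric(0),
                      se = numeric(0), p = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
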