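# Anchored piecewise-linear ALSFRS-R trajectories and the time-to-threshold
# statistic.  ALSFRS-R Total runs 0-48 and declines with disease progression;
# the trajectory is anchored at 48 at disease onset (time 0) and at 0 at
# death when the death date is known.

#' Build an anchored ALSFRS-R visit series
#'
#' Prepends the onset anchor (0 months, score 48), appends the death anchor
#' (death month, score 0) when known, sorts by time and averages duplicate
#' timestamps.
#'
#' @param months visit times in months from disease onset.
#' @param scores ALSFRS-R Total at each visit, within `[0, 48]`.
#' @param death_month months from onset to death, or `NULL` if unknown.
#' @param id optional patient identifier carried through.
#' @return A `visit_series` list: `points` (data frame month/score, sorted),
#'   `death_month`, `id`.
#' @examples
#' s <- build_anchored_series(12, 36, death_month = 30)
#' s$points
#' @export
build_anchored_series <- function(months = numeric(0), scores = numeric(0),
                                  death_month = NULL, id = NA_character_) {
  stopifnot(length(months) == length(scores))
  if (any(is.na(months)) || any(is.na(scores))) stop("NA in visit data")
  if (any(months < 0)) stop("visit before disease onset (negative month)")
  if (any(scores < 0 | scores > 48)) stop("ALSFRS-R score outside [0, 48]")
  m <- c(0, months)
  s <- c(48, scores)
  if (!is.null(death_month) && !is.na(death_month)) {
    if (death_month <= 0) stop("death month must be positive")
    m <- c(m, death_month)
    s <- c(s, 0)
  } else {
    death_month <- NA_real_
  }
  agg <- stats::aggregate(list(score = s), by = list(month = m), FUN = mean)
  agg <- agg[order(agg$month), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(points = agg, death_month = death_month, id = id),
            class = "visit_series")
}

#' Interpolated time from onset to an ALSFRS-R threshold
#'
#' Walks the anchored piecewise-linear trajectory in time order and returns
#' the first time the score reaches threshold `i`: an exact hit at an
#' observed point returns that point's time, otherwise the first descending
#' crossing is linearly interpolated between the bracketing points.  A
#' trajectory that never reaches `i` (no death anchor and all scores above
#' `i`) yields `NA` — undefined, to be excluded downstream, not an error.
#'
#' @param series a `visit_series` from [build_anchored_series()].
#' @param i threshold score within `[0, 48]`.
#' @return A list: `id`, `threshold`, `t` (months or `NA`), `segment`
#'   (index of the segment used; 0 for an exact hit at a point).
#' @examples
#' s <- build_anchored_series(12, 36, death_month = 30)
#' time_to_threshold(s, 24)$t  # 18
#' @export
time_to_threshold <- function(series, i) {
  stopifnot(inherits(series, "visit_series"))
  if (i < 0 || i > 48) stop("threshold outside [0, 48]")
  m <- series$points$month
  s <- series$points$score
  n <- length(m)
  for (k in seq_len(n)) {
    if (s[k] == i) {
      return(list(id = series$id, threshold = i, t = m[k], segment = 0L))
    }
    if (k < n && s[k] > i && s[k + 1] < i) {
      t <- m[k] + (s[k] - i) / (s[k] - s[k + 1]) * (m[k + 1] - m[k])
      return(list(id = series$id, threshold = i, t = t, segment = k))
    }
  }
  list(id = series$id, threshold = i, t = NA_real_, segment = NA_integer_)
}

#' Cohort table of times to an ALSFRS-R threshold
#'
#' Computes the interpolated time to threshold `i` for every patient, drops
#' undefined times, then trims the top and bottom `trim_frac` of times
#' agnostic of any grouping.
#'
#' @param series_list list of `visit_series`.
#' @param i threshold score.
#' @param trim_frac per-tail trimming fraction (default 0.05).
#' @return Data frame: id, t (months), one row per retained patient.
#' @export
threshold_table <- function(series_list, i, trim_frac = 0.05) {
  tt <- vapply(series_list, function(s) time_to_threshold(s, i)$t, numeric(1))
  ids <- vapply(series_list, function(s) as.character(s$id), character(1))
  def <- !is.na(tt)
  if (sum(def) < 3) stop("fewer than 3 patients with a defined time to threshold")
  tt <- tt[def]; ids <- ids[def]
  keep <- trim_extremes(tt, trim_frac)
  data.frame(id = ids[keep], t = tt[keep], stringsAsFactors = FALSE)
}

#' Group-averaged time-to-threshold trajectories
#'
#' For each threshold, computes per-patient times, drops undefined times,
#' trims extremes agnostic of genotype, then summarizes mean and standard
#' error within each subgroup.  Groups with fewer than 2 retained patients at
#' a threshold are omitted with a warning.
#'
#' @param series_list list of `visit_series`.
#' @param groups group label per patient (e.g. WTA subgroup code).
#' @param thresholds scores at which to evaluate, each within `[0, 48]`.
#' @param trim_frac per-tail trimming fraction.
#' @return Data frame: group, threshold, mean, se, n.
#' @export
group_trajectories <- function(series_list, groups, thresholds,
                               trim_frac = 0.05) {
  stopifnot(length(series_list) == length(groups))
  if (any(thresholds < 0 | thresholds > 48)) stop("threshold outside [0, 48]")
  rows <- list()
  omitted <- character(0)
  for (i in thresholds) {
    tt <- vapply(series_list, function(s) time_to_threshold(s, i)$t, numeric(1))
    def <- which(!is.na(tt))
    if (length(def) < 3) next
    keep <- def[trim_extremes(tt[def], trim_frac)]
    for (grp in sort(unique(groups))) {
      v <- tt[keep][groups[keep] == grp]
      if (length(v) < 2) {
        omitted <- c(omitted, sprintf("%s@%d", grp, i))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        group = grp, threshold = i, mean = mean(v),
        se = stats::sd(v) / sqrt(length(v)), n = length(v))
    }
  }
  if (length(omitted) > 0) {
    warning("groups omitted (fewer than 2 defined times): ",
            paste(unique(omitted), collapse = ", "))
  }
  if (length(rows) == 0) {
    return(data.frame(group = character(0), threshold = numeric(0),
                      mean = numeric(0), se = numeric(0), n = integer(0)))
  }
  do.call(rbind, rows)
}

#' Threshold robustness scan of the subgroup association
#'
#' For each threshold in `3..45`, regresses the retained per-patient times on
#' the ordinal subgroup code and records the slope and p-value, checking that
#' the significance at the primary threshold (24) is not an artifact of the
#' threshold choice.
#'
#' @param series_list list of `visit_series`.
#' @param code integer subgroup code per patient.
#' @param thresholds integer thresholds, each within `[3, 45]`.
#' @param trim_frac per-tail trimming fraction.
#' @return Data frame: threshold, slope, se, p, n (`NA` rows where the fit is
#'   degenerate at that threshold).
#' @export
threshold_scan <- function(series_list, code, thresholds = 3:45,
                           trim_frac = 0.05) {
  stopifnot(length(series_list) == length(code))
  if (any(thresholds < 3 | thresholds > 45)) {
    stop("scan thresholds must lie within [3, 45]")
  }
  if (length(unique(code[!is.na(code)])) < 2) stop("need at least 2 subgroups")
  out <- data.frame(threshold = thresholds, slope = NA_real_, se = NA_real_,
                    p = NA_real_, n = NA_integer_)
  for (r in seq_along(thresholds)) {
    i <- thresholds[r]
    tt <- vapply(series_list, function(s) time_to_threshold(s, i)$t, numeric(1))
    def <- which(!is.na(tt) & !is.na(code))
    if (length(def) < 3) next
    keep <- tryCatch(def[trim_extremes(tt[def], trim_frac)],
                     error = function(e) integer(0))
    if (length(keep) < 3 || length(unique(code[keep])) < 2) next
    y <- tt[keep]; x <- code[keep]
    if (stats::var(y) == 0) next
    fit <- summary(stats::lm(y ~ x))$coefficients
    if (!"x" %in% rownames(fit)) next
    out$slope[r] <- fit["x", 1]
    out$se[r]    <- fit["x", 2]
    out$p[r]     <- fit["x", 4]
    out$n[r]     <- length(keep)
  }
  out
}
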