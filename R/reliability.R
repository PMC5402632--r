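# Reliability and validity statistics for interruption sets.
#
# Two interruption label maps (two operators, fully- vs semi-automated, or
# algorithm vs visual scoring) are compared by voxel overlap: interruptions
# count as matching when they overlap by at least 20 voxels (0.011 mm^3 at
# 82 um), the smallest intra-cortical volume the detector can return. Joint-
# level ratings are compared with the single-measures two-way random-effects
# absolute-agreement intraclass correlation, ICC(2,1).

#' Match interruptions between two label maps
#'
#' Candidate pairs are label pairs whose voxel sets overlap by at least
#' `min_overlap_voxels`. Pairs are assigned greedily one-to-one by descending
#' overlap (ties: smaller label pair first), so each label appears in at most
#' one pair.
#'
#' @param a,b [label_map()]s on the same lattice.
#' @param min_overlap_voxels minimal overlap for a match (default 20).
#' @return A list of class `cb_match_result`: `n_a`, `n_b`, `n_match`, and a
#'   data frame `pairs` with `label_a`, `label_b`, `overlap_voxels`.
#' @export
match_interruptions <- function(a, b, min_overlap_voxels = 20L) {
  stopifnot(inherits(a, "cb_labelmap"), inherits(b, "cb_labelmap"))
  check_same_lattice(a, b, "label maps")
  min_overlap_voxels <- as.integer(min_overlap_voxels)
  if (min_overlap_voxels < 1L)
    stop_validation("min_overlap_voxels must be >= 1")
  n_a <- n_labels(a)
  n_b <- n_labels(b)
  sel <- a$data > 0L & b$data > 0L
  pairs <- data.frame(label_a = integer(0), label_b = integer(0),
                      overlap_voxels = integer(0))
  if (any(sel)) {
    la <- a$data[sel]; lb <- b$data[sel]
    key <- (la - 1) * as.double(n_b) + lb
    tab <- table(key)
    kv <- as.numeric(names(tab))
    cand <- data.frame(label_a = as.integer((kv - 1) %/% n_b) + 1L,
                       label_b = as.integer((kv - 1) %% n_b) + 1L,
                       overlap_voxels = as.integer(tab))
    cand <- cand[cand$overlap_voxels >= min_overlap_voxels, , drop = FALSE]
    cand <- cand[order(-cand$overlap_voxels, cand$label_a, cand$label_b), ,
                 drop = FALSE]
    used_a <- logical(n_a); used_b <- logical(n_b)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ia <- cand$label_a[i]; ib <- cand$label_b[i]
      if (!used_a[ia] && !used_b[ib]) {
        keep[i] <- TRUE
        used_a[ia] <- TRUE
        used_b[ib] <- TRUE
      }
    }
    pairs <- cand[keep, , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(n_a = n_a, n_b = n_b, n_match = nrow(pairs), pairs = pairs,
                 min_overlap_voxels = min_overlap_voxels),
            class = "cb_match_result")
}

#' @export
print.cb_match_result <- function(x, ...) {
  cat(sprintf("<match result> %d vs %d interruptions, %d matching (>= %d voxels overlap)\n",
              x$n_a, x$n_b, x$n_match, x$min_overlap_voxels))
  invisible(x)
}

#' Proportion of matching interruptions
#'
#' `n_match / (n_a + n_b - n_match) * 100`: the percentage of interruptions
#' found at exactly the same location by both raters, relative to the union
#' of both sets.
#'
#' @param n_a,n_b interruption counts of the two raters.
#' @param n_match number of matching interruptions.
#' @return Percentage in `[0, 100]`.
#' @export
proportion_matching <- function(n_a, n_b, n_match) {
  check_counts(n_a, n_b, n_match)
  if (n_a == 0 && n_b == 0)
    stop_validation("proportion of matching interruptions is undefined when both sets are empty")
  n_match / (n_a + n_b - n_match) * 100
}

#' Positive predictive value of the algorithm versus visual scoring
#'
#' `n_match / n_algorithm * 100`: the fraction of algorithm detections
#' confirmed by the gold standard.
#'
#' @param n_match matching interruptions between algorithm and visual scoring.
#' @param n_algorithm interruptions detected by the algorithm (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
positive_predictive_value <- function(n_match, n_algorithm) {
  check_counts(n_algorithm, n_match)
  if (n_algorithm == 0)
    stop_validation("PPV is undefined when the algorithm detected no interruptions")
  if (n_match > n_algorithm)
    stop_validation("n_match cannot exceed n_algorithm")
  n_match / n_algorithm * 100
}

#' Sensitivity of the algorithm versus visual scoring
#'
#' `n_match / n_visual * 100`: the fraction of visually scored interruptions
#' found by the algorithm.
#'
#' @param n_match matching interruptions between algorithm and visual scoring.
#' @param n_visual interruptions found by visual scoring (> 0).
#' @return Percentage in `[0, 100]`.
#' @export
sensitivity <- function(n_match, n_visual) {
  check_counts(n_visual, n_match)
  if (n_visual == 0)
    stop_validation("sensitivity is undefined when visual scoring found no interruptions")
  if (n_match > n_visual)
    stop_validation("n_match cannot exceed n_visual")
  n_match / n_visual * 100
}

check_counts <- function(...) {
  for (x in list(...)) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
        x != round(x))
      stop_validation("counts must be single non-negative integers")
  }
  invisible(TRUE)
}

#' Intraclass correlation ICC(2,1)
#'
#' Single-measures intraclass correlation from a two-way random-effects model
#' with absolute agreement, computed from the ANOVA mean squares (between
#' subjects MSR, between raters MSC, residual MSE):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The 95% confidence interval uses the standard F-distribution construction
#' (McGraw & Wong).
#'
#' @param ratings numeric matrix or data frame, one row per joint (subject),
#'   one column per rater; at least 2 rows and 2 columns, no missing cells.
#' @param conf_level confidence level (default 0.95).
#' @return A list with `icc`, `ci95 = c(lower, upper)`, the mean squares,
#'   and the table dimensions `n` (subjects) and `k` (raters).
#' @export
icc_two_way_random_absolute <- function(ratings, conf_level = 0.95) {
  x <- as.matrix(ratings)
  if (!is.numeric(x)) stop_validation("ratings must be numeric")
  if (anyNA(x)) stop_validation("ratings must have no missing cells")
  n <- nrow(x); k <- ncol(x)
  if (n < 2L || k < 2L)
    stop_validation("ratings need at least 2 joints and 2 raters")
  grand <- mean(x)
  rowm <- rowMeans(x)
  colm <- colMeans(x)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)
  MSC <- n * sum((colm - grand)^2) / (k - 1)
  resid <- x - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) + grand
  MSE <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- MSR + (k - 1) * MSE + k * (MSC - MSE) / n
  if (abs(denom) < .Machine$double.eps * max(1, abs(MSR)))
    stop_validation("ICC is undefined: the ratings have zero total variance")
  icc <- (MSR - MSE) / denom

  alpha <- 1 - conf_level
  if (MSE <= 0 && MSC <= MSE) {
    # degenerate perfectly consistent table: ICC is exactly defined, CI collapses
    ci <- c(icc, icc)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    ci <- c(lower, upper)
  }
  list(icc = icc, ci95 = ci,
       ms = list(MSR = MSR, MSC = MSC, MSE = MSE),
       n = n, k = k, conf_level = conf_level)
}
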