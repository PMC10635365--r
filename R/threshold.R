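# Threshold analytics: how similar must two drugs be before they share
# pharmacological behaviour, and where is the operating point that
# balances substitute quality against substitute supply?

#' Fraction of drug pairs with positive tau above a similarity threshold
#'
#' Among pairs whose chosen similarity metric is at least `threshold`
#' (inclusive, so the DACS maximum sqrt(2) is attainable by identical
#' drugs), the proportion whose Kendall tau is strictly positive;
#' tau = 0 encodes "no information" and never counts as positive.
#'
#' @param pairs A `pair_similarity` data frame.
#' @param metric One of `"tc"`, `"mcc"`, `"dacs"`, or `"random"`
#'   (uniform noise in \[0,1\], the null reference curve).
#' @param threshold Similarity threshold.
#' @param random_seed Seed for the `"random"` metric.
#' @return Proportion in \[0,1\], or `NA` when no pair qualifies
#'   (an empty selection carries no information).
#' @export
fraction_positive_tau <- function(pairs, metric = c("dacs", "tc", "mcc", "random"),
                                  threshold, random_seed = 1L) {
  metric <- match.arg(metric)
  stopifnot_scalar_number(threshold, "threshold")
  vals <- metric_values(pairs, metric, random_seed)
  sel <- vals >= threshold
  if (!any(sel)) return(NA_real_)
  mean(pairs$tau[sel] > 0)
}

metric_values <- function(pairs, metric, random_seed = 1L) {
  if (!all(c("tc", "mcc", "dacs", "tau") %in% names(pairs)))
    dacs_abort("`pairs` must be a pair_similarity table")
  switch(metric,
    tc = pairs$tc, mcc = pairs$mcc, dacs = pairs$dacs,
    random = with_seed(random_seed, stats::runif(nrow(pairs))),
    dacs_abort("unknown metric '%s'", metric))
}

#' Fraction-positive curve over a threshold grid
#'
#' Applies [fraction_positive_tau()] at each grid point and records how
#' many pairs remain above each threshold.
#'
#' @inheritParams fraction_positive_tau
#' @param grid Strictly increasing numeric vector of thresholds
#'   (default 0 to 1.42 in steps of 0.01, covering the DACS range).
#' @return A data frame of class `threshold_curve` with columns
#'   `threshold`, `fraction`, `n_pairs`.
#' @export
threshold_curve <- function(pairs, metric = c("dacs", "tc", "mcc", "random"),
                            grid = seq(0, 1.42, by = 0.01), random_seed = 1L) {
  metric <- match.arg(metric)
  check_grid(grid)
  vals <- metric_values(pairs, metric, random_seed)
  pos <- pairs$tau > 0
  n_pairs <- vapply(grid, function(t) sum(vals >= t), integer(1))
  fraction <- vapply(grid, function(t) {
    sel <- vals >= t
    if (!any(sel)) NA_real_ else mean(pos[sel])
  }, numeric(1))
  out <- data.frame(threshold = grid, fraction = fraction, n_pairs = n_pairs)
  attr(out, "metric") <- metric
  class(out) <- c("threshold_curve", "data.frame")
  out
}

check_grid <- function(grid) {
  if (!is.numeric(grid) || length(grid) < 1L || anyNA(grid))
    dacs_abort("`grid` must be a non-empty numeric vector")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    dacs_abort("`grid` must be strictly increasing")
}

#' Fraction-positive heatmap over TC x MCC bins
#'
#' Bins all pairs by (TC, MCC) and reports, per non-empty bin, the
#' fraction with strictly positive tau, plus the marginal histograms of
#' TC and MCC.
#'
#' @param pairs A `pair_similarity` data frame.
#' @param tc_bins,mcc_bins Increasing bin-edge vectors; intervals are
#'   left-closed, the last right-closed.
#' @return A list of class `dacs_heatmap`: `fraction` and `counts`
#'   matrices (rows = TC bins, columns = MCC bins; `fraction` is `NA`
#'   for empty bins), and `tc_hist`, `mcc_hist` marginal counts.
#' @export
dacs_heatmap <- function(pairs, tc_bins = seq(0, 1, by = 0.1),
                         mcc_bins = seq(-1, 1, by = 0.1)) {
  check_grid(tc_bins); check_grid(mcc_bins)
  if (length(tc_bins) < 2L || length(mcc_bins) < 2L)
    dacs_abort("bin-edge vectors need at least two edges")
  bx <- cut(pairs$tc, tc_bins, include.lowest = TRUE, right = FALSE)
  by <- cut(pairs$mcc, mcc_bins, include.lowest = TRUE, right = FALSE)
  # cut(right = FALSE) leaves the top edge open; fold exact maxima in
  bx[pairs$tc == tc_bins[length(tc_bins)]] <- levels(bx)[nlevels(bx)]
  by[pairs$mcc == mcc_bins[length(mcc_bins)]] <- levels(by)[nlevels(by)]
  if (anyNA(bx) || anyNA(by))
    dacs_abort("pair similarity values fall outside the bin edges")
  counts <- table(bx, by)
  pos <- tapply(pairs$tau > 0, list(bx, by), mean)
  structure(list(
    fraction = unclass(pos),
    counts = unclass(counts),
    tc_bins = tc_bins, mcc_bins = mcc_bins,
    tc_hist = as.vector(table(bx)), mcc_hist = as.vector(table(by)),
    n_pairs = nrow(pairs)), class = "dacs_heatmap")
}

#' @export
print.dacs_heatmap <- function(x, ...) {
  cat(sprintf("dacs_heatmap: %d pairs in %d x %d (TC x MCC) bins, %d non-empty\n",
              x$n_pairs, nrow(x$counts), ncol(x$counts), sum(x$counts > 0)))
  invisible(x)
}

#' Number of usable substitute compounds per DACS threshold
#'
#' For each threshold in `grid`, counts the candidate drugs whose DACS
#' similarity to at least one original drug reaches the threshold. Each
#' candidate is counted once however many originals it matches, so the
#' curve is the size of the usable substitute pool, non-increasing in
#' the threshold.
#'
#' @param originals,candidates [drug_library()] objects; identifier
#'   spaces should be disjoint (shared ids are matched by DACS like any
#'   other candidate).
#' @param universe Protein universe for the MCC component; default is
#'   the union of both libraries' target sets.
#' @param grid Threshold grid, strictly increasing.
#' @return A data frame of class `threshold_curve` with columns
#'   `threshold`, `n_substitutes`.
#' @export
substitute_count_curve <- function(originals, candidates, universe = NULL,
                                   grid = seq(0, 1.42, by = 0.01)) {
  check_grid(grid)
  best <- best_dacs_per_candidate(originals, candidates, universe)
  out <- data.frame(
    threshold = grid,
    n_substitutes = vapply(grid, function(t) sum(best >= t), integer(1)))
  class(out) <- c("threshold_curve", "data.frame")
  out
}

# DACS of every (original, candidate) pair; returns, per candidate, the
# maximum over originals. Candidates without a fingerprint are dropped
# with a warning.
cross_dacs <- function(originals, candidates, universe = NULL) {
  stopifnot(inherits(originals, "drug_library"),
            inherits(candidates, "drug_library"))
  if (is.null(universe))
    universe <- unique(c(unlist(originals$targets), unlist(candidates$targets)))
  fpo <- originals$fingerprints
  fpc <- candidates$fingerprints
  if (ncol(fpo) != ncol(fpc))
    dacs_abort("fingerprint length mismatch between libraries: %d vs %d",
               ncol(fpo), ncol(fpc))
  if (anyNA(fpo))
    dacs_abort("original drug(s) without fingerprints: %s",
               paste(originals$drug_id[rowSums(is.na(fpo)) > 0], collapse = ", "))
  keep <- rowSums(is.na(fpc)) == 0
  if (!all(keep)) {
    warning(sprintf("skipping %d candidate(s) without fingerprints: %s",
                    sum(!keep),
                    paste(candidates$drug_id[!keep], collapse = ", ")),
            call. = FALSE)
    fpc <- fpc[keep, , drop = FALSE]
  }
  cand_ids <- candidates$drug_id[keep]
  storage.mode(fpo) <- "double"; storage.mode(fpc) <- "double"
  inter <- tcrossprod(fpo, fpc)
  uni <- outer(rowSums(fpo), rowSums(fpc), "+") - inter
  tc <- ifelse(uni == 0, 0, inter / uni)
  mcc <- cross_target_mcc(originals$targets, candidates$targets[cand_ids], universe)
  d <- sqrt(tc^2 + pmax(mcc, 0)^2)
  dimnames(d) <- list(originals$drug_id, cand_ids)
  d
}

best_dacs_per_candidate <- function(originals, candidates, universe = NULL) {
  d <- cross_dacs(originals, candidates, universe)
  apply(d, 2L, max)
}

#' Select the operating DACS cutoff from the two threshold curves
#'
#' The substitute-supply curve (counts, falling in the threshold) is
#' min-max normalised to \[0,1\] and intersected with the
#' fraction-positive curve (quality, rising). The crossing point — the
#' threshold where normalised supply equals quality, linearly
#' interpolated between adjacent grid points — balances the two
#' quantities; with several crossings the one at the highest threshold
#' is returned. A contiguous run of exact ties flanked by opposite
#' signs counts as one crossing located where the curves first meet
#' (on a cleanly separated cohort both curves sit at exactly 1.0 across
#' the whole within/between gap, and the first tie is the informative
#' point); a tie run flanked by equal signs is a tangency, not a
#' crossing.
#'
#' @param fraction_curve A [threshold_curve()] with a `fraction` column.
#' @param count_curve A curve over the same grid with an
#'   `n_substitutes` (or `n_pairs`) column.
#' @return A list of class `cutoff_result`: `dacs_cutoff`,
#'   `fraction_positive_at_cutoff`, `n_substitutes_at_cutoff`, and
#'   `crossed` (`FALSE` with `dacs_cutoff = NA` when the curves never
#'   cross on the grid).
#' @export
select_optimal_cutoff <- function(fraction_curve, count_curve) {
  if (!isTRUE(all.equal(fraction_curve$threshold, count_curve$threshold)))
    dacs_abort("the two curves must share the same threshold grid")
  grid <- fraction_curve$threshold
  f <- fraction_curve$fraction
  counts <- count_curve$n_substitutes %||% count_curve$n_pairs
  if (is.null(counts)) dacs_abort("`count_curve` lacks a count column")
  rng <- range(counts)
  g <- if (rng[1] == rng[2]) rep(0, length(counts))
       else (counts - rng[1]) / (rng[2] - rng[1])
  cross_at <- find_crossings(grid, f - g)
  if (!length(cross_at)) {
    res <- list(dacs_cutoff = NA_real_,
                fraction_positive_at_cutoff = NA_real_,
                n_substitutes_at_cutoff = NA_real_, crossed = FALSE)
  } else {
    t0 <- max(cross_at)
    res <- list(
      dacs_cutoff = t0,
      fraction_positive_at_cutoff = interp_at(grid, f, t0),
      n_substitutes_at_cutoff = interp_at(grid, counts, t0),
      crossed = TRUE)
  }
  class(res) <- "cutoff_result"
  res
}

# Locations where a difference curve crosses zero. A sign flip between
# adjacent grid points is located by linear interpolation. A contiguous
# run of exact zeros flanked by opposite signs is one crossing event,
# located at its first tie point (where the curves first meet); a run
# flanked by equal signs is a tangency, not a crossing. Undefined (NA)
# points are excluded and crossings are never interpolated across them.
find_crossings <- function(grid, d) {
  ok <- which(!is.na(d))
  cross_at <- numeric(0)
  runs <- split(ok, cumsum(c(1L, diff(ok) != 1L)))  # contiguous defined spans
  for (idx in runs) {
    dd <- d[idx]; gg <- grid[idx]
    k <- 1L
    while (k < length(dd)) {
      if (dd[k] == 0) { k <- k + 1L; next }
      if (dd[k + 1L] == 0) {
        j <- k + 1L
        while (j < length(dd) && dd[j + 1L] == 0) j <- j + 1L
        if (j < length(dd) && dd[j + 1L] * dd[k] < 0)
          cross_at <- c(cross_at, gg[k + 1L])
        k <- j
      } else if (dd[k] * dd[k + 1L] < 0) {
        w <- dd[k] / (dd[k] - dd[k + 1L])
        cross_at <- c(cross_at, gg[k] + w * (gg[k + 1L] - gg[k]))
        k <- k + 1L
      } else k <- k + 1L
    }
  }
  cross_at
}

interp_at <- function(grid, vals, t0) {
  ok <- !is.na(vals)
  stats::approx(grid[ok], vals[ok], xout = t0, rule = 2)$y
}

#' @export
print.cutoff_result <- function(x, ...) {
  if (!x$crossed) {
    cat("cutoff_result: curves do not cross on the grid\n")
  } else {
    cat(sprintf(
      "cutoff_result: DACS cutoff %.3f (fraction tau>0: %.3f; substitutes: %.0f)\n",
      x$dacs_cutoff, x$fraction_positive_at_cutoff, x$n_substitutes_at_cutoff))
  }
  invisible(x)
}
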