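# Dataset augmentation by compound substitution, labeling, and the
# ratio-preserving training-set expansion.

#' Map each original drug to its admissible substitutes
#'
#' For every original drug, lists the candidate compounds whose DACS
#' similarity to it reaches the cutoff, sorted by descending DACS then
#' identifier. A candidate with the same identifier as the original is
#' never its own substitute; candidates lacking a fingerprint are
#' skipped with a warning.
#'
#' @param originals,candidates [drug_library()] objects.
#' @param universe Protein universe for the MCC component.
#' @param cutoff DACS cutoff in \[0, sqrt(2)\].
#' @return A named list of class `substitute_map`: per original drug a
#'   data frame with columns `drug_id`, `dacs`.
#' @export
build_substitute_map <- function(originals, candidates, universe = NULL,
                                 cutoff) {
  stopifnot_scalar_number(cutoff, "cutoff")
  if (cutoff < 0 || cutoff > sqrt(2) + 1e-12)
    dacs_abort("`cutoff` must lie in [0, sqrt(2)]")
  d <- cross_dacs(originals, candidates, universe)
  out <- lapply(rownames(d), function(orig) {
    v <- d[orig, ]
    v <- v[names(v) != orig & v >= cutoff]
    ord <- order(-v, names(v))
    data.frame(drug_id = names(v)[ord], dacs = unname(v)[ord],
               stringsAsFactors = FALSE)
  })
  names(out) <- rownames(d)
  structure(out, cutoff = cutoff, class = "substitute_map")
}

#' @export
print.substitute_map <- function(x, ...) {
  ns <- vapply(unclass(x), nrow, integer(1))
  cat(sprintf(
    "substitute_map: %d original drugs, cutoff %.3f, %d substitute links (%d drugs with >=1)\n",
    length(x), attr(x, "cutoff"), sum(ns), sum(ns > 0)))
  invisible(x)
}

ensure_instance_ids <- function(instances) {
  if (is.null(instances$instance_id))
    instances$instance_id <- sprintf("I%05d", seq_len(nrow(instances)))
  if (anyDuplicated(instances$instance_id))
    dacs_abort("duplicate instance_id values")
  instances
}

#' Augment a synergy dataset by compound substitution
#'
#' For each original instance (drug_a, drug_b, cell line, score) and
#' each position in turn (a, then b), every admissible substitute of
#' the drug at that position generates a new instance on the same cell
#' line inheriting the parent's synergy score — the central assumption:
#' a compound with very similar chemistry and targets triggers the same
#' combination effect. Generated pairs where the substitute equals the
#' partner drug are dropped; duplicates on the (canonical pair, cell
#' line) key are removed keeping originals first, then the earliest
#' generated occurrence (conflicting parents are reported via a
#' warning).
#'
#' @param instances Data frame of original synergy instances with
#'   columns `drug_a`, `drug_b`, `cell_line`, `synergy_score`, optional
#'   `qa_score` and `instance_id`.
#' @param subs A [build_substitute_map()] result.
#' @return Data frame with the original columns plus `instance_id`,
#'   `provenance` (`"original"`/`"augmented"`), `parent_id`, and
#'   `substituted_position` (`"a"`, `"b"`, or `"none"`). Attribute
#'   `n_generated` holds the pre-deduplication generated count.
#' @export
augment_dataset <- function(instances, subs) {
  stopifnot(inherits(subs, "substitute_map"))
  need <- c("drug_a", "drug_b", "cell_line", "synergy_score")
  if (!all(need %in% names(instances)))
    dacs_abort("instances need columns %s", paste(need, collapse = ", "))
  if (!is.null(instances$provenance) && any(instances$provenance != "original"))
    dacs_abort("augmenting an already-augmented dataset is not allowed")
  instances <- ensure_instance_ids(instances)
  cp <- canonical_pair(instances$drug_a, instances$drug_b)
  instances$drug_a <- cp$a; instances$drug_b <- cp$b
  if (any(instances$drug_a == instances$drug_b))
    dacs_abort("instances with drug_a == drug_b are invalid")
  instances$provenance <- "original"
  instances$parent_id <- NA_character_
  instances$substituted_position <- "none"
  if (is.null(instances$qa_score)) instances$qa_score <- NA_real_

  gen <- list()
  for (pos in c("a", "b")) {
    repl_col <- if (pos == "a") "drug_a" else "drug_b"
    keep_col <- if (pos == "a") "drug_b" else "drug_a"
    sub_n <- vapply(unclass(subs)[instances[[repl_col]]],
                    function(s) if (is.null(s)) 0L else nrow(s), integer(1))
    idx <- rep(seq_len(nrow(instances)), sub_n)
    if (!length(idx)) next
    sub_ids <- unlist(lapply(unclass(subs)[instances[[repl_col]]],
                             function(s) if (is.null(s)) character(0) else s$drug_id),
                      use.names = FALSE)
    partner <- instances[[keep_col]][idx]
    ok <- sub_ids != partner
    if (!any(ok)) next
    cpn <- canonical_pair(sub_ids[ok], partner[ok])
    gen[[pos]] <- data.frame(
      instance_id = NA_character_,
      drug_a = cpn$a, drug_b = cpn$b,
      cell_line = instances$cell_line[idx][ok],
      synergy_score = instances$synergy_score[idx][ok],
      qa_score = instances$qa_score[idx][ok],
      provenance = "augmented",
      parent_id = instances$instance_id[idx][ok],
      substituted_position = pos,
      stringsAsFactors = FALSE)
  }
  # interleave per parent in (a, b) order so generation order is
  # "for each instance, position a then b"
  gen_all <- if (length(gen)) do.call(rbind, gen) else NULL
  n_dropped_self <- 0L
  if (!is.null(gen_all) && nrow(gen_all)) {
    ord <- order(match(gen_all$parent_id, instances$instance_id),
                 match(gen_all$substituted_position, c("a", "b")))
    gen_all <- gen_all[ord, ]
    key <- paste(gen_all$drug_a, gen_all$drug_b, gen_all$cell_line, sep = "\r")
    okey <- paste(instances$drug_a, instances$drug_b, instances$cell_line, sep = "\r")
    dup <- duplicated(key) | key %in% okey
    if (any(dup)) {
      first_score <- instances$synergy_score[match(key[dup], okey)]
      gfirst <- match(key[dup], key)
      first_score[is.na(first_score)] <- gen_all$synergy_score[gfirst[is.na(first_score)]]
      n_conflict <- sum(abs(first_score - gen_all$synergy_score[dup]) > 1e-9)
      if (n_conflict > 0)
        warning(sprintf(
          "dropped %d duplicate generated instance(s) whose synergy score conflicts with the kept occurrence",
          n_conflict), call. = FALSE)
    }
    gen_all <- gen_all[!dup, ]
    if (nrow(gen_all))
      gen_all$instance_id <- sprintf("A%06d", seq_len(nrow(gen_all)))
  }
  cols <- c("instance_id", "drug_a", "drug_b", "cell_line", "synergy_score",
            "qa_score", "provenance", "parent_id", "substituted_position")
  out <- rbind(instances[, cols],
               if (!is.null(gen_all)) gen_all[, cols])
  rownames(out) <- NULL
  attr(out, "n_original") <- nrow(instances)
  attr(out, "n_generated") <- nrow(out) - nrow(instances)
  out
}

#' Label synergy instances for classification
#'
#' Scores at or above `syn_cut` are synergistic, at or below `ant_cut`
#' antagonistic; the ambiguous middle band is excluded.
#'
#' @param instances Data frame with a `synergy_score` column.
#' @param syn_cut,ant_cut Label cutoffs (defaults 20 and -20).
#' @return The labeled subset with an added `label` column, class
#'   `labeled_instances`; its class balance is available through
#'   [class_balance()] on the attached counts (attributes `n_synergistic`,
#'   `n_antagonistic`, `n_excluded`).
#' @export
label_instances <- function(instances, syn_cut = 20, ant_cut = -20) {
  stopifnot_scalar_number(syn_cut, "syn_cut")
  stopifnot_scalar_number(ant_cut, "ant_cut")
  if (syn_cut <= ant_cut) dacs_abort("`syn_cut` must exceed `ant_cut`")
  s <- instances$synergy_score
  if (is.null(s)) dacs_abort("instances need a `synergy_score` column")
  label <- ifelse(s >= syn_cut, "synergistic",
                  ifelse(s <= ant_cut, "antagonistic", NA_character_))
  keep <- !is.na(label)
  out <- instances[keep, , drop = FALSE]
  out$label <- label[keep]
  rownames(out) <- NULL
  attr(out, "n_synergistic") <- sum(out$label == "synergistic")
  attr(out, "n_antagonistic") <- sum(out$label == "antagonistic")
  attr(out, "n_excluded") <- sum(!keep)
  class(out) <- c("labeled_instances", "data.frame")
  out
}

#' @export
print.labeled_instances <- function(x, ...) {
  cb <- class_balance(attr(x, "n_synergistic"), attr(x, "n_antagonistic"))
  cat(sprintf(
    "labeled_instances: %d synergistic + %d antagonistic = %d (%.1f%% synergistic); %d ambiguous excluded\n",
    cb$n_synergistic, cb$n_antagonistic, cb$total, cb$pct_synergistic,
    attr(x, "n_excluded")))
  invisible(x)
}

#' Class-balance summary from class counts
#'
#' @param n_synergistic,n_antagonistic Non-negative instance counts.
#' @return List with `n_synergistic`, `n_antagonistic`, `total`, and
#'   `pct_synergistic` (percentage of the total, 1 decimal semantics
#'   left to the caller).
#' @export
class_balance <- function(n_synergistic, n_antagonistic) {
  stopifnot_scalar_number(n_synergistic, "n_synergistic")
  stopifnot_scalar_number(n_antagonistic, "n_antagonistic")
  total <- n_synergistic + n_antagonistic
  list(n_synergistic = n_synergistic,
       n_antagonistic = n_antagonistic,
       total = total,
       pct_synergistic = if (total > 0) 100 * n_synergistic / total else NA_real_)
}

#' Expand a training set from an augmented pool, preserving class ratio
#'
#' Adds augmented instances to a labeled training set so that the
#' synergistic:antagonistic ratio of the training set is preserved
#' (added counts within one instance of exact proportionality). The
#' addition is maximal under that constraint and the pool's per-class
#' availability; when one class runs short the other is limited
#' accordingly and the unused pool size is reported as the `shortfall`
#' attribute. Selection within a class is a seeded shuffle, so the
#' result is deterministic given `seed`.
#'
#' Every pool instance must derive from a parent inside `train` — the
#' guard against augmented copies of held-out instances leaking into
#' training.
#'
#' @param train Labeled original instances (with `label`,
#'   `instance_id`).
#' @param pool Labeled augmented instances (with `label`, `parent_id`).
#' @param seed Integer seed for within-class selection.
#' @return `train` plus the selected pool rows; attributes `n_added`
#'   (per class) and `shortfall` (pool rows unusable under the ratio
#'   constraint).
#' @export
ratio_preserving_augment <- function(train, pool, seed = 1L) {
  if (!nrow(pool)) {
    attr(train, "n_added") <- c(synergistic = 0L, antagonistic = 0L)
    attr(train, "shortfall") <- 0L
    return(train)
  }
  if (is.null(train$label) || is.null(pool$label))
    dacs_abort("both `train` and `pool` must carry a `label` column")
  if (is.null(pool$parent_id) || anyNA(pool$parent_id))
    dacs_abort("pool instances must carry `parent_id`")
  outside <- setdiff(pool$parent_id, train$instance_id)
  if (length(outside))
    dacs_abort("pool instance(s) derive from parents outside the training set: %s",
               paste(utils::head(outside, 5L), collapse = ", "))
  ns <- sum(train$label == "synergistic")
  na <- sum(train$label == "antagonistic")
  if (ns == 0L || na == 0L)
    dacs_abort("training set must contain both classes")
  pool_s <- which(pool$label == "synergistic")
  pool_a <- which(pool$label == "antagonistic")
  alpha <- min(length(pool_s) / ns, length(pool_a) / na)
  k_s <- floor(alpha * ns); k_a <- floor(alpha * na)
  sel_s <- with_seed(seed, sample(pool_s))[seq_len(k_s)]
  sel_a <- with_seed(seed + 1L, sample(pool_a))[seq_len(k_a)]
  add <- pool[sort(c(sel_s, sel_a)), , drop = FALSE]
  keep_cols <- intersect(names(train), names(add))
  out <- rbind(as.data.frame(train)[, keep_cols, drop = FALSE],
               as.data.frame(add)[, keep_cols, drop = FALSE])
  rownames(out) <- NULL
  class(out) <- class(train)
  attr(out, "n_added") <- c(synergistic = k_s, antagonistic = k_a)
  attr(out, "shortfall") <- nrow(pool) - k_s - k_a
  out
}

#' Mean, spread and histogram of synergy scores
#'
#' Population mean and standard deviation plus a fixed-width histogram,
#' used to check that augmentation does not distort the synergy-score
#' distribution (augmented scores are inherited, so only the mixture
#' weights can shift).
#'
#' @param instances Data frame with `synergy_score`, or a numeric
#'   vector of scores.
#' @param binwidth Histogram bin width (default 5 score units).
#' @return List of class `synergy_summary`: `n`, `mean`, `sd`
#'   (population), `histogram` (data frame `mid`, `count`).
#' @export
synergy_distribution_summary <- function(instances, binwidth = 5) {
  s <- if (is.numeric(instances)) instances else instances$synergy_score
  if (is.null(s) || !length(s)) dacs_abort("no synergy scores supplied")
  if (anyNA(s)) dacs_abort("synergy scores contain missing values")
  m <- mean(s)
  sdev <- sqrt(mean((s - m)^2))
  lo <- floor(min(s) / binwidth) * binwidth
  hi <- ceiling(max(s) / binwidth) * binwidth
  if (hi == lo) hi <- lo + binwidth
  breaks <- seq(lo, hi, by = binwidth)
  h <- graphics::hist(s, breaks = breaks, plot = FALSE)
  structure(list(n = length(s), mean = m, sd = sdev,
                 histogram = data.frame(mid = h$mids, count = h$counts)),
            class = "synergy_summary")
}

#' @export
print.synergy_summary <- function(x, ...) {
  cat(sprintf("synergy_summary: n = %d, mean %.1f +/- %.1f (population sd)\n",
              x$n, x$mean, x$sd))
  invisible(x)
}
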