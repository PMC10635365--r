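# Pairwise drug-similarity metrics and the DACS score.
#
# Three complementary views of drug-drug similarity are combined:
#   * pharmacological response: Kendall tau-b between monotherapy pIC50
#     profiles over the cell lines both drugs were tested on;
#   * mechanism of action: Matthews correlation over the 2x2 table of
#     proteins targeted by both / one / neither drug in a fixed universe;
#   * chemistry: Tanimoto coefficient between binary fingerprints.
# The DACS score fuses chemistry and mechanism: sqrt(TC^2 + max(MCC,0)^2).

#' Concordance counts between two monotherapy profiles
#'
#' Classifies every pair of shared cell lines as concordant, discordant,
#' or tied (in the first list only, the second list only, or both), the
#' raw counts entering the tau-b formula.
#'
#' @param x,y Named numeric vectors mapping cell-line identifiers to
#'   pIC50 values. Only cell lines named in both vectors are used.
#' @return A list with components `nc` (concordant), `nd` (discordant),
#'   `n1` (tied only in `x`), `n2` (tied only in `y`), `nb` (tied in
#'   both) and `m` (number of shared cell lines).
#' @seealso [kendall_tau_b()]
#' @export
concordance_counts <- function(x, y) {
  common <- intersect(names(x), names(y))
  xv <- unname(x[common]); yv <- unname(y[common])
  m <- length(common)
  if (m < 2L)
    return(list(nc = 0L, nd = 0L, n1 = 0L, n2 = 0L, nb = 0L, m = m))
  idx <- utils::combn(m, 2L)
  dx <- sign(xv[idx[2L, ]] - xv[idx[1L, ]])
  dy <- sign(yv[idx[2L, ]] - yv[idx[1L, ]])
  list(
    nc = sum(dx * dy > 0),
    nd = sum(dx * dy < 0),
    n1 = sum(dx == 0 & dy != 0),
    n2 = sum(dx != 0 & dy == 0),
    nb = sum(dx == 0 & dy == 0),
    m  = m
  )
}

#' Kendall tau-b between two monotherapy pIC50 profiles
#'
#' Rank correlation with tie correction,
#' \deqn{\tau_b = (n_c - n_d) / \sqrt{(n_c+n_d+n_1)(n_c+n_d+n_2)},}
#' computed over the intersection of cell lines. Two drugs with a
#' positive tau inhibit growth of the same cell lines and are inert
#' against the same cell lines, i.e. trigger similar pharmacological
#' responses. By convention the coefficient is 0 when fewer than two
#' cell lines are shared, and 0 when either list is constant over the
#' intersection (the denominator vanishes): no evidence, no association.
#'
#' Ties in pIC50 are detected by exact equality of the parsed values.
#'
#' @inheritParams concordance_counts
#' @return tau-b in \[-1, 1\].
#' @examples
#' a <- c(L1 = 5.1, L2 = 6.0, L3 = 7.2)
#' b <- c(L1 = 4.8, L2 = 5.5, L3 = 6.9)
#' kendall_tau_b(a, b)  # identical ranking -> 1
#' @export
kendall_tau_b <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || anyNA(x) || anyNA(y) ||
      any(!is.finite(x)) || any(!is.finite(y)))
    dacs_abort("pIC50 profiles must be finite numeric vectors")
  if (is.null(names(x)) || is.null(names(y)))
    dacs_abort("pIC50 profiles must be named by cell line")
  cc <- concordance_counts(x, y)
  if (cc$m < 2L) return(0)
  denom <- sqrt((cc$nc + cc$nd + cc$n1) * (cc$nc + cc$nd + cc$n2))
  if (denom == 0) return(0)
  max(-1, min(1, (cc$nc - cc$nd) / denom))
}

#' Matthews correlation between two drugs' target sets
#'
#' Builds the 2x2 contingency of a fixed protein universe — `T` proteins
#' targeted by both drugs, `A` only by the first, `B` only by the
#' second, `N` by neither — and returns
#' \deqn{MCC = (TN - AB) / \sqrt{(T+A)(T+B)(N+A)(N+B)}.}
#' A high positive value indicates substantially overlapping molecular
#' targets, hence a similar mechanism of action. When any marginal is
#' zero (a drug with no targets, or targeting the whole universe) the
#' ratio is undefined and 0 is returned.
#'
#' @param targets_a,targets_b Character vectors of protein identifiers;
#'   must be subsets of `universe`.
#' @param universe Character vector: every protein under consideration.
#' @return MCC in \[-1, 1\].
#' @export
target_mcc <- function(targets_a, targets_b, universe) {
  targets_a <- unique(as.character(targets_a))
  targets_b <- unique(as.character(targets_b))
  universe <- unique(as.character(universe))
  bad <- setdiff(c(targets_a, targets_b), universe)
  if (length(bad))
    dacs_abort("target(s) outside the protein universe: %s",
               paste(utils::head(bad, 5L), collapse = ", "))
  ct <- target_contingency(targets_a, targets_b, length(universe))
  mcc_from_contingency(ct$T, ct$N, ct$A, ct$B)
}

target_contingency <- function(targets_a, targets_b, universe_size) {
  Tt <- length(intersect(targets_a, targets_b))
  A <- length(targets_a) - Tt
  B <- length(targets_b) - Tt
  N <- universe_size - Tt - A - B
  list(T = Tt, N = N, A = A, B = B, universe_size = universe_size)
}

mcc_from_contingency <- function(Tt, N, A, B) {
  marg <- c(Tt + A, Tt + B, N + A, N + B)
  if (any(marg == 0)) return(0)
  max(-1, min(1, (Tt * N - A * B) / sqrt(prod(marg))))
}

#' Tanimoto coefficient between binary fingerprints
#'
#' Shared on-bits divided by the union of on-bits. Fingerprints must
#' have the same length; two all-zero fingerprints score 0 (no shared
#' chemistry evidence).
#'
#' @param fp_a,fp_b Logical or 0/1 numeric vectors of equal length.
#' @return Tanimoto coefficient in \[0, 1\].
#' @export
tanimoto <- function(fp_a, fp_b) {
  a <- as.logical(fp_a); b <- as.logical(fp_b)
  if (length(a) != length(b))
    dacs_abort("fingerprint length mismatch: %d vs %d", length(a), length(b))
  if (anyNA(a) || anyNA(b))
    dacs_abort("fingerprints must be binary with no missing values")
  uni <- sum(a | b)
  if (uni == 0) return(0)
  sum(a & b) / uni
}

#' The DACS drug action/chemical similarity score
#'
#' Euclidean combination of chemical and mechanistic similarity,
#' \deqn{DACS = \sqrt{TC^2 + \max(MCC, 0)^2},}
#' ranging over \[0, sqrt(2)\]. Negative MCC values carry no evidence of
#' shared action and are clamped to 0 before squaring, so one
#' sufficiently strong component can carry a pair over a threshold on
#' its own.
#'
#' @param tc Tanimoto coefficient(s) in \[0, 1\].
#' @param mcc Target-set MCC value(s) in \[-1, 1\].
#' @return Numeric vector of DACS scores.
#' @examples
#' dacs_score(0.3, 0.4)   # 0.5
#' dacs_score(0.5, -0.2)  # 0.5: negative MCC clamped
#' @export
dacs_score <- function(tc, mcc) {
  if (!is.numeric(tc) || !is.numeric(mcc) || anyNA(tc) || anyNA(mcc))
    dacs_abort("`tc` and `mcc` must be numeric without missing values")
  if (any(tc < 0 | tc > 1))
    dacs_abort("`tc` out of [0, 1]")
  if (any(mcc < -1 | mcc > 1))
    dacs_abort("`mcc` out of [-1, 1]")
  sqrt(tc^2 + pmax(mcc, 0)^2)
}

#' Assemble a drug library
#'
#' Bundles identifiers, optional SMILES, binary fingerprints and target
#' sets into the record the similarity and augmentation stages consume.
#' Fingerprints are computed from SMILES with [path_fingerprint()] when
#' not supplied directly; any externally computed fixed-length binary
#' fingerprint matrix (e.g. Open Babel FP2 bits) may be passed instead.
#'
#' @param drug_id Character vector of unique drug identifiers.
#' @param smiles Optional character vector of SMILES strings (NA allowed
#'   per drug).
#' @param fingerprints Optional 0/1 matrix, one row per drug; rows of NA
#'   mark drugs without a fingerprint.
#' @param targets Optional named list of protein-identifier vectors.
#' @param nbits Fingerprint length used when hashing SMILES.
#' @return An object of class `drug_library`.
#' @export
drug_library <- function(drug_id, smiles = NULL, fingerprints = NULL,
                         targets = NULL, nbits = 1024L) {
  drug_id <- as.character(drug_id)
  if (anyDuplicated(drug_id))
    dacs_abort("duplicate drug_id: %s",
               paste(unique(drug_id[duplicated(drug_id)]), collapse = ", "))
  n <- length(drug_id)
  if (is.null(fingerprints)) {
    if (is.null(smiles)) dacs_abort("supply `smiles` or `fingerprints`")
    fingerprints <- path_fingerprint(smiles, nbits = nbits)
  } else {
    fingerprints <- as.matrix(fingerprints)
    if (nrow(fingerprints) != n)
      dacs_abort("fingerprint matrix must have one row per drug")
  }
  rownames(fingerprints) <- drug_id
  if (is.null(targets)) {
    targets <- rep(list(character()), n)
    names(targets) <- drug_id
  } else {
    targets <- lapply(targets, as.character)
    missing <- setdiff(drug_id, names(targets))
    targets[missing] <- rep(list(character()), length(missing))
    targets <- targets[drug_id]
  }
  structure(
    list(drug_id = drug_id,
         smiles = if (is.null(smiles)) rep(NA_character_, n) else as.character(smiles),
         fingerprints = fingerprints,
         targets = targets),
    class = "drug_library")
}

#' @export
print.drug_library <- function(x, ...) {
  cat(sprintf("drug_library: %d drugs, %d fingerprint bits, %d with targets\n",
              length(x$drug_id), ncol(x$fingerprints),
              sum(lengths(x$targets) > 0)))
  invisible(x)
}

# Convert a long monotherapy table (DRUG, CELL_LINE, PIC50) into the
# named-list-of-named-vectors form the scalar operations take.
#' Monotherapy table to per-drug profile list
#'
#' @param mono A data frame with columns `DRUG`, `CELL_LINE`, `PIC50`.
#' @return Named list: drug id -> named numeric vector (cell -> pIC50).
#' @export
profile_list <- function(mono) {
  need <- c("DRUG", "CELL_LINE", "PIC50")
  if (!all(need %in% names(mono)))
    dacs_abort("monotherapy table needs columns %s", paste(need, collapse = ", "))
  if (any(!is.finite(mono$PIC50)))
    dacs_abort("non-finite pIC50 values in monotherapy table")
  key <- paste(mono$DRUG, mono$CELL_LINE)
  if (anyDuplicated(key))
    dacs_abort("duplicate (drug, cell line) monotherapy rows: %s",
               paste(utils::head(unique(key[duplicated(key)]), 5L), collapse = "; "))
  split_idx <- split(seq_len(nrow(mono)), mono$DRUG)
  lapply(split_idx, function(i) {
    v <- mono$PIC50[i]
    names(v) <- mono$CELL_LINE[i]
    v
  })
}

#' All-pairs similarity table for a drug library
#'
#' Computes TC, target MCC, Kendall tau-b and DACS for every unordered
#' pair of drugs in the library: n drugs give n(n-1)/2 rows in
#' canonical (lexicographic) pair order.
#'
#' @param library A [drug_library()].
#' @param profiles Optional named list of monotherapy profiles (see
#'   [profile_list()]); pairs lacking two common cell lines get tau 0.
#' @param universe Protein universe for [target_mcc()]; defaults to the
#'   union of all target sets in the library.
#' @return A data frame of class `pair_similarity` with columns
#'   `drug_a`, `drug_b`, `tc`, `mcc`, `tau`, `n_common_cells`, `dacs`.
#' @export
pairwise_similarity <- function(library, profiles = NULL, universe = NULL) {
  stopifnot(inherits(library, "drug_library"))
  ids <- sort(library$drug_id)
  n <- length(ids)
  if (n < 2L) dacs_abort("need at least two drugs")
  if (is.null(universe)) universe <- unique(unlist(library$targets))

  fp <- library$fingerprints[ids, , drop = FALSE]
  if (anyNA(fp))
    dacs_abort("drug(s) without fingerprints: %s",
               paste(ids[rowSums(is.na(fp)) > 0], collapse = ", "))
  storage.mode(fp) <- "double"
  inter <- tcrossprod(fp)
  on_bits <- rowSums(fp)
  uni <- outer(on_bits, on_bits, "+") - inter
  tc_mat <- ifelse(uni == 0, 0, inter / uni)

  mcc_mat <- cross_target_mcc(library$targets[ids], library$targets[ids], universe)

  ii <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  jj <- sequence((n - 1L):1L) + ii
  drug_a <- ids[ii]; drug_b <- ids[jj]

  tau <- numeric(length(ii))
  ncc <- integer(length(ii))
  if (!is.null(profiles)) {
    for (k in seq_along(ii)) {
      pa <- profiles[[drug_a[k]]]; pb <- profiles[[drug_b[k]]]
      if (!is.null(pa) && !is.null(pb)) {
        ncc[k] <- length(intersect(names(pa), names(pb)))
        tau[k] <- kendall_tau_b(pa, pb)
      }
    }
  }
  tc <- tc_mat[cbind(ii, jj)]
  mcc <- mcc_mat[cbind(ii, jj)]
  out <- data.frame(
    drug_a = drug_a, drug_b = drug_b,
    tc = tc, mcc = mcc, tau = tau,
    n_common_cells = ncc,
    dacs = dacs_score(tc, mcc),
    stringsAsFactors = FALSE)
  class(out) <- c("pair_similarity", "data.frame")
  out
}

# MCC between every pair (row set x column set) of target lists, from
# incidence-matrix cross products; degenerate marginals give 0.
cross_target_mcc <- function(targets_rows, targets_cols, universe) {
  U <- length(universe)
  inc <- function(tl) {
    m <- matrix(0, length(tl), U, dimnames = list(names(tl), NULL))
    for (i in seq_along(tl)) {
      idx <- match(tl[[i]], universe)
      if (anyNA(idx))
        dacs_abort("target(s) outside the protein universe: %s",
                   paste(utils::head(tl[[i]][is.na(idx)], 5L), collapse = ", "))
      m[i, idx] <- 1
    }
    m
  }
  Zr <- inc(targets_rows); Zc <- inc(targets_cols)
  Tt <- tcrossprod(Zr, Zc)
  na <- rowSums(Zr); nb <- rowSums(Zc)
  A <- outer(na, nb, function(x, y) x) - Tt
  B <- outer(na, nb, function(x, y) y) - Tt
  N <- U - Tt - A - B
  num <- Tt * N - A * B
  m1 <- Tt + A; m2 <- Tt + B; m3 <- N + A; m4 <- N + B
  den <- sqrt(m1 * m2 * m3 * m4)
  out <- ifelse(m1 == 0 | m2 == 0 | m3 == 0 | m4 == 0, 0,
                num / ifelse(den == 0, 1, den))
  out[] <- pmax(-1, pmin(1, out))   # clamp rounding spill, keep dims
  out
}

#' @export
print.pair_similarity <- function(x, ...) {
  cat(sprintf("pair_similarity: %d drug pairs\n", nrow(x)))
  cat(sprintf("  DACS: min %.3f, median %.3f, max %.3f\n",
              min(x$dacs), stats::median(x$dacs), max(x$dacs)))
  cat(sprintf("  pairs with tau > 0: %d (%.1f%%)\n",
              sum(x$tau > 0), 100 * mean(x$tau > 0)))
  print.data.frame(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat(sprintf("  ... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}
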