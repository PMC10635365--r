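# Synthetic cohorts with the statistical structure the augmentation
# method assumes: drugs fall into latent pharmacological clusters whose
# members share chemistry (mutated copies of a cluster scaffold
# molecule), protein targets, and monotherapy response profiles, and
# whose pairwise synergy is a cluster-pair property. Every table the
# real pipeline consumes is emulated, so all stages run without
# downloads.

#' Specification of a synthetic drug-synergy cohort
#'
#' Defaults describe a small but structured study: 12 pharmacological
#' clusters of 4 original drugs, 40 candidate substitutes drawn from
#' the same clusters, 25 cell lines spread over 5 tissue groups,
#' 300-gene expression profiles, a 150-protein target universe, and
#' synergy driven by a latent cluster-pair surface of magnitude
#' `synergy_effect_size` with additive Gaussian noise.
#'
#' @param n_clusters Number of latent drug clusters.
#' @param drugs_per_cluster Original drugs per cluster.
#' @param n_candidates Candidate substitute compounds (assigned to
#'   random clusters; no monotherapy profiles, like database compounds
#'   never screened in the synergy study).
#' @param n_cell_lines Number of cell lines.
#' @param tissues Names of the five tissue groups.
#' @param n_genes Genes in the expression matrix.
#' @param fingerprint_length Fingerprint bits.
#' @param within_cluster_bit_overlap Controls the shared-bit rate
#'   within a cluster: each drug is the cluster scaffold decorated with
#'   `round((1 - overlap) * scaffold_length)` (at least one)
#'   drug-specific substituent branches; 1 requires identical drugs and
#'   is rejected when a cluster holds more than one drug.
#' @param target_overlap Probability a drug keeps each cluster target.
#' @param response_noise_sd Gaussian sd added to the cluster pIC50
#'   surface, in pIC50 units.
#' @param synergy_effect_size Magnitude of the latent cluster-pair
#'   synergy base (score units).
#' @param synergy_noise_sd Gaussian sd of instance-level synergy noise.
#' @param n_instances Synergy instances to draw.
#' @param universe_size Size of the protein universe.
#' @param targets_per_cluster Proteins in each cluster's target set.
#' @param scaffold_length Atoms in each cluster scaffold SMILES.
#' @param prob_synergistic Probability a cluster pair's latent base is
#'   positive (mirrors the ~3:1 synergistic imbalance of real synergy
#'   screens).
#' @param seed Master seed; all tables derive from it reproducibly.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_clusters = 12L, drugs_per_cluster = 4L,
                        n_candidates = 40L, n_cell_lines = 25L,
                        tissues = c("breast", "digestive", "excretory",
                                    "respiratory", "other"),
                        n_genes = 300L, fingerprint_length = 1024L,
                        within_cluster_bit_overlap = 0.85,
                        target_overlap = 0.8,
                        response_noise_sd = 0.3,
                        synergy_effect_size = 30,
                        synergy_noise_sd = 10,
                        n_instances = 400L,
                        universe_size = 150L,
                        targets_per_cluster = 12L,
                        scaffold_length = 14L,
                        prob_synergistic = 0.72,
                        seed = 1L) {
  spec <- as.list(environment())
  counts <- c("n_clusters", "drugs_per_cluster", "n_candidates",
              "n_cell_lines", "n_genes", "fingerprint_length",
              "n_instances", "universe_size", "targets_per_cluster",
              "scaffold_length")
  for (nm in counts)
    if (!is.numeric(spec[[nm]]) || spec[[nm]] < 1) dacs_abort("`%s` must be positive", nm)
  for (nm in c("within_cluster_bit_overlap", "target_overlap", "prob_synergistic"))
    if (spec[[nm]] < 0 || spec[[nm]] > 1) dacs_abort("`%s` must lie in [0, 1]", nm)
  if (within_cluster_bit_overlap >= 1 && drugs_per_cluster > 1L)
    dacs_abort("overlap 1 would force identical drugs within a cluster")
  if (length(tissues) < 1L) dacs_abort("at least one tissue group required")
  class(spec) <- "cohort_spec"
  spec
}

SCAFFOLD_ALPHABET <- c("C", "N", "O", "S", "P")

# One cluster member: the shared backbone decorated with drug-specific
# substituent branches, the way an analog series varies around a common
# scaffold. Backbone paths (the shared fingerprint bits) stay intact;
# branches contribute the drug-private bits.
decorate_scaffold <- function(scaffold, n_dec) {
  n_dec <- min(n_dec, length(scaffold))
  pos <- sort(sample(length(scaffold), n_dec))
  out <- scaffold
  for (p in pos) {
    branch <- paste(sample(SCAFFOLD_ALPHABET, sample(1:2, 1L), replace = TRUE),
                    collapse = "")
    out[p] <- paste0(out[p], "(", branch, ")")
  }
  paste(out, collapse = "")
}

#' Generate a synthetic cohort
#'
#' Draws every table from the spec under a single master seed (split
#' into independent per-table streams): cluster scaffold molecules and
#' their per-drug mutants, cluster target sets, cluster-by-cell pIC50
#' surfaces plus per-drug noise, tissue-structured expression profiles,
#' and synergy instances scored from the latent cluster-pair surface.
#' Latent cluster labels and the synergy surface are returned for test
#' assertions; the pipeline itself never reads them.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort`: `drugs` and `candidates`
#'   ([drug_library()] objects), `drug_clusters`, `candidate_clusters`,
#'   `profiles`, `universe`, `cells` (`CELL_LINE`, `TISSUE`),
#'   `expression` (genes x cells), `instances`, `latent` (cluster-pair
#'   x tissue base surface), `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- split_seed(spec$seed, 8L)

  n_drugs <- spec$n_clusters * spec$drugs_per_cluster
  # one shared identifier namespace, interleaved: compound identifiers in
  # real databases carry no information about which study a drug sits in,
  # so substitutes must not sort systematically before or after originals
  # (canonical pair ordering would otherwise funnel every substitute into
  # the same feature slot)
  drug_ids <- sprintf("C%04d", 2L * seq_len(n_drugs) - 1L)
  cand_ids <- sprintf("C%04d", 2L * seq_len(spec$n_candidates))
  n_dec <- max(1L, round((1 - spec$within_cluster_bit_overlap) * spec$scaffold_length))

  # chemistry: cluster scaffolds and mutated members
  chem <- with_seed(seeds[1], {
    scaffolds <- replicate(spec$n_clusters,
      sample(SCAFFOLD_ALPHABET, spec$scaffold_length, replace = TRUE),
      simplify = FALSE)
    drug_cluster <- rep(seq_len(spec$n_clusters), each = spec$drugs_per_cluster)
    cand_cluster <- sample(spec$n_clusters, spec$n_candidates, replace = TRUE)
    list(drug_cluster = drug_cluster, cand_cluster = cand_cluster,
         drug_smiles = vapply(drug_cluster, function(cl)
           decorate_scaffold(scaffolds[[cl]], n_dec), character(1)),
         cand_smiles = vapply(cand_cluster, function(cl)
           decorate_scaffold(scaffolds[[cl]], n_dec), character(1)))
  })

  # targets: cluster sets plus per-drug dropout and private additions
  universe <- sprintf("P%04d", seq_len(spec$universe_size))
  tg <- with_seed(seeds[2], {
    cluster_targets <- replicate(spec$n_clusters,
      sample(universe, min(spec$targets_per_cluster, spec$universe_size)),
      simplify = FALSE)
    draw <- function(cl) {
      keep <- cluster_targets[[cl]][stats::runif(length(cluster_targets[[cl]])) <
                                      spec$target_overlap]
      extra <- sample(universe, 2L)
      out <- unique(c(keep, extra))
      if (!length(out)) out <- sample(universe, 1L)
      out
    }
    list(drugs = lapply(chem$drug_cluster, draw),
         cands = lapply(chem$cand_cluster, draw))
  })
  names(tg$drugs) <- drug_ids
  names(tg$cands) <- cand_ids

  # cells and tissues (balanced round-robin assignment)
  cell_ids <- sprintf("CL%02d", seq_len(spec$n_cell_lines))
  cells <- data.frame(
    CELL_LINE = cell_ids,
    TISSUE = rep_len(spec$tissues, spec$n_cell_lines),
    stringsAsFactors = FALSE)

  # monotherapy: cluster-by-cell response surface + per-drug noise;
  # candidate compounds carry no monotherapy profiles
  profiles <- with_seed(seeds[3], {
    base <- matrix(stats::rnorm(spec$n_clusters * spec$n_cell_lines, 6, 1),
                   spec$n_clusters, spec$n_cell_lines,
                   dimnames = list(NULL, cell_ids))
    out <- lapply(seq_len(n_drugs), function(i) {
      v <- base[chem$drug_cluster[i], ] +
        stats::rnorm(spec$n_cell_lines, 0, spec$response_noise_sd)
      names(v) <- cell_ids
      v
    })
    names(out) <- drug_ids
    out
  })

  # expression: tissue base profile + per-cell noise
  expression <- with_seed(seeds[4], {
    tis_base <- matrix(stats::rnorm(spec$n_genes * length(spec$tissues)),
                       spec$n_genes, length(spec$tissues),
                       dimnames = list(sprintf("G%04d", seq_len(spec$n_genes)),
                                       spec$tissues))
    m <- tis_base[, cells$TISSUE, drop = FALSE] +
      matrix(stats::rnorm(spec$n_genes * spec$n_cell_lines, 0, 0.5),
             spec$n_genes, spec$n_cell_lines)
    colnames(m) <- cell_ids
    m
  })

  # latent synergy surface: cluster pair x tissue
  n_cl <- spec$n_clusters
  latent <- with_seed(seeds[5], {
    base <- matrix(0, n_cl, n_cl)
    signs <- sample(c(1, -1), n_cl * (n_cl + 1) / 2, replace = TRUE,
                    prob = c(spec$prob_synergistic, 1 - spec$prob_synergistic))
    k <- 0L
    for (i in seq_len(n_cl)) for (j in i:n_cl) {
      k <- k + 1L
      base[i, j] <- base[j, i] <- signs[k] * spec$synergy_effect_size
    }
    tis_mod <- matrix(stats::rnorm(n_cl^2 * length(spec$tissues), 0, 5),
                      n_cl^2, length(spec$tissues),
                      dimnames = list(NULL, spec$tissues))
    list(base = base, tissue_mod = tis_mod)
  })
  latent_value <- function(cl_a, cl_b, tissue) {
    # symmetric in the cluster pair: synergy is a property of the
    # unordered combination
    lo <- pmin(cl_a, cl_b); hi <- pmax(cl_a, cl_b)
    latent$base[cbind(lo, hi)] +
      latent$tissue_mod[cbind((lo - 1L) * n_cl + hi, match(tissue, spec$tissues))]
  }

  # synergy instances over original drugs
  instances <- with_seed(seeds[6], {
    ia <- sample(n_drugs, 4L * spec$n_instances, replace = TRUE)
    ib <- sample(n_drugs, 4L * spec$n_instances, replace = TRUE)
    keep <- ia != ib
    ia <- ia[keep]; ib <- ib[keep]
    cell <- sample(spec$n_cell_lines, length(ia), replace = TRUE)
    cp <- canonical_pair(drug_ids[ia], drug_ids[ib])
    key <- paste(cp$a, cp$b, cell_ids[cell])
    keep2 <- !duplicated(key)
    take <- utils::head(which(keep2), spec$n_instances)
    ia <- ia[take]; ib <- ib[take]; cell <- cell[take]
    cp <- canonical_pair(drug_ids[ia], drug_ids[ib])
    tissue <- cells$TISSUE[cell]
    mu <- latent_value(chem$drug_cluster[ia], chem$drug_cluster[ib], tissue)
    data.frame(
      instance_id = sprintf("I%05d", seq_along(take)),
      drug_a = cp$a, drug_b = cp$b,
      cell_line = cell_ids[cell],
      synergy_score = mu + stats::rnorm(length(take), 0, spec$synergy_noise_sd),
      qa_score = stats::runif(length(take), -3, 1),
      stringsAsFactors = FALSE)
  })

  structure(list(
    drugs = drug_library(drug_ids, smiles = chem$drug_smiles,
                         targets = tg$drugs, nbits = spec$fingerprint_length),
    candidates = drug_library(cand_ids, smiles = chem$cand_smiles,
                              targets = tg$cands, nbits = spec$fingerprint_length),
    drug_clusters = stats::setNames(chem$drug_cluster, drug_ids),
    candidate_clusters = stats::setNames(chem$cand_cluster, cand_ids),
    profiles = profiles,
    universe = universe,
    cells = cells,
    expression = expression,
    instances = instances,
    latent = c(latent, list(value = latent_value)),
    spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "cohort: %d drugs, %d candidates, %d cell lines (%d tissues), %d synergy instances\n",
    length(x$drugs$drug_id), length(x$candidates$drug_id),
    nrow(x$cells), length(unique(x$cells$TISSUE)), nrow(x$instances)))
  invisible(x)
}

#' A tiny hand-checkable cohort
#'
#' A fixed micro-cohort — four original drugs, two candidate
#' substitutes, four cell lines, six synergy instances — small enough
#' that every similarity value, substitute set and augmented instance
#' can be enumerated by hand. All values are literal constants, so
#' regeneration is byte-identical.
#'
#' @return A list shaped like [generate_cohort()] output (class
#'   `cohort`, without latent fields).
#' @export
worked_fixture <- function() {
  universe <- sprintf("P%02d", 1:10)
  drugs <- drug_library(
    c("d1", "d2", "d3", "d4"),
    smiles = c("CCCCO", "CCCCN", "NCCS", "OCCCCO"),
    targets = list(d1 = c("P01", "P02", "P03"),
                   d2 = c("P01", "P02", "P04"),
                   d3 = c("P07", "P08"),
                   d4 = c("P02", "P03", "P09")),
    nbits = 64L)
  candidates <- drug_library(
    c("s1", "s2"),
    smiles = c("CCCCO", "SCCCS"),
    targets = list(s1 = c("P01", "P02", "P03"), s2 = c("P07", "P10")),
    nbits = 64L)
  cells <- data.frame(
    CELL_LINE = c("c1", "c2", "c3", "c4"),
    TISSUE = c("breast", "digestive", "breast", "respiratory"),
    stringsAsFactors = FALSE)
  profiles <- list(
    d1 = c(c1 = 5.0, c2 = 6.0, c3 = 7.0, c4 = 8.0),
    d2 = c(c1 = 5.2, c2 = 6.1, c3 = 7.3, c4 = 8.2),
    d3 = c(c1 = 8.0, c2 = 7.0, c3 = 6.0, c4 = 5.0),
    d4 = c(c1 = 5.1, c2 = 6.2, c3 = 7.1))
  expression <- matrix(
    c(1, 0, 0, 2,
      0, 1, 0, 1,
      0, 0, 1, 0,
      1, 1, 0, 0,
      0, 1, 1, 1),
    nrow = 5, byrow = TRUE,
    dimnames = list(sprintf("G%02d", 1:5), cells$CELL_LINE))
  instances <- data.frame(
    instance_id = sprintf("I%05d", 1:6),
    drug_a = c("d1", "d1", "d2", "d1", "d3", "d2"),
    drug_b = c("d2", "d3", "d3", "d4", "d4", "d4"),
    cell_line = c("c1", "c2", "c1", "c3", "c4", "c2"),
    synergy_score = c(30, -25, 5, 42, -31, 24),
    qa_score = c(0.5, -1, 0, 1, -2, 0.25),
    stringsAsFactors = FALSE)
  structure(list(
    drugs = drugs, candidates = candidates, profiles = profiles,
    universe = universe, cells = cells, expression = expression,
    instances = instances,
    spec = NULL), class = "cohort")
}
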