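# Readers and writers for the tabular formats. TSV is the canonical
# dialect (tab-separated, header row, UTF-8, '.' decimal, '#' comment
# lines carrying provenance); CSV is accepted on read by extension.
# Identifiers are opaque strings: no case folding, no trimming beyond
# what the parser does.

io_sep <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

read_checked <- function(path, required, numeric_cols = character(0),
                         what = "table") {
  if (!file.exists(path)) dacs_abort("%s file not found: %s", what, path)
  df <- utils::read.delim(path, sep = io_sep(path), header = TRUE,
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  miss <- setdiff(required, names(df))
  if (length(miss))
    dacs_abort("%s: missing column(s) %s", path, paste(miss, collapse = ", "))
  for (cc in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & !is.na(df[[cc]]) & df[[cc]] != "")
    if (length(bad))
      dacs_abort("%s: malformed number in column %s, line %d (value '%s')",
                 path, cc, bad[1] + 1L, df[[cc]][bad[1]])
    df[[cc]] <- v
  }
  dup <- which(duplicated(df))
  if (length(dup))
    dacs_abort("%s: duplicate row(s) at line(s) %s", path,
               paste(utils::head(dup + 1L, 10L), collapse = ", "))
  df
}

#' Read a monotherapy pIC50 table
#'
#' Columns `DRUG`, `CELL_LINE`, `PIC50`; duplicate (drug, cell line)
#' rows are rejected with their line numbers.
#'
#' @param path TSV/CSV file path.
#' @return Data frame with the three columns.
#' @export
read_monotherapy <- function(path) {
  df <- read_checked(path, c("DRUG", "CELL_LINE", "PIC50"), "PIC50",
                     "monotherapy")
  key <- paste(df$DRUG, df$CELL_LINE)
  dup <- which(duplicated(key))
  if (length(dup))
    dacs_abort("%s: duplicate (drug, cell line) row(s) at line(s) %s", path,
               paste(utils::head(dup + 1L, 10L), collapse = ", "))
  df
}

#' Read a drug-target association table
#'
#' STITCH-style columns `DRUG`, `PROTEIN`, optional `SCORE`. An
#' optional confidence filter keeps associations with
#' `SCORE >= min_score` (default: no filter, since reported analyses
#' use the associations as exported).
#'
#' @param path TSV/CSV file path.
#' @param min_score Optional confidence threshold.
#' @return Named list: drug id -> character vector of protein ids.
#' @export
read_targets <- function(path, min_score = NULL) {
  df <- read_checked(path, c("DRUG", "PROTEIN"), "SCORE", "drug-target")
  if (!is.null(min_score)) {
    if (is.null(df$SCORE))
      dacs_abort("%s: confidence filter requested but no SCORE column", path)
    df <- df[df$SCORE >= min_score, , drop = FALSE]
  }
  lapply(split(df$PROTEIN, df$DRUG), unique)
}

#' Read a drug SMILES table
#'
#' Columns `DRUG`, `SMILES`.
#'
#' @param path TSV/CSV file path.
#' @return Named character vector of SMILES keyed by drug id.
#' @export
read_smiles <- function(path) {
  df <- read_checked(path, c("DRUG", "SMILES"), what = "SMILES")
  dup <- which(duplicated(df$DRUG))
  if (length(dup))
    dacs_abort("%s: duplicate DRUG at line(s) %s", path,
               paste(dup + 1L, collapse = ", "))
  stats::setNames(df$SMILES, df$DRUG)
}

#' Read a synergy-instance table
#'
#' Columns `DRUG_A`, `DRUG_B`, `CELL_LINE`, `SYNERGY_SCORE`, optional
#' `QA`, `INSTANCE_ID`, `PROVENANCE`, `PARENT_ID`,
#' `SUBSTITUTED_POSITION`, `LABEL`. Referential integrity against a
#' drug library and cell list can be enforced.
#'
#' @param path TSV/CSV file path.
#' @param known_drugs,known_cells Optional identifier vectors; rows
#'   referencing anything else are rejected with their line numbers.
#' @return Data frame in the package's internal column naming
#'   (`drug_a`, `drug_b`, `cell_line`, `synergy_score`, `qa_score`, ...).
#' @export
read_synergy <- function(path, known_drugs = NULL, known_cells = NULL) {
  df <- read_checked(path, c("DRUG_A", "DRUG_B", "CELL_LINE", "SYNERGY_SCORE"),
                     c("SYNERGY_SCORE", "QA"), "synergy")
  if (!is.null(known_drugs)) {
    bad <- which(!(df$DRUG_A %in% known_drugs) | !(df$DRUG_B %in% known_drugs))
    if (length(bad))
      dacs_abort("%s: unknown drug at line(s) %s", path,
                 paste(utils::head(bad + 1L, 10L), collapse = ", "))
  }
  if (!is.null(known_cells)) {
    bad <- which(!(df$CELL_LINE %in% known_cells))
    if (length(bad))
      dacs_abort("%s: unknown cell line at line(s) %s", path,
                 paste(utils::head(bad + 1L, 10L), collapse = ", "))
  }
  out <- data.frame(drug_a = df$DRUG_A, drug_b = df$DRUG_B,
                    cell_line = df$CELL_LINE,
                    synergy_score = df$SYNERGY_SCORE,
                    stringsAsFactors = FALSE)
  if (!is.null(df$QA)) out$qa_score <- df$QA
  if (!is.null(df$INSTANCE_ID)) out$instance_id <- df$INSTANCE_ID
  if (!is.null(df$PROVENANCE)) out$provenance <- df$PROVENANCE
  if (!is.null(df$PARENT_ID)) {
    out$parent_id <- df$PARENT_ID
    out$parent_id[out$parent_id == ""] <- NA_character_
  }
  if (!is.null(df$SUBSTITUTED_POSITION)) out$substituted_position <- df$SUBSTITUTED_POSITION
  if (!is.null(df$LABEL)) out$label <- df$LABEL
  out
}

#' Read a gene-expression matrix
#'
#' First column `GENE`, remaining columns one per cell line.
#'
#' @param path TSV/CSV file path.
#' @return Numeric matrix genes x cell lines.
#' @export
read_expression <- function(path) {
  df <- read_checked(path, "GENE", what = "expression")
  m <- as.matrix(df[, setdiff(names(df), "GENE"), drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) dacs_abort("%s: non-numeric expression values", path)
  rownames(m) <- df$GENE
  m
}

#' Read cell-line metadata
#'
#' Columns `CELL_LINE`, `TISSUE`.
#'
#' @param path TSV/CSV file path.
#' @return Data frame with the two columns.
#' @export
read_cell_meta <- function(path) {
  df <- read_checked(path, c("CELL_LINE", "TISSUE"), what = "cell metadata")
  dup <- which(duplicated(df$CELL_LINE))
  if (length(dup))
    dacs_abort("%s: duplicate CELL_LINE at line(s) %s", path,
               paste(dup + 1L, collapse = ", "))
  df[, c("CELL_LINE", "TISSUE")]
}

#' Write a table as canonical TSV
#'
#' Tab-separated, header row, '.' decimal, numbers at a fixed 6
#' significant digits so reruns diff clean, preceded by '#' provenance
#' comment lines (package version plus any caller-supplied entries —
#' never a timestamp, so identical runs are byte-identical).
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param provenance Optional named character vector added to the
#'   header comments (e.g. `c(seed = "17")`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, provenance = NULL) {
  df <- as.data.frame(df)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    out <- formatC(v, digits = 6, format = "g")
    out[is.na(v)] <- "NA"
    trimws(out)
  })
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# dacsaug %s",
                     as.character(utils::packageVersion("dacsaug"))), con)
  for (nm in names(provenance))
    writeLines(sprintf("# %s=%s", nm, provenance[[nm]]), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: synergy data frame -> canonical column names for output
synergy_out_columns <- function(df) {
  map <- c(instance_id = "INSTANCE_ID", drug_a = "DRUG_A", drug_b = "DRUG_B",
           cell_line = "CELL_LINE", synergy_score = "SYNERGY_SCORE",
           qa_score = "QA", provenance = "PROVENANCE", parent_id = "PARENT_ID",
           substituted_position = "SUBSTITUTED_POSITION", label = "LABEL")
  keep <- intersect(names(map), names(df))
  out <- df[, keep, drop = FALSE]
  names(out) <- map[keep]
  out
}

#' Write a synergy-instance table
#'
#' @param df Synergy instances in internal column naming.
#' @param path Output path.
#' @param provenance Passed to [write_tsv()].
#' @return `path`, invisibly.
#' @export
write_synergy <- function(df, path, provenance = NULL) {
  write_tsv(synergy_out_columns(df), path, provenance)
}

#' Write all cohort tables to a directory
#'
#' Emits the six canonical files: `synergy.tsv`, `monotherapy.tsv`,
#' `targets.tsv`, `smiles.tsv`, `expression.tsv`, `cell_lines.tsv`,
#' plus `candidates_smiles.tsv` / `candidates_targets.tsv` and
#' `universe.txt` when the cohort carries a candidate library.
#'
#' @param cohort A `cohort` (see [generate_cohort()], [worked_fixture()]).
#' @param dir Output directory (created if needed).
#' @param provenance Passed to [write_tsv()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, provenance = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_synergy(cohort$instances, p("synergy.tsv"), provenance)
  mono <- do.call(rbind, lapply(names(cohort$profiles), function(d)
    data.frame(DRUG = d, CELL_LINE = names(cohort$profiles[[d]]),
               PIC50 = unname(cohort$profiles[[d]]),
               stringsAsFactors = FALSE)))
  write_tsv(mono, p("monotherapy.tsv"), provenance)
  tg <- function(lib) do.call(rbind, lapply(lib$drug_id, function(d)
    if (length(lib$targets[[d]]))
      data.frame(DRUG = d, PROTEIN = lib$targets[[d]], stringsAsFactors = FALSE)))
  write_tsv(tg(cohort$drugs), p("targets.tsv"), provenance)
  write_tsv(data.frame(DRUG = cohort$drugs$drug_id,
                       SMILES = cohort$drugs$smiles, stringsAsFactors = FALSE),
            p("smiles.tsv"), provenance)
  expr <- data.frame(GENE = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, p("expression.tsv"), provenance)
  write_tsv(cohort$cells, p("cell_lines.tsv"), provenance)
  writeLines(cohort$universe, p("universe.txt"))
  if (!is.null(cohort$candidates)) {
    write_tsv(data.frame(DRUG = cohort$candidates$drug_id,
                         SMILES = cohort$candidates$smiles,
                         stringsAsFactors = FALSE),
              p("candidates_smiles.tsv"), provenance)
    write_tsv(tg(cohort$candidates), p("candidates_targets.tsv"), provenance)
  }
  invisible(dir)
}

#' Read a cohort directory back into memory
#'
#' Counterpart of [write_cohort()]; enforces referential integrity of
#' the synergy table against the drug and cell identifiers.
#'
#' @param dir Directory holding the canonical files.
#' @param nbits Fingerprint length used when hashing the SMILES.
#' @return A list of class `cohort` (without latent ground truth).
#' @export
read_cohort <- function(dir, nbits = 1024L) {
  p <- function(f) file.path(dir, f)
  smiles <- read_smiles(p("smiles.tsv"))
  targets <- read_targets(p("targets.tsv"))
  drugs <- drug_library(names(smiles), smiles = unname(smiles),
                        targets = targets, nbits = nbits)
  universe <- if (file.exists(p("universe.txt"))) readLines(p("universe.txt"))
              else unique(unlist(targets))
  cells <- read_cell_meta(p("cell_lines.tsv"))
  instances <- read_synergy(p("synergy.tsv"), known_drugs = names(smiles),
                            known_cells = cells$CELL_LINE)
  candidates <- NULL
  if (file.exists(p("candidates_smiles.tsv"))) {
    csm <- read_smiles(p("candidates_smiles.tsv"))
    ctg <- if (file.exists(p("candidates_targets.tsv")))
      read_targets(p("candidates_targets.tsv")) else NULL
    candidates <- drug_library(names(csm), smiles = unname(csm),
                               targets = ctg, nbits = nbits)
  }
  structure(list(
    drugs = drugs, candidates = candidates,
    profiles = profile_list(read_monotherapy(p("monotherapy.tsv"))),
    universe = universe, cells = cells,
    expression = read_expression(p("expression.tsv")),
    instances = instances, spec = NULL), class = "cohort")
}
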