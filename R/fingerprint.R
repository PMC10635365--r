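# Path-based binary molecular fingerprints from SMILES.
#
# The default fingerprint hashes all linear atom-bond paths of 2-7 atoms
# of the molecular graph into a fixed-length bit vector, the same family
# of descriptor as Open Babel's FP2. The hash is documented and stable:
# a path string (atom labels interleaved with bond symbols, taken in the
# lexicographically smaller of its two reading directions) is folded
# byte-by-byte with h <- (h * 31 + byte) mod (2^31 - 1); the bit index
# is h mod nbits, 1-based.

SMILES_ORGANIC <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
SMILES_AROMATIC <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string into a molecular graph
#'
#' A deliberately small SMILES reader covering the constructs needed for
#' fingerprinting: organic-subset and bracket atoms, aromatic lowercase
#' atoms, single/double/triple/aromatic bonds, branches, ring closures
#' (including `%nn`), and dot-separated components. Stereo bond symbols
#' `/` and `\` are read as single bonds; charges, isotopes and explicit
#' hydrogen counts inside brackets are accepted and ignored.
#'
#' @param smiles A single SMILES string.
#' @return A list with `atoms` (character labels, aromatic atoms
#'   suffixed `:ar`) and `bonds` (data frame `i`, `j`, `order` where
#'   aromatic order is the symbol `":"`).
#' @keywords internal
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles))
    dacs_abort("`smiles` must be a single string")
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  atoms <- character(0)
  bi <- integer(0); bj <- integer(0); bo <- character(0)
  prev <- 0L              # index of the atom to bond the next atom to
  pending_bond <- ""      # explicit bond symbol awaiting the next atom
  stack <- integer(0)     # branch return points
  rings <- list()         # open ring closures: number -> c(atom, bond)
  pos <- 1L

  add_atom <- function(label) {
    atoms[[length(atoms) + 1L]] <<- label
    cur <- length(atoms)
    if (prev > 0L) {
      ord <- pending_bond
      if (ord == "") {
        aromatic <- endsWith(atoms[prev], ":ar") && endsWith(label, ":ar")
        ord <- if (aromatic) ":" else "-"
      }
      bi[[length(bi) + 1L]] <<- prev
      bj[[length(bj) + 1L]] <<- cur
      bo[[length(bo) + 1L]] <<- ord
    }
    pending_bond <<- ""
    prev <<- cur
  }

  close_ring <- function(num) {
    key <- as.character(num)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending_bond)
      pending_bond <<- ""
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      ord <- if (pending_bond != "") pending_bond
             else if (open$bond != "") open$bond
             else if (endsWith(atoms[open$atom], ":ar") && endsWith(atoms[prev], ":ar")) ":"
             else "-"
      bi[[length(bi) + 1L]] <<- open$atom
      bj[[length(bj) + 1L]] <<- prev
      bo[[length(bo) + 1L]] <<- ord
      pending_bond <<- ""
    }
  }

  while (pos <= n) {
    ch <- chars[pos]
    if (ch == "[") {
      close_pos <- pos
      while (close_pos <= n && chars[close_pos] != "]") close_pos <- close_pos + 1L
      if (close_pos > n) dacs_abort("unmatched '[' in SMILES: %s", smiles)
      body <- paste(chars[(pos + 1L):(close_pos - 1L)], collapse = "")
      sym <- regmatches(body, regexpr("[A-Za-z][a-z]?", body))
      if (!length(sym)) dacs_abort("bracket atom without element in SMILES: %s", smiles)
      aromatic <- sym %in% SMILES_AROMATIC
      label <- paste0(toupper(substr(sym, 1L, 1L)), substring(sym, 2L))
      if (aromatic) label <- paste0(toupper(sym), ":ar")
      add_atom(label)
      pos <- close_pos + 1L
    } else if (pos < n && paste0(ch, chars[pos + 1L]) %in% c("Cl", "Br")) {
      add_atom(paste0(ch, chars[pos + 1L]))
      pos <- pos + 2L
    } else if (ch %in% SMILES_ORGANIC || ch == "*") {
      add_atom(ch)
      pos <- pos + 1L
    } else if (ch %in% SMILES_AROMATIC) {
      add_atom(paste0(toupper(ch), ":ar"))
      pos <- pos + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- "-"; pos <- pos + 1L
    } else if (ch == "=") {
      pending_bond <- "="; pos <- pos + 1L
    } else if (ch == "#") {
      pending_bond <- "#"; pos <- pos + 1L
    } else if (ch == ":") {
      pending_bond <- ":"; pos <- pos + 1L
    } else if (ch == "(") {
      if (prev == 0L) dacs_abort("branch before any atom in SMILES: %s", smiles)
      stack <- c(stack, prev); pos <- pos + 1L
    } else if (ch == ")") {
      if (!length(stack)) dacs_abort("unmatched ')' in SMILES: %s", smiles)
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      pos <- pos + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(as.integer(ch)); pos <- pos + 1L
    } else if (ch == "%") {
      if (pos + 2L > n) dacs_abort("truncated '%%nn' ring closure in SMILES: %s", smiles)
      close_ring(as.integer(paste0(chars[pos + 1L], chars[pos + 2L])))
      pos <- pos + 3L
    } else if (ch == ".") {
      prev <- 0L; pending_bond <- ""; pos <- pos + 1L
    } else {
      dacs_abort("unsupported SMILES character '%s' in: %s", ch, smiles)
    }
  }
  if (length(stack)) dacs_abort("unmatched '(' in SMILES: %s", smiles)
  if (length(rings)) dacs_abort("unclosed ring bond(s) in SMILES: %s", smiles)
  list(atoms = atoms,
       bonds = data.frame(i = bi, j = bj, order = bo, stringsAsFactors = FALSE))
}

hash_fragment <- function(s, nbits) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  (h %% nbits) + 1L
}

#' Linear-path binary fingerprint of a molecule
#'
#' Enumerates every simple path of 2 to `max_atoms` atoms in the
#' molecular graph, writes it as an atom/bond string, canonicalises the
#' reading direction, and hashes each distinct fragment to one of
#' `nbits` bit positions (see the hash documented in this file's
#' header). Drugs across one library must use the same `nbits`.
#'
#' @param smiles Character vector of SMILES strings; `NA` entries give
#'   all-`NA` fingerprint rows (drugs without a known structure).
#' @param nbits Fingerprint length in bits (default 1024).
#' @param max_atoms Longest path length in atoms (default 7).
#' @return A 0/1 integer matrix with `length(smiles)` rows and `nbits`
#'   columns (rows of `NA` for missing SMILES).
#' @export
path_fingerprint <- function(smiles, nbits = 1024L, max_atoms = 7L) {
  stopifnot(is.character(smiles), nbits >= 2L, max_atoms >= 2L)
  out <- matrix(0L, length(smiles), nbits)
  for (s in seq_along(smiles)) {
    if (is.na(smiles[s])) { out[s, ] <- NA_integer_; next }
    g <- parse_smiles(smiles[s])
    natoms <- length(g$atoms)
    if (natoms == 0L) next
    adj <- vector("list", natoms)
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[k]; j <- g$bonds$j[k]; o <- g$bonds$order[k]
      adj[[i]] <- rbind(adj[[i]], c(j, k))
      adj[[j]] <- rbind(adj[[j]], c(i, k))
    }
    frags <- new.env(parent = emptyenv())
    walk <- function(path_atoms, path_bonds, visited) {
      depth <- length(path_atoms)
      if (depth >= 2L) {
        fwd <- frag_string(g, path_atoms, path_bonds)
        rev_s <- frag_string(g, rev(path_atoms), rev(path_bonds))
        assign(if (fwd <= rev_s) fwd else rev_s, TRUE, envir = frags)
      }
      if (depth == max_atoms) return(invisible())
      nb <- adj[[path_atoms[depth]]]
      if (is.null(nb)) return(invisible())
      for (r in seq_len(nrow(nb))) {
        nxt <- nb[r, 1L]
        if (!visited[nxt]) {
          visited[nxt] <- TRUE
          walk(c(path_atoms, nxt), c(path_bonds, nb[r, 2L]), visited)
          visited[nxt] <- FALSE
        }
      }
      invisible()
    }
    for (a in seq_len(natoms)) {
      visited <- logical(natoms)
      visited[a] <- TRUE
      walk(a, integer(0), visited)
    }
    for (fr in ls(frags)) out[s, hash_fragment(fr, nbits)] <- 1L
  }
  out
}

frag_string <- function(g, path_atoms, path_bonds) {
  parts <- character(2L * length(path_atoms) - 1L)
  parts[seq(1L, length(parts), by = 2L)] <- g$atoms[path_atoms]
  if (length(path_bonds))
    parts[seq(2L, length(parts), by = 2L)] <- g$bonds$order[path_bonds]
  paste(parts, collapse = "")
}
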