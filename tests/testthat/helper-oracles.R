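# Independent brute-force oracles, kept deliberately naive: they loop
# over every pair / every protein and never share code with the
# implementation they check.

# tau-b by explicit classification of all m(m-1)/2 shared-cell pairs
brute_tau <- function(x, y) {
  common <- intersect(names(x), names(y))
  if (length(common) < 2L) return(0)
  xv <- x[common]; yv <- y[common]
  nc <- nd <- n1 <- n2 <- 0L
  m <- length(common)
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    dx <- xv[j] - xv[i]; dy <- yv[j] - yv[i]
    if (dx == 0 && dy == 0) next
    else if (dx == 0) n1 <- n1 + 1L
    else if (dy == 0) n2 <- n2 + 1L
    else if (sign(dx) == sign(dy)) nc <- nc + 1L
    else nd <- nd + 1L
  }
  den <- sqrt(nc + nd + n1) * sqrt(nc + nd + n2)
  if (den == 0) 0 else (nc - nd) / den
}

# MCC from the explicitly enumerated 2x2 table over the universe
brute_mcc <- function(a, b, universe) {
  Tt <- N <- A <- B <- 0L
  for (p in universe) {
    ina <- p %in% a; inb <- p %in% b
    if (ina && inb) Tt <- Tt + 1L
    else if (ina) A <- A + 1L
    else if (inb) B <- B + 1L
    else N <- N + 1L
  }
  den <- sqrt(Tt + A) * sqrt(Tt + B) * sqrt(N + A) * sqrt(N + B)
  if (den == 0) 0 else (Tt * N - A * B) / den
}

brute_tanimoto <- function(fa, fb) {
  fa <- as.logical(fa); fb <- as.logical(fb)
  u <- sum(fa | fb)
  if (u == 0) 0 else sum(fa & fb) / u
}

# small helper: a drug library from explicit bit lists
lib_from_bits <- function(ids, bit_sets, nbits = 16L, targets = NULL) {
  fp <- matrix(0L, length(ids), nbits)
  for (i in seq_along(bit_sets)) fp[i, bit_sets[[i]]] <- 1L
  drug_library(ids, fingerprints = fp, targets = targets)
}
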