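# Internal helpers shared across modules.

dacs_abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so seeded helpers do not disturb the caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# Derive k reproducible sub-seeds (< 2^31) from one master seed, so each
# synthetic table is independently regenerable.
split_seed <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Canonical ordering of a drug pair
#'
#' Every stored pair uses lexicographic order by drug identifier, so one
#' unordered pair has exactly one representation.
#'
#' @param a,b Character vectors of drug identifiers (recycled together).
#' @return A list with components `a` and `b`, where `a <= b` elementwise.
#' @export
canonical_pair <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- b < a
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    dacs_abort("`%s` must be a single finite number", name)
}
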