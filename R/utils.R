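# Internal helpers: amino-acid alphabet, deterministic keyed seeding, and
# RNG-stream isolation used by the surrogate predictor and the simulator.

# The 20 proteinogenic residues; X is tolerated on input (unknown residue)
# but never emitted by the simulator.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @noRd
aaIndex <- function(chars) {
  idx <- match(chars, AA20)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    stop("illegal residue character(s): ", paste(bad, collapse = ", "))
  }
  idx
}

# 32-bit multiplicative string hash (double arithmetic stays exact below
# 2^53, so the modular reduction is safe). Used only to derive RNG seeds
# from string keys; the randomness quality comes from the seeded stream.
#' @noRd
strHash <- function(key) {
  bytes <- utf8ToInt(key)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 4294967296
  h
}

# Map a string key to a valid set.seed() integer, deterministically.
#' @noRd
keyedSeed <- function(...) {
  as.integer(strHash(paste(..., sep = "\r")) %% 2147483647)
}

# Evaluate expr under a private RNG stream, restoring the caller's stream
# afterwards (including the "no seed yet" state).
#' @noRd
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derived sub-stream seeds: one global seed, fixed offsets per stage, so
# adding a stage never perturbs the draws of earlier stages.
#' @noRd
subSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stopifnotScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(name, " must be a single number in [", lower, ", ", upper, "]")
  invisible(x)
}
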