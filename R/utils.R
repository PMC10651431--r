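#' The 20-letter amino-acid alphabet
#'
#' One-letter codes of the 20 standard amino acids, the only residue
#' symbols accepted in sequences and mutation codes.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

KCAL_PER_KJ <- 1 / 4.184

#' Convert free-energy values between kJ/mol and kcal/mol
#'
#' The package stores ddG in kcal/mol (the benchmark-literature
#' convention); source tables frequently report kJ/mol. The conversion is
#' linear and exactly invertible (1 kcal = 4.184 kJ).
#'
#' @param x Numeric vector of energies.
#' @return Numeric vector in the target unit.
#' @export
kj_to_kcal <- function(x) x * KCAL_PER_KJ

#' @rdname kj_to_kcal
#' @export
kcal_to_kj <- function(x) x * 4.184

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state, so
#' seeded components (mock embeddings, subsampling, fixture generation)
#' never perturb surrounding code and are bitwise reproducible.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Deterministic 31-bit string hash, used to derive per-row seeds for the
# mock backbone. Plain polynomial hash in double arithmetic (exact below
# 2^53), reduced mod a Mersenne prime so it is a valid set.seed() value.
hash31 <- function(...) {
  key <- paste(..., sep = "\r")
  codes <- utf8ToInt(key)
  h <- 2166136261 %% 2147483647
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# stopifnot with a formatted message
abort_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
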