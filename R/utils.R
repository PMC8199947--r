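# Shared helpers: controlled seeding, numeric utilities.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`, and
#' restores the previous state, so library internals never perturb user
#' randomness.
#'
#' @param seed integer seed (reduced modulo 2^31 - 1).
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(as.integer(abs(as.numeric(seed)) %% 2147483646))
  expr
}

#' Derive a stage seed from a root seed
#'
#' All pipeline randomness fans out from one root seed by fixed per-stage
#' offsets; derived seeds stay below 2^31.
#'
#' @param root integer root seed.
#' @param offset integer stage offset.
#' @return integer seed.
#' @export
deriveSeed <- function(root, offset) {
  as.integer(((abs(as.numeric(root)) %% 97651) * 20011 +
                abs(as.numeric(offset)) * 7919) %% 2147483629)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b binary matrices of equal dimension.
#' @return 2|A&B| / (|A| + |B|); defined as 1 when both masks are empty.
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- a != 0; b <- b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Row-wise softmax with max-shift stabilisation.
softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Soft-threshold operator used by the proximal L1 steps.
softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

# FNV-1a hash of a serialised R object; used for checkpoint provenance.
paramHash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

stopIfNot3Channel <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("expected an H x W x 3 array of red, green, blue channels")
}
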