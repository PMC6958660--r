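# Internal helpers shared across modules.

PCG_STATES <- c("S1", "systole", "S2", "diastole")
PCG_CLASSES <- c("normal", "HFpEF", "HFrEF")

#' Derive a reproducible child seed from a master seed and a label
#'
#' One master seed fans out to per-stage (or per-recording) streams so that
#' every stage of a run is independently reproducible. The derivation is a
#' small deterministic hash kept below 2^31 - 1.
#'
#' @param seed Integer master seed.
#' @param salt Character label (e.g. `"synth"`, `"cv"`) or an integer index.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, salt) {
  if (is.character(salt)) salt <- sum(utf8ToInt(salt) * seq_along(utf8ToInt(salt)))
  h <- (as.double(seed) * 48271 + as.double(salt) * 16807 + 12345) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under `set.seed(seed)`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Numerically stable sigmoid.
sigmoid <- function(x) 1 / (1 + exp(-x))

# min-max scale a vector to [0, 1]; (numerically) constant input maps to
# all zeros rather than amplifying rounding noise.
minmax01 <- function(x) {
  rng <- range(x)
  span <- rng[2] - rng[1]
  if (span <= max(1e-12, 1e-9 * abs(rng[2]))) return(rep(0, length(x)))
  (x - rng[1]) / span
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
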