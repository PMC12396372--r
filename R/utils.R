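## Internal helpers shared across modules: deterministic string hashing,
## scoped RNG, and small numeric utilities.

#' Deterministic 31-bit string hash
#'
#' Polynomial rolling hash over the raw bytes of `x`, reduced modulo
#' 2^31 - 1. Stable across R sessions and platforms (no dependence on R's
#' internal hashing), which makes it usable to derive RNG seeds from entity
#' identifiers.
#'
#' @param x character scalar.
#' @param seed integer offset mixed into the hash.
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
.stringHash <- function(x, seed = 0L) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- as.integer(charToRaw(x))
  mod <- 2147483647  # 2^31 - 1, prime
  h <- (as.numeric(seed) %% mod)
  for (b in bytes) {
    h <- (h * 131 + b + 1) %% mod
  }
  as.integer(h)
}

## Run `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is restored afterwards.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

## Numerically stable log(sigmoid(x)) and sigmoid(x).
.logSigmoid <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))

.sigmoid <- function(x) 1 / (1 + exp(-x))

## Row-wise softmax of a matrix, numerically stabilised.
.rowSoftmax <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - mx)
  e / rowSums(e)
}

.isWholeNumber <- function(x, tol = 1e-8) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && abs(x - round(x)) < tol
}

## Consistent condition helper: all user-facing errors carry a class so the
## command-line layer can distinguish user errors from internal ones.
.dtiStop <- function(msg, class = "graphDTI_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
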