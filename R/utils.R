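#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and a stage label.
# Keeps all stage seeds below 2^31 and decoupled, so toggling one stage does
# not shift the random stream of another.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587) + 1L
}

# Run an expression under a local RNG state so library code does not disturb
# the caller's random stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# z-score a numeric vector; constant input is an error unless allow_constant
zscore <- function(x, allow_constant = FALSE) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    if (allow_constant) return(rep(0, length(x)))
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
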