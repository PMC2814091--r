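# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip values into a closed interval
#'
#' @param x numeric vector or matrix.
#' @param lo,hi interval bounds.
#' @return `x` with values outside `[lo, hi]` replaced by the nearest bound.
#' @keywords internal
clip <- function(x, lo = 0, hi = 1) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

#' Derive a reproducible child seed from a master seed and a stream tag
#'
#' Sub-generators (annotation, methylation, expression, ...) draw from
#' independently seeded streams so that adding one stage never perturbs the
#' randomness of another. The derivation is a small deterministic integer
#' hash of the tag folded into the master seed, kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param tag character stream label.
#' @return an integer seed.
#' @keywords internal
child_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483563L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483563L + 1)
}

# run an expression with a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

is_fraction <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}
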