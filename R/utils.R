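# internal helpers shared across modules

# all RNG flows from explicit seeds; wrappers never touch the caller's
# global .Random.seed
.withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

# derive a stream seed from a master seed; kept below 2^31 - 1
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(k)) %% 2147483646L) + 1L
}

# deterministic small hash of a string, for per-animal seed derivation
.stringSeed <- function(s) {
  codes <- utf8ToInt(s)
  as.integer(sum(codes * seq_along(codes)) %% 100000L)
}

.assertFlag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be TRUE or FALSE", name), call. = FALSE)
  invisible(x)
}

.assertNumber <- function(x, name, lower = -Inf, upper = Inf,
                          strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x)
  if (ok) ok <- if (strict) x > lower && x < upper else
    x >= lower && x <= upper
  if (!ok)
    stop(sprintf("'%s' must be a single number in %s%g, %g%s", name,
                 if (strict) "(" else "[", lower, upper,
                 if (strict) ")" else "]"), call. = FALSE)
  invisible(x)
}

.logistic <- function(x, mid, scale) stats::plogis((x - mid) / scale)

# machine floor applied to powers and probabilities before any log
.EPS <- 1e-12
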