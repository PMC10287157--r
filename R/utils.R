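## Internal helpers shared across modules.

# Deterministic child seed from a master seed and a stream name.
# Kept below 2^31 so it is always a valid R integer.
.childSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483587) + 1L
}

# Evaluate expr with a temporary RNG state seeded from (seed, stream).
.withSeed <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(.childSeed(seed, stream))
  force(expr)
}

.softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

.rectify <- function(x) pmax(x, 0)

# Grouped row means: average rows of `m` in consecutive groups of size k,
# dropping a trailing partial group.
.binRows <- function(m, k, FUN = "mean") {
  n <- (nrow(m) %/% k) * k
  if (n == 0) return(matrix(numeric(0), 0, ncol(m)))
  g <- rep(seq_len(n %/% k), each = k)
  s <- rowsum(m[seq_len(n), , drop = FALSE], g, reorder = FALSE)
  dimnames(s) <- NULL
  if (FUN == "mean") s / k else s
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
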