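# Internal helpers shared across the package.

# Evaluate `expr` under a private RNG state seeded by `seed`; the caller's
# RNG state is untouched. A NULL seed uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Derive a child seed from a root seed and a stage counter, kept below 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) %% 1e6) * 2048 + 7919 * (k %% 1000) + k %/% 1000) %% 2147483647L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Cheap deterministic content hash (FNV-1a, 32-bit) for run-report headers.
fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(paste(s, collapse = "\n"))) {
    h <- bitwXor(as.integer(h %% 2147483648), as.integer(b))
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483648))
}

is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

stop_scalar_count <- function(x, name, positive = TRUE) {
  if (length(x) != 1 || !is.numeric(x) || !is_wholenumber(x) ||
      (positive && x <= 0)) {
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  }
  as.integer(round(x))
}
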