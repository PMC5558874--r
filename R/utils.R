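# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count mismatches between equal-length strings and one reference string
#'
#' Vectorised Hamming distance of each element of `x` to `ref`. All elements
#' of `x` must have exactly `nchar(ref)` characters.
#'
#' @param x character vector of candidate strings.
#' @param ref single reference string.
#' @return integer vector of mismatch counts, one per element of `x`.
#' @keywords internal
#' @noRd
mismatch_to_ref <- function(x, ref) {
  if (!length(x)) return(integer(0))
  w <- nchar(ref)
  if (any(nchar(x) != w)) stop("all candidates must have the reference length")
  m <- matrix(charToRaw(paste(x, collapse = "")), nrow = w)
  as.integer(colSums(m != charToRaw(ref)))
}

# Pairwise Hamming distance between two equal-length string vectors
# (elementwise). Used by tests' brute-force oracles too, so kept exact and dumb.
hamming_pairs <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  if (!length(a)) return(integer(0))
  w <- unique(c(nchar(a), nchar(b)))
  if (length(w) != 1L) stop("strings must share one length")
  ma <- matrix(charToRaw(paste(a, collapse = "")), nrow = w)
  mb <- matrix(charToRaw(paste(b, collapse = "")), nrow = w)
  as.integer(colSums(ma != mb))
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
# caller's state afterwards so simulation stages never perturb user RNG.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Derive a reproducible sub-stream seed from a root seed and a stream name,
# so library construction, founder sampling, growth and read simulation are
# independently reproducible. Plain 32-bit arithmetic hash; not cryptographic.
stream_seed <- function(seed, stream) {
  h <- 0
  for (k in utf8ToInt(as.character(stream))) h <- (h * 131 + k) %% 2147483629
  as.integer((as.numeric(seed) %% 2147483629 * 48271 + h) %% 2147483629)
}

# Byte-stable TSV writer: fixed column order, no quoting, no row names.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
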