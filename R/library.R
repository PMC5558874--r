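# Barcode library: the set of random tags carried by the lentiviral vector,
# each flanked by constant anchor sequences used for extraction.

DNA_BASES <- c("A", "C", "G", "T")

# Default amplicon layout: a fully random 30-nt tag between fixed 20-nt
# anchors. The real oligo design is not public; only anchor-delimited
# extraction is exercised downstream, so any non-self-similar anchors serve.
DEFAULT_ANCHOR5 <- "GATCCTCGAGGTCGACGGTA"
DEFAULT_ANCHOR3 <- "CCTAGGTTAACTGCAGTCGA"
DEFAULT_TAG_LENGTH <- 30L

#' Construct a barcode library object
#'
#' @param tags character vector of unique, equal-length A/C/G/T tag sequences.
#' @param anchor5,anchor3 constant sequences flanking the tag in the amplicon.
#' @return object of class `barcode_library` with fields `tags`, `anchor5`,
#'   `anchor3` and `length` (tag length in nt).
#' @export
barcode_library <- function(tags, anchor5 = DEFAULT_ANCHOR5,
                            anchor3 = DEFAULT_ANCHOR3) {
  tags <- as.character(tags)
  if (!length(tags)) stop("library must contain at least one tag")
  L <- nchar(tags[1])
  if (any(nchar(tags) != L)) stop("all tags must have the same length")
  if (any(grepl("[^ACGT]", tags))) stop("tags must use only A/C/G/T")
  if (anyDuplicated(tags)) stop("tags must be unique within the library")
  for (a in c(anchor5, anchor3)) {
    if (!nzchar(a) || grepl("[^ACGT]", a)) stop("anchors must be non-empty A/C/G/T strings")
  }
  if (grepl(anchor5, anchor3, fixed = TRUE) || grepl(anchor3, anchor5, fixed = TRUE))
    stop("neither anchor may contain the other as a substring")
  structure(list(tags = tags, anchor5 = anchor5, anchor3 = anchor3,
                 length = as.integer(L)),
            class = "barcode_library")
}

#' Generate a random barcode library
#'
#' Draws `n` distinct tags uniformly from the `4^length` possible sequences,
#' emulating a random-oligo lentiviral barcode library (real libraries reach
#' complexities above 100,000 unique tags).
#'
#' @param n number of unique tags; must not exceed `4^length`.
#' @param length tag length in nucleotides.
#' @param anchors length-2 character vector `c(anchor5, anchor3)`.
#' @param seed integer seed; the same seed reproduces the same library.
#' @return a [barcode_library()] object with exactly `n` tags.
#' @examples
#' lib <- generate_library(5, 8, seed = 1)
#' lib$tags
#' @export
generate_library <- function(n, length,
                             anchors = c(DEFAULT_ANCHOR5, DEFAULT_ANCHOR3),
                             seed = 1L) {
  n <- as.integer(n)
  length <- as.integer(length)
  if (n < 1L) stop("n must be positive")
  if (length < 1L) stop("tag length must be positive")
  if (n > 4^length)
    stop("impossible library: ", n, " unique tags exceed 4^", length,
         " possible sequences")
  tags <- with_seed(seed, {
    out <- character(0)
    while (length(out) < n) {
      need <- n - length(out)
      m <- matrix(sample(DNA_BASES, (need + 8L) * length, replace = TRUE),
                  ncol = length)
      draw <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
      out <- unique(c(out, draw))
    }
    out[seq_len(n)]
  })
  barcode_library(tags, anchors[[1]], anchors[[2]])
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("barcode_library: %d tags of %d nt (anchors %d/%d nt)\n",
              length(x$tags), x$length, nchar(x$anchor5), nchar(x$anchor3)))
  invisible(x)
}
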