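# Minimal single-end FASTQ I/O. The reader validates the 4-line record
# structure and reports the index of the first malformed record, which is the
# error contract the pipeline relies on; qualities are carried as-is and a
# fixed dummy quality string is written (the pipeline is quality-agnostic).

fastq_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Write reads to a FASTQ file
#'
#' @param seqs character vector of read sequences.
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @param ids read identifiers (without the leading `@`).
#' @param quality_char single character used to fill the quality line
#'   (Phred+33).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path,
                        ids = sprintf("read%07d", seq_along(seqs)),
                        quality_char = "I") {
  if (length(ids) != length(seqs)) stop("ids and seqs must have equal length")
  con <- fastq_connection(path, "wb")
  on.exit(close(con))
  if (length(seqs)) {
    qual <- strrep(quality_char, nchar(seqs))
    rec <- rbind(paste0("@", ids), seqs, "+", qual)
    writeLines(as.vector(rec), con)
  }
  invisible(path)
}

#' Read a single-end FASTQ file
#'
#' @param path FASTQ path (optionally gzipped).
#' @return data.frame with columns `id` and `seq`, one row per read; empty
#'   files give zero rows.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- fastq_connection(path, "rb")
  on.exit(close(con))
  lines <- readLines(con)
  n <- length(lines)
  if (n == 0L) return(data.frame(id = character(0), seq = character(0),
                                 stringsAsFactors = FALSE))
  if (n %% 4L != 0L)
    stop("malformed FASTQ record ", n %/% 4L + 1L, " in ", path,
         ": truncated record (", n %% 4L, " of 4 lines)")
  hdr <- lines[seq(1L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1L], " in ", path,
         ": expected '@' header and '+' separator")
  data.frame(id = sub("^@", "", hdr), seq = lines[seq(2L, n, by = 4L)],
             stringsAsFactors = FALSE)
}
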