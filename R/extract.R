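# Anchor-delimited tag extraction: FASTQ reads -> raw per-sample barcode
# count tables.

#' Extract barcode tags from reads by anchor matching
#'
#' Locates `anchor5` in each read allowing substitutions (best-scoring, then
#' leftmost, candidate position), takes the following `tag_length` bases as
#' the tag, and requires `anchor3` immediately after. The mismatch budget
#' `max_anchor_mismatch` is shared across both anchors; a read is a no-call
#' (`NA`) if either anchor fails, the read is too short, or the tag contains
#' non-ACGT characters. Candidate anchor positions are found with
#' [Biostrings::vmatchPattern()]; no indel alignment is attempted
#' (substitution-dominated MiSeq errors).
#'
#' @param reads character vector of read sequences.
#' @param anchor5,anchor3 constant flanking sequences.
#' @param tag_length expected tag length (nt).
#' @param max_anchor_mismatch total substitutions tolerated across both
#'   anchors (default 2).
#' @return character vector of tags, `NA` for no-calls, same length as
#'   `reads`.
#' @export
extract_tags <- function(reads, anchor5, anchor3, tag_length,
                         max_anchor_mismatch = 2L) {
  if (!nzchar(anchor5) || !nzchar(anchor3)) stop("anchors must be non-empty")
  tag_length <- as.integer(tag_length)
  if (tag_length < 1L) stop("tag_length must be positive")
  mm <- as.integer(max_anchor_mismatch)
  out <- rep(NA_character_, length(reads))
  if (!length(reads)) return(out)
  len5 <- nchar(anchor5); len3 <- nchar(anchor3)
  min_len <- len5 + tag_length + len3
  ok <- !is.na(reads) & nchar(reads) >= min_len & !grepl("[^ACGTN]", reads)
  if (!any(ok)) return(out)
  idx <- which(ok)
  # fast path: a leftmost exact anchor5 occurrence is always the
  # best-scoring leftmost candidate, so the mismatch-tolerant scan is only
  # needed for reads without an exact match
  exact <- regexpr(anchor5, reads[idx], fixed = TRUE)
  grp <- idx[exact > 0L]
  starts <- as.integer(exact[exact > 0L])
  rest <- idx[exact < 0L]
  if (mm > 0L && length(rest)) {
    subj <- Biostrings::DNAStringSet(reads[rest])
    hits <- Biostrings::vmatchPattern(anchor5, subj, max.mismatch = mm,
                                      fixed = TRUE)
    nh <- S4Vectors::elementNROWS(hits)
    if (sum(nh)) {
      ir <- unlist(hits, use.names = FALSE)
      grp <- c(grp, rep(rest, nh))          # original read index per candidate
      starts <- c(starts, BiocGenerics::start(ir))
    }
  }
  if (!length(grp)) return(out)
  widths <- nchar(reads)[grp]
  keep <- starts >= 1L & starts + len5 - 1L <= widths
  grp <- grp[keep]; starts <- starts[keep]
  if (!length(grp)) return(out)
  mm5 <- mismatch_to_ref(substr(reads[grp], starts, starts + len5 - 1L), anchor5)
  keep <- mm5 <= mm
  grp <- grp[keep]; starts <- starts[keep]; mm5 <- mm5[keep]
  if (!length(grp)) return(out)
  # best-scoring candidate per read, leftmost on ties
  o <- order(grp, mm5, starts)
  first <- !duplicated(grp[o])
  grp <- grp[o][first]; starts <- starts[o][first]; mm5 <- mm5[o][first]
  tag_start <- starts + len5
  a3_start <- tag_start + tag_length
  fits <- a3_start + len3 - 1L <= nchar(reads)[grp]
  grp <- grp[fits]; tag_start <- tag_start[fits]; a3_start <- a3_start[fits]
  mm5 <- mm5[fits]
  if (!length(grp)) return(out)
  tag <- substr(reads[grp], tag_start, tag_start + tag_length - 1L)
  mm3 <- mismatch_to_ref(substr(reads[grp], a3_start, a3_start + len3 - 1L),
                         anchor3)
  good <- (mm5 + mm3 <= mm) & !grepl("[^ACGT]", tag)
  out[grp[good]] <- tag[good]
  out
}

#' Count extracted tags in one sample
#'
#' @param reads character vector of read sequences from a single sample.
#' @param anchor5,anchor3,tag_length,max_anchor_mismatch extraction
#'   parameters, see [extract_tags()].
#' @param sample_id sample identifier carried into the table.
#' @return object of class `count_table`: list with `sample_id`, `counts`
#'   (named integer vector, tag -> reads, sorted by tag),
#'   `total_reads_input` and `total_reads_assigned`.
#' @export
count_sample <- function(reads, anchor5, anchor3, tag_length,
                         max_anchor_mismatch = 2L, sample_id = "sample") {
  tags <- extract_tags(reads, anchor5, anchor3, tag_length,
                       max_anchor_mismatch)
  tags <- tags[!is.na(tags)]
  counts <- if (length(tags)) {
    tb <- table(tags)
    stats::setNames(as.integer(tb), names(tb))
  } else {
    warning("sample '", sample_id, "': no reads yielded a tag")
    stats::setNames(integer(0), character(0))
  }
  counts <- counts[sort(names(counts))]
  new_count_table(sample_id, counts, total_reads_input = length(reads))
}

new_count_table <- function(sample_id, counts, total_reads_input,
                            reference_total = NULL) {
  structure(list(sample_id = sample_id, counts = counts,
                 total_reads_input = as.integer(total_reads_input),
                 total_reads_assigned = as.integer(sum(counts)),
                 reference_total = reference_total),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table '%s': %d tags, %d/%d reads assigned\n",
              x$sample_id, length(x$counts), x$total_reads_assigned,
              x$total_reads_input))
  invisible(x)
}

SHEET_COLUMNS <- c("sample_id", "run_id", "mouse_id", "lineage_id", "organ",
                   "generation", "barcoded_cells", "total_cells",
                   "transduction_fraction", "fastq_path")

#' Read and validate a sample sheet
#'
#' @param path TSV with columns sample_id, run_id, mouse_id, lineage_id,
#'   organ, generation, barcoded_cells, total_cells, transduction_fraction,
#'   fastq_path.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- read_tsv(path)
  missing <- setdiff(SHEET_COLUMNS, names(sheet))
  if (length(missing))
    stop("sample sheet is missing required columns: ",
         paste(missing, collapse = ", "))
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in sample sheet: ", paste(unique(dup), collapse = ", "))
  sheet
}

#' Load a sequencing run into count tables
#'
#' Reads each sample's FASTQ and extracts tag counts, preserving the run
#' grouping needed for cross-sample contamination filtering.
#'
#' @param sheet sample-sheet data.frame (or TSV path) with one row per
#'   sample; `fastq_path` entries are resolved relative to `fastq_dir` when
#'   not absolute.
#' @param fastq_dir directory prefix for relative FASTQ paths.
#' @param anchor5,anchor3,tag_length,max_anchor_mismatch extraction
#'   parameters.
#' @return object of class `count_run`: list with `tables` (sample_id ->
#'   `count_table`) and `meta` (the sheet).
#' @export
load_run <- function(sheet, fastq_dir = ".",
                     anchor5 = DEFAULT_ANCHOR5, anchor3 = DEFAULT_ANCHOR3,
                     tag_length = DEFAULT_TAG_LENGTH,
                     max_anchor_mismatch = 2L) {
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup))
    stop("duplicate sample_id in sample sheet: ", paste(unique(dup), collapse = ", "))
  tables <- list()
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    fp <- sheet$fastq_path[i]
    if (!file.exists(fp)) fp <- file.path(fastq_dir, sheet$fastq_path[i])
    if (!file.exists(fp))
      stop("FASTQ file for sample '", sid, "' not found: ", sheet$fastq_path[i])
    reads <- read_fastq(fp)$seq
    tables[[sid]] <- count_sample(reads, anchor5, anchor3, tag_length,
                                  max_anchor_mismatch, sample_id = sid)
  }
  structure(list(tables = tables, meta = sheet), class = "count_run")
}

# Build a count_run directly from in-memory simulated reads, bypassing disk.
count_run_from_experiment <- function(experiment, max_anchor_mismatch = 2L) {
  cfg <- experiment$config
  if (is.null(experiment$reads))
    stop("experiment has no reads; call simulate_reads() first")
  tables <- list()
  for (sid in names(experiment$reads)) {
    tables[[sid]] <- count_sample(experiment$reads[[sid]], cfg$anchor5,
                                  cfg$anchor3, cfg$tag_length,
                                  max_anchor_mismatch, sample_id = sid)
  }
  structure(list(tables = tables, meta = experiment$sheet),
            class = "count_run")
}
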