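# Clone calling: the three filters applied to raw barcode counts before any
# statistic is computed -- a read-fraction detection threshold, removal of
# single-base sequencing-error barcodes, and removal of within-run
# cross-sample (index-hopping) contamination.

filter_log_row <- function(stage, sample_id, tag, reason, reference_value) {
  data.frame(stage = stage, sample_id = sample_id, tag = tag, reason = reason,
             reference_value = reference_value, stringsAsFactors = FALSE)
}

empty_filter_log <- function() {
  filter_log_row(character(0), character(0), character(0), character(0),
                 numeric(0))
}

reference_total <- function(ct) ct$reference_total %||% ct$total_reads_assigned

#' Remove barcodes below the detection threshold
#'
#' Removes every tag whose read count is at most `min_frac` of the sample's
#' assigned-read total, so that all survivors comprise strictly more than
#' `min_frac` (default 0.01%) of the total. By default the total is fixed at
#' the pre-filter assigned total, making the lowest-count-first removal
#' equivalent to a single cutoff; `recompute_total = TRUE` re-normalises the
#' total after each removal instead (the iterative variant).
#'
#' @param ct a `count_table`.
#' @param min_frac detection threshold as a fraction of total reads, in
#'   `[0, 1)`.
#' @param recompute_total recompute the total during iterative removal.
#' @return filtered `count_table` with a `filter_log` attribute.
#' @export
threshold_filter <- function(ct, min_frac = 1e-4, recompute_total = FALSE) {
  if (!is.numeric(min_frac) || min_frac < 0 || min_frac >= 1)
    stop("min_frac must be in [0, 1)")
  cnt <- ct$counts
  total <- reference_total(ct)
  if (recompute_total) {
    o <- order(cnt, names(cnt))      # lowest first, lexicographic tie-break
    sorted <- cnt[o]
    tot <- sum(sorted)
    drop <- logical(length(sorted))
    for (i in seq_along(sorted)) {
      if (sorted[i] <= min_frac * tot) {
        drop[i] <- TRUE
        tot <- tot - sorted[i]
      } else break  # cutoff only shrinks, so all larger counts survive
    }
    removed <- sorted[drop]
  } else {
    removed <- cnt[cnt <= min_frac * total]
  }
  keep <- cnt[!names(cnt) %in% names(removed)]
  log <- if (length(removed)) {
    filter_log_row("threshold", ct$sample_id, names(removed),
                   "count at or below detection threshold",
                   as.numeric(removed))
  } else empty_filter_log()
  out <- new_count_table(ct$sample_id, keep, ct$total_reads_input,
                         reference_total = total)
  attr(out, "filter_log") <- log
  out
}

#' Remove single-base-error barcodes
#'
#' A tag `c` is removed when some tag `p` in the same sample lies at Hamming
#' distance 1 and `count(p) >= parent_ratio * count(c)` -- the directional-
#' adjacency convention operationalising "single base changes from
#' high-frequency barcodes". Decisions are made against the original input
#' counts in a single pass (no chaining), and removed reads are discarded,
#' not merged into the parent.
#'
#' @param ct a `count_table` whose tags all share one length.
#' @param parent_ratio minimum parent:child count ratio for removal.
#' @return filtered `count_table` with a `filter_log` attribute.
#' @export
hamming_collapse <- function(ct, parent_ratio = 10) {
  cnt <- ct$counts
  tags <- names(cnt)
  if (length(tags) > 1L) {
    L <- unique(nchar(tags))
    if (length(L) != 1L) stop("mixed tag lengths in sample '", ct$sample_id, "'")
    # hash every distance-1 neighbour instead of all-pairs comparison
    max_parent <- numeric(length(tags))
    self <- seq_along(tags)
    for (pos in seq_len(L)) {
      for (b in DNA_BASES) {
        v <- tags
        substr(v, pos, pos) <- b
        hit <- match(v, tags)
        sel <- !is.na(hit) & hit != self
        if (any(sel))
          max_parent[sel] <- pmax(max_parent[sel], cnt[hit[sel]])
      }
    }
    drop <- max_parent >= parent_ratio * cnt
  } else {
    drop <- logical(length(tags))
    max_parent <- numeric(length(tags))
  }
  log <- if (any(drop)) {
    filter_log_row("hamming", ct$sample_id, tags[drop],
                   "single base change from high-frequency barcode",
                   max_parent[drop])
  } else empty_filter_log()
  out <- new_count_table(ct$sample_id, cnt[!drop], ct$total_reads_input,
                         reference_total = reference_total(ct))
  attr(out, "filter_log") <- log
  out
}

#' Remove cross-sample contamination within a sequencing run
#'
#' A tag is removed from sample `s` when some sample of the same run with a
#' *different* lineage contains the identical tag at strictly higher
#' frequency (count / assigned-read total per sample). Samples sharing a
#' `lineage_id` -- a mouse and its serial-transplant descendants -- never
#' trigger removal against each other, since they legitimately share
#' barcodes; frequency ties keep the tag in both samples.
#'
#' @param tables named list of `count_table`s from one run.
#' @param meta data.frame with columns `sample_id`, `run_id`, `lineage_id`.
#' @return list of filtered `count_table`s with `filter_log` attributes.
#' @export
cross_sample_clean <- function(tables, meta) {
  runs <- unique(meta$run_id[meta$sample_id %in% names(tables)])
  if (length(runs) > 1L)
    stop("cross_sample_clean expects samples from a single run, got: ",
         paste(runs, collapse = ", "))
  lineage <- stats::setNames(meta$lineage_id, meta$sample_id)
  long <- do.call(rbind, lapply(tables, function(ct) {
    if (!length(ct$counts)) return(NULL)
    data.frame(sample_id = ct$sample_id, tag = names(ct$counts),
               count = as.numeric(ct$counts),
               freq = as.numeric(ct$counts) / reference_total(ct),
               stringsAsFactors = FALSE)
  }))
  out <- tables
  if (is.null(long) || !nrow(long)) {
    for (s in names(out)) attr(out[[s]], "filter_log") <- empty_filter_log()
    return(out)
  }
  long$lineage <- lineage[long$sample_id]
  # per (tag, lineage) maximum frequency, then per tag the best and the best
  # from any other lineage; a sample's competitor is whichever applies
  key <- paste(long$tag, long$lineage, sep = "\r")
  agg_f <- tapply(long$freq, key, max)
  parts <- strsplit(names(agg_f), "\r", fixed = TRUE)
  agg <- data.frame(tag = vapply(parts, `[`, "", 1L),
                    lineage = vapply(parts, `[`, "", 2L),
                    freq = as.numeric(agg_f), stringsAsFactors = FALSE)
  o <- order(agg$tag, -agg$freq)
  agg <- agg[o, ]
  first <- !duplicated(agg$tag)
  top <- agg[first, ]
  best1 <- stats::setNames(top$freq, top$tag)
  best1_lin <- stats::setNames(top$lineage, top$tag)
  rest <- agg[!first, ]
  rest <- rest[rest$lineage != best1_lin[rest$tag], , drop = FALSE]
  first2 <- !duplicated(rest$tag)
  best2 <- stats::setNames(rest$freq[first2], rest$tag[first2])
  comp <- ifelse(long$lineage == best1_lin[long$tag],
                 unname(best2[long$tag]), unname(best1[long$tag]))
  comp[is.na(comp)] <- -Inf
  long$removed <- comp > long$freq
  long$competitor <- comp
  for (s in names(out)) {
    sel <- long$sample_id == s & long$removed
    drop_tags <- long$tag[sel]
    ct <- out[[s]]
    keep <- ct$counts[!names(ct$counts) %in% drop_tags]
    log <- if (length(drop_tags)) {
      filter_log_row("cross_sample", s, drop_tags,
                     "identical barcode at higher frequency in another lineage",
                     long$competitor[sel])
    } else empty_filter_log()
    out[[s]] <- new_count_table(s, keep, ct$total_reads_input,
                                reference_total = reference_total(ct))
    attr(out[[s]], "filter_log") <- log
  }
  out
}

#' Call clones for every sample of a run
#'
#' Applies [threshold_filter()], then [hamming_collapse()], then
#' [cross_sample_clean()], with all thresholds referenced to each sample's
#' pre-filter assigned-read total, and renormalises frequencies over the
#' retained reads.
#'
#' @param run a `count_run` from [load_run()], or a named list of
#'   `count_table`s (then `meta` is required).
#' @param meta sample metadata (sample_id, run_id, lineage_id).
#' @param min_frac detection threshold (fraction of assigned reads).
#' @param parent_ratio single-base-error collapse ratio.
#' @param recompute_total iterative-total variant of the threshold filter.
#' @return named list of `clone_table`s: each a list with `sample_id`,
#'   `clones` (tag -> frequency of retained reads), `counts` (retained read
#'   counts), `retained_reads` and `filter_log`.
#' @export
call_clones <- function(run, meta = NULL, min_frac = 1e-4, parent_ratio = 10,
                        recompute_total = FALSE) {
  if (inherits(run, "count_run")) {
    tables <- run$tables
    if (is.null(meta)) meta <- run$meta
  } else tables <- run
  if (is.null(meta)) stop("sample metadata is required")
  tables <- lapply(tables, function(ct) {
    ct$reference_total <- ct$total_reads_assigned
    ct
  })
  logs <- lapply(tables, function(ct) empty_filter_log())
  step <- function(tabs, f) {
    out <- lapply(tabs, f)
    for (s in names(out))
      logs[[s]] <<- rbind(logs[[s]], attr(out[[s]], "filter_log"))
    out
  }
  tables <- step(tables, function(ct)
    threshold_filter(ct, min_frac, recompute_total))
  tables <- step(tables, function(ct) hamming_collapse(ct, parent_ratio))
  cleaned <- cross_sample_clean(tables, meta)
  for (s in names(cleaned))
    logs[[s]] <- rbind(logs[[s]], attr(cleaned[[s]], "filter_log"))
  lapply(stats::setNames(names(cleaned), names(cleaned)), function(s) {
    ct <- cleaned[[s]]
    tot <- sum(ct$counts)
    clone_table(s, counts = ct$counts,
                clones = if (tot > 0) ct$counts / tot else
                  stats::setNames(numeric(0), character(0)),
                retained_reads = tot, filter_log = logs[[s]])
  })
}

clone_table <- function(sample_id, counts, clones, retained_reads,
                        filter_log = empty_filter_log()) {
  structure(list(sample_id = sample_id,
                 clones = stats::setNames(as.numeric(clones), names(clones)),
                 counts = counts, retained_reads = as.integer(retained_reads),
                 filter_log = filter_log),
            class = "clone_table")
}

#' @export
print.clone_table <- function(x, ...) {
  cat(sprintf("clone_table '%s': %d clones over %d retained reads (%d tags filtered)\n",
              x$sample_id, length(x$clones), x$retained_reads,
              nrow(x$filter_log)))
  invisible(x)
}
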