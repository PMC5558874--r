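# Pipeline orchestration: write a complete synthetic run to disk, run
# extraction -> clone calling -> statistics over a run directory, and build
# engrafting-frequency tables. The analysis/ scripts are thin drivers over
# these functions.

#' Write a synthetic sequencing run to a directory
#'
#' Simulates a full experiment and writes per-sample FASTQ files, the sample
#' sheet, ground-truth and read-provenance TSVs, and a manifest recording the
#' seed and parameters -- everything needed to run the analysis pipeline
#' against known truth.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param gzip write gzipped FASTQ.
#' @return the simulated experiment (invisibly), with `sheet$fastq_path`
#'   filled in.
#' @export
simulate_run_dir <- function(config, out_dir, gzip = FALSE) {
  config <- validate_sim_config(config)
  expt <- simulate_reads(simulate_experiment(config))
  run_dir <- file.path(out_dir, "run1")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (gzip) ".fastq.gz" else ".fastq"
  for (sid in names(expt$reads)) {
    fp <- file.path(run_dir, paste0(sid, ext))
    write_fastq(expt$reads[[sid]], fp, ids = expt$read_ids[[sid]])
    expt$sheet$fastq_path[expt$sheet$sample_id == sid] <- fp
  }
  write_tsv(expt$sheet, file.path(out_dir, "sample_sheet.tsv"))
  write_tsv(truth_table(expt), file.path(out_dir, "truth.tsv"))
  prov <- expt$provenance[order(expt$provenance$read_id), , drop = FALSE]
  write_tsv(prov, file.path(out_dir, "provenance.tsv"))
  manifest <- list(seed = config$seed,
                   parameters = config[setdiff(names(config), "organs")],
                   organs = lapply(config$organs, unclass))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(expt)
}

clone_table_df <- function(tab) {
  if (!length(tab$clones))
    return(data.frame(tag = character(0), count = integer(0),
                      frequency = numeric(0)))
  o <- order(names(tab$clones))
  data.frame(tag = names(tab$clones)[o],
             count = as.integer(tab$counts[o]),
             frequency = as.numeric(tab$clones[o]),
             stringsAsFactors = FALSE)
}

#' Run the analysis pipeline over a sequencing run
#'
#' Extraction, clone calling and per-sample statistics over a run directory
#' produced by [simulate_run_dir()] (or real data laid out the same way).
#' Writes, under `out_dir`: one clone-table TSV per sample
#' (`clones_<sample>.tsv`: tag, count, frequency), `filter_log.tsv` (every
#' filter decision), `extraction_summary.tsv`, `sample_metrics.tsv`
#' (richness, Shannon, max clone frequency) and `run_summary.json` with all
#' thresholds, so every report is self-describing.
#'
#' @param sheet sample sheet (data.frame or TSV path).
#' @param out_dir report directory (created if needed).
#' @param fastq_dir prefix for relative FASTQ paths.
#' @param anchor5,anchor3,tag_length,max_anchor_mismatch extraction
#'   parameters.
#' @param min_frac,parent_ratio,recompute_total clone-calling parameters.
#' @return named list of `clone_table`s, invisibly.
#' @export
run_pipeline <- function(sheet, out_dir, fastq_dir = ".",
                         anchor5 = DEFAULT_ANCHOR5,
                         anchor3 = DEFAULT_ANCHOR3,
                         tag_length = DEFAULT_TAG_LENGTH,
                         max_anchor_mismatch = 2L,
                         min_frac = 1e-4, parent_ratio = 10,
                         recompute_total = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  run <- load_run(sheet, fastq_dir, anchor5, anchor3, tag_length,
                  max_anchor_mismatch)
  clones <- call_clones(run, min_frac = min_frac, parent_ratio = parent_ratio,
                        recompute_total = recompute_total)
  for (sid in names(clones))
    write_tsv(clone_table_df(clones[[sid]]),
              file.path(out_dir, paste0("clones_", sid, ".tsv")))
  log <- do.call(rbind, lapply(clones, `[[`, "filter_log"))
  rownames(log) <- NULL
  write_tsv(log[order(log$stage, log$sample_id, log$tag), , drop = FALSE],
            file.path(out_dir, "filter_log.tsv"))
  extraction <- do.call(rbind, lapply(run$tables, function(ct)
    data.frame(sample_id = ct$sample_id,
               total_reads_input = ct$total_reads_input,
               total_reads_assigned = ct$total_reads_assigned)))
  write_tsv(extraction, file.path(out_dir, "extraction_summary.tsv"))
  metrics <- do.call(rbind, lapply(clones, function(tab) {
    m <- suppressWarnings(richness_metrics(tab))
    data.frame(sample_id = tab$sample_id, richness = m$richness,
               shannon = m$shannon, max_freq = m$max_freq,
               retained_reads = tab$retained_reads)
  }))
  write_tsv(metrics, file.path(out_dir, "sample_metrics.tsv"))
  summary <- list(
    n_samples = length(clones),
    parameters = list(anchor5 = anchor5, anchor3 = anchor3,
                      tag_length = tag_length,
                      max_anchor_mismatch = max_anchor_mismatch,
                      min_frac = min_frac, parent_ratio = parent_ratio,
                      recompute_total = recompute_total),
    total_clones = sum(metrics$richness),
    tags_filtered = nrow(log))
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(clones)
}

#' Engrafting-cell frequency table for dose groups
#'
#' Applies [lic_frequency()] row-wise to a table of dose groups, producing
#' the standard limiting-dilution summary (one engrafting cell per N
#' transplanted barcoded cells).
#'
#' @param df data.frame with columns `total_cells`,
#'   `transduction_fraction`, `barcodes_recovered` and optionally `label`.
#' @return `df` with `barcoded_cells` and `lic_denominator` columns added;
#'   the frequency for each row is `1:lic_denominator`.
#' @export
engraftment_frequency_table <- function(df) {
  need <- c("total_cells", "transduction_fraction", "barcodes_recovered")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("missing required columns: ", paste(missing, collapse = ", "))
  if (any(!is.finite(df$barcodes_recovered) | df$barcodes_recovered <= 0))
    stop("barcodes_recovered must be positive in every row (rows: ",
         paste(which(!is.finite(df$barcodes_recovered) |
                       df$barcodes_recovered <= 0), collapse = ", "), ")")
  est <- lapply(seq_len(nrow(df)), function(i)
    lic_frequency(df$total_cells[i], df$transduction_fraction[i],
                  df$barcodes_recovered[i]))
  df$barcoded_cells <- vapply(est, `[[`, numeric(1), "barcoded_cells")
  df$lic_denominator <- vapply(est, function(e) as.numeric(e$denominator_N),
                               numeric(1))
  df
}

#' Published engrafting-frequency inputs
#'
#' The dose-group inputs of the four barcoded primograft ALL samples
#' (transplanted cell numbers, transduction fractions and mean spleen
#' barcode recovery across replicate mice) used to estimate engrafting-cell
#' frequencies.
#'
#' @return data.frame with columns `label`, `total_cells`,
#'   `transduction_fraction`, `barcodes_recovered`, `n_mice`.
#' @export
engraftment_inputs <- function() {
  read_tsv(system.file("extdata", "engraftment_inputs.tsv",
                       package = "clonetrack", mustWork = TRUE))
}
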