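# Clonal statistics: Nei gene diversity H and differentiation G, richness
# and dominance metrics, serial-transplant persistence, multi-organ sharing,
# and the limiting-dilution engrafting-cell frequency.

clone_freqs <- function(x) {
  if (inherits(x, "clone_table")) x$clones
  else if (is.numeric(x)) x
  else stop("expected a clone_table or a numeric frequency vector")
}

#' Nei gene diversity of one sample
#'
#' `H = 1 - sum(p^2)`: the probability that two reads drawn at random carry
#' different barcodes.
#'
#' @param p frequency vector (sums to 1 within `tol`) or a `clone_table`.
#' @param tol tolerance on the frequency sum.
#' @return H in `[0, 1)`.
#' @examples
#' gene_diversity(c(0.5, 0.5))  # 0.5
#' @export
gene_diversity <- function(p, tol = 1e-6) {
  p <- clone_freqs(p)
  if (any(p < 0)) stop("frequencies must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("frequencies must sum to 1 (got ", format(sum(p)), ")")
  1 - sum(p^2)
}

# Align frequency vectors onto the union tag universe, zero-filling.
align_freqs <- function(samples) {
  samples <- lapply(samples, clone_freqs)
  tags <- sort(unique(unlist(lapply(samples, names))))
  if (is.null(tags) || !length(tags))
    stop("samples share no named tag universe")
  mat <- vapply(samples, function(p) {
    v <- stats::setNames(numeric(length(tags)), tags)
    v[names(p)] <- p
    v
  }, numeric(length(tags)))
  matrix(mat, nrow = length(tags),
         dimnames = list(tags, NULL))   # stays a matrix for 1-tag universes
}

#' Nei differentiation index G between samples
#'
#' Decomposes diversity over two or more samples on their union tag universe:
#' `H_S` is the mean within-sample diversity, `H_T` the diversity of the
#' equal-weight mean frequency vector, and `G = (H_T - H_S) / H_T` (0 when
#' `H_T = 0`). G is 0 for identical compositions and 1 for completely
#' differentiated ones. The plain 1973 definition is the default;
#' `correction = "unbiased"` applies the small-sample factor `n/(n-1)` to
#' each within-sample diversity using per-sample read counts `n`.
#'
#' @param samples list (length >= 2) of named frequency vectors or
#'   `clone_table`s.
#' @param correction `"none"` (default) or `"unbiased"`.
#' @param sample_sizes read counts per sample, required for the unbiased
#'   correction; taken from `retained_reads` when `samples` are
#'   `clone_table`s.
#' @return object of class `diversity_result`: list with `H_per_sample`,
#'   `H_S`, `H_T` and `G`.
#' @examples
#' nei_G(list(a = c(A = 1), b = c(B = 1)))$G  # 1: complete differentiation
#' @export
nei_G <- function(samples, correction = c("none", "unbiased"),
                  sample_sizes = NULL) {
  correction <- match.arg(correction)
  if (length(samples) < 2L) stop("at least two samples are required")
  if (is.null(sample_sizes) && correction == "unbiased")
    sample_sizes <- vapply(samples, function(x)
      if (inherits(x, "clone_table")) x$retained_reads
      else stop("sample_sizes required for the unbiased correction"), 0)
  mat <- align_freqs(samples)
  H <- apply(mat, 2, function(p) 1 - sum(p^2))
  if (correction == "unbiased") {
    if (any(sample_sizes < 2)) stop("sample sizes must be >= 2 for correction")
    H <- H * sample_sizes / (sample_sizes - 1)
  }
  H_S <- mean(H)
  H_T <- 1 - sum(rowMeans(mat)^2)
  G <- if (H_T > 0) (H_T - H_S) / H_T else 0
  nm <- names(samples) %||% paste0("sample", seq_along(samples))
  structure(list(H_per_sample = stats::setNames(H, nm), H_S = H_S,
                 H_T = H_T, G = G),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("diversity_result: H_S = %.4f, H_T = %.4f, G = %.4f (%d samples)\n",
              x$H_S, x$H_T, x$G, length(x$H_per_sample)))
  invisible(x)
}

#' Engrafting-cell frequency from a limiting-dilution transplant
#'
#' The estimate used for barcoded transplants:
#' `N = (total cells transplanted) x (transduction fraction) / (barcodes
#' recovered from spleen)`, reported as one engrafting cell per `N`
#' transplanted barcoded cells. `N` is rounded half-up to the nearest
#' integer and floored at 1.
#'
#' @param total_cells cells transplanted (the transduced pool; co-injected
#'   unlabelled carrier cells are excluded).
#' @param transduction_fraction fraction of those cells carrying a barcode.
#' @param barcodes_recovered barcodes recovered from the spleen (mean across
#'   replicate mice for a dose group); must be positive.
#' @param label optional sample/dose-group label.
#' @return object of class `frequency_estimate`: list with `label`,
#'   `barcoded_cells`, `barcodes_recovered` and `denominator_N`.
#' @examples
#' lic_frequency(100000, 0.10, 662)$denominator_N  # 15, i.e. 1:15
#' @export
lic_frequency <- function(total_cells, transduction_fraction,
                          barcodes_recovered, label = NA_character_) {
  if (!is.numeric(barcodes_recovered) || barcodes_recovered <= 0)
    stop("barcodes_recovered must be positive")
  barcoded <- total_cells * transduction_fraction
  N <- max(1L, as.integer(floor(barcoded / barcodes_recovered + 0.5)))
  structure(list(label = label, barcoded_cells = barcoded,
                 barcodes_recovered = barcodes_recovered,
                 denominator_N = N),
            class = "frequency_estimate")
}

#' @export
print.frequency_estimate <- function(x, ...) {
  cat(sprintf("frequency_estimate%s: %g barcoded cells / %g barcodes -> 1:%d\n",
              if (is.na(x$label)) "" else paste0(" '", x$label, "'"),
              x$barcoded_cells, x$barcodes_recovered, x$denominator_N))
  invisible(x)
}

#' Serial-transplant persistence of dominant clones
#'
#' Counts the parent-sample barcodes above the dominance cut (default 1%)
#' and how many of them are detected (frequency at or above `detect_frac`,
#' default 0.01%) in at least one serial-transplant recipient.
#'
#' @param parent `clone_table` (or named frequency vector) of the parent
#'   sample.
#' @param children list of recipient `clone_table`s / frequency vectors.
#' @param dominance_frac dominance cut in the parent.
#' @param detect_frac detection floor in the recipients.
#' @return list with `n_dominant`, `n_detected` and `fraction`
#'   (`n_detected / n_dominant`; `NaN` when no clone passes the cut).
#' @export
persistence <- function(parent, children, dominance_frac = 0.01,
                        detect_frac = 1e-4) {
  if (!length(children)) stop("at least one recipient sample is required")
  p <- clone_freqs(parent)
  dominant <- names(p)[p > dominance_frac]
  detected <- vapply(dominant, function(tag) {
    any(vapply(children, function(ch) {
      f <- clone_freqs(ch)
      !is.na(f[tag]) && f[tag] >= detect_frac
    }, logical(1)))
  }, logical(1))
  list(n_dominant = length(dominant), n_detected = sum(detected),
       fraction = sum(detected) / length(dominant))
}

#' Multi-organ sharing of dominant spleen clones
#'
#' For each organ, the fraction of reference-sample (spleen) barcodes above
#' the dominance cut that are detected in that organ at or above the
#' detection floor.
#'
#' @param reference spleen `clone_table` or named frequency vector.
#' @param others named list of per-organ `clone_table`s / frequency vectors.
#' @param dominance_frac dominance cut in the reference.
#' @param detect_frac detection floor in the other organs.
#' @return named numeric vector of detected fractions, one per organ.
#' @export
site_sharing <- function(reference, others, dominance_frac = 0.01,
                         detect_frac = 1e-4) {
  p <- clone_freqs(reference)
  if (!length(p)) stop("reference sample is empty")
  dominant <- names(p)[p > dominance_frac]
  vapply(others, function(org) {
    f <- clone_freqs(org)
    if (!length(dominant)) return(NaN)
    mean(vapply(dominant, function(tag)
      !is.na(f[tag]) && f[tag] >= detect_frac, logical(1)))
  }, numeric(1))
}

#' Richness and dominance metrics of one sample
#'
#' @param ct `clone_table` or named frequency vector.
#' @param top_k cumulative-frequency ranks to report.
#' @return list with `richness` (clone count), `shannon` (-sum p log p),
#'   `max_freq`, and `top_k_cumfreq` (cumulative frequency of the k most
#'   abundant clones). An empty sample returns zeros with a warning.
#' @export
richness_metrics <- function(ct, top_k = c(1L, 5L, 10L)) {
  p <- clone_freqs(ct)
  if (!length(p)) {
    warning("empty clone table: all metrics are zero")
    return(list(richness = 0L, shannon = 0, max_freq = 0,
                top_k_cumfreq = stats::setNames(rep(0, length(top_k)),
                                                paste0("top", top_k))))
  }
  ps <- sort(p, decreasing = TRUE)
  cum <- cumsum(ps)
  kc <- vapply(top_k, function(k) cum[min(k, length(ps))], numeric(1))
  list(richness = length(p),
       shannon = -sum(p[p > 0] * log(p[p > 0])),
       max_freq = ps[[1]],
       top_k_cumfreq = stats::setNames(kc, paste0("top", top_k)))
}

#' Pooled richness across samples
#'
#' @param tables list of `clone_table`s / named frequency vectors.
#' @return list with `per_sample` (richness of each) and `union` (size of
#'   the union of clone sets, always >= the per-sample maximum).
#' @export
pooled_richness <- function(tables) {
  if (!length(tables)) stop("at least one table is required")
  per <- vapply(tables, function(t) length(clone_freqs(t)), integer(1))
  un <- length(unique(unlist(lapply(tables, function(t) names(clone_freqs(t))))))
  list(per_sample = per, union = un)
}
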