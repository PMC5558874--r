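# Shared fixtures and independent oracles used across test files.

# Build a count_table directly from a named count vector.
make_counts <- function(counts, sample_id = "s1", total_input = sum(counts)) {
  counts <- counts[sort(names(counts))]
  clonetrack:::new_count_table(sample_id, counts, total_input)
}

# Minimal sample metadata for cross-sample filtering tests.
make_meta <- function(sample_ids, lineage_ids, run_id = "run1") {
  data.frame(sample_id = sample_ids, run_id = run_id,
             lineage_id = lineage_ids, stringsAsFactors = FALSE)
}

# Brute-force all-pairs oracle for the single-base-error collapse rule:
# tag c is removed iff some tag p at Hamming distance 1 has
# count(p) >= ratio * count(c). Independent of the package's
# neighbour-hashing implementation.
hamming_collapse_oracle <- function(counts, ratio = 10) {
  tags <- names(counts)
  n <- length(tags)
  drop <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sum(strsplit(tags[i], "")[[1]] != strsplit(tags[j], "")[[1]])
      if (d == 1 && counts[j] >= ratio * counts[i]) drop[i] <- TRUE
    }
  }
  counts[!drop]
}

# Definitional recomputation of Nei's H_S, H_T and G over the union tag
# universe, written from first principles (explicit loops).
nei_G_oracle <- function(samples) {
  tags <- sort(unique(unlist(lapply(samples, names))))
  k <- length(samples)
  H <- numeric(k)
  pooled <- setNames(numeric(length(tags)), tags)
  for (i in seq_len(k)) {
    p <- setNames(numeric(length(tags)), tags)
    p[names(samples[[i]])] <- samples[[i]]
    H[i] <- 1 - sum(p * p)
    pooled <- pooled + p / k
  }
  H_S <- sum(H) / k
  H_T <- 1 - sum(pooled * pooled)
  list(H_S = H_S, H_T = H_T,
       G = if (H_T > 0) (H_T - H_S) / H_T else 0)
}

# Random tag set of given size/length (distinct tags), for filter tests.
random_tags <- function(n, len) {
  repeat {
    tags <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
      "")
    if (!anyDuplicated(tags)) return(tags)
  }
}

# Small error-free single-mouse configuration used by several oracle tests.
tiny_clean_config <- function(seed = 11, dose = 50, depth = 20000) {
  sim_config(n_library_tags = 5000, tag_length = 12,
             anchor5 = "ACGGTCATCC", anchor3 = "TGGTCTAGCA",
             doses = dose, mice_per_dose = 1, engraftment_probability = 1,
             moi = 0, organs = list(organ_spec("spleen", n_cells = 1e5)),
             growth_cv = 1, read_depth = depth, substitution_rate = 0,
             pcr_sigma = 0, hop_rate = 0, seed = seed)
}
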