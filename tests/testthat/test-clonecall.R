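test_that("the detection threshold removes tags at or below 0.01% of reads", {
  ct <- make_counts(c(A = 9000L, B = 990L, C = 9L, D = 1L))
  out <- threshold_filter(ct, 1e-4)
  expect_setequal(names(out$counts), c("A", "B", "C"))  # cutoff 1: D removed
  expect_equal(attr(out, "filter_log")$tag, "D")
  # min_frac 0 is the identity
  expect_identical(threshold_filter(ct, 0)$counts, ct$counts)
  # uniform table well above the cutoff is untouched
  uni <- make_counts(setNames(rep(100L, 100), random_tags(100, 8)))
  expect_length(threshold_filter(uni, 1e-4)$counts, 100)
  expect_error(threshold_filter(ct, 1), "min_frac")
  expect_error(threshold_filter(ct, -0.1), "min_frac")
})

test_that("the iterative-total threshold variant re-normalises as it removes", {
  # one dominant tag and many rare ones: removing rare tags shrinks the
  # total, so the recomputed cutoff can only spare tags, never doom them
  rare <- setdiff(random_tags(60, 8), "TTTTTTTT")[1:50]
  cnt <- setNames(c(1e6L, rep(80L, 50)), c("TTTTTTTT", rare))
  ct <- make_counts(cnt[sort(names(cnt))])
  fixed <- threshold_filter(ct, 1e-4)
  iter <- threshold_filter(ct, 1e-4, recompute_total = TRUE)
  expect_true(all(names(fixed$counts) %in% names(iter$counts)))
  # with the fixed total the rare tags fall below 0.01% x 1,004,000
  expect_equal(length(fixed$counts), 1)
  expect_equal(length(iter$counts), 1)
})

test_that("single-base-error collapse follows the parent-ratio rule", {
  out <- hamming_collapse(make_counts(c(ACGT = 1000L, ACGA = 5L)), 10)
  expect_identical(names(out$counts), "ACGT")
  out2 <- hamming_collapse(make_counts(c(ACGT = 1000L, ACGA = 500L)), 10)
  expect_length(out2$counts, 2)
  expect_error(hamming_collapse(make_counts(c(ACGT = 10L, ACG = 5L))),
               "mixed tag lengths")
})

test_that("collapse decisions use original counts in a single pass", {
  # chain A(1000) -> B(90) -> C(9): B is removed by A, and C is removed by B
  # (decided against B's original count) even though B itself is removed;
  # A survives because no neighbour dominates it
  ct <- make_counts(c(AAAA = 1000L, AAAC = 90L, AACC = 9L))
  out <- hamming_collapse(ct, 10)
  expect_identical(names(out$counts), "AAAA")
  # removed reads are discarded, never merged into the parent
  expect_equal(out$counts[["AAAA"]], 1000L)
})

test_that("collapse matches the all-pairs oracle on random tables", {
  set.seed(123)
  for (rep in 1:20) {
    tags <- random_tags(20, 10)
    counts <- setNames(as.integer(10^runif(20, 1, 4)), tags)
    # plant distance-1 errors at 1% of the parent count
    parents <- sample(tags, 5)
    for (p in parents) {
      child <- p
      pos <- sample(10, 1)
      substr(child, pos, pos) <- sample(setdiff(c("A", "C", "G", "T"),
                                                substr(p, pos, pos)), 1)
      if (!child %in% names(counts))
        counts[child] <- max(1L, as.integer(counts[p] * 0.01))
    }
    ct <- make_counts(counts)
    got <- hamming_collapse(ct, 10)$counts
    want <- hamming_collapse_oracle(ct$counts, 10)
    expect_identical(got, want[sort(names(want))])
  }
})

test_that("cross-sample cleaning removes lower-frequency copies across lineages", {
  # 0.5% in mouse1 vs 3% in mouse2 (different lineages): removed from mouse1
  t1 <- make_counts(setNames(c(50L, 9950L), c("AAAA", "CCCC")), "s1")
  t2 <- make_counts(setNames(c(300L, 9700L), c("AAAA", "GGGG")), "s2")
  meta <- make_meta(c("s1", "s2"), c("m1", "m2"))
  out <- cross_sample_clean(list(s1 = t1, s2 = t2), meta)
  expect_false("AAAA" %in% names(out$s1$counts))
  expect_true("AAAA" %in% names(out$s2$counts))
  # same lineage (serial transplant): never removed
  meta_same <- make_meta(c("s1", "s2"), c("m1", "m1"))
  out2 <- cross_sample_clean(list(s1 = t1, s2 = t2), meta_same)
  expect_true("AAAA" %in% names(out2$s1$counts))
  # equal frequencies in two lineages: both kept (strictly higher only)
  t3 <- make_counts(setNames(c(100L, 900L), c("AAAA", "CCCC")), "s3")
  t4 <- make_counts(setNames(c(100L, 900L), c("AAAA", "GGGG")), "s4")
  out3 <- cross_sample_clean(list(s3 = t3, s4 = t4),
                             make_meta(c("s3", "s4"), c("m3", "m4")))
  expect_true("AAAA" %in% names(out3$s3$counts))
  expect_true("AAAA" %in% names(out3$s4$counts))
  # samples from two runs are rejected
  expect_error(cross_sample_clean(list(s1 = t1, s2 = t2),
                                  data.frame(sample_id = c("s1", "s2"),
                                             run_id = c("r1", "r2"),
                                             lineage_id = c("m1", "m2"))),
               "single run")
})

test_that("each filter is a contraction and is idempotent", {
  set.seed(99)
  meta <- make_meta(c("s1", "s2", "s3"), c("m1", "m2", "m3"))
  for (rep in 1:10) {
    tabs <- lapply(c("s1", "s2", "s3"), function(s) {
      n <- sample(5:25, 1)
      make_counts(setNames(as.integer(10^runif(n, 0, 4)),
                           random_tags(n, 8)), s)
    })
    names(tabs) <- c("s1", "s2", "s3")
    for (s in names(tabs)) {
      a <- threshold_filter(tabs[[s]], 1e-3)
      b <- threshold_filter(a, 1e-3)
      expect_true(all(names(a$counts) %in% names(tabs[[s]]$counts)))
      expect_identical(a$counts, b$counts)
      h1 <- hamming_collapse(tabs[[s]], 10)
      h2 <- hamming_collapse(h1, 10)
      expect_true(all(names(h1$counts) %in% names(tabs[[s]]$counts)))
      expect_identical(h1$counts, h2$counts)
    }
    c1 <- cross_sample_clean(tabs, meta)
    c2 <- cross_sample_clean(c1, meta)
    expect_identical(lapply(c1, `[[`, "counts"), lapply(c2, `[[`, "counts"))
  }
})

test_that("clone calling renormalises over retained reads", {
  # four mutually distant tags playing the A/B/C/D roles of the worked
  # example, so the collapse filter cannot interfere
  tags <- c(A = "AAAAAAAA", B = "CCCCCCCC", C = "GGGGGGGG", D = "TTTTTTTT")
  ct <- make_counts(setNames(c(9000L, 990L, 9L, 1L), tags))
  meta <- make_meta("s1", "m1")
  cl <- call_clones(list(s1 = ct), meta)$s1
  expect_equal(cl$retained_reads, 9999L)
  expect_equal(cl$clones[tags[1:3]],
               setNames(c(9000, 990, 9) / 9999, tags[1:3]))
  expect_equal(sum(cl$clones), 1, tolerance = 1e-9)
  expect_equal(cl$filter_log$tag, unname(tags["D"]))
})

test_that("a table that filters to nothing yields an empty clone table", {
  ct <- make_counts(setNames(rep(1L, 5), random_tags(5, 6)),
                    total_input = 1e6)
  ct$counts <- ct$counts  # 5 assigned reads, cutoff 1e-4 * 5 < 1 keeps all
  # force removal via a large min_frac
  cl <- call_clones(list(s1 = ct), make_meta("s1", "m1"), min_frac = 0.5)$s1
  expect_length(cl$clones, 0)
  expect_equal(cl$retained_reads, 0L)
  expect_equal(nrow(cl$filter_log), 5)
})

test_that("filter order is immaterial on hop-free simulated data", {
  cfg <- tiny_clean_config(seed = 19, dose = 40, depth = 30000)
  cfg$mice_per_dose <- 2L
  cfg$substitution_rate <- 0.005
  ex <- simulate_reads(simulate_experiment(cfg))
  run <- clonetrack:::count_run_from_experiment(ex)
  tabs <- lapply(run$tables, function(ct) {
    ct$reference_total <- ct$total_reads_assigned
    threshold_filter(ct, 1e-4)
  })
  ham_then_cross <- cross_sample_clean(lapply(tabs, hamming_collapse),
                                       run$meta)
  cross_then_ham <- lapply(cross_sample_clean(tabs, run$meta),
                           hamming_collapse)
  expect_identical(lapply(ham_then_cross, `[[`, "counts"),
                   lapply(cross_then_ham, `[[`, "counts"))
})
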