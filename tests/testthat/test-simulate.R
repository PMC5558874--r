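lib12 <- generate_library(200, 12, seed = 5)

test_that("founder sampling honours the engraftment model", {
  cfg <- tiny_clean_config()
  # engraftment probability 1 with single integrations: exactly dose founders
  f <- simulate_founders(lib12, cfg, dose = 10, seed = 1)
  expect_equal(nrow(f), 10)
  expect_length(founder_tags(f), 10)
  # engraftment probability 0: empty founder set
  cfg0 <- cfg; cfg0$engraftment_probability <- 0
  expect_equal(nrow(simulate_founders(lib12, cfg0, dose = 10, seed = 1)), 0)
  expect_error(simulate_founders(lib12, cfg, dose = 0), "positive")
  expect_error(simulate_founders(lib12, cfg, dose = -5), "positive")
})

test_that("founder counts match binomial moments across replicates", {
  # dose x p Bernoulli engraftment: mean founder count over seeds should sit
  # within 3 standard errors of dose * p
  cfg <- tiny_clean_config()
  cfg$engraftment_probability <- 0.15
  dose <- 1000; reps <- 500
  n <- vapply(seq_len(reps), function(r)
    length(unique(simulate_founders(lib12, cfg, dose, seed = r)$cell)),
    numeric(1))
  se <- sqrt(dose * 0.15 * 0.85 / reps)
  expect_lt(abs(mean(n) - dose * 0.15), 3 * se)
})

test_that("multiple integrations follow a zero-truncated Poisson", {
  cfg <- tiny_clean_config()
  cfg$moi <- 0.5
  f <- simulate_founders(lib12, cfg, dose = 5000, seed = 9)
  k <- table(table(f$cell))
  # every engrafted cell has at least one tag; mean integrations per cell
  # matches lambda / (1 - exp(-lambda))
  expected_mean <- 0.5 / (1 - exp(-0.5))
  expect_lt(abs(nrow(f) / length(unique(f$cell)) - expected_mean), 0.05)
  expect_true(all(as.integer(names(k)) >= 1))
})

test_that("organ models behave as constructed", {
  cfg <- tiny_clean_config()
  f <- simulate_founders(lib12, cfg, dose = 40, seed = 2)
  tr <- simulate_organs(f, cfg, seed = 3)
  expect_equal(sum(tr$organs$spleen$clone_ab), 1e5)
  expect_setequal(names(tr$organs$spleen$tag_ab), unique(f$tag))
  # a single-niche, single-founder bone contains exactly one clone
  cfg1 <- cfg
  cfg1$organs <- list(organ_spec("femur", "niche", n_cells = 1000,
                                 n_niches = 1, niche_founders = 1))
  tr1 <- simulate_organs(f, cfg1, seed = 4)
  expect_equal(sum(tr1$organs$femur$clone_ab > 0), 1)
  # empty founder sets cannot expand
  empty <- f[0, , drop = FALSE]
  expect_error(simulate_organs(empty, cfg), "empty")
})

test_that("even growth reproduces founder frequencies in pooled organs", {
  cfg <- tiny_clean_config()
  cfg$growth_cv <- 0
  f <- simulate_founders(lib12, cfg, dose = 20, seed = 6)
  cfg$organs <- list(organ_spec("spleen", n_cells = 2e5))
  tr <- simulate_organs(f, cfg, seed = 7)
  freq <- tr$organs$spleen$clone_ab / sum(tr$organs$spleen$clone_ab)
  # multinomial sampling noise only: each clone within 4 SE of 1/20
  se <- sqrt(0.05 * 0.95 / 2e5)
  expect_true(all(abs(freq - 0.05) < 4 * se))
})

test_that("simulated reads carry the expected substitution load", {
  cfg <- sim_config(n_library_tags = 500, tag_length = 30,
                    doses = 100, mice_per_dose = 1,
                    engraftment_probability = 1, moi = 0,
                    organs = list(organ_spec("spleen", n_cells = 1e5)),
                    read_depth = 1e5, substitution_rate = 0.01,
                    pcr_sigma = 0, hop_rate = 0, seed = 21)
  ex <- simulate_reads(simulate_experiment(cfg))
  reads <- ex$reads[[1]]
  prov <- ex$provenance
  # reads are anchor5 + tag + anchor3; the 30-nt tag region is error-free
  # with probability 0.99^30
  tag_region <- substr(reads, nchar(cfg$anchor5) + 1,
                       nchar(cfg$anchor5) + 30)
  p_clean <- mean(tag_region == prov$true_tag)
  expected <- 0.99^30
  se <- sqrt(expected * (1 - expected) / length(reads))
  expect_lt(abs(p_clean - expected), 3 * se)
})

test_that("error-free single-clone samples yield identical reads", {
  cfg <- tiny_clean_config(dose = 1, depth = 50)
  ex <- simulate_reads(simulate_experiment(cfg))
  reads <- ex$reads[[1]]
  expect_length(reads, 50)
  expect_length(unique(reads), 1)
  expect_identical(unique(reads),
                   paste0(cfg$anchor5, ex$provenance$true_tag[1], cfg$anchor3))
})

test_that("index hopping conserves reads and reassigns them within the run", {
  cfg <- sim_config(n_library_tags = 500, tag_length = 12,
                    anchor5 = "ACGGTCATCC", anchor3 = "TGGTCTAGCA",
                    doses = 50, mice_per_dose = 3,
                    engraftment_probability = 1, moi = 0,
                    organs = list(organ_spec("spleen", n_cells = 1e4)),
                    read_depth = 5000, substitution_rate = 0, pcr_sigma = 0,
                    hop_rate = 0.3, seed = 31)
  ex <- simulate_reads(simulate_experiment(cfg))
  expect_equal(sum(lengths(ex$reads)), 3 * 5000)   # conservation
  prov <- ex$provenance
  expect_true(all(prov$sample[prov$hopped] != prov$origin[prov$hopped]))
  expect_true(all(prov$sample[!prov$hopped] == prov$origin[!prov$hopped]))
  expect_gt(sum(prov$hopped), 0)
  # hop_rate 1 with two samples swaps every read
  cfg2 <- cfg; cfg2$mice_per_dose <- 2L; cfg2$hop_rate <- 1
  ex2 <- simulate_reads(simulate_experiment(cfg2))
  expect_true(all(ex2$provenance$sample != ex2$provenance$origin))
})

test_that("identical configuration and seed reproduce reads bit-identically", {
  cfg <- tiny_clean_config(seed = 41, dose = 30, depth = 2000)
  cfg$substitution_rate <- 0.01
  cfg$pcr_sigma <- 0.5
  ex1 <- simulate_reads(simulate_experiment(cfg))
  ex2 <- simulate_reads(simulate_experiment(cfg))
  expect_identical(ex1$reads, ex2$reads)
  expect_identical(ex1$provenance, ex2$provenance)
  expect_identical(truth_table(ex1), truth_table(ex2))
})

test_that("serial transplants inherit the parent lineage and its barcodes", {
  cfg <- tiny_clean_config(seed = 51, dose = 30, depth = 5000)
  cfg$generations <- 2L
  cfg$secondary_dose <- 2000L
  cfg$secondaries_per_mouse <- 1L
  ex <- simulate_experiment(cfg)
  expect_setequal(unique(ex$sheet$generation), c(1L, 2L))
  expect_equal(unique(ex$sheet$lineage_id), "m01")
  child <- ex$mice[["m01_g2a"]]
  expect_true(all(child$truth$founders$tag %in% ex$mice$m01$truth$founders$tag))
})

test_that("configuration validation names the offending key", {
  expect_error(sim_config(doses = c(100, -5)), "doses")
  expect_error(sim_config(hop_rate = 2), "hop_rate")
  expect_error(sim_config(n_library_tags = 20, tag_length = 2),
               "n_library_tags")
  expect_error(sim_config(engraftment_probability = -0.1),
               "engraftment_probability")
})
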