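# Forward simulation of a barcoded xenograft experiment with exact ground
# truth: transduction -> transplant bottleneck -> organ-specific expansion ->
# serial transplants -> sequencing reads.

# Zero-truncated Poisson integrations per transduced cell, by inverse CDF so
# the RNG cost is one uniform per cell regardless of moi.
ztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  u <- stats::runif(n, min = stats::ppois(0, lambda), max = 1)
  pmax(1L, stats::qpois(u, lambda))
}

lognormal_pars <- function(cv) {
  sdlog <- sqrt(log(1 + cv^2))
  c(meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate the founder cells of one transplanted mouse
#'
#' Each of the `dose` transplanted barcoded cells carries k lentiviral
#' integrations, k ~ Poisson(`moi`) conditioned on k >= 1, with tags drawn
#' uniformly (with replacement) from the library; each cell independently
#' engrafts with probability `engraftment_probability`. Untransduced carrier
#' cells are not simulated: they carry no tag and consume no randomness, so
#' diluting the inoculum changes nothing downstream.
#'
#' @param library a [barcode_library()].
#' @param config a [sim_config()] (supplies `moi` and
#'   `engraftment_probability`).
#' @param dose number of barcoded cells transplanted (> 0).
#' @param seed integer seed.
#' @return object of class `founder_set`: a data.frame with one row per
#'   (engrafting cell, integration) pair, columns `cell` and `tag`; the tag
#'   multiset of the founders. Attribute `dose` records the transplanted dose.
#' @export
simulate_founders <- function(library, config, dose, seed = config$seed) {
  dose <- as.integer(dose)
  if (is.na(dose) || dose <= 0L) stop("dose must be a positive integer")
  with_seed(seed, {
    k <- ztpois(dose, config$moi)
    engrafts <- stats::runif(dose) < config$engraftment_probability
    cells <- which(engrafts)
    k <- k[engrafts]
    tags <- if (sum(k)) sample(library$tags, sum(k), replace = TRUE) else character(0)
    out <- data.frame(cell = rep(cells, k), tag = tags,
                      stringsAsFactors = FALSE)
    structure(out, class = c("founder_set", "data.frame"), dose = dose)
  })
}

#' Tag multiset carried by a founder set
#' @param founders a `founder_set`.
#' @return character vector of tags, one entry per integration.
#' @export
founder_tags <- function(founders) founders$tag

#' Simulate terminal clone abundances in each harvested organ
#'
#' Every founder cell receives a log-normal whole-animal expansion factor
#' (coefficient of variation `growth_cv`). Pooled organs (spleen and its
#' parts, meninges) are independent multinomial samples of the whole-animal
#' clone vector, reflecting the spleen's sampling of the circulating pool.
#' Niche organs (single femurs/tibias) are built from `n_niches` niches, each
#' colonised by `niche_founders` clones drawn proportionally to whole-animal
#' abundance and re-expanded independently -- so single bones are dominated
#' by few, randomly favoured clones.
#'
#' @param founders a non-empty [simulate_founders()] result.
#' @param config a [sim_config()] (supplies `growth_cv` and `organs`).
#' @param seed integer seed.
#' @return object of class `organ_truth`: list with `founders`, `clone_tags`
#'   (cell id -> tags), `whole_animal` (clone expansion weights), and
#'   `organs` -- per organ, `clone_ab` (cells per founder clone) and `tag_ab`
#'   (cells per tag; a clone with k tags is credited to all k).
#' @export
simulate_organs <- function(founders, config, seed = config$seed) {
  if (!nrow(founders)) stop("founder set is empty: no engrafted cells to expand")
  cells <- sort(unique(founders$cell))
  n <- length(cells)
  clone_tags <- split(founders$tag, factor(founders$cell, levels = cells))
  lp <- lognormal_pars(config$growth_cv)
  with_seed(seed, {
    w <- stats::rlnorm(n, lp["meanlog"], lp["sdlog"])
    names(w) <- as.character(cells)
    organs <- list()
    for (org in config$organs) {
      clone_ab <- switch(org$model,
        pooled = stats::rmultinom(1, org$n_cells, prob = w)[, 1],
        niche = {
          ab <- integer(n)
          per_niche <- round(org$n_cells / org$n_niches)
          for (j in seq_len(org$n_niches)) {
            chosen <- sample.int(n, min(org$niche_founders, n), prob = w)
            e <- stats::rlnorm(length(chosen), lp["meanlog"], lp["sdlog"])
            ab[chosen] <- ab[chosen] + stats::rmultinom(1, per_niche, prob = e)[, 1]
          }
          ab
        })
      names(clone_ab) <- as.character(cells)
      ta <- tapply(clone_ab[as.character(founders$cell)], founders$tag, sum)
      tag_ab <- stats::setNames(as.integer(ta), names(ta))
      tag_ab <- tag_ab[sort(names(tag_ab))]
      organs[[org$name]] <- list(clone_ab = clone_ab, tag_ab = tag_ab)
    }
    structure(list(founders = founders, clone_tags = clone_tags,
                   whole_animal = w, organs = organs),
              class = "organ_truth")
  })
}

# Draw the founder set of a serial-transplant recipient by re-transplanting
# secondary_dose cells sampled from the parent's spleen clone abundances.
sample_secondary_founders <- function(parent_truth, config, seed,
                                      source_organ = NULL) {
  organs <- parent_truth$organs
  if (is.null(source_organ))
    source_organ <- if ("spleen" %in% names(organs)) "spleen" else names(organs)[1]
  clone_ab <- organs[[source_organ]]$clone_ab
  clone_ab <- clone_ab[clone_ab > 0]
  if (!length(clone_ab)) stop("source organ has no cells to re-transplant")
  with_seed(seed, {
    picked <- sample(names(clone_ab), config$secondary_dose, replace = TRUE,
                     prob = clone_ab)
    engrafts <- stats::runif(config$secondary_dose) < config$engraftment_probability
    picked <- picked[engrafts]
    tags <- parent_truth$clone_tags[picked]
    out <- data.frame(cell = rep(seq_along(picked), lengths(tags)),
                      tag = unlist(tags, use.names = FALSE),
                      stringsAsFactors = FALSE)
    structure(out, class = c("founder_set", "data.frame"),
              dose = config$secondary_dose)
  })
}

#' Simulate a complete barcoding experiment (truth level)
#'
#' Runs library construction, per-mouse founder sampling and organ expansion
#' for every dose group and serial-transplant generation in `config`, and
#' assembles the sample sheet and ground-truth tables. Sequencing reads are
#' added by [simulate_reads()].
#'
#' @param config a [sim_config()].
#' @return object of class `sim_experiment`: list with `config`, `library`,
#'   `sheet` (one row per sample: sample_id, run_id, mouse_id, lineage_id,
#'   organ, generation, barcoded_cells, total_cells, transduction_fraction,
#'   fastq_path), `truth` (sample_id -> named integer tag abundances) and
#'   `mice` (per-mouse founder sets and organ truths).
#' @export
simulate_experiment <- function(config) {
  seed <- config$seed
  lib <- generate_library(config$n_library_tags, config$tag_length,
                          c(config$anchor5, config$anchor3),
                          seed = stream_seed(seed, "library"))
  mice <- list()
  rows <- list()
  truth <- list()

  add_mouse <- function(mouse_id, lineage_id, generation, founders, dose) {
    if (!nrow(founders)) return(NULL)  # mouse never develops leukaemia
    tr <- simulate_organs(founders, config,
                          seed = stream_seed(seed, paste0("growth_", mouse_id)))
    mice[[mouse_id]] <<- list(mouse_id = mouse_id, lineage_id = lineage_id,
                              generation = generation, dose = dose,
                              truth = tr)
    for (org in config$organs) {
      sid <- paste(mouse_id, org$name, sep = "_")
      truth[[sid]] <<- tr$organs[[org$name]]$tag_ab
      rows[[sid]] <<- data.frame(
        sample_id = sid, run_id = "run1", mouse_id = mouse_id,
        lineage_id = lineage_id, organ = org$name, generation = generation,
        barcoded_cells = dose,
        total_cells = as.integer(round(dose / config$transduction_fraction)),
        transduction_fraction = config$transduction_fraction,
        fastq_path = NA_character_, stringsAsFactors = FALSE)
    }
    invisible(NULL)
  }

  m <- 0L
  for (dose in config$doses) {
    for (i in seq_len(config$mice_per_dose)) {
      m <- m + 1L
      mouse_id <- sprintf("m%02d", m)
      founders <- simulate_founders(
        lib, config, dose, seed = stream_seed(seed, paste0("founders_", mouse_id)))
      add_mouse(mouse_id, mouse_id, 1L, founders, dose)
      if (config$generations > 1L && !is.null(mice[[mouse_id]])) {
        parents <- mouse_id
        for (g in 2L:config$generations) {
          nxt <- character(0)
          for (p in parents) {
            if (is.null(mice[[p]])) next
            for (r in seq_len(config$secondaries_per_mouse)) {
              child <- sprintf("%s_g%d%s", p, g, letters[r])
              f2 <- sample_secondary_founders(
                mice[[p]]$truth, config,
                seed = stream_seed(seed, paste0("founders_", child)))
              add_mouse(child, mouse_id, g, f2, config$secondary_dose)
              if (!is.null(mice[[child]])) nxt <- c(nxt, child)
            }
          }
          parents <- nxt
        }
      }
    }
  }
  sheet <- do.call(rbind, rows)
  rownames(sheet) <- NULL
  structure(list(config = config, library = lib, sheet = sheet,
                 truth = truth, mice = mice),
            class = "sim_experiment")
}

# Apply independent per-base substitutions to equal-length reads.
# One global draw of error positions (without replacement over the
# read x position grid) keeps the model exact and vectorised.
mutate_reads <- function(seqs, rate) {
  n <- length(seqs)
  if (rate <= 0 || n == 0L) return(seqs)
  len <- nchar(seqs[1])
  m <- stats::rbinom(1, n * len, rate)
  if (m == 0) return(seqs)
  idx <- sample.int(n * len, m)
  read <- (idx - 1L) %/% len + 1L
  pos <- (idx - 1L) %% len + 1L
  cur <- substring(seqs[read], pos, pos)
  shift <- sample.int(3, m, replace = TRUE)
  newb <- DNA_BASES[(match(cur, DNA_BASES) + shift - 1L) %% 4L + 1L]
  occ <- stats::ave(seq_len(m), read, FUN = seq_along)
  for (k in seq_len(max(occ))) {
    sel <- occ == k
    i <- read[sel]
    s2 <- seqs[i]
    substr(s2, pos[sel], pos[sel]) <- newb[sel]
    seqs[i] <- s2
  }
  seqs
}

#' Simulate sequencing reads for every sample of an experiment
#'
#' Per sample, `read_depth` reads of `anchor5 + tag + anchor3` are drawn with
#' probability proportional to true tag abundance times a per-tag log-normal
#' PCR amplification factor (resampled per sample, so bias never mimics
#' heritable clone behaviour). Each base is substituted independently with
#' probability `substitution_rate`, then each read is reassigned to a
#' uniformly chosen other sample of the same run with probability `hop_rate`
#' (index hopping). Read totals across the run are conserved by hopping.
#'
#' @param experiment a [simulate_experiment()] result.
#' @param seed integer seed (defaults to the experiment's root seed).
#' @return the experiment, with `reads` (sample_id -> character vector of
#'   read sequences) and `provenance` (data.frame: read_id, origin, sample,
#'   true_tag, hopped) filled in.
#' @export
simulate_reads <- function(experiment, seed = experiment$config$seed) {
  config <- experiment$config
  samples <- names(experiment$truth)
  seq_list <- vector("list", length(samples))
  tag_list <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    s <- samples[i]
    ab <- experiment$truth[[s]]
    ab <- ab[ab > 0]
    if (!length(ab)) {
      seq_list[[i]] <- character(0); tag_list[[i]] <- character(0); next
    }
    lp_sig <- config$pcr_sigma
    res <- with_seed(stream_seed(seed, paste0("reads_", s)), {
      pcr <- stats::rlnorm(length(ab), -lp_sig^2 / 2, lp_sig)
      nreads <- stats::rmultinom(1, config$read_depth, prob = ab * pcr)[, 1]
      tags <- rep(names(ab), nreads)
      seqs <- rep(paste0(config$anchor5, names(ab), config$anchor3), nreads)
      list(tags = tags, seqs = mutate_reads(seqs, config$substitution_rate))
    })
    seq_list[[i]] <- res$seqs
    tag_list[[i]] <- res$tags
  }
  depths <- lengths(seq_list)
  origin <- rep(samples, depths)
  seqs <- unlist(seq_list, use.names = FALSE)
  tags <- unlist(tag_list, use.names = FALSE)
  final <- origin
  hopped <- logical(length(seqs))
  if (config$hop_rate > 0 && length(samples) > 1L && length(seqs)) {
    idx <- match(origin, samples)
    hopped <- with_seed(stream_seed(seed, "hop"),
                        stats::runif(length(seqs)) < config$hop_rate)
    nh <- sum(hopped)
    if (nh) {
      r <- with_seed(stream_seed(seed, "hop_dest"),
                     sample.int(length(samples) - 1L, nh, replace = TRUE))
      dest <- ifelse(r >= idx[hopped], r + 1L, r)
      final[hopped] <- samples[dest]
    }
  }
  read_id <- sprintf("%s_r%07d", origin,
                     unlist(lapply(depths, seq_len), use.names = FALSE))
  provenance <- data.frame(read_id = read_id, origin = origin,
                           sample = final, true_tag = tags, hopped = hopped,
                           stringsAsFactors = FALSE)
  experiment$reads <- split(seqs, factor(final, levels = samples))
  experiment$read_ids <- split(read_id, factor(final, levels = samples))
  experiment$provenance <- provenance
  experiment
}

#' Ground-truth table of an experiment as a data frame
#'
#' @param experiment a [simulate_experiment()] result.
#' @return data.frame with columns mouse, generation, organ, tag,
#'   true_abundance (cells), sorted for byte-stable output.
#' @export
truth_table <- function(experiment) {
  out <- list()
  for (m in experiment$mice) {
    for (org_name in names(m$truth$organs)) {
      ab <- m$truth$organs[[org_name]]$tag_ab
      ab <- ab[ab > 0]
      if (!length(ab)) next
      out[[paste(m$mouse_id, org_name)]] <- data.frame(
        mouse = m$mouse_id, generation = m$generation, organ = org_name,
        tag = names(ab), true_abundance = as.integer(ab),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df[order(df$mouse, df$generation, df$organ, df$tag), , drop = FALSE]
}
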