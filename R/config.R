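# Simulation configuration: the experimental conditions of a barcoded
# xenotransplant study, from library complexity through sequencing noise.

#' Describe one organ sampled at harvest
#'
#' Two growth models are available. `pooled` organs (spleen, spleen parts,
#' meninges) sample the circulating blast pool, so their composition is a
#' multinomial draw from the whole-animal clone abundances. `niche` organs
#' (individual femurs and tibias) are assembled from a small number of
#' marrow niches, each colonised by a few founders that then expand
#' independently -- the focal-growth mechanism that produces stochastic
#' clonal dominance in single bones.
#'
#' @param name organ name used in sample ids (e.g. `"spleen"`, `"femur_L"`).
#' @param model `"pooled"` or `"niche"`.
#' @param n_cells number of cells sampled from the organ at harvest.
#' @param n_niches number of independent niches (niche model only).
#' @param niche_founders founder clones colonising each niche.
#' @return a list of class `organ_spec`.
#' @export
organ_spec <- function(name, model = c("pooled", "niche"), n_cells = 1e6,
                       n_niches = 5L, niche_founders = 10L) {
  model <- match.arg(model)
  stopifnot(nzchar(name), n_cells >= 1, n_niches >= 1, niche_founders >= 1)
  structure(list(name = name, model = model, n_cells = as.integer(n_cells),
                 n_niches = as.integer(n_niches),
                 niche_founders = as.integer(niche_founders)),
            class = "organ_spec")
}

default_organs <- function() {
  list(
    organ_spec("spleen",   "pooled"),
    organ_spec("femur_L",  "niche"),
    organ_spec("femur_R",  "niche"),
    organ_spec("meninges", "pooled")
  )
}

#' Simulation configuration for a barcoded xenograft experiment
#'
#' Defaults describe a typical primograft ALL barcoding study: a library of
#' 100,000 random 30-nt tags, transduction capped near 10% to limit multiple
#' lentiviral integrations (modelled as zero-truncated Poisson with mean
#' `moi`), intrafemoral transplants of 100-10,000 barcoded cells into
#' replicate mice, engraftment as an independent per-cell Bernoulli event,
#' log-normal clonal expansion, and MiSeq-style single-end sequencing with
#' PCR amplification bias, per-base substitution error and within-run index
#' hopping.
#'
#' @param n_library_tags unique tags in the lentiviral library.
#' @param tag_length tag length (nt); `n_library_tags` must be at most
#'   `4^tag_length`.
#' @param anchor5,anchor3 constant sequences flanking the tag in each read.
#' @param transduction_fraction fraction of injected cells carrying a barcode.
#' @param moi mean lentiviral integrations per transduced cell
#'   (Poisson, conditioned on at least one); a cell carrying k tags
#'   contributes its abundance to all k tags.
#' @param doses barcoded cells transplanted per mouse, one entry per dose
#'   group.
#' @param mice_per_dose replicate mice per dose group.
#' @param unlabelled_cells untransduced carrier cells co-injected per mouse;
#'   they never engraft a barcode and never enter reads, so they affect no
#'   statistic (the dilution control).
#' @param engraftment_probability probability that a transplanted barcoded
#'   cell engrafts and founds a clone.
#' @param organs list of [organ_spec()] objects harvested per mouse.
#' @param growth_cv coefficient of variation of the log-normal per-founder
#'   expansion factor (0 = perfectly even growth).
#' @param read_depth sequencing reads per sample.
#' @param substitution_rate per-base substitution error probability.
#' @param pcr_sigma log-scale SD of the per-tag, per-sample PCR amplification
#'   multiplier (0 = unbiased amplification).
#' @param hop_rate probability a read is reassigned to a uniformly chosen
#'   other sample of the same sequencing run (index hopping).
#' @param generations serial transplant generations (1 = primary only).
#' @param secondary_dose cells re-transplanted from the parent spleen into
#'   each secondary/tertiary recipient.
#' @param secondaries_per_mouse recipients re-transplanted per parent mouse.
#' @param seed root seed; every stage draws from a named sub-stream of it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_library_tags = 100000L,
                       tag_length = DEFAULT_TAG_LENGTH,
                       anchor5 = DEFAULT_ANCHOR5,
                       anchor3 = DEFAULT_ANCHOR3,
                       transduction_fraction = 0.10,
                       moi = 0.1,
                       doses = c(100L, 1000L, 10000L),
                       mice_per_dose = 3L,
                       unlabelled_cells = 0L,
                       engraftment_probability = 0.1,
                       organs = default_organs(),
                       growth_cv = 1.0,
                       read_depth = 1e5,
                       substitution_rate = 0.001,
                       pcr_sigma = 0.5,
                       hop_rate = 0.001,
                       generations = 1L,
                       secondary_dose = 10000L,
                       secondaries_per_mouse = 2L,
                       seed = 1L) {
  cfg <- list(n_library_tags = as.integer(n_library_tags),
              tag_length = as.integer(tag_length),
              anchor5 = anchor5, anchor3 = anchor3,
              transduction_fraction = transduction_fraction,
              moi = moi,
              doses = as.integer(doses),
              mice_per_dose = as.integer(mice_per_dose),
              unlabelled_cells = as.integer(unlabelled_cells),
              engraftment_probability = engraftment_probability,
              organs = organs,
              growth_cv = growth_cv,
              read_depth = as.integer(read_depth),
              substitution_rate = substitution_rate,
              pcr_sigma = pcr_sigma,
              hop_rate = hop_rate,
              generations = as.integer(generations),
              secondary_dose = as.integer(secondary_dose),
              secondaries_per_mouse = as.integer(secondaries_per_mouse),
              seed = as.integer(seed))
  validate_sim_config(structure(cfg, class = "sim_config"))
}

validate_sim_config <- function(cfg) {
  chk_prob <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      stop("invalid value for '", key, "': must be a probability in [0,1]")
  }
  chk_count <- function(x, key, min = 0L) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < min))
      stop("invalid value for '", key, "': must be >= ", min)
  }
  chk_count(cfg$n_library_tags, "n_library_tags", 1L)
  chk_count(cfg$tag_length, "tag_length", 1L)
  if (cfg$n_library_tags > 4^cfg$tag_length)
    stop("invalid value for 'n_library_tags': exceeds 4^tag_length")
  chk_prob(cfg$transduction_fraction, "transduction_fraction")
  if (cfg$transduction_fraction == 0) stop("invalid value for 'transduction_fraction': must be > 0")
  chk_count(cfg$moi, "moi")
  if (!length(cfg$doses)) stop("invalid value for 'doses': at least one dose required")
  chk_count(cfg$doses, "doses", 1L)
  chk_count(cfg$mice_per_dose, "mice_per_dose", 1L)
  chk_count(cfg$unlabelled_cells, "unlabelled_cells", 0L)
  chk_prob(cfg$engraftment_probability, "engraftment_probability")
  if (!length(cfg$organs)) stop("invalid value for 'organs': at least one organ required")
  for (o in cfg$organs)
    if (!inherits(o, "organ_spec")) stop("invalid value for 'organs': entries must be organ_spec objects")
  if (anyDuplicated(vapply(cfg$organs, `[[`, "", "name")))
    stop("invalid value for 'organs': organ names must be unique")
  chk_count(cfg$growth_cv, "growth_cv")
  chk_count(cfg$read_depth, "read_depth", 1L)
  chk_prob(cfg$substitution_rate, "substitution_rate")
  chk_count(cfg$pcr_sigma, "pcr_sigma")
  chk_prob(cfg$hop_rate, "hop_rate")
  chk_count(cfg$generations, "generations", 1L)
  chk_count(cfg$secondary_dose, "secondary_dose", 1L)
  chk_count(cfg$secondaries_per_mouse, "secondaries_per_mouse", 1L)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: %d-tag library (%d nt), doses {%s} x %d mice, engraftment p=%.3g\n",
    "  organs: %s\n  depth %d, sub %.4g, pcr_sigma %.3g, hop %.4g, generations %d, seed %d\n"),
    x$n_library_tags, x$tag_length, paste(x$doses, collapse = ","),
    x$mice_per_dose, x$engraftment_probability,
    paste(vapply(x$organs, function(o) paste0(o$name, "[", o$model, "]"), ""),
          collapse = ", "),
    x$read_depth, x$substitution_rate, x$pcr_sigma, x$hop_rate,
    x$generations, x$seed))
  invisible(x)
}
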