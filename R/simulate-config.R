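#' Simulation configuration
#'
#' Holds every knob of the synthetic-data generator. The generator plants,
#' with known ("truth-table") parameters, each statistical structure the
#' analysis modules assume: a sub-100-bp eccDNA size mode, GC-biased and
#' gene/Alu-density-coupled placement, a bimodal H/L per-sample abundance
#' split, copy-number profiles whose wGII tracks the abundance groups,
#' expression matrices with planted fold changes, and survival cohorts with
#' a planted hazard ratio.
#'
#' @param seed master seed; every generator derives its own stream from it
#'   via [derive_seed()], so outputs are byte-identical under one seed.
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (recycled over chromosomes).
#' @param gc_landscape vector of per-window target GC fractions, recycled
#'   across `gc_window` windows; a single value gives a uniform landscape.
#' @param gc_window window size (bp) at which the GC landscape is realized.
#' @param gene_density_gradient genes per Mb at the start and end of each
#'   chromosome; density interpolates linearly across `density_window`
#'   windows.
#' @param repeat_fraction genome fraction covered by repeat elements
#'   (default 0.525, the approximate repeat content of the human genome).
#' @param density_window window (bp) at which gene/Alu densities are
#'   measured for placement coupling; at least 10 kb.
#' @param size_mode modal eccDNA length in bp (default 80, reproducing the
#'   sub-100-bp primary subtype of circle-seq catalogs).
#' @param size_sigma log-scale spread of the log-normal length distribution.
#' @param gc_bias placement weight exponent beta (weight proportional to
#'   `exp(beta * windowGC)`); 0 plants no GC preference.
#' @param density_coupling numeric `c(a, b)`: placement weight factor
#'   `1 + a * geneDensity + b * AluDensity` with densities scaled to `[0,1]`.
#' @param element_weights optional named per-class placement multipliers
#'   (e.g. `c(SINE = 3)`): a record whose midpoint falls inside an element
#'   of the class is that many times as likely as a background position
#'   (multipliers multiply where classes overlap).
#' @param n_samples number of catalogs; the first half are H, the rest L.
#' @param abundance_split named `c(H=, L=)` mean catalog sizes (records).
#' @param mapped_reads_range uniform range for per-sample mapped-read totals.
#' @param wgii_targets named `c(H=, L=)` target wGII per group.
#' @param wgii_noise_sd between-sample sd of the wGII target (the coupling
#'   strength dial: smaller means tighter abundance-instability coupling).
#' @param n_genes,n_de,fold_change,expr_sigma expression generator: total
#'   genes, planted DE genes (half up, half down in H), group-mean fold
#'   change, and log2-scale noise sd.
#' @param expr_n_per_group samples (or cells) per group in the expression
#'   matrix.
#' @param survival_hr hazard ratio of the high-score stratum.
#' @param censoring_rate fraction of patients independently censored.
#' @param surv_n patients in the survival cohort.
#' @param baseline_hazard exponential baseline hazard (per day).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chrom = 4L,
                       chrom_length = 1e6,
                       gc_landscape = 0.41,
                       gc_window = 1e4,
                       gene_density_gradient = c(5, 50),
                       repeat_fraction = 0.525,
                       density_window = 1e4,
                       size_mode = 80,
                       size_sigma = 0.45,
                       gc_bias = 0,
                       density_coupling = c(a = 0, b = 0),
                       element_weights = NULL,
                       n_samples = 18L,
                       abundance_split = c(H = 4000, L = 400),
                       mapped_reads_range = c(1.5e7, 2.5e7),
                       wgii_targets = c(H = 0.6, L = 0.1),
                       wgii_noise_sd = 0.05,
                       n_genes = 2000L,
                       n_de = 200L,
                       fold_change = 1.5,
                       expr_sigma = 0.5,
                       expr_n_per_group = 100L,
                       survival_hr = 2,
                       censoring_rate = 0.2,
                       surv_n = 300L,
                       baseline_hazard = 1 / 1000) {
  cfg <- as.list(environment())
  assert_that(all(cfg$gc_landscape >= 0 & cfg$gc_landscape <= 1),
              "gc_landscape fractions must be in [0,1]")
  assert_that(cfg$repeat_fraction >= 0 && cfg$repeat_fraction <= 1,
              "repeat_fraction must be in [0,1]")
  assert_that(cfg$censoring_rate >= 0 && cfg$censoring_rate <= 1,
              "censoring_rate must be in [0,1]")
  assert_that(cfg$n_chrom >= 1 && cfg$chrom_length > 0,
              "genome dimensions must be positive")
  assert_that(cfg$size_mode > 0 && cfg$size_sigma > 0,
              "size distribution parameters must be positive")
  assert_that(cfg$gc_bias >= 0, "gc_bias must be >= 0")
  assert_that(cfg$n_samples >= 2, "need at least two samples")
  assert_that(cfg$fold_change > 0, "fold_change must be positive")
  assert_that(cfg$survival_hr > 0, "survival_hr must be positive")
  if (!is.null(cfg$element_weights)) {
    assert_that(!is.null(names(cfg$element_weights)) &&
                  all(names(cfg$element_weights) %in% REPEAT_CLASSES) &&
                  all(cfg$element_weights > 0),
                "element_weights must be positive and named by repeat class")
  }
  if (is.null(names(cfg$density_coupling))) {
    names(cfg$density_coupling) <- c("a", "b")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' H/L group labels implied by a configuration
#'
#' The first `ceiling(n_samples / 2)` samples form the high-abundance (H)
#' group, the remainder the low (L) group.
#'
#' @param config a [sim_config].
#' @return character vector of `"H"` / `"L"` labels.
#' @export
sim_group_labels <- function(config) {
  n_h <- ceiling(config$n_samples / 2)
  c(rep("H", n_h), rep("L", config$n_samples - n_h))
}
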