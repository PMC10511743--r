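# Scenario configuration for the synthetic-data generator.

#' Scenario configuration for synthetic wet-up data
#'
#' Bundles and validates every tunable of the generator. Defaults emulate
#' the study system: 3 field plots sampled destructively at 0, 3, 24, 48, 72
#' and 168 h after wet-up (metagenomes and SIP omit the 3 h point), viral
#' richness declining by half over the week while viral biomass rises
#' several-fold, 17% of vOTUs carrying an integrase gene, and roughly a
#' third of virome reads mapping to the vOTU set.
#'
#' @param seed single integer; all randomness derives from it via named
#'   substreams, so equal configs give byte-identical datasets.
#' @param n_plots number of replicate field plots (microcosm triplicates).
#' @param time_points_h virome sampling times in hours, strictly increasing.
#' @param metagenome_time_points_h metagenome sampling times (no 3 h point).
#' @param sip_time_points_h times with density-fractionated (qSIP) data.
#' @param n_votus,n_mags catalog sizes. `n_votus = 0` yields an empty but
#'   valid dataset.
#' @param richness_decline_frac target fractional drop of mean vOTU richness
#'   from the first to the last time point, in \[0, 1\].
#' @param biomass_fold_change latent fold increase of viral DNA per gram
#'   soil over the time course (positive).
#' @param frac_integrase fraction of vOTUs carrying an integrase gene.
#' @param frac_circular fraction of multi-tool vOTUs that circularize.
#' @param response_mix named fractions over the five response categories
#'   (`early`, `late`, `ubiquitous`, `zero_and_168`, `other`); must sum
#'   to 1.
#' @param persistent_frac fraction of each plot's vOTU pool given a
#'   persistent response template (the rest are transients shaping the
#'   richness decline).
#' @param plot_pool_frac fraction of the catalog seen by each plot
#'   (plot-specific composition with partial overlap).
#' @param frac_active fraction of genomes that incorporate isotope.
#' @param ape_range range of true atom fraction excess for active genomes.
#' @param true_ape optional named numeric vector (genome id -> atom fraction
#'   excess in \[0, 1\]) overriding the random assignment.
#' @param abundance_cv lognormal coefficient of variation of abundance
#'   noise; 0 makes abundances, read fractions and breadths deterministic.
#' @param density_sd sd (g/mL) of the recorded fraction densities
#'   (measurement noise).
#' @param profile_sd sd (g/mL) of the Gaussian density profile of a
#'   genome's DNA within a gradient.
#' @param n_fractions density fractions per tube.
#' @param density_range range (g/mL) spanned by the fraction grid.
#' @param gc_range range of genome GC content (sets unlabeled densities).
#' @param viral_read_fraction mean fraction of virome reads mapping to the
#'   vOTU set.
#' @param viral_read_fraction_sd replicate-level sd of that fraction.
#' @param dna_yield_t0 virome DNA yield at time 0 (ng per g soil).
#' @param loss_rate 16S rRNA copies lost per gram soil per day.
#' @param rrna_copies_per_cell rRNA gene copies per cell.
#' @param burst_sizes burst-size grid for the mortality model.
#' @param sample_total_reads library size per sample.
#' @param tube_dna_ng total DNA recovered per SIP tube (ng).
#' @param n_host_links vOTUs with planted CRISPR-spacer host links.
#' @param n_lysogens planted lysogen alignments passing every filter.
#' @param n_prophages prophage coverage records (3 of them active).
#' @return validated list of class `"scenario_config"`.
#' @export
scenario_config <- function(seed = 1L,
                            n_plots = 3L,
                            time_points_h = c(0, 3, 24, 48, 72, 168),
                            metagenome_time_points_h = c(0, 24, 48, 72, 168),
                            sip_time_points_h = c(24, 48, 72, 168),
                            n_votus = 400L,
                            n_mags = 60L,
                            richness_decline_frac = 0.5,
                            biomass_fold_change = 5,
                            frac_integrase = 0.17,
                            frac_circular = 0.2,
                            response_mix = c(early = 0.25, late = 0.10,
                                             ubiquitous = 0.15,
                                             zero_and_168 = 0.15,
                                             other = 0.35),
                            persistent_frac = 0.45,
                            plot_pool_frac = 0.7,
                            frac_active = 0.4,
                            ape_range = c(0.1, 0.5),
                            true_ape = NULL,
                            abundance_cv = 0.2,
                            density_sd = 0.003,
                            profile_sd = 0.012,
                            n_fractions = 20L,
                            density_range = c(1.61, 1.81),
                            gc_range = c(0.35, 0.65),
                            viral_read_fraction = 0.353,
                            viral_read_fraction_sd = 0.03,
                            dna_yield_t0 = 1.5,
                            loss_rate = 2e9,
                            rrna_copies_per_cell = 6,
                            burst_sizes = c(1, 10, 25, 50, 100, 200),
                            sample_total_reads = 2e6,
                            tube_dna_ng = 500,
                            n_host_links = 20L,
                            n_lysogens = 3L,
                            n_prophages = 12L) {
  cfg <- as.list(environment())
  chk_frac <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      stop(nm, " must be in [0, 1]")
  }
  if (length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single integer")
  if (is.unsorted(time_points_h, strictly = TRUE))
    stop("time_points_h must be strictly increasing")
  if (is.unsorted(metagenome_time_points_h, strictly = TRUE) ||
      is.unsorted(sip_time_points_h, strictly = TRUE))
    stop("time axes must be strictly increasing")
  for (nm in c("richness_decline_frac", "frac_integrase", "frac_circular",
               "persistent_frac", "plot_pool_frac", "frac_active",
               "viral_read_fraction"))
    chk_frac(cfg[[nm]], nm)
  chk_frac(ape_range, "ape_range")
  chk_frac(gc_range, "gc_range")
  if (!is.null(true_ape)) {
    chk_frac(true_ape, "true_ape")
    if (is.null(names(true_ape))) stop("true_ape must be named by genome id")
  }
  need <- c("early", "late", "ubiquitous", "zero_and_168", "other")
  if (!setequal(names(response_mix), need))
    stop("response_mix must be named: ", paste(need, collapse = ", "))
  chk_frac(response_mix, "response_mix")
  if (abs(sum(response_mix) - 1) > 1e-9)
    stop("response_mix fractions must sum to 1")
  cfg$response_mix <- response_mix[need]
  if (biomass_fold_change <= 0) stop("biomass_fold_change must be positive")
  if (n_votus < 0 || n_mags < 0 || n_plots < 1)
    stop("counts must be non-negative (n_plots >= 1)")
  if (n_fractions < 2L) stop("n_fractions must be >= 2")
  if (any(c(abundance_cv, density_sd, profile_sd) < 0))
    stop("noise levels must be >= 0")
  structure(cfg, class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  %d plots x {%s} h; %d vOTUs, %d MAGs; seed %d\n",
              x$n_plots, paste(x$time_points_h, collapse = ","),
              x$n_votus, x$n_mags, as.integer(x$seed)))
  cat(sprintf("  richness decline %.2f, biomass fold %.1f, integrase %.2f\n",
              x$richness_decline_frac, x$biomass_fold_change,
              x$frac_integrase))
  invisible(x)
}
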