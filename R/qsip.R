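# qSIP: atom percent excess (APE) from buoyant-density shifts, with
# bootstrap confidence intervals and the study's detection/CI filters.
#
# Formula chain (standard 18O-qSIP):
#   GC         = (W_light - 1.646057) / 0.083506
#   M_light    = 0.496 * GC + 307.691            [g/mol per bp]
#   M_lab      = (W_lab / W_light) * M_light
#   M_heavymax = M_light + 12.07747              [full 18O labeling]
#   APE        = (M_lab - M_light) / (M_heavymax - M_light)
#                  * (1 - 0.002000429)           [natural 18O abundance]

.qsip_const <- list(
  gc_intercept = 1.646057,
  gc_slope     = 0.083506,
  m_slope      = 0.496,
  m_intercept  = 307.691,
  delta_m_max  = 12.07747,
  nat_abund_18o = 0.002000429
)

#' qSIP constants
#'
#' Returns the constants of the density-to-enrichment formula chain: the
#' GC-from-density linear map, the molecular-weight-from-GC map, the maximum
#' per-base-pair mass gain under full 18O labeling, and the natural 18O
#' abundance.
#'
#' @return named list of constants.
#' @export
qsip_constants <- function() .qsip_const

#' Abundance-weighted mean buoyant density
#'
#' The density centroid of one genome in one ultracentrifuge tube:
#' `W = sum(density_i * y_i) / sum(y_i)` with weights
#' `y_i = rel_abund_i * dna_ng_i` (relative abundance in the fraction scaled
#' by the DNA mass of the fraction). Fractions with zero DNA are dropped
#' before weighting. When every weight is zero the centroid is undefined and
#' `NA` is returned with a warning.
#'
#' @param density fraction densities (g/mL).
#' @param rel_abund per-fraction relative abundance of the genome.
#' @param dna_ng per-fraction DNA mass (ng).
#' @return weighted mean density (g/mL) or `NA`.
#' @export
weighted_mean_density <- function(density, rel_abund, dna_ng) {
  if (length(density) == 0L) stop("need at least one fraction")
  if (!(length(density) == length(rel_abund) &&
        length(density) == length(dna_ng)))
    stop("density, rel_abund and dna_ng must align")
  keep <- dna_ng > 0
  y <- rel_abund[keep] * dna_ng[keep]
  if (sum(y) <= 0) {
    warning("all weights zero: weighted mean density undefined")
    return(NA_real_)
  }
  sum(density[keep] * y) / sum(y)
}

#' Atom fraction excess from light and labeled densities
#'
#' Applies the qSIP formula chain (see [qsip_constants()]) to the unlabeled
#' (`w_light`) and labeled (`w_lab`) density centroids of a genome. Returns 0
#' when `w_lab == w_light`; a labeled centroid lighter than the unlabeled one
#' yields a negative value, deliberately not clipped, so downstream
#' confidence-interval filters can see it.
#'
#' @param w_light,w_lab density centroids (g/mL); vectorized.
#' @return atom fraction excess (0-1 scale; 0.30 means 30 atom percent
#'   excess).
#' @export
#' @examples
#' ape_from_densities(1.70, 1.72)  # ~0.2994
ape_from_densities <- function(w_light, w_lab) {
  if (any(w_light <= 0)) stop("w_light must be positive")
  k <- .qsip_const
  gc <- (w_light - k$gc_intercept) / k$gc_slope
  m_light <- k$m_slope * gc + k$m_intercept
  m_lab <- (w_lab / w_light) * m_light
  ((m_lab - m_light) / k$delta_m_max) * (1 - k$nat_abund_18o)
}

#' Labeled density implied by an atom fraction excess
#'
#' Exact inverse of [ape_from_densities()] in its second argument; used by
#' the synthetic-data generator to place labeled density profiles.
#'
#' @param w_light unlabeled density centroid (g/mL).
#' @param ape atom fraction excess in \[0, 1\].
#' @return labeled density centroid (g/mL).
#' @export
density_for_ape <- function(w_light, ape) {
  if (any(w_light <= 0)) stop("w_light must be positive")
  if (any(ape < 0 | ape > 1)) stop("ape must be in [0, 1]")
  k <- .qsip_const
  gc <- (w_light - k$gc_intercept) / k$gc_slope
  m_light <- k$m_slope * gc + k$m_intercept
  m_lab <- m_light + ape / (1 - k$nat_abund_18o) * k$delta_m_max
  w_light * m_lab / m_light
}

#' Bootstrap APE estimate from replicate tube centroids
#'
#' Resamples replicate tubes with replacement within each treatment,
#' averages the resampled centroids, applies the formula chain, and reports
#' the bootstrap median with a percentile confidence interval. The point of
#' resampling at the tube level is that tubes (one per field plot) are the
#' independent experimental units.
#'
#' @param w_light_reps unlabeled per-tube density centroids (one per
#'   replicate tube).
#' @param w_lab_reps labeled per-tube density centroids.
#' @param n_boot number of bootstrap draws (default 1000); must be >= 1.
#' @param ci_level confidence level for the percentile interval
#'   (default 0.90).
#' @param seed optional integer seed; fixed seed gives identical intervals.
#' @return list `median_ape`, `ci_low`, `ci_high`, `n_boot`.
#' @export
bootstrap_ape <- function(w_light_reps, w_lab_reps, n_boot = 1000L,
                          ci_level = 0.90, seed = NULL) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
  w_light_reps <- w_light_reps[is.finite(w_light_reps)]
  w_lab_reps <- w_lab_reps[is.finite(w_lab_reps)]
  if (length(w_light_reps) == 0L || length(w_lab_reps) == 0L)
    stop("need at least one finite centroid per treatment")
  draw <- function() {
    wl <- mean(sample(w_light_reps, length(w_light_reps), replace = TRUE))
    wh <- mean(sample(w_lab_reps, length(w_lab_reps), replace = TRUE))
    ape_from_densities(wl, wh)
  }
  apes <- if (is.null(seed)) replicate(n_boot, draw())
          else with_seed(seed, replicate(n_boot, draw()))
  qs <- stats::quantile(apes, c((1 - ci_level) / 2, 0.5,
                                1 - (1 - ci_level) / 2), names = FALSE)
  list(median_ape = qs[2L], ci_low = qs[1L], ci_high = qs[3L],
       n_boot = as.integer(n_boot))
}

#' Per-genome APE estimates from density-fraction tables
#'
#' The full qSIP stage: joins the long per-genome fraction abundance table
#' with fraction metadata, applies the triplicate detection rule (a genome
#' must be present, per [presence_calls()] SIP semantics, in all replicate
#' tubes of both the labeled and unlabeled treatment at a time point),
#' computes per-tube density centroids, and bootstraps an APE estimate per
#' genome and time. Estimates whose confidence interval drops below zero are
#' marked `passes_ci = FALSE`; downstream summaries exclude them.
#'
#' Excluding a genome that fails the triplicate rule never alters the
#' estimates of other genomes (estimates are computed independently).
#'
#' @param fraction_abund long table: `genome_id`, `plot`, `treatment`
#'   (`"16O"`/`"18O"`), `time_h`, `fraction_index`, `rel_abund`, `breadth`.
#' @param fraction_meta fraction metadata: `plot`, `treatment`, `time_h`,
#'   `fraction_index`, `density_gml`, `dna_ng`.
#' @param breadth_cutoff SIP detection breadth (default 0.50).
#' @param min_replicates tubes required per treatment (default 3).
#' @param n_boot,ci_level see [bootstrap_ape()].
#' @param seed integer seed; per-genome draws use derived substreams.
#' @return data.table `genome_id`, `time_h`, `median_ape`, `ci_low`,
#'   `ci_high`, `n_boot`, `passes_ci`.
#' @export
qsip_ape <- function(fraction_abund, fraction_meta, breadth_cutoff = 0.50,
                     min_replicates = 3L, n_boot = 1000L, ci_level = 0.90,
                     seed = 1L) {
  need_cols(fraction_abund, c("genome_id", "plot", "treatment", "time_h",
                              "fraction_index", "rel_abund", "breadth"),
            "fraction_abund")
  need_cols(fraction_meta, c("plot", "treatment", "time_h",
                             "fraction_index", "density_gml", "dna_ng"),
            "fraction_meta")
  fa <- data.table::as.data.table(fraction_abund)
  fm <- data.table::as.data.table(fraction_meta)
  if (any(fm$dna_ng < 0)) stop("dna_ng must be >= 0")
  # triplicate detection in both treatments
  det <- fa[, .(detected = max(breadth) >= breadth_cutoff),
            by = .(genome_id, treatment, time_h, plot)]
  by_tr <- det[, .(present = sum(detected) >= min_replicates),
               by = .(genome_id, treatment, time_h)]
  ok <- by_tr[, .(pass = all(present) && data.table::uniqueN(treatment) == 2L),
              by = .(genome_id, time_h)][pass == TRUE]
  if (nrow(ok) == 0L)
    return(data.table::data.table(genome_id = character(0),
                                  time_h = numeric(0),
                                  median_ape = numeric(0),
                                  ci_low = numeric(0), ci_high = numeric(0),
                                  n_boot = integer(0),
                                  passes_ci = logical(0)))
  dt <- merge(fa, fm, by = c("plot", "treatment", "time_h",
                             "fraction_index"))
  dt <- dt[ok[, .(genome_id, time_h)], on = c("genome_id", "time_h")]
  tubes <- dt[, .(w = weighted_mean_density(density_gml, rel_abund,
                                            dna_ng)),
              by = .(genome_id, time_h, treatment, plot)]
  est <- tubes[, {
    wl <- w[treatment == "16O"]
    wh <- w[treatment == "18O"]
    b <- bootstrap_ape(wl, wh, n_boot = n_boot, ci_level = ci_level,
                       seed = substream_seed(seed,
                                             paste0(genome_id[1L], "@",
                                                    time_h[1L])))
    .(median_ape = b$median_ape, ci_low = b$ci_low, ci_high = b$ci_high,
      n_boot = b$n_boot)
  }, by = .(genome_id, time_h)]
  # strictly-negative lower CI fails; tolerance guards the exactly-zero
  # (unenriched, noise-free) case against floating-point jitter
  est[, passes_ci := ci_low >= -1e-9]
  data.table::setorder(est, genome_id, time_h)
  est[]
}

#' Lineage-level enrichment summary
#'
#' Summarizes confidence-passing APE estimates per lineage, genome type
#' (e.g. MAG vs vOTU) and time: mean APE with standard error, the number of
#' enriched genomes, and how many are newly enriched (first time point at
#' which the genome passes). Lineage x type x time combinations with no
#' passing estimate are omitted (with a message when estimates were dropped
#' by the CI filter).
#'
#' @param estimates output of [qsip_ape()].
#' @param genome_info data.frame with `genome_id`, `type` and `lineage`.
#' @return list: `ape` (lineage, type, time_h, mean_ape, sem_ape, n),
#'   `counts` (lineage, type, time_h, n_total, n_new).
#' @export
enrichment_summary <- function(estimates, genome_info) {
  need_cols(estimates, c("genome_id", "time_h", "median_ape", "ci_low",
                         "passes_ci"), "estimates")
  need_cols(genome_info, c("genome_id", "type", "lineage"), "genome_info")
  est <- data.table::as.data.table(estimates)
  dropped <- sum(!est$passes_ci)
  if (dropped > 0L)
    message(dropped, " estimate(s) removed by the CI-below-zero filter")
  est <- est[passes_ci == TRUE]
  gi <- data.table::as.data.table(genome_info)[, .(genome_id, type, lineage)]
  dt <- merge(est, gi, by = "genome_id")
  ape <- dt[, .(mean_ape = mean(median_ape), sem_ape = sem(median_ape),
                n = .N), by = .(lineage, type, time_h)]
  dt[, first_time := min(time_h), by = genome_id]
  counts <- dt[, .(n_total = .N, n_new = sum(time_h == first_time)),
               by = .(lineage, type, time_h)]
  data.table::setorder(ape, lineage, type, time_h)
  data.table::setorder(counts, lineage, type, time_h)
  list(ape = ape[], counts = counts[])
}

#' Fraction of one genome set detected in another assay
#'
#' Convenience overlap summary, e.g. the share of isotopically enriched
#' vOTUs that were also detected as virions in viromes.
#'
#' @param ids character vector (e.g. enriched vOTU ids).
#' @param detected_ids character vector of ids detected in the other assay.
#' @return fraction of `ids` found in `detected_ids`.
#' @export
detection_overlap <- function(ids, detected_ids) {
  ids <- unique(ids)
  if (length(ids) == 0L) return(0)
  length(intersect(ids, unique(detected_ids))) / length(ids)
}
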