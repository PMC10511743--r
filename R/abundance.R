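# Presence calling, relative abundance, richness/biomass trajectories,
# ordination, and flag-level aggregation.

# A sample is one sequencing library: plot x time x assay (x treatment x
# fraction for SIP libraries). Used as matrix column keys.
sample_key <- function(records) {
  tr <- if ("treatment" %in% names(records)) records$treatment else "none"
  fr <- if ("fraction_index" %in% names(records)) records$fraction_index
        else NA
  tr[is.na(tr)] <- "none"
  key <- paste(records$plot, records$time_h, records$assay, tr, sep = "|")
  ifelse(is.na(fr), key, paste(key, fr, sep = "|"))
}

#' Relative abundance matrix from mapping records
#'
#' Relative abundance is mapped reads divided by total reads in the sample.
#' Genome x sample pairs with no record are 0. Column sums are at most 1; the
#' remainder is unmapped reads.
#'
#' @param records data.frame of mapping records with columns `genome_id`,
#'   `plot`, `time_h`, `assay`, `mapped_reads`, `sample_total_reads`
#'   (optionally `treatment`, `fraction_index`).
#' @return numeric matrix (genomes x samples) with a `samples` attribute
#'   holding per-column metadata.
#' @export
relative_abundance <- function(records) {
  need_cols(records, c("genome_id", "plot", "time_h", "assay",
                       "mapped_reads", "sample_total_reads"), "records")
  rec <- data.table::as.data.table(records)
  rec[, sample_id := sample_key(rec)]
  bad <- rec[sample_total_reads <= 0, unique(sample_id)]
  if (length(bad))
    stop("zero total reads in sample(s): ", paste(bad, collapse = ", "))
  if (any(rec$mapped_reads > rec$sample_total_reads))
    stop("mapped_reads exceeds sample_total_reads")
  rec[, rel := mapped_reads / sample_total_reads]
  if (nrow(rec) == 0L)
    return(structure(matrix(numeric(0), 0, 0), samples = rec[0L]))
  wide <- data.table::dcast(rec, genome_id ~ sample_id, value.var = "rel",
                            fun.aggregate = sum, fill = 0)
  mat <- as.matrix(wide[, -1L])
  rownames(mat) <- wide$genome_id
  meta <- unique(rec[, .(sample_id, plot, time_h, assay)])
  data.table::setkey(meta, sample_id)
  structure(mat, samples = meta[colnames(mat)])
}

#' Breadth-based presence calls
#'
#' Presence is decided from breadth of coverage (covered bases / genome
#' length):
#' * `virome` / `metagenome`: present in a plot x time sample when breadth is
#'   at least `breadth_cutoff` (default 0.80) in that sample.
#' * `sip_fraction`: a genome is detected in one replicate tube (plot x
#'   treatment x time) when its best per-fraction breadth reaches
#'   `breadth_cutoff` (default 0.50); it is called present for a treatment x
#'   time only when detected in at least `min_replicates` (default 3, i.e.
#'   all triplicate) tubes.
#'
#' Lowering the cutoff never removes a presence (monotonicity).
#'
#' @param records mapping records (see [relative_abundance()]) with
#'   `covered_bases` and `genome_length`.
#' @param assay one of `"virome"`, `"metagenome"`, `"sip_fraction"`.
#' @param breadth_cutoff breadth threshold in (0, 1]; assay-specific default.
#' @param min_replicates triplicate requirement for SIP presence.
#' @return data.table: `genome_id`, `plot`, `time_h`, `present` for
#'   virome/metagenome; `genome_id`, `treatment`, `time_h`, `n_detected`,
#'   `present` for SIP fractions.
#' @export
presence_calls <- function(records,
                           assay = c("virome", "metagenome", "sip_fraction"),
                           breadth_cutoff = NULL, min_replicates = 3L) {
  assay <- match.arg(assay)
  breadth_cutoff <- breadth_cutoff %||%
    switch(assay, virome = 0.80, metagenome = 0.80, sip_fraction = 0.50)
  if (breadth_cutoff <= 0 || breadth_cutoff > 1)
    stop("breadth_cutoff must be in (0, 1]")
  need_cols(records, c("genome_id", "plot", "time_h", "assay",
                       "covered_bases", "genome_length"), "records")
  rec <- data.table::as.data.table(records)[assay, on = "assay"]
  rec <- rec[!is.na(genome_id)]
  if (any(rec$covered_bases > rec$genome_length))
    stop("covered_bases exceeds genome_length")
  rec[, breadth := covered_bases / genome_length]
  if (assay %in% c("virome", "metagenome")) {
    out <- rec[, .(present = any(breadth >= breadth_cutoff)),
               by = .(genome_id, plot, time_h)]
  } else {
    det <- rec[, .(detected = max(breadth) >= breadth_cutoff),
               by = .(genome_id, treatment, time_h, plot)]
    out <- det[, .(n_detected = sum(detected),
                   present = sum(detected) >= min_replicates),
               by = .(genome_id, treatment, time_h)]
  }
  data.table::setorderv(out, intersect(c("genome_id", "plot", "treatment",
                                         "time_h"), names(out)))
  out[]
}

#' Richness trajectory and trend
#'
#' Counts unique genomes called present per plot and time, averages across
#' plots (standard error uses the number of plots), and fits an OLS trend of
#' the per-plot (per-microcosm) counts against time.
#'
#' @param presence presence table from [presence_calls()] (virome flavor).
#' @return list: `per_plot` (plot, time_h, richness), `series` (time_h, mean
#'   richness, sem), `trend` ([ols_trend()] output; `defined = FALSE` with a
#'   single time point).
#' @export
richness_series <- function(presence) {
  need_cols(presence, c("genome_id", "plot", "time_h", "present"),
            "presence")
  pres <- data.table::as.data.table(presence)
  per_plot <- pres[, .(richness = sum(present)), by = .(plot, time_h)]
  data.table::setorder(per_plot, plot, time_h)
  series <- per_plot[, .(mean_richness = mean(richness),
                         sem = sem(richness)), by = time_h]
  data.table::setorder(series, time_h)
  trend <- ols_trend(per_plot$time_h, as.numeric(per_plot$richness))
  list(per_plot = per_plot[], series = series[], trend = trend)
}

#' Viral biomass trajectory and trend
#'
#' Viral biomass per gram soil is approximated as total extracted DNA yield
#' times the fraction of reads mapping to the vOTU set. The trend regression
#' uses per-microcosm points (plots x times).
#'
#' @param dna_yields data.frame with `plot`, `time_h`, `dna_ng_per_g`.
#' @param viral_read_fraction scalar in \[0, 1\], or data.frame with `plot`,
#'   `time_h`, `viral_read_fraction`.
#' @return list: `per_plot` (plot, time_h, biomass ng/g), `series`,
#'   `trend`, and `fold_change` (mean biomass at last time / first time;
#'   `NA` when the first-time mean is 0).
#' @export
biomass_series <- function(dna_yields, viral_read_fraction) {
  need_cols(dna_yields, c("plot", "time_h", "dna_ng_per_g"), "dna_yields")
  if (any(dna_yields$dna_ng_per_g < 0)) stop("DNA yields must be >= 0")
  yl <- data.table::as.data.table(dna_yields)
  if (is.data.frame(viral_read_fraction)) {
    need_cols(viral_read_fraction, c("plot", "time_h",
                                     "viral_read_fraction"),
              "viral_read_fraction")
    yl <- merge(yl, data.table::as.data.table(viral_read_fraction),
                by = c("plot", "time_h"))
  } else {
    if (any(viral_read_fraction < 0 | viral_read_fraction > 1))
      stop("viral_read_fraction must be in [0, 1]")
    vrf_scalar <- viral_read_fraction
    yl[, viral_read_fraction := vrf_scalar]
  }
  yl[, biomass := dna_ng_per_g * viral_read_fraction]
  per_plot <- yl[, .(plot, time_h, biomass)]
  data.table::setorder(per_plot, plot, time_h)
  series <- per_plot[, .(mean_biomass = mean(biomass), sem = sem(biomass)),
                     by = time_h]
  data.table::setorder(series, time_h)
  first <- series$mean_biomass[1L]
  fold <- if (isTRUE(first > 0))
    series$mean_biomass[nrow(series)] / first else NA_real_
  list(per_plot = per_plot[], series = series[],
       trend = ols_trend(per_plot$time_h, per_plot$biomass),
       fold_change = fold)
}

#' Bray-Curtis dissimilarity and principal coordinates analysis
#'
#' Computes pairwise Bray-Curtis dissimilarity between sample columns and a
#' classical PCoA (eigendecomposition of the double-centered squared
#' dissimilarities). Negative eigenvalues are reported, not dropped;
#' variance-explained fractions are taken over the positive eigenvalues only.
#'
#' All-zero samples have no defined Bray-Curtis distance; they are assigned
#' dissimilarity 1 against non-zero samples (0 against other all-zero
#' samples) and flagged.
#'
#' @param mat genomes x samples abundance matrix with at least 2 columns.
#' @return list: `dissimilarity` (symmetric matrix, zero diagonal),
#'   `points` (samples x axes), `eigenvalues`, `variance_explained`
#'   (per returned axis, over positive eigenvalues), `flagged_samples`.
#' @export
bray_curtis_pcoa <- function(mat) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  n <- ncol(mat)
  if (n < 2L) stop("need at least 2 samples")
  zero <- colSums(mat) == 0
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  nz <- which(!zero)
  if (length(nz) >= 2L) {
    d[nz, nz] <- as.matrix(vegan::vegdist(t(mat[, nz, drop = FALSE]),
                                          method = "bray"))
  }
  if (any(zero)) {
    d[zero, !zero] <- 1
    d[!zero, zero] <- 1
    warning("all-zero sample(s) flagged: ",
            paste(colnames(mat)[zero], collapse = ", "))
  }
  k <- n - 1L
  pc <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k,
                                         eig = TRUE))
  eig <- pc$eig
  pos <- sum(eig[eig > 0])
  ve <- if (pos > 0) ifelse(eig > 0, eig / pos, 0) else rep(NA_real_, n)
  naxes <- ncol(pc$points)
  list(dissimilarity = d,
       points = pc$points,
       eigenvalues = eig,
       variance_explained = ve[seq_len(naxes)],
       flagged_samples = colnames(mat)[zero])
}

#' Aggregate abundances and richness by a genome-level flag
#'
#' Sums per-sample relative abundance and counts genomes with non-zero
#' abundance within each flag class (e.g. integrase-encoding or not,
#' prophage-containing MAG or not). Class sums conserve column totals.
#'
#' @param mat genomes x samples abundance matrix.
#' @param flags vector of flag values named by genome id, covering all rows
#'   of `mat`.
#' @return list: `abundance` (flag x sample summed relative abundance),
#'   `richness` (flag x sample counts of genomes with abundance > 0).
#' @export
aggregate_by_flag <- function(mat, flags) {
  if (!is.matrix(mat)) mat <- as.matrix(mat)
  miss <- setdiff(rownames(mat), names(flags))
  if (length(miss))
    stop("flags missing for genome(s): ", paste(miss, collapse = ", "))
  f <- as.character(flags[rownames(mat)])
  ab <- rowsum(mat, f)
  rich <- rowsum((mat > 0) + 0, f)
  list(abundance = ab, richness = rich)
}

#' Fraction of genomes present in every plot and time point
#'
#' Share of genomes (among those with at least one presence) that are called
#' present in every plot x time combination covered by the table.
#'
#' @param presence presence table from [presence_calls()] (virome flavor).
#' @return fraction in \[0, 1\].
#' @export
ubiquitous_fraction <- function(presence) {
  need_cols(presence, c("genome_id", "plot", "time_h", "present"),
            "presence")
  pres <- data.table::as.data.table(presence)
  ncells <- nrow(unique(pres[, .(plot, time_h)]))
  per <- pres[, .(n_present = sum(present)), by = genome_id]
  eligible <- per[n_present > 0L]
  if (nrow(eligible) == 0L) return(0)
  mean(eligible$n_present == ncells)
}
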