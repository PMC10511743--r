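# Lysogeny evidence: cross-mapping candidates, alignment-based lysogen
# filter, prophage-activity coverage ratio, integrase enrichment test.

#' Candidate prophage-bearing contigs from cross-mapping
#'
#' Metagenome contigs where virome reads cover at least `min_covered` bases
#' but not the full contig (breadth < 1) suggest a viral genome embedded in
#' bacterial sequence rather than a free virion.
#'
#' @param coverages data.frame with `contig_id`, `contig_len`,
#'   `covered_bases` (a `breadth` column is used if present, otherwise
#'   computed as covered_bases / contig_len).
#' @param min_covered minimum covered bases (default 1000).
#' @return character vector of candidate contig ids.
#' @export
candidate_prophage_contigs <- function(coverages, min_covered = 1000L) {
  need_cols(coverages, c("contig_id", "contig_len", "covered_bases"),
            "coverages")
  if (any(coverages$covered_bases > coverages$contig_len))
    stop("covered_bases exceeds contig_len")
  br <- if ("breadth" %in% names(coverages)) coverages$breadth
        else coverages$covered_bases / coverages$contig_len
  keep <- coverages$covered_bases >= min_covered & br < 1
  as.character(coverages$contig_id[keep])
}

#' Alignment filter for lysogen candidates
#'
#' A vOTU aligned to a metagenome contig is a lysogen candidate when the
#' alignment is long and near-identical and the contig carries substantial
#' non-viral flanking sequence: identity > `min_identity` percent, e-value
#' <= `max_evalue`, total flanking region > `min_flank` bp and aligned
#' section >= `min_align` bp. Relaxing any threshold can only grow the
#' accepted set, and the filter is idempotent.
#'
#' @param alignments data.frame with `pct_identity`, `evalue`, `flank_len`
#'   (contig length outside the aligned span, total across both sides) and
#'   `align_len`.
#' @param min_identity percent identity threshold (default 90, exclusive).
#' @param max_evalue e-value ceiling (default 1e-100).
#' @param min_flank flanking-length threshold in bp (default 10000,
#'   exclusive).
#' @param min_align alignment-length threshold in bp (default 10000,
#'   inclusive).
#' @return the accepted subset of `alignments`.
#' @export
lysogen_alignment_filter <- function(alignments, min_identity = 90,
                                     max_evalue = 1e-100,
                                     min_flank = 10000L,
                                     min_align = 10000L) {
  need_cols(alignments, c("pct_identity", "evalue", "flank_len",
                          "align_len"), "alignments")
  if (any(alignments$flank_len < 0)) stop("flank_len must be >= 0")
  keep <- alignments$pct_identity > min_identity &
    alignments$evalue <= max_evalue &
    alignments$flank_len > min_flank &
    alignments$align_len >= min_align
  alignments[keep, , drop = FALSE]
}

#' Prophage activity from differential coverage
#'
#' A prophage is scored active when it is replicating faster than its host
#' chromosome, i.e. the ratio of mean read coverage inside the prophage
#' coordinates to the mean coverage of the flanking host region reaches
#' `ratio_threshold` (default 1.65, the convention of coverage-ratio
#' prophage-activity tools). A zero flanking coverage makes the ratio
#' undefined (`NA`, flagged).
#'
#' @param prophage data.frame with `mag_id`, `prophage_cov` and `flank_cov`
#'   (mean coverages; coordinates are 0-based half-open upstream of this
#'   call and do not enter the ratio).
#' @param ratio_threshold activity threshold on the coverage ratio.
#' @return data.table `mag_id`, `ratio`, `active` (NA where undefined).
#' @export
prophage_activity <- function(prophage, ratio_threshold = 1.65) {
  need_cols(prophage, c("mag_id", "prophage_cov", "flank_cov"), "prophage")
  if (any(prophage$prophage_cov < 0) || any(prophage$flank_cov < 0))
    stop("coverages must be >= 0")
  dt <- data.table::as.data.table(prophage)
  dt[, ratio := ifelse(flank_cov > 0, prophage_cov / flank_cov, NA_real_)]
  if (any(is.na(dt$ratio)))
    warning("zero flanking coverage: activity undefined for some prophages")
  dt[, active := ratio >= ratio_threshold]
  dt[, .(mag_id, ratio, active)][]
}

#' Chi-square test for integrase enrichment
#'
#' Pearson chi-square (df = 1, no continuity correction) on a 2x2 table of
#' integrase-encoding vs not, crossed with detection in dry soil vs first
#' detection after wet-up. Tests whether vOTUs appearing only after wet-up
#' are enriched in integrase genes, as expected under mass prophage
#' induction.
#'
#' @param counts 2x2 numeric matrix of non-negative counts with positive row
#'   and column sums.
#' @return list `statistic`, `p_value`, `df`, `expected`.
#' @export
#' @examples
#' integrase_enrichment_test(matrix(c(20, 10, 10, 20), 2))
integrase_enrichment_test <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("degenerate margins: a row or column sums to zero")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter), expected = ht$expected)
}
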