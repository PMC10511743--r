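# Tab-separated I/O for the pipeline's table schemas. All readers validate
# required columns; all writers emit plain TSV so datasets are diffable.

#' Read a genome catalog TSV
#'
#' Columns: `id`, `length_bp`, `circular` (0/1), `tools` (comma list),
#' `integrase` (0/1), `source`, `host_lineage`.
#'
#' @param path file path.
#' @return data.table with `circular`/`integrase` as logical.
#' @export
read_catalog <- function(path) {
  dt <- data.table::fread(path, sep = "\t", colClasses =
                            list(character = "id"))
  need_cols(dt, c("id", "length_bp", "circular", "tools", "integrase"),
            "catalog file")
  dt[, circular := as.logical(circular)]
  dt[, integrase := as.logical(integrase)]
  dt[]
}

#' Read a mapping-record TSV
#'
#' Columns: `genome_id`, `plot`, `time_h`, `assay`, `treatment`,
#' `fraction_index`, `mapped_reads`, `covered_bases`, `genome_length`,
#' `sample_total_reads`.
#'
#' @param path file path.
#' @return data.table of mapping records.
#' @export
read_mapping <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need_cols(dt, c("genome_id", "plot", "time_h", "assay", "mapped_reads",
                  "covered_bases", "genome_length", "sample_total_reads"),
            "mapping file")
  dt[]
}

#' Read density-fraction metadata TSV
#'
#' Columns: `plot`, `treatment`, `time_h`, `fraction_index`, `density_gml`,
#' `dna_ng`.
#'
#' @param path file path.
#' @return data.table of fraction records.
#' @export
read_fractions <- function(path) {
  dt <- data.table::fread(path, sep = "\t")
  need_cols(dt, c("plot", "treatment", "time_h", "fraction_index",
                  "density_gml", "dna_ng"), "fraction file")
  dt[]
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' One file per table (`votu_catalog.tsv`, `virome_mapping.tsv`, ...), plus
#' the truth ledger under `truth_*.tsv`. Byte-stable for a fixed config.
#'
#' @param dataset a `"wetup_dataset"`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tabs <- list(
    votu_catalog = dataset$votu_catalog,
    mag_catalog = dataset$mag_catalog,
    ani_pairs = dataset$ani_pairs,
    virome_mapping = dataset$virome_mapping,
    metagenome_mapping = dataset$metagenome_mapping,
    dna_yields = dataset$dna_yields,
    loss_rates = dataset$loss_rates,
    sip_fraction_meta = dataset$sip_fraction_meta,
    sip_fraction_abund = dataset$sip_fraction_abund,
    spacer_hits = dataset$spacer_hits,
    host_predictions = dataset$host_predictions,
    lysogen_alignments = dataset$lysogen_alignments,
    contig_coverage = dataset$contig_coverage,
    prophage_coverage = dataset$prophage_coverage,
    truth_categories = dataset$truth$categories,
    truth_presence = dataset$truth$presence,
    truth_ape = dataset$truth$ape,
    truth_hosts = dataset$truth$hosts)
  paths <- character(0)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    data.table::fwrite(tabs[[nm]], p, sep = "\t")
    paths <- c(paths, p)
  }
  invisible(paths)
}
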