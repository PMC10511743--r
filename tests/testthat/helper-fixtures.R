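# Small fixtures built in code.

tiny_catalog <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    length_bp = c(12000, 50000, 5000, 9000),
    circular = c(FALSE, FALSE, TRUE, FALSE),
    tools = c("vs1,vibrant", "dvf", "vs2,seeker", "vs1,vibrant,seeker"),
    integrase = c(TRUE, FALSE, FALSE, TRUE),
    source = "virome",
    stringsAsFactors = FALSE)
}

# one virome mapping record
vrec <- function(genome_id, plot, time_h, breadth, reads = 100,
                 len = 10000, total = 1000, assay = "virome",
                 treatment = "none", fraction_index = NA_integer_) {
  data.frame(genome_id = genome_id, plot = plot, time_h = time_h,
             assay = assay, treatment = treatment,
             fraction_index = fraction_index, mapped_reads = reads,
             covered_bases = round(breadth * len), genome_length = len,
             sample_total_reads = total, stringsAsFactors = FALSE)
}

small_config <- function(...) {
  scenario_config(seed = 11, n_votus = 60, n_mags = 10, ...)
}
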