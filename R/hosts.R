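# CRISPR-spacer host filtering and consensus (lowest-common-ancestor)
# host taxonomy.

LINEAGE_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
                   "species")

#' Parse a semicolon-delimited lineage string
#'
#' Lineages are ordered domain-to-species with up to 7 ranks. Trailing empty
#' ranks are allowed (a lineage resolved only to phylum has 2 ranks); an
#' empty rank above a named one is a gap and raises an error. The sentinel
#' `"unknown"` (or an empty/NA string) parses to a zero-length lineage.
#'
#' @param x a single lineage string, e.g. `"Bacteria;Actinobacteria"`.
#' @return character vector of named ranks (possibly length 0).
#' @export
parse_lineage <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return(character(0))
  x <- trimws(x)
  if (!nzchar(x) || identical(tolower(x), "unknown")) return(character(0))
  ranks <- trimws(strsplit(x, ";", fixed = TRUE)[[1L]])
  if (length(ranks) > length(LINEAGE_RANKS))
    stop("lineage has more than ", length(LINEAGE_RANKS), " ranks: ", x)
  named <- nzchar(ranks)
  last <- if (any(named)) max(which(named)) else 0L
  if (last > 0L && !all(named[seq_len(last)]))
    stop("lineage has a gap rank: ", x)
  ranks[seq_len(last)]
}

# inverse of parse_lineage; zero-length -> "unknown"
lineage_string <- function(ranks) {
  if (length(ranks) == 0L) "unknown" else paste(ranks, collapse = ";")
}

#' Filter CRISPR spacer-protospacer hits
#'
#' A spacer hit links a vOTU to a host only when the full spacer aligns with
#' no more than one mismatch and no gaps: `mismatches <= max_mismatches`,
#' `gaps == 0`, and `align_len == spacer_len`.
#'
#' @param hits data.frame with columns `mismatches`, `gaps`, `align_len`,
#'   `spacer_len` (plus any id/lineage columns, passed through).
#' @param max_mismatches default 1.
#' @return the accepted subset of `hits`.
#' @export
filter_spacer_hits <- function(hits, max_mismatches = 1L) {
  need_cols(hits, c("mismatches", "gaps", "align_len", "spacer_len"),
            "hits")
  if (any(hits$align_len > hits$spacer_len))
    stop("align_len exceeds spacer_len")
  keep <- hits$mismatches <= max_mismatches & hits$gaps == 0 &
    hits$align_len == hits$spacer_len
  hits[keep, , drop = FALSE]
}

#' Consensus host lineage across prediction sources
#'
#' A single prediction is retained unchanged. Multiple predictions are
#' resolved to the deepest rank at which all agree (greatest common prefix),
#' truncated there; disagreement already at the domain rank yields
#' `"unknown"`. Predictions that are themselves `"unknown"` carry no
#' information and are ignored; if nothing remains the consensus is
#' `"unknown"`. The result is order-invariant and is a prefix of every
#' informative input lineage.
#'
#' @param lineages character vector of semicolon-delimited lineage strings
#'   (one per prediction source). Must be non-empty.
#' @return consensus lineage string (possibly `"unknown"`).
#' @export
#' @examples
#' consensus_host(c("Bacteria;Actinobacteria;Mycobacteriales",
#'                  "Bacteria;Actinobacteria;Streptomycetales"))
consensus_host <- function(lineages) {
  if (length(lineages) == 0L) stop("no host predictions supplied")
  parsed <- lapply(lineages, parse_lineage)
  parsed <- parsed[vapply(parsed, length, integer(1)) > 0L]
  if (length(parsed) == 0L) return("unknown")
  if (length(parsed) == 1L) return(lineage_string(parsed[[1L]]))
  depth <- min(vapply(parsed, length, integer(1)))
  agree <- 0L
  for (d in seq_len(depth)) {
    names_d <- vapply(parsed, `[`, character(1), d)
    if (length(unique(names_d)) == 1L) agree <- d else break
  }
  if (agree == 0L) return("unknown")
  lineage_string(parsed[[1L]][seq_len(agree)])
}

#' Host-assignment coverage summary
#'
#' Fractions of vOTUs carrying a non-"unknown" host lineage resolved at
#' least to the domain rank and at least to the phylum rank. The phylum
#' fraction can never exceed the domain fraction.
#'
#' @param assignments data.frame with `votu_id` and `host_lineage`.
#' @param n_total denominator; defaults to the number of rows (pass the full
#'   catalog size when `assignments` omits unassigned vOTUs).
#' @return list with `domain`, `phylum` (fractions) and `n_total`.
#' @export
host_assignment_summary <- function(assignments, n_total = NULL) {
  need_cols(assignments, c("votu_id", "host_lineage"), "assignments")
  n_total <- n_total %||% nrow(assignments)
  if (n_total < nrow(assignments))
    stop("n_total smaller than the number of assignments")
  depths <- vapply(assignments$host_lineage,
                   function(l) length(parse_lineage(l)), integer(1))
  list(domain = if (n_total > 0) sum(depths >= 1L) / n_total else 0,
       phylum = if (n_total > 0) sum(depths >= 2L) / n_total else 0,
       n_total = n_total)
}
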