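# vOTU catalog construction: consensus prediction filter, dereplication,
# integrase/circularity partitioning.

#' Consensus viral-prediction and size/circularity filter
#'
#' A contig is retained as a vOTU candidate when it was called viral by at
#' least `min_tools` independent predictors AND is either predicted to be a
#' circularized contig (implying a complete genome) or at least `min_length`
#' bp long. Single-tool predictions are discarded regardless of length.
#'
#' @param catalog data.frame with columns `id`, `length_bp`, `circular`
#'   (logical or 0/1) and `tools` (comma-separated predictor names, or a list
#'   column of character vectors).
#' @param min_tools minimum number of distinct predictors (default 2).
#' @param min_length minimum length in bp for linear contigs (default 10000).
#' @return character vector of retained ids.
#' @export
#' @examples
#' cat <- data.frame(id = c("a", "b"), length_bp = c(12000, 50000),
#'                   circular = FALSE, tools = c("vs1,vibrant", "dvf"))
#' consensus_viral_filter(cat)  # "a"
consensus_viral_filter <- function(catalog, min_tools = 2L,
                                   min_length = 10000L) {
  need_cols(catalog, c("id", "length_bp", "circular", "tools"), "catalog")
  if (nrow(catalog) == 0L) return(character(0))
  if (any(catalog$length_bp <= 0)) stop("catalog lengths must be positive")
  ntools <- if (is.list(catalog$tools)) {
    vapply(catalog$tools, function(t) length(unique(t[nzchar(t)])), integer(1))
  } else {
    vapply(strsplit(as.character(catalog$tools), ",", fixed = TRUE),
           function(t) length(unique(trimws(t[nzchar(trimws(t))]))),
           integer(1))
  }
  keep <- ntools >= min_tools &
    (as.logical(catalog$circular) | catalog$length_bp >= min_length)
  as.character(catalog$id[keep])
}

#' Dereplicate sequences by ANI and alignment breadth
#'
#' Single-linkage clustering over pairs with `ani >= ani_min` and
#' `breadth >= breadth_min` (breadth = aligned fraction of the shorter
#' sequence). Every id in `lengths` becomes a vertex, so sequences with no
#' qualifying pair form singleton clusters. The cluster representative is the
#' longest member; length ties break to the lexicographically smallest id.
#'
#' @param pairs data.frame with columns `id_a`, `id_b`, `ani`, `breadth`
#'   (fractions in \[0, 1\]); treated as undirected. May have zero rows.
#' @param lengths named numeric vector of sequence lengths (bp), or a
#'   data.frame with columns `id` and `length_bp`.
#' @param ani_min,breadth_min clustering thresholds (defaults 0.95, 0.85).
#' @return data.table with columns `id`, `cluster` (integer label), `rep_id`
#'   (cluster representative) and `representative` (logical).
#' @export
dereplicate_votus <- function(pairs, lengths, ani_min = 0.95,
                              breadth_min = 0.85) {
  if (is.data.frame(lengths)) {
    need_cols(lengths, c("id", "length_bp"), "lengths")
    lengths <- setNames(as.numeric(lengths$length_bp),
                        as.character(lengths$id))
  }
  ids <- names(lengths)
  if (is.null(ids) || anyDuplicated(ids))
    stop("lengths must be uniquely named by sequence id")
  if (nrow(pairs) > 0L) {
    need_cols(pairs, c("id_a", "id_b", "ani", "breadth"), "pairs")
    unknown <- setdiff(unique(c(pairs$id_a, pairs$id_b)), ids)
    if (length(unknown))
      stop("unknown id(s) in pairs: ", paste(unknown, collapse = ", "))
    edges <- pairs[pairs$ani >= ani_min & pairs$breadth >= breadth_min &
                     pairs$id_a != pairs$id_b, c("id_a", "id_b"),
                   drop = FALSE]
  } else {
    edges <- data.frame(id_a = character(0), id_b = character(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  memb <- igraph::components(g)$membership[ids]
  out <- data.table::data.table(id = ids, cluster = as.integer(memb),
                                length_bp = unname(lengths))
  # longest member represents the cluster; ties -> lexicographic id
  data.table::setorder(out, cluster, -length_bp, id)
  out[, rep_id := id[1L], by = cluster]
  out[, representative := id == rep_id]
  out[, length_bp := NULL]
  data.table::setorder(out, id)
  out[]
}

#' Partition a catalog by integrase presence and circularity
#'
#' Cross-tabulates catalog entries by whether they encode an integrase gene
#' (putative temperate lifestyle) and whether the contig circularizes
#' (implying genome completeness). Cell counts always sum to the input count.
#'
#' @param catalog data.frame with logical (or 0/1) columns `integrase` and
#'   `circular`.
#' @return data.table with columns `integrase`, `circular`, `n` and
#'   `fraction` (of all entries); attribute `integrase_fraction` carries the
#'   overall integrase-positive share.
#' @export
partition_by_integrase <- function(catalog) {
  need_cols(catalog, c("integrase", "circular"), "catalog")
  dt <- data.table::data.table(integrase = as.logical(catalog$integrase),
                               circular = as.logical(catalog$circular))
  cells <- data.table::CJ(integrase = c(FALSE, TRUE),
                          circular = c(FALSE, TRUE))
  counts <- dt[, .(n = .N), by = .(integrase, circular)]
  out <- counts[cells, on = c("integrase", "circular")]
  out[is.na(n), n := 0L]
  out[, fraction := if (nrow(dt) > 0L) n / nrow(dt) else 0]
  data.table::setattr(out, "integrase_fraction",
                      if (nrow(dt) > 0L) mean(dt$integrase) else NA_real_)
  out[]
}
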