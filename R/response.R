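# Temporal response categories for persistent vOTUs.

RESPONSE_CATEGORIES <- c("ubiquitous", "early", "late", "zero_and_168",
                         "other")

#' Persistent vOTU filter
#'
#' A vOTU is persistent within a field plot when it is present at
#' `min_times` (default 3) or more time points there. Persistence is the
#' admission rule for response-category classification.
#'
#' @param presence presence table (`genome_id`, `plot`, `time_h`, `present`).
#' @param min_times minimum number of presence time points.
#' @return data.table `genome_id`, `plot`, `n_times` for persistent pairs.
#' @export
persistent_filter <- function(presence, min_times = 3L) {
  need_cols(presence, c("genome_id", "plot", "time_h", "present"),
            "presence")
  pres <- data.table::as.data.table(presence)
  out <- pres[, .(n_times = sum(present)), by = .(genome_id, plot)]
  out <- out[n_times >= min_times]
  data.table::setorder(out, genome_id, plot)
  out[]
}

#' Classify one persistent presence vector into a response category
#'
#' Categories, evaluated in fixed precedence so they are mutually exclusive:
#'
#' 1. `ubiquitous`: present at every time point.
#' 2. `early`: present at 0, 3 and 24 h, and at every later time point either
#'    absent or (when abundances are supplied) drastically decreased, i.e.
#'    abundance below `drastic_drop_frac` times the mean abundance over the
#'    0-24 h window. With `drastic_drop_frac = 0` (or no abundances) "early"
#'    requires literal absence after 24 h.
#' 3. `late`: absent through 24 h and present at the first later time point
#'    (48 h); persistence then guarantees detection through the series.
#' 4. `zero_and_168`: present in dry soil (0 h) and at the end of the series
#'    (168 h) plus at least one other time point, without being ubiquitous.
#' 5. `other`: everything else.
#'
#' @param present logical vector over the ordered time points.
#' @param times numeric time points in hours (default `c(0,3,24,48,72,168)`).
#' @param abundance optional numeric abundances aligned with `present`,
#'   enabling the "drastically decrease" clause of `early`.
#' @param drastic_drop_frac drop threshold as a fraction of the early-window
#'   mean abundance (default 0.1).
#' @return one of `"ubiquitous"`, `"early"`, `"late"`, `"zero_and_168"`,
#'   `"other"`.
#' @export
#' @examples
#' classify_response(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))   # early
#' classify_response(c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))   # late
#' classify_response(c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))   # zero_and_168
classify_response <- function(present, times = c(0, 3, 24, 48, 72, 168),
                              abundance = NULL, drastic_drop_frac = 0.1) {
  present <- as.logical(present)
  if (length(present) != length(times))
    stop("present and times must align")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  if (sum(present) < 3L)
    stop("vector is not persistent (fewer than 3 presences)")
  early_idx <- which(times <= 24)
  late_idx <- which(times > 24)
  if (all(present)) return("ubiquitous")
  if (all(present[early_idx])) {
    dropped <- if (is.null(abundance) || drastic_drop_frac == 0) {
      !any(present[late_idx])
    } else {
      ref <- mean(abundance[early_idx])
      all(!present[late_idx] |
            abundance[late_idx] < drastic_drop_frac * ref)
    }
    if (dropped) return("early")
  }
  if (!any(present[early_idx]) && present[late_idx[1L]]) return("late")
  if (present[1L] && present[length(times)]) return("zero_and_168")
  "other"
}

#' Classify all persistent vOTUs per plot
#'
#' Applies [persistent_filter()] then [classify_response()] to each
#' persistent genome x plot presence vector.
#'
#' @param presence presence table (`genome_id`, `plot`, `time_h`, `present`),
#'   optionally with an `abundance` column used for the drastic-drop clause.
#' @param drastic_drop_frac see [classify_response()].
#' @param min_times persistence threshold.
#' @return data.table `genome_id`, `plot`, `category`.
#' @export
classify_response_table <- function(presence, drastic_drop_frac = 0.1,
                                    min_times = 3L) {
  pres <- data.table::as.data.table(presence)
  keep <- persistent_filter(pres, min_times = min_times)
  pres <- pres[keep[, .(genome_id, plot)], on = c("genome_id", "plot")]
  # densify: a genome without a record at some sampled time is absent there
  all_times <- sort(unique(data.table::as.data.table(presence)$time_h))
  grid <- pres[, data.table::CJ(time_h = all_times), by = .(genome_id, plot)]
  pres <- pres[grid, on = c("genome_id", "plot", "time_h")]
  pres[is.na(present), present := FALSE]
  if ("abundance" %in% names(pres)) pres[is.na(abundance), abundance := 0]
  has_ab <- "abundance" %in% names(pres)
  data.table::setorder(pres, genome_id, plot, time_h)
  out <- pres[, .(category = classify_response(
    present, times = time_h,
    abundance = if (has_ab) abundance else NULL,
    drastic_drop_frac = drastic_drop_frac)),
    by = .(genome_id, plot)]
  out[]
}

#' Host composition per response category
#'
#' Counts unique vOTUs per putative host phylum within each response category
#' and plot. vOTUs without a resolvable phylum are tallied under `"unknown"`.
#'
#' @param categories table from [classify_response_table()].
#' @param hosts data.frame with `genome_id` and `host_lineage`
#'   (semicolon-delimited ranks, `"unknown"`, or empty).
#' @return data.table `plot`, `category`, `phylum`, `n`.
#' @export
category_host_composition <- function(categories, hosts) {
  need_cols(categories, c("genome_id", "plot", "category"), "categories")
  need_cols(hosts, c("genome_id", "host_lineage"), "hosts")
  cats <- data.table::as.data.table(categories)
  hs <- data.table::as.data.table(hosts)[, .(genome_id, host_lineage)]
  dt <- merge(cats, hs, by = "genome_id", all.x = TRUE)
  dt[, phylum := vapply(host_lineage, function(l) {
    r <- parse_lineage(l)
    if (length(r) >= 2L) r[2L] else "unknown"
  }, character(1))]
  out <- dt[, .(n = data.table::uniqueN(genome_id)),
            by = .(plot, category, phylum)]
  data.table::setorder(out, plot, category, -n, phylum)
  out[]
}
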