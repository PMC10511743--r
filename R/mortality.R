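# Virion-based model of the viral contribution to microbial mortality.
#
# Virions are counted from extracted viral DNA mass and mean genome length;
# microbial deaths are counted from the 16S rRNA copy loss rate; the two are
# related through an assumed burst size (virions released per lysed cell).

AVOGADRO <- 6.0221e23      # molecules per mole
BP_G_PER_MOL <- 660        # grams per mole per base pair (double-stranded)
NG_PER_G <- 1e9

#' Virions per gram soil from viral DNA mass
#'
#' `virions = (X_ng * 6.0221e23) / (N_bp * 660 * 1e9)`: the number of
#' genome-length DNA molecules contained in `x_ng` nanograms of viral DNA,
#' assuming a mean genome length of `n_bp` base pairs at 660 g/mol/bp.
#'
#' @param x_ng viral DNA per gram soil (ng); vectorized, must be >= 0.
#' @param n_bp mean viral genome length (bp); must be positive.
#' @return virions per gram soil.
#' @export
#' @examples
#' virions_from_dna(1, 21254)  # ~4.29e7
virions_from_dna <- function(x_ng, n_bp) {
  if (any(n_bp <= 0)) stop("genome length must be positive")
  if (any(x_ng < 0)) stop("DNA mass must be >= 0")
  (x_ng * AVOGADRO) / (n_bp * BP_G_PER_MOL * NG_PER_G)
}

#' Microbial cells died from the 16S rRNA loss rate
#'
#' Converts a loss rate of 16S rRNA gene copies per gram soil per day into
#' cells per gram over a period: `cells = loss_rate * days /
#' copies_per_cell`. Six rRNA copies per cell is the study's conservative
#' default.
#'
#' @param loss_rate 16S rRNA copies lost per gram per day.
#' @param days elapsed days.
#' @param copies_per_cell rRNA gene copies per microbial cell (default 6).
#' @return cells died per gram soil.
#' @export
cells_died <- function(loss_rate, days, copies_per_cell = 6) {
  if (any(copies_per_cell <= 0)) stop("copies_per_cell must be positive")
  if (any(loss_rate < 0) || any(days < 0))
    stop("loss_rate and days must be >= 0")
  loss_rate * days / copies_per_cell
}

#' Percent of microbial mortality attributable to viral lysis
#'
#' `contribution = 100 * (virions / burst_size) / cells_died`: the observed
#' virions imply `virions / burst_size` lysed cells, expressed as a percent
#' of total observed cell deaths. Contribution is therefore exactly
#' inversely proportional to burst size (the burst-1 value divided by b).
#'
#' Note on the formula direction: dividing by burst size is what reproduces
#' the reported monotonicity (largest contribution at burst size 1, e.g.
#' 46.6% at burst 1 vs 0.23% at burst 200 cumulatively at 168 h); a
#' multiplication would invert that ordering.
#'
#' @param virions virions per gram soil.
#' @param burst_size virions released per lysed cell; must be >= 1.
#' @param cells_died total microbial deaths per gram soil. Zero deaths make
#'   the contribution undefined: `NA` is returned for those entries with a
#'   warning.
#' @return percent contribution (may exceed 100 if virions outnumber
#'   implied deaths).
#' @export
viral_contribution <- function(virions, burst_size, cells_died) {
  if (any(burst_size < 1)) stop("burst_size must be >= 1")
  if (any(virions < 0)) stop("virions must be >= 0")
  out <- 100 * (virions / burst_size) / cells_died
  undef <- !is.na(cells_died) & cells_died == 0
  if (any(undef)) {
    warning("contribution undefined where cells_died == 0; returning NA")
    out[undef] <- NA_real_
  }
  out
}

#' Cumulative contribution series
#'
#' Running sum of per-time contributions, literally as stated: each time
#' point reports the sum of all previous time points plus itself. Undefined
#' (`NA`) entries contribute 0 to the running sum and are flagged via the
#' `undefined` attribute.
#'
#' @param contributions per-time contributions ordered by time.
#' @return cumulative series (same length), with attribute `undefined`
#'   marking positions that were `NA` on input.
#' @export
#' @examples
#' cumulative_contribution(c(10, 5, 2))  # 10 15 17
cumulative_contribution <- function(contributions) {
  undef <- is.na(contributions)
  x <- contributions
  x[undef] <- 0
  structure(cumsum(x), undefined = undef)
}

#' Full mortality model over a burst-size grid
#'
#' For each time point: counts virions from viral DNA (Eq. virions), counts
#' cells died from the 16S loss rate over the elapsed days, and evaluates
#' the per-time and cumulative percent contribution for every burst size.
#' `days = "cumulative"` (default) uses days since wet-up (`time_h / 24`);
#' `days = "interval"` uses the interval since the previous time point.
#' Time 0 has zero elapsed days, hence zero observed deaths and an
#' undefined (flagged `NA`) contribution.
#'
#' @param inputs data.frame with `time_h`, `viral_dna_ng_per_g` and
#'   `loss_rate_copies_per_g_day`; one row per time point (average plots
#'   first, or pass one plot at a time).
#' @param mean_genome_len_bp mean viral genome length (bp).
#' @param rrna_copies_per_cell rRNA copies per cell (default 6).
#' @param burst_sizes burst-size grid (default `c(1, 10, 25, 50, 100, 200)`).
#' @param days `"cumulative"` or `"interval"`.
#' @return data.table: `time_h`, `burst_size`, `virions`, `cells_died`,
#'   `contribution_pct`, `cumulative_pct`, `undefined`.
#' @export
mortality_model <- function(inputs, mean_genome_len_bp,
                            rrna_copies_per_cell = 6,
                            burst_sizes = c(1, 10, 25, 50, 100, 200),
                            days = c("cumulative", "interval")) {
  days <- match.arg(days)
  need_cols(inputs, c("time_h", "viral_dna_ng_per_g",
                      "loss_rate_copies_per_g_day"), "inputs")
  dt <- data.table::as.data.table(inputs)
  data.table::setorder(dt, time_h)
  if (anyDuplicated(dt$time_h)) stop("one row per time point required")
  elapsed <- switch(days,
                    cumulative = dt$time_h / 24,
                    interval = c(dt$time_h[1L], diff(dt$time_h)) / 24)
  dt[, virions := virions_from_dna(viral_dna_ng_per_g, mean_genome_len_bp)]
  dt[, cells := cells_died(loss_rate_copies_per_g_day, elapsed,
                           rrna_copies_per_cell)]
  out <- data.table::rbindlist(lapply(burst_sizes, function(b) {
    contrib <- suppressWarnings(viral_contribution(dt$virions, b, dt$cells))
    cum <- cumulative_contribution(contrib)
    data.table::data.table(time_h = dt$time_h, burst_size = b,
                           virions = dt$virions, cells_died = dt$cells,
                           contribution_pct = contrib,
                           cumulative_pct = as.numeric(cum),
                           undefined = attr(cum, "undefined"))
  }))
  out[]
}

#' Genome-length sensitivity of the mortality contribution
#'
#' Recomputes the contribution varying mean genome length only (DNA mass,
#' burst size and cell mortality held fixed) and regresses
#' log10(contribution) on log10(length). Because virions scale as 1/N, the
#' analytic slope is exactly -1.
#'
#' @param x_ng viral DNA per gram soil (ng), fixed.
#' @param burst_size fixed burst size.
#' @param cells fixed cells died per gram; must be > 0.
#' @param lengths genome-length grid (bp); at least 3 positive, non-constant
#'   values.
#' @return list `slope`, `intercept`, `r`, `r_squared`, `p_value`, `n` from
#'   [ols_trend()], plus `contributions`.
#' @export
genome_length_sensitivity <- function(x_ng, burst_size, cells, lengths) {
  if (length(lengths) < 3L) stop("need at least 3 genome lengths")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (length(unique(lengths)) < 2L)
    stop("regression undefined for a constant length grid")
  if (cells <= 0) stop("cells must be > 0")
  contrib <- viral_contribution(virions_from_dna(x_ng, lengths),
                                burst_size, cells)
  fit <- ols_trend(log10(lengths), log10(contrib))
  c(fit, list(contributions = contrib))
}
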