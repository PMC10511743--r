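# Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ordinary least-squares trend for a two-variable regression
#'
#' Fits `y ~ x` and reports the slope, intercept, Pearson r, R-squared and the
#' two-sided p-value of the slope. Used for the richness/biomass trend tests
#' and the genome-length sensitivity analysis.
#'
#' A regression on fewer than two distinct `x` values is undefined and is
#' returned with `defined = FALSE` rather than an error, so callers can report
#' counts without a trend. A constant response is treated as a zero slope with
#' zero R-squared (no variance to explain).
#'
#' @param x,y numeric vectors of equal length; non-finite pairs are dropped.
#' @return list with `slope`, `intercept`, `r`, `r_squared`, `p_value`, `n`,
#'   `defined`.
#' @export
#' @examples
#' ols_trend(1:5, c(2, 4, 6, 8, 10))$slope
ols_trend <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  undef <- list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                r_squared = NA_real_, p_value = NA_real_, n = n,
                defined = FALSE)
  if (n < 2L || length(unique(x)) < 2L) return(undef)
  if (stats::var(y) == 0) {
    return(list(slope = 0, intercept = y[1L], r = 0, r_squared = 0,
                p_value = 1, n = n, defined = TRUE))
  }
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  p <- if (n > 2L) unname(sm$coefficients[2L, 4L]) else NA_real_
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r = unname(stats::cor(x, y)),
       r_squared = sm$r.squared,
       p_value = p,
       n = n,
       defined = TRUE)
}

# standard error of the mean; n counts non-missing values
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# Derive a reproducible integer sub-seed (< 2^31) from a global seed and a
# stream name, so every generator stage draws from its own named substream.
substream_seed <- function(seed, name) {
  u <- utf8ToInt(name)
  h <- sum(u * seq_along(u) * 97) %% 104729
  as.integer((as.integer(seed) %% 500000L) * 2003L + h)
}

# Evaluate expr under a temporary RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# assert columns exist in a table, with a caller-facing message
need_cols <- function(x, cols, what = deparse(substitute(x))) {
  miss <- setdiff(cols, names(x))
  if (length(miss))
    stop(sprintf("%s is missing column(s): %s", what,
                 paste(miss, collapse = ", ")))
  invisible(TRUE)
}
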