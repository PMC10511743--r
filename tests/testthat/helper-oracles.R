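# Independent brute-force oracles. These deliberately re-derive each
# quantity from its defining formula, not from the package implementation.

# Bray-Curtis from the defining formula sum|x-y| / sum(x+y)
bray_brute <- function(x, y) {
  if (sum(x) + sum(y) == 0) return(0)
  sum(abs(x - y)) / sum(x + y)
}

# Pearson chi-square from expected counts
chisq_brute <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# lowest common ancestor by pairwise prefix reduction
lca_brute <- function(lineages) {
  split1 <- function(s) {
    if (identical(tolower(trimws(s)), "unknown") || !nzchar(trimws(s)))
      return(character(0))
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  }
  parts <- Filter(length, lapply(lineages, split1))
  if (length(parts) == 0) return("unknown")
  pref <- parts[[1]]
  for (p in parts[-1]) {
    k <- 0
    for (i in seq_len(min(length(pref), length(p)))) {
      if (pref[i] == p[i]) k <- i else break
    }
    pref <- pref[seq_len(k)]
    if (length(pref) == 0) break
  }
  if (length(pref) == 0) "unknown" else paste(pref, collapse = ";")
}

# closed-form two-variable OLS with two-sided slope test
ols_brute <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * sum((y - mean(y))^2))
  sse <- sum((y - intercept - slope * x)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept, r = r, r_squared = r^2,
       p_value = 2 * pt(-abs(t), n - 2))
}

# classical PCoA by hand: double-center -0.5 * D^2 and eigendecompose
pcoa_brute <- function(d) {
  n <- nrow(d)
  a <- -0.5 * d^2
  j <- diag(n) - matrix(1 / n, n, n)
  eigen(j %*% a %*% j, symmetric = TRUE)
}

# response-category oracle written as set logic over the 6-point axis
# (independent restructuring of the published category definitions)
category_oracle <- function(v) {
  stopifnot(length(v) == 6)
  idx <- which(v)
  if (length(idx) < 3) return(NA_character_)
  if (length(idx) == 6) return("ubiquitous")
  if (all(c(1, 2, 3) %in% idx) && !any(idx > 3)) return("early")
  if (!any(idx <= 3) && 4 %in% idx) return("late")
  if (all(c(1, 6) %in% idx)) return("zero_and_168")
  "other"
}
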