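test_that("relative abundance divides by sample totals and conserves", {
  rec <- rbind(vrec("g1", 1, 0, 0.9, reads = 10, total = 1000),
               vrec("g2", 1, 0, 0.9, reads = 0, total = 1000))
  m <- relative_abundance(rec)
  expect_equal(unname(m["g1", 1]), 0.01)
  expect_equal(unname(m["g2", 1]), 0)

  # two genomes covering the whole library -> column sum 1
  rec2 <- rbind(vrec("g1", 1, 0, 0.9, reads = 300, total = 1000),
                vrec("g2", 1, 0, 0.9, reads = 700, total = 1000))
  expect_equal(unname(colSums(relative_abundance(rec2))), 1)

  # zero total reads must name the offending sample
  bad <- vrec("g1", 2, 24, 0.9, total = 0)
  expect_error(relative_abundance(bad), "2\\|24")
})

test_that("presence calls follow the assay-specific breadth rules", {
  expect_true(presence_calls(vrec("g", 1, 0, 0.85), "virome")$present)
  expect_false(presence_calls(vrec("g", 1, 0, 0.79), "virome")$present)

  # SIP: breadth >= 0.5 required in all three replicate tubes
  sip3 <- do.call(rbind, lapply(1:3, function(p)
    vrec("g", p, 24, breadth = c(0.55, 0.55, 0.4)[p],
         assay = "sip_fraction", treatment = "18O", fraction_index = 1L)))
  out <- presence_calls(sip3, "sip_fraction")
  expect_false(out$present)
  expect_equal(out$n_detected, 2L)

  sip3$covered_bases <- 0.55 * 10000
  expect_true(presence_calls(sip3, "sip_fraction")$present)

  expect_error(presence_calls(sip3, "amplicon"), "arg")
  expect_error(presence_calls(sip3, "virome", breadth_cutoff = 0), "0, 1")
})

test_that("presence is monotone in the breadth cutoff", {
  set.seed(5)
  rec <- do.call(rbind, lapply(1:40, function(i)
    vrec(paste0("g", i), sample(1:3, 1), sample(c(0, 24, 168), 1),
         breadth = runif(1))))
  cuts <- c(0.9, 0.7, 0.5, 0.3)
  prev <- NULL
  for (ct in cuts) {
    cur <- presence_calls(rec, "virome", breadth_cutoff = ct)
    if (!is.null(prev)) {
      j <- merge(prev, cur, by = c("genome_id", "plot", "time_h"))
      expect_true(all(j$present.y >= j$present.x))  # lowering adds only
    }
    prev <- cur
  }
})

test_that("richness series counts, averages, and regresses per microcosm", {
  mk <- function(n, t) do.call(rbind, lapply(seq_len(n), function(i)
    vrec(paste0("g", i), 1, t, 0.9)))
  rec <- rbind(mk(5, 0), mk(4, 24), mk(3, 168))
  rs <- richness_series(presence_calls(rec, "virome"))
  expect_equal(rs$per_plot$richness, c(5L, 4L, 3L))
  expect_lt(rs$trend$slope, 0)

  # constant presence -> zero slope, zero R2
  recc <- rbind(mk(4, 0), mk(4, 24), mk(4, 168))
  tc <- richness_series(presence_calls(recc, "virome"))$trend
  expect_equal(tc$slope, 0)
  expect_equal(tc$r_squared, 0)

  # single time point: counts fine, regression undefined
  r1 <- richness_series(presence_calls(mk(5, 0), "virome"))
  expect_equal(r1$per_plot$richness, 5L)
  expect_false(r1$trend$defined)
})

test_that("OLS trend matches the closed-form oracle", {
  set.seed(9)
  for (i in 1:20) {
    x <- rnorm(8)
    y <- 2 * x + rnorm(8)
    a <- ols_trend(x, y)
    b <- ols_brute(x, y)
    expect_equal(a$slope, b$slope)
    expect_equal(a$intercept, b$intercept)
    expect_equal(a$r_squared, b$r_squared)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("biomass series multiplies yields by read fraction", {
  yl <- data.frame(plot = 1, time_h = c(0, 168), dna_ng_per_g = c(2, 2))
  bs <- biomass_series(yl, 0.35)
  expect_equal(bs$per_plot$biomass, c(0.7, 0.7))
  expect_equal(biomass_series(yl, 0)$per_plot$biomass, c(0, 0))
  expect_error(biomass_series(yl, 1.5), "\\[0, 1\\]")
})

test_that("Bray-Curtis + PCoA match brute-force formula and eigendecomposition", {
  # identical columns -> 0; disjoint support -> 1
  m <- cbind(s1 = c(1, 2, 0), s2 = c(1, 2, 0), s3 = c(0, 0, 5))
  pc <- bray_curtis_pcoa(m)
  expect_equal(unname(pc$dissimilarity["s1", "s2"]), 0)
  expect_equal(unname(pc$dissimilarity["s1", "s3"]), 1)
  expect_equal(diag(pc$dissimilarity), setNames(rep(0, 3), colnames(m)))

  # 3-sample toy: axis-1 variance fraction against a hand eigendecomposition
  toy <- cbind(a = c(5, 1, 0), b = c(2, 3, 1), c = c(0, 1, 6))
  res <- bray_curtis_pcoa(toy)
  ev <- pcoa_brute(res$dissimilarity)$values
  expect_equal(res$variance_explained[1],
               ev[1] / sum(ev[ev > 0]), tolerance = 1e-10)

  # all-zero sample flagged, distance 1 to non-zero samples
  mz <- cbind(s1 = c(1, 2), s2 = c(0, 0), s3 = c(2, 1))
  expect_warning(rz <- bray_curtis_pcoa(mz), "all-zero")
  expect_equal(unname(rz$dissimilarity["s2", "s1"]), 1)
  expect_equal(rz$flagged_samples, "s2")

  expect_error(bray_curtis_pcoa(matrix(1, 2, 1)), "2 samples")
})

test_that("flag aggregation conserves column totals", {
  m <- rbind(g1 = c(0.01, 0.03), g2 = c(0.02, 0), g3 = c(0.05, 0.01))
  fl <- c(g1 = "int", g2 = "int", g3 = "no")
  ag <- aggregate_by_flag(m, fl)
  expect_equal(unname(ag$abundance["int", 1]), 0.03)
  expect_equal(colSums(ag$abundance), colSums(m))
  expect_equal(unname(ag$richness["int", 2]), 1)
  expect_error(aggregate_by_flag(m, fl[-1]), "missing")
})

test_that("ubiquitous fraction counts genomes present everywhere", {
  pres <- data.table::CJ(genome_id = paste0("m", 1:10), plot = 1:2,
                         time_h = c(0, 24))
  pres[, present := TRUE]
  pres[genome_id %in% paste0("m", 1:6) & time_h == 24 & plot == 2,
       present := FALSE]
  expect_equal(ubiquitous_fraction(pres), 0.4)
})
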