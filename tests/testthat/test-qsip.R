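test_that("weighted mean density weights by abundance x DNA mass", {
  expect_equal(weighted_mean_density(c(1.70, 1.72), c(1, 1), c(1, 1)), 1.71)
  expect_equal(weighted_mean_density(1.71, 1, 1), 1.71)
  expect_equal(weighted_mean_density(c(1.70, 1.72), c(1, 3), c(1, 1)),
               1.715)
  # zero-DNA fractions are dropped before weighting
  expect_equal(weighted_mean_density(c(1.70, 1.72, 1.90), c(1, 3, 5),
                                     c(1, 1, 0)), 1.715)
  expect_warning(w <- weighted_mean_density(c(1.7, 1.72), c(0, 0), c(1, 1)),
                 "undefined")
  expect_true(is.na(w))
  expect_error(weighted_mean_density(numeric(0), numeric(0), numeric(0)),
               "fraction")
})

test_that("APE chain reproduces hand-computed values", {
  expect_equal(ape_from_densities(1.70, 1.70), 0)
  # frozen hand evaluation: GC = 0.6460, M_light = 308.011,
  # M_lab = 311.635, ratio 0.30004 x (1 - 0.002000429) = 0.29944
  expect_equal(ape_from_densities(1.70, 1.72), 0.29944, tolerance = 1e-4)
  # maximum labeling: W_lab at M_heavymax recovers ~0.998
  k <- qsip_constants()
  gc <- (1.70 - k$gc_intercept) / k$gc_slope
  m_light <- k$m_slope * gc + k$m_intercept
  w_max <- 1.70 * (m_light + k$delta_m_max) / m_light
  expect_equal(ape_from_densities(1.70, w_max), 1 - k$nat_abund_18o,
               tolerance = 1e-12)
  # lighter labeled centroid -> negative, not clipped
  expect_lt(ape_from_densities(1.70, 1.69), 0)
})

test_that("APE is strictly increasing in the labeled density and inverts", {
  w_lab <- seq(1.70, 1.76, by = 0.005)
  apes <- ape_from_densities(1.70, w_lab)
  expect_true(all(diff(apes) > 0))
  for (a in c(0, 0.1, 0.3, 0.6, 0.998)) {
    expect_equal(ape_from_densities(1.70, density_for_ape(1.70, a)), a,
                 tolerance = 1e-12)
  }
  expect_error(density_for_ape(1.70, 1.2), "\\[0, 1\\]")
})

test_that("bootstrap collapses at zero noise and is seed-deterministic", {
  b <- bootstrap_ape(rep(1.70, 3), rep(1.72, 3), n_boot = 200, seed = 4)
  expect_equal(b$median_ape, ape_from_densities(1.70, 1.72))
  expect_equal(b$ci_high - b$ci_low, 0)

  wl <- c(1.699, 1.700, 1.701)
  wh <- c(1.719, 1.721, 1.720)
  b1 <- bootstrap_ape(wl, wh, n_boot = 500, seed = 7)
  b2 <- bootstrap_ape(wl, wh, n_boot = 500, seed = 7)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$median_ape && b1$median_ape <= b1$ci_high)
  expect_error(bootstrap_ape(wl, wh, n_boot = 0), "n_boot")
})

test_that("qsip_ape enforces the triplicate rule and the CI filter", {
  cfg <- small_config(abundance_cv = 0, density_sd = 0)
  ds <- generate_dataset(cfg)
  est <- qsip_ape(ds$sip_fraction_abund, ds$sip_fraction_meta,
                  n_boot = 30, seed = 2)
  # 2-of-3 decoys never estimated
  expect_length(intersect(est$genome_id, ds$truth$sip_decoys), 0)
  # zero noise: every estimate matches its planted enrichment
  tr <- merge(est, ds$truth$ape, by = "genome_id")
  expect_lt(max(abs(tr$median_ape - tr$true_ape)), 1e-6)
  expect_true(all(est$passes_ci))

  # a negative lower CI marks the estimate for removal
  fake <- data.table::copy(est[1:2])
  fake$ci_low <- c(-0.01, 0.02)
  fake$passes_ci <- fake$ci_low >= 0
  gi <- unique(data.frame(genome_id = fake$genome_id, type = "votu",
                          lineage = "Bacteria;Actinobacteria"))
  expect_message(sm <- enrichment_summary(fake, gi), "removed")
  expect_equal(sum(sm$counts$n_total), 1L)
})

test_that("excluding one genome never changes another's estimate", {
  cfg <- small_config(abundance_cv = 0.1, density_sd = 0.002)
  ds <- generate_dataset(cfg)
  fa <- ds$sip_fraction_abund
  full <- qsip_ape(fa, ds$sip_fraction_meta, n_boot = 25, seed = 9)
  drop_g <- full$genome_id[1]
  sub <- qsip_ape(fa[fa$genome_id != drop_g], ds$sip_fraction_meta,
                  n_boot = 25, seed = 9)
  cmp <- merge(full[full$genome_id != drop_g], sub,
               by = c("genome_id", "time_h"))
  expect_equal(cmp$median_ape.x, cmp$median_ape.y)
  expect_equal(cmp$ci_low.x, cmp$ci_low.y)
})

test_that("enrichment summary aggregates by lineage and counts new genomes", {
  est <- data.table::data.table(
    genome_id = c("v1", "v1", "v2", "m1"),
    time_h = c(24, 48, 48, 24),
    median_ape = c(0.2, 0.3, 0.4, 0.25),
    ci_low = 0.05, ci_high = 0.5, n_boot = 10L, passes_ci = TRUE)
  gi <- data.frame(genome_id = c("v1", "v2", "m1"),
                   type = c("votu", "votu", "mag"),
                   lineage = "Bacteria;Actinobacteria")
  sm <- enrichment_summary(est, gi)
  a48 <- sm$ape[sm$ape$time_h == 48 & sm$ape$type == "votu", ]
  expect_equal(a48$mean_ape, mean(c(0.3, 0.4)))
  c48 <- sm$counts[sm$counts$time_h == 48 & sm$counts$type == "votu", ]
  expect_equal(c48$n_total, 2L)
  expect_equal(c48$n_new, 1L)  # v2 first appears at 48 h
})

test_that("detection overlap computes the enriched-and-virion share", {
  expect_equal(detection_overlap(paste0("v", 1:177), paste0("v", 1:58)),
               58 / 177)
  expect_equal(detection_overlap(character(0), "v1"), 0)
})
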