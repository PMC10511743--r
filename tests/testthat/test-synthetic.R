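test_that("config validation rejects malformed scenarios", {
  expect_error(scenario_config(time_points_h = c(0, 24, 24)), "increasing")
  expect_error(scenario_config(richness_decline_frac = 1.2), "\\[0, 1\\]")
  expect_error(scenario_config(response_mix = c(early = 0.5, late = 0.5,
                                                ubiquitous = 0,
                                                zero_and_168 = 0,
                                                other = 0.1)), "sum to 1")
  expect_error(scenario_config(biomass_fold_change = 0), "positive")
  expect_error(scenario_config(true_ape = c(0.3)), "named")
  expect_error(scenario_config(true_ape = c(v1 = 1.5)), "\\[0, 1\\]")
})

test_that("generation is byte-stable for a fixed seed", {
  a <- generate_dataset(small_config())
  b <- generate_dataset(small_config())
  for (nm in c("votu_catalog", "mag_catalog", "ani_pairs",
               "virome_mapping", "metagenome_mapping", "dna_yields",
               "loss_rates", "sip_fraction_meta", "sip_fraction_abund",
               "spacer_hits", "lysogen_alignments", "prophage_coverage")) {
    expect_identical(a[[nm]], b[[nm]], label = nm)
  }
  expect_identical(a$truth$categories, b$truth$categories)
  # and a different seed actually changes things
  c <- generate_dataset(scenario_config(seed = 12, n_votus = 60,
                                        n_mags = 10))
  expect_false(identical(a$virome_mapping, c$virome_mapping))
})

test_that("an empty scenario generates empty tables without error", {
  ds <- generate_dataset(scenario_config(n_votus = 0, n_mags = 0))
  expect_equal(nrow(ds$votu_catalog), 0)
  expect_equal(nrow(ds$virome_mapping), 0)
  expect_equal(nrow(ds$sip_fraction_abund), 0)
  expect_length(ds$truth$kept, 0)
})

test_that("every mapping record references a catalog genome and truth covers it", {
  ds <- generate_dataset(small_config())
  expect_true(all(ds$virome_mapping$genome_id %in% ds$votu_catalog$id))
  expect_true(all(ds$metagenome_mapping$genome_id %in% ds$mag_catalog$id))
  expect_true(all(ds$sip_fraction_abund$genome_id %in%
                    c(ds$votu_catalog$id, ds$mag_catalog$id)))
  # truth ledger covers what was planted
  expect_true(all(ds$truth$categories$genome_id %in% ds$truth$kept))
  expect_true(all(ds$truth$ape$genome_id %in%
                    c(ds$votu_catalog$id, ds$mag_catalog$id)))
})

test_that("per-sample relative abundances sum to at most 1", {
  ds <- generate_community(small_config())
  m <- relative_abundance(ds$virome_mapping)
  expect_true(all(colSums(m) <= 1 + 1e-12))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("richness decline and biomass rise match the configured world", {
  ds <- generate_community(small_config(abundance_cv = 0))
  rs <- richness_series(presence_calls(ds$virome_mapping, "virome"))
  first <- rs$series$mean_richness[1]
  last <- rs$series$mean_richness[nrow(rs$series)]
  expect_equal(last / first, 0.5, tolerance = 0.06)
  expect_lt(rs$trend$slope, 0)

  ds2 <- generate_mortality_inputs(ds)
  bs <- biomass_series(ds$dna_yields, ds$truth$viral_read_fraction)
  expect_equal(bs$fold_change, ds$config$biomass_fold_change,
               tolerance = 1e-6)  # deterministic at zero noise
  expect_gt(bs$trend$slope, 0)
})

test_that("plot pools overlap only partially (plot-specific composition)", {
  ds <- generate_community(small_config())
  pres <- data.table::as.data.table(ds$truth$presence)[present == TRUE]
  pools <- split(pres$genome_id, pres$plot)
  pools <- lapply(pools, unique)
  shared <- Reduce(intersect, pools)
  uni <- Reduce(union, pools)
  expect_gt(length(shared), 0)
  expect_lt(length(shared), length(uni))
})

test_that("planted response categories are recovered exactly at zero noise", {
  ds <- generate_community(small_config(abundance_cv = 0))
  cats <- classify_response_table(
    presence_calls(ds$virome_mapping, "virome"))
  truth <- ds$truth$categories[ds$truth$categories$category != "transient"]
  m <- merge(cats, truth, by = c("genome_id", "plot"))
  expect_equal(nrow(m), nrow(truth))
  expect_true(all(m$category.x == m$category.y))
  # planted host mix per category recovered
  hc <- category_host_composition(cats, ds$truth$hosts)
  expect_equal(sum(hc$n), nrow(m))
})

test_that("SIP profiles encode the configured enrichment", {
  # true APE 0: labeled and unlabeled centroids coincide
  cfg0 <- small_config(abundance_cv = 0, density_sd = 0, frac_active = 0)
  ds0 <- generate_sip_profiles(generate_community(cfg0))
  fa <- merge(ds0$sip_fraction_abund, ds0$sip_fraction_meta,
              by = c("plot", "treatment", "time_h", "fraction_index"))
  fa <- data.table::as.data.table(fa)
  g <- fa$genome_id[1]
  w <- fa[genome_id == g,
          .(w = weighted_mean_density(density_gml, rel_abund, dna_ng)),
          by = .(treatment, plot, time_h)]
  expect_equal(max(w$w) - min(w$w), 0, tolerance = 1e-9)

  # zero-noise closed loop: bootstrap recovers planted truth to <= 1e-6
  cfg <- small_config(abundance_cv = 0, density_sd = 0)
  ds <- generate_sip_profiles(generate_community(cfg))
  est <- qsip_ape(ds$sip_fraction_abund, ds$sip_fraction_meta,
                  n_boot = 20, seed = 3)
  tr <- merge(est, ds$truth$ape, by = "genome_id")
  expect_gt(nrow(tr), 0)
  expect_lt(max(abs(tr$median_ape - tr$true_ape)), 1e-6)

  # out-of-range enrichment is rejected up front
  expect_error(small_config(true_ape = c(vOTU_0001 = -0.1)), "\\[0, 1\\]")
})

test_that("mortality inputs are non-negative and cumulative series behave", {
  ds <- generate_mortality_inputs(generate_community(small_config()))
  mi <- ds$mortality_inputs
  expect_true(all(mi$per_plot$viral_dna_ng_per_g >= 0))
  expect_true(all(mi$per_plot$loss_rate_copies_per_g_day >= 0))
  mm <- mortality_model(mi$mean, mi$mean_genome_len_bp,
                        burst_sizes = mi$burst_sizes)
  expect_true(all(is.finite(mm$cumulative_pct)))
  for (b in unique(mm$burst_size)) {
    expect_true(all(diff(mm$cumulative_pct[mm$burst_size == b]) >= 0))
  }
  # zero loss rate flags the time point as undefined
  bad <- data.table::copy(mi$mean)
  bad$loss_rate_copies_per_g_day[2] <- 0
  mb <- mortality_model(bad, mi$mean_genome_len_bp, burst_sizes = 1)
  expect_true(mb$undefined[2])
})

test_that("planted evidence passes its filters and decoys fail theirs", {
  ds <- generate_dataset(small_config())
  fh <- filter_spacer_hits(ds$spacer_hits)
  truth <- ds$truth$spacer_truth
  expect_setequal(fh$spacer_id, truth$spacer_id[truth$should_pass])
  # each decoy violates exactly one criterion
  decoys <- ds$spacer_hits[!ds$spacer_hits$should_pass, ]
  viol <- (decoys$mismatches > 1) + (decoys$gaps > 0) +
    (decoys$align_len != decoys$spacer_len)
  expect_true(all(viol == 1))

  la <- lysogen_alignment_filter(ds$lysogen_alignments)
  expect_setequal(la$votu_id, ds$truth$lysogens)

  cand <- candidate_prophage_contigs(ds$contig_coverage)
  expect_true(length(cand) >= 1)

  act <- prophage_activity(ds$prophage_coverage)
  expect_setequal(act$mag_id[act$active], ds$truth$active_prophages)

  # consensus host recovery from the planted prediction database
  hp <- data.table::as.data.table(ds$host_predictions)
  cons <- hp[, .(lineage = consensus_host(lineage)), by = votu_id]
  ct <- merge(cons, ds$truth$consensus_hosts, by = "votu_id")
  expect_true(all(ct$lineage == ct$expected_lineage))

  # zero planted lysogens -> empty filter output
  ds0 <- generate_dataset(small_config(n_lysogens = 0))
  keep0 <- lysogen_alignment_filter(ds0$lysogen_alignments)
  expect_equal(nrow(keep0), 0)
})

test_that("dataset round-trips through the TSV writers", {
  ds <- generate_dataset(scenario_config(seed = 2, n_votus = 20,
                                         n_mags = 5))
  dir <- file.path(tempdir(), "wetupvir-roundtrip")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  cat2 <- read_catalog(file.path(dir, "votu_catalog.tsv"))
  expect_equal(nrow(cat2), nrow(ds$votu_catalog))
  expect_identical(cat2$id, ds$votu_catalog$id)
  map2 <- read_mapping(file.path(dir, "virome_mapping.tsv"))
  expect_equal(nrow(map2), nrow(ds$virome_mapping))
  fr2 <- read_fractions(file.path(dir, "sip_fraction_meta.tsv"))
  expect_equal(nrow(fr2), nrow(ds$sip_fraction_meta))
})
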