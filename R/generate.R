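# Synthetic wet-up dataset generator. Every stage draws from a named
# substream of the global seed, so a fixed config is byte-stable, and each
# stage records what it planted in the truth ledger.

# pool of host lineages (NCBI-style rank names), Actinobacteria and
# Proteobacteria deliberately most frequent
.lineage_pool <- c(
  "Bacteria;Actinobacteria;Actinomycetia;Streptomycetales;Streptomycetaceae;Streptomyces;Streptomyces luteus",
  "Bacteria;Actinobacteria;Actinomycetia;Mycobacteriales;Mycobacteriaceae;Mycolicibacterium;Mycolicibacterium arenae",
  "Bacteria;Actinobacteria;Thermoleophilia;Gaiellales;Gaiellaceae;Gaiella;Gaiella humicola",
  "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Xanthobacteraceae;Bradyrhizobium;Bradyrhizobium arenosum",
  "Bacteria;Proteobacteria;Alphaproteobacteria;Hyphomicrobiales;Methylobacteriaceae;Microvirga;Microvirga arida",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Erwiniaceae;Pantoea;Pantoea graminis",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Lysobacterales;Lysobacteraceae;Lysobacter;Lysobacter humi",
  "Bacteria;Acidobacteria;Acidobacteriia;Acidobacteriales;Acidobacteriaceae;Edaphobacter;Edaphobacter siccus",
  "Bacteria;Chloroflexi;Ktedonobacteria;Ktedonobacterales;Ktedonobacteraceae;Ktedonobacter;Ktedonobacter praticola",
  "Bacteria;Firmicutes;Bacilli;Bacillales;Bacillaceae;Bacillus;Bacillus pratensis",
  "Archaea;Thermoproteota;Nitrososphaeria;Nitrososphaerales;Nitrososphaeraceae;Nitrososphaera;Nitrososphaera camporum"
)
.lineage_weights <- c(0.14, 0.10, 0.08, 0.12, 0.10, 0.09, 0.07, 0.09, 0.07,
                      0.07, 0.07)

.tool_pool <- c("virsorter", "virsorter2", "vibrant", "deepvirfinder",
                "seeker")

# presence templates classified as "other": persistent but matching no
# named category (indices into the 6-point default time axis)
.other_patterns <- list(c(2L, 3L, 4L), c(3L, 4L, 5L), c(2L, 4L, 5L),
                        c(2L, 3L, 4L, 5L), c(3L, 4L, 5L, 6L))

# deterministic DNA-yield ramp carrying the biomass fold change
.yield_curve <- function(times, y0, fold) {
  tmax <- max(times)
  if (tmax == 0) return(rep(y0, length(times)))
  y0 * (1 + (fold - 1) * (times / tmax)^0.7)
}

lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

empty_mapping <- function() {
  data.table::data.table(genome_id = character(0), plot = integer(0),
                         time_h = numeric(0), assay = character(0),
                         treatment = character(0),
                         fraction_index = integer(0),
                         mapped_reads = integer(0),
                         covered_bases = numeric(0),
                         genome_length = numeric(0),
                         sample_total_reads = numeric(0))
}

#' Generate the synthetic community: catalogs, presence, virome/metagenome
#' mapping, DNA yields and loss rates
#'
#' Builds the vOTU and MAG catalogs, gives every plot a partially
#' overlapping vOTU pool, assigns persistent vOTUs a response-category
#' presence template (per `response_mix`) and transient vOTUs single
#' detections allocated so mean richness declines by
#' `richness_decline_frac` from the first to the last time point, then
#' emits virome mapping records whose read counts follow lognormal
#' abundances and whose DNA-yield series carries `biomass_fold_change`.
#' Everything planted is recorded in the `truth` ledger.
#'
#' @param config a [scenario_config()].
#' @return list of class `"wetup_dataset"`: `config`, `votu_catalog`,
#'   `mag_catalog`, `ani_pairs`, `virome_mapping`, `metagenome_mapping`,
#'   `dna_yields`, `loss_rates`, `truth`.
#' @export
generate_community <- function(config) {
  if (!inherits(config, "scenario_config"))
    stop("config must be a scenario_config")
  cfg <- config
  times <- cfg$time_points_h
  J <- length(times)
  plots <- seq_len(cfg$n_plots)

  truth <- list()
  ds <- list(config = cfg)

  # ---- catalogs -----------------------------------------------------------
  ds$votu_catalog <- with_seed(substream_seed(cfg$seed, "votu_catalog"), {
    n <- cfg$n_votus
    if (n == 0L) {
      data.table::data.table(id = character(0), length_bp = numeric(0),
                             circular = logical(0), tools = character(0),
                             integrase = logical(0), source = character(0),
                             host_lineage = character(0))
    } else {
      id <- sprintf("vOTU_%04d", seq_len(n))
      length_bp <- pmax(2000, round(rlnorm(n, log(16000), 0.5)))
      multi <- runif(n) < 0.88
      tools <- vapply(seq_len(n), function(i) {
        k <- if (multi[i]) sample(2:3, 1L) else 1L
        paste(sample(.tool_pool, k), collapse = ",")
      }, character(1))
      circular <- multi & runif(n) < cfg$frac_circular
      # a slice of multi-tool linear contigs falls below the size cutoff
      short <- which(multi & !circular & runif(n) < 0.05)
      length_bp[short] <- round(runif(length(short), 3000, 9000))
      integrase <- runif(n) < cfg$frac_integrase
      source <- ifelse(runif(n) < 0.95, "virome", "metagenome")
      host <- sample(.lineage_pool, n, replace = TRUE,
                     prob = .lineage_weights)
      # most hosts known only to genus or shallower; ~7% unknown
      host <- vapply(host, function(l) {
        r <- parse_lineage(l)
        lineage_string(r[seq_len(sample(2:6, 1L))])
      }, character(1))
      host[runif(n) < 0.07] <- "unknown"
      data.table::data.table(id = id, length_bp = length_bp,
                             circular = circular, tools = tools,
                             integrase = integrase, source = source,
                             host_lineage = unname(host))
    }
  })
  truth$kept <- consensus_viral_filter(ds$votu_catalog)

  ds$mag_catalog <- with_seed(substream_seed(cfg$seed, "mag_catalog"), {
    n <- cfg$n_mags
    data.table::data.table(
      id = sprintf("MAG_%03d", seq_len(n)),
      length_bp = if (n) round(rlnorm(n, log(3.5e6), 0.3)) else numeric(0),
      lineage = if (n) sample(.lineage_pool, n, replace = TRUE,
                              prob = .lineage_weights) else character(0))
  })

  # planted near-duplicate pairs exercising the dereplication rule
  ds$ani_pairs <- with_seed(substream_seed(cfg$seed, "ani_pairs"), {
    k <- length(truth$kept)
    if (k < 8L) {
      truth$dup_clusters <- list()
      data.table::data.table(id_a = character(0), id_b = character(0),
                             ani = numeric(0), breadth = numeric(0))
    } else {
      ids <- truth$kept[1:8]
      truth$dup_clusters <- list(c(ids[1], ids[2]), c(ids[3], ids[4]))
      data.table::data.table(
        id_a = c(ids[1], ids[3], ids[5], ids[7]),
        id_b = c(ids[2], ids[4], ids[6], ids[8]),
        ani = c(0.97, 0.99, 0.97, 0.93),      # last fails ANI
        breadth = c(0.90, 0.88, 0.80, 0.90))  # third fails breadth
    }
  })

  # ---- per-plot pools, response templates, transient allocation ----------
  kept <- truth$kept
  presence_rows <- vector("list", cfg$n_plots)
  cat_rows <- vector("list", cfg$n_plots)
  with_seed(substream_seed(cfg$seed, "community_structure"), {
    for (p in plots) {
      pool <- sort(sample(kept, round(length(kept) * cfg$plot_pool_frac)))
      np <- length(pool)
      if (np == 0L) next
      pool <- sample(pool)  # shuffle before splitting
      n_pers <- round(cfg$persistent_frac * np)
      pers <- pool[seq_len(n_pers)]
      trans <- setdiff(pool, pers)

      mix <- cfg$response_mix
      counts <- diff(round(cumsum(c(0, mix)) * n_pers))
      names(counts) <- names(mix)
      cat_of <- rep(names(counts), counts)
      cat_of <- c(cat_of, rep("other", n_pers - length(cat_of)))

      tmpl <- matrix(FALSE, n_pers, J)
      early_cols <- which(times <= 24)
      late_cols <- which(times > 24)
      mid_cols <- setdiff(seq_len(J), c(1L, J))
      for (i in seq_len(n_pers)) {
        tmpl[i, ] <- switch(cat_of[i],
          ubiquitous = rep(TRUE, J),
          early = seq_len(J) %in% early_cols,
          late = seq_len(J) %in% late_cols,
          zero_and_168 = {
            v <- rep(FALSE, J)
            v[c(1L, J, mid_cols[sample.int(length(mid_cols), 1L)])] <- TRUE
            v
          },
          other = {
            v <- rep(FALSE, J)
            pat <- .other_patterns[[sample(length(.other_patterns), 1L)]]
            v[pat[pat <= J]] <- TRUE
            v
          })
      }

      # transient detections fill per-time slots so richness interpolates
      # from R1 down to (1 - decline) * R1
      r_pers <- colSums(tmpl)
      d <- cfg$richness_decline_frac
      cj <- 1 - d * (seq_len(J) - 1) / (J - 1)
      r1 <- (length(trans) + sum(r_pers)) / sum(cj)
      alloc <- pmax(0L, round(r1 * cj - r_pers))
      tr_tmpl <- matrix(FALSE, length(trans), J)
      ti <- 1L
      for (j in seq_len(J)) {
        take <- min(alloc[j], length(trans) - ti + 1L)
        if (take > 0L) {
          tr_tmpl[ti:(ti + take - 1L), j] <- TRUE
          ti <- ti + take
        }
      }

      genome <- c(pers, trans)
      tm <- rbind(tmpl, tr_tmpl)
      presence_rows[[p]] <- data.table::data.table(
        genome_id = rep(genome, each = J), plot = p,
        time_h = rep(times, length(genome)),
        present = as.vector(t(tm)))
      cat_rows[[p]] <- data.table::data.table(
        genome_id = c(pers, trans), plot = p,
        category = c(cat_of, rep("transient", length(trans))))
    }
  })
  truth$presence <- data.table::rbindlist(presence_rows)
  if (ncol(truth$presence) == 0L)
    truth$presence <- data.table::data.table(genome_id = character(0),
                                             plot = integer(0),
                                             time_h = numeric(0),
                                             present = logical(0))
  truth$categories <- data.table::rbindlist(cat_rows)
  if (ncol(truth$categories) == 0L)
    truth$categories <- data.table::data.table(genome_id = character(0),
                                               plot = integer(0),
                                               category = character(0))
  truth$hosts <- ds$votu_catalog[id %in% kept,
                                 .(genome_id = id, host_lineage)]

  # ---- virome mapping -----------------------------------------------------
  lens <- setNames(ds$votu_catalog$length_bp, ds$votu_catalog$id)
  ds$virome_mapping <- with_seed(substream_seed(cfg$seed, "virome"), {
    if (nrow(truth$presence) == 0L) empty_mapping() else {
      base <- with_seed(substream_seed(cfg$seed, "abund_base"), {
        b <- data.table::CJ(genome_id = kept, plot = plots)
        b[, w0 := rlnorm(.N, 0, 1)]
        b
      })
      rows <- list()
      vrf_truth <- list()
      cats <- truth$categories
      for (p in plots) {
        for (j in seq_len(J)) {
          t_h <- times[j]
          here <- truth$presence[plot == p & time_h == t_h &
                                   present == TRUE]
          if (nrow(here) == 0L) next
          g <- here$genome_id
          cat_g <- cats[plot == p][match(g, genome_id), category]
          # temporal multipliers: late responders and ubiquitous vOTUs grow,
          # making the 168 h community less even
          mult <- rep(1, length(g))
          grow <- (t_h / max(times))^1
          mult[cat_g %in% c("late", "ubiquitous")] <-
            1 + 6 * grow
          w <- base[plot == p][match(g, genome_id), w0] * mult *
            lognoise(length(g), cfg$abundance_cv)
          vrf <- if (cfg$abundance_cv > 0) {
            min(0.9, max(0.01, rnorm(1, cfg$viral_read_fraction,
                                     cfg$viral_read_fraction_sd)))
          } else cfg$viral_read_fraction
          vrf_truth[[length(vrf_truth) + 1L]] <-
            data.table::data.table(plot = p, time_h = t_h,
                                   viral_read_fraction = vrf)
          # (vrf_truth accumulated in the enclosing function frame)
          reads <- round(cfg$sample_total_reads * vrf * w / sum(w))
          br <- if (cfg$abundance_cv > 0)
            rbeta(length(g), 38, 2) else rep(0.95, length(g))
          # low-breadth decoys: absent pool genomes with a handful of reads
          absent <- truth$presence[plot == p & time_h == t_h &
                                     present == FALSE, genome_id]
          nd <- min(length(absent), max(0L, round(0.1 * length(absent))))
          dec <- if (nd > 0L) sample(absent, nd) else character(0)
          g_all <- c(g, dec)
          reads_all <- c(reads, if (nd) round(runif(nd, 20, 80)) else
            integer(0))
          br_all <- c(br, if (nd) runif(nd, 0.05, 0.3) else numeric(0))
          rows[[length(rows) + 1L]] <- data.table::data.table(
            genome_id = g_all, plot = p, time_h = t_h, assay = "virome",
            treatment = "none", fraction_index = NA_integer_,
            mapped_reads = as.integer(reads_all),
            covered_bases = round(br_all * lens[g_all]),
            genome_length = unname(lens[g_all]),
            sample_total_reads = cfg$sample_total_reads)
        }
      }
      truth$viral_read_fraction <- data.table::rbindlist(vrf_truth)
      data.table::rbindlist(rows)
    }
  })
  if (is.null(truth$viral_read_fraction))
    truth$viral_read_fraction <-
      data.table::data.table(plot = integer(0), time_h = numeric(0),
                             viral_read_fraction = numeric(0))

  # ---- metagenome mapping (MAGs) -----------------------------------------
  ds$metagenome_mapping <-
    with_seed(substream_seed(cfg$seed, "metagenome"), {
      mags <- ds$mag_catalog
      if (nrow(mags) == 0L) empty_mapping() else {
        mt <- cfg$metagenome_time_points_h
        ubiq <- runif(nrow(mags)) < 0.45
        rows <- list()
        for (p in plots) {
          for (t_h in mt) {
            here <- ubiq | runif(nrow(mags)) < 0.6
            g <- mags$id[here]
            w <- rlnorm(length(g), 0, 1)
            reads <- round(cfg$sample_total_reads * 0.6 * w / sum(w))
            br <- if (cfg$abundance_cv > 0) rbeta(length(g), 30, 2)
                  else rep(0.94, length(g))
            rows[[length(rows) + 1L]] <- data.table::data.table(
              genome_id = g, plot = p, time_h = t_h, assay = "metagenome",
              treatment = "none", fraction_index = NA_integer_,
              mapped_reads = as.integer(reads),
              covered_bases = round(br * mags$length_bp[here]),
              genome_length = mags$length_bp[here],
              sample_total_reads = cfg$sample_total_reads)
          }
        }
        truth$ubiquitous_mags <- mags$id[ubiq]
        data.table::rbindlist(rows)
      }
    })
  if (is.null(truth$ubiquitous_mags)) truth$ubiquitous_mags <- character(0)

  # ---- yields and loss rates ---------------------------------------------
  yc <- .yield_curve(times, cfg$dna_yield_t0, cfg$biomass_fold_change)
  ds$dna_yields <- data.table::CJ(plot = plots, time_h = times)[
    , dna_ng_per_g := rep(yc, times = cfg$n_plots)][]
  ds$loss_rates <- data.table::data.table(
    time_h = times, loss_rate_copies_per_g_day = cfg$loss_rate)

  ds$truth <- truth
  class(ds) <- "wetup_dataset"
  ds
}

#' Generate SIP density-fraction profiles
#'
#' For each genome carried into the SIP assay, places a Gaussian buoyant-
#' density profile over the fraction grid: centered at the GC-implied light
#' density in the unlabeled (16O) treatment and at the density implied by
#' the genome's true atom fraction excess (via [density_for_ape()]) in the
#' 18O treatment. Recorded fraction densities get measurement noise
#' (`density_sd`); per-fraction abundances get lognormal noise
#' (`abundance_cv`). With both at zero the formula chain round-trips the
#' true enrichment to numerical precision.
#'
#' Active genomes become detectable at a planted first-detection time
#' (newly enriched genomes peak at 48 h); a few decoy genomes are detected
#' in only 2 of 3 tubes to exercise the triplicate rule.
#'
#' @param dataset output of [generate_community()].
#' @param config defaults to `dataset$config`.
#' @return the dataset with `sip_fraction_meta`, `sip_fraction_abund` and
#'   truth-ledger additions (`ape`, `sip_decoys`).
#' @export
generate_sip_profiles <- function(dataset, config = dataset$config) {
  cfg <- config
  ds <- dataset
  kept <- ds$truth$kept
  mags <- ds$mag_catalog$id
  stimes <- cfg$sip_time_points_h
  plots <- seq_len(cfg$n_plots)
  mids <- seq(cfg$density_range[1], cfg$density_range[2],
              length.out = cfg$n_fractions)

  if (length(kept) + length(mags) == 0L) {
    ds$sip_fraction_meta <- data.table::data.table(
      plot = integer(0), treatment = character(0), time_h = numeric(0),
      fraction_index = integer(0), density_gml = numeric(0),
      dna_ng = numeric(0))
    ds$sip_fraction_abund <- data.table::data.table(
      genome_id = character(0), plot = integer(0),
      treatment = character(0), time_h = numeric(0),
      fraction_index = integer(0), rel_abund = numeric(0),
      breadth = numeric(0))
    ds$truth$ape <- data.table::data.table(
      genome_id = character(0), type = character(0),
      true_ape = numeric(0), first_time = numeric(0))
    ds$truth$sip_decoys <- character(0)
    return(ds)
  }

  out <- with_seed(substream_seed(cfg$seed, "sip"), {
    genomes <- c(kept, mags)
    type <- c(rep("votu", length(kept)), rep("mag", length(mags)))
    active <- runif(length(genomes)) < cfg$frac_active
    ape <- ifelse(active,
                  runif(length(genomes), cfg$ape_range[1], cfg$ape_range[2]),
                  0)
    if (!is.null(cfg$true_ape)) {
      hit <- names(cfg$true_ape)[names(cfg$true_ape) %in% genomes]
      ape[match(hit, genomes)] <- cfg$true_ape[hit]
      active[match(hit, genomes)] <- cfg$true_ape[hit] > 0
    }
    # which genomes enter the SIP assay at all
    in_sip <- active | runif(length(genomes)) < 0.45
    # first time a genome is detectable; newly active genomes peak at 48 h
    fprob <- c(0.25, 0.4, 0.2, 0.15)[seq_along(stimes)]
    fprob <- fprob / sum(fprob)
    first <- ifelse(active,
                    stimes[sample.int(length(stimes), length(genomes),
                                      replace = TRUE, prob = fprob)],
                    stimes[1L])
    sel <- which(in_sip)
    decoys <- {
      cand <- sel[!active[sel]]
      if (length(cand) >= 2L && cfg$n_plots >= 3L)
        genomes[sample(cand, min(3L, length(cand)))]
      else character(0)
    }

    gc <- runif(length(genomes), cfg$gc_range[1], cfg$gc_range[2])
    w_light <- .qsip_const$gc_intercept + .qsip_const$gc_slope * gc
    w_lab <- density_for_ape(w_light, ape)
    a_base <- rlnorm(length(genomes), 0, 0.8)

    meta_rows <- list()
    ab_rows <- list()
    for (p in plots) {
      for (tr in c("16O", "18O")) {
        for (t_h in stimes) {
          g_idx <- sel[first[sel] <= t_h]
          # decoys drop out of one tube entirely
          if (length(decoys))
            g_idx <- g_idx[!(genomes[g_idx] %in% decoys & p == 1L)]
          if (length(g_idx) == 0L) next
          centers <- if (tr == "18O") w_lab[g_idx] else w_light[g_idx]
          wmat <- vapply(centers, function(cc) {
            pr <- dnorm(mids, cc, cfg$profile_sd)
            pr / sum(pr)
          }, numeric(length(mids)))          # fractions x genomes
          wmat <- wmat * a_base[g_idx][col(wmat)]
          if (cfg$abundance_cv > 0)
            wmat <- wmat * matrix(lognoise(length(wmat), cfg$abundance_cv),
                                  nrow(wmat))
          dens <- mids + if (cfg$density_sd > 0)
            rnorm(length(mids), 0, cfg$density_sd) else 0
          frac_mass <- rowSums(wmat)
          dna <- cfg$tube_dna_ng * frac_mass / sum(frac_mass)
          rel <- sweep(wmat, 1L, pmax(frac_mass, .Machine$double.xmin),
                       "/")
          br <- if (cfg$abundance_cv > 0)
            rbeta(length(g_idx), 38, 2) else rep(0.95, length(g_idx))
          meta_rows[[length(meta_rows) + 1L]] <- data.table::data.table(
            plot = p, treatment = tr, time_h = t_h,
            fraction_index = seq_along(mids), density_gml = dens,
            dna_ng = dna)
          ab_rows[[length(ab_rows) + 1L]] <- data.table::data.table(
            genome_id = rep(genomes[g_idx], each = length(mids)),
            plot = p, treatment = tr, time_h = t_h,
            fraction_index = rep(seq_along(mids), length(g_idx)),
            rel_abund = as.vector(rel),
            breadth = rep(br, each = length(mids)))
        }
      }
    }
    list(meta = data.table::rbindlist(meta_rows),
         abund = data.table::rbindlist(ab_rows),
         ape = data.table::data.table(genome_id = genomes, type = type,
                                      true_ape = ape,
                                      first_time = first)[in_sip | active],
         decoys = decoys)
  })
  ds$sip_fraction_meta <- out$meta
  ds$sip_fraction_abund <- out$abund
  ds$truth$ape <- out$ape
  ds$truth$sip_decoys <- out$decoys
  ds
}

#' Generate mortality-model inputs
#'
#' Combines the DNA-yield series with the realized viral read fraction of
#' each virome sample (viral DNA ng/g = yield x read fraction), the mean
#' genome length of the filtered vOTU catalog, and the 16S loss-rate
#' series.
#'
#' @param dataset output of [generate_community()].
#' @param config defaults to `dataset$config`.
#' @return the dataset with `mortality_inputs`: list of `per_plot` and
#'   `mean` input tables, `mean_genome_len_bp`, `rrna_copies_per_cell`,
#'   `burst_sizes`.
#' @export
generate_mortality_inputs <- function(dataset, config = dataset$config) {
  cfg <- config
  ds <- dataset
  vm <- ds$virome_mapping
  if (nrow(vm) == 0L) {
    ds$mortality_inputs <- list(
      per_plot = data.table::data.table(plot = integer(0),
                                        time_h = numeric(0),
                                        viral_dna_ng_per_g = numeric(0),
                                        loss_rate_copies_per_g_day =
                                          numeric(0)),
      mean = data.table::data.table(time_h = numeric(0),
                                    viral_dna_ng_per_g = numeric(0),
                                    loss_rate_copies_per_g_day = numeric(0)),
      mean_genome_len_bp = NA_real_,
      rrna_copies_per_cell = cfg$rrna_copies_per_cell,
      burst_sizes = cfg$burst_sizes)
    return(ds)
  }
  vrf <- vm[, .(viral_read_fraction =
                  sum(mapped_reads) / sample_total_reads[1L]),
            by = .(plot, time_h)]
  dt <- merge(ds$dna_yields, vrf, by = c("plot", "time_h"))
  dt <- merge(dt, ds$loss_rates, by = "time_h")
  dt[, viral_dna_ng_per_g := dna_ng_per_g * viral_read_fraction]
  per_plot <- dt[, .(plot, time_h, viral_dna_ng_per_g,
                     loss_rate_copies_per_g_day)]
  data.table::setorder(per_plot, plot, time_h)
  mean_in <- per_plot[, .(viral_dna_ng_per_g = mean(viral_dna_ng_per_g),
                          loss_rate_copies_per_g_day =
                            mean(loss_rate_copies_per_g_day)),
                      by = time_h]
  data.table::setorder(mean_in, time_h)
  ds$mortality_inputs <- list(
    per_plot = per_plot[], mean = mean_in[],
    mean_genome_len_bp =
      mean(ds$votu_catalog[id %in% ds$truth$kept, length_bp]),
    rrna_copies_per_cell = cfg$rrna_copies_per_cell,
    burst_sizes = cfg$burst_sizes)
  ds
}

#' Generate evidence tables: spacer hits, host predictions, lysogen
#' alignments, contig coverage, prophage coverage
#'
#' Plants `n_host_links` true CRISPR-spacer host links that pass the spacer
#' filter (plus decoys violating exactly one criterion each),
#' single-source taxonomic host predictions for most remaining vOTUs,
#' `n_lysogens` alignments passing every lysogeny threshold (plus decoys
#' failing exactly one each), cross-mapping contig-coverage records, and
#' prophage coverage records of which three are active. Expected outcomes
#' are recorded in the truth ledger.
#'
#' @param dataset output of [generate_community()].
#' @param config defaults to `dataset$config`.
#' @return the dataset with `spacer_hits`, `host_predictions`,
#'   `lysogen_alignments`, `contig_coverage`, `prophage_coverage` and truth
#'   additions (`spacer_truth`, `consensus_hosts`, `lysogens`,
#'   `active_prophages`).
#' @export
generate_evidence_tables <- function(dataset, config = dataset$config) {
  cfg <- config
  ds <- dataset
  kept <- ds$truth$kept
  out <- with_seed(substream_seed(cfg$seed, "evidence"), {
    hosts <- ds$truth$hosts
    known <- hosts[host_lineage != "unknown"]
    nl <- min(cfg$n_host_links, nrow(known))
    linked <- if (nl > 0L) known[sample(.N, nl)] else known[0L]
    hit_rows <- list()
    cons_rows <- list()
    src_types <- c("mag", "unbinned_contig", "spacer_db")
    for (i in seq_len(nrow(linked))) {
      v <- linked$genome_id[i]
      lin <- parse_lineage(linked$host_lineage[i])
      n_src <- sample(1:3, 1L)
      if (n_src == 1L || length(lin) < 2L) {
        srcs <- lineage_string(lin)
        expected <- lineage_string(lin)
      } else {
        d <- sample(seq_len(length(lin) - 1L), 1L)
        srcs <- c(lineage_string(lin),
                  replicate(n_src - 1L,
                            lineage_string(lin[seq_len(d)])))
        expected <- lineage_string(lin[seq_len(d)])
      }
      for (s in seq_along(srcs)) {
        sl <- sample(28:40, 1L)
        hit_rows[[length(hit_rows) + 1L]] <- data.table::data.table(
          spacer_id = sprintf("sp_%s_%d", v, s),
          source = sample(src_types, 1L), source_lineage = srcs[s],
          votu_id = v, mismatches = sample(0:1, 1L), gaps = 0L,
          align_len = sl, spacer_len = sl, evalue = 1e-8,
          should_pass = TRUE)
      }
      cons_rows[[length(cons_rows) + 1L]] <- data.table::data.table(
        votu_id = v, expected_lineage = expected)
    }
    # decoys: each violates exactly one spacer criterion
    pool <- setdiff(kept, linked$genome_id)
    nd <- min(3L, length(pool))
    if (nd > 0L) {
      dv <- sample(pool, nd)
      mk <- function(v, mm, gp, short) {
        sl <- 33L
        data.table::data.table(
          spacer_id = paste0("decoy_", v),
          source = "spacer_db",
          source_lineage = .lineage_pool[1L], votu_id = v,
          mismatches = mm, gaps = gp,
          align_len = sl - short, spacer_len = sl, evalue = 1e-8,
          should_pass = FALSE)
      }
      args <- list(c(2L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
      for (k in seq_len(nd))
        hit_rows[[length(hit_rows) + 1L]] <-
          mk(dv[k], args[[k]][1], args[[k]][2], args[[k]][3])
    }
    spacer_hits <- if (length(hit_rows)) data.table::rbindlist(hit_rows)
      else data.table::data.table(spacer_id = character(0),
                                  source = character(0),
                                  source_lineage = character(0),
                                  votu_id = character(0),
                                  mismatches = integer(0),
                                  gaps = integer(0), align_len = integer(0),
                                  spacer_len = integer(0),
                                  evalue = numeric(0),
                                  should_pass = logical(0))

    # single-source (sequence-taxonomy) predictions for ~93% of the rest
    rest <- setdiff(kept, linked$genome_id)
    singles <- if (length(rest))
      hosts[genome_id %in% rest][runif(.N) < 0.93 &
                                   host_lineage != "unknown"]
    else hosts[0L]
    host_predictions <- data.table::rbindlist(list(
      spacer_hits[should_pass == TRUE,
                  .(votu_id, source, lineage = source_lineage)],
      singles[, .(votu_id = genome_id, source = "sequence_taxonomy",
                  lineage = host_lineage)]))
    if (nrow(singles))
      cons_rows[[length(cons_rows) + 1L]] <-
        singles[, .(votu_id = genome_id, expected_lineage = host_lineage)]
    consensus_truth <- if (length(cons_rows))
      data.table::rbindlist(cons_rows)
      else data.table::data.table(votu_id = character(0),
                                  expected_lineage = character(0))

    # lysogen alignments
    nlys <- min(cfg$n_lysogens, length(kept))
    lys <- if (nlys > 0L) sample(kept, nlys) else character(0)
    pass <- data.table::data.table(
      votu_id = lys, contig_id = paste0("ctg_", seq_len(nlys)),
      pct_identity = runif(nlys, 92, 99),
      align_len = round(runif(nlys, 11000, 20000)),
      evalue = 1e-150, flank_len = round(runif(nlys, 12000, 30000)))
    dpool <- setdiff(kept, lys)
    ndl <- min(4L, length(dpool))
    dec <- if (ndl > 0L) {
      dv <- sample(dpool, ndl)
      base <- data.table::data.table(
        votu_id = dv, contig_id = paste0("dctg_", seq_len(ndl)),
        pct_identity = 95, align_len = 12000L, evalue = 1e-150,
        flank_len = 15000L)
      if (ndl >= 1L) base$pct_identity[1L] <- 85
      if (ndl >= 2L) base$evalue[2L] <- 1e-50
      if (ndl >= 3L) base$flank_len[3L] <- 8000L
      if (ndl >= 4L) base$align_len[4L] <- 6000L
      base
    } else pass[0L]
    lysogen_alignments <- data.table::rbindlist(list(pass, dec))

    # cross-mapping contig coverage: 3 candidates, 3 failures
    contig_coverage <- data.table::data.table(
      contig_id = paste0("mctg_", 1:6),
      contig_len = c(40000, 55000, 80000, 30000, 2000, 25000),
      covered_bases = c(12000, 1500, 30000, 900, 2000, 800))

    # prophage coverage: 3 active, rest near parity
    npro <- cfg$n_prophages
    mag_ids <- if (nrow(ds$mag_catalog)) {
      sample(ds$mag_catalog$id, npro, replace =
               npro > nrow(ds$mag_catalog))
    } else paste0("MAG_x", seq_len(npro))
    flank <- runif(npro, 4, 12)
    ratio <- c(rep(2.0, min(3L, npro)),
               runif(max(0L, npro - 3L), 0.8, 1.3))
    prophage_coverage <- data.table::data.table(
      mag_id = mag_ids, contig_id = paste0("pctg_", seq_len(npro)),
      start = 10000L, end = 45000L,
      prophage_cov = flank * ratio, flank_cov = flank)

    list(spacer_hits = spacer_hits, host_predictions = host_predictions,
         consensus_truth = consensus_truth,
         lysogen_alignments = lysogen_alignments,
         contig_coverage = contig_coverage,
         prophage_coverage = prophage_coverage,
         lysogens = lys,
         active_prophages = mag_ids[seq_len(min(3L, npro))])
  })
  ds$spacer_hits <- out$spacer_hits
  ds$host_predictions <- out$host_predictions
  ds$lysogen_alignments <- out$lysogen_alignments
  ds$contig_coverage <- out$contig_coverage
  ds$prophage_coverage <- out$prophage_coverage
  ds$truth$spacer_truth <- out$spacer_hits[, .(spacer_id, votu_id,
                                               should_pass)]
  ds$truth$consensus_hosts <- out$consensus_truth
  ds$truth$lysogens <- out$lysogens
  ds$truth$active_prophages <- out$active_prophages
  ds
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_community()], [generate_sip_profiles()],
#' [generate_mortality_inputs()] and [generate_evidence_tables()] in order.
#'
#' @param config a [scenario_config()].
#' @return a `"wetup_dataset"` with all tables and the full truth ledger.
#' @export
generate_dataset <- function(config = scenario_config()) {
  ds <- generate_community(config)
  ds <- generate_sip_profiles(ds)
  ds <- generate_mortality_inputs(ds)
  ds <- generate_evidence_tables(ds)
  ds
}

#' @export
print.wetup_dataset <- function(x, ...) {
  cat("<wetup_dataset>\n")
  cat(sprintf("  %d vOTUs (%d kept), %d MAGs, %d plots\n",
              nrow(x$votu_catalog), length(x$truth$kept),
              nrow(x$mag_catalog), x$config$n_plots))
  cat(sprintf("  virome mapping: %d records; SIP abundance: %d records\n",
              nrow(x$virome_mapping),
              if (!is.null(x$sip_fraction_abund))
                nrow(x$sip_fraction_abund) else 0L))
  invisible(x)
}
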