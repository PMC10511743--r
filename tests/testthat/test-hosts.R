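test_that("lineage parsing enforces the no-gap invariant", {
  expect_equal(parse_lineage("Bacteria;Actinobacteria"),
               c("Bacteria", "Actinobacteria"))
  expect_equal(parse_lineage("unknown"), character(0))
  expect_equal(parse_lineage(""), character(0))
  expect_equal(parse_lineage("Bacteria;Actinobacteria;;"),
               c("Bacteria", "Actinobacteria"))
  expect_error(parse_lineage("Bacteria;;Actinomycetia"), "gap")
  expect_error(parse_lineage("a;b;c;d;e;f;g;h"), "ranks")
})

test_that("spacer filter requires full-length, gap-free, <=1 mismatch hits", {
  hits <- data.frame(
    spacer_id = c("ok1", "gap", "short", "mm2"),
    mismatches = c(1, 0, 0, 2),
    gaps = c(0, 1, 0, 0),
    align_len = c(33, 33, 32, 33),
    spacer_len = 33)
  out <- filter_spacer_hits(hits)
  expect_equal(out$spacer_id, "ok1")
  expect_error(filter_spacer_hits(transform(hits, align_len = 40)),
               "exceeds")
})

test_that("consensus host follows the published worked examples", {
  expect_equal(
    consensus_host(c("Bacteria;Actinobacteria;ClassA",
                     "Bacteria;Actinobacteria;ClassB")),
    "Bacteria;Actinobacteria")
  expect_equal(consensus_host(c("Bacteria;Firmicutes",
                                "Archaea;Thermoproteota")), "unknown")
  single <- "Bacteria;Proteobacteria;Gammaproteobacteria"
  expect_equal(consensus_host(single), single)
  expect_error(consensus_host(character(0)), "predictions")
})

test_that("consensus host equals the pairwise-prefix oracle on random sets", {
  set.seed(23)
  pool <- list(
    c("Bacteria", "Actinobacteria", "Actinomycetia", "Streptomycetales"),
    c("Bacteria", "Actinobacteria", "Thermoleophilia"),
    c("Bacteria", "Proteobacteria", "Alphaproteobacteria"),
    c("Archaea", "Thermoproteota"))
  for (i in 1:100) {
    k <- sample(1:4, 1)
    lins <- vapply(seq_len(k), function(j) {
      base <- pool[[sample(length(pool), 1)]]
      paste(base[seq_len(sample(length(base), 1))], collapse = ";")
    }, character(1))
    expect_equal(consensus_host(lins), lca_brute(lins), label =
                   paste(lins, collapse = " | "))
  }
})

test_that("consensus host is order-invariant, idempotent, and prefix-valid", {
  set.seed(29)
  lins <- c("Bacteria;Actinobacteria;Actinomycetia",
            "Bacteria;Actinobacteria;Thermoleophilia;Gaiellales",
            "Bacteria;Actinobacteria")
  cons <- consensus_host(lins)
  for (i in 1:5)
    expect_equal(consensus_host(sample(lins)), cons)
  expect_equal(consensus_host(cons), cons)
  # output is a prefix of every informative input
  expect_true(all(startsWith(lins, cons)))
  # unknown predictions carry no information
  expect_equal(consensus_host(c("unknown", lins)), cons)
  expect_equal(consensus_host(c("unknown", "unknown")), "unknown")
})

test_that("host assignment summary nests phylum within domain", {
  asg <- data.frame(
    votu_id = paste0("v", 1:5),
    host_lineage = c("Bacteria;Actinobacteria", "Bacteria", "unknown",
                     "Bacteria;Proteobacteria;Gammaproteobacteria", ""))
  s <- host_assignment_summary(asg)
  expect_equal(s$domain, 3 / 5)
  expect_equal(s$phylum, 2 / 5)
  expect_lte(s$phylum, s$domain)
  # explicit denominator (unassigned vOTUs not in the table)
  s2 <- host_assignment_summary(asg, n_total = 10)
  expect_equal(s2$domain, 0.3)
  # none assigned
  expect_equal(host_assignment_summary(asg[0, ], n_total = 4)$domain, 0)
})

test_that("phylum fraction never exceeds domain fraction on random tables", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    lin <- sample(c("unknown", "Bacteria", "Bacteria;Actinobacteria",
                    "Bacteria;Proteobacteria;Alphaproteobacteria"),
                  n, replace = TRUE)
    s <- host_assignment_summary(data.frame(votu_id = seq_len(n),
                                            host_lineage = lin))
    expect_lte(s$phylum, s$domain)
  }
})
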