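Package: wetupvir
Title: Soil Virus Dynamics After Wet-Up: vOTU Trajectories, qSIP Activity,
    and Viral Contribution to Microbial Mortality
Version: 0.1.0
Authors@R:
    person("wetupvir", "developers", email = "wetupvir@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying soil virus dynamics following rewetting
    ("wet-up") of seasonally dry soil from tabular read-mapping and
    density-fraction inputs. Implements viral operational taxonomic unit
    (vOTU) catalog construction (multi-tool consensus prediction filter,
    size/circularity filter, ANI-based dereplication, integrase
    partitioning), breadth-based presence calling, relative abundance,
    richness and biomass trajectories with trend regressions, Bray-Curtis
    ordination, temporal response-category classification, CRISPR-spacer
    host filtering with consensus (lowest-common-ancestor) host taxonomy,
    quantitative stable isotope probing (qSIP) atom percent excess
    estimation with bootstrap confidence intervals, lysogeny evidence
    filters, and a virion-based model of the viral contribution to
    microbial mortality. A synthetic-data generator with a known truth
    ledger makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    stats,
    utils,
    vegan
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
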