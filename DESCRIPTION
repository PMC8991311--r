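Package: edimatch
Title: Expanded DNA Indirect Matching for Forensic STR Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying how forensic DNA databases develop
    investigative leads through indirect matching. Simulates
    multi-generation populations with autosomal STR, Y-STR, X and
    mitochondrial markers under Mendelian transmission with stepwise
    mutation and identical twinning; provides identity-by-descent
    kinship likelihood ratios, direct and partial matching, familial
    searching, and lineage search-key (Y-STR, mtDNA, male X) grouping
    of forensic profiles; runs the tiered expanded-indirect-matching
    workflow that classifies unsolved cases into direct hits, close-kin
    leads and genealogy referrals; and includes database-growth
    regression and cost-benefit calculators for database expansion,
    twin-based sibship extrapolation and national projections.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
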