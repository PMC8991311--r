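# edimatch

Forensic DNA databases solve crimes by matching crime-scene ("forensic")
STR profiles against indexes of known individuals. Roughly half of
forensic profiles never hit a known profile directly. **edimatch** is an
R package for studying the two ways the effective reach of such a
database can grow: physically, by adding known profiles (valued here
with database-growth regression and cost-benefit arithmetic), and
scientifically, by *indirect matching* — using the DNA that relatives
share to turn a solved case into an investigative lead for an unsolved
one. The package implements the expanded indirect-matching idea in which
lineage markers act as *search keys*: Y-STR haplotypes (paternal),
mitochondrial types (maternal) and male X profiles (maternal) group
forensic cases that may involve related perpetrators, and an autosomal
kinship likelihood ratio then decides whether a grouped pair is worth
reporting.

It is aimed at forensic statisticians and database policy analysts who
want a fully simulated, inspectable test bed: no real database extract
is required (or used).

## What is inside

* **Synthetic populations** — multi-generation pedigrees with
  Hardy-Weinberg founders; Mendelian autosomal/X transmission; paternal
  Y-STR haplotypes and maternal mitochondrial types; symmetric
  single-step STR mutation; identical twinning at 1/250 births; and
  offender / forensic / unidentified-remains database membership with
  familial enrichment (`simulate_population()`, `assign_memberships()`).
* **Kinship likelihood ratios** — for genotypes g1, g2 and a
  relationship with IBD (identity-by-descent) probabilities
  (k0, k1, k2),

  LR = [ k0 P(g2|0 IBD) + k1 P(g2|g1, 1 IBD) + k2 P(g2|g1, 2 IBD) ] / P(g2 | unrelated)

  with an optional Balding–Nichols coancestry (theta) adjustment
  (`single_locus_lr()`, `profile_lr()`, `rank_database()`).
* **Searching** — direct matching, partial-match scanning with a
  two-threshold kinship rule, ranked familial searching with Y-STR
  concordance flags, and lineage search-key grouping
  (`direct_search()`, `partial_match_scan()`, `familial_search()`,
  `key_match_groups()`).
* **The tiered workflow** — direct search, then key grouping plus
  kinship evaluation, classifying every forensic case as `direct_hit`,
  `close_kin_lead`, `igg_referral` or `unresolved` (`run_edim()`).
* **Business-case calculators** — database-growth regression,
  profiles-per-hit, expansion cost-benefit, identical-twin sibship
  extrapolation, national projection and the universal-database case
  (`fit_hits_regression()`, `expansion_cost_benefit()`,
  `twin_extrapolation()`, `edim_national_projection()`,
  `universal_db_case()`).

The numbered scripts under `analysis/` run the full study:
`01_database_growth.R`, `02_business_cases.R`,
`03_population_baseline.R`, `04_edim_workflow.R`, each writing its
tables under `results/`.

## Worked example

The canonical scenario: two full brothers have each left a forensic
profile in a separate unsolved sexual assault; one of them ("Bob") also
has a known offender profile from an earlier burglary conviction.

```r
library(edimatch)
bd <- make_bob_doug_fixture()
reports <- run_edim(bd$indexes, edim_config(key_order = "y_str"))
reports[, c("case_id", "outcome", "matched_record", "anchor_case",
            "log10_lr")]
#>     case_id        outcome matched_record anchor_case log10_lr
#> 1  case-bob     direct_hit          K-BOB        <NA>       NA
#> 2 case-doug close_kin_lead          K-BOB       F-BOB 6.206462
```

Bob's case hits his own offender record directly. Doug has no known
profile, so direct search fails — but the brothers share a Y-STR
haplotype, their cases fall into one Y-key group, and the sibling
likelihood ratio (log10 LR = 6.2, i.e. the genotype pair is about 1.6
million times more probable under full sibship than under unrelatedness)
clears the close-kin criterion. Doug's case is reported as a close-kin
lead anchored on Bob, the known individual around whom investigators
would build a family tree.

The business-case side is deterministic arithmetic on published inputs:

```r
expansion_cost_benefit(expansion_inputs())
#> benefit $1,872,336,534  cost $34,980,900  $53.52 per $1  ROI 5352%
twin_extrapolation(twin_inputs())
#> estimated sibling pairs 134,000; sibling-match chance 19.14%
edim_national_projection(twin_inputs())
#> +9,563 cases solved/yr; 250,741 further crimes prevented; $109.18B saved
```

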