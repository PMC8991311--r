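---
title: "Expanded indirect matching: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanded indirect matching: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edimatch)
```

This vignette is the package's account of its science: the genetic and
statistical models it implements, the parameters that matter, what the
synthetic data do and do not emulate, and the choices made where the
design was genuinely open.

## The problem

A forensic DNA database holds STR profiles of known individuals
(offenders, arrestees, and — searchable on both sides — unidentified
human remains) and forensic profiles from unsolved crime scenes. Direct
searching associates a forensic profile with a known individual only
when the same person (or an identical twin) is in the database.
Indirect matching extends the database's reach to relatives: a profile
that *almost* matches, or that shares a lineage marker, may point to a
sibling, parent or child of the person who left the crime-scene sample.
The package implements the whole chain — population and database
simulation, kinship statistics, searching, and the tiered workflow that
classifies each unsolved case — plus the cost-benefit arithmetic used to
argue the value of database growth.

## Kinship likelihood ratios

At one autosomal locus with genotypes $g_1$ and $g_2$, a relationship
hypothesis $H$ is parameterised by Cotterman coefficients
$(k_0, k_1, k_2)$ — the probabilities that the pair shares 0, 1 or 2
alleles identical by descent (IBD). The likelihood ratio against
unrelatedness is

$$\mathrm{LR} = \frac{k_0\,P_0(g_2) + k_1\,P_1(g_2 \mid g_1) +
k_2\,P_2(g_2 \mid g_1)}{P_0(g_2)},$$

where $P_0$ is the genotype probability for an unrelated individual,
$P_1$ conditions on one IBD allele copied uniformly from $g_1$, and
$P_2$ is the indicator that $g_2 = g_1$. Multi-locus ratios multiply
across loci (computed as sums of $\log_{10}$ values). The coefficients
are exact Mendelian enumerations: parent–child $(0,1,0)$, full siblings
$(1/4, 1/2, 1/4)$, half siblings $(1/2, 1/2, 0)$.

**Coancestry.** With `theta > 0`, every "fresh" (non-IBD) allele draw
uses the Balding–Nichols conditional form
$p'(a) = \{\theta\,n_a + (1-\theta)\,p_a\}/\{1 + (n-1)\,\theta\}$ given
the $n$ alleles already observed (the two alleles of $g_1$, plus the
first allele of $g_2$ when drawing the second). IBD copies are not new
draws and add no conditioning counts. Because the underlying Dirichlet
urn is exchangeable, the resulting conditional genotype distributions
are proper — the tests verify by exhaustive enumeration that they sum
to 1 and that $E[\mathrm{LR} \mid \text{unrelated}] = 1$ exactly, for
$\theta = 0$ and $\theta > 0$. `theta = 0` (the default) reduces to the
plain product-of-frequencies form and is cross-checked against an
independently coded textbook pattern-case oracle at $10^{-12}$.

**Mutation and exclusions.** Mutation is deliberately *not* folded into
the likelihood ratio. A zero single-locus ratio (e.g. opposite
homozygotes under parent–child) is counted as an exclusion; with any
exclusion the combined ratio is reported as 0 and its log as undefined.
Callers that need robustness to germline mutation use the
exclusion-tolerant variant (the product over non-excluded loci), which
the partial-match confirmatory check relies on. This keeps the statistic
transparent: the user sees how many loci excluded rather than having a
mutation model silently absorb them.

## The synthetic population

No public database extract exists at individual level, so the study runs
on simulated populations (`simulate_population()`):

* **Founders** are drawn under Hardy–Weinberg from the frequency set;
  each founder gets a unique mitochondrial label.
* **Transmission**: each child receives one autosomal allele per locus
  from each parent; sons copy the father's Y haplotype; all children
  copy the mother's mitochondrial label; sons take one maternal X allele
  per locus, daughters one maternal pick plus the father's X.
* **Mutation** is symmetric single-step (±1 repeat, reflecting at ladder
  ends) at per-locus, per-meiosis rates `mut_auto` and `mut_y`
  (default 0.002, typical of forensic STR loci); the mitochondrial label
  is replaced wholesale with probability `mut_mt` (default 0.001).
  Reflection keeps mutated alleles on the frequency ladder, so every
  simulated allele has a defined frequency.
* **Twinning**: each birth becomes an identical (monozygotic) twin pair
  with probability `twin_rate = 1/250`, the approximate human incidence;
  twins are full profile clones. Dizygotic twins are ordinary siblings
  and are not modelled separately.
* **Mating** pairs males and females randomly within a generation with a
  best-effort reshuffle to avoid full-sibling matings; offspring counts
  are Poisson with mean `mean_children = 2.2`, a round
  replacement-or-above fertility chosen so three–four generations yield
  a stable caseload.

Database membership (`assign_memberships()`) is independent Bernoulli
per role, after which first-degree relatives of included individuals are
re-drawn with odds multiplied by `familial_enrichment`, reflecting the
observed familial clustering of database membership. Forensic records
retain their true source id purely for evaluation against ground truth.

**What the generator does not emulate:** mixtures, allelic dropout and
degradation, population substructure or assortative mating, linkage
between loci (all loci segregate independently, including X loci),
immigration, or age structure. Passing tests therefore demonstrate the
correctness and calibration of the statistics and workflow under clean
single-source profiles — not performance on degraded casework samples.

## Frequency panels

`generate_frequency_set()` builds synthetic panels; the study baseline is
20 autosomal + 17 Y(+ 4 X where used) loci with 8 consecutive integer
repeat alleles and Dirichlet(2)-distributed frequencies. That gives
expected heterozygosity $1 - 3/17 \approx 0.82$, in the range of real
forensic autosomal STR panels. Allele labels are decimal repeat counts
as canonical text (trailing zeros stripped, so `9.30` equals `9.3`);
comparison is on the numeric repeat count.

## Searching and the tiered workflow

* **Direct search**: equality at every mutually typed autosomal locus
  with at least `min_shared_loci = 15` compared. Identical twins match
  by construction — STR profiles cannot separate them.
* **Partial matching** follows the two-threshold rule: a pair sharing at
  least `allele_share_threshold` alleles and not directly matching is
  emitted when it passes the primary combined-LR threshold under one
  first-order hypothesis (full sibling or parent–child) *and* a lower
  confirmatory threshold under the complementary hypothesis, the latter
  computed on the exclusion-tolerant ratio (a true sibling pair carries
  at least one strict parent–child exclusion locus about 88% of the time
  at 20 loci, so a strict confirmatory ratio would reject nearly all
  true siblings).
* **Familial search** ranks a known index under both first-order
  hypotheses, merges by the larger ratio, and flags candidates whose Y
  haplotype differs beyond the mutation allowance as `Y-excluded` —
  coincidental autosomal similarity, not a paternal relative.
* **Search-key grouping** links forensic cases sharing a lineage key:
  Y haplotypes equal up to `y_max_mismatch_loci = 1` single-step
  differences (one germline mutation), exact mitochondrial labels, or
  identical male X profiles. Groups are connected components of that
  relation; autosomally identical (same-source) records are deduplicated
  first. Male X identity is a corroborating signal only: brothers draw
  each X allele from the mother's two copies, so they differ wherever
  she is heterozygous and they drew different copies.
* **The tiered workflow** (`run_edim()`) tries direct search first, then
  each key in `key_order`. An unsolved case whose key-group mate's case
  was directly solved, with pair log10 LR at or above
  `close_kin_log10_lr = 3`, becomes a close-kin lead anchored on that
  solved case's known individual. Key-matched cases without such an
  anchor are referred for investigative genetic genealogy (a terminal
  flag — consumer-database searching is out of scope) or left
  unresolved. Key groups are computed over *all* forensic cases so that
  a solved case can anchor an unsolved one, which is exactly the
  two-brother worked scenario; one report is issued per forensic case.
  Unidentified-remains records anchor leads like offender records by
  default (`uhr_as_known = TRUE`), since they are searchable on the
  known side; the flag exists because policy on this differs.

### Calibrated thresholds

The policy defaults were set from pilot simulations at the 20-locus,
8-allele baseline (600 simulated pairs per condition) and are design
choices of this package, not any jurisdiction's policy:

| parameter | default | basis |
|---|---|---|
| `allele_share_threshold` | 18 | 99th percentile of unrelated-pair sharing; below the 1st percentile for true siblings |
| `lr_threshold_sib`, `lr_threshold_pc` | 100 | ~95% of true sibling pairs above; no unrelated pair in 600 came near |
| `lr_confirm` | 10 | passed by >99% of true siblings on the tolerant complementary ratio |
| `close_kin_log10_lr` | 3 | a conventional reporting threshold; ~87% of true sibling pairs clear it at 20 loci |

## The calibrated uplift experiment

The identical-twin extrapolation argues: twin pairs are found by
duplicate-profile quality control; twinning has known incidence 1/250;
so 536 observed twin pairs in a 700,000-entry database imply about
134,000 sibling pairs, i.e. a 19.14% chance that a case's source has a
sibling in the database. `simulate_edim_calibration()` realises that
claim generatively: each unsolved case's perpetrator has, with
probability 134,000/700,000, a full brother whose own case is directly
solvable, and the workflow must recover those cases as close-kin leads
through the Y key. The measured uplift converges to the analytic rate
times the kinship detection probability at the close-kin threshold
(~0.87), i.e. about 16.8% against the analytic 19.14% — the gap is the
price of requiring log10 LR ≥ 3 rather than any evidence of sibship.
The acceptance run uses 50 replicates of 200 cases; the test suite's
smaller version checks the detected count against exact binomial bounds.

## Business-case arithmetic

The calculators reproduce published point arithmetic with an explicit
rounding ledger, since the source presentations round silently:
regression slopes are displayed to 4 decimals (half-up) before taking
the reciprocal; hit rates and per-dollar ratios to 2 decimals; solved
and prevented counts are integer parts (floor); benefits are rounded to
the nearest dollar; the sibling-match percentage enters the national
projection as its two-decimal display value (a four-decimal proportion).
Two source inconsistencies are handled by computing from stated inputs:
the expansion table's printed analysis cost disagrees with its own
inputs by $1M (the computed $34,980,900 is used — it alone reproduces
the table's $53.52 per-dollar ratio), and the universal-database
narrative's trillion-scale totals disagree internally by factors of
10–100 (the computed ~$668B benefit chain is reported instead; only the
58,539 additional solved cases figure is treated as reliable).

## Numerical and degenerate-input choices

Ranking sorts on summed log10 ratios with ties broken by ascending
record id; excluded pairs sort below all non-excluded ones.
Zero-probability inputs error early with the offending field named.
Empty indexes and header-only files yield empty, correctly typed
results. All generators take explicit integer seeds and restore the
caller's RNG state, so identical seeds give bit-identical populations,
memberships and reports. Problem sizes in the tests — ~10,000-individual
populations for transmission invariants, ~10,000 births for twin
incidence, 200 ranking replicates against 999-profile indexes, 50
calibration replicates of 200 cases — were chosen to give stable
statistics at desk scale.

## Known limitations

Single-source profiles only; no mixture interpretation or probabilistic
genotyping. Kinship hypotheses cover the first-order set plus half
siblings; more distant kinship is deferred to the genealogy referral.
Mitochondrial types are opaque labels, not sequences, so near-match
(heteroplasmy-tolerant) mitochondrial searching cannot be expressed.
The economic models are point arithmetic with no uncertainty intervals,
as in their source presentations.
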