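---
title: "Auditing seafood mislabeling with COI barcodes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing seafood mislabeling with COI barcodes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishaudit)
```

`fishaudit` turns a market survey of seafood — samples purchased under
commercial names, barcoded at the mitochondrial COI locus — into
mislabeling rates, substitution patterns, and the statistics used to test
supply/demand explanations of seafood fraud. This vignette documents the
model behind each stage, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology is genuinely open.

## 1. The audit model

A **survey sample** is one purchased specimen: provenance metadata (city,
vendor type ∈ {fish market, grocery store, restaurant}, source of the name
∈ {label, menu, verbal}) plus the commercial name the vendor used and the
sample's COI sequence. A **catalog** maps commercial names to the species
legitimately sold under them. The package's central definition:

> a sample is *mislabeled* when the genetically identified species is
> accepted for the vendor's commercial name in **none** of the supplied
> catalogs.

This union rule is deliberately conservative: each additional catalog can
only move samples from mislabeled to correct, never the reverse — a
monotonicity property asserted in the test suite.

For every focal commercial name the audit reports the full
mislabeling/substitutability accounting. With verbal sample number $V$
(samples sold under the name), correctly labeled $C$, mislabeling
frequency $M$, and substitutability frequency $S$ (mislabeled samples
*elsewhere* whose substitute species is accepted under the focal name):

$$V = C + M, \qquad \text{confirmed} = C + S, \qquad
\text{over/sub} = V - \text{confirmed},$$

with mislabeling percentage $100M/V$ and over/sub-representation
percentage $100\,(V-\text{confirmed})/\text{confirmed}$. Confirmed
samples proxy the *net availability* of a species in the market;
mislabeling diversity (distinct substitute species sold under the name)
and substitutability frequency/diversity proxy *demand*. These identities
hold in exact integer arithmetic on every dataset, which the tests verify
on random count tables and on full simulated surveys.

Two further products are derived from the mislabeled calls: the
**substitution network** (one edge per substitute-species × commercial-name
pair, weighted by count; a name's in-degree is its mislabeling diversity)
and the **category matrix**, which aggregates edges over three broad origin
groups — wild marine bony fish, wild elasmobranchs, and
freshwater/anadromous aquaculture fish — oriented (substitute category,
labeled-name category).

## 2. Barcode identification

### Percent identity

`pairwise_identity()` scores a global alignment with match +1, mismatch
−1 and linear gap −2, with terminal gaps free **on the longer sequence
only**: the shorter sequence must be contained in the alignment. Identity
is $100 \times \text{matches}/\text{aligned columns}$, the free
terminal-gap columns excluded from the denominator and internal gap
columns counted as non-matches. Both strands are always tried; queries
need not be oriented.

The containment requirement is a deliberate design decision. Under a
fully ends-free alignment with this scoring, the optimal alignment of two
*unrelated* sequences degenerates to a short perfect overlap — a dozen
matching bases score higher than any honest full-length alignment — and
"identity" saturates at 100% for strangers. Requiring the shorter
sequence to align in full preserves what the statistic is for: a 550-bp
barcode read is compared against a full-length reference without being
penalized for the missing ends, while unrelated sequences score near the
random-alignment baseline (~50–60%). The implementation rides on
`Biostrings::pairwiseAlignment(type = "local-global")`; the test suite
checks it against an independently written dynamic-programming aligner
with the same semantics.

### Search and consensus

`search_library()` ranks entries by identity (stable tie order by
accession) behind a 12-mer prefilter: only entries sharing at least one
k-mer with the query (either strand) are aligned. On barcode-like data
the prefilter is a pure speed-up — oracle equivalence with exhaustive
search is a tested invariant — and a query sharing no 12-mer with any
entry returns an empty, flagged hit list rather than a forced guess.

`consensus_assign()` implements the threshold-consensus rule
(species-level threshold 98% identity, configurable):

* all libraries agree on one species at ≥ threshold → species-level call;
* libraries disagree but within one genus, all ≥ threshold → the single
  species with the highest identity, noted as genus-level agreement;
* an exact within-library tie at the top (identities equal after rounding
  to 0.01%, the reproducibility scale of the similarity scores) → all
  tied species are reported as a multi-species candidate set;
* best identity < threshold → genus-level confidence if ≥ the genus floor
  (default 90%), otherwise unidentified.

Two open points were resolved as follows. The threshold is applied **per
library**, not to the cross-library maximum; the cross-library maximum
only breaks genus-level agreement. And a library whose best hit falls
below the threshold *abstains* when another library meets it (recorded in
the notes), rather than vetoing the call — the strict per-library reading
would let a single library with a missing reference record drag every
affected sample to genus level. Libraries that disagree at ≥ threshold
across *different* genera — a case that clean reference data should never
produce — keep both species as candidates with a "library conflict" note.

The genus floor of 90% is a convention: published surveys report cases in
the low nineties as reliable only at genus level without stating a
cutoff, so the floor is exposed as a parameter.

### Calling

Generic names are excluded before calling; unidentified samples are
excluded from species-level tallies; a multi-species candidate set counts
as *correct* if **any** candidate is accepted (conservative — ties never
inflate mislabeling). When mislabeled, the substitute species is the
highest-identity candidate, ties broken alphabetically. A commercial name
found in no catalog is reported as a distinct `unknown_name` status, not
silently counted as mislabeled: with a name-to-species mapping absent,
neither verdict is justified.

Genus-level identifications are called using the genus-representative
candidate and flagged in the notes, so sensitivity re-runs can exclude
them.

## 3. The statistics layer

* **Wilson score intervals** for every rate, with the normal quantile
  computed from `alpha` (default 0.05), never hard-coded. The interval
  always contains $k/n$; empirical coverage over 2000 binomial draws at
  $p \in \{0.1, 0.3, 0.5\}$, $n \in \{50, 376\}$ is asserted within
  [93%, 97%].
* **2×2 Pearson chi-squares without continuity correction** — fixed
  behavior, matched to the convention of the surveys this package serves
  and verified in the tests against a direct $\sum (O-E)^2/E$
  computation. Pairwise comparisons across strata are reported
  unadjusted, as is conventional in this literature; a Holm-adjusted
  column is available (`adjust = TRUE`) but off by default.
* **OLS regressions** of per-name mislabeling percentage on the
  availability/demand proxies, $R^2$ as squared Pearson correlation,
  two-sided $p$ from $F(1, n-2)$. Landings/import volumes span orders of
  magnitude across species, so `availability_regression()` always
  regresses on $\log_{10}(\text{tons})$; the base does not affect $R^2$.

Excluded calls (generic, unidentified, unknown-name) never enter a rate
denominator.

## 4. What the synthetic generator emulates

The generator exists so that every downstream stage has ground truth.
Its default conditions reproduce the structure of a 2018 three-city
Mexican market survey:

* **Sampling frame**: 376 analyzable samples under 48 commercial names
  (plus 7 under the generic name *pescado*); 18 focal names carry the
  survey's exact verbal sample counts (316 samples) and its per-name
  mislabeling rates as their true mislabeling probabilities; the 30 rare
  names share the residual rate (17/60). City margins 120/150/106 and
  vendor margins 107/78/191; name sources drawn at 22/33/45%.
* **Species pool**: 180 available species across the three origin
  categories, supply-weighted by a Zipf law with exponent 1.3. The pool
  is deliberately larger than the ~100 species such a survey observes:
  the market draws on a regional fauna of thousands of species, and the
  heavy singleton tail (about half of observed species seen exactly
  once) only arises when many rare species are available but seldom
  drawn. With these defaults a simulated survey observes ~95–110
  species, ~50 of them substitutes, with a singleton fraction near 0.45.
* **Sequences**: one frame-clean anchor per species under the vertebrate
  mitochondrial code (frame 1 only — COI barcodes are mid-gene, so no
  start codon is required). Congeners derive from a shared random genus
  ancestor, each species mutated on its own disjoint, evenly spread
  position set, which guarantees every inter-species pair at least
  $1.5 \times$ the minimum divergence (default 0.05) in scattered
  differences that alignment gaps cannot bypass, while congeners remain
  far more similar to each other (~92.5% identity) than to other genera
  (~55%). Queries are anchors mutated at a within-species divergence
  drawn uniformly from [0, 0.01] — the conventional COI barcode-gap
  arrangement, keeping intra- and inter-species divergence separated by
  the 98% rule with margin.
* **Substitution structure**: substitute species are drawn from supply
  weights tempered by an exponent `substitution_gamma` (default 0.8 in
  the study conditions; 1 would be purely availability-driven),
  re-normalized over the species *not* accepted for the focal name. The
  tempering reproduces the observed substitute spectrum: a few
  high-supply species dominate while a long tail of rare species each
  substitutes once or twice.
* **Reproducibility**: a single PRNG stream seeded once per run; the
  same (pool, design, seed) produces byte-identical output.

`mutate_sequence()` makes exactly `round(divergence × length)`
substitutions (never indels). When a drawn substitution would create an
in-frame stop codon, the replacement *base* is re-drawn among the
remaining non-stop alternatives at the same position — at any position of
a non-stop codon at least one non-stop substitution exists under the
vertebrate mitochondrial code (checked by enumeration of the code), so
the requested substitution count is always achieved exactly and the
operation cannot fail.

**What it does not emulate** — and therefore what passing tests do not
show about real data: no indels, chimeras, heteroplasmy, sequencing
error profiles or chromatogram ambiguity; no incomplete lineage sorting
or introgression (real *Thunnus* barcodes can be genuinely
indistinguishable; synthetic congeners tie only when constructed to); no
correlation between vendor type and name source (labels in shops, menus
in restaurants are sampled independently); reference-library taxonomy is
correct by construction, whereas real GenBank/BOLD records carry
misannotations. The optional `unidentifiable_rate` produces unrelated
(frame-clean but foreign) sequences as a stand-in for the
bacterial-contamination failures of real surveys, not a sequencing-error
model.

## 5. Numerical choices and degenerate inputs

* Percentages are reported to 2 decimals, rounded half away from zero
  (base R's banker's rounding would turn 2.5 into 2).
* The over/sub-representation percentage is emitted as missing when
  confirmed samples are zero — never ±Inf.
* When a substitute species is accepted under several audited names, its
  substitution events are credited once, to the accepting name with the
  most verbal samples (alphabetical on ties) — double counting would
  break the network/audit consistency identities; `credit = "all"`
  switches to crediting every accepting name.
* Exact identity ties are defined after rounding to 0.01%.
* Empty reference libraries, zero-margin 2×2 tables, zero-variance
  predictors, non-positive tonnage under the log transform, and survey
  names with certain mislabeling but no possible substitute all fail
  with explicit errors rather than propagating NaN.
* `audit_name()` of a name absent from the calls returns an all-zero
  audit row, since "never seen" is an answer, not an error.

## 6. Problem sizes in the tests

The suite runs entirely on synthetic data built at test time: corpora of
50 species × 20 queries for the search-equivalence and
self-identification properties; 200 replicated surveys of 50–100 samples
for mislabeling-probability recovery; 2000 binomial draws per condition
for Wilson coverage; 200 simulated 2×2 tables for the chi-square type-I
rate; 20 seeds of the full 383-sample default survey (sequence noise
disabled) for the species-spectrum property. These sizes were chosen to
make sampling noise small relative to the asserted bands while keeping
the default test run in a few minutes. `scripts/acceptance.R` runs one
complete 383-sample pipeline with identification against two 180-entry
libraries.

## 7. Known limitations

* Identity is computed from one optimal alignment; among co-optimal
  alignments the reported identity follows the aligner's tie-breaking.
* The k-mer prefilter's oracle equivalence is a tested property of
  barcode-like data (high-identity relatives always share 12-mers), not
  a mathematical guarantee for arbitrary inputs.
* Name matching is exact after normalization (case, diacritics,
  whitespace); misspelled vendor names are out of scope by design.
* The audit framework measures availability and demand *within the
  survey*; its proxies inherit the survey's sampling design and are not
  population estimates.
* The landings regression supports one predictor year; time-series
  modeling of landings is out of scope.
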