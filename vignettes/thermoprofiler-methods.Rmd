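---
title: "Methods: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoprofiler)
```

`thermoprofiler` analyses the downstream, tabular half of a geothermal
metagenome survey: alignment hit tables, mapping summaries and count
matrices in; taxonomy assignments, diversity statistics, enrichment
tables and pathway-completeness reports out. This vignette documents
the statistical machinery, the conventions chosen where several were
defensible, and what the synthetic validation does and does not
demonstrate.

## Taxonomic assignment by LCA

Queries (metagenomic ORFs or OTU representative sequences) arrive as
BLAST-style tabular hits against references of known lineage. Hits are
first filtered at e-value ≤ 1e-5 (inclusive) and alignment coverage
≥ 80% of the reference gene length. Applying the coverage rule to hits
lacking a reference length is an error, never a silent pass — a hit
file in the 12-column dialect simply cannot be coverage-filtered. In
amplicon (OTU) mode the coverage filter is disabled: the stated rule
applies to ORF alignments, and we do not extrapolate it.

The best-hit set is every filtered hit whose bit score falls within
`bitscore_tie_tol` of the maximum (default 0: exact ties, matching the
idea of "multiple best hits with equal scores"; real aligners emit
near-ties, so the margin is configurable). The candidate lineage is the
deepest rank prefix shared by all best hits, and the final rank is the
shallower of that LCA rank and the rank permitted by the maximum
identity among best hits:

| best identity | deepest permitted rank |
|---|---|
| ≥ 95% | species |
| ≥ 85% | genus |
| ≥ 65% | phylum |
| < 65% | unassigned |

A single 70% hit to a species is therefore reported at phylum, not at
family: the three identity thresholds name three ranks, and we take
them at face value. Intermediate ranks (class, order, family) still
occur — when tied best hits at ≥ 85% identity agree only down to one of
them. The alternative convention (allowing family/order/class at the
65% floor) was considered and rejected because the threshold wording
names phylum as the level that 65% identity supports.

The monotonicity this scheme implies — raising thresholds can never
deepen an assignment — is asserted as a property test, and the whole
procedure is checked against a brute-force lineage-intersection oracle
on randomly generated hit sets.

## Counting rules and functional quantification

Gene counting from paired-end mapping summaries accepts exactly two
cases: both mates on the same gene (contributing 2 reads) and one mate
mapped with the other unmapped (contributing 1). Pairs split across two
genes contribute nothing — fractional assignment is not attempted,
since the accepted cases are unambiguous and the split case is not.
Because "a pair counts 2" versus "a pair counts 1" doubles every count,
the unit is explicit (`unit = "reads"` default, `"fragments"`
available). Genes totalling fewer than 10 reads across samples are
removed as ambiguous.

Functional annotation takes the single best hit per gene, accepted only
at bit score ≥ 60 and e-value ≤ 1e-6 (both inclusive). KO relative
abundance divides each sample's summed KO counts by that sample's
*annotated* total: unannotated genes are excluded from the denominator,
so the columns describe composition of the annotated gene pool. A
sample with no annotated counts is an error naming the sample.

Genome quantification counts concordant pairs with both mates at ≥ 90%
identity, scales by 2 (reads per pair), divides by genome length and by
library size, and renormalises columns to proportions. The final
proportion scale is a choice — the normalisation endpoint is otherwise
underdetermined — and makes samples directly comparable; the
pre-normalisation rates are available via `relative = FALSE`.
"Library size" is taken as the QC-passed read total supplied by the
caller, not the mapped total.

## Diversity

Rarefaction subsamples each count column without replacement
(multivariate hypergeometric, by sequential conditional draws) at each
requested depth, default 100 to 2.2 million in steps of 0.1 million,
averaging observed features over 10 iterations; every
(sample, depth, iteration) triple draws from its own substream of the
master seed, so adding a depth never perturbs another's draws. Depths
beyond a sample's total yield `NA` rather than extrapolation.

Shannon diversity uses base 2 by default (the common amplicon-pipeline
convention); gene-level analyses conventionally use natural log, and
the base is an explicit argument everywhere it matters. Pielou's
evenness for a single-species community is defined as 0 (its H/log S
form is 0/0 there).

Hellinger distance is the Euclidean distance between square-rooted
column proportions (bounded by √2); unweighted UniFrac is the fraction
of branch length, over branches leading to any leaf present in either
community, that leads to leaves of exactly one. Both are checked
against independent implementations (vegan, picante) and, for UniFrac,
against a brute-force branch enumeration oracle. PCoA is classical
metric scaling of the double-centred squared distances; negative
eigenvalues are reported as-is (a non-Euclidean input is a fact worth
surfacing, not clipping), with explained fractions taken over the
positive part of the spectrum.

## The exact rank-sum test and its tie convention

With three samples against four, asymptotic Mann-Whitney p-values are
meaningless; the test enumerates all C(n, nₐ) group-label assignments
over the observed mid-rank multiset (up to a combined n of 12, beyond
which a seeded sample of assignments is used). The one-tailed p is the
*smaller tail* of group A's U statistic under that null, and the
two-sided p doubles it, capped at 1.

Two details earn their keep here. First, tail-doubling (rather than
summing both tails of the asymmetric tied null) is the convention that
reproduces the printed field-sample comparisons exactly: temperature
p = 0.057, pH p = 0.571, TDS p = 0.171 from the seven on-site
measurements. Second, the smaller-tail formulation matters under ties:
mid-ranks can make U's permutation distribution asymmetric, so the
superficially equivalent "P(U ≤ min(U_A, U_B))" can fall below the
distribution's support entirely and return p = 0; the smaller-tail form
is bounded below by 2/C(n, nₐ), as an exact test must be.

Tukey multiple comparisons (for observed species across the three
temperature classes) use one-way ANOVA pooled variance with
studentized-range adjustment. Zero pooled variance with unequal means
is reported as p = 0 with a warning rather than NaN. The temperature
classes are moderately high (40–55 °C), high (55–75 °C) and extremely
high (≥ 75 °C); the boundary value 55 °C is assigned to the moderate
class by default (the two stated ranges both name it), and the choice
is a documented argument.

## Enrichment

The per-KO odds ratio is a stated convention, not a derived quantity:
group-mean relative abundances p̄ₐ, p̄_b are treated as odds,
OR = [p̄ₐ/(1−p̄ₐ)]/[p̄_b/(1−p̄_b)], with a pseudocount ε = 1e-6
substituted for an exactly-zero group mean so the ratio stays finite.
It is simple, symmetric under group exchange, and monotone in the
abundance difference. The enrichment call is OR > 1 by default, with a
configurable margin since any hard cut here is arbitrary.

Pathway-level Fisher tests tabulate enrichment-called KOs in/out of
each pathway by direction, with the two-sided exact hypergeometric p,
BH-FDR across pathways, and a log odds (Haldane 0.5 correction when a
cell is zero) whose positive sign marks the first group — KO counts,
not abundance-weighted counts, populate the table, since the quantity
of interest is the proportion of enriched KOs.

Reporter scores convert per-KO p-values (from the exact rank-sum test
across samples) to z = Φ⁻¹(1−p), score a pathway as Σz/√k, and
standardise against μₖ, σₖ estimated from 1000 seeded draws of k KOs
from the analysis universe. Two clamps keep z finite: p = 0 (warned)
rises to the machine minimum and p = 1 — common under a discrete exact
null, where many KOs sit at the null's upper bound — is capped at
1 − 1e-10. A degenerate background (σₖ = 0, e.g. every KO at the same
p) is an error, not a division by zero. The reported direction is the
sign of the abundance-weighted mean direction of member KOs.

## Correlation screening

Each feature's per-sample abundance is correlated with temperature by
Spearman's ρ (Pearson on mid-ranks). For n ≤ 8 the two-sided p is exact
by enumeration of all n! orderings (5 040 at the study's n = 7 — the
smallest attainable p is 2/5040 ≈ 4e-4); permuting one variable leaves
its rank multiset fixed, so the whole null collapses to one matrix
product over permuted rank sums, memoised per n. Beyond n = 8 a seeded
Monte Carlo null is used. Features pass when BH-FDR ≤ 0.05 *and*
|ρ| ≥ 0.7; constant features are reported as not assessable rather than
given ρ = 0.

## The synthetic generator: what it emulates, and what not

`synth_scenario()` defaults encode the study design itself: seven
samples in two site groups (3 + 4) carrying the seven recorded on-site
temperature, pH and TDS values — so the group statistics above are
reproduced from the default design with no further input. Taxon
abundances are log-normal (σ = 0.5 by default, a typical
between-sample dispersion for microbial relative abundances) with
multinomial read allocation, which keeps every count column summing
exactly to the requested depth. Planted temperature-correlated taxa
follow exp(±2.5·z(T) + σ·ε); planted enriched pathways have their KOs'
expected gene counts multiplied by the stated fold in the stated group.
Hit tables give each query a unique best hit to its own reference
(97% identity) plus decoys to a congener (88%) and a same-family
neighbour (70%), so LCA has a known right answer and species-level
accuracy on these bundles must be 100%. Each artifact draws from its
own substream of the master seed, so adding one never perturbs another.

What the generator does *not* emulate: sequence content and alignment
noise (hit identities are stylised, not drawn from an error model),
chimeras and contamination, compositional coupling beyond the shared
multinomial denominator, phylogenetic signal in abundances (the tree is
a random coalescent, independent of the abundance model), and database
incompleteness. Passing recovery tests therefore demonstrates that the
*statistical chain* is implemented correctly and is sensitive at the
study's sample size under clean planted signals — not that the
pipeline is robust to upstream artefacts of real surveys.

Recovery tests run at σ = 0.1: at n = 7 the exact-permutation/BH
pipeline can only flag near-monotone signals (the second-ranked
feature must reach p ≤ 0.0025 under BH at 40 taxa, while the
second-smallest attainable exact p is 2.8e-3), so the recovery
condition is a low-dispersion scenario in which the planted monotone
signal dominates the noise. The default σ = 0.5 remains the realistic
setting for general use. Test and acceptance bundles use 12–40 taxa,
10–20 genes per taxon and depths of 5 000–100 000 reads — sizes at
which every stage's behaviour is exercised while the full suite runs in
well under a minute.

## Degenerate inputs and numerical conventions

All-zero sample columns cannot be normalised and error by name.
Readers reject rather than coerce: malformed hit rows, duplicate
feature ids, non-numeric cells, lineages with rank gaps, pathways with
empty KO sets and trees missing branch lengths all fail with
coordinates. Counts round-trip TSV exactly; proportions are written at
17 significant digits (round-trip error < 1e-12). Temperatures below
40 °C fall outside the three thermal classes and map to `NA`.
`pathway_fisher()` and `reporter_scores()` order group labels
alphabetically (overridable via `group_a`), so swapping label order
flips log-odds signs and nothing else.

## Known limitations

- The LCA engine assumes one lineage per reference; strain-level
  ambiguity within a reference id is invisible to it.
- The exact rank-sum and Spearman nulls are enumerated; far beyond the
  study's sample sizes they switch to seeded sampling, with Monte Carlo
  error the tests bound at ~0.02.
- Pathways are flat KO sets; KEGG module AND/OR logic is not modelled,
  so "completeness" means enzyme-set coverage, not guaranteed flux.
- The pipeline consumes upstream outputs as given; no attempt is made
  to model alignment or assembly error.
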