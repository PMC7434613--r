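---
title: "Methods: paralog conservation scoring, ACMG-lite classification, and enrichment tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog conservation scoring, ACMG-lite classification, and enrichment tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paravar)
```

This vignette is the package's own account of its methods: the model and
its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic generator does and does not emulate, the
numerical choices, and the places where the design was genuinely open and
a decision had to be made.

## The model

A gene family of paralogs (here, the nine voltage-gated sodium channel
α-subunits) shares enough linear sequence that a multiple protein
alignment gives every gene's residues a common coordinate: the *alignment
index position* (column). The working hypothesis is that columns
intolerant to variation across the whole family are functionally
important, so disease-cohort variants should sit at more conserved
columns than population variants do, and variants from different paralogs
hitting the *same* column corroborate each other.

The pipeline therefore needs four ingredients: a per-column conservation
score, a residue-to-column map for each gene, a variant classification
that separates plausibly pathogenic from benign variants, and tests for
positional enrichment of the former.

### Conservation and the parazscore

For column $j$ with $n_j$ non-gap entries, raw conservation is the modal
residue frequency

$$c_j = \frac{\max_a n_j(a)}{n_j},$$

where $a$ ranges over the 20 standard amino acids. Gaps are excluded from
the count rather than treated as a 21st state: a gap says the paralog has
no homologous residue there, not that it disagrees. Columns with
$n_j < \texttt{min\_nongap}$ (default 3) are flagged unusable and carry
no score — with fewer than three family members represented, a modal
frequency is closer to noise than to conservation.

The **parazscore** of a usable column is the z-score of $c_j$ across
usable columns, with the population ($n$) denominator:

$$z_j = \frac{c_j - \bar c}{\sqrt{\tfrac1m\sum_k (c_k - \bar c)^2}}.$$

Negative values mark columns less conserved than the family average;
the maximum marks columns identical in every represented paralog. The
profile asserts its own normalization (mean 0, sd 1 over usable columns,
to 1e-9) and is invariant to row order and to fully gapped rows.

Two caveats are deliberate. First, the published paralog conservation
score this mirrors is distributed as a resource, not a formula; whether
it uses identity, similarity classes or model-based conservation is not
stated. This package's definition — modal-frequency z-scoring — is the
simplest statistic consistent with the described behaviour (negative =
less conserved, maximal = identical in all paralogs). It is flagged, not
guessed: published per-variant scores in the packaged cohort table are
carried in a `parazscore_published` column as descriptive input and are
never recomputed or compared numerically against this package's scores.
Second, this is *paralog* conservation only; cross-species (ortholog)
conservation and phylogeny-weighted schemes are out of scope.

### Index mapping and the built-in aligner

Coordinates are 1-based on both sides (residue positions and columns),
matching HGVS convention. The maps are mutually inverse on non-gap
positions and strictly increasing, which is property-tested.

The pipeline is designed to *consume* a precomputed aligned FASTA — the
alignment behind the published analysis is not public, and pretending to
reproduce it would be misleading. The packaged nine-gene alignment is
therefore generated in code and labelled synthetic
(`synthetic_vgsc_alignment()`); it guarantees the packaged variant
tables' reference residues and realizes the known SCN4A-F103/SCN10A-S102
shared column via a single leading gap, but its conservation values are
not comparable to published ones.

A small progressive Needleman–Wunsch aligner (`align_family()`) exists so
synthetic families can be exercised end-to-end. Its design favours
determinism over alignment quality: guide order is input order, profile
columns are scored as the average pairwise residue score, gaps cost a
single linear `gap` penalty per residue-vs-gap pair (no separate opening
penalty — affine gaps would add parameters without changing what the
synthetic tests can show), and dynamic-programming ties resolve
diagonal > up > left. It is validated against exhaustive enumeration of
all alignments of tiny strings.

## Classification

### In-silico consensus

Up to six predictor scores (SIFT, PolyPhen-2 HVAR and HDIV, Mutation
Assessor, FATHMM, LRT) enter a majority rule: **damaging** when at least
4 of the 6 call an effect; **benign** when at most 2 do with at least 4
available; **insufficient** when fewer than 4 tools have scores. The
source rule only defines the damaging side ("a minimum of 4 of 6");
calling exactly 3 of 6 **conflicting** is this implementation's reading
of the boundary, documented as such. Tool thresholds are configuration,
not published values: the defaults (SIFT ≤ 0.05, PolyPhen-2 ≥ 0.5,
Mutation Assessor ≥ 1.9, FATHMM ≤ −1.5, LRT ≤ 0.001) follow each tool's
common usage, and each tool's documented score range is enforced.
Splice variants are damaging-tier at a combined splice-tool likelihood of
50% or more; the boundary is inclusive ("50% or more").

### ACMG-lite

The published analysis applied full ACMG review without recording which
criteria fired per variant; re-deriving expert judgement would mean
inventing evidence. The engine here is a deliberately small, fixed,
fully documented simplification:

| evidence | code | weight |
|---|---|---|
| nonsense (stop gain) | PVS1-like | pathogenic, strong |
| de novo (when inheritance known) | PS2-like | pathogenic, strong |
| AF below the rarity threshold | PM2-like | pathogenic, **moderate** |
| consensus damaging or splice ≥ 50% | PP3-like | pathogenic, supporting |
| AF at/above the threshold | BS1-like | benign, strong |
| consensus benign | BP4-like | benign, supporting |

Combining, in order: strong evidence in both directions → VUS flagged
conflicting; ≥ 2 pathogenic-strong → P; exactly 1 pathogenic-strong → LP;
benign-strong without pathogenic-strong → LB (B when the consensus is
also benign); anything else → VUS. Every record gets exactly one class,
and two monotonicity properties are enforced by property tests: adding
pathogenic-direction evidence never moves the class toward benign, and
raising the allele frequency never moves it toward pathogenic.

Rarity is only *moderate* evidence because these channel genes show
reduced penetrance — presence in gnomAD at very low frequency is
compatible with pathogenicity, so complete absence is not required. The
default threshold is the field's rare-variant cut, AF < 0.001, with
AF = 0 (absent from the population database) passing; a missing AF is
treated as 0 by default (configurable). "Conflicting evidence" means
evidence fired in both directions or a conflicting consensus.

Consequence, stated plainly: the engine reproduces the packaged cohort
table's printed classes only for the mechanically determined rows
(nonsense → LP; rare missense/splice without further evidence → VUS).
Rows whose printed class required unstated expert evidence are carried
with their `acmg_published` label as input and excluded from automated
equality tests.

### Deduplication and descriptive counts

The unique-variant key is `(gene, cDNA)`: a protein-level key would merge
distinct cDNA changes that predict the same substitution, which breaks
per-allele recurrence counting. Carrier counts are distinct case ids per
key. Age strings ("3 months 22 days") are parsed to days with 1 month =
30.44 days and used only descriptively. One known discrepancy is kept
rather than papered over: the cohort study's summary text says 9/10 cases
were under 6 months, but its own per-case ages give 8/10;
`cohort_summary()` reports the table-derived 8 and the fixture README
documents the difference.

## Enrichment statistics

**Welch t.** The case-versus-population comparison of parazscores uses
the unpaired two-tailed t-test *without* the equal-variance assumption
(Welch–Satterthwaite df). The source describes only an "unpaired t test";
Welch is chosen because the designs compared are strongly unbalanced
(tens of case variants against population-scale control sets), where the
pooled-variance test is the wrong default. Degenerate groups (n < 2 or
zero variance) raise an error naming the group.

**Fisher exact.** Both clustering tests — {damaging?, parazscore above
the cut?} and {damaging?, transmembrane?} — share one kernel: the exact
two-sided p summing, over the hypergeometric support implied by the fixed
margins, all tables no more probable than the observed one, with the
customary one-part-in-1e7 tie tolerance. It is verified against full
combinatorial enumeration on every non-degenerate table with margins
≤ 20 (tolerance 1e-12) and against `stats::fisher.test` as an independent
cross-check. Zero-margin tables are uninformative and return p = 1 with a
warning rather than an error, so a screening loop does not die on a
degenerate subset. "Conserved" is operationalized as parazscore > 0 —
above family-average conservation — because no cut is published; it is
exposed as `conserved_cut`. Rows with region `"unknown"` (no architecture
for the gene) are dropped from the transmembrane table rather than
counted as extramembrane. Labels for these tests follow the source
analysis: variants called damaging by the prediction-tool consensus
versus the rest.

**Permutation co-positioning.** The published co-occurrence result has no
stated formula, so the null is explicit Monte Carlo: redraw the case
columns from the control column pool B times (with replacement, so the
null is frequency-weighted by the pool's multiplicities; a
without-replacement mode checks the pool is large enough) and count, per
`mode`, either case variants landing in a supplied set of
disease-associated columns or cross-gene same-column pairs. The p-value
is the add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(1+B)$,
which is never zero and attains $1/(B+1)$ when the observed statistic
beats every draw. Default B = 9999; a seed is required for runs meant to
be reproducible (the CLI insists on one). The known disease-position set
is an *optional input* and is never fabricated — target mode refuses to
run without it. Calibration is property-tested: with case columns drawn
from the pool itself the rejection rate at 0.05 stays nominal, and tiny
instances match complete enumeration over all draws.

No multiple-testing correction is applied across the handful of tests;
none is described for the analysis being mirrored, and the package
reports raw two-sided p-values.

## The synthetic generator

`sim_config()` defines the generative model: an ancestral sequence of
length $L$; a fraction of columns designated conserved; per-copy
substitution rates (low on conserved columns, high elsewhere) with
uniform replacement over the 19 alternative residues; case variants
landing on a conserved column with excess probability `enrichment_delta`
(0 reduces cases to the control distribution — the basis of the
calibration tests); control positions uniform; prediction panels whose
damaging-call probability rises with conservation (`panel_strength`);
and a three-part log-uniform allele-frequency mixture (weights
0.7/0.2/0.1 over [1e-6, 1e-4], [1e-4, 1e-3], [1e-3, 1e-2]) so the 0.001
filter is exercised on both sides. Defaults mirror the mirrored study's
shape: 74 case variants (its missense set) against 1000 population
variants — a desk-scale stand-in for a population database — across nine
paralogs, with a strong (0.5) conserved-site enrichment. Everything is
deterministic under the config seed (variants use stream `seed + 1` so
family and variants are independently reproducible), and synthesized
records are reference-consistent by construction.

What it does *not* emulate — and therefore what passing tests do not
show about real data: no substitution matrix or rate heterogeneity
beyond the two-rate scheme (the replacement model is explicitly
non-biological), no phylogenetic structure among paralogs (independent
copies of one ancestor), no mutational hotspots or CpG effects, no
linkage/haplotypes or trio genotypes, and domain architectures are a
deterministic tiling rather than real channel topology. Tests on this
generator validate the *machinery* (mapping, scoring, test calibration
and power under a known truth), not biological conclusions.

Simulation sizes used by the test-suite and acceptance script are the
package's own choices balancing resolution against desk-scale runtime:
type-I calibration at 500–1000 replicates of small designs (40/60
variants, L = 100), power at 100 replicates of the 200/2000, L = 200,
nine-paralog design, and the Fisher/permutation oracles at exhaustive
small-margin / tiny-instance scales where enumeration is exact.

## Numerical choices and degenerate inputs

- 1-based coordinates everywhere; FASTA headers use the `gene|transcript`
  dialect with `|` separator; gap character `-` only; FASTA wrapped at 60.
- Profile normalization asserted to 1e-9; z-scoring uses the population
  denominator; an all-identical or unusable profile is an explicit
  `profile` error, not NaNs.
- Fisher tie tolerance 1 + 1e-7, matching the conventional definition of
  "as or less probable".
- Blank AF is missing and distinct from an explicit 0; AF and splice
  likelihood are range-checked on ingestion with row numbers in errors.
- A missense reference residue disagreeing with the alignment is an
  error by default; under `skip_mismatch` the row is kept, unannotated,
  with the reason recorded — never silently dropped.
- Deduplication with conflicting protein annotations under one key is a
  consistency error.
- DP ties in the aligner resolve diagonal > up > left, fixed, so all
  outputs are byte-reproducible.

## Known limitations

The conservation score is a reimplementation, not the published resource;
published per-variant scores and expert ACMG classes are inputs. The
ACMG-lite engine is six evidence codes, not the full framework
(functional-study codes enter only as whatever the user encodes in the
label column). HGVS support covers substitutions only (no
dup/del/ins/fs), and ingestion is the curated variant table — not VCF,
not raw sequencing. The built-in aligner is for synthetic tests, not for
producing production alignments. Published p-values that depend on the
unpublished alignment/score resource and disease-position set are out of
reach at desk scale by design; the property-based suite covers the
statistical machinery instead.
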