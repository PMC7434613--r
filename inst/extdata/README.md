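# Packaged variant tables

## cohort_variants.tsv

Curated cohort annotation: 12 rows covering 11 unique voltage-gated sodium
channel (VGSC) variants carried by 10 sudden-unexpected-death-in-pediatrics
cases. One case carries two SCN1A variants in cis; two siblings share the
SCN1B nonsense variant, so it appears in two rows. All 11 variants pass the
gnomAD allele-frequency rarity rule (AF < 0.001; an AF of 0 means absent
from gnomAD and passes). Seven of the ten cases have an abnormal
hippocampus on neuropathology.

Two columns are *descriptive inputs*, never recomputed here:

- `parazscore_published` — the originally reported paralog conservation
  scores. They come from an unpublished alignment/score resource and are
  **not** comparable to the parazscores this package computes from its
  synthetic stand-in alignment.
- `acmg_published` — the original expert ACMG classes. The package's
  ACMG-lite engine reproduces them only for the mechanically determined
  rows (nonsense -> LP; rare missense/splice without further evidence ->
  VUS). Rows whose published class required expert evidence not present in
  this table (L1296M "P", E1308D "LP", G682V "LP", L61P "LP", K724R "P")
  are excluded from automated equality checks.

Known discrepancy, kept as-is: the originating study's summary text states
that 9/10 cases were younger than 6 months at death, but the per-case ages
in its own cohort table (transcribed here) give 8/10 (the 20-month and
8-year cases are over; all others under). `cohort_summary()` reports the
table-derived 8.

Annotation note: every missense row of this table annotates against
`synthetic_vgsc_alignment()` without reference mismatch (the stand-in is
constructed to guarantee this); the SCN10A splice variant and the SCN1B
nonsense variant are not mappable onto the alpha-subunit alignment and
carry no alignment column.

## literature_variants_synthetic.tsv

**Synthetic reconstruction — not real data.** The per-variant supplementary
table of the literature review is unpublished; this fixture realizes its
printed marginal counts exactly (82 unique variants, 103 individuals, 109
carrier rows, six individuals with two variants, per-gene counts SCN1A 3 /
SCN4A 6 / SCN5A 62 / SCN10A 4 / SCN1B 3 / SCN3B 3 / SCN4B 1, twelve
recurrent variants in 39 individuals topped by SCN5A R1193Q with 8 carriers
and L567Q with 7, 14 variants with AF >= 0.001 carried by 31 individuals,
82 variants at 81 distinct amino-acid positions, and a 3-variant SCN1A
overlap with the cohort table so the merged set has 90 unique variants).
Positions, prediction scores, allele-frequency values and `original_class`
labels beyond those marginals are synthesized under a fixed seed
(`literature_variants_synthetic()` regenerates the table byte-identically).
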