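---
title: "riboTE: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{riboTE: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

riboTE analyzes ribosome-profiling experiments that probe
translation-initiation control — the prototypical design being a cell line
treated with an eIF4A helicase inhibitor (e.g. Silvestrol) versus vehicle,
with ribosome-footprint (RF) and fragmented-mRNA libraries sequenced for
each condition. The package covers the full path from aligned reads to
biological conclusions: positional counting, translation-efficiency (TE)
statistics, and a 5'UTR structure/sequence characterization engine. This
vignette documents the models behind each stage, the tunable parameters,
and the design decisions taken where the methodology was genuinely open.

## Quantification model

**Positional assignment.** RF reads report the position of the ribosome,
not the read ends. Counts are assigned to the genomic base in the ribosomal
P-site, a fixed offset from the read's 5' end (`psite_position()`): `start +
offset` on the plus strand, mirrored from the 5' end on the minus strand.
The offset defaults to 12 nt — the field-standard value for ~32-nt
footprints — and is configurable per read length
(`psite_offset_table()`). mRNA-seq counts are assigned to the read midpoint
(`midpoint_position()`), flooring toward the 5' end for even lengths.

**Exclusion rules.** Two conservative filters are applied at
`build_count_profile()`: reads reported with more than one alignment are
discarded at the read level, and genomic positions covered by more than one
canonical transcript are masked at the position level (reads assigned there
are counted as "masked", not attributed to either gene). Masking is
strand-agnostic, reflecting that the exclusion is defined on genomic
positions. A read-conservation identity (input = non-unique + skipped +
masked + counted) is enforced by tests on every simulated dataset.

**RPKM and effective length.** `rpkm()` uses reads per kilobase per million
mapped reads. Whether masked positions should shrink the denominator is
ambiguous; we default to the *effective* length (non-excluded positions
only) and expose `length_mode = "full"` as the alternative in
`quantify_genes()`.

## TE statistics

TE = RF-RPKM / mRNA-RPKM per gene; the treatment effect is the fold change
ΔTE = TE~treated~ / TE~control~. `te_analysis()` computes per-gene z-scores
and calls genes *decreased* (z < −1.5) or *increased* (z > +1.5).

Three open choices and their resolutions:

* **z-space.** z-scores are computed on log2(ΔTE), not the raw ratio: the
  raw ratio is bounded below by zero and cannot be symmetric about its
  mean, whereas empirical log2 ΔTE distributions are approximately
  symmetric. `z_space = "ratio"` is available. Standardization uses the
  population (1/n) standard deviation; tests pin mean 0 / sd 1 to 1e-9.
* **Replicates and time points.** Replicate libraries (and multiple
  treatment time points) are pooled by summing counts before RPKM
  (`replicate_mode = "pool"`); `"mean-te"` computes TE per replicate pair
  and averages. Pooling is the variance-minimizing default when replicate
  library sizes are comparable.
* **Robust filter.** "Sufficiently represented" is operationalized as a
  minimum count in *every* library (`min_count`, default 32). Genes failing
  it are reported as `unquantified` and never enter the z-standardization.

Pool contrasts (free energy, length, GC between gene classes) use a
two-tailed Mann–Whitney U test. `mann_whitney_u()` computes the exact null
by enumerating group labelings (midranks for ties) up to n = 16, and a
tie-corrected, continuity-corrected normal approximation above; tests
verify the exact mode against an independent brute-force oracle and against
`wilcox.test()` on tie-free data.

## The folding engine

`mfe_fold()` and `partition_function()` implement the classic
nested-secondary-structure dynamic programs (minimum free energy with
traceback; McCaskill inside/outside with base-pair probabilities) over a
loop-decomposed nearest-neighbor energy: hairpins, helix stacks, bulges,
interior loops with an asymmetry penalty, and affine multiloops, plus a
terminal AU/GU penalty at every helix end adjacent to a loop or the
exterior. `structure_energy()` scores any given dot-bracket under the same
decomposition and is deliberately implemented independently of the dynamic
program — the test suite folds hundreds of short random sequences and
checks the engine exactly against exhaustive enumeration scored by this
function (MFE identical; partition function to 1e-9 relative; base-pair
probabilities to 1e-9).

Numerical and structural choices:

* Allowed pairs AU/UA/CG/GC/GU/UG; `N` never pairs; minimum hairpin loop 3
  nt; lonely pairs allowed; no pseudoknots.
* Interior loops are capped at 30 unpaired nt (standard practice; makes the
  interior-loop scan O(1) per pair). Loop penalties beyond the tabulated
  sizes follow the Jacobson–Stockmayer `1.75·RT·ln(n/n_max)` extrapolation.
* RT is fixed at 0.616 kcal/mol (37 °C). The partition function rescales
  weights per nucleotide (anchored on the MFE) so that ensembles of
  1,000-nt GC-rich sequences stay inside double range.
* Ties in the MFE traceback are broken deterministically, preferring the
  5'-most opening pair; a dG of exactly 0 is always reported with the
  all-unpaired structure.
* The base-pair-probability (outside) pass is O(n^4) worst case and can be
  switched off (`return_bpp = FALSE`); the ensemble free energy itself only
  needs the O(n^3) inside pass. A ~950-nt 5'UTR folds in a few seconds.

**Parameterization.** The engine is strictly parameter-table-driven
(`read_energy_model()`; plain-text format documented in the shipped file).
The default table, `nn-compact-1`, is a compact set of Watson–Crick and
wobble stack energies with standard loop initiation penalties, in the style
of the published nearest-neighbor rules; it omits dangling ends, coaxial
stacking and tetraloop bonuses. Published per-UTR free energies in this
literature often come from statistical-learning scoring models whose
learned potentials differ systematically from physical nearest-neighbor
tables; absolute dG values from different parameterizations are therefore
not directly comparable. What is robust across parameterizations — and what
the test suite asserts — is the *ordering* of sequences by structure
content (for the five shipped reporter 5'UTRs: ROCK1 < ARF6wt < ARF6mut <
PFN2 < CyclinD1) and all within-model comparisons (pool contrasts, window
profiles, mutation design).

**Window profiles.** `window_profile()` slides a 20-nt window (step 1 by
default) and reports per-window MFE and GC%. On structured UTRs the two
tracks anti-correlate — localized structure coincides with GC clusters —
which is the basis for choosing mutation targets (`structured_windows()`).

**Mutation designer.** `design_destructuring_mutations()` reconstructs, as
an algorithm, the manual procedure of removing base-pairing interactions
from structured regions by single-nucleotide changes. Moves are restricted
to the GC-preserving substitutions A↔U and G↔C inside caller-supplied
windows; protected motifs (by default every (CGG)₄ occurrence) and the 3'
start-codon context are frozen. The greedy loop accepts the substitution
that most raises the refolded window dG, subject to the full-length dG not
becoming more negative, and stops when windows reach the threshold or no
improving move exists; infeasible windows are reported as unresolved rather
than raised as errors. Acceptance is property-based (dG raised; length, GC
and motifs preserved) — base-identity to any particular published mutant is
explicitly not a goal, since that would require the original scoring model.

## 5'UTR signature scheme

`classify_top()` calls a strict 5'TOP (cap-adjacent C followed by an
uninterrupted pyrimidine run of 4–15 nt) and a relaxed TOP-like class (run
≥ 5 starting within the first 4 nt); both definitions are configurable
because the literature varies. `detect_cgg4()` reports all, including
overlapping, occurrences of the 12-nt (CGG)₄ quartet and separately the
9-nt form, since the two lengths are described inconsistently in the
literature. `assign_category()` resolves the category scheme — structured
(dG below a threshold, default −104 kcal/mol, set at the typical mean dG of
eIF4A-dependent 5'UTR pools), variant (alternative TSS or 5'UTR intron),
TOP, other — by a documented precedence. Because published category tables
of this kind can sum to more than 100% (overlapping membership),
`signature_summary()` emits *both* a precedence-resolved table (sums to
100) and an overlap table (may exceed 100).

Variant 5'UTR detection (`detect_utr_variants()`) is annotation-driven: a
gene is variant iff its transcripts have distinct genomic TSS coordinates
or an exon junction upstream of the coding start. Canonical transcripts
default to the longest-CDS policy (ties: longer transcript, then
lexicographic id), since proprietary "canonical" flags of genome browsers
are not reproducible offline; the policy is a parameter.

## The synthetic experiment generator

`simulate_transcriptome()` / `simulate_counts()` / `emit_alignments()`
generate a fully specified experiment so every pipeline stage is testable
without downloads. The generator's defaults *are* the emulated study
conditions:

* Two conditions, two library types, 2 replicates each; ~7.5% of genes
  treatment-sensitive with log2 TE shifts from Normal(−2.5, 0.5), 2.5%
  resistant from Normal(+1.8, 0.4).
* Counts are negative binomial with a single dispersion (default 0.05,
  which reproduces replicate log-RPKM correlations in the mid-0.9s typical
  of good profiling replicates; dispersion 0 gives the Poisson limit).
  mRNA means are identical across conditions — the treatment acts on
  translation only — and footprint means are anchored on the
  control-condition totals so an unshifted gene has the same expected
  footprint count in both conditions.
* Sequencing depth defaults to 2,500 reads per gene per library, echoing
  experiments of this design (tens of millions of mapped reads over
  ~17,700 transcripts). At this depth the median control footprint count
  per gene is well above 200.
* 5'UTR pools differ by sensitivity class: sensitive genes draw long UTRs
  (log-normal targeting a ~490-nt mean, capped at 600 nt), lower GC
  (59.8%), and are enriched for planted GC-rich stems (a segment and its
  reverse complement written a short spacer apart, so window profiles show
  dG minima on GC peaks) and for variant genes (a second transcript from a
  downstream TSS). Insensitive genes target ~224 nt / 66.9% GC, resistant
  genes ~172 nt / 71.2% GC. The pool means are taken from the reported
  characteristics of eIF4A-dependent versus independent 5'UTR pools.
* Footprint lengths are Normal(32, 1.5) truncated to [26, 36]; mRNA reads
  are 50 nt. Reads are placed so the P-site falls uniformly in the CDS
  (mRNA: uniform over the transcript), and re-counting emitted reads
  recovers the input counts exactly when masking is off.
* Everything is deterministic under `seed` — same seed, byte-identical
  FASTA/SAM/TSV.

What the generator does **not** emulate: real human 5'UTR sequence families
(its UTRs are i.i.d. backgrounds plus planted stems), rRNA contamination
and ligation biases, multi-exon gene structure at scale (simulated genes
are single-exon except variant second transcripts), elongation-level
ribosome dynamics, and alignment ambiguity (emitted reads are unique).
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not performance on real
libraries.

## Problem sizes used by the test suite

The end-to-end checks run a 2,000-gene experiment (fixed seed) for
parameter recovery — sensitivity and false-discovery of the z-call against
ground truth — and fold the called-decreased pool against a fixed-seed
300-gene subsample of the insensitive pool for the signature contrasts
(the rank tests are overwhelming at that size; folding the full insensitive
pool adds minutes without changing the conclusion). Engine-exactness tests
use 200 random 8–14-nt sequences against exhaustive enumeration.

## Known limitations

* Absolute dG values depend on the energy table; only within-model
  comparisons and cross-model orderings should be interpreted.
* The exact Mann–Whitney mode enumerates subsets and is limited to n ≤ 16;
  above that the tie-corrected normal approximation is used.
* `te_analysis()` implements the z-threshold rule of this analysis style;
  it is not a replacement for count-model differential testing (no
  shrinkage, no multiple-testing control beyond the fixed threshold).
* The base-pair-probability pass is quartic in sequence length; for
  sequences beyond a few hundred nt request only the ensemble free energy.
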