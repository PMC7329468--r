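---
title: "Methods: detecting and comparing nuclear copies of organellar DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and comparing nuclear copies of organellar DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`norgscan` quantifies endosymbiotic DNA transfer: it detects NUMTs and
NUPTs (nuclear insertions of mitochondrial and plastid DNA) in genome
assemblies and runs the comparative statistics used to ask whether a trait
— canonically desiccation tolerance — is associated with norgDNA content.
This vignette is the package's account of its models, parameters, numerical
choices and limitations.

## Coordinates and data model

Everything tabular is a tibble. Intervals are uniformly 0-based, half-open,
on the forward strand, with strand stored as a flag; the 1-based inclusive
conventions of FASTA-adjacent formats (tabular hit tables, GFF3) are
converted at the boundary by `read_tabular_hits()` / `read_gff_features()`
and restored on write. This single internal convention removes the
off-by-one ambiguity that plagues mixed-format pipelines. Assembly level
(contig / scaffold / chromosome / complete) is user-supplied metadata — it
comes from the source database and cannot be inferred from sequence.
`N` residues participate in alignment as universal mismatches, which is
conservative: runs of `N` can never inflate a hit.

## Local search

The search reproduces the classic organelle-vs-nucleus survey
configuration: match +2, mismatch −3, gap existence 5, gap extension 2,
word size 11, E ≤ 10⁻⁴ (`scoring_scheme()`). A gap of length *g* costs
`5 + 2g` — the convention of the standard nucleotide search tool, where the
first gapped residue pays both existence and extension; `gap_convention =
"open-first"` switches to `5 + 2(g−1)` for users who read the costs the
other way. The internal exhaustive aligner (`smith_waterman()`) uses the
same convention, so the seed-and-extend engine and its oracle are
consistent by construction.

**Statistics.** E-values follow Karlin–Altschul theory,
`E = K·m·n·e^(−λS)`. λ is the unique positive root of
`Σᵢⱼ pᵢpⱼ e^(λ sᵢⱼ) = 1`, solved to 10⁻¹² by bracketed root finding; for
a match/mismatch scheme the step distribution is two-point, so the
*i*-step random walk needed for `K` is binomial and each term of the
classical series `σ = Σᵢ (1/i)[P(Sᵢ ≥ 0) + P̃(Sᵢ < 0)]` is computed
exactly, truncating when a term drops below 10⁻¹² (at most 3000 terms).
Gapped searches reuse the ungapped `(λ, K)` for the same substitution
scores — the standard approximation, documented rather than hidden. For
the default scheme on a uniform background this gives λ = 0.6337 and
K = 0.408, matching the values printed by the reference search tool.
Search-space lengths `m`, `n` are raw sequence lengths; no edge-effect
correction is applied (it matters only for sequences shorter than a
typical alignment).

**Algorithm.** Exact 11-mers seed ungapped X-drop extensions
(`x_drop = 20` score units); a per-diagonal reach marker keeps each
diagonal's exploration linear. Extensions reaching `gap_trigger`
(default 40, deliberately above the 22 a bare seed scores, so random seeds
do not reach the gapped stage) are clustered — chains join when within
`chain_gap = 150` bp in the subject and `chain_drift = 24` diagonals — and
each cluster is aligned by the full affine-gap dynamic program in a padded
window (`window_pad = 120` bp). The window grows adaptively (in 256 bp
steps) while the optimal alignment touches a window edge, so window
truncation cannot clip an alignment. On problems small enough to afford it
(≤ 10⁶ cells) one exhaustive pass is added, guaranteeing the reported best
hit equals the true optimal local alignment whenever any chain triggers.
Low-complexity masking is exposed as a configuration placeholder only
(`dust = "off"`): the surveys this reproduces ran with tool defaults, and
the synthetic benchmark does not generate low-complexity sequence.

Both subject strands are searched by logically reverse-complementing the
subject; reported subject intervals are always forward-strand ascending.
Circular organellar queries are doubled, hits starting in the second copy
are dropped, and a retained hit may have `q_end` beyond the query length,
meaning it spans the origin; a duplicate of the same nuclear locus seeded
in the other copy is removed by subject-interval containment. All
tie-breaks are deterministic (lowest subject start, then lowest query
start), so identical inputs give byte-identical outputs.

`smith_waterman()` is quadratic and capped (`max_cells`, default 2.5·10⁷);
it exists as the exhaustive reference and for small problems, not for
genome-scale search. Every reported alignment carries a CIGAR path;
`rescore_alignment()` replays it, and the test suite requires the replayed
score to equal the reported one.

## Contamination, deduplication, summaries

Organellar molecules mistakenly assembled into the nuclear set appear as
short contigs nearly fully covered by hits. A nuclear sequence is flagged
when **both** length ≤ `max_contig_length` (default 10 kb — organellar
genomes up to ~2 Mb exist, but assembled contaminant contigs of the
organelles surveyed here are far smaller) **and** hit coverage ≥
`min_covered_fraction` (default 0.95, "completely matched" with room for
edge effects). Both knobs are explicit because the underlying notions of
"short" and "complete" are not standardized. Flagged sequences lose their
hits and are subtracted from the genome size used for densities; per-Mb
densities otherwise use total assembly length including `N` runs, which is
what is recoverable from public assemblies.

The same nuclear locus found from several organellar regions is one
insertion: `merge_hits()` unions subject intervals overlapping by ≥ 1 bp.
Abutting-but-disjoint intervals are *not* merged at the default
`merge_gap = 0` — adjacency is a different event from rediscovery — and
`merge_gap > 0` merges intervals separated by at most that many bases. A
segment records the union interval, its best identity, and its
contributing hits. In plants, a nuclear interval claimed by both organelles
(promiscuous DNA) has no standard resolution; `resolve_promiscuous()`
assigns it to the organelle whose hits reach the higher bit score, with an
option to report both claims. Feature-class attribution gives a segment
class *c* (CDS / tRNA / rRNA / other) when any contributing hit's query
interval overlaps a class-*c* feature by ≥ 1 bp; segments may carry several
classes, and a segment touching no annotation is `other`. Human-readable
tables round total lengths half-up to integer kilobases; all computation
stays in base pairs.

## Comparative statistics

**Paired design.** A lineage with two member species contributes the
arithmetic mean of their values; pairs are tolerant vs. control.
`wilcoxon_signed_rank()` drops zero differences (the classical treatment),
mid-ranks ties, and reports the smaller rank sum. The p-value is exact —
the full distribution over 2ⁿ sign assignments, computed by the usual
rank-polynomial convolution — when n ≤ 25 and ranks are untied; otherwise
a normal approximation with tie and continuity corrections is used, and the
`method` field says which. The all-zero-differences design returns p = 1
with n_effective = 0 rather than an error. No multiple-testing correction
is applied across metrics, matching how such surveys report their four
content metrics.

**PGLS.** For trait y and predictor x on n species,
`y = α + βx + ε, ε ~ N(0, σ²V(λ))`, where `V` holds shared root-to-tip
branch lengths and Pagel's λ scales its off-diagonal entries. For fixed λ
the GLS solution is obtained by Cholesky whitening; λ is chosen to maximize
the profile log-likelihood over [0, 1] on a 0.01 grid with golden-section
refinement inside the bracketing interval — a global grid first, because
the profile can be multi-modal. ML is the default (REML is an option); the
two were the era-typical choices of comparative packages and ML is the more
common default. The slope's p-value uses a t distribution on n − 2 degrees
of freedom regardless of λ having been estimated — standard PGLS practice,
and a documented caveat since it ignores the uncertainty in λ. R² is
`1 − RSS/TSS` in the whitened space, with TSS about the GLS-weighted mean;
this is the natural GLS generalization, and the λ = 0 case collapses to
ordinary R². A species observed for both organelles enters as **two
samples** (one NUMT, one NUPT row), never a combined norgDNA value; the
covariance duplicates that tip with a negligible (10⁻⁸) separating branch,
which keeps `V(λ)` positive definite while making the two rows
phylogenetically identical for every practical purpose. Assembly levels
are coded numerically: contig = 1 vs everything higher = 2, or (excluding
contigs) scaffold = 3 vs chromosome/complete = 4.

**Spearman.** ρ is the Pearson correlation of mid-ranked vectors; for
n ≤ 9 the two-sided p-value is an exact enumeration over permutations,
above that a t approximation on n − 2 degrees of freedom.

The test suite cross-checks each of these against independent routes:
`stats::wilcox.test`, full sign-assignment and permutation enumerations
written in the tests themselves, `nlme::gls` with `ape::corPagel`, and
OLS equivalence at λ = 0 and on star trees (asserted to 10⁻⁸).

## The synthetic-data generator

The generator produces every input with known truth. Organellar genomes
are i.i.d. sequence at a chosen GC with non-overlapping CDS/tRNA/rRNA
features of class-typical lengths. Insertions are random organellar
substrings — half reverse-complemented by default — planted at positions
at least `min_spacing = 200` bp apart (so seed chains cannot bridge
distinct truths and truth-to-segment mapping stays one-to-one), with
per-site substitutions at rate (100 − identity)/100 and a 2:1
transition:transversion ratio; small indels are available but off by
default, keeping realized identity exactly recomputable. A fifth of the
fragments are planted with divergence 0 to anchor exact-boundary checks.
The defaults — 50 insertions of 200–2000 bp at 85–100 % identity in a 2 Mb
background — are a realistic norgDNA landscape for a compact animal
genome, at a scale a desk machine searches in seconds.

Two generator details are deliberate design choices rather than realism.
First, the single nuclear bases flanking each planted fragment are set to
mismatch the organellar continuation over a 12 bp zone, and for exact
copies the junction neighbourhood is verified with the exhaustive aligner
(flanks are resampled in the rare case chance homology, e.g. via a 1 bp
gap, would extend the optimal alignment past the boundary). This makes
"the planted interval" and "the optimal alignment" coincide exactly, so
boundary recovery is a well-defined test. Second, contaminant contigs are
verbatim organellar substrings, the worst case the contamination filter
must catch.

What the generator does **not** emulate: repeat landscapes and segmental
duplications (no post-insertion NUMT–NUMT duplication), low-complexity
sequence, sequencing or assembly error, GC heterogeneity along the genome,
and insertion-age structure. Passing the recovery benchmarks therefore
demonstrates the machinery is correct on clean signal, not that real-genome
surveys are free of repeat-driven artefacts — on real data the identity
histogram and contamination report should be inspected.

Trees are pure-birth with exponential waiting times (`ape::rphylo`);
traits are `y = α + βx + ε` with `ε` drawn through the Cholesky factor of
`σ²V(λ)`. Paired designs draw the control side i.i.d. from a skewed
(lognormal) law, like per-genome insertion counts, with an additive shift
for the alternative.

## Problem sizes and budgets

The shipped validation uses: 100 random hit sets (≤ 500 intervals) against
a per-base marking oracle; 100 random short pairs (query ≤ 100 bp, subject
≤ 300 bp) against the exhaustive aligner; one 2 Mb genome with 50 planted
insertions for recovery (recall and per-base precision); 200 replicates of
a 100-tip tree with λ = 0.8 and slope 1 for PGLS recovery; 2000 null
replicates of the 24-pair design for Wilcoxon calibration; and 20 random
contamination configurations. These sizes make the whole suite run in
about a minute and a half while leaving the Monte-Carlo margins
comfortable. Full-scale surveys of real assemblies (hundreds of genomes,
Gb-scale plants) are out of scope for the internal aligner — use an
external search and feed the tabular hits in via `hits =` /
`read_tabular_hits()`.

## Known limitations

- The internal aligner aims at correctness and reproducibility, not speed
  parity with production search tools; translated searches and masking are
  not implemented.
- Gapped E-values inherit the ungapped `(λ, K)`; absolute E-values for
  heavily gapped alignments are approximate (the threshold behaviour is
  dominated by λ, which is exact for the substitution scores).
- NUMTs/NUPTs are not distinguished from ancestral nuclear sequences of
  organellar origin that predate the sampled organelle (the usual
  approximation in this literature); insertion dating is out of scope.
- The λ-profile t-test for the PGLS slope conditions on the estimated λ.
- Abundance metrics enter PGLS untransformed by default; counts are
  skewed, and a log10(x+1) transform is available where that matters.
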