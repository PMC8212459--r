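---
title: "Methods: classification, duplication, Ka/Ks and expression calls in drebfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classification, duplication, Ka/Ks and expression calls in drebfam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drebfam)
```

`drebfam` packages the standard genome-wide survey of the AP2/ERF (DREB)
transcription-factor family — classification, duplication mapping,
molecular evolution, phylogeny, expression patterns — as tested R
functions. This vignette records the models, the tunable parameters, the
numerical choices, and the places where the published workflow left the
design genuinely open and we had to decide.

## Family classification

The decision tree follows the Arabidopsis-derived convention for AP2/ERF
superfamilies, applied in a fixed order to each protein's domain hits:

1. two or more AP2/ERF domains → **AP2** subfamily;
2. at least one AP2/ERF plus a B3 domain → **RAV**;
3. a single AP2/ERF domain lacking the conserved WLG tripeptide anywhere
   inside the hit span → **atypical** (excluded from subgrouping, the way
   genome surveys drop "WLG-less" hits);
4. a single WLG-bearing domain → **DREB** candidate (Group A) when the
   domain's 14th residue is V, **ERF** (Group B) when it is A.

The V14-vs-A14 rule is the Sakuma-style criterion that the V14/E19
literature presupposes; when position 14 is neither V nor A (or the domain
is shorter than 19 residues) we fall back to global similarity against
fixed DREB and ERF domain consensus cores (`ap2_consensus()`). Domain
positions count the first residue of the (envelope) hit as position 1;
HMMER envelope coordinates are used because they are the inclusive domain
extent. Whether WLG-less proteins should be excluded before or after the
DREB/ERF split is ambiguous in the published account; we exclude them
first, so the four labels plus DREB/ERF partition every input.

DREB subgrouping is motif-based. Motifs are degenerate consensus patterns
matched exactly, position set by position, with no mismatch allowance
(`scan_motif()`, leftmost non-overlapping). The DREB1-type NLS is encoded
as `[PK]K[RK][PR][AT]GR[TK]KFRETRHP`; its two published renderings
disagree at position 8 (T/K vs any residue), so that position is
configurable (`nls_pos8_any`). The published description says the NLS and
DSAW "nestle up" to the domain without giving distances; we fixed windows
of **30 residues upstream** for the NLS, **10 residues downstream** for
DSAW, and the **final 15 residues** for LWSY, all configurable. A-1
requires the DREB1 NLS in its window; A-2 requires CMIV-1
(`[KR]GKGGPxN`) anywhere upstream of the domain; both kinds of evidence
together raise an ambiguity error rather than a silent tie-break. The
PKK-like DREB2 NLS (`RKxPAKGSKKGCMxGKGGPENxx`) is recorded as a flag only,
because real DREB2 proteins can lack it while keeping CMIV-1. Subgroups
A-3…A-6 are reported collectively as `other-A`; the deep analysis in this
workflow concerns A-1/A-2 only.

## Physicochemical profile

`physchem()` reimplements the ProtParam quantities from their published
constant tables: average (not monoisotopic) residue masses plus one water
for MW; Kyte–Doolittle hydropathies for GRAVY; the aliphatic index
`100·(fA + 2.9 fV + 3.9 (fI+fL))` in mole fractions; the Guruprasad
dipeptide weight table for the instability index `10/L · Σ DIWV`; and the
theoretical pI by bisection on the Bjellqvist charge model (N/C termini
plus D, E, C, Y, H, K, R side chains), tolerance 10⁻⁴ pH units. Unknown
residues (X) are skipped with length renormalisation for MW/GRAVY/AI and
make pI/II unavailable, since charge and dipeptide contributions of X are
undefined. A useful sanity property, tested over random peptides:
appending K never lowers the pI and appending D never raises it.

## Allele grouping and naming

In an autopolyploid the same locus appears on homologous chromosomes
(Chr2A–2D style). The published account never states its grouping
procedure, so we made the rule explicit and configurable: two genes are
co-allelic when their chromosomes share a number but not a haplotype
letter and their proteins are ≥ 95% identical under global
(Needleman–Wunsch, BLOSUM62) alignment; the partition is the transitive
closure. A qualifying pair on the *same* haplotype is biologically a
duplicate, not an allele pair, and is kept separate with a warning. Loci
are lettered in (chromosome, start) order of their first-occurring allele
and alleles suffixed −1…−k in coordinate order, reproducing the
`SsDREB1A-2` naming scheme.

## Tandem duplication

The classical windowing rule — a chromosomal region within 200 kb holding
two or more family genes is a tandem-duplication event — is implemented as
a graph: same-chromosome, mutually homologous gene pairs with gap ≤ window
are joined, clusters are connected components, singletons are dropped. The
gap is measured from the end of the upstream gene to the start of the
downstream one (conservative and unambiguous; midpoint-based gaps would
depend on gene lengths). Homology means a provided edge with identity
≥ 0.4, or every same-chromosome pair when no edges are given.

The homology requirement is not decoration: on the published SsDREB1
coordinates the two Chr2D clusters sit < 200 kb apart, so pure-distance
windowing necessarily merges them into one component (3 clusters total),
while homology-restricted edges reproduce all four published clusters
exactly. The published separation was presumably made by MCScanX's
intervening-gene/homology criteria, which we do not re-implement; both
behaviours are exposed (`edges = NULL` vs an edge table) and both are
asserted in the tests. Genes that are not tandem but carry an
inter-chromosomal (or beyond-window) homology edge are labelled
`segmental/WGD-candidate` — a candidate label only, since proper
collinearity-block inference is out of scope.

## Ka/Ks (NG86) and divergence time

The estimator is Nei–Gojobori (1986) with equal pathway weights and
Jukes–Cantor correction, matching what lightweight "easy Ka/Ks"
calculators implement, and producing the single Ks that the divergence
clock consumes. Per codon, the synonymous site count is the fraction of
the nine single-nucleotide neighbours that preserve the amino acid; a
neighbour that creates a stop codon counts as nonsynonymous, which keeps
`N + S = 3 ×` analyzable codons exactly (an invariant the tests assert).
Site counts are averaged over the two sequences. For codons differing at
k positions, all k! substitution orderings are enumerated; orderings that
pass through a stop codon are excluded, and in the rare degenerate case
where every ordering is blocked, all orderings are used with stop steps
counted as nonsynonymous. Codons containing a gap or ambiguous base in
either sequence are dropped pairwise. `pn ≥ 3/4` or `ps ≥ 3/4` marks the
result saturated (rates undefined) instead of raising an error. Note that
for essentially unrelated sequences the raw counts can give `Sd > S`; that
regime is exactly what the saturation flag covers, and the
`Nd ≤ N, Sd ≤ S` bounds are asserted at realistic divergence.

The selection test is a two-sided Fisher exact test on
`[Nd, N−Nd; Sd, S−Sd]` rounded half-away-from-zero — explicitly an
approximation, since NG86 counts are fractional and the published
workflow reports significance stars without stating a method. Divergence
time is the exact formula `T = Ks/(2r)·10⁻⁶` Mya with
`r = 6.1 × 10⁻⁹` substitutions/site/year (a grass-lineage synonymous
clock), configurable. Applying it to the published Ks table reproduces
every published time to ≤ 0.36% relative — the residual scatter is
consistent with Ks being printed to three decimals (± 0.0005 absolute,
up to ~0.6% relative at Ks ≈ 0.08), which is why the acceptance bound is
0.6%; the published times were evidently computed from unrounded Ks.

`codon_align()` threads a protein alignment onto CDSs (each protein gap →
one codon gap) after verifying the translation residue by residue; a
single terminal stop codon is tolerated and stripped, any other length
mismatch is an error.

## Poisson distances, NJ, bootstrap

Protein distances use the Poisson correction `d = −ln(1 − p)` with
pairwise deletion: for each pair, only sites where neither sequence has a
gap/X are compared, matching the common MEGA configuration for
family-level NJ trees. `p = 1` gives an undefined distance (NA), and a
pair with no comparable sites is an error naming the pair.

`nj_tree()` is the Saitou–Nei agglomeration with the standard Q
criterion. Ties in Q are broken by the smallest (i, j) index pair in the
current matrix order — an arbitrary but fixed rule that makes the
topology deterministic; the final three nodes are resolved exactly by the
three-point formula, and negative branch lengths are clamped to zero by
default (disable with `clamp_negative = FALSE`). On additive matrices the
algorithm is exact, which the tests verify against independently
generated random trees (and cross-check against `ape::nj`). Branch
lengths are serialised at 15 significant digits so newick round-trips
stay below 10⁻⁹ absolute error.

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds each replicate via Poisson distances + NJ, and reports, for each
bipartition of the full-data tree, the percentage of replicates
containing it — supports on the full-data tree, not a majority-rule
consensus, which is the MEGA convention. Replicates with undefined
distances are skipped and tallied (`bootstrap_skipped` attribute) rather
than silently dropped. The seed is a required argument; identical seeds
give identical supports.

## Synthetic data: what it emulates, what it does not

The generators replace the external genome with fixtures whose ground
truth is known by construction; every generator is a pure function of
(spec, seed).

* `make_protein()` realises domain copies as fixed 60-residue consensus
  cores with the diagnostic positions (14, 19, WLG at 26–28) set as
  requested, and plants motifs as concrete members of their degenerate
  patterns at window-consistent offsets, separated by ≥ 2 random
  residues. Background residues are uniform over the 20 amino acids.
  Contradictory requests (a DSAW flank on a WLG-less domain) error.
* `make_genome_fixture()` scatters non-cluster genes > 200 kb apart and
  plants tandem clusters as runs of genes with identical proteins (and
  identical CDSs — recent tandem duplicates) whose adjacent gaps stay
  below the requested `max_gap`; homology edges and a truth table are
  emitted alongside the FASTA/GFF3/domtblout files.
* `mutate_cds_pair()` draws Poisson numbers of synonymous and
  nonsynonymous events with expectations `Ks·S` and `Ka·N` computed from
  the ancestor's NG86 site counts, then applies them as uniform draws
  over the eligible single-nucleotide transitions of the current
  sequence. This matches NG86's equal-weight neighbour assumption, so the
  estimator recovers the targets without calibration fudges (the
  acceptance run measures the recovery). Synonymous moves are
  rejection-filtered to keep the mutated codon's pathway-averaged
  nonsynonymous difference from the ancestral codon at zero — without
  this, two synonymous hits in one codon can create substitution
  orderings with nonsynonymous steps, and a pure-Ks pair would show a
  fractional Nd. Stop codons are never created. Targets are capped below
  0.7 to stay clear of saturation.
* `make_expression_fixture()` uses a fixed 26-sample design (leaf/stalk
  tissues, a 4-zone leaf gradient, two diurnal cycles, paired cold and
  drought contrasts) and per-pattern baselines (e.g. constitutive 10
  FPKM, undetectable 0.2, gradient 2→54, cold induction 200-fold over a
  control of 1), with multiplicative log-normal noise of parameter σ
  (default 0.2 — the published workflow states no noise model, so this is
  a package choice of a realistic magnitude for FPKM replicates).

What the fixtures do **not** emulate: real domain sequence diversity (an
HMM search is consumed as a hit table, not re-scored against variable
domains), intron structure, genome-scale background gene density,
RNA-seq count noise at the read level, or batch effects. Passing the
recovery tests therefore shows the *decision rules* are implemented
correctly and are robust to multiplicative noise — not that the pipeline
would reproduce any particular genome's counts, which depend on the
external genome and HMM scoring.

## Expression calls

All calls are descriptive fold-change classifications; the underlying
series have no replicates, so no differential-expression model is fitted.
Defaults: detection threshold FPKM < 1 for "undetectable" (no published
value; FPKM 1 is the conventional floor), ratio pseudocount 0.01,
fold cutoff 2, Spearman |ρ| ≥ 0.8 for "gradually
increasing/decreasing" (the published wording is qualitative), interior
peak with ≥ 2-fold margin for "peaked", per-cycle fold required
independently in every diurnal series, and stress induction requiring
both the fold and a treated value ≥ 1 FPKM, combinable across paired
series with an all/any policy. Raising `min_fold` can only remove
induced calls (a monotonicity property under test). The qPCR concordance
statistic is the squared Pearson correlation of paired FPKM and relative
expression vectors.

## Problem sizes and determinism

The test suite and acceptance script use desk-scale sizes chosen to make
the statistical checks sharp while staying quick: 200 random ≤ 6-codon
pairs against the exhaustive-pathway oracle (the pathway enumeration is
exact there), 50 simulated 300-codon pairs for parameter recovery, 50
random additive matrices of up to 8 taxa, 1000 bootstrap replicates on a
6-leaf alignment, 68 planted proteins for classifier recovery, and 80
genes under σ = 0.2 noise for expression recovery. Every stochastic
routine takes an explicit seed, restores the caller's RNG state, and is
byte-reproducible per seed.

## Known limitations

* HMM scoring is out of scope; classification quality on real genomes
  depends on the upstream hit table (e.g. Pfam PF00847 search settings).
* The DREB/ERF fallback consensus is a fixed core, not a trained profile;
  proteins with neither V nor A at position 14 are rare but their
  fallback label should be treated as a suggestion.
* The Fisher test on rounded fractional counts is approximate by
  construction.
* Segmental/WGD labels are candidates, not collinearity-verified calls.
* The allele-identity threshold (0.95) is a configurable convention; the
  published procedure is unstated.
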