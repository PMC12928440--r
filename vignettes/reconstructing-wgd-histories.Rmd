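---
title: "Reconstructing recurrent WGDs and descending dysploidy with WGDpaint"
author: "WGDpaint authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing recurrent WGDs and descending dysploidy with WGDpaint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WGDpaint)
```

## The problem

Polyploid plant genomes carry the superimposed traces of repeated
whole-genome duplications (WGDs) and of the diploidization that follows
them: gene fractionation, chromosome fusions, and descending dysploidy —
the reduction of the base chromosome number without loss of genome
content. In grasses, the dominant fusion mechanism is the nested
chromosome insertion (NCI), in which one whole chromosome inserts between
the arms of another, leaving a diagnostic outer–inner–outer ancestry
pattern along the fused chromosome.

WGDpaint re-implements, at desk scale and with every stage testable
against scripted ground truth, a comparative-genomics workflow that
reconstructs such histories from coding sequences and gene positions:

1. **Homology** — filter all-vs-all similarity hits and extract reciprocal
   best hits (RBH).
2. **Divergence** — estimate synonymous divergence (Ks) per homolog pair
   with a protein-guided codon alignment and the Nei–Gojobori (1986)
   counting estimator, model the Ks distribution as a Gaussian mixture,
   and convert peaks to time with a molecular clock.
3. **Synteny** — chain collinear homolog pairs into syntenic blocks and
   measure syntenic depth ratios between genomes.
4. **Karyotype painting** — assign each focal gene an ancestral-chromosome
   origin by bitscore-weighted bootstrap over multi-species homology
   evidence, validate origins along syntenic blocks, and call NCIs,
   end-to-end fusions and translocations from the painted chromosome
   structure.

A genome-history simulator generates multi-species inputs descending from
the 12-chromosome grass ancestor, so recovery of a known history can be
asserted end to end.

## Homology filtering and RBH

`filterHits()` applies the four standard criteria per hit: e-value
strictly below 1e-5, percent identity at least 70, alignment length at
least 60 bp, and removal of every hit touching a CDS whose soft-masked
(lowercase) fraction strictly exceeds 25%. The repeat rule operates on the
gene, not the hit: one repeat-rich CDS removes all its hits. Soft-masked
FASTA must be read case-preserving (`Biostrings::readBStringSet`); the
DNA-alphabet readers normalise case and would erase the masking signal.

`reciprocalBestHits()` collapses multiple HSPs per gene pair to the best
HSP, then keeps (a, b) iff each is the other's maximal-bitscore hit. Ties
are broken by lower e-value, higher identity, then lexicographic subject
id — the published thresholds say nothing about ties, so the rule is
chosen for determinism and symmetry (swapping the two directions yields
the same unordered pair set).

## Ks estimation

`alignCodons()` aligns the translated proteins globally (BLOSUM62, affine
gaps 10/0.5) and threads codons back through the protein alignment, so
indels are whole-codon events. `ng86()` then counts synonymous and
nonsynonymous sites and differences:

* Sites: per codon, the fraction of the nine single-nucleotide changes
  that preserve the amino acid, averaged between the two sequences.
  Changes that create a stop codon count as nonsynonymous, so
  S + N = 3 × (compared codons) exactly. (Some codeml builds exclude stop
  changes from the site denominator instead; the discrepancy is small and
  documented rather than chased.)
* Differences: codon pairs differing at d positions are averaged over all
  d! orderings of single steps; orderings that pass through a stop codon
  are excluded (if all are blocked, all are used).
* Multiple hits: Jukes–Cantor correction
  $d = -\tfrac{3}{4}\log(1 - \tfrac{4}{3}p)$, undefined (saturation flag)
  at $p \ge 3/4$.

Only gap-free, stop-free, unambiguous A/C/G/T columns are compared;
ambiguity codes are excluded. The estimator is checked in the test suite
against a pathway-enumeration oracle written independently, with exact
equality required on every fixture.

`filterKs()` retains $0.01 \le Ks < 3$: the lower bound discards nearly
identical copies (alleles, very recent tandems), the upper bound
saturated divergence.

## Mixture dating

`fitKsMixture()` fits univariate Gaussian mixtures by EM with unequal
variances, stopping when the log-likelihood improves by less than 0.001
(the conventional setting for Ks-peak modelling), and selects the number
of components by BIC — the source analyses never state how the peak count
was chosen, so an explicit information criterion is used. Initialisation
is deterministic (quantile-spaced means), making the selected fit
seed-independent; the seed only drives the bootstrap, which resamples the
Ks vector with replacement and refits with k fixed, reporting the spread
of each component mean. The reported "mode" of a peak is the fitted
component mean.

`ksToMya()` applies the molecular clock $T = Ks / (2\mu)$ with the
monocot synonymous rate $\mu = 6.5\times10^{-9}$ substitutions/site/year,
rounding half-up to one decimal Mya as divergence tables conventionally
print; `peakInterval()` converts (mean − sd, mean, mean + sd) to a
(min, mode, max) window, flooring negative lower bounds at zero with a
flag.

## Synteny chaining by progressive gap relaxation

`chainBlocks()` works per (chromosome A, chromosome B) combination and
per orientation (ascending and descending rank progressions are distinct
blocks). The gap criterion — at most `max_gap` intervening genes between
consecutive pairs — is applied on **both** genomes, the stricter reading
of a criterion stated only as a gene count; a single-genome variant would
only relax chains and is not offered.

Extraction is tightest-first: the longest chains are extracted under a
gap allowance of 0, then the allowance is raised one legal level at a
time up to `max_gap`, re-extracting at each level; chains with fewer than
`min_pairs` (default 5) pairs are never extracted. Two properties
motivated this over single-pass longest-chain extraction:

* **Coherence.** A long chain that bridges two distant collinear runs
  with one large jump can otherwise cannibalise both runs and leave
  sub-threshold fragments.
* **Monotonicity by construction.** The ladder of gap levels under a
  smaller cap is a prefix of the ladder under a larger cap, so the set of
  chained pairs can only grow with `max_gap`. With single-pass
  extraction the chained-pair total can occasionally *increase* when the
  gap is tightened (observed on ~3% of random instances); an exact
  maximum-coverage partition with a minimum-block-size constraint has no
  tractable algorithm, so the guarantee is obtained structurally instead.

A known consequence is that one biological block whose internal gaps vary
may be reported as two or three adjacent blocks extracted at different
levels; counts of chained pairs and syntenic depth are unaffected.

`syntenicDepth()` counts, per reference chromosome, the distinct partner
chromosomes covered by at least one block; the modal depth reflects the
cumulative ploidy difference (a diploid against a double-WGD genome shows
mode 4). `assemblePseudochromosomes()` assigns scaffolds to the reference
chromosome holding the plurality of their chained pairs, breaking ties
toward the lower-numbered chromosome with a flag.

## Karyotype painting

`mapHitsToAncestral()` converts each comparative hit into the ancestral
chromosome(s) implied by the chromosome homology map. A hit whose
comparator chromosome maps to several ancestral chromosomes splits its
bitscore equally among them; per-origin masses are then normalised by the
total bitscore, giving a probability vector that sums to one. (The
alternative — crediting the full bitscore to every implied origin — would
break normalisation.) A packaged homology map with published grass
chromosome homologies ships in `inst/extdata/`.

`bootstrapAssign()` draws 1000 replicates of m labels (m = number of
evidence hits, preserving each gene's evidence weight) and scores an
origin's support as the fraction of replicates in which it is the
majority, ties split equally. Replicates are drawn as a *balanced*
bootstrap: the pooled labels match the empirical frequencies exactly
(largest-remainder rounding) and are permuted into replicates. Each
replicate remains an m-label resample, but support estimates carry far
less Monte-Carlo noise than independent multinomial draws — at 1000
replicates, plain resampling has a standard error of about 0.016 on
support values, uncomfortably close to the 0.05 decision margin. An
assignment is unique iff support ≥ 0.5 and the margin over the runner-up
is ≥ 0.05; otherwise all origins within the margin of the best are kept
as candidates.

`paintBlocks()` cross-validates assignments along syntenic blocks built
at the stricter painting gap of 20: the origin shared by a block's
unambiguous members becomes the block origin, ambiguous members inherit
it when it is among their candidates, and blocks split where unambiguous
members disagree. `terminateTransitionZones()` excises sliding windows
(default 10 genes) whose ambiguous fraction exceeds 0.5 — both defaults
configurable, since "a high proportion" is not quantified anywhere — and
flags them as transition zones. Block validation intersects evidence
across comparator species rather than requiring per-species agreement.

`callRearrangements()` reads the painted segment order per chromosome
(segments shorter than 5 genes are noise-filtered), reduces innermost
outer–inner–outer patterns to NCI calls (a nested
A2–A10–A12–A10–A2 pattern yields the A12-into-A10 insertion first, then
A10-into-A2, with an explicit nesting depth), and classifies residual
junctions: a junction mirrored by its reciprocal on another chromosome is
a translocation; a partner origin truncated elsewhere without
reciprocity is flagged unresolved; the rest are end-to-end fusions.
Because an unresolved junction carries translocation-like evidence, only
clean end fusions (and NCIs) count as chromosome-reducing when stage
karyotypes are reconstructed — otherwise a translocation whose short
exchanged tail paints below the segment floor on one side would wrongly
shrink the reconstructed count.
`karyotypeStages()` then classifies each distinct event by the number of
final chromosome copies exhibiting it — events in all $2^w$ copies
(w = WGD count, inferred from the modal per-origin copy number) predate
the first WGD; events in half the copies fall between the WGDs — and
reconstructs the chromosome count at each stage.

## The genome-history simulator

`simulateScenario()` applies an ordered event list (WGD, NCI,
translocation, fractionation, divergence pulse, speciation) to an
ancestral genome of 12 chromosomes × 50 genes (50 genes/chromosome is a
desk-scale choice — enough for painting segments well above the
5-gene noise floor — as no informative-gene density is stated anywhere).
Sequence divergence is simulated per codon: synonymous (and optionally
nonsynonymous) codon replacements at a per-codon probability calibrated
by a short bisection pre-run against the package's own NG86 estimator, so
requested Ks targets are met to within the test tolerance (±0.05 at
targets 0.06–0.9). NCI breakpoints default to uniform interior positions;
scripted scenarios place them mid-arm so all painted segments clear the
noise floor. Gene coordinates are emitted 0-based half-open (BED
convention); soft-masking marks a configurable fraction of genes with
>25% lowercase to exercise the repeat filter.

`spartinaScenario()` encodes the replay used throughout the tests: a
rice-like diploid reference splits first; two ancestral NCIs (A10 into
A2, A9 into A6) reduce 12 → 10; a diploid outgroup splits; WGD1 doubles
to 20; five NCIs (A12 nested into the fused A2–A10 chromosome, A12 into
A7, A5 into A3, A11 into A3, A11 into A8) and one reciprocal distal
translocation between the fused A6–A9 chromosome and A1 reduce 20 → 15;
WGD2 doubles to 30; two sister species split last. Divergence pulses
place the WGD1 peak near Ks 0.28 and the sister-species split near 0.074.
One caveat is inherent to any strictly bifurcating simulator: paralogs
duplicated before speciation cannot be less diverged than orthologs, so
the replay's WGD2 peak sits at the interspecific divergence rather than
below it as published estimates (which likely reflect allopolyploid
origins) would have it; a small shared drift pulse after WGD2 keeps
orthologs the closest hits so RBH and painting behave correctly.

Because running an aligner is out of scope, the simulator also emits the
all-vs-all similarity tables the pipeline consumes
(`simulateSimilarityHits()`): its genes carry no indels, so identity is a
direct per-base comparison, bitscore is proportional to matching bases,
and sub-threshold noise hits are added at a low rate. This keeps the
pipeline deterministic and offline.

## What the tests do and do not show

Everything asserted end to end runs on simulated data: clean orthology,
no tandem arrays, no transposable elements, uniform gene spacing,
homogeneous substitution rates, and a single genome per species. Passing
the recovery tests therefore shows the *pipeline logic* is correct —
filters behave at their boundaries, the estimator matches enumeration,
chaining matches an exact oracle, painting recovers a known history — not
that real assemblies would yield the same counts; genome-scale pair and
block counts require the real data and are out of scope. Problem sizes
were chosen for the package's test suite: 50 genes/chromosome (~2,400
focal genes), 1000 bootstrap replicates, mixtures of up to 3,000 values,
chaining instances of up to 200 genes.

## Worked example

```{r example, eval = FALSE}
replay <- runSpartinaReplay(genes_per_chrom = 50, seed = 1)
replay$stages$n_pre_wgd1       # 10 chromosomes after the shared fusions
replay$stages$n_between_wgds   # 15 chromosomes before the second WGD
replay$depth$modal_depth       # 4: diploid outgroup vs double-WGD genome
replay$karyotype               # painted segments and called events

fit <- fitKsMixture(replay$ks_pairs$Ks, k_range = 1:3, n_bootstrap = 0)
divergenceTable(fit)           # Ks modes with (min, mode, max) Mya windows
```

## Numerical choices, in one place

| Quantity | Default | Why |
|---|---|---|
| e-value / identity / length / repeat | 1e-5 (strict <), 70%, 60 bp, 25% (strict >) | canonical permissive-RBH thresholds |
| Ks range | [0.01, 3) | allelic noise below, saturation above |
| EM tolerance / selection | 0.001 log-lik change / BIC over k ≤ 5 | conventional Ks-mixture settings; explicit criterion for k |
| clock | 6.5e-9 subs/site/yr, T = Ks/(2µ), half-up 1 decimal | monocot synonymous rate; table-style rounding |
| block minimum / gaps | 5 pairs; 100 (synteny), 20 (painting) | detection of WGD blocks vs painting stringency |
| bootstrap | 1000 replicates, balanced; unique iff support ≥ 0.5, margin ≥ 0.05 | variance-reduced resampling against a 0.05 margin |
| transition zones | window 10 genes, ambiguous fraction > 0.5 | "high proportion" quantified as a configurable default |
| min painted segment | 5 genes | matches the synteny block minimum |
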