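---
title: "Methods: MLST marker statistics, simulation design, and in-silico PCR"
author: "markerMLST"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MLST marker statistics, simulation design, and in-silico PCR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerMLST)
```

This vignette documents the models and numerical choices behind the
package: how each statistic is defined, what the strain-panel simulator
does and does not emulate, and where a genuinely open design decision was
resolved.

## The problem

Separating *Bacillus subtilis* from *B. siamensis*, *B. velezensis*,
*B. amyloliquefaciens* and *B. atrophaeus* is not possible from 16S rRNA
(≥ 99% cross-species identity) or carbohydrate-fermentation profiles.
Housekeeping genes used in MLST schemes diverge far more between these
species (protein-coding loci reach ~67–82% cross-species identity while
staying ~99% identical within species), which supports two assays: a
phylogenetic one (trees over single loci or scheme concatenations) and a
PCR one (primers placed on windows conserved within the target species but
mismatched in all relatives). The package computes the statistics that
drive marker choice and then builds and screens the primers.

## Typing statistics

**Alleles.** At each locus, strains with byte-identical sequences (after
uppercasing) share an allele; ids are assigned in order of first
occurrence. This is the strict MLST convention — a single substitution
creates a new allele.

**Polymorphic sites.** A column of the per-locus alignment is polymorphic
when ≥ 2 distinct bases from `A/C/G/T` occur. Columns containing `N` or a
gap in *any* strain are excluded entirely — the conservative SNP-calling
convention, chosen because a partially observed column cannot be
classified reliably.

**Typing efficiency.** TE = k/P, alleles per polymorphic site. For a
monomorphic locus (P = 0) TE is undefined and reported as `NA`; the
division by zero is made explicit rather than silently mapped to 0,
because "no polymorphism" and "inefficient typing" are different
statements.

**Discriminatory power.** The Hunter–Gaston unbiased form
DP = 1 − Σⱼ nⱼ(nⱼ−1)/[N(N−1)] — the probability that two strains drawn
without replacement carry different alleles. This is the standard MLST
estimator for the "likelihood that two strains differentiate"; a test
verifies it exactly against brute-force pair enumeration. We make no claim
of reproducing any particular published DP column: printed DP values in
the motivating table cannot be reconstructed from its own allele counts
under this (or the biased Simpson) form with N = 21, so DP is validated as
a property, not against printed numbers.

**dN/dS.** Nei–Gojobori (1986): per codon, each position contributes the
fraction of its three single-base alternatives that are synonymous to the
synonymous site count (changes to stop codons count as nonsynonymous);
observed differences between codon pairs are averaged with equal weight
over all minimal substitution pathways. Pathways passing through a stop
codon are excluded (the standard rule); in the rare case that every
pathway is blocked the average falls back to all pathways rather than
dropping the codon. Proportions are Jukes–Cantor corrected,
d = −(3/4)·ln(1 − 4p/3); p ≥ 3/4 is saturated and the pair is excluded
with a message. The locus-wide ratio is mean pairwise dN over mean
pairwise dS. Modified (transition/transversion-weighted) counting and
codon-model ML estimators are deliberately out of scope; with them, exact
reproduction of any published per-locus dN/dS would depend on unstated
software settings, so the package validates its implementation against
exhaustive pathway enumeration and against simulation recovery instead.

**Marker ranking.** Two orderings, mirroring how marker loci are chosen in
practice: (a) descending polymorphic sites (ties: descending alleles, then
locus name) — the "most variable locus" criterion; (b) ascending minimum
between-species identity — the "lowest cross-species homology" criterion.
The top locus of each is flagged.

## Identity and trees

Percent identity uses Needleman–Wunsch global alignment with linear gap
penalty (+1/−1/−2 defaults) and the BLAST-like convention: matched columns
over all alignment columns, counting singly-gapped columns as mismatches.
`N` never matches anything. When a locus set is equal-length and gap-free
— always true for simulator output, whose model has no indels —
`speciesIdentitySummary()` takes a per-column (Hamming) fast path; at high
divergence the full aligner can only report equal-or-higher identity
(gaps can buy back matches), so the fast path is the conservative choice
for the identity bands, and a test pins the two routes together at low
divergence.

Trees are built by Saitou–Nei neighbor joining on p-distances (proportion
of differing sites among sites where both strains have an unambiguous
base). NJ-on-p-distance replaces likelihood inference deliberately: the
claim being checked — each species' strains form a clade — is a topology
property that is robust to the inference method at these divergences, and
ML adds model-selection burden without changing that verdict. Negative NJ
branch lengths are clamped to zero with the deficit moved to the sister
branch, preserving path lengths through the parent. Bootstrap support is
out of scope. The five published concatenation schemes ship as built-ins;
their gene names are canonicalized to the seventeen panel locus names
(printed variants `ptA`, `pur`, `tpi` are stored as `pta`, `purH`,
`tpiA`) so every scheme resolves against a panel.

## In-silico PCR

Annealing is modelled as ungapped Hamming matching with a 3' anchor: a
primer binds where it has at most `maxMismatches` (default 2) mismatches
overall and none in its `anchorLen` (default 3) 3'-terminal bases. The
defaults encode the empirical rule that 3'-terminal mismatches are what
kill extension; a thermodynamic duplex model would require parameters the
assay being emulated never reported, and would make results
non-deterministic across parameter sets. Product length runs from the 5'
end of the forward footprint to the 5' end of the reverse footprint, both
footprints included — the convention under which the bundled pycA and
aroE pairs have expected products of 233 bp (20 + 191 + 22) and 278 bp
(20 + 237 + 21). Both template orientations are searched by default, so
reverse-complementing a template never changes the reported product
lengths. Melting temperatures use the Wallace rule, 2(A+T) + 4(G+C),
which is composition-only and hence identical for a primer and its
reverse complement.

Window discovery requires candidate windows to be invariant across all
target-species strains and to carry at least `minMismatches` (default 3)
differences against the corresponding window of *every* non-target
strain, at least one of them within the 3'-terminal three positions (this
3' requirement is waived when `minMismatches = 0`, which then simply
enumerates target-invariant windows). With the default PCR tolerance of 2
mismatches, 3 guaranteed differences suffice to abolish non-target
amplification by count alone; the 3' requirement is a second, independent
safeguard. Coordinates in all reports are 1-based inclusive.

## The simulator

`generatePanel()` emulates the structure of the comparative-genomics
panel: 5 species with 6+3+5+4+3 = 21 strains, the 17 housekeeping loci at
their published lengths, and one slow-evolving non-coding 16S-like locus.
Three of its design choices matter for interpretation:

* **Star phylogeny.** Each locus has one random root; each species
  ancestor derives independently from it, and each strain independently
  from its ancestor. This reproduces the two observed identity bands and
  the species-monophyly signal with trivially verifiable ground truth,
  but it does not emulate a realistic species tree, recombination,
  rate heterogeneity across sites, or indels. Passing tests therefore
  demonstrate that the *pipeline* recovers planted structure, not that it
  would behave identically on real genomes.

* **Divergence calibration.** `pInter` is the target *pairwise*
  inter-species substitution proportion: each species ancestor receives
  `floor(pInter × L / 2)` accepted substitutions, so two species are
  separated by about `pInter × L` along the two branches. (Assigning the
  full `pInter × L` per branch would double pairwise divergence and push
  protein loci below the ~67% identity floor and the 16S-like locus below
  99%.) Defaults: 0.25 / 0.005 (inter/intra) for protein loci, 0.008 /
  0.001 for the 16S-like locus. These place within-species identity near
  99%, protein cross-species identity near 75–80%, and 16S cross-species
  identity near 99.2% — the observed bands. Substitution *counts* are
  deterministic (floor of proportion × length) while positions are
  random, keeping the bands tight across seeds; one RNG substream per
  (seed, locus, species, strain) ensures adding a strain never perturbs
  the others.

* **Selection.** Coding-locus mutation is accept/reject: proposals are
  uniform over sites and alternative bases; stop-creating proposals are
  always rejected, synonymous ones always accepted, nonsynonymous ones
  accepted with probability `omegaTarget` (default 0.4). Because
  proposals are uniform over exactly the change space that Nei–Gojobori
  site counting weights, the realized dN/dS tracks `omegaTarget`; the
  stop-rejection rule removes a slice of the nonsynonymous flux that NG
  sites still count, biasing recovery slightly downward (panel-wide
  recovery lands near 0.35–0.40 for a target of 0.4, within the ±0.1
  recovery tolerance the tests use).

Planted diagnostic windows are copied invariant into every target-species
strain and given exactly 4 substitutions in each non-target species
ancestor, at least one in the window's 3'-terminal three positions and
one in its first three (so both primer orientations keep an anchor
mismatch). Four rather than the minimal three means a single chance
back-mutation during strain-level divergence still leaves more than the
2-mismatch PCR tolerance. The default windows sit on pycA and aroE,
spaced to yield 233 bp and 278 bp products — the sizes of the published
diagnostic pairs.

The locus length for `mutL` is 1890 bp rather than the published 1892,
the nearest multiple of three, since the codon-aware mutator operates on
whole codons.

## Problem sizes and determinism

The test suite regenerates all fixtures in code. The simulation-backed
checks use the default 21-strain configuration at: 20 seeds for dN/dS
recovery, 10 seeds for identity bands and for species monophyly of all
five schemes plus all 17 protein loci, and 3 seeds for end-to-end primer
design/specificity; property checks use 1000 random allele tables for DP
and the full 61 × 61 sense-codon space for pathway counting. These sizes
keep the suite within a few minutes while leaving each estimate's Monte
Carlo error well inside the asserted tolerances. Every stochastic step is
seeded; `generatePanel()` is bit-reproducible for a fixed seed, and
`emitDataset()` output is byte-identical across runs.

## Known limitations

* Exact reproduction of published per-locus dN/dS and DP columns is not
  attempted (unstated estimator settings; see above). The printed TE
  column, which is pure arithmetic on printed counts, is reproduced
  exactly.
* The aligner is a primitive global aligner suitable for same-gene
  pairs; it is not a substitute for a proper multiple-sequence alignment
  when input loci differ in length by more than a few indels.
* The PCR model ignores primer-dimer/hairpin formation, degenerate
  bases, and thermodynamic annealing; a window that passes in silico can
  still fail at the bench.
* `speciesMonophyletic()` treats singleton species as trivially
  monophyletic.
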