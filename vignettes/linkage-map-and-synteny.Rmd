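---
title: "Pseudo-testcross mapping, scaffold anchoring and Oxford-grid synteny with ddRADmap"
author: "ddRADmap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pseudo-testcross mapping, scaffold anchoring and Oxford-grid synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddRADmap)
```

# Scope

ddRADmap implements the computational chain of a ddRAD-based genetic-mapping
and comparative-genomics workflow for a diploid outbred cross: genotype
quality control and pseudo-testcross recoding, sex-specific linkage-map
construction with error correction and map-length/coverage statistics,
anchoring and ordering of draft-assembly scaffolds on the maps, and
Oxford-grid synteny analysis with inference of post-whole-genome-duplication
(WGD) fusion/fission scenarios.  A synthetic-data module generates every
input with known ground truth, so the whole chain is testable without raw
sequencing data.  Read processing, alignment, variant calling and the
whole-genome aligner that produces conserved-segment tables are out of
scope; the package consumes their tabular outputs.

# The mapping model

## Pseudo-testcross genotypes

In an outbred F1 family, a marker heterozygous in exactly one parent
segregates 1:1 in the progeny, like a backcross.  Calls are coded `A`
(homozygote), `H` (heterozygote), and `B` for the alternate homozygote;
under the backcross model `B/H` is a synonym of `A/H`, so
`recodePseudoTestcross()` folds `B` into `A` before analysis.  Markers
informative in the dam build the female map, markers informative in the
sire the male map; loci heterozygous in both parents (or several SNPs
co-located in one restriction-site locus) tie the two maps together.

QC applies, in either order (the filters commute): a completeness filter
keeping markers typed in at least `minTyped` individuals (default the
"more than 95%" rule, `ceiling(0.95 n)`, i.e. 88 of 92), and a Mendelian
segregation-distortion test, the 1-d.f. chi-square
$\chi^2 = (n_A - n_H)^2/(n_A + n_H)$ against 1:1 with exclusion at
$P < 0.001$ (no continuity correction).

## Two-point linkage, grouping, ordering

For each marker pair, `pairwiseLinkage()` counts progeny typed at both
($N$) and recombinants ($R$, phase chosen so $R \le N/2$), with
$\hat r = R/N$ and
$\mathrm{LOD} = R\log_{10}(2\hat r) + (N-R)\log_{10}(2(1-\hat r))$.
Linkage groups are the connected components of the graph with edges at
LOD $\ge$ 7.0 (`groupMarkers()`); singletons are reported separately.

Marker order within a group minimises the sum of adjacent recombination
fractions (SARF).  Groups of up to eight markers are solved exactly by
permutation enumeration — this makes the small-group behaviour a checkable
contract — and larger groups use greedy seriation from the
strongest-linked pair refined by 2-opt segment reversals, relocation of
segments of up to three markers (either orientation) and an exhaustive
sliding-window ripple of width six, iterated to a fixed point.  Ties are
deterministic: equal-SARF optima resolve to the lexicographically smallest
marker sequence, and each group is oriented with its lexicographically
smaller terminal marker first.  Whole-group reversal leaves the SARF and
the map length unchanged, so orientation is a pure convention.

Map positions are cumulative Kosambi distances over adjacent intervals,
$d = 25\ln\frac{1+2r}{1-2r}$ cM with inverse
$r = \tanh(0.02\,d)/2$; an adjacent pair estimated unlinked is capped at
$r = 0.4999$ before the transform so distances stay finite.  Distances are
summed from two-point estimates rather than re-estimated by a multipoint
hidden-Markov model; this keeps every number reproducible from the
pairwise table at the cost of some upward bias when genotyping errors are
present (errors inflate adjacent $\hat r$ by about $2\varepsilon$).

## Error-LOD masking

A genotype whose two flanking calls agree with each other and disagree
with it implies a double crossover in two short intervals — far more
likely a genotyping error.  `errorLodScan()` scores each such call with
$\mathrm{errorLOD} = \log_{10}\frac{\varepsilon(1-r_L)(1-r_R)}
{(1-\varepsilon)\,r_L\,r_R}$, masks calls above 2 as missing, and the map
is rebuilt once on the corrected data (completeness filter, linkage,
grouping and ordering re-run).  Two numerical points matter:

* the observed flanking fractions are themselves inflated by error —
  two independent calls disagree with probability
  $e_2 = 2\varepsilon(1-\varepsilon)$ even at zero genetic distance — so
  the scan first deconvolves $r = (r_\mathrm{obs} - e_2)/(1 - 2e_2)$,
  flooring at $r_\mathrm{min} = 10^{-4}$.  Without this, co-located
  marker stacks (several SNPs in one restriction-site locus) would never
  present the tight flanks the rule is designed around, and the
  threshold-2 rule would never fire at realistic marker spacing;
* the prior error probability defaults to $\varepsilon = 0.01$ and one
  correction pass is performed.  The rule only detects errors flanked by
  tight intervals; isolated errors between ~2 cM intervals give an error
  LOD near 1.5 and are (correctly, given the likelihood) left alone.

## Map length and coverage

`correctedLength()` applies the per-group inflation $(m+1)/(m-1)$ for
chromosome ends beyond the terminal markers, and `genomeCoverage()`
computes $c = 1 - e^{-2dn/L}$.  What to use for $m$ (and the average
interval $d$) is genuinely ambiguous when markers stack at shared
positions: `mapSummary()` defaults to unique co-segregation-binned
positions from `binCosegregating()` (markers with zero observed
recombinants merge transitively into one position), with
`useUniquePositions = FALSE` switching to raw marker counts.  The bundled
published per-group table is summarised with raw marker counts, since
per-group position counts are not part of that table; $d$ is taken as
total observed length over the number of adjacent intervals and coverage
uses the corrected total length.

## Pairing the sex maps

`pairSexMaps()` pairs female and male groups sharing at least two
physical loci (`locus_id`), and when two male groups pair to one female
group and any cross-group marker pair reaches LOD 4.0, the male groups
are merged and the male map rebuilt — the situation arises when a
low-recombination region leaves a male chromosome split at the stricter
grouping threshold.

# Scaffold anchoring and ordering

`assignMarkers()` filters similarity hits at E-value $10^{-20}$ and
applies the two-fold rule: a marker whose best and second-best scaffolds
differ by less than a factor of two in bit score is withheld as
ambiguous (hits to the same scaffold never block assignment; exactly
two-fold is assigned).  A multi-marker scaffold's anchor point per sex is
the median cM of its markers — robust to one bad marker — and scaffolds
whose markers span more than one linkage group are conflict-flagged and
excluded from ordering (`detectConflicts()` also reports intra-group
spans above 20 cM).  Ordering follows the female-first rule set of
`orderScaffolds()`: rank by female anchor position; within a tied female
position, rank by the male map only when the male-separable scaffolds
jointly outweigh (in bp) the longest tied scaffold, otherwise rank only
the longest; male-only-anchored scaffolds are never ranked; orientation
is always unknown.  Equal-length ties break by scaffold id.

# Oxford grids, ohnologs and rearrangement scenarios

`buildGrid()` tabulates conserved segments by chromosome pair (segments
unplaced in either species are excluded and counted), `classifyBoxes()`
counts syntenic boxes — single cells holding at least 6 segment pairs,
"high" boxes at least 16, percentages over gridded segments with integer
rounding — and `detectOneToTwo()` reports outgroup chromosomes whose
segments concentrate on two focal chromosomes (defaults: jointly at
least 75% of the row, each at least 3 segments; the thresholds are
configurable and are not claimed to reproduce qualitative calls made by
eye).  `detectOhnologQuadruplets()` reports the two-to-two pattern in
which both members of a focal pair share at least 3 segments with both
members of a sister-species paralogous pair.

`predictGrid()` applies a WGD followed by a scenario's fusion and
fission events and classifies each chromosome pair as
orthologous-large (shared duplicate copy), paralogous-small (paralogous
copies of one ancestral region) or empty.  `rankScenarios()` scores a
candidate against an observed grid, maximised over row/column
relabellings: +1 for an observed-nonzero cell under a predicted-nonempty
cell, −1 for an observed cell of at least `tSmall = 3` segments under a
predicted-empty cell, −1 for a predicted-nonempty cell with no observed
segments; observed cells below `tSmall` over empty predictions are
ignorable noise.  Scenarios whose chromosome counts do not match the
grid are incomparable (−Inf).  Ties — notably a single common-lineage
fusion versus two independent same-partner fusions, which predict
identical grids — break by fewer events (parsimony), then input order.
The penalty on predicted-nonempty/observed-zero cells is what demotes a
fusion-plus-fission alternative whose extra paralogous row is absent
from the data.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is tested:

* **Karyotype**: 19 chromosomes by default (2n = 38), ~92 cM and ~60 Mb
  each — the scale of the eel-like teleost map the pipeline targets.
* **Meiosis**: the transmitted parental phase is a two-state Markov
  chain along ordered loci with switch probability equal to the
  inverse-Kosambi fraction of each interval.  This is a modelling
  simplification — no crossover process, no interference beyond the
  Kosambi implicit amount — chosen so adjacent recombination fractions
  are exactly consistent with the estimator's convention, enabling clean
  parameter-recovery tests.
* **Family**: 92 progeny by default.  Loci are dam-, sire- or
  both-informative (0.375/0.375/0.25); a both-informative locus is
  emitted as a co-located dam-read/sire-read marker pair sharing a
  `locus_id`, which is how fully informative loci anchor the two sex
  maps here.  Each locus emits a second co-located SNP with probability
  0.5 (`snpsPerLocus = 1.5`, the density typical of ~100 bp
  restriction-site tags); the resulting zero-distance stacks are what
  give the error scan tight flanks to work with.
* **Noise**: symmetric homozygote/heterozygote flips at rate 0.01 and
  missingness 0.02.  No real error/missingness rates are published for
  the motivating data; these defaults are conventional for
  reduced-representation genotyping and configurable.
* **Digestion**: BamHI (G|GATCC) by MspI (C|CGG) with a 120–180 bp
  size window; `digestGenome()` returns exactly the two-enzyme bounded,
  size-selected fragments (1-based inclusive coordinates), and
  `compareDigestProtocols()` allocates a read budget multinomially over
  ddRAD loci versus all single-enzyme flanks.
* **Scaffolds**: chromosomes are tiled exactly (lengths sum to the
  chromosome length); each marker hits its true scaffold with a high bit
  score and a configurable fraction get a decoy hit whose true/decoy
  ratio is uniform on (1.2, 2.8) — straddling 2.0 so both branches of
  the ambiguity rule are exercised.
* **WGD histories**: every ancestral chromosome contributes a fixed
  number of segments, duplication doubles them, events relabel
  locations, and with a configurable confusion probability a segment's
  detected partner in the second species is reassigned to the
  paralogous chromosome — emulating the vague orthology assignment
  between ohnologous chromosomes of species that diverged soon after
  the duplication.

What the generator does **not** emulate: read-level sequencing noise and
quality scores, PCR duplicates, allele dropout and reference bias,
locus-specific missingness, segregation-distortion clusters,
non-uniform recombination (deserts around centromeres), unequal
chromosome sizes within a genome, and assembly misjoins other than the
decoy-hit mechanism.  Passing recovery tests therefore demonstrates the
correctness of the estimators under the stated stochastic model, not
robustness to every artefact of real ddRAD data.

# Numerical choices and problem sizes

* rf floor inside the LOD, $10^{-6}$; unlinked-rf cap 0.4999; flank
  floor $r_\mathrm{min} = 10^{-4}$; one error-correction pass.
* Exhaustive ordering up to 8 markers; ripple window 6; refinement
  iterated to a strict fixed point, so results are deterministic.
* The test-suite and acceptance-script problem sizes are chosen to keep
  the whole suite in a few minutes on one core: 20 (suite) or 5
  (script) replicates of a 19-chromosome family with 53 loci × 1.5 SNPs
  (~80 markers) per chromosome and 92 progeny; 500 random small groups
  against the brute-force ordering oracle; 1000 random grids against
  the box-scan oracle; 200 seeded WGD replicates at confusion 0.3 for
  scenario recovery.

# Known limitations

* Two-point SARF ordering at n = 92 resolves marker order to roughly
  the interval scale of the rf standard error (~1.5 cM).  In noisy
  replicates the mean per-group rank correlation with the true order is
  about 0.993, but individual groups — typically chromosome ends, where
  a terminal block reversal costs almost no SARF — can fall noticeably
  lower, and the SARF optimum itself sometimes prefers a locally wrong
  arrangement.  Resolving this would require multipoint likelihood
  ordering, which is deliberately out of scope.
* Map lengths summed from two-point estimates remain inflated by
  whatever genotyping error the scan cannot detect (isolated errors
  between ~2 cM flanks).
* Scenario ranking enumerates chromosome relabellings exhaustively and
  is meant for the small subgrids (2–4 chromosomes per species) that
  fusion/fission arguments concern, not whole-genome grids.
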