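---
title: "From genome to markers: the SSRtools analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From genome to markers: the SSRtools analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SSRtools)
```

SSRtools implements the complete computational chain of a genome-wide SSR
(simple sequence repeat, microsatellite) marker study in plant germplasm:
repeat mining, primer design, cross-species transferability, per-locus
diversity statistics, germplasm clustering, Bayesian admixture inference
with Evanno model choice, and GLM/MLM marker–trait association.  This
vignette explains the models and procedures, the tunable parameters and
their defaults, the numerical choices, and what the bundled simulations do
and do not demonstrate about real data.

## SSR mining

A perfect SSR is a maximal tandem array of a primitive 1–6 bp motif.
`findSSRs()` reports an array when its complete-repeat count reaches the
period's threshold; the defaults (`miningThresholds()`) are ten repeats for
mononucleotides, six for dinucleotides and five for tri- through
hexanucleotides — the common genome-survey setting for this marker class.
Three conventions pin the output down:

* **Primitive period.** Every array is reported once, under its smallest
  period.  A poly-A run is a mononucleotide locus; it is never re-described
  as an "AA" dinucleotide.  Internally this falls out of requiring the
  leading motif of each maximal periodic segment to be primitive: a
  periodicity argument (two periods `p > q` on a segment of length at least
  `p + q` force a common divisor period) guarantees that a primitive
  leading motif implies minimal period.
* **Complete repeats.** Trailing partial repeats are trimmed, so
  `length == period * repeats` always holds, and the reported start is the
  leftmost phase of the maximal segment.
* **Canonical motif classes.** `canonicalMotif()` folds phase and strand:
  the class representative is the lexicographically smallest string among
  all cyclic rotations of the motif and of its reverse complement.  T-runs
  fold into class "A"; GA, TC and CT repeats all fold into "AG".  This
  minimality rule reproduces the folded classes conventionally reported
  (A, AT, AG, AAT, AAAT, ...) and is idempotent, which the tests exploit.

Arrays never cross non-ACGT characters.  Soft-masked lowercase is folded to
uppercase by default — masked repeats are still repeats; a mining run that
should skip masked regions can pre-process the sequence instead.

Genome-wide summaries (`summarizeSSRs()`) report relative abundance
(loci/Mb) and relative density (bp/Mb).  The denominator is the full
scanned assembly span including Ns by default; `genomeSize(excludeN =
TRUE)` exposes the N-free alternative, because published abundance figures
are frequently inconsistent about which denominator was used and both
readings should be checkable.  The per-sequence count versus length
Pearson correlation is reported only with three or more sequences;
with fewer it is `NA` rather than an error, since a two-chromosome toy
genome is legitimate input.

The mining scanner is verified two ways: against a deliberately naive
quadratic oracle that tests every (start, period, extension) triple, on
hundreds of random and repeat-dense sequences; and against planted-truth
genomes from `generateGenome()`, where every above-threshold plant must be
recovered at exact coordinates and every one-repeat-short plant must be
absent.

## Primer design

`designPrimers()` enumerates all (left, right) primer windows in the
flanks whose product contains the repeat array, then filters on the
classic validation constraints: product 100–250 bp, primer length
18–24 nt, Tm 50–60 °C, GC 40–60 %, and a maximum Tm difference of 3 °C
within a pair (`primerConstraints()`).  Melting temperature uses the
Wallace rule `2(A+T) + 4(G+C)` below 14 nt and `64.9 + 41(GC − 16.4)/len`
from 14 nt — deliberately simple, monotone in GC, and sufficient for a
50–60 °C acceptance window; nearest-neighbour thermodynamics could be
slotted in without touching the search.  The published protocols this
emulates name only an annealing window, which is treated here as a Tm
window.  Candidates are ranked by Tm balance, then product-size centrality,
then coordinates, so output order is reproducible.  No dimer or hairpin
screening is performed.

## Cross-species transferability (e-PCR)

`epcr()` places a primer pair on a target sequence under the transfer
rules: ungapped alignment, at most five mismatches in the 5' part of each
primer, **zero** mismatches in a fixed 3' anchor (default 5 bp — the rule
"no mismatches at the 3' end" needs an operational anchor length, which is
exposed), at least 90 % identity per primer, convergent orientation on
either strand, product at most 2 kb.  Identity is computed per primer over
its full length, the stricter of the two possible readings of a pairwise
homology threshold.  Candidate placements come from
`Biostrings::matchPattern()`; the anchor constraint is then checked
per hit.  A BLAST pre-screen is unnecessary at these scales because the
decisive published filters are exactly the mismatch/anchor/identity rules.

`buildSyntenyLinks()` applies the published post-filters: amplicons on
scaffold-like sequences (configurable regular expression) are dropped at
both endpoints, and multiple amplicons of one marker on one target
chromosome collapse to the single best placement (fewest total mismatches,
then smallest coordinate), yielding one link per (marker, target
chromosome) and per-chromosome-pair counts — the numeric content behind a
Circos transferability figure.  Reproducing any particular published
cross-species count would require the corresponding genome assemblies and
is out of scope.

## Diversity statistics

For each locus, allele frequencies come from the non-missing diploid calls
(two observations per individual, pairwise-complete across loci).
`locusSummary()` reports: observed allele number Na; effective allele
number `Ne = 1/Σp²`; observed heterozygosity Ho; Nei's gene diversity
`H = 1 − Σp²`; unbiased expected heterozygosity `He = 2n/(2n−1) · H`;
Shannon's index `I = −Σ p ln p`; and Botstein's polymorphism information
content `PIC = 1 − Σp² − Σ_{i<j} 2p_i²p_j²`.  The identities
`Ne = 1/(1 − H)` and `PIC ≤ H ≤ I` hold exactly and are property-tested on
random draws.  Markers classify as highly polymorphic at `PIC ≥ 0.5`,
moderate in `(0.25, 0.5)` and low at `PIC ≤ 0.25`, applied to unrounded
values.

One published 42-marker table bundled as a fixture
(`chayoteDiversityTable()`) prints every row with `Ho + He = 1.00`
exactly, which no standard He estimator produces; SSRtools implements the
standard unbiased estimator and does not imitate that artefact.  The
fixture is used only for what it is good for: checking that the package's
summary and classification code reproduces the table's own totals, means
and class counts (153 alleles, mean Na 3.64, mean PIC 0.41, 14 high-PIC
markers).  Note the table also contains one marker at exactly PIC = 0.25,
which the stated boundaries classify as "low" — on unrounded values the
low class therefore counts 9, although the accompanying narrative says 8.

## Clustering

Genotypes are binarized to allele presence/absence bands per locus
(`alleleBands()`), the encoding gel-band-based similarity programs use.
`similarityMatrix()` scores pairs over jointly typed bands with simple
matching (the common default for this data type), Dice or Jaccard, and
returns distance `1 − s`.

`upgma()` is written out explicitly rather than delegated, because its
contract includes a deterministic tie-break (smallest original (row,
column) index pair) that generic implementations do not promise; the
tests cross-check heights and cophenetic distances against
`hclust(method = "average")` on random inputs.  Merges happen at height
d/2, so leaf depth equals half the cophenetic distance, the tree is
ultrametric by construction, and ultrametric inputs are reproduced
exactly.  Newick output uses branch lengths rounded to 6 decimals for
byte-stable files.

`pcoa()` performs Gower double-centering of `−d²/2` and a symmetric
eigendecomposition.  Coordinates are eigenvectors scaled by the square
root of their eigenvalues; negative eigenvalues (non-Euclidean input) are
excluded from both the coordinates and the percent-explained denominator —
the simplest defensible convention; no Cailliez correction is applied.
Classical scaling (`cmdscale`) serves as the reference implementation in
the tests, never as the code path.

## Admixture inference

`fitAdmixture()` implements the admixture model with independent allele
frequencies: individual i has membership proportions `Q_i ~
Dirichlet(alpha)`, population k has per-locus allele frequencies `P_kl ~
Dirichlet(lambda)`, and each allele copy picks an origin population from
`Q_i` and then an allele from that population's frequencies.  A Gibbs
sweep (in compiled code, using R's RNG so runs are seed-reproducible)
alternates: origins `Z | P, Q`; frequencies `P | Z`; proportions
`Q | Z`; and, by default, a random-walk Metropolis update of the
admixture hyperparameter alpha under a flat prior on (0, 10) with
proposal sd 0.025 — the behaviour of the standard samplers for this
model, and important in practice: with crisp population structure the
posterior drives alpha small, which sharpens the Q estimates; holding
alpha at 1 leaves them diluted toward the prior.  Set `inferAlpha =
FALSE` in `mcmcConfig()` to fix alpha.  Missing allele copies are simply
skipped in the Z update; no imputation.

The model evidence is estimated from the post-burn-in log-likelihood trace
as `mean(lnL) − var(lnL)/2`, the estimator the established model-choice
workflow relies on.  `structureScan()` runs replicate chains over a K
range (deterministic per-run seeds derived from the base seed) and
`evannoDeltaK()` computes, per interior K, the replicate-averaged absolute
second difference of L(K) divided by sd(L(K)); the arg-max is the
suggested K.  ΔK is undefined at the boundary K values and wherever the
replicate sd is zero, and a flat ΔK profile raises a warning rather than a
confident answer.

Desk-scale defaults (1,000 burn-in, 10,000 main iterations) are a tenth of
the full-scale setting (10,000 / 100,000 / 10 replicates / K 1–10), which
remains reachable through `mcmcConfig()`.  The bundled recovery checks use
a planted two-population panel (40 individuals, 30 biallelic loci with
allele frequencies 0.9 versus 0.1, 200 + 1,000 iterations, 3 replicates,
K = 1–4) and require the ΔK peak at K = 2 in at least 9 of 10 seeds.

## Marker–trait association

`glmScan()` regresses the (numerically coded) trait on genotype-class
indicators per marker — the coding that handles multi-allelic SSRs without
assuming additivity; allele-dosage coding is available for biallelic
loci — plus an intercept and optionally K−1 admixture covariates.  The
marker is tested by a partial F-test; `PVE = 100 (RSS_reduced −
RSS_full)/TSS`.

`mlmScan()` adds a polygenic random effect with covariance `σ_g² · 2K`,
with `K` an allele-sharing IBS kinship (`ibsKinship()`: 1 for identical
genotypes, 0.5 for one shared allele copy, 0 otherwise, averaged over
jointly typed loci).  The kinship spectrum is bent by clipping eigenvalues
within numerical noise of zero; genuinely indefinite matrices are
rejected.  The variance ratio is profiled by one-dimensional REML on the
eigen-rotated model (one eigendecomposition, reused across markers when
the markers are fully typed), and the marker is tested by the partial
F-test on the whitened fit.  With identity kinship the whitening is a
scalar and MLM reproduces GLM exactly — a collapse the tests assert to
1e-6 relative.  Raw p-values are reported; the emulated workflow applies
plain thresholds, so no multiplicity correction is imposed by default.

Trait encodings for the fruit phenotypes (peel color white/light
green/green/dark green as 0–3; spine none/very low as 0–1) are package
conventions — published category tables rarely state numeric codes — and
are exposed via `traitCodes()`.  Whether Q, kinship or both enter a scan
is the caller's choice, since published methods statements are often
ambiguous on this point; both arguments are independently optional.

## Synthetic data: what it does and does not show

The generators exist so every stage is testable without any external
download, at the scale of the emulated study design (35 accessions, 42
markers, two clusters):

* `generateGenome()` plants exact perfect arrays in i.i.d. background at a
  chosen GC, fixes flanking bases that would extend an array, and returns
  the truth table.  Background repeats still arise by chance — that is
  realistic and intended — so recovery is scored on planted loci, and
  full-output equivalence is checked against the brute-force oracle, not
  against an assumption that only plants exist.
* `generateStructuredGenotypes()` draws Q from Dirichlet(alpha), allele
  frequencies either given or drifted from ancestral frequencies by a
  divergence parameter F (Dirichlet analogue of the Balding–Nichols
  model), then samples allele copies through the same generative model the
  admixture sampler inverts.  Defaults (alpha 0.2, F 0.3, four alleles,
  2 % missing) produce panels that look like a moderately diverged
  germplasm collection.
* `generatePhenotype()` builds traits as effect × reference-allele dosage
  plus Gaussian noise scaled to a target heritability, recording realized
  per-marker PVE.

All generators are bit-reproducible under (spec, seed).  What passing
tests on these data do **not** show: microsatellite mutation realism (no
stepwise mutation, no homoplasy), linkage (loci are independent), genuine
He estimator behaviour under inbreeding, or the behaviour of the e-PCR
rules under structural variation — conclusions about real germplasm still
require real genotypes.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive everywhere in memory and in GFF3;
  BED output converts to 0-based half-open.
* Monomorphic loci yield Na 1 and zeros for Ne−1, H, He, I, Ho, PIC
  rather than errors; loci with fewer than two typed individuals error.
* Constant or rank-deficient markers are skipped with a warning in the
  association scans, not silently dropped.
* UPGMA rejects NA distances; PCoA rejects asymmetric input; eigenvalues
  below `1e-9 × max|eigenvalue|` are treated as null.
* The problem sizes used in the bundled checks (10 kb oracle sequences,
  40 × 30 admixture panels, 100 × 200 null scans) were chosen as the
  smallest sizes at which the corresponding statistical claims are
  comfortably testable.

## A worked mini-pipeline

```{r pipeline}
set.seed(1)
planted <- data.frame(seq_id = "chr1", pos = c(2000, 4000),
                      motif = c("AT", "AAG"), repeats = c(8, 6))
g <- generateGenome(c(chr1 = 8000L), gc = 0.4, planted = planted, seed = 2)
loci <- mineSSRs(g$sequences)
summarizeSSRs(loci, c(chr1 = 8000))

sim <- generateStructuredGenotypes(seed = 3)   # 35 x 42 two-cluster panel
head(summaryTable(sim$genotypes)$perLocus, 3)

d <- similarityMatrix(sim$genotypes)
pcoa(d)$percentExplained[1:2]

scan <- structureScan(sim$genotypes,
                      mcmcConfig(burnIn = 200, mainIterations = 800,
                                 replicates = 3, kRange = 1:4, seed = 4))
scan$bestK
```

## Known limitations

Imperfect and compound microsatellites are not modelled; primer design has
no thermodynamic secondary-structure screen; e-PCR is ungapped; the
admixture sampler implements the independent-frequencies model only (no
linkage model, no correlated-frequencies prior, no CLUMPP-style multi-run
alignment); MLM fits one variance component; and the published accession
panels this toolkit emulates cannot be reproduced exactly here because
their raw genotype calls are not printed in any table.
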