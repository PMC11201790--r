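# SSRtools

An R toolkit for genome-wide SSR (simple sequence repeat / microsatellite)
marker studies in plant germplasm — the kind of study that mines a genome
assembly for repeats, designs and validates primer panels, and then uses
the resulting co-dominant markers to describe diversity, structure and
marker–trait associations in a germplasm collection.

The pipeline covers, end to end:

1. **SSR mining** — perfect 1–6 bp tandem arrays under per-period
   minimum-repeat thresholds (mono ≥ 10, di ≥ 6, tri–hexa ≥ 5 by default),
   with motif classes folded over phase and strand (poly-T → "A";
   GA/TC/CT → "AG"), and genome-wide summaries: counts by period, relative
   abundance (loci/Mb), relative density (bp/Mb), motif-class frequencies,
   count-versus-length correlation.
2. **Primer design** — exhaustive flank search under product 100–250 bp,
   length 18–24 nt, Tm 50–60 °C (Wallace / GC rules), GC 40–60 %,
   pair ΔTm ≤ 3 °C.
3. **Transferability (e-PCR)** — ungapped primer placement on other
   genomes with ≤ 5 mismatches 5' of a zero-mismatch 3' anchor and ≥ 90 %
   per-primer identity; scaffold and duplicate filtering down to one
   synteny link per (marker, target chromosome), plus chromosome-pair
   counts and Circos-style link files.
4. **Diversity statistics** — per locus Na, Ne = 1/Σp², Ho,
   He = 2n/(2n−1)·(1−Σp²), Shannon's I = −Σp ln p, Nei's H = 1−Σp², and
   Botstein's PIC = 1 − Σp² − Σ_{i<j} 2p_i²p_j², with the standard
   high (≥ 0.5) / moderate / low (≤ 0.25) PIC classification.
5. **Clustering** — allele-band similarity (simple matching / Dice /
   Jaccard), deterministic UPGMA with Newick output, and PCoA with
   per-axis percent variance explained.
6. **Admixture** — a STRUCTURE-style Gibbs sampler (compiled, seed
   reproducible) for the admixture model with independent allele
   frequencies and sampled alpha, replicate scans over K, and Evanno
   ΔK = mean|L″(K)| / sd L(K) model choice.
7. **Association** — GLM (marker + structure covariates, partial F-test,
   PVE) and MLM (adding a polygenic effect with IBS kinship, profiled
   REML on the kinship eigen-spectrum).
8. **Synthetic data** — genomes with planted SSR truth, structured diploid
   genotypes with known admixture proportions, and phenotypes with known
   marker effects, so every stage above is testable with exact ground
   truth.

Central containers follow Bioconductor conventions: mined loci are
`GRanges`, genotype panels are an S4 `GenotypeMatrix` with validity
checks, admixture fits are S4 `AdmixtureResult` objects with accessors
(`membershipQ()`, `alleleFreqP()`, `lnProbData()`).

## Worked example

```r
library(SSRtools)

# a small genome with two planted repeats
planted <- data.frame(seq_id = "chr1", pos = c(2000, 4000),
                      motif = c("AT", "AAG"), repeats = c(8, 6))
g <- generateGenome(c(chr1 = 8000L), gc = 0.4, planted = planted, seed = 2)
loci <- mineSSRs(g$sequences)
summarizeSSRs(loci, c(chr1 = 8000))
#> SSR mining summary
#>   total loci: 2  (total 34 bp, mean 17.0 bp)
#>   relative abundance: 250.00 loci/Mb, density: 4250.00 bp/Mb
#>   by period: 1:0 (0.00%)  2:1 (50.00%)  3:1 (50.00%)  ...

# a 35-accession, 42-marker two-cluster panel with known structure
sim <- generateStructuredGenotypes(seed = 3)
st  <- summaryTable(sim$genotypes)
round(st$means[c("Na", "Ne", "Ho", "He", "PIC")], 2)
#>   Na   Ne   Ho   He  PIC
#> 3.29 1.98 0.40 0.46 0.40

scan <- structureScan(sim$genotypes,
                      mcmcConfig(burnIn = 200, mainIterations = 800,
                                 replicates = 3, kRange = 1:4, seed = 4))
scan$bestK
#> [1] 2
```

The bundled `chayoteDiversityTable()` fixture — a published table of
per-marker diversity statistics for 42 polymorphic SSRs scored in 35
chayote (*Sechium edule*) accessions — feeds the same summary code:

```r
st <- summaryTable(chayoteDiversityTable())
sum(st$perLocus$Na)            # 153 alleles
round(unname(st$means["PIC"]), 2)  # 0.41
st$classCounts                 # low 9, moderate 19, high 14
```

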