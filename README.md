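# ModifierScan

Mapping genetic modifiers of a survival phenotype in a two-inbred-strain
mouse cross.

## The problem

In mouse models of vascular Ehlers–Danlos syndrome (vEDS; heterozygous
*Col3a1* glycine substitutions), the C57BL/6-like background dies early of
aortic rupture while a 129-like background is strongly protective. To find
the loci responsible, the two strains are intercrossed for four generations
and mixed-background females are bred to mutant males on the susceptible
background, producing a cohort in which every animal carries 0 or 1
protective-strain allele at each locus. Survival is stratified into
extremes — death from rupture between 1 and 12 weeks (cases) versus
survival past 24 weeks (controls) — and each marker is tested with a
sex-adjusted logistic regression:

    logit P(case) = b0 + b1 · dosage + b2 · [male]

where dosage counts protective-strain alleles. Genome-wide significance is
Bonferroni over the number of LD blocks (alpha / m after pruning to one SNP
per block at r² ≤ 0.5); the significant region is bounded by the closest
non-significant flanking markers, and genes inside it are triaged by aorta
expression and putatively functional inter-strain variation (splice,
nonsense, frameshift, or missense/indel with deleteriousness score
≤ −2.5).

The package is Bioconductor-style R: genotype calls live in a
`SummarizedExperiment` subclass, gene/region overlap uses
`GenomicRanges`, survival statistics use `survival`, and every stage —
breeding-design simulator, stratification, QC cascade, LD pruning, scan,
region delineation, triage — is an exported, tested function. See the
vignette (`vignettes/modifier-mapping.Rmd`) for the model, the pinned
numerical choices, and what the simulator does and does not emulate.

## Worked example

The bundled demo runs the whole pipeline on simulated data with a
protective locus (per-allele OR 0.2293) planted near 110.5 Mb of
chromosome 11:

```r
library(ModifierScan)
res <- runPipeline(pipelineConfig(outDir = "demo_out"))

res$qc$report
#> QC cascade: 626 markers in, 573 released
#>   call_rate              removed      8  remaining    618
#>   maf                    removed     26  remaining    592
#>   het_rate               removed      6  remaining    586
#>   hom_missing            removed      3  remaining    583
#>   parental_concordance   removed      6  remaining    577
#>   f1_concordance         removed      4  remaining    573
#>   no-calls among released: 151 / 110589 (0.14%)

res$scan
#> ScanResult: 171 markers tested; Bonferroni threshold 0.0002924 (alpha 0.05 / 171 blocks)
#>   2 significant marker(s); peak chr11_m030 (chr 11, bp 112971326): p = 1.26e-05, OR = 0.1994 (95% CI 0.0967-0.4111)

res$region
#> Region chr 11: 86,426,523-112,971,326 bp (26.5 Mb), peak chr11_m030 at 112,971,326 bp

res$candidates[res$candidates$candidate, c("symbol", "differentiallyExpressed", "rank")]
#>    symbol differentiallyExpressed rank
#> 1    Bptf                    TRUE    1
#> 4    Helz                    TRUE    2
#> 9    Tmc6                   FALSE    4
#> 11 Tnrc6c                   FALSE    5
#> 12 Map2k6                    TRUE    3
```

Reading the output: the QC cascade removed 53 of 626 simulated markers
(each injected defect class at its intended stage; the released panel's
no-call rate matches the calibrated 0.14%). LD pruning reduced 573 released
markers to 171 quasi-independent blocks; the scan found a significant
protective signal on chromosome 11 (estimated OR 0.20 per protective
allele, near the planted 0.2293), whose peak sits two markers from the
planted locus — with this marker spacing, LD localizes the signal only to
the neighborhood. The delineated region is wide (26.5 Mb) because the
pruned scan grid is sparse; the triage report then recovers the planted
modifier gene analog (*Map2k6*) among five candidates, ranked behind no
other differentially expressed gene on its side of the list. Many seeds
yield no significant marker at all: at n = 187 the design is marginally
powered, as the real one was.

Per-stage functions (`simulateCross()`, `stratifySurvival()`, `runQC()`,
`ldPrune()`, `genomeScan()`, `delineateRegion()`, `triageCandidates()`)
expose every intermediate, and `writePedMap()`/`readPedMap()` round-trip
PLINK text PED/MAP.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the headline simulation quantity: it simulates 500 replicate
terminal cohorts (n = 187; 96 males, 91 females) through the full breeding
program with a planted protective locus of per-allele OR 0.2293, fits the
sex-adjusted logistic model at the planted marker in each replicate, and
writes the mean odds-ratio estimate as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

Runtime is a few minutes on one CPU; all randomness derives from `--seed`.
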