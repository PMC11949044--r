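---
title: "Mapping survival modifiers in a two-strain mouse cross"
author: "ModifierScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping survival modifiers in a two-strain mouse cross}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ModifierScan)
```

## The scientific problem

Vascular Ehlers–Danlos syndrome (vEDS) is caused by heterozygous *COL3A1*
mutations; in mouse models carrying a glycine substitution in type III
collagen, the C57BL/6-like (strain A) genetic background confers a high risk
of early death from aortic rupture, while a 129-like background (strain B)
is strongly protective. Loci at which a strain-B allele changes severity —
*modifier loci* — can be mapped by crossing the strains, scoring survival in
mutant offspring of mixed background, and asking where strain-B allele
dosage associates with outcome.

ModifierScan implements that analysis end to end: a simulator of the
breeding design and phenotypes (so every downstream stage is testable
without any external data), extreme-phenotype stratification of survival
records, an ordered SNP QC cascade, pairwise LD pruning, a sex-adjusted
logistic genome scan with Bonferroni-over-blocks significance, delineation
of the significant region, and candidate-gene triage.

## The breeding design and its simulation

Two fully inbred founder strains, opposite homozygotes at every informative
marker, are intercrossed for four generations of wild-type animals
(F1–F4) to accumulate recombination between strain-specific chromosomes.
F4 females are then bred to pure strain-A males heterozygous for the
disease mutation. Each terminal offspring therefore carries one recombinant
mixed-background autosomal haplotype (from its dam) and one pure strain-A
haplotype (from its sire), so strain-B dosage is 0 or 1 at every autosomal
marker, each with expectation 1/2. Only mutant offspring (probability 1/2;
the sire is heterozygous) are retained — the phenotype is undefined for
non-mutants. Because the sire is strain-A at every marker, mutation
transmission carries no marker information and is simulated as an
independent fair coin.

Meiosis uses the **Haldane model**: crossover counts on a chromosome of
genetic length $L$ Morgans are Poisson($L$), crossover positions are
uniform, and there is no interference, giving the map function
$r = (1 - e^{-2d})/2$. The design source does not state a map function;
Haldane is the simplest defensible choice and makes closed-form checks
possible. The male X is transmitted to daughters without recombination; the
Y passes to sons as a strain label.

Choices a user can revisit (defaults in parentheses):

* **Marker panel** (`defaultGeneticMap()`): 19 autosomes plus X and a token
  Y pair, 32 markers per autosome (608 autosomal markers) — the scale of a
  post-pruning panel (~615 quasi-independent blocks), not of the full 143k
  array, for desk-scale runtime. Autosome lengths taper 98→55 cM and
  195→61 Mb, echoing the mouse genome.
* **Generation sizes** (`crossScheme()`: 20, 30, 40, 60, then 187 terminal
  mutants): the real expansion sizes are not published; these expand the
  colony each generation as described and keep a replicate cohort under a
  second of runtime. Sex quotas for the terminal cohort can be fixed
  exactly (96 M / 91 F reproduces the analyzed cohort's composition).
* **Mating** is random, monogamous within a generation; selfing is
  impossible by construction and sib mating is allowed.

One consequence worth knowing: with colony sizes this small, genetic drift
through the F1–F4 bottlenecks is substantial. Individual pedigrees can fix
chromosome segments for either strain, so single-pedigree allele
frequencies at a marker scatter around 0.5 far more than binomial sampling
alone predicts (the test suite therefore assesses transmission neutrality
across replicate pedigrees), and occasionally a segment fixed for strain B
makes every terminal offspring heterozygous there — such markers are
legitimately removed by the heterozygosity QC filter.

## The phenotype model

The binary severe/mild outcome follows a logistic model on the linear
predictor

$$\mathrm{logit}\,P(\text{severe}) = \beta_0 + \beta_{sex}\,[\text{male}]
  + \beta_{locus}\,\text{dosage},$$

with an optional sex-by-locus interaction (default 0). Defaults plant a
protective per-allele odds ratio $e^{\beta_{locus}} = 0.2293$ and a male
excess of $e^{\beta_{sex}} = 4.94$ (the cross-product odds ratio of the
observed sex-by-severity table); `tuneBaseline()` solves $\beta_0$
numerically so the expected severe fraction matches a target (default
96/187 ≈ 51%) under the cohort's sex and dosage mix. Note the planted
$\beta_{sex}$ is a marginal quantity re-used as a conditional coefficient;
the small difference is irrelevant at this effect size and is absorbed by
the baseline tuning.

Severe animals die of rupture at a uniform time in days 8–84 (only the
window is known; uniform is the least-informative choice); mild animals
survive past day 168. Small fractions (2%, 3%, 4%) of first-week deaths,
intermediate-window rupture deaths and non-rupture deaths are generated so
the exclusion rules downstream have work to do; set them to zero to make
the analyzed cohort exactly the simulated one.

## Stratification

Cases are rupture deaths with $7 < t \le 84$ days; controls survive
strictly beyond 168 days (alive, censored, or death from any cause after
that day); everything else is excluded with a recorded reason
(`died_first_week`, `intermediate_death`, `non_rupture_death`,
`censored_early`, or `missing_cause` for deaths without a recorded cause —
flagged, never dropped). Week boundaries are pinned as 1 week = 7 days,
12 weeks = 84, 24 weeks = 168; whether the source's "between 1 and 12
weeks" window is closed at 12 weeks is not stated, and the package pins
$t \le 84$ as a case. Both bounds are `stratificationRule()` parameters.

Survival-side statistics use standard machinery: Kaplan–Meier curves and
the unstratified Mantel–Cox log-rank test (via the `survival` package) and
a two-sided Fisher exact test for the sex-by-severity table, with the
cross-product odds ratio.

## The QC cascade

Filters run in a fixed order, each on the survivors of the previous:

1. **Call rate**: markers called in < 90% of samples are assay failures
   (exactly 90% passes — the rule says "less than").
2. **MAF = 0**: monomorphic markers.
3. **Heterozygote rate** > 80% (strictly) or = 0.
4. **Missing homozygote class**: AA or BB frequency = 0.
5. **Parental concordance**: the two founder-strain reference profiles
   must be opposite homozygotes.
6. **F1 concordance**: all F1 reference profiles must be heterozygous.

All frequencies are computed over called genotypes only, across **all
genotyped samples including the parental and F1 reference profiles**. This
is load-bearing: terminal-cross offspring are only ever AA or AB, so
without the strain-B references (which carry BB) rule 4 would remove every
marker. It also matches the released-call arithmetic of the design this
package emulates, where the number of genotyped samples exceeds the mapping
cohort. A no-call inside a reference profile fails the marker
(conservative); `qcThresholds(missingProfileFails = FALSE)` relaxes this.
Hemizygous male X calls are coded homozygous, as arrays report them, and Y
markers are called only in males (so Y markers fail the call-rate filter
whenever the sample set is mixed-sex — by design).

The report object enforces its own bookkeeping (removed + remaining must
reconcile at every stage) in its validity method, and the missing-call rate
is no-calls over released markers × samples, as a percentage to two
decimals.

## LD pruning

"One marker per LD block" is implemented as PLINK-style pairwise pruning:
sliding windows of 50 SNPs advancing by 5; within a window the
later-position member of any pair with $r^2 > 0.5$ is removed ($r^2$ =
squared Pearson correlation of dosages, missing entries pairwise-deleted,
zero variance treated as $r^2 = 0$ with a warning). Which PLINK mode and
values produced the published 615-SNP panel cannot be determined from the
text; the pairwise method with its defaults is pinned here, configurable
via `pruneParams()`, and recorded in the pipeline manifest.

## The genome scan

Each marker is tested with the logistic model
$\mathrm{logit}\,P(\text{case}) = b_0 + b_1\,\text{dosage} +
b_2\,[\text{male}]$, fitted by iteratively reweighted least squares after
collapsing duplicate covariate patterns (at most four per marker in the
terminal design, which makes the ~2×10⁵ fits of the null-calibration test
suite cheap). Convergence: max |score| < 1e-8 or relative log-likelihood
change < 1e-10, within 50 iterations. Quasi-complete separation (any
|coefficient| > 15) is flagged and no p-value is reported, mirroring how
PLINK emits NA; constant design columns are flagged degenerate and the scan
continues. Animals missing a dosage are dropped for that marker only.

Wald statistics use a fixed 1.96 multiplier (not 1.959964): the published
interval reconstructs exactly under log-symmetry with 1.96. Genome-wide
significance is $\alpha / m$ with $m$ the number of scanned (pruned)
markers — the source equates LD blocks with its pruned SNP set. Male X
dosage is coded 0/1 (haploid) by default with a `"diploid"` switch, since
the original coding is unstated.

## Region delineation and candidate triage

The peak is the smallest-p marker (ties: smaller bp). The mapped region is
bounded by the closest **non-significant** flanking markers on each side of
the contiguous significant run containing the peak — the reading under
which the published interval is a closed interval bounded by markers
outside the run; at a chromosome end the outermost scanned marker bounds
the region. Coordinates are 1-based inclusive everywhere.

Genes overlapping the region by ≥ 1 bp are triaged by: (1) aorta
expression; (2) at least one putatively functional variant between the
strains — splice-site, nonsense or frameshift unconditionally, missense or
indel only if the supplied deleteriousness score is ≤ −2.5 (the published
PROVEAN default; the one score printed in the source, −3.66, passes);
(3) differential expression, used as a ranking boost rather than a hard
filter (configurable). Genes with missing annotation are flagged
unevaluable, never silently passed. Deleteriousness scores and
differential-expression flags are **inputs** — the package does not predict
consequences or analyze RNA-seq.

The bundled `inst/extdata/synthetic_chr11_*.tsv` tables are synthetic
stand-ins (as their filenames say) for the real region annotation, built so
that 12 genes yield 5 candidates of which 3 are differentially expressed.

## Determinism and the pipeline

`runPipeline()` chains every stage, writes one schema-stamped TSV per
stage, and records a manifest with parameters, per-stage seeds and MD5
checksums. A single master seed derives per-stage seeds by hashing the
stage name (`stageSeed()`, kept below $2^{31}$), so identical
configurations are byte-identical and single stages can be rerun in
isolation.

At the default cohort size the scan is only marginally powered — as was
the design it emulates, whose peak p (7.08×10⁻⁵) sat just under its
threshold (0.05/615 ≈ 8.13×10⁻⁵). Roughly a quarter to a third of seeds
yield a genome-wide significant locus; the bundled demo seed (5) is one
that does. Simulation-based checks in the test suite therefore use
replicate averages, not single runs.

## What a green test does and does not establish

The simulator emulates: opposite-homozygote founders with a configurable
non-informative fraction, four-generation intercross recombination under
Haldane, the terminal-cross 0/1 dosage design, a logistic severe/mild
outcome with sex and locus effects, survival times in the stated windows,
and genotyping defects (whole-assay failure, per-call missingness at the
observed 0.14% rate, monomorphism, excess heterozygosity, reference-profile
discordance) assigned to disjoint marker sets so each QC stage can be
audited exactly.

It does **not** emulate: litter structure or parental age, crossover
interference, real mouse LD or marker-density structure, array intensity
space (genotypes are calls from the start), selection before genotyping
(asserted absent in the source design), or sex-specific autosomal effects.
Green tests establish internal correctness of the statistics and
bookkeeping on this stated world — not that the package would reproduce
the published scan on the real array data, which are not consumed here.

## Known limitations

* Single-locus, additive model only; no kinship/mixed-model correction
  (unnecessary in this balanced terminal design, harmful to power at this
  scale) and no sex-stratified scans.
* No competing-risks survival modeling; exclusions are categorical.
* The logistic OR estimator is finite-sample biased away from the null and
  Jensen's inequality pushes the mean of replicate OR estimates above the
  planted value (≈ 0.238 vs 0.2293 at n = 187); the acceptance tolerance
  accommodates this honestly rather than correcting the estimator.
* PED/MAP support is the two-allele text dialect only (no binary BED, no
  VCF).
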