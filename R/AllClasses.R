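#' @import methods
#' @importFrom stats setNames rbinom rpois runif pnorm qnorm uniroot cor
#'   fisher.test binomial pchisq complete.cases
#' @importFrom utils read.delim write.table head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' GeneticMap: marker panel with genetic and physical coordinates
#'
#' Holds an ordered marker panel across chromosomes, each marker carrying a
#' genetic (cM) and physical (bp, 1-based) position, together with per-
#' chromosome metadata (class: autosome, X or Y). Markers must be strictly
#' increasing in both coordinate systems within a chromosome, mirroring the
#' layout of genotyping arrays used for inbred mouse strains.
#'
#' @slot markers data.frame with columns `id`, `chrom`, `cM`, `bp`.
#' @slot chromInfo data.frame with columns `name`, `class`.
#' @export
setClass("GeneticMap",
  slots = c(markers = "data.frame", chromInfo = "data.frame"))

setValidity("GeneticMap", function(object) {
  mk <- object@markers
  ci <- object@chromInfo
  msgs <- character()
  need <- c("id", "chrom", "cM", "bp")
  if (!all(need %in% names(mk)))
    return(paste("markers must have columns", paste(need, collapse = ", ")))
  if (!all(c("name", "class") %in% names(ci)))
    return("chromInfo must have columns name, class")
  if (!all(ci$class %in% c("autosome", "X", "Y")))
    msgs <- c(msgs, "chromosome class must be autosome, X or Y")
  if (anyDuplicated(mk$id))
    msgs <- c(msgs, "duplicate marker ids")
  if (!all(mk$chrom %in% ci$name))
    msgs <- c(msgs, "marker chromosome not in chromInfo")
  if (any(mk$cM < 0) || any(mk$bp < 1))
    msgs <- c(msgs, "cM must be >= 0 and bp >= 1")
  for (ch in unique(mk$chrom)) {
    sub <- mk[mk$chrom == ch, ]
    if (nrow(sub) > 1 &&
        (any(diff(sub$cM) <= 0) || any(diff(sub$bp) <= 0)))
      msgs <- c(msgs, sprintf(
        "markers on chromosome %s not strictly increasing in cM and bp", ch))
  }
  if (length(msgs)) msgs else TRUE
})

#' CrossPopulation: simulated pedigree members with founder-labelled haplotypes
#'
#' Container for simulated animals. Each individual carries, per chromosome, a
#' pair of haplotypes coded as founder-origin labels (0 = strain A, 1 = strain
#' B) at every marker of the associated [GeneticMap]. Males carry a single X
#' haplotype (from the dam) and a Y origin label (from the sire).
#'
#' @slot individuals list of individual records (see [simulateCross()]).
#' @slot map the [GeneticMap] the haplotypes are indexed against.
#' @export
setClass("CrossPopulation",
  slots = c(individuals = "list", map = "GeneticMap"))

setValidity("CrossPopulation", function(object) {
  ok <- vapply(object@individuals, function(x)
    all(c("id", "sex", "generation", "mutant", "haplos") %in% names(x)),
    logical(1))
  if (!all(ok)) "malformed individual records" else TRUE
})

#' CrossGenotypes: genotype calls as a SummarizedExperiment
#'
#' Genotype calls (markers x samples) in founder-allele coding
#' (`"AA"`, `"AB"`, `"BB"`, `"NC"` for no-call), stored in the `"calls"`
#' assay. `rowData` carries the marker panel (chrom, cM, bp and, for
#' simulated data, any injected defect class); `colData` carries sample id,
#' sex, generation and role. Roles distinguish the mapping cohort
#' (`"cohort"`) from the parental-strain and F1 reference profiles
#' (`"founderA"`, `"founderB"`, `"f1"`) that the QC cascade requires.
#' After QC a `"dosage"` assay (strain-B allele count 0/1/2, NA = missing)
#' is added.
#'
#' @export
setClass("CrossGenotypes", contains = "SummarizedExperiment")

setValidity("CrossGenotypes", function(object) {
  msgs <- character()
  if (!"calls" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "must have a 'calls' assay")
  else {
    calls <- SummarizedExperiment::assay(object, "calls")
    bad <- !(calls %in% c("AA", "AB", "BB", "NC"))
    if (any(bad)) msgs <- c(msgs, "calls must be AA/AB/BB/NC")
  }
  if (!"role" %in% names(SummarizedExperiment::colData(object)))
    msgs <- c(msgs, "colData must have a 'role' column")
  if (length(msgs)) msgs else TRUE
})

#' QCReport: bookkeeping of the ordered SNP filter cascade
#'
#' Records, stage by stage, how many markers each filter removed and how many
#' remained, plus the released-call accounting (number of released markers,
#' genotyped samples, and no-calls among released calls) from which the
#' missing-data rate is derived.
#'
#' @slot stages data.frame with columns `stage`, `removed`, `remaining`.
#' @slot nMarkersIn number of markers entering the cascade.
#' @slot nReleased number of markers released by the cascade.
#' @slot nSamples number of genotyped samples (cohort plus reference profiles).
#' @slot nNoCalls number of no-calls among released genotype calls.
#' @export
setClass("QCReport",
  slots = c(stages = "data.frame", nMarkersIn = "numeric",
            nReleased = "numeric", nSamples = "numeric",
            nNoCalls = "numeric"))

setValidity("QCReport", function(object) {
  st <- object@stages
  if (!all(c("stage", "removed", "remaining") %in% names(st)))
    return("stages must have columns stage, removed, remaining")
  prev <- c(object@nMarkersIn, st$remaining[-nrow(st)])
  if (nrow(st) && !all(st$remaining == prev - st$removed))
    return("stage counts do not reconcile (removed + remaining != previous)")
  TRUE
})

#' ScanResult: per-marker association results of the genome scan
#'
#' One row per tested marker with the logistic effect of strain-B allele
#' dosage (sex-adjusted), its Wald statistics, odds ratio with 95% CI, fit
#' status, and the Bonferroni-over-blocks significance call.
#'
#' @slot results data.frame, one row per marker (see [genomeScan()]).
#' @slot alpha family-wise error rate used for the Bonferroni threshold.
#' @slot nTests number of markers tested (the Bonferroni denominator).
#' @slot threshold genome-wide per-marker significance threshold.
#' @export
setClass("ScanResult",
  slots = c(results = "data.frame", alpha = "numeric",
            nTests = "numeric", threshold = "numeric"))

#' Region: significant interval delineated from a genome scan
#'
#' A 1-based inclusive physical interval on one chromosome, bounded by the
#' closest non-significant markers flanking the significant run that contains
#' the peak marker.
#'
#' @slot chrom chromosome name.
#' @slot startBp,endBp 1-based inclusive interval bounds.
#' @slot peakId,peakBp id and position of the smallest-p marker.
#' @export
setClass("Region",
  slots = c(chrom = "character", startBp = "numeric", endBp = "numeric",
            peakId = "character", peakBp = "numeric"))

setValidity("Region", function(object) {
  if (object@startBp >= object@endBp) return("start must be < end")
  if (object@peakBp < object@startBp || object@peakBp > object@endBp)
    return("peak must lie within the region")
  TRUE
})
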