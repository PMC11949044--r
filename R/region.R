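#' Delineate the significant region around the peak marker
#'
#' The peak is the smallest-p marker (ties broken by smaller bp). The region
#' is the interval flanked by the closest non-significant markers on either
#' side of the contiguous run of significant markers containing the peak;
#' where the run reaches a chromosome end, the outermost scanned marker on
#' that chromosome bounds the region.
#'
#' @param scan a [ScanResult-class] with at least one significant marker.
#' @return A [Region-class].
#' @export
delineateRegion <- function(scan) {
  res <- scanResults(scan)
  sig <- which(res$significant)
  if (length(sig) == 0) stop("no genome-wide significant marker")
  peakPool <- res[sig, ]
  peak <- peakPool[order(peakPool$p, peakPool$bp), ][1, ]
  onChr <- which(res$chrom == peak$chrom)
  sigChr <- res$significant[onChr]
  pk <- which(res$id[onChr] == peak$id)
  lo <- pk
  while (lo > 1 && sigChr[lo - 1]) lo <- lo - 1
  hi <- pk
  while (hi < length(onChr) && sigChr[hi + 1]) hi <- hi + 1
  startBp <- res$bp[onChr[max(1, lo - 1)]]
  endBp <- res$bp[onChr[min(length(onChr), hi + 1)]]
  new("Region", chrom = peak$chrom, startBp = startBp, endBp = endBp,
      peakId = peak$id, peakBp = peak$bp)
}

#' @rdname accessors
#' @export
setMethod("regionWidth", "Region",
          function(x, ...) (x@endBp - x@startBp) / 1e6)

setMethod("show", "Region", function(object) {
  cat(sprintf(
    "Region chr %s: %s-%s bp (%.1f Mb), peak %s at %s bp\n",
    object@chrom, format(object@startBp, big.mark = ",", scientific = FALSE),
    format(object@endBp, big.mark = ",", scientific = FALSE),
    regionWidth(object), object@peakId,
    format(object@peakBp, big.mark = ",", scientific = FALSE)))
})

#' Genes overlapping the mapped region
#'
#' Returns genes overlapping the region interval by at least 1 bp on the
#' region's chromosome. Coordinates are 1-based inclusive throughout.
#'
#' @param genes data.frame with columns `symbol`, `chrom`, `start_bp`,
#'   `end_bp` (plus any annotation columns, carried through).
#' @param region a [Region-class].
#' @return The overlapping subset of `genes`.
#' @export
genesInRegion <- function(genes, region) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start_bp, genes$end_bp))
  q <- GenomicRanges::GRanges(
    region@chrom, IRanges::IRanges(region@startBp, region@endBp))
  hits <- GenomicRanges::findOverlaps(gr, q, minoverlap = 1)
  out <- genes[S4Vectors::queryHits(hits), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate triage criteria
#'
#' The three-criterion gene filter: (1) expressed in the aorta; (2) carries
#' at least one putatively functional variant between the strains —
#' splice-site, nonsense or frameshift unconditionally, missense or
#' insertion/deletion only when the deleteriousness score is at or below
#' the cutoff (default -2.5, the published PROVEAN default; more negative =
#' more damaging); (3, secondary ranking) differential aortic expression
#' between the strains boosts a candidate but is not required.
#'
#' @param requireExpression require aorta expression (criterion 1).
#' @param allowedClasses variant classes that qualify unconditionally.
#' @param scoredClasses classes that qualify only under the score cutoff.
#' @param missenseScoreCutoff deleterious iff score <= cutoff.
#' @param requireDifferentialExpression if TRUE, differential expression
#'   becomes a hard criterion instead of a ranking boost.
#' @return Criteria list.
#' @export
triageCriteria <- function(requireExpression = TRUE,
                           allowedClasses = c("splice", "nonsense",
                                              "frameshift"),
                           scoredClasses = c("missense", "indel"),
                           missenseScoreCutoff = -2.5,
                           requireDifferentialExpression = FALSE) {
  stopifnot(is.finite(missenseScoreCutoff))
  list(requireExpression = requireExpression,
       allowedClasses = allowedClasses, scoredClasses = scoredClasses,
       missenseScoreCutoff = missenseScoreCutoff,
       requireDifferentialExpression = requireDifferentialExpression)
}

#' Triage genes in the mapped region
#'
#' Applies the [triageCriteria()] to every gene, keeping all genes in the
#' report with per-criterion pass/fail and reasons. Genes with missing
#' annotation on a required field are flagged unevaluable, never silently
#' passed. Candidates are ranked with differentially expressed genes first.
#'
#' @param genes gene table (see [genesInRegion()]) with logical columns
#'   `aorta_expressed` and `differentially_expressed`.
#' @param variants data.frame with columns `symbol`, `class` and `score`
#'   (score may be NA for classes that qualify unconditionally).
#' @param criteria a [triageCriteria()].
#' @return data.frame, one row per gene: `symbol`, `expressed`,
#'   `functionalVariant`, `differentiallyExpressed`, `unevaluable`,
#'   `candidate`, `rank` (NA for non-candidates), `reason`.
#' @export
triageCandidates <- function(genes, variants,
                             criteria = triageCriteria()) {
  qualifies <- function(sym) {
    v <- variants[variants$symbol == sym, , drop = FALSE]
    if (nrow(v) == 0) return(FALSE)
    uncond <- v$class %in% criteria$allowedClasses
    scored <- v$class %in% criteria$scoredClasses & !is.na(v$score) &
      v$score <= criteria$missenseScoreCutoff
    any(uncond | scored)
  }
  n <- nrow(genes)
  expressed <- as.logical(genes$aorta_expressed)
  de <- as.logical(genes$differentially_expressed)
  fv <- vapply(genes$symbol, qualifies, logical(1))
  unevaluable <- is.na(expressed) | is.na(de)
  candidate <- !unevaluable & fv &
    (!criteria$requireExpression | expressed) &
    (!criteria$requireDifferentialExpression | de)
  reason <- ifelse(unevaluable, "missing annotation",
            ifelse(candidate, "passes all criteria",
            ifelse(!fv & !expressed, "not expressed; no functional variant",
            ifelse(!fv, "no functional variant", "not expressed"))))
  out <- data.frame(symbol = genes$symbol, expressed = expressed,
                    functionalVariant = fv, differentiallyExpressed = de,
                    unevaluable = unevaluable, candidate = candidate,
                    rank = NA_integer_, reason = reason,
                    stringsAsFactors = FALSE)
  cand <- which(out$candidate)
  if (length(cand)) {
    ordc <- cand[order(!out$differentiallyExpressed[cand],
                       out$symbol[cand])]
    out$rank[ordc] <- seq_along(ordc)
  }
  rownames(out) <- NULL
  out
}
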