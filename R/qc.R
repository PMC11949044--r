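#' QC thresholds
#'
#' Numeric thresholds of the SNP filter cascade. Boundary semantics follow
#' the filter definitions: a marker is removed when its call rate is
#' strictly below `minCallRate` (exactly 90\% passes) and when its
#' heterozygote rate is strictly above `maxHetRate`.
#'
#' @param minCallRate minimum fraction of called genotypes (default 0.90).
#' @param maxHetRate maximum heterozygote frequency (default 0.80).
#' @param missingProfileFails if TRUE (default), a no-call in a parental or
#'   F1 reference profile fails the concordance check for that marker
#'   (conservative); if FALSE, missing profiles are ignored.
#' @return A thresholds list.
#' @export
qcThresholds <- function(minCallRate = 0.90, maxHetRate = 0.80,
                         missingProfileFails = TRUE) {
  stopifnot(minCallRate > 0, minCallRate <= 1,
            maxHetRate > 0, maxHetRate <= 1)
  list(minCallRate = minCallRate, maxHetRate = maxHetRate,
       missingProfileFails = missingProfileFails)
}

# genotype-class frequencies among called genotypes, per marker (rows)
.callFreqs <- function(calls) {
  called <- calls != "NC"
  n <- rowSums(called)
  list(n = n,
       fAA = rowSums(calls == "AA") / pmax(n, 1),
       fAB = rowSums(calls == "AB") / pmax(n, 1),
       fBB = rowSums(calls == "BB") / pmax(n, 1))
}

#' Call-rate filter
#'
#' Removes markers whose fraction of called genotypes (over all genotyped
#' samples, reference profiles included) is strictly below the threshold:
#' whole-assay failures. Exactly 90\% passes.
#'
#' @param calls character matrix of calls (markers x samples).
#' @param thresholds a [qcThresholds()].
#' @return List with `keep` (logical per marker) and `removed` (count).
#' @export
filterCallRate <- function(calls, thresholds = qcThresholds()) {
  if (ncol(calls) == 0) stop("no individuals")
  rate <- rowMeans(calls != "NC")
  keep <- rate >= thresholds$minCallRate
  list(keep = keep, removed = sum(!keep))
}

#' Informativeness filters
#'
#' Applies, in order and each on the survivors of the previous, the three
#' marker-informativeness rules: (1) minor allele frequency equal to 0;
#' (2) heterozygote rate strictly greater than the threshold or equal to 0;
#' (3) either homozygote class (AA or BB) absent. All frequencies are
#' computed over called genotypes only, across all genotyped samples
#' including the reference profiles (in a terminal-cross cohort the BB class
#' exists only in the strain-B references, so excluding them would void the
#' homozygote rule).
#'
#' @param calls character matrix of calls (markers x samples).
#' @param thresholds a [qcThresholds()].
#' @return List with `keep` (logical per marker), `removedMAF`,
#'   `removedHet`, `removedHom` (counts per rule).
#' @export
filterInformativeness <- function(calls, thresholds = qcThresholds()) {
  fr <- .callFreqs(calls)
  pA <- fr$fAA + fr$fAB / 2
  maf <- pmin(pA, 1 - pA)
  keep <- maf > 0
  removedMAF <- sum(!keep)
  badHet <- keep & (fr$fAB > thresholds$maxHetRate | fr$fAB == 0)
  removedHet <- sum(badHet)
  keep <- keep & !badHet
  badHom <- keep & (fr$fAA == 0 | fr$fBB == 0)
  removedHom <- sum(badHom)
  keep <- keep & !badHom
  list(keep = keep, removedMAF = removedMAF, removedHet = removedHet,
       removedHom = removedHom)
}

#' Parental and F1 concordance filters
#'
#' A marker is retained only if (1) the two parental-strain reference
#' profiles are opposite homozygotes and (2) every F1 reference profile is
#' heterozygous. A no-call in any profile fails the marker (conservative
#' default; see [qcThresholds()]).
#'
#' @param calls character matrix of calls (markers x samples).
#' @param roles character vector of sample roles aligned with the columns
#'   (`cohort`, `founderA`, `founderB`, `f1`).
#' @param thresholds a [qcThresholds()].
#' @return List with `keep`, `removedParental`, `removedF1`.
#' @export
filterConcordance <- function(calls, roles, thresholds = qcThresholds()) {
  a <- calls[, roles == "founderA", drop = FALSE]
  b <- calls[, roles == "founderB", drop = FALSE]
  f1 <- calls[, roles == "f1", drop = FALSE]
  if (ncol(a) == 0 || ncol(b) == 0 || ncol(f1) == 0)
    stop("parental and F1 reference profiles are required")
  profileOK <- function(m, want) {
    hit <- m == want
    miss <- m == "NC"
    if (thresholds$missingProfileFails) rowSums(hit) == ncol(m)
    else rowSums(hit | miss) == ncol(m) & rowSums(!miss) > 0
  }
  opposite <- (profileOK(a, "AA") & profileOK(b, "BB")) |
              (profileOK(a, "BB") & profileOK(b, "AA"))
  removedParental <- sum(!opposite)
  f1Het <- profileOK(f1, "AB")
  keepF1 <- opposite & f1Het
  removedF1 <- sum(opposite & !f1Het)
  list(keep = keepF1, removedParental = removedParental,
       removedF1 = removedF1)
}

#' Run the full QC cascade
#'
#' Applies the ordered filter cascade — call rate, MAF = 0, heterozygote
#' rate, missing homozygote class, parental concordance, F1 concordance —
#' each stage on the survivors of the previous, and converts surviving
#' calls of the mapping cohort to strain-B allele dosage. The cascade is
#' idempotent: rerunning it on its own output removes nothing.
#'
#' @param cg a [CrossGenotypes-class] including reference profiles.
#' @param thresholds a [qcThresholds()].
#' @return List with `genotypes` (the filtered [CrossGenotypes-class], with
#'   a `dosage` assay added) and `report` (a [QCReport-class]).
#' @export
runQC <- function(cg, thresholds = qcThresholds()) {
  calls <- SummarizedExperiment::assay(cg, "calls")
  roles <- SummarizedExperiment::colData(cg)$role
  nIn <- nrow(calls)

  s1 <- filterCallRate(calls, thresholds)
  keep <- s1$keep
  s2 <- filterInformativeness(calls[keep, , drop = FALSE], thresholds)
  keep[keep] <- s2$keep
  s3 <- filterConcordance(calls[keep, , drop = FALSE], roles, thresholds)
  keep[keep] <- s3$keep

  removed <- c(call_rate = s1$removed, maf = s2$removedMAF,
               het_rate = s2$removedHet, hom_missing = s2$removedHom,
               parental_concordance = s3$removedParental,
               f1_concordance = s3$removedF1)
  remaining <- nIn - cumsum(removed)
  stages <- data.frame(stage = names(removed), removed = unname(removed),
                       remaining = unname(remaining))
  if (sum(keep) == 0) {
    print(stages)
    stop("QC cascade removed every marker")
  }
  out <- cg[keep, ]
  released <- SummarizedExperiment::assay(out, "calls")
  report <- new("QCReport", stages = stages, nMarkersIn = nIn,
                nReleased = sum(keep), nSamples = ncol(released),
                nNoCalls = sum(released == "NC"))
  dos <- dosageMatrix(out, roles = unique(roles))
  SummarizedExperiment::assays(out)$dosage <- dos
  list(genotypes = out, report = report)
}

#' @rdname accessors
#' @export
setMethod("qcStages", "QCReport", function(x, ...) x@stages)

#' Missing-call rate of released genotypes
#'
#' No-calls divided by total released genotype calls (released markers x
#' genotyped samples), as a percentage rounded to two decimals.
#'
#' @rdname accessors
#' @export
setMethod("missingRate", "QCReport", function(x, ...) {
  if (x@nReleased <= 0) stop("no released markers")
  round(100 * x@nNoCalls / (x@nReleased * x@nSamples), 2)
})

setMethod("show", "QCReport", function(object) {
  cat("QC cascade:", object@nMarkersIn, "markers in,",
      object@nReleased, "released\n")
  st <- object@stages
  for (i in seq_len(nrow(st)))
    cat(sprintf("  %-22s removed %6d  remaining %6d\n",
                st$stage[i], st$removed[i], st$remaining[i]))
  cat(sprintf("  no-calls among released: %d / %d (%.2f%%)\n",
              object@nNoCalls, object@nReleased * object@nSamples,
              missingRate(object)))
})
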