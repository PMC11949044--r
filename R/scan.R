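#' Genome scan configuration
#'
#' @param alpha family-wise error rate for the Bonferroni-over-blocks
#'   threshold.
#' @param maleXDosage male X dosage coding for association (`"haploid"`
#'   codes hemizygotes 0/1, the default; `"diploid"` codes them 0/2).
#' @return Configuration list.
#' @export
scanConfig <- function(alpha = 0.05,
                       maleXDosage = c("haploid", "diploid")) {
  stopifnot(alpha > 0, alpha < 1)
  list(alpha = alpha, maleXDosage = match.arg(maleXDosage))
}

#' Sex-adjusted logistic genome scan
#'
#' Fits, at every marker, the logistic model
#' logit P(case) = b0 + b1 * dosage + b2 * male, where dosage counts
#' strain-B alleles, and reports the per-allele Wald odds ratio with 95\%
#' CI and two-sided p. Animals with a missing dosage are dropped for that
#' marker only. The genome-wide threshold is alpha divided by the number of
#' scanned markers (one per LD block after pruning); markers with
#' p <= threshold are flagged significant. Separated or degenerate fits are
#' retained in the table with empty statistics.
#'
#' @param dosage numeric matrix (markers x animals) of strain-B dosages,
#'   NA = missing; rownames are marker ids, colnames animal ids.
#' @param strat stratified cohort from [stratifySurvival()]; only `case`
#'   and `control` animals present in the dosage columns are used.
#' @param map a [GeneticMap-class] covering the markers.
#' @param config a [scanConfig()].
#' @return A [ScanResult-class]; results are sorted by (chromosome, bp).
#' @export
genomeScan <- function(dosage, strat, map, config = scanConfig()) {
  if (nrow(dosage) == 0) stop("no markers to scan")
  kept <- strat[strat$class %in% c("case", "control"), ]
  ids <- intersect(colnames(dosage), kept$id)
  if (length(ids) < 2) stop("no overlapping case/control animals")
  kept <- kept[match(ids, kept$id), ]
  dosage <- dosage[, ids, drop = FALSE]
  y <- as.integer(kept$class == "case")
  male <- as.integer(kept$sex == "M")

  mk <- markers(map)
  ord <- match(rownames(dosage), mk$id)
  res <- data.frame(
    id = rownames(dosage),
    chrom = mk$chrom[ord], bp = mk$bp[ord],
    beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
    or = NA_real_, ciLow = NA_real_, ciHigh = NA_real_,
    status = "degenerate", nUsed = 0L,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(dosage))) {
    d <- dosage[i, ]
    ok <- !is.na(d)
    res$nUsed[i] <- sum(ok)
    if (sum(ok) < 2) next
    fit <- fitLogistic(y[ok], cbind(dose = d[ok], male = male[ok]))
    res$status[i] <- fit$status
    if (!is.na(fit$beta[["dose"]])) res$beta[i] <- fit$beta[["dose"]]
    if (fit$status == "ok") {
      w <- waldCI(fit$beta[["dose"]], fit$se[["dose"]])
      res$se[i] <- fit$se[["dose"]]
      res$z[i] <- w$z
      res$p[i] <- w$p
      res$or[i] <- w$or
      res$ciLow[i] <- w$lower
      res$ciHigh[i] <- w$upper
    }
  }
  nTests <- nrow(res)
  thr <- bonferroniThreshold(config$alpha, nTests)
  res$significant <- !is.na(res$p) & res$p <= thr
  res <- res[order(match(res$chrom, chromInfo(map)$name), res$bp), ]
  rownames(res) <- NULL
  new("ScanResult", results = res, alpha = config$alpha, nTests = nTests,
      threshold = thr)
}

#' @rdname accessors
#' @export
setMethod("scanResults", "ScanResult", function(x, ...) x@results)

#' @rdname accessors
#' @export
setMethod("scanThreshold", "ScanResult", function(x, ...) x@threshold)

#' @rdname accessors
#' @export
setMethod("significantMarkers", "ScanResult", function(x, ...)
  x@results[x@results$significant, ])

setMethod("show", "ScanResult", function(object) {
  cat("ScanResult:", nrow(object@results), "markers tested;",
      "Bonferroni threshold", signif(object@threshold, 4),
      sprintf("(alpha %.3g / %d blocks)\n", object@alpha, object@nTests))
  sig <- significantMarkers(object)
  if (nrow(sig) == 0) cat("  no genome-wide significant marker\n")
  else {
    top <- sig[which.min(sig$p), ]
    cat(sprintf("  %d significant marker(s); peak %s (chr %s, bp %d): p = %.3g, OR = %.4f (95%% CI %.4f-%.4f)\n",
                nrow(sig), top$id, top$chrom, top$bp, top$p, top$or,
                top$ciLow, top$ciHigh))
  }
})

#' Manhattan plot table
#'
#' Plot-ready table with -log10 p per marker; separated/degenerate markers
#' are emitted with an empty value.
#'
#' @param scan a [ScanResult-class].
#' @return data.frame with columns `id`, `chrom`, `bp`, `neglog10p`,
#'   `significant`.
#' @export
manhattanTable <- function(scan) {
  res <- scanResults(scan)
  data.frame(id = res$id, chrom = res$chrom, bp = res$bp,
             neglog10p = ifelse(is.na(res$p), NA_real_, -log10(res$p)),
             significant = res$significant, stringsAsFactors = FALSE)
}
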