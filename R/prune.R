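#' LD pruning parameters
#'
#' Pairwise sliding-window pruning parameters (the PLINK-style
#' `--indep-pairwise` defaults pinned here): window of 50 SNPs advancing by
#' 5, removing the later marker of any pair with r-squared above 0.5.
#'
#' @param windowSize window size in SNPs.
#' @param stepSize window advance in SNPs.
#' @param r2Threshold squared-correlation threshold above which the later
#'   marker of a pair is removed.
#' @return Parameter list.
#' @export
pruneParams <- function(windowSize = 50, stepSize = 5, r2Threshold = 0.5) {
  stopifnot(windowSize > stepSize, stepSize >= 1,
            r2Threshold > 0, r2Threshold <= 1)
  list(windowSize = windowSize, stepSize = stepSize,
       r2Threshold = r2Threshold)
}

#' Pairwise linkage disequilibrium (r-squared)
#'
#' Squared Pearson correlation of two dosage vectors; pairs with a missing
#' entry are dropped. Zero variance (after pairwise deletion) is undefined
#' and treated as r2 = 0 with a warning.
#'
#' @param a,b numeric dosage vectors of equal length.
#' @return r-squared in [0, 1].
#' @export
pairwiseR2 <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) {
    warning("fewer than 2 complete pairs; r2 undefined, using 0")
    return(0)
  }
  a <- a[ok]; b <- b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    warning("zero variance; r2 undefined, using 0")
    return(0)
  }
  cor(a, b)^2
}

#' Prune markers to approximately one per LD block
#'
#' Greedy pairwise pruning within a sliding window, per chromosome: for each
#' window of `windowSize` markers (advancing by `stepSize`), every pair of
#' still-retained markers with r-squared above the threshold loses its
#' later-position member. Deterministic given marker order; at least one
#' marker survives on every chromosome that had any.
#'
#' @param dosage numeric matrix (markers x individuals), rows ordered by
#'   chromosome and position; rownames are marker ids.
#' @param map a [GeneticMap-class] covering the rows.
#' @param params a [pruneParams()].
#' @return List with `keep` (marker ids retained, in input order) and
#'   `removed` (ids removed).
#' @export
ldPrune <- function(dosage, map, params = pruneParams()) {
  mk <- markers(map)
  mk <- mk[match(rownames(dosage), mk$id), ]
  stopifnot(!anyNA(mk$id))
  keep <- rep(TRUE, nrow(dosage))
  suppressWarnings(
    for (ch in unique(mk$chrom)) {
      idx <- which(mk$chrom == ch)
      n <- length(idx)
      starts <- unique(c(seq(1, max(1, n - params$windowSize + 1),
                             by = params$stepSize)))
      for (s in starts) {
        win <- idx[s:min(s + params$windowSize - 1, n)]
        for (i in seq_along(win)) {
          if (!keep[win[i]]) next
          for (j in seq_along(win)) {
            if (j <= i || !keep[win[j]]) next
            r2 <- pairwiseR2(dosage[win[i], ], dosage[win[j], ])
            if (r2 > params$r2Threshold) keep[win[j]] <- FALSE
          }
        }
      }
    }
  )
  list(keep = rownames(dosage)[keep], removed = rownames(dosage)[!keep])
}
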