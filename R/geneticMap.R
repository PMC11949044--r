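#' Construct a genetic map
#'
#' @param markers data.frame with columns `id`, `chrom`, `cM`, `bp`
#'   (1-based). Markers must be strictly increasing in both cM and bp within
#'   each chromosome.
#' @param chromInfo data.frame with columns `name` and
#'   `class` (`"autosome"`, `"X"` or `"Y"`). If missing, inferred from the
#'   marker table: chromosomes named "X"/"Y" get those classes, everything
#'   else is autosomal.
#' @return A [GeneticMap-class] object.
#' @export
#' @examples
#' mk <- data.frame(id = c("m1", "m2"), chrom = "1", cM = c(0, 10),
#'                  bp = c(1e6, 2e6))
#' GeneticMap(mk)
GeneticMap <- function(markers, chromInfo = NULL) {
  markers$id <- as.character(markers$id)
  markers$chrom <- as.character(markers$chrom)
  if (is.null(chromInfo)) {
    nm <- unique(markers$chrom)
    chromInfo <- data.frame(
      name = nm,
      class = ifelse(nm == "X", "X", ifelse(nm == "Y", "Y", "autosome")),
      stringsAsFactors = FALSE)
  }
  chromInfo$name <- as.character(chromInfo$name)
  ord <- order(match(markers$chrom, chromInfo$name), markers$bp)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  new("GeneticMap", markers = markers, chromInfo = chromInfo)
}

#' Default desk-scale marker panel
#'
#' Builds a marker panel shaped like a post-QC, post-pruning genotyping-array
#' panel for a biparental mouse cross: 19 autosomes plus X (and a token Y
#' pair), with roughly 600 informative autosomal markers in total. Autosome
#' genetic lengths taper from ~98 cM (chr 1) to ~55 cM (chr 19) and physical
#' lengths from ~195 Mb to ~61 Mb, echoing the mouse genome. Markers are
#' evenly spaced in cM with collinear bp positions. The full ~143k-marker
#' array can be emulated by raising `markersPerAutosome`.
#'
#' @param markersPerAutosome markers per autosome (default 32, giving
#'   19 x 32 = 608 autosomal markers).
#' @param markersX markers on the X chromosome.
#' @param markersY markers on the Y chromosome.
#' @return A [GeneticMap-class].
#' @export
defaultGeneticMap <- function(markersPerAutosome = 32, markersX = 16,
                              markersY = 2) {
  nAuto <- 19
  lenCM <- seq(98, 55, length.out = nAuto)
  lenMb <- seq(195, 61, length.out = nAuto)
  rows <- vector("list", nAuto + 2)
  for (i in seq_len(nAuto)) {
    n <- markersPerAutosome
    cM <- seq(0, lenCM[i], length.out = n)
    bp <- round(seq(3e6, lenMb[i] * 1e6, length.out = n))
    rows[[i]] <- data.frame(
      id = sprintf("chr%d_m%03d", i, seq_len(n)),
      chrom = as.character(i), cM = cM, bp = bp)
  }
  cMX <- seq(0, 80, length.out = markersX)
  rows[[nAuto + 1]] <- data.frame(
    id = sprintf("chrX_m%03d", seq_len(markersX)),
    chrom = "X", cM = cMX,
    bp = round(seq(3e6, 171e6, length.out = markersX)))
  rows[[nAuto + 2]] <- data.frame(
    id = sprintf("chrY_m%03d", seq_len(markersY)),
    chrom = "Y", cM = seq(0, 1, length.out = markersY),
    bp = round(seq(1e6, 2e6, length.out = markersY)))
  GeneticMap(do.call(rbind, rows))
}

#' @rdname accessors
#' @export
setMethod("markers", "GeneticMap", function(x, ...) x@markers)

#' @rdname accessors
#' @export
setMethod("chromInfo", "GeneticMap", function(x, ...) x@chromInfo)

#' @param class optional chromosome class (`"autosome"`, `"X"`, `"Y"`) to
#'   restrict the count to.
#' @rdname accessors
#' @export
setMethod("nMarkers", "GeneticMap", function(x, class = NULL, ...) {
  if (is.null(class)) return(nrow(x@markers))
  keep <- x@chromInfo$name[x@chromInfo$class %in% class]
  sum(x@markers$chrom %in% keep)
})

setMethod("show", "GeneticMap", function(object) {
  ci <- object@chromInfo
  cat("GeneticMap with", nrow(object@markers), "markers on",
      nrow(ci), "chromosomes\n")
  for (cl in c("autosome", "X", "Y")) {
    n <- nMarkers(object, class = cl)
    if (n > 0) cat(" ", cl, ":", n, "markers\n")
  }
})

# cM positions of the markers of one chromosome, plus its map length (Morgans)
.chromMap <- function(map, chrom) {
  cM <- map@markers$cM[map@markers$chrom == chrom]
  list(cM = cM, lengthM = if (length(cM)) max(cM) / 100 else 0)
}
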