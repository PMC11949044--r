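#' Genotyping noise model
#'
#' Defect rates injected into simulated genotype calls so that every stage
#' of the QC cascade has work to do. Defect classes are assigned to disjoint
#' random marker subsets and recorded in the output's `rowData`, so tests
#' can verify that each defective marker is removed by the intended filter:
#' \describe{
#'   \item{assay_failure}{whole-marker elevated missingness (call rate
#'     drops below 90\%); removed by the call-rate filter.}
#'   \item{monomorphic}{all samples called AA; removed by the MAF filter.}
#'   \item{excess_het}{calls converted to AB at rate `excessHetRate`
#'     (> 80\%); removed by the heterozygosity filter.}
#'   \item{missing_homozygote}{strain-B reference profiles called AB, so the
#'     BB class is absent; removed by the homozygote filter.}
#'   \item{parental_discordant}{strain-A reference profiles called BB, so
#'     the founders are not opposite homozygotes; removed by the parental
#'     concordance filter.}
#'   \item{f1_discordant}{F1 reference profiles called AA; removed by the
#'     F1 concordance filter.}
#' }
#' The default per-call missing probability 0.0014 reproduces the 0.14\%
#' missing-data rate observed on the real array.
#'
#' @param perCallMissing probability any individual call is a no-call.
#' @param assayFailureFrac fraction of markers with whole-assay failure.
#' @param assayFailureMissing per-call no-call probability at failed assays.
#' @param monomorphicFrac fraction of markers forced monomorphic.
#' @param excessHetFrac fraction of markers with excess heterozygosity.
#' @param excessHetRate per-call AB conversion rate at excess-het markers.
#' @param missingHomFrac fraction of markers whose BB class is erased.
#' @param parentalDiscordantFrac fraction of markers with discordant
#'   parental profiles.
#' @param f1DiscordantFrac fraction of markers with non-heterozygous F1
#'   profiles.
#' @return A noise model parameter list.
#' @export
noiseModel <- function(perCallMissing = 0.0014, assayFailureFrac = 0.01,
                       assayFailureMissing = 0.5, monomorphicFrac = 0.02,
                       excessHetFrac = 0.01, excessHetRate = 0.9,
                       missingHomFrac = 0.005,
                       parentalDiscordantFrac = 0.005,
                       f1DiscordantFrac = 0.005) {
  m <- list(perCallMissing = perCallMissing,
            assayFailureFrac = assayFailureFrac,
            assayFailureMissing = assayFailureMissing,
            monomorphicFrac = monomorphicFrac,
            excessHetFrac = excessHetFrac, excessHetRate = excessHetRate,
            missingHomFrac = missingHomFrac,
            parentalDiscordantFrac = parentalDiscordantFrac,
            f1DiscordantFrac = f1DiscordantFrac)
  if (any(unlist(m) < 0) || any(unlist(m) > 1))
    stop("all noise model rates must be probabilities in [0, 1]")
  m
}

# dosage (0/1/2) -> call string
.doseToCall <- function(d) c("AA", "AB", "BB")[d + 1L]

#' Generate raw genotype calls with injected noise
#'
#' Converts a simulated population's haplotypes into array-style genotype
#' calls (`AA`/`AB`/`BB`/`NC`) in founder-allele coding and appends the
#' parental-strain and F1 reference profiles the QC cascade requires. Noise
#' and marker defects are injected per the [noiseModel()]. Hemizygous male X
#' calls are coded as homozygous (as genotyping arrays report them); Y
#' markers are called only in males. At non-informative markers (founders
#' sharing an allele) every sample is called AA.
#'
#' @param pop a [CrossPopulation-class].
#' @param founders founder definition from [makeFounders()].
#' @param noise a [noiseModel()].
#' @param seed optional RNG seed.
#' @param nRefPerClass reference profiles per class (strain A, strain B,
#'   F1); all reference samples are female.
#' @return A [CrossGenotypes-class]; `rowData` records the marker panel,
#'   informativeness and injected defect class; `colData` records id, sex,
#'   generation and role.
#' @export
genotypeWithNoise <- function(pop, founders, noise = noiseModel(),
                              seed = NULL, nRefPerClass = 2) {
  if (!is.null(seed)) set.seed(seed)
  map <- pop@map
  mk <- markers(map)
  ci <- chromInfo(map)
  inds <- individuals(pop)
  nM <- nrow(mk)
  cls <- ci$class[match(mk$chrom, ci$name)]
  informative <- founders$informative[mk$id]

  cohortCall <- function(ind) {
    d <- integer(nM)
    for (ch in unique(mk$chrom)) {
      sel <- mk$chrom == ch
      k <- ci$class[ci$name == ch]
      if (k == "Y") {
        d[sel] <- if (ind$sex == "M") 2L * ind$yOrigin else NA_integer_
      } else {
        hp <- ind$haplos[[ch]]
        d[sel] <- if (length(hp) == 1L) 2L * hp$h1 else hp$h1 + hp$h2
      }
    }
    out <- rep("NC", nM)
    ok <- !is.na(d)
    out[ok] <- .doseToCall(d[ok])
    out[!informative] <- ifelse(is.na(d[!informative]), "NC", "AA")
    out
  }
  calls <- vapply(inds, cohortCall, character(nM))

  refCall <- function(dose) {
    out <- .doseToCall(rep(dose, nM))
    out[!informative] <- "AA"
    out[cls == "Y"] <- "NC"  # female reference samples
    out
  }
  refs <- cbind(
    matrix(refCall(0L), nM, nRefPerClass),
    matrix(refCall(2L), nM, nRefPerClass),
    matrix(refCall(1L), nM, nRefPerClass))
  calls <- cbind(calls, refs)
  nS <- ncol(calls)
  refRole <- rep(c("founderA", "founderB", "f1"), each = nRefPerClass)

  # assign disjoint defect classes among informative non-Y markers
  defect <- rep("none", nM)
  eligible <- which(informative & cls != "Y")
  fr <- c(assay_failure = noise$assayFailureFrac,
          monomorphic = noise$monomorphicFrac,
          excess_het = noise$excessHetFrac,
          missing_homozygote = noise$missingHomFrac,
          parental_discordant = noise$parentalDiscordantFrac,
          f1_discordant = noise$f1DiscordantFrac)
  counts <- round(fr * nM)
  if (sum(counts) > length(eligible))
    stop("defect fractions exceed the available informative markers")
  picked <- sample(eligible, sum(counts))
  defect[picked] <- rep(names(counts), counts)

  bRef <- which(refRole == "founderB") + length(inds)
  aRef <- which(refRole == "founderA") + length(inds)
  f1Ref <- which(refRole == "f1") + length(inds)
  for (j in which(defect == "monomorphic")) calls[j, ] <- "AA"
  for (j in which(defect == "excess_het")) {
    conv <- runif(nS) < noise$excessHetRate
    calls[j, conv] <- "AB"
  }
  for (j in which(defect == "missing_homozygote")) calls[j, bRef] <- "AB"
  for (j in which(defect == "parental_discordant")) calls[j, aRef] <- "BB"
  for (j in which(defect == "f1_discordant")) calls[j, f1Ref] <- "AA"
  for (j in which(defect == "assay_failure")) {
    nc <- runif(nS) < noise$assayFailureMissing
    calls[j, nc] <- "NC"
  }
  if (noise$perCallMissing > 0) {
    nc <- runif(length(calls)) < noise$perCallMissing
    calls[nc] <- "NC"
  }

  colData <- S4Vectors::DataFrame(
    id = c(vapply(inds, `[[`, character(1), "id"),
           paste0(refRole, "_ref", sequence(rep(nRefPerClass, 3)))),
    sex = c(vapply(inds, `[[`, character(1), "sex"),
            rep("F", 3 * nRefPerClass)),
    generation = c(vapply(inds, `[[`, character(1), "generation"),
                   rep("reference", 3 * nRefPerClass)),
    role = c(rep("cohort", length(inds)), refRole))
  rowData <- S4Vectors::DataFrame(
    mk, class = cls, informative = unname(informative), defect = defect)
  dimnames(calls) <- list(mk$id, colData$id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowData = rowData, colData = colData)
  new("CrossGenotypes", se)
}

#' Strain-B dosage matrix from genotype calls
#'
#' Converts calls to counts of the strain-B allele: AA = 0, AB = 1, BB = 2,
#' NC = missing. On the X chromosome, male homozygous calls are counted
#' haploid by default (AA = 0, BB = 1), the coding used for association;
#' `maleXDosage = "diploid"` keeps the 0/2 coding.
#'
#' @param cg a [CrossGenotypes-class].
#' @param roles sample roles to include (default the mapping cohort only).
#' @param maleXDosage `"haploid"` or `"diploid"` male X coding.
#' @return Integer matrix (markers x samples), NA = missing.
#' @export
dosageMatrix <- function(cg, roles = "cohort",
                         maleXDosage = c("haploid", "diploid")) {
  maleXDosage <- match.arg(maleXDosage)
  keep <- SummarizedExperiment::colData(cg)$role %in% roles
  calls <- SummarizedExperiment::assay(cg, "calls")[, keep, drop = FALSE]
  d <- matrix(NA_integer_, nrow(calls), ncol(calls),
              dimnames = dimnames(calls))
  d[calls == "AA"] <- 0L
  d[calls == "AB"] <- 1L
  d[calls == "BB"] <- 2L
  if (maleXDosage == "haploid") {
    rd <- SummarizedExperiment::rowData(cg)
    xm <- which(rd$class == "X")
    male <- SummarizedExperiment::colData(cg)$sex[keep] == "M"
    if (length(xm) && any(male))
      d[xm, male] <- d[xm, male, drop = FALSE] %/% 2L
  }
  d
}
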