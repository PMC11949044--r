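#' Write genotypes as PLINK text PED/MAP
#'
#' PED: six leading columns (family = sample role, individual id, sire 0,
#' dam 0, sex 1 = M / 2 = F, phenotype 0 = missing) followed by two
#' allele columns per marker (`A`/`B`; missing = `0 0`). MAP: chromosome,
#' marker id, cM, bp. Round-trips with [readPedMap()].
#'
#' @param cg a [CrossGenotypes-class].
#' @param pedPath,mapPath output paths.
#' @param phenotype optional numeric phenotype per sample (PLINK coding:
#'   1 = control, 2 = case, 0 = missing).
#' @return Invisibly, the two paths.
#' @export
writePedMap <- function(cg, pedPath, mapPath, phenotype = NULL) {
  calls <- SummarizedExperiment::assay(cg, "calls")
  cd <- SummarizedExperiment::colData(cg)
  rd <- SummarizedExperiment::rowData(cg)
  alleles <- c(AA = "A A", AB = "A B", BB = "B B", NC = "0 0")
  if (is.null(phenotype)) phenotype <- rep(0, ncol(calls))
  lines <- vapply(seq_len(ncol(calls)), function(j) {
    paste(cd$role[j], cd$id[j], 0, 0, ifelse(cd$sex[j] == "M", 1, 2),
          phenotype[j], paste(alleles[calls[, j]], collapse = " "))
  }, character(1))
  writeLines(lines, pedPath)
  mapDf <- data.frame(rd$chrom, rownames(calls), rd$cM, rd$bp)
  write.table(mapDf, mapPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(c(ped = pedPath, map = mapPath))
}

#' Read PLINK text PED/MAP into genotype calls
#'
#' Inverse of [writePedMap()]: parses the marker map and the per-individual
#' allele pairs back into a [CrossGenotypes-class] (`A A` = AA, `A B` or
#' `B A` = AB, `B B` = BB, `0 0` = no-call). Ragged rows or unknown allele
#' codes raise an error naming the offending line.
#'
#' @param pedPath,mapPath input paths.
#' @return A [CrossGenotypes-class]; the PED family column is restored as
#'   the sample role and the phenotype column as `colData$phenotype`.
#' @export
readPedMap <- function(pedPath, mapPath) {
  mapDf <- read.delim(mapPath, header = FALSE,
                      col.names = c("chrom", "id", "cM", "bp"),
                      colClasses = c("character", "character", "numeric",
                                     "numeric"))
  nM <- nrow(mapDf)
  lines <- readLines(pedPath)
  parse1 <- function(i) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * nM)
      stop(sprintf("PED line %d: expected %d fields, found %d", i,
                   6 + 2 * nM, length(f)))
    al <- matrix(f[-(1:6)], nrow = 2)
    bad <- !(al %in% c("A", "B", "0"))
    if (any(bad))
      stop(sprintf("PED line %d: unknown allele code '%s'", i,
                   al[bad][1]))
    g <- paste0(pmin(al[1, ], al[2, ]), pmax(al[1, ], al[2, ]))
    calls <- c("00" = "NC", "AA" = "AA", "AB" = "AB", "BB" = "BB")[g]
    if (anyNA(calls))
      stop(sprintf("PED line %d: half-missing genotype", i))
    list(meta = f[1:6], calls = unname(calls))
  }
  parsed <- lapply(seq_along(lines), parse1)
  calls <- vapply(parsed, `[[`, character(nM), "calls")
  meta <- t(vapply(parsed, `[[`, character(6), "meta"))
  colData <- S4Vectors::DataFrame(
    id = meta[, 2],
    sex = ifelse(meta[, 5] == "1", "M", "F"),
    generation = NA_character_,
    role = meta[, 1],
    phenotype = as.numeric(meta[, 6]))
  ci <- unique(mapDf$chrom)
  rowData <- S4Vectors::DataFrame(
    id = mapDf$id, chrom = mapDf$chrom, cM = mapDf$cM, bp = mapDf$bp,
    class = ifelse(ci[match(mapDf$chrom, ci)] == "X", "X",
                   ifelse(ci[match(mapDf$chrom, ci)] == "Y", "Y",
                          "autosome")))
  dimnames(calls) <- list(mapDf$id, colData$id)
  new("CrossGenotypes", SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowData = rowData, colData = colData))
}

# schema-stamped TSV: first line "#schema: <cols>", validated on read
.writeTsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#schema: ", paste(names(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readTsv <- function(path, required = NULL) {
  first <- readLines(path, n = 1)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (startsWith(first, "#schema: ")) {
    declared <- strsplit(sub("^#schema: ", "", first), "\t")[[1]]
    if (!identical(declared, names(df)))
      stop("TSV schema mismatch in ", path)
  }
  if (!is.null(required) && !all(required %in% names(df)))
    stop(path, " must have columns ", paste(required, collapse = ", "))
  df
}

#' Read and write phenotype tables
#'
#' TSV with columns `id`, `sex`, `survival_days`, `death_cause`,
#' `generation` (and any extra columns, carried through), stamped with a
#' schema header comment that the reader validates.
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @return `readPhenotypes()`: the data.frame; `writePhenotypes()`: the
#'   path, invisibly.
#' @export
writePhenotypes <- function(pheno, path) .writeTsv(pheno, path)

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path)
  .readTsv(path, c("id", "sex", "survival_days", "death_cause"))

#' Read gene and variant annotation tables
#'
#' Gene table: `symbol`, `chrom`, `start_bp`, `end_bp` (1-based inclusive),
#' `aorta_expressed`, `differentially_expressed`. Variant table: `symbol`,
#' `variant_id`, `bp`, `cdna`, `protein`, `class` (splice, nonsense,
#' frameshift, missense, indel), `score` (deleteriousness, more negative =
#' more damaging; may be empty).
#'
#' @param path file path.
#' @return data.frame.
#' @export
readGeneTable <- function(path) {
  g <- .readTsv(path, c("symbol", "chrom", "start_bp", "end_bp",
                        "aorta_expressed", "differentially_expressed"))
  g$chrom <- as.character(g$chrom)
  g
}

#' @rdname readGeneTable
#' @export
readVariantTable <- function(path) {
  v <- .readTsv(path, c("symbol", "class"))
  bad <- !v$class %in% c("splice", "nonsense", "frameshift", "missense",
                         "indel")
  if (any(bad)) stop("unknown variant class: ", v$class[bad][1])
  if (!"score" %in% names(v)) v$score <- NA_real_
  v
}
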