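# Shared fixtures, built in code. Heavy objects are created once here and
# reused across test files.

# tiny two-autosome map: chr "1" has markers every 10 cM, chr "2" two markers
tinyMap <- function() {
  GeneticMap(rbind(
    data.frame(id = sprintf("a%02d", 1:11), chrom = "1",
               cM = seq(0, 100, by = 10), bp = seq(1e6, 101e6, by = 10e6)),
    data.frame(id = c("b1", "b2"), chrom = "2", cM = c(0, 10),
               bp = c(1e6, 2e6))))
}

# hand-built individual: heterozygous (F1-like) at every marker of `map`
f1Individual <- function(map, sex = "F") {
  mk <- markers(map)
  haplos <- lapply(split(mk$id, mk$chrom), function(ids)
    list(h1 = rep(0L, length(ids)), h2 = rep(1L, length(ids))))
  list(id = "f1", sex = sex, generation = "F1", mutant = FALSE,
       haplos = haplos, yOrigin = if (sex == "M") 1L else NA_integer_)
}

# moderate shared cohort on the default panel (used by several files)
.sharedMap <- defaultGeneticMap()
.sharedFounders <- makeFounders(.sharedMap)
.sharedPop <- simulateCross(.sharedMap, .sharedFounders,
                            crossScheme(nTerminal = 187,
                                        terminalMales = 96,
                                        terminalFemales = 91),
                            seed = 421)
.sharedLocus <- local({
  mk <- markers(.sharedMap)
  chr11 <- mk[mk$chrom == "11", ]
  chr11$id[which.min(abs(chr11$bp - 110.5e6))]
})

# calls matrix + roles for hand-crafted QC fixtures: one row per marker
# described as c(cohort genotypes..., founderA x2, founderB x2, f1 x2)
qcFixture <- function(rows) {
  calls <- do.call(rbind, rows)
  rownames(calls) <- names(rows)
  nCohort <- ncol(calls) - 6
  roles <- c(rep("cohort", nCohort), rep(c("founderA", "founderB", "f1"),
                                         each = 2))
  list(calls = calls, roles = roles)
}

# wrap a calls matrix as a CrossGenotypes on a synthetic 1-chromosome map
asCrossGenotypes <- function(calls, roles, chrom = "1") {
  n <- nrow(calls)
  rowData <- S4Vectors::DataFrame(
    id = rownames(calls), chrom = chrom, cM = seq_len(n),
    bp = seq_len(n) * 1e6, class = "autosome")
  colData <- S4Vectors::DataFrame(
    id = paste0("s", seq_len(ncol(calls))),
    sex = "F", generation = NA_character_, role = roles)
  dimnames(calls) <- list(rowData$id, colData$id)
  new("CrossGenotypes", SummarizedExperiment::SummarizedExperiment(
    assays = list(calls = calls), rowData = rowData, colData = colData))
}
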