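#' Derive a per-stage RNG seed from the master seed
#'
#' Stage seeds are a deterministic hash of the master seed and the stage
#' name, kept below 2^31 so they are valid R integer seeds; stages can
#' therefore be rerun in isolation and reproduce the full-pipeline run.
#'
#' @param masterSeed integer master seed.
#' @param stage stage name.
#' @return Integer seed.
#' @export
stageSeed <- function(masterSeed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(masterSeed) * 48271 + h * 16807) %% 2147483647L)
}

#' End-to-end pipeline configuration
#'
#' Collects every module's parameters, each defaulting to its pinned value,
#' plus the master seed and output directory.
#'
#' @param seed master seed; per-stage seeds derive from it via
#'   [stageSeed()]. The bundled demo seed (5) is one at which the planted
#'   protective locus attains genome-wide significance; at the default
#'   cohort size the scan is only marginally powered (as the design it
#'   emulates was), so many seeds yield no significant marker.
#' @param outDir output directory for stage TSVs (created if needed).
#' @param map a [GeneticMap-class].
#' @param scheme breeding scheme ([crossScheme()]).
#' @param model phenotype model ([phenotypeModel()]); default plants the
#'   protective locus at a marker near 110.5 Mb of chromosome 11.
#' @param noise genotyping noise ([noiseModel()]).
#' @param nonInformativeFrac fraction of non-informative markers
#'   ([makeFounders()]).
#' @param thresholds QC thresholds ([qcThresholds()]).
#' @param prune LD pruning parameters ([pruneParams()]).
#' @param scan scan configuration ([scanConfig()]).
#' @param criteria triage criteria ([triageCriteria()]).
#' @param rule stratification rule ([stratificationRule()]).
#' @param genesPath,variantsPath annotation tables for candidate triage;
#'   defaults to the bundled synthetic chromosome-11 tables.
#' @return Configuration list.
#' @export
pipelineConfig <- function(seed = 5, outDir = tempfile("pipeline"),
                           map = defaultGeneticMap(),
                           scheme = crossScheme(),
                           model = NULL,
                           noise = noiseModel(),
                           nonInformativeFrac = 0.02,
                           thresholds = qcThresholds(),
                           prune = pruneParams(),
                           scan = scanConfig(),
                           criteria = triageCriteria(),
                           rule = stratificationRule(),
                           genesPath = system.file(
                             "extdata", "synthetic_chr11_genes.tsv",
                             package = "ModifierScan"),
                           variantsPath = system.file(
                             "extdata", "synthetic_chr11_variants.tsv",
                             package = "ModifierScan")) {
  if (is.null(model)) {
    mk <- markers(map)
    chr11 <- mk[mk$chrom == "11", ]
    locus <- chr11$id[which.min(abs(chr11$bp - 110.5e6))]
    model <- phenotypeModel(locusMarker = locus)
  }
  list(seed = seed, outDir = outDir, map = map, scheme = scheme,
       model = model, noise = noise,
       nonInformativeFrac = nonInformativeFrac, thresholds = thresholds,
       prune = prune, scan = scan, criteria = criteria, rule = rule,
       genesPath = genesPath, variantsPath = variantsPath)
}

#' Run the full mapping pipeline
#'
#' Executes simulate -> phenotype -> stratify -> QC -> LD prune -> genome
#' scan -> region delineation -> candidate triage, writing one TSV per
#' stage into the output directory and returning all in-memory objects plus
#' a manifest (parameters, per-stage seeds, stage counts and output-file
#' MD5 checksums). Identical configuration and seed give byte-identical
#' outputs. A scan with no significant marker stops at delineation with the
#' stage outputs retained in the result.
#'
#' @param config a [pipelineConfig()].
#' @return List: `population`, `phenotypes`, `strat`, `qc`, `pruned`
#'   (retained marker ids), `scan`, `region` (NULL if none significant),
#'   `candidates` (NULL likewise), `manifest`.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  counts <- list()

  founders <- makeFounders(config$map, config$nonInformativeFrac,
                           seed = stageSeed(config$seed, "founders"))
  out$population <- simulateCross(config$map, founders, config$scheme,
                                  seed = stageSeed(config$seed, "simulate"))
  out$phenotypes <- assignPhenotypes(out$population, config$model,
                                     seed = stageSeed(config$seed,
                                                      "phenotype"))
  writePhenotypes(out$phenotypes,
                  file.path(config$outDir, "phenotypes.tsv"))
  counts$simulate <- length(individuals(out$population))

  out$strat <- stratifySurvival(out$phenotypes, config$rule)
  .writeTsv(out$strat, file.path(config$outDir, "stratified.tsv"))
  counts$stratify <- sum(out$strat$class != "excluded")

  cg <- genotypeWithNoise(out$population, founders, config$noise,
                          seed = stageSeed(config$seed, "genotype"))
  writePedMap(cg, file.path(config$outDir, "raw.ped"),
              file.path(config$outDir, "raw.map"))
  out$qc <- runQC(cg, config$thresholds)
  .writeTsv(qcStages(out$qc$report),
            file.path(config$outDir, "qc_report.tsv"))
  counts$qc <- out$qc$report@nReleased

  dos <- dosageMatrix(out$qc$genotypes)
  pruned <- ldPrune(dos, config$map, config$prune)
  out$pruned <- pruned$keep
  counts$prune <- length(pruned$keep)

  out$scan <- genomeScan(dos[pruned$keep, , drop = FALSE], out$strat,
                         config$map, config$scan)
  .writeTsv(scanResults(out$scan),
            file.path(config$outDir, "association.tsv"))
  .writeTsv(manhattanTable(out$scan),
            file.path(config$outDir, "manhattan.tsv"))
  counts$scan <- nrow(scanResults(out$scan))

  out$region <- NULL
  out$candidates <- NULL
  if (nrow(significantMarkers(out$scan)) > 0) {
    out$region <- delineateRegion(out$scan)
    genes <- readGeneTable(config$genesPath)
    variants <- readVariantTable(config$variantsPath)
    inRegion <- genesInRegion(genes, out$region)
    out$candidates <- triageCandidates(inRegion, variants,
                                       config$criteria)
    .writeTsv(out$candidates,
              file.path(config$outDir, "candidates.tsv"))
    .writeTsv(data.frame(chrom = out$region@chrom,
                         start_bp = out$region@startBp,
                         end_bp = out$region@endBp,
                         peak = out$region@peakId,
                         width_mb = round(regionWidth(out$region), 1)),
              file.path(config$outDir, "region.tsv"))
    counts$region <- 1L
    counts$triage <- sum(out$candidates$candidate)
  } else {
    counts$region <- 0L
    message("no genome-wide significant marker; ",
            "region delineation and triage skipped")
  }

  files <- list.files(config$outDir, full.names = TRUE)
  out$manifest <- list(
    seed = config$seed,
    stageSeeds = vapply(c("founders", "simulate", "phenotype", "genotype"),
                        function(s) stageSeed(config$seed, s), numeric(1)),
    parameters = config[c("nonInformativeFrac", "scheme", "model", "noise",
                          "thresholds", "prune", "scan", "criteria",
                          "rule")],
    counts = counts,
    checksums = tools::md5sum(files))
  out
}
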