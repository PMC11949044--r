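test_that("Haldane map function matches its closed form and limits", {
  expect_equal(haldaneRecombination(0), 0)
  expect_equal(haldaneRecombination(0.10), (1 - exp(-0.2)) / 2)
  expect_equal(haldaneRecombination(0.10), 0.09063, tolerance = 1e-4)
  expect_lt(abs(haldaneRecombination(10) - 0.5), 1e-8)
  d <- seq(0, 3, by = 0.05)
  expect_true(all(diff(haldaneRecombination(d)) > 0))
  expect_error(haldaneRecombination(-0.1), "non-negative")
})

test_that("meiosis produces mosaics with Haldane recombinant fractions", {
  map <- GeneticMap(data.frame(id = c("m1", "m2"), chrom = "1",
                               cM = c(0, 10), bp = c(1e6, 2e6)))
  parent <- list(id = "p", sex = "F", generation = "F1", mutant = FALSE,
                 haplos = list("1" = list(h1 = c(0L, 0L), h2 = c(1L, 1L))),
                 yOrigin = NA_integer_)
  # homozygous parent: recombination invisible
  hom <- parent
  hom$haplos[["1"]]$h2 <- c(0L, 0L)
  for (i in 1:5) expect_identical(meiosis(hom, "1", map), c(0L, 0L))
  expect_error(meiosis(parent, "7", map), "unknown chromosome")
  # recombinant fraction between markers 10 cM apart ~ Haldane closed form
  set.seed(11)
  n <- 1e5
  rec <- 0L
  for (i in seq_len(n)) {
    g <- meiosis(parent, "1", map)
    rec <- rec + (g[1] != g[2])
  }
  rExp <- haldaneRecombination(0.10)
  se <- sqrt(rExp * (1 - rExp) / n)
  expect_lt(abs(rec / n - rExp), 3 * se)
})

test_that("crossover count over a 1-Morgan chromosome is Poisson(1)", {
  # dense 0.1 cM marker grid: origin switches are a near-exact crossover
  # count (double crossovers within an interval are essentially invisible
  # only with probability ~5e-7 per interval)
  dense <- GeneticMap(data.frame(id = sprintf("d%04d", 1:1001),
                                 chrom = "1", cM = seq(0, 100, by = 0.1),
                                 bp = seq_len(1001) * 1e5))
  parent <- f1Individual(dense)
  set.seed(12)
  n <- 2e4
  switches <- vapply(seq_len(n), function(i)
    sum(diff(meiosis(parent, "1", dense)) != 0), numeric(1))
  expect_lt(abs(mean(switches) - 1), 3 * sqrt(1 / n))
  expect_lt(abs(stats::var(switches) - 1), 0.08)
  # with sparse markers (10 cM apart) the visible switch count drops to
  # the sum of interval recombination fractions, 10 * r(0.1)
  sparse <- tinyMap()
  parentS <- f1Individual(sparse)
  sw <- vapply(seq_len(n), function(i)
    sum(diff(meiosis(parentS, "1", sparse)) != 0), numeric(1))
  expSw <- 10 * haldaneRecombination(0.1)
  expect_lt(abs(mean(sw) - expSw), 3 * sqrt(expSw * (1 - expSw / 10) / n))
})

test_that("breeding program respects design constraints", {
  map <- tinyMap()
  founders <- makeFounders(map)
  pop <- simulateCross(map, founders, crossScheme(nTerminal = 50),
                       seed = 99)
  inds <- individuals(pop)
  expect_length(inds, 50)
  expect_true(all(vapply(inds, `[[`, logical(1), "mutant")))
  expect_true(all(vapply(inds, `[[`, character(1), "generation") ==
                    "terminal"))
  # sire contributes only strain-A alleles: second autosomal haplotype pure 0
  for (ind in inds) {
    expect_true(all(ind$haplos[["1"]]$h2 == 0L))
    expect_true(all(ind$haplos[["2"]]$h2 == 0L))
  }
  # autosomal dosage in {0, 1}
  d <- dosageAtMarker(pop, "a05")
  expect_true(all(d %in% 0:1))
  expect_error(simulateCross(map, founders, crossScheme(nF2 = 3)),
               "breeders")
})

test_that("F1 animals are heterozygous at every informative autosomal marker", {
  map <- tinyMap()
  founders <- makeFounders(map)
  damA <- ModifierScan:::.inbredIndividual("a", "F", "P", 0L, map)
  sireB <- ModifierScan:::.inbredIndividual("b", "M", "P", 1L, map)
  set.seed(3)
  kid <- ModifierScan:::.mate(damA, sireB, "k", "F", "F1", map,
                              ModifierScan:::.chromCache(map))
  for (ch in c("1", "2"))
    expect_true(all(kid$haplos[[ch]]$h1 + kid$haplos[[ch]]$h2 == 1L))
})

test_that("transmission is neutral: strain-B dosage frequency ~ 0.5", {
  # a single pedigree carries substantial drift through the small
  # intercross generations, so neutrality (expectation 0.5) is assessed
  # across replicate pedigrees with the empirical between-replicate SE
  map <- tinyMap()
  founders <- makeFounders(map)
  nrep <- 30
  freqs <- vapply(seq_len(nrep), function(r) {
    pop <- simulateCross(map, founders, crossScheme(nTerminal = 60),
                         seed = 5100 + r)
    vapply(c("a01", "a06", "a11", "b2"),
           function(m) mean(dosageAtMarker(pop, m)), numeric(1))
  }, numeric(4))
  for (i in 1:4) {
    tstat <- (mean(freqs[i, ]) - 0.5) /
      (stats::sd(freqs[i, ]) / sqrt(nrep))
    expect_lt(abs(tstat), 3.5)
  }
})

test_that("X and Y transmission follow sex rules", {
  pop <- .sharedPop
  inds <- individuals(pop)
  sexes <- vapply(inds, `[[`, character(1), "sex")
  males <- inds[sexes == "M"]
  females <- inds[sexes == "F"]
  # males: single X haplotype; Y label from the pure strain-A sire
  expect_true(all(vapply(males, function(i)
    length(i$haplos[["X"]]) == 1L, logical(1))))
  expect_true(all(vapply(males, `[[`, integer(1), "yOrigin") == 0L))
  # females: two X haplotypes; the sire-derived one is pure strain A
  expect_true(all(vapply(females, function(i)
    length(i$haplos[["X"]]) == 2L && all(i$haplos[["X"]]$h2 == 0L),
    logical(1))))
})

test_that("simulation is deterministic under a fixed seed", {
  map <- tinyMap()
  founders <- makeFounders(map)
  p1 <- simulateCross(map, founders, crossScheme(nTerminal = 20), seed = 8)
  p2 <- simulateCross(map, founders, crossScheme(nTerminal = 20), seed = 8)
  expect_identical(individuals(p1), individuals(p2))
  m <- phenotypeModel(locusMarker = "a05")
  expect_identical(assignPhenotypes(p1, m, seed = 4),
                   assignPhenotypes(p2, m, seed = 4))
})

test_that("LD between marker pairs decays with genetic distance", {
  pop <- .sharedPop
  mk <- markers(.sharedMap)
  chr1 <- mk$id[mk$chrom == "1"]
  d <- vapply(chr1, function(m) dosageAtMarker(pop, m), numeric(187))
  r2near <- pairwiseR2(d[, 1], d[, 2])    # ~3.2 cM apart
  r2far <- pairwiseR2(d[, 1], d[, 20])    # ~61 cM apart
  expect_gt(r2near, r2far)
  expect_gt(r2near, 0.5)
  expect_lt(r2far, 0.3)
})

test_that("phenotype model honours its logistic structure", {
  map <- tinyMap()
  founders <- makeFounders(map)
  pop <- simulateCross(map, founders, crossScheme(nTerminal = 600),
                       seed = 31)
  # null locus and null sex effect: severe rate = plogis(baseline)
  m0 <- phenotypeModel(locusMarker = "a05", locusOR = 1, sexEffect = 0,
                       baselineLogit = 0.3, fracFirstWeek = 0,
                       fracIntermediate = 0, fracNonRupture = 0)
  ph0 <- assignPhenotypes(pop, m0, seed = 7)
  sev <- ph0$death_cause == "rupture"
  p <- stats::plogis(0.3)
  expect_lt(abs(mean(sev) - p), 3 * sqrt(p * (1 - p) / 600))
  # and independence from dosage (chi-square not significant)
  expect_gt(stats::chisq.test(table(sev, ph0$dosage))$p.value, 0.001)
  # protective locus: dosage-1 animals have a lower severe rate
  m1 <- phenotypeModel(locusMarker = "a05", fracFirstWeek = 0,
                       fracIntermediate = 0, fracNonRupture = 0)
  ph1 <- assignPhenotypes(pop, m1, seed = 8)
  sev1 <- ph1$death_cause == "rupture"
  expect_lt(mean(sev1[ph1$dosage == 1]), mean(sev1[ph1$dosage == 0]))
  # all-male cohort with null locus: severe fraction ~ plogis(b + sexEffect)
  popM <- pop
  popM@individuals <- lapply(popM@individuals, function(i) {
    i$sex <- "M"
    i$haplos[["X"]] <- list(h1 = i$haplos[["X"]]$h1)
    i$yOrigin <- 0L
    i
  })
  m2 <- phenotypeModel(locusMarker = "a05", locusOR = 1, sexEffect = 1,
                       baselineLogit = -0.5, fracFirstWeek = 0,
                       fracIntermediate = 0, fracNonRupture = 0)
  ph2 <- assignPhenotypes(popM, m2, seed = 9)
  p2 <- stats::plogis(0.5)
  expect_lt(abs(mean(ph2$death_cause == "rupture") - p2),
            3 * sqrt(p2 * (1 - p2) / 600))
})

test_that("tuned baseline hits the target severe fraction in expectation", {
  b <- tuneBaseline(96 / 187, log(4.94), log(0.2293))
  pM <- 0.5 * (stats::plogis(b + log(4.94)) +
               stats::plogis(b + log(4.94) + log(0.2293)))
  pF <- 0.5 * (stats::plogis(b) + stats::plogis(b + log(0.2293)))
  expect_equal(0.5 * pM + 0.5 * pF, 96 / 187, tolerance = 1e-8)
})

test_that("genotyping emits reference profiles and calibrated noise", {
  pop <- .sharedPop
  zero <- noiseModel(perCallMissing = 0, assayFailureFrac = 0,
                     monomorphicFrac = 0, excessHetFrac = 0,
                     missingHomFrac = 0, parentalDiscordantFrac = 0,
                     f1DiscordantFrac = 0)
  cg <- genotypeWithNoise(pop, .sharedFounders, zero, seed = 2)
  calls <- SummarizedExperiment::assay(cg, "calls")
  rd <- SummarizedExperiment::rowData(cg)
  cd <- SummarizedExperiment::colData(cg)
  notY <- rd$class != "Y"
  # zero noise: full call rate off the Y (Y is not called in females)
  expect_true(all(calls[notY, ] != "NC"))
  # reference profiles: founders opposite homozygotes, F1 heterozygous
  expect_true(all(calls[notY, cd$role == "founderA"] == "AA"))
  expect_true(all(calls[notY, cd$role == "founderB"] == "BB"))
  expect_true(all(calls[notY, cd$role == "f1"] == "AB"))
  # no monomorphic informative marker among cohort+refs
  informative <- rd$informative & notY
  expect_true(all(apply(calls[informative, ], 1,
                        function(x) length(unique(x[x != "NC"])) > 1)))
  # forced whole-assay failure drives call rate below 90%
  noisy <- genotypeWithNoise(pop, .sharedFounders,
                             noiseModel(perCallMissing = 0,
                                        assayFailureFrac = 0.02,
                                        assayFailureMissing = 1),
                             seed = 3)
  fail <- SummarizedExperiment::rowData(noisy)$defect == "assay_failure"
  expect_true(any(fail))
  cr <- rowMeans(SummarizedExperiment::assay(noisy, "calls")[fail, ,
                                                             drop = FALSE]
                 != "NC")
  expect_true(all(cr < 0.90))
  # per-call missing rate 0.0014 recovered within 3 binomial SEs
  m <- genotypeWithNoise(pop, .sharedFounders,
                         noiseModel(perCallMissing = 0.0014,
                                    assayFailureFrac = 0,
                                    monomorphicFrac = 0,
                                    excessHetFrac = 0, missingHomFrac = 0,
                                    parentalDiscordantFrac = 0,
                                    f1DiscordantFrac = 0),
                         seed = 4)
  mc <- SummarizedExperiment::assay(m, "calls")[notY, ]
  rate <- mean(mc == "NC")
  expect_lt(abs(rate - 0.0014),
            3 * sqrt(0.0014 * (1 - 0.0014) / length(mc)))
})
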