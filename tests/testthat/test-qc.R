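# shorthand genotype rows for crafted fixtures
G <- function(...) c(...)

test_that("call-rate filter uses a strict 90% boundary", {
  calls <- rbind(
    m1 = rep("AA", 10),                          # 10/10
    m2 = c(rep("AA", 9), "NC"),                  # 9/10 = 90%: passes
    m3 = c(rep("AA", 8), "NC", "NC"))            # 8/10: removed
  res <- filterCallRate(calls)
  expect_equal(unname(res$keep), c(TRUE, TRUE, FALSE))
  expect_error(filterCallRate(calls[, 0, drop = FALSE]), "individuals")
  mixed <- rbind(
    a = rep("AB", 20),
    b = c(rep("AB", 19), "NC"),
    c = c(rep("AB", 18), "NC", "NC"),            # 90% exactly
    d = c(rep("AB", 17), rep("NC", 3)),          # 85%
    e = c(rep("AB", 10), rep("NC", 10)))         # 50%
  expect_equal(filterCallRate(mixed)$removed, 2)
})

test_that("informativeness rules fire in the stated order", {
  calls <- rbind(
    mono = rep("AA", 20),                                  # MAF = 0
    hihet = c(rep("AB", 17), "AA", "BB", "AA"),            # 85% AB
    nohet = c(rep("AA", 10), rep("BB", 10)),               # AB freq 0
    nobb = c(rep("AA", 12), rep("AB", 8)),                 # BB freq 0
    clean = c(rep("AA", 8), rep("AB", 8), rep("BB", 4)))
  res <- filterInformativeness(calls)
  expect_equal(unname(res$keep),
               c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(res$removedMAF, 1)
  expect_equal(res$removedHet, 2)   # hihet (>80%) and nohet (= 0)
  expect_equal(res$removedHom, 1)
  # frequencies use called genotypes only: no-calls out of the denominator
  m <- rbind(x = c(rep("AB", 17), rep("NC", 4)))  # 17/17 called are AB
  expect_false(filterInformativeness(m)$keep[1])
})

test_that("parental and F1 concordance rules", {
  fx <- qcFixture(list(
    good = G(rep("AA", 4), "AA", "AA", "BB", "BB", "AB", "AB"),
    badP = G(rep("AA", 4), "AA", "AA", "AA", "AA", "AB", "AB"),
    badF1 = G(rep("AA", 4), "AA", "AA", "BB", "BB", "AA", "AB"),
    flipped = G(rep("BB", 4), "BB", "BB", "AA", "AA", "AB", "AB"),
    missP = G(rep("AA", 4), "NC", "AA", "BB", "BB", "AB", "AB")))
  res <- filterConcordance(fx$calls, fx$roles)
  expect_equal(unname(res$keep), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(res$removedParental, 2)  # badP and missP (conservative)
  expect_equal(res$removedF1, 1)
  # configurable: ignore missing profile calls
  lax <- filterConcordance(fx$calls, fx$roles,
                           qcThresholds(missingProfileFails = FALSE))
  expect_true(lax$keep[["missP"]])
  expect_error(filterConcordance(fx$calls[, 1:6], fx$roles[1:6]),
               "profiles")
})

test_that("crafted 12-marker cascade reproduces hand-derived stage counts", {
  # 12 markers: 2 low call rate, 3 monomorphic, 1 excess-het, 1 missing
  # homozygote class, 2 parental-discordant, 3 clean -> 3 released
  clean <- G("AA", "AB", "AB", "BB", "AA", "AA", "BB", "BB", "AB", "AB")
  fx <- qcFixture(list(
    lowcr1 = G(rep("NC", 3), "AB", "AA", "AA", "BB", "BB", "AB", "AB"),
    lowcr2 = G(rep("NC", 4), "AA", "AA", "BB", "BB", "AB", "AB"),
    mono1 = G(rep("AA", 10)),
    mono2 = G(rep("AA", 10)),
    mono3 = G(rep("BB", 10)),
    hihet = G(rep("AB", 9), "AA"),
    nobb = G("AA", "AB", "AB", "AA", "AA", "AA", "AB", "AB", "AB", "AB"),
    badP1 = G("AA", "AB", "AB", "BB", "BB", "BB", "BB", "BB", "AB", "AB"),
    badP2 = G("AA", "AB", "AB", "BB", "AA", "AA", "AA", "BB", "AB", "AB"),
    ok1 = clean, ok2 = clean, ok3 = clean))
  cg <- asCrossGenotypes(fx$calls, fx$roles)
  res <- runQC(cg)
  st <- qcStages(res$report)
  expect_equal(st$removed, c(2, 3, 1, 1, 2, 0))
  expect_equal(st$remaining, c(10, 7, 6, 5, 3, 3))
  expect_equal(res$report@nReleased, 3)
  expect_equal(sort(rownames(res$genotypes)), c("ok1", "ok2", "ok3"))
  # released dosage coding: AA=0, AB=1, BB=2, NC=NA
  dos <- SummarizedExperiment::assay(res$genotypes, "dosage")
  expect_equal(unname(dos["ok1", 1:4]), c(0, 1, 1, 2))
})

test_that("cascade conserves counts, is idempotent and order-invariant", {
  pop <- .sharedPop
  cg <- genotypeWithNoise(pop, .sharedFounders, noiseModel(), seed = 10)
  res <- runQC(cg)
  st <- qcStages(res$report)
  expect_equal(st$remaining,
               res$report@nMarkersIn - cumsum(st$removed))
  expect_equal(st$remaining[nrow(st)], res$report@nReleased)
  # idempotent: rerunning on its own output removes nothing
  res2 <- runQC(res$genotypes)
  expect_equal(sum(qcStages(res2$report)$removed), 0)
  expect_equal(rownames(res2$genotypes), rownames(res$genotypes))
  # permuting individual order never changes which markers are removed
  perm <- sample(ncol(cg))
  resP <- runQC(cg[, perm])
  expect_equal(rownames(resP$genotypes), rownames(res$genotypes))
})

test_that("each injected defect class is removed by its intended stage", {
  pop <- .sharedPop
  noise <- noiseModel(perCallMissing = 0, assayFailureFrac = 0.01,
                      assayFailureMissing = 1, monomorphicFrac = 0.02,
                      excessHetFrac = 0.01, missingHomFrac = 0.005,
                      parentalDiscordantFrac = 0.005,
                      f1DiscordantFrac = 0.005)
  cg <- genotypeWithNoise(pop, .sharedFounders, noise, seed = 44)
  rd <- SummarizedExperiment::rowData(cg)
  res <- runQC(cg)
  st <- qcStages(res$report)
  rem <- setNames(st$removed, st$stage)
  nY <- sum(rd$class == "Y")  # female refs uncalled: Y fails call rate
  expect_equal(rem[["call_rate"]],
               sum(rd$defect == "assay_failure") + nY)
  expect_equal(rem[["maf"]], sum(rd$defect == "monomorphic"))
  # drift can fix a marker for strain B in the dam pool, making every
  # terminal offspring heterozygous: such clean markers legitimately trip
  # the heterozygosity rule alongside the injected excess-het markers
  expect_gte(rem[["het_rate"]], sum(rd$defect == "excess_het"))
  expect_equal(rem[["hom_missing"]], sum(rd$defect == "missing_homozygote"))
  expect_equal(rem[["parental_concordance"]],
               sum(rd$defect == "parental_discordant"))
  expect_equal(rem[["f1_concordance"]], sum(rd$defect == "f1_discordant"))
  # stage attribution: each injected class fails exactly its own filter
  calls <- SummarizedExperiment::assay(cg, "calls")
  s1 <- filterCallRate(calls)
  expect_true(all(!s1$keep[rd$defect == "assay_failure"]))
  surv <- calls[s1$keep, , drop = FALSE]
  rdS <- rd[s1$keep, ]
  s2 <- filterInformativeness(surv)
  expect_true(all(!s2$keep[rdS$defect %in%
                             c("monomorphic", "excess_het",
                               "missing_homozygote")]))
  expect_true(all(s2$keep[rdS$defect %in%
                            c("parental_discordant", "f1_discordant")]))
  # every released marker is defect-free
  expect_true(all(SummarizedExperiment::rowData(res$genotypes)$defect ==
                    "none"))
})

test_that("missing rate arithmetic and report validity", {
  # released-call bookkeeping consistent with the class invariant
  stages <- data.frame(
    stage = c("call_rate", "maf", "het_rate", "hom_missing"),
    removed = c(3942, 97595, 707, 6461),
    remaining = c(139504, 41909, 41202, 34741))
  rep1 <- new("QCReport", stages = stages, nMarkersIn = 143446,
              nReleased = 32218, nSamples = 173, nNoCalls = 7917)
  expect_equal(missingRate(rep1), 0.14)
  rep2 <- new("QCReport", stages = stages[0, ], nMarkersIn = 10,
              nReleased = 200, nSamples = 1, nNoCalls = 0)
  expect_equal(missingRate(rep2), 0)
  rep3 <- new("QCReport", stages = stages[0, ], nMarkersIn = 10,
              nReleased = 200, nSamples = 1, nNoCalls = 1)
  expect_equal(missingRate(rep3), 0.5)
  # broken bookkeeping is rejected by the validity method
  bad <- stages
  bad$remaining[2] <- 99
  expect_error(new("QCReport", stages = bad, nMarkersIn = 143446,
                   nReleased = 32218, nSamples = 173, nNoCalls = 7917),
               "reconcile")
})
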