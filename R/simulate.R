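#' Haldane map function
#'
#' Converts a genetic map distance in Morgans to a recombination fraction
#' under the Haldane model (crossovers form a Poisson process with no
#' interference): r = (1 - exp(-2d)) / 2.
#'
#' @param d map distance in Morgans (non-negative; may be a vector).
#' @return Recombination fraction(s) in [0, 0.5).
#' @export
#' @examples
#' haldaneRecombination(0.10)  # 10 cM -> ~0.0906
haldaneRecombination <- function(d) {
  if (any(d < 0)) stop("map distance must be non-negative")
  (1 - exp(-2 * d)) / 2
}

# Draw one gamete from a haplotype pair on a chromosome of length `lengthM`
# Morgans with markers at `cM` positions. Poisson crossover count, uniform
# crossover placement, random starting strand.
.gamete <- function(h1, h2, cM, lengthM) {
  start1 <- runif(1) < 0.5
  k <- rpois(1L, lengthM)
  if (k == 0L) return(if (start1) h1 else h2)
  xo <- sort(runif(k, 0, lengthM * 100))
  onFirst <- (findInterval(cM, xo) %% 2L == 0L) == start1
  out <- h2
  out[onFirst] <- h1[onFirst]
  out
}

#' Simulate one meiosis
#'
#' Returns a gamete haplotype (founder-origin labels per marker) for one
#' chromosome of one parent. Autosomes and female X recombine with a
#' Poisson(L) crossover count over the chromosome's L Morgans (Haldane, no
#' interference). The male X is transmitted to daughters without
#' recombination; the Y label passes to sons unchanged.
#'
#' @param parent an individual record from a [CrossPopulation].
#' @param chrom chromosome name.
#' @param map the [GeneticMap-class].
#' @param seed optional RNG seed.
#' @return Integer vector of founder-origin labels (0 = strain A,
#'   1 = strain B), or a single label for the Y.
#' @export
meiosis <- function(parent, chrom, map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ci <- chromInfo(map)
  if (!chrom %in% ci$name) stop("unknown chromosome: ", chrom)
  cls <- ci$class[ci$name == chrom]
  if (cls == "Y") {
    if (parent$sex != "M") stop("Y transmission requires a male parent")
    return(parent$yOrigin)
  }
  cm <- .chromMap(map, chrom)
  hp <- parent$haplos[[chrom]]
  if (cls == "X" && parent$sex == "M") return(hp$h1)
  .gamete(hp$h1, hp$h2, cm$cM, cm$lengthM)
}

#' Define the two inbred founder strains
#'
#' The founders are fully homozygous and, at informative markers, opposite
#' homozygotes (strain A carries the A allele, strain B the B allele). A
#' configurable fraction of markers is non-informative (both strains share
#' the A allele); such markers are monomorphic in the cross and exist to
#' exercise the minor-allele-frequency QC filter.
#'
#' @param map a [GeneticMap-class].
#' @param nonInformativeFrac fraction of markers at which the strains share
#'   an allele (default 0: every marker informative, as on a pre-selected
#'   strain-discriminating panel).
#' @param strainA,strainB strain display names.
#' @param seed optional RNG seed for choosing non-informative markers.
#' @return A founder-pair definition (list with `strainA`, `strainB` and a
#'   per-marker logical `informative` vector named by marker id).
#' @export
makeFounders <- function(map, nonInformativeFrac = 0, strainA = "BL6",
                         strainB = "129", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- markers(map)
  informative <- setNames(rep(TRUE, nrow(mk)), mk$id)
  if (nonInformativeFrac > 0) {
    n <- round(nonInformativeFrac * nrow(mk))
    informative[sample(nrow(mk), n)] <- FALSE
  }
  list(strainA = strainA, strainB = strainB, informative = informative)
}

# Build a fully inbred individual (all haplotypes = `label`).
.inbredIndividual <- function(id, sex, generation, label, map,
                              mutant = FALSE) {
  ci <- chromInfo(map)
  mk <- markers(map)
  haplos <- list()
  for (i in seq_len(nrow(ci))) {
    ch <- ci$name[i]
    cls <- ci$class[i]
    if (cls == "Y") next
    n <- sum(mk$chrom == ch)
    h <- rep(as.integer(label), n)
    haplos[[ch]] <-
      if (cls == "X" && sex == "M") list(h1 = h) else list(h1 = h, h2 = h)
  }
  list(id = id, sex = sex, generation = generation, mutant = mutant,
       haplos = haplos,
       yOrigin = if (sex == "M") as.integer(label) else NA_integer_)
}

# Mate two individuals; chromCache pre-extracts cM/length per chromosome.
.mate <- function(dam, sire, id, sex, generation, map, chromCache,
                  mutant = FALSE) {
  haplos <- list()
  for (cc in chromCache) {
    ch <- cc$name
    if (cc$class == "Y") next
    if (cc$class == "X") {
      hd <- .gamete(dam$haplos[[ch]]$h1, dam$haplos[[ch]]$h2, cc$cM,
                    cc$lengthM)
      haplos[[ch]] <- if (sex == "M") list(h1 = hd)
                      else list(h1 = hd, h2 = sire$haplos[[ch]]$h1)
    } else {
      haplos[[ch]] <- list(
        h1 = .gamete(dam$haplos[[ch]]$h1, dam$haplos[[ch]]$h2, cc$cM,
                     cc$lengthM),
        h2 = .gamete(sire$haplos[[ch]]$h1, sire$haplos[[ch]]$h2, cc$cM,
                     cc$lengthM))
    }
  }
  list(id = id, sex = sex, generation = generation, mutant = mutant,
       haplos = haplos,
       yOrigin = if (sex == "M") sire$yOrigin else NA_integer_)
}

.chromCache <- function(map) {
  ci <- chromInfo(map)
  lapply(seq_len(nrow(ci)), function(i) {
    cm <- .chromMap(map, ci$name[i])
    list(name = ci$name[i], class = ci$class[i], cM = cm$cM,
         lengthM = cm$lengthM)
  })
}

#' Breeding scheme parameters
#'
#' Generation sizes for the intercross and the terminal cross. Defaults
#' expand the colony generation by generation (20, 30, 40, 60), then produce
#' a terminal mapping cohort of 187 mutant offspring. `terminalMales` /
#' `terminalFemales`, when given, fix the terminal cohort's sex composition
#' exactly (offspring of a sex whose quota is filled are not retained);
#' otherwise sex is a fair Bernoulli draw.
#'
#' @param nF1,nF2,nF3,nF4 animals per intercross generation (each >= 4 so
#'   both sexes can be represented by at least two breeders).
#' @param nTerminal number of mutant terminal offspring to retain.
#' @param terminalMales,terminalFemales optional exact sex quotas (must sum
#'   to `nTerminal`).
#' @return A scheme parameter list.
#' @export
crossScheme <- function(nF1 = 20, nF2 = 30, nF3 = 40, nF4 = 60,
                        nTerminal = 187, terminalMales = NULL,
                        terminalFemales = NULL) {
  sizes <- c(F1 = nF1, F2 = nF2, F3 = nF3, F4 = nF4)
  if (any(sizes < 4)) stop("each generation needs >= 2 breeders per sex")
  if (!is.null(terminalMales) != !is.null(terminalFemales))
    stop("give both terminalMales and terminalFemales or neither")
  if (!is.null(terminalMales) &&
      terminalMales + terminalFemales != nTerminal)
    stop("terminal sex quotas must sum to nTerminal")
  list(sizes = sizes, nTerminal = nTerminal, terminalMales = terminalMales,
       terminalFemales = terminalFemales)
}

# Random monogamous pairing of one generation; offspring distributed
# round-robin over pairs. Selfing is impossible (pairs are one dam x one
# sire); sib mating is allowed.
.nextGeneration <- function(parents, n, generation, map, chromCache,
                            idPrefix) {
  sexes <- vapply(parents, `[[`, character(1), "sex")
  dams <- parents[sexes == "F"]
  sires <- parents[sexes == "M"]
  if (length(dams) < 2 || length(sires) < 2)
    stop("insufficient breeders in generation preceding ", generation)
  np <- min(length(dams), length(sires))
  dams <- sample(dams, np)
  sires <- sample(sires, np)
  lapply(seq_len(n), function(i) {
    p <- ((i - 1) %% np) + 1
    .mate(dams[[p]], sires[[p]], sprintf("%s_%03d", idPrefix, i),
          if (runif(1) < 0.5) "F" else "M", generation, map, chromCache)
  })
}

#' Simulate the breeding program
#'
#' Runs the full design: two inbred founder strains are intercrossed for four
#' generations of wild-type animals (P -> F1 -> F2 -> F3 -> F4, random
#' monogamous pairing, no selfing), accumulating recombination between the
#' strain-specific chromosomes; F4 females are then bred to pure strain-A
#' males heterozygous for the disease mutation. Each terminal offspring
#' inherits one recombinant mixed-background haplotype from its dam and one
#' pure strain-A haplotype from its sire, so autosomal strain-B dosage is 0
#' or 1 at every marker. Offspring carry the mutation with probability 1/2;
#' only mutant offspring are retained (the phenotype is only defined for
#' mutants).
#'
#' @param map a [GeneticMap-class].
#' @param founders founder definition from [makeFounders()].
#' @param scheme breeding scheme from [crossScheme()].
#' @param seed optional RNG seed.
#' @return A [CrossPopulation-class] of terminal mutant offspring.
#' @export
simulateCross <- function(map, founders, scheme = crossScheme(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- .chromCache(map)
  # P: two breeding pairs per strain; F1 produced from reciprocal crosses
  pa <- lapply(1:2, function(i) list(
    .inbredIndividual(sprintf("A_F%d", i), "F", "P", 0L, map),
    .inbredIndividual(sprintf("A_M%d", i), "M", "P", 0L, map)))
  pb <- lapply(1:2, function(i) list(
    .inbredIndividual(sprintf("B_F%d", i), "F", "P", 1L, map),
    .inbredIndividual(sprintf("B_M%d", i), "M", "P", 1L, map)))
  nF1 <- scheme$sizes[["F1"]]
  f1 <- lapply(seq_len(nF1), function(i) {
    if (i %% 2 == 1)
      .mate(pa[[1]][[1]], pb[[1]][[2]], sprintf("F1_%03d", i),
            if (runif(1) < 0.5) "F" else "M", "F1", map, cc)
    else
      .mate(pb[[2]][[1]], pa[[2]][[2]], sprintf("F1_%03d", i),
            if (runif(1) < 0.5) "F" else "M", "F1", map, cc)
  })
  gen <- f1
  for (g in c("F2", "F3", "F4"))
    gen <- .nextGeneration(gen, scheme$sizes[[g]], g, map, cc, g)
  # terminal cross: F4 females x strain-A heterozygous-mutant males
  sexes <- vapply(gen, `[[`, character(1), "sex")
  dams <- gen[sexes == "F"]
  if (length(dams) < 2) stop("insufficient F4 dams for the terminal cross")
  sires <- lapply(seq_along(dams), function(i)
    .inbredIndividual(sprintf("sireA_%03d", i), "M", "terminal_sire", 0L,
                      map, mutant = TRUE))
  np <- length(dams)
  quotaM <- scheme$terminalMales
  quotaF <- scheme$terminalFemales
  out <- vector("list", scheme$nTerminal)
  kept <- 0L
  i <- 0L
  while (kept < scheme$nTerminal) {
    i <- i + 1L
    if (i > 200L * scheme$nTerminal)
      stop("terminal cross failed to reach requested cohort size")
    mutant <- runif(1) < 0.5
    sex <- if (runif(1) < 0.5) "F" else "M"
    if (!mutant) next  # non-mutants discarded at birth
    if (!is.null(quotaM)) {
      if (sex == "M" && quotaM == 0L) next
      if (sex == "F" && quotaF == 0L) next
      if (sex == "M") quotaM <- quotaM - 1L else quotaF <- quotaF - 1L
    }
    p <- ((kept) %% np) + 1L
    kept <- kept + 1L
    out[[kept]] <- .mate(dams[[p]], sires[[p]],
                         sprintf("T_%03d", kept), sex, "terminal", map, cc,
                         mutant = TRUE)
  }
  new("CrossPopulation", individuals = out, map = map)
}

#' @rdname accessors
#' @export
setMethod("individuals", "CrossPopulation", function(x, ...) x@individuals)

setMethod("show", "CrossPopulation", function(object) {
  sexes <- vapply(object@individuals, `[[`, character(1), "sex")
  cat("CrossPopulation with", length(object@individuals), "individuals (",
      sum(sexes == "F"), "F /", sum(sexes == "M"), "M ) on",
      nMarkers(object@map), "markers\n")
})

#' Strain-B allele dosage at one marker
#'
#' Counts strain-B (label 1) alleles carried by each individual at a marker.
#' Autosomes and female X count both haplotypes (0/1/2); the hemizygous male
#' X counts the single haplotype (0/1).
#'
#' @param pop a [CrossPopulation-class].
#' @param markerId marker id on the population's map.
#' @return Named integer vector of dosages.
#' @export
dosageAtMarker <- function(pop, markerId) {
  mk <- markers(pop@map)
  j <- match(markerId, mk$id)
  if (is.na(j)) stop("marker not on map: ", markerId)
  ch <- mk$chrom[j]
  if (chromInfo(pop@map)$class[chromInfo(pop@map)$name == ch] == "Y")
    stop("dosage undefined for Y markers")
  idx <- which(mk$id[mk$chrom == ch] == markerId)
  vapply(individuals(pop), function(ind) {
    hp <- ind$haplos[[ch]]
    if (length(hp) == 1L) hp$h1[idx] else hp$h1[idx] + hp$h2[idx]
  }, integer(1)) |>
    setNames(vapply(individuals(pop), `[[`, character(1), "id"))
}
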