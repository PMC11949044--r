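#' Survival phenotype model
#'
#' Parameters of the binary severe/mild outcome and its survival-time
#' generator. The probability of the severe outcome (death from aortic
#' rupture in the early window) follows a logistic model:
#' logit P(severe) = baseline + sexEffect * [male] + locusEffect * dosage
#' (+ interaction * [male] * dosage), where dosage counts protective
#' strain-B alleles at the modifier locus. The default per-allele odds ratio
#' is 0.2293 (protective) and the default male log-odds increment is the
#' cross-product odds ratio of the observed sex-by-severity table (~4.94).
#' Severe animals die of rupture at a uniform time in `severeWindow` days;
#' mild animals survive past `controlMin` days. Small fractions of animals
#' draw fates that the stratification stage must exclude (first-week deaths,
#' intermediate-window rupture deaths, non-rupture deaths), exercising the
#' exclusion rules.
#'
#' @param locusMarker marker id of the planted modifier locus.
#' @param locusOR per-allele odds ratio of the severe outcome for a strain-B
#'   allele (protective when < 1).
#' @param sexEffect log-odds added for males.
#' @param interaction optional sex-by-locus log-odds interaction.
#' @param baselineLogit baseline log-odds for a dosage-0 female; if `NULL`
#'   it is tuned with [tuneBaseline()] so the expected severe fraction is
#'   `targetSevere` under a 50:50 sex mix and 50:50 dosage mix.
#' @param targetSevere expected severe fraction used when tuning (default
#'   0.513, the observed 96/187).
#' @param severeWindow rupture-death window in days for severe animals.
#' @param controlMin mild animals survive strictly beyond this day.
#' @param fracFirstWeek,fracIntermediate,fracNonRupture fractions of animals
#'   assigned excluded fates (death in days (0,7]; rupture death in days
#'   (84,168]; non-rupture death in days (7,168]).
#' @return A phenotype model parameter list.
#' @export
phenotypeModel <- function(locusMarker, locusOR = 0.2293,
                           sexEffect = log(4.94), interaction = 0,
                           baselineLogit = NULL, targetSevere = 96 / 187,
                           severeWindow = c(8, 84), controlMin = 168,
                           fracFirstWeek = 0.02, fracIntermediate = 0.03,
                           fracNonRupture = 0.04) {
  stopifnot(locusOR > 0, length(severeWindow) == 2,
            severeWindow[1] < severeWindow[2], controlMin > severeWindow[2],
            fracFirstWeek >= 0, fracIntermediate >= 0, fracNonRupture >= 0,
            fracFirstWeek + fracIntermediate + fracNonRupture < 1)
  m <- list(locusMarker = locusMarker, locusEffect = log(locusOR),
            sexEffect = sexEffect, interaction = interaction,
            severeWindow = severeWindow, controlMin = controlMin,
            fracFirstWeek = fracFirstWeek,
            fracIntermediate = fracIntermediate,
            fracNonRupture = fracNonRupture)
  m$baselineLogit <- if (is.null(baselineLogit))
    tuneBaseline(targetSevere, sexEffect, m$locusEffect, interaction)
  else baselineLogit
  m
}

#' Tune the baseline log-odds for a target severe fraction
#'
#' Solves for the baseline logit b such that the expected severe fraction,
#' averaged over the sex mix and the modifier-dosage distribution, equals
#' `target`:
#' mean over (sex, dosage) of plogis(b + sexEffect*male + locusEffect*dose
#' + interaction*male*dose) = target.
#'
#' @param target desired expected severe fraction.
#' @param sexEffect,locusEffect,interaction model log-odds terms.
#' @param maleFrac fraction of males in the cohort.
#' @param doseProb probabilities of dosages `0:(length(doseProb)-1)`
#'   (default c(0.5, 0.5): the terminal-cross 0/1 design).
#' @return The baseline logit.
#' @export
tuneBaseline <- function(target, sexEffect, locusEffect, interaction = 0,
                         maleFrac = 0.5, doseProb = c(0.5, 0.5)) {
  doses <- seq_along(doseProb) - 1
  f <- function(b) {
    pm <- sum(doseProb * stats::plogis(
      b + sexEffect + locusEffect * doses + interaction * doses))
    pf <- sum(doseProb * stats::plogis(b + locusEffect * doses))
    maleFrac * pm + (1 - maleFrac) * pf - target
  }
  uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Assign survival phenotypes to a terminal cohort
#'
#' Draws each animal's fate under a [phenotypeModel()]: first the excluded
#' fates (first-week death, intermediate-window rupture, non-rupture death)
#' at their configured fractions, then severe/mild by the logistic model on
#' sex and modifier dosage. Severe: rupture death uniform over
#' `severeWindow` days. Mild: alive past `controlMin` days (censoring time
#' uniform over (controlMin, 365]).
#'
#' @param pop a [CrossPopulation-class] of terminal mutant offspring.
#' @param model a [phenotypeModel()].
#' @param seed optional RNG seed.
#' @return data.frame with columns `id`, `sex`, `generation`, `dosage`,
#'   `survival_days`, `death_cause` (`rupture`, `other` or `alive`).
#' @export
assignPhenotypes <- function(pop, model, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  inds <- individuals(pop)
  n <- length(inds)
  dosage <- dosageAtMarker(pop, model$locusMarker)
  sex <- vapply(inds, `[[`, character(1), "sex")
  male <- as.integer(sex == "M")
  eta <- model$baselineLogit + model$sexEffect * male +
    model$locusEffect * dosage + model$interaction * male * dosage
  u <- runif(n)
  f1 <- model$fracFirstWeek
  f2 <- f1 + model$fracIntermediate
  f3 <- f2 + model$fracNonRupture
  fate <- ifelse(u < f1, "first_week",
          ifelse(u < f2, "intermediate",
          ifelse(u < f3, "non_rupture",
          ifelse(runif(n) < stats::plogis(eta), "severe", "mild"))))
  t <- numeric(n)
  cause <- character(n)
  w <- fate == "first_week"
  t[w] <- runif(sum(w), 0.5, 7)
  cause[w] <- "rupture"
  w <- fate == "intermediate"
  t[w] <- runif(sum(w), model$severeWindow[2], model$controlMin)
  cause[w] <- "rupture"
  w <- fate == "non_rupture"
  t[w] <- runif(sum(w), 7, model$controlMin)
  cause[w] <- "other"
  w <- fate == "severe"
  t[w] <- runif(sum(w), model$severeWindow[1], model$severeWindow[2])
  cause[w] <- "rupture"
  w <- fate == "mild"
  t[w] <- runif(sum(w), model$controlMin + 1, 365)
  cause[w] <- "alive"
  data.frame(
    id = vapply(inds, `[[`, character(1), "id"),
    sex = sex,
    generation = vapply(inds, `[[`, character(1), "generation"),
    dosage = as.integer(dosage),
    survival_days = t,
    death_cause = cause,
    stringsAsFactors = FALSE)
}
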