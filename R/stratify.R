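#' Extreme-phenotype stratification rule
#'
#' Case/control coding of survival records. Cases ("severe") are deaths from
#' aortic rupture after the first week and within the early window; controls
#' ("mild") are animals surviving strictly beyond the late threshold.
#' Week boundaries are pinned as 1 week = 7 days (case window t > 7 and
#' t <= 84) and 24 weeks = 168 days (control requires t > 168). Everything
#' else is excluded with a recorded reason.
#'
#' @param caseWindowDays rupture-death window (exclusive lower, inclusive
#'   upper bound) defining cases.
#' @param controlThresholdDays survival strictly beyond this day defines
#'   controls, regardless of eventual cause.
#' @return A stratification rule list.
#' @export
stratificationRule <- function(caseWindowDays = c(7, 84),
                               controlThresholdDays = 168) {
  stopifnot(length(caseWindowDays) == 2,
            caseWindowDays[1] < caseWindowDays[2],
            controlThresholdDays > caseWindowDays[2])
  list(caseWindowDays = caseWindowDays,
       controlThresholdDays = controlThresholdDays)
}

#' Stratify survival records into cases, controls and exclusions
#'
#' Applies the extreme-phenotype rule: case iff rupture death with
#' 7 < t <= 84 days; control iff survival beyond 168 days (alive, censored
#' or dying of any cause after that day); all other animals are excluded
#' with a reason — `died_first_week` (t <= 7), `intermediate_death`
#' (rupture death in (84, 168]), `non_rupture_death` (other-cause death at
#' t <= 168), `censored_early` (alive/censored at t <= 168), or
#' `missing_cause` (death with no recorded cause — flagged, never silently
#' dropped).
#'
#' @param pheno data.frame with columns `id`, `sex`, `survival_days`,
#'   `death_cause` (`rupture`, `other`, `censored`, `alive`, or NA).
#' @param rule a [stratificationRule()].
#' @return The input with added columns `class`
#'   (`case`/`control`/`excluded`) and `exclusion_reason`; the per-sex
#'   class counts are attached as attribute `"counts"`.
#' @export
stratifySurvival <- function(pheno, rule = stratificationRule()) {
  need <- c("id", "sex", "survival_days", "death_cause")
  if (!all(need %in% names(pheno)))
    stop("phenotype table needs columns ", paste(need, collapse = ", "))
  if (any(is.na(pheno$survival_days)))
    stop("every record needs a survival time")
  t <- pheno$survival_days
  cause <- as.character(pheno$death_cause)
  dead <- !cause %in% c("alive", "censored")
  lo <- rule$caseWindowDays[1]
  hi <- rule$caseWindowDays[2]
  ctrl <- rule$controlThresholdDays

  cls <- rep("excluded", nrow(pheno))
  reason <- rep(NA_character_, nrow(pheno))
  isCase <- dead & !is.na(cause) & cause == "rupture" & t > lo & t <= hi
  isControl <- t > ctrl
  cls[isCase] <- "case"
  cls[isControl & !isCase] <- "control"
  ex <- cls == "excluded"
  reason[ex & dead & is.na(cause)] <- "missing_cause"
  left <- ex & is.na(reason)
  reason[left & t <= lo] <- "died_first_week"
  left <- ex & is.na(reason)
  reason[left & dead & cause == "rupture" & t > hi] <- "intermediate_death"
  left <- ex & is.na(reason)
  reason[left & dead] <- "non_rupture_death"
  left <- ex & is.na(reason)
  reason[left] <- "censored_early"

  out <- pheno
  out$class <- cls
  out$exclusion_reason <- reason
  attr(out, "counts") <- table(sex = out$sex, class = out$class)
  out
}

#' Sex-by-severity association
#'
#' Two-sided Fisher's exact test (hypergeometric enumeration) and
#' cross-product odds ratio on the sex x case/control table of a stratified
#' cohort. Excluded animals are ignored.
#'
#' @param strat output of [stratifySurvival()], or a 2x2 matrix with rows
#'   (control, case) and columns (F, M).
#' @return List with `table`, `p` (two-sided exact), and `oddsRatio`
#'   (cross-product: odds of case in males over females).
#' @export
sexAssociation <- function(strat) {
  if (is.matrix(strat)) {
    tab <- strat
  } else {
    kept <- strat[strat$class %in% c("case", "control"), ]
    tab <- table(factor(kept$class, c("control", "case")),
                 factor(kept$sex, c("F", "M")))
    tab <- unclass(tab)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in sex-by-class table; no association testable")
    return(list(table = tab, p = 1, oddsRatio = NA_real_))
  }
  p <- fisher.test(tab)$p.value
  orr <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
  list(table = tab, p = p, oddsRatio = orr)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate S(t) = prod over event times <= t of
#' (1 - d_i / n_i) per group, with right-censoring handled by risk-set
#' decrement without a step.
#'
#' @param time survival times (> 0).
#' @param event 1 = death, 0 = censored.
#' @param group optional group labels (one curve per group).
#' @return data.frame with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv` — one row per observed time per group.
#' @export
kaplanMeier <- function(time, event, group = NULL) {
  if (length(time) == 0) stop("empty survival table")
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(time))
  if (any(tapply(time, group, length) == 0)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(group), length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, surv = sm$surv,
             stringsAsFactors = FALSE)
}

#' Log-rank (Mantel-Cox) test
#'
#' Unstratified two-group log-rank test: observed minus expected deaths
#' accumulated over shared event times, with the hypergeometric variance;
#' the statistic is chi-squared on 1 df.
#'
#' @param time survival times.
#' @param event 1 = death, 0 = censored.
#' @param group two-level group labels.
#' @return List with `chisq`, `df` and `p`.
#' @export
logrankTest <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("log-rank test requires exactly two groups")
  if (any(table(g) == 0)) stop("empty group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chisq = sd$chisq, df = 1,
       p = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
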