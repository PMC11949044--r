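#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit used by the genome scan. Duplicate
#' covariate patterns are collapsed to binomial counts before fitting (the
#' scan's designs have at most four patterns: dosage x sex), which makes the
#' per-marker fit cheap. Convergence is declared when the maximum absolute
#' score falls below 1e-8 or the relative log-likelihood change falls below
#' 1e-10, within 50 iterations. Quasi-complete separation (any coefficient
#' diverging beyond |beta| > 15) is flagged and no p-value is reported for
#' such fits; a constant design column is flagged degenerate.
#'
#' @param y binary outcome vector (0/1 or logical).
#' @param X covariate matrix (no intercept column; one is added).
#' @return List: `beta` (named, intercept first), `se`, `converged`,
#'   `status` (`"ok"`, `"separation"` or `"degenerate"`), `iterations`,
#'   `logLik`.
#' @export
fitLogistic <- function(y, X) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  empty <- list(beta = setNames(rep(NA_real_, ncol(X) + 1),
                                c("(Intercept)", colnames(X))),
                se = NULL, converged = FALSE, iterations = 0L,
                logLik = NA_real_)
  empty$se <- empty$beta
  if (sum(y) == 0 || sum(y) == length(y) ||
      any(apply(X, 2, function(v) length(unique(v)) < 2))) {
    empty$status <- "degenerate"
    return(empty)
  }
  key <- do.call(paste, c(as.data.frame(X), sep = "\r"))
  grp <- match(key, unique(key))
  k <- max(grp)
  s <- as.vector(rowsum(y, grp))
  n <- as.vector(rowsum(rep(1, length(y)), grp))
  Xc <- cbind("(Intercept)" = 1, X[!duplicated(grp), , drop = FALSE])

  p <- ncol(Xc)
  beta <- rep(0, p)
  ll <- -Inf
  status <- "ok"
  converged <- FALSE
  iter <- 0L
  H <- NULL
  while (iter < 50L) {
    iter <- iter + 1L
    eta <- drop(Xc %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(Xc, s - n * mu))
    w <- n * mu * (1 - mu)
    H <- crossprod(Xc, Xc * w)
    delta <- tryCatch(solve(H, score), error = function(e) NULL)
    if (is.null(delta)) { status <- "degenerate"; break }
    beta <- beta + delta
    eta <- drop(Xc %*% beta)
    llNew <- sum(s * eta - n * log1p(exp(eta)))
    if (max(abs(beta)) > 15) { status <- "separation"; break }
    if (max(abs(score)) < 1e-8 ||
        abs(llNew - ll) < 1e-10 * (abs(ll) + 1e-10)) {
      converged <- TRUE
      ll <- llNew
      break
    }
    ll <- llNew
  }
  if (status == "degenerate") {
    empty$status <- "degenerate"
    return(empty)
  }
  se <- rep(NA_real_, p)
  if (status == "ok") {
    cv <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cv)) status <- "degenerate" else se <- sqrt(diag(cv))
  }
  list(beta = setNames(beta, colnames(Xc)),
       se = setNames(se, colnames(Xc)),
       converged = converged, status = status, iterations = iter,
       logLik = ll)
}

#' Wald odds ratio, confidence interval and p-value
#'
#' OR = exp(beta) with 95\% bounds exp(beta -/+ 1.96 * SE) (the multiplier
#' is fixed at 1.96) and a two-sided p from the standard normal tail of
#' z = beta / SE.
#'
#' @param beta log-odds estimate.
#' @param se its standard error (> 0).
#' @return List: `or`, `lower`, `upper`, `z`, `p`.
#' @export
waldCI <- function(beta, se) {
  stopifnot(se > 0)
  z <- beta / se
  list(or = exp(beta), lower = exp(beta - 1.96 * se),
       upper = exp(beta + 1.96 * se), z = z, p = 2 * pnorm(-abs(z)))
}

#' Bonferroni genome-wide significance threshold
#'
#' Family-wise alpha divided by the number of quasi-independent tests (the
#' LD-pruned marker count, equating LD blocks with pruned SNPs).
#'
#' @param alpha family-wise error rate.
#' @param nTests number of tests.
#' @return Per-marker p-value threshold.
#' @export
bonferroniThreshold <- function(alpha = 0.05, nTests) {
  stopifnot(alpha > 0, alpha < 1, nTests >= 1)
  alpha / nTests
}
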