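#' Fit a Cox proportional-hazards model (Breslow ties)
#'
#' Wraps `survival::coxph` with Breslow tie handling and returns a
#' [CoxFit-class] summary: per-covariate log-hazard ratios with standard
#' errors, hazard ratios with Wald 95% confidence intervals, Wald p-values,
#' the partial log-likelihood at the optimum, and a convergence flag.
#' Monotone likelihood (perfect separation, diverging coefficients) is
#' flagged via a warning rather than returned silently. Covariates that are
#' constant (unidentifiable) are reported with beta = 0, HR = 1 and NA
#' uncertainty.
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators (1 = event observed).
#' @param covariates numeric vector or matrix (one column per covariate).
#' @return A [CoxFit-class].
#' @examples
#' fit <- fitCox(c(5, 8, 2, 9, 4), c(1, 1, 1, 0, 1), c(1.2, 0.1, 2.0, -1, 0.5))
#' fit
#' @export
fitCox <- function(times, events, covariates) {
  covariates <- as.matrix(covariates)
  if (is.null(colnames(covariates)))
    colnames(covariates) <- paste0("x", seq_len(ncol(covariates)))
  stopifnot(length(times) == length(events), nrow(covariates) == length(times))
  if (any(!is.finite(covariates))) stop("covariates must be finite")
  if (sum(events) < 1) stop("at least one event is required")

  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ covariates,
                    ties = "breslow", control = survival::coxph.control(iter.max = 200)),
    warning = function(w) {
      if (grepl("infinite|Loglik converged before variable|beta may be infinite",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation)
    warning("monotone partial likelihood: a coefficient may be infinite (perfect separation)")

  beta <- coef(fit)
  names(beta) <- colnames(covariates)
  se <- sqrt(diag(fit$var))
  if (length(se) < length(beta)) se <- rep(NA_real_, length(beta))
  names(se) <- names(beta)
  aliased <- is.na(beta)
  beta[aliased] <- 0
  se[aliased] <- NA_real_
  z <- beta / se
  out <- new("CoxFit",
    coefficients = beta, se = se, hr = exp(beta),
    ciLow = exp(beta - 1.96 * se), ciHigh = exp(beta + 1.96 * se),
    p = 2 * stats::pnorm(-abs(z)),
    logLik = as.numeric(fit$loglik[2]),
    converged = is.null(fit$info) || fit$iter < 200,
    model = fit)
  out
}

#' Proportional-hazards diagnostic via scaled Schoenfeld residuals
#'
#' Per-covariate test of the proportional-hazards assumption: correlation of
#' scaled Schoenfeld residuals with rank-transformed event time, giving a
#' 1-df chi-square statistic per covariate (via `survival::cox.zph` with the
#' rank transform).
#'
#' @param fit a [CoxFit-class] from [fitCox()].
#' @return data.frame with columns `covariate`, `chisq`, `df`, `p`
#'   (per-covariate rows; no global row).
#' @export
phTest <- function(fit) {
  stopifnot(is(fit, "CoxFit"))
  if (!fit@converged) stop("phTest requires a converged fit")
  ev <- fit@model$nevent
  if (is.null(ev)) ev <- sum(fit@model$y[, ncol(fit@model$y)])
  if (ev < 3) stop("at least 3 events are required for the PH diagnostic")
  zph <- survival::cox.zph(fit@model, transform = "rank", global = FALSE)
  tab <- as.data.frame(zph$table)
  data.frame(covariate = names(fit@coefficients),
             chisq = tab$chisq, df = tab$df, p = tab$p,
             row.names = NULL)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment `p * m / rank` with tail-minimum monotonicity
#' enforcement, as implemented by `stats::p.adjust(method = "BH")`, with
#' validation of the input range.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, order-preserving, never smaller than the input.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Harrell's concordance index for censored survival data
#'
#' Probability, over admissible pairs (pairs in which the shorter observed
#' time ends in an event), that the sample with the higher risk score fails
#' earlier; score ties count 0.5. Higher scores must indicate higher risk
#' (shorter survival); negate the score when evaluating a protective
#' quantity. Computed via `survival::concordance(..., reverse = TRUE)`.
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @param scores risk scores (higher = higher risk).
#' @return C-index in \[0, 1\].
#' @examples
#' concordanceIndex(c(1, 2, 3, 4), c(1, 1, 1, 1), c(4, 3, 2, 1)) # 1
#' @export
concordanceIndex <- function(times, events, scores) {
  stopifnot(length(times) == length(events), length(times) == length(scores))
  cc <- survival::concordance(survival::Surv(times, events) ~ scores, reverse = TRUE)
  cnt <- cc$count
  npairs <- cnt["concordant"] + cnt["discordant"] + cnt["tied.x"]
  if (npairs == 0) stop("no admissible pairs (all times censored or tied)")
  as.numeric(cc$concordance)
}

#' Two-group log-rank test
#'
#' Standard two-group log-rank chi-square with 1 degree of freedom
#' (via `survival::survdiff`).
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @param groups two-level grouping (factor/character/binary).
#' @return list with `statistic` (chi-square), `df` and `p`.
#' @export
logrankTest <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("exactly two non-empty groups are required")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(statistic = as.numeric(sd$chisq), df = 1L,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive survival times.
#' @param events 0/1 event indicators.
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `surv`; the
#'   survival curve steps down only at event times.
#' @export
kmEstimate <- function(times, events) {
  stopifnot(length(times) >= 1, length(times) == length(events))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv)
}

#' Exact 1-D two-cluster cutoff
#'
#' Exact solution of two-means clustering in one dimension: every cluster in
#' an optimal solution is an interval of the sorted values, so the optimum is
#' found by scanning all n-1 sorted split points and minimizing the
#' within-cluster sum of squares. The cutoff is the midpoint of the two
#' cluster means. Deterministic, order-invariant.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return list with `cutoff`, `labels` (factor "low"/"high" in input order),
#'   `centers` (low mean, high mean), `wcss`.
#' @examples
#' kmeans2Cutoff(c(0, 0, 0, 10, 10, 10))$cutoff # 5
#' @export
kmeans2Cutoff <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2)
  if (length(unique(values)) < 2) stop("values are constant; no 2-cluster split exists")
  n <- length(values)
  s <- sort(values)
  cs <- cumsum(s); cs2 <- cumsum(s^2)
  k <- seq_len(n - 1)                       # size of the low cluster
  # WCSS = sum(x^2) - (sum_low)^2/k - (sum_high)^2/(n-k), per split
  sumLow <- cs[k]; sumHigh <- cs[n] - sumLow
  wcss <- cs2[n] - sumLow^2 / k - sumHigh^2 / (n - k)
  # ties between equal adjacent values give identical partitions; take the
  # first minimizing split with a genuine value gap
  valid <- s[k] < s[k + 1]
  wcss[!valid] <- Inf
  best <- which.min(wcss)
  mLow <- sumLow[best] / best
  mHigh <- (cs[n] - sumLow[best]) / (n - best)
  cutoff <- (mLow + mHigh) / 2
  labels <- factor(ifelse(values > cutoff, "high", "low"), levels = c("low", "high"))
  list(cutoff = cutoff, labels = labels, centers = c(low = mLow, high = mHigh),
       wcss = wcss[best])
}

#' Stratify a cohort into low/high risk groups by one gene's expression
#'
#' Splits samples at the exact two-cluster cutoff of the supplied expression
#' values (real or predicted expression run through the identical code path),
#' then evaluates the high-vs-low group with Cox regression adjusted for age,
#' sex and stage (group hazard ratio, 95% CI, Wald p), the unadjusted
#' two-group log-rank test, and Harrell's C-index of the adjusted model's
#' linear predictor.
#'
#' @param values per-sample expression values for one gene, in the order of
#'   `clinical` rows.
#' @param clinical data.frame with columns `age`, `sex`, `stage`,
#'   `os_months`, `os_event`.
#' @param gene gene identifier for reporting.
#' @param stageEncoding `"ordinal"` (1-4, default) or `"dummy"`.
#' @return A [StratificationResult-class].
#' @export
stratifyByExpression <- function(values, clinical, gene = "gene",
                                 stageEncoding = c("ordinal", "dummy")) {
  stageEncoding <- match.arg(stageEncoding)
  stopifnot(length(values) == nrow(clinical))
  km <- kmeans2Cutoff(values)
  grp <- km$labels
  if (any(tabulate(grp, 2L) == 0L)) stop("degenerate cutoff: one group is empty")
  X <- cbind(group_high = as.numeric(grp == "high"),
             age = clinical$age, sex = as.numeric(clinical$sex))
  if (stageEncoding == "ordinal") {
    X <- cbind(X, stage = as.numeric(clinical$stage))
  } else {
    st <- factor(clinical$stage)
    X <- cbind(X, stats::model.matrix(~ st)[, -1, drop = FALSE])
  }
  fit <- fitCox(clinical$os_months, clinical$os_event, X)
  lp <- as.numeric(X %*% fit@coefficients)
  new("StratificationResult",
      gene = gene, cutoff = km$cutoff, groups = grp,
      hr = fit@hr[["group_high"]], ciLow = fit@ciLow[["group_high"]],
      ciHigh = fit@ciHigh[["group_high"]], p = fit@p[["group_high"]],
      logrankP = logrankTest(clinical$os_months, clinical$os_event, grp)$p,
      cIndex = concordanceIndex(clinical$os_months, clinical$os_event, lp),
      fit = fit)
}
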