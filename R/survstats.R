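#' @include AllClasses.R AllGenerics.R
NULL

#' Mann-Whitney rank test
#'
#' Two-sided Mann-Whitney U comparison of two samples. U is computed from
#' rank sums with ties sharing mid-ranks; the p-value is exact (from the
#' null distribution of U) when the combined sample size is at most 12 and
#' there are no ties, and otherwise uses the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param x,y numeric samples (both nonempty).
#' @return List with \code{U} (the statistic for x vs y: number of (x, y)
#'   pairs with x > y, ties counted 1/2), \code{p} (two-sided), and
#'   \code{exact} (logical, whether the exact null distribution was used).
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mannWhitney <- function(x, y) {
    if (length(x) == 0L || length(y) == 0L)
        stop("both samples must be nonempty")
    nx <- length(x); ny <- length(y)
    r <- rank(c(x, y))
    U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    ties <- any(duplicated(c(x, y)))
    exact <- (nx + ny <= 12L) && !ties
    p <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
    list(U = U, p = p, exact = exact)
}

#' Wald statistic from a coefficient and its standard error
#'
#' @param beta coefficient estimate.
#' @param se standard error (> 0).
#' @return (beta / se)^2, referred to chi-square with 1 df.
#' @examples
#' waldStatistic(4.013, 2.195)  # 3.34 to two decimals
#' @export
waldStatistic <- function(beta, se) {
    stopifnot(all(se > 0))
    (beta / se)^2
}

#' Univariate Cox proportional-hazards regression with Wald test
#'
#' Fits the Cox partial likelihood for a single covariate (Breslow tie
#' handling by default), reporting the log-hazard coefficient B, its
#' standard error from the observed information, the Wald statistic
#' (B/SE)^2 and the two-sided p-value from chi-square(1).
#'
#' @param covariate numeric per-subject covariate.
#' @param time survival/censoring times in months (> 0).
#' @param event 1 = death observed, 0 = censored.
#' @param ties "breslow" (default) or "efron".
#' @return A [CoxFit-class].
#' @examples
#' set.seed(1)
#' x <- rnorm(40); t <- rexp(40, 0.05 * exp(0.5 * x))
#' coxUnivariate(x, t, rep(1, 40))
#' @export
coxUnivariate <- function(covariate, time, event,
                          ties = c("breslow", "efron")) {
    ties <- match.arg(ties)
    stopifnot(length(covariate) == length(time),
              length(time) == length(event))
    keep <- stats::complete.cases(covariate, time, event)
    if (sum(!keep) > 0)
        message("coxUnivariate: dropping ", sum(!keep),
                " subject(s) with missing covariate or survival data")
    covariate <- covariate[keep]; time <- time[keep]; event <- event[keep]
    if (any(time <= 0)) stop("survival times must be positive")
    if (sum(event) < 2L)
        stop("need at least 2 observed events")
    if (stats::sd(covariate) == 0)
        stop("non-identifiable: covariate is constant")
    diverged <- FALSE
    fit <- withCallingHandlers(
        survival::coxph(survival::Surv(time, event) ~ covariate,
                        ties = ties),
        warning = function(w) {
            if (grepl("converged before|infinite|out of iterations",
                      conditionMessage(w)))
                diverged <<- TRUE
            invokeRestart("muffleWarning")
        })
    beta <- unname(stats::coef(fit)[1])
    se <- sqrt(unname(fit$var[1, 1]))
    if (diverged || !is.finite(beta) || !is.finite(se) || abs(beta) > 50 * se)
        stop("divergence error: monotone partial likelihood, no finite ",
             "maximum (|beta| escaping); covariate separates the risk sets")
    wald <- waldStatistic(beta, se)
    new("CoxFit", beta = beta, se = se, wald = wald,
        p = stats::pchisq(wald, df = 1, lower.tail = FALSE),
        n = length(time), nEvents = as.integer(sum(event)))
}

#' Dichotomize survival at the cohort median time
#'
#' Labels a subject 1 when its survival time is greater than or equal to
#' the cohort median time (mid-point of the central order statistics for
#' even n), 0 otherwise. This is the outcome used for ROC evaluation of a
#' feature as a predictor of longer-than-median overall survival. Note the
#' labelling uses observed times only; censoring is ignored here (a
#' documented reconstruction choice, see the methods vignette).
#'
#' @param time per-subject survival times (>= 2 subjects).
#' @return Integer 0/1 labels.
#' @examples
#' dichotomizeSurvival(c(1, 2, 3, 4))  # 0 0 1 1
#' @export
dichotomizeSurvival <- function(time) {
    if (length(time) < 2L) stop("need at least 2 subjects")
    as.integer(time >= stats::median(time))
}

#' ROC analysis of a feature against a binary outcome
#'
#' Rank-based AUC (ties counted 1/2), oriented so the reported AUC is at
#' least 0.5; the direction slot records whether large or small feature
#' values predict the positive class. The operating threshold maximizes
#' Youden's J = sensitivity + specificity - 1 over the observed feature
#' values (ties resolved toward the lower threshold). The 95\% CI uses the
#' Hanley-McNeil variance and the p-value tests AUC = 0.5 via the
#' equivalent Mann-Whitney comparison of feature values between classes.
#'
#' @param feature numeric per-subject feature values.
#' @param outcome 0/1 labels; both classes must be present.
#' @return An [ROCResult-class].
#' @examples
#' rocAnalysis(c(1, 2, 0, 1), c(1, 1, 0, 0))  # rawAuc = 0.875
#' @export
rocAnalysis <- function(feature, outcome) {
    stopifnot(length(feature) == length(outcome))
    keep <- stats::complete.cases(feature, outcome)
    if (sum(!keep) > 0)
        message("rocAnalysis: dropping ", sum(!keep),
                " subject(s) with missing values")
    feature <- feature[keep]; outcome <- as.integer(outcome[keep])
    if (!all(outcome %in% c(0L, 1L))) stop("outcome must be 0/1")
    n1 <- sum(outcome == 1L); n0 <- sum(outcome == 0L)
    if (n1 == 0L || n0 == 0L)
        stop("single-class outcome: both classes must be present")
    mw <- mannWhitney(feature[outcome == 1L], feature[outcome == 0L])
    rawAuc <- mw$U / (n1 * n0)
    direction <- if (rawAuc >= 0.5) ">=" else "<="
    A <- if (rawAuc >= 0.5) rawAuc else 1 - rawAuc
    # Youden scan over observed values as candidate thresholds
    cand <- sort(unique(feature))
    best <- c(J = -Inf, thr = NA, sens = NA, spec = NA)
    for (t in cand) {
        pred <- if (direction == ">=") feature >= t else feature <= t
        sens <- sum(pred & outcome == 1L) / n1
        spec <- sum(!pred & outcome == 0L) / n0
        J <- sens + spec - 1
        if (J > best["J"] + 1e-12) # strict: ties keep the lower threshold
            best <- c(J = J, thr = t, sens = sens, spec = spec)
    }
    # Hanley-McNeil variance of the AUC estimate
    Q1 <- A / (2 - A)
    Q2 <- 2 * A^2 / (1 + A)
    seA <- sqrt((A * (1 - A) + (n1 - 1) * (Q1 - A^2) +
                 (n0 - 1) * (Q2 - A^2)) / (n1 * n0))
    new("ROCResult", auc = A, rawAuc = rawAuc,
        threshold = unname(best["thr"]),
        sensitivity = unname(best["sens"]), specificity = unname(best["spec"]),
        ciLower = max(0, A - 1.96 * seA), ciUpper = min(1, A + 1.96 * seA),
        p = mw$p, direction = direction)
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function. Subjects censored at an
#' event time are counted at risk at that time (the standard convention).
#' S(0) = 1 is implicit; the returned table starts at the first observed
#' time.
#'
#' @param time survival/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame with columns time, n_risk, n_event, n_censor, surv.
#' @examples
#' kmCurve(c(1, 2, 3), c(1, 0, 1))  # S(1) = 2/3, S(3) = 0
#' @export
kmCurve <- function(time, event) {
    stopifnot(length(time) >= 1L, length(time) == length(event))
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               n_censor = fit$n.censor, surv = fit$surv)
}

#' Median-split Kaplan-Meier comparison with log-rank test
#'
#' Splits the cohort at the median of a feature (group "high": feature >=
#' median; group "low": feature < median), estimates a Kaplan-Meier curve
#' per group and compares them with the log-rank chi-square(1) test.
#'
#' @param feature per-subject feature values.
#' @param time,event survival records.
#' @return List with \code{curves} (named list of two [kmCurve()] tables),
#'   \code{group} (factor "low"/"high" per subject), \code{chisq},
#'   \code{p} and \code{median} (the split point).
#' @export
medianSplitKM <- function(feature, time, event) {
    stopifnot(length(feature) == length(time),
              length(time) == length(event))
    keep <- stats::complete.cases(feature, time, event)
    feature <- feature[keep]; time <- time[keep]; event <- event[keep]
    med <- stats::median(feature)
    grp <- factor(ifelse(feature >= med, "high", "low"),
                  levels = c("low", "high"))
    if (nlevels(droplevels(grp)) < 2L)
        stop("degenerate split: all feature values on one side of the median")
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    chisq <- unname(sd$chisq)
    list(curves = list(low = kmCurve(time[grp == "low"], event[grp == "low"]),
                       high = kmCurve(time[grp == "high"], event[grp == "high"])),
         group = grp, chisq = chisq,
         p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
         median = med)
}
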