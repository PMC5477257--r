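test_that("Mann-Whitney U and exact p match full-enumeration values", {
    # all C(4,2) = 6 labelings of {1,2,3,4}: U = 0 is one of two extremes
    mw <- mannWhitney(c(1, 2), c(3, 4))
    expect_equal(mw$U, 0)
    expect_true(mw$exact)
    expect_equal(mw$p, 2 / 6, tolerance = 1e-12)
    # identical multisets: U = n^2/2, p ~ 1
    mw2 <- mannWhitney(c(3, 1, 2), c(1, 2, 3))
    expect_equal(mw2$U, 9 / 2)
    expect_gt(mw2$p, 0.99)
    expect_error(mannWhitney(numeric(0), 1), "nonempty")
})

test_that("Mann-Whitney p is symmetric in its arguments and tracks a
           permutation oracle at n = 15/15", {
    set.seed(91)
    for (rep in 1:3) {
        x <- rnorm(15); y <- rnorm(15, 0.4)
        expect_equal(mannWhitney(x, y)$p, mannWhitney(y, x)$p,
                     tolerance = 1e-12)
        pPerm <- permMWp(x, y, B = 20000L)
        expect_lt(abs(mannWhitney(x, y)$p - pPerm), 0.02)
    }
})

test_that("Wald statistic reproduces (B/SE)^2 and the CoxFit invariant
           holds by construction", {
    expect_equal(round(waldStatistic(4.013, 2.195), 2), 3.34)
    set.seed(101)
    x <- rnorm(60)
    fit <- coxUnivariate(x, rexp(60, exp(0.4 * x) / 25), rbinom(60, 1, 0.8))
    expect_equal(waldStat(fit), (coef(fit) / seCoef(fit))^2)
    expect_equal(pValue(fit),
                 pchisq(waldStat(fit), 1, lower.tail = FALSE))
})

test_that("Cox beta matches 1-D maximization of an explicitly coded Breslow
           partial likelihood on toy data", {
    toys <- list(
        list(x = c(0.1, -0.5, 1.2, 0.7, -1.0, 0.3),
             time = c(3, 5, 7, 2, 9, 4), event = c(1, 1, 0, 1, 1, 1)),
        list(x = c(2, 1, 0, -1, -2, 0.5),
             time = c(1, 2, 2, 4, 8, 6), event = c(1, 1, 1, 0, 1, 1)))
    for (toy in toys) {
        fit <- coxUnivariate(toy$x, toy$time, toy$event)
        opt <- optimize(function(b) breslowLogLik(b, toy$x, toy$time,
                                                  toy$event),
                        interval = c(-10, 10), maximum = TRUE,
                        tol = 1e-9)
        expect_equal(coef(fit), opt$maximum, tolerance = 1e-4)
    }
})

test_that("Cox estimation is equivariant under covariate negation and
           rejects pathological inputs", {
    set.seed(111)
    x <- rnorm(50); t <- rexp(50, exp(0.5 * x) / 20); e <- rep(1, 50)
    f1 <- coxUnivariate(x, t, e); f2 <- coxUnivariate(-x, t, e)
    expect_equal(coef(f1), -coef(f2), tolerance = 1e-10)
    expect_equal(seCoef(f1), seCoef(f2), tolerance = 1e-10)
    expect_error(coxUnivariate(rep(1, 10), rexp(10, 1), rep(1, 10)),
                 "constant")
    expect_error(coxUnivariate(rnorm(10), rexp(10, 1), rep(0, 10)),
                 "2 observed events")
    # perfectly separating covariate: monotone likelihood
    expect_error(
        coxUnivariate(1:12, sort(rexp(12, 1), decreasing = TRUE),
                      rep(1, 12)),
        "divergence|monotone")
})

test_that("median-split outcome labels follow the >= rule", {
    expect_identical(dichotomizeSurvival(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L))
    expect_identical(dichotomizeSurvival(rep(7, 5)), rep(1L, 5))
    set.seed(121)
    t <- runif(30, 1, 60)
    lab <- dichotomizeSurvival(t)
    expect_identical(lab, as.integer(t >= median(t)))
    expect_gte(sum(lab), ceiling(30 / 2))
})

test_that("ROC analysis matches pairwise enumeration, attains perfect
           separation, and satisfies the U identity", {
    # positives {1,2} vs negatives {0,1}: pairs (1>0)+(1=1)/2+(2>0)+(2>1)
    r <- rocAnalysis(c(1, 2, 0, 1), c(1, 1, 0, 0))
    expect_equal(r@rawAuc, 3.5 / 4)
    rp <- rocAnalysis(c(10, 11, 1, 2), c(1, 1, 0, 0))
    expect_equal(auc(rp), 1)
    yp <- youdenPoint(rp)
    expect_equal(unname(yp["sensitivity"]), 1)
    expect_equal(unname(yp["specificity"]), 1)
    expect_error(rocAnalysis(1:4, c(1, 1, 1, 1)), "single-class")

    set.seed(131)
    for (rep in 1:50) {
        n <- sample(6:30, 1)
        f <- sample(1:6, n, replace = TRUE)  # heavy ties
        o <- rbinom(n, 1, 0.5)
        if (length(unique(o)) < 2) next
        r <- rocAnalysis(f, o)
        u <- mannWhitney(f[o == 1], f[o == 0])$U
        expect_identical(r@rawAuc, u / (sum(o == 1) * sum(o == 0)))
    }
})

test_that("AUC and its confidence interval agree with an independent ROC
           implementation", {
    skip_if_not_installed("pROC")
    set.seed(141)
    f <- rnorm(40); o <- rbinom(40, 1, 0.5)
    r <- rocAnalysis(f, o)
    ref <- pROC::roc(o, f, quiet = TRUE, direction = "auto")
    expect_equal(auc(r), as.numeric(pROC::auc(ref)), tolerance = 1e-12)
    # Hanley-McNeil interval is close to (not identical to) DeLong's
    ci <- as.numeric(pROC::ci.auc(ref, method = "delong"))
    expect_lt(abs(r@ciLower - ci[1]), 0.08)
    expect_lt(abs(r@ciUpper - ci[3]), 0.08)
})

test_that("Kaplan-Meier estimates match the hand product-limit computation", {
    km <- kmCurve(c(1, 2, 3), c(1, 0, 1))
    expect_equal(km$surv[km$time == 1], 2 / 3)
    expect_equal(km$surv[km$time == 3], 0)
    # without censoring KM is the empirical survival function
    t <- c(2, 4, 4, 7, 9)
    km2 <- kmCurve(t, rep(1, 5))
    ecdfS <- sapply(km2$time, function(u) mean(t > u))
    expect_equal(km2$surv, ecdfS)
    # all censored: S stays 1
    km3 <- kmCurve(c(1, 5, 9), c(0, 0, 0))
    expect_true(all(km3$surv == 1))
    # survival is non-increasing within [0, 1]
    expect_true(all(diff(km2$surv) <= 0))
    expect_true(all(km2$surv >= 0 & km2$surv <= 1))
})

test_that("median-split log-rank is null for identical groups and powered
           under a strong hazard ratio", {
    feat <- c(1, 1, 2, 2); tm <- c(5, 8, 5, 8); ev <- c(1, 1, 1, 1)
    ms <- medianSplitKM(feat, tm, ev)
    expect_equal(ms$chisq, 0, tolerance = 1e-12)
    expect_equal(ms$p, 1)
    expect_error(medianSplitKM(rep(3, 6), rexp(6), rep(1, 6)),
                 "degenerate split")

    set.seed(151)
    ps <- replicate(30, {
        x <- rep(c(0, 1), each = 50)
        t <- rexp(100, 0.05 * 3^x)          # hazard ratio 3
        medianSplitKM(x + rnorm(100, 0, 1e-3), t, rep(1, 100))$p
    })
    expect_lt(median(ps), 0.05)
})
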