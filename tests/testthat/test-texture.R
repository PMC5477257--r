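test_that("quantization maps the HU range onto 0..G-1 with clamped top bin", {
    cfg <- quantizationConfig(8L, lo = -10, hi = 500)
    s <- matrix(c(-10, 500, 0, 244.9), 2, 2)
    mk <- matrix(TRUE, 2, 2)
    lv <- quantizeSlice(s, mk, cfg)
    expect_identical(lv[1, 1], 0L)          # HU = lo -> level 0
    expect_identical(lv[2, 1], 7L)          # HU = hi -> level G-1
    cfg2 <- quantizationConfig(2L, lo = 0, hi = 10)
    lv2 <- quantizeSlice(matrix(c(1, 9), 1, 2), matrix(TRUE, 1, 2), cfg2)
    expect_identical(as.vector(lv2), c(0L, 1L))
    # sentinel outside the mask, empty mask and contract violations error
    mk[1, 2] <- FALSE
    expect_true(is.na(quantizeSlice(s, mk, cfg)[1, 2]))
    expect_error(quantizeSlice(s, matrix(FALSE, 2, 2), cfg), "empty-ROI")
    expect_error(quantizeSlice(matrix(600, 1, 1), matrix(TRUE, 1, 1), cfg),
                 "contract")
})

test_that("quantized level histogram matches explicit bin edges", {
    set.seed(31)
    cfg <- quantizationConfig(16L, lo = -10, hi = 500)
    s <- matrix(runif(400, -10, 500), 20, 20)
    lv <- quantizeSlice(s, matrix(TRUE, 20, 20), cfg)
    edges <- seq(-10, 500, length.out = 17)
    oracle <- table(cut(as.vector(s), edges, include.lowest = TRUE,
                        right = FALSE))
    oracle[16] <- oracle[16] + sum(s == 500)   # top edge closed
    expect_equal(as.vector(table(factor(as.vector(lv), levels = 0:15))),
                 as.vector(oracle))
})

test_that("GLCM of simple textures matches complete hand enumeration", {
    # constant 1x3 strip: only (2,2) pairs
    g <- computeGLCM(matrix(2L, 1, 3), nLevels = 3, thetas = 0)
    expect_equal(glcmMatrix(g)[3, 3], 1)
    expect_equal(sum(glcmMatrix(g)), 1)
    # 2x2 with columns 0 and 1: horizontal symmetric mass split
    g2 <- computeGLCM(matrix(c(0L, 0L, 1L, 1L), 2, 2), nLevels = 2,
                      thetas = 0)
    expect_equal(glcmMatrix(g2)[1, 2], 0.5)
    expect_equal(glcmMatrix(g2)[2, 1], 0.5)
})

test_that("masked GLCM equals the brute-force pair enumerator on random
           instances over all orientation subsets", {
    set.seed(41)
    thetaSets <- unlist(lapply(1:4, function(k)
        combn(c(0, 45, 90, 135), k, simplify = FALSE)), recursive = FALSE)
    for (rep in 1:60) {
        nr <- sample(2:8, 1); nc <- sample(2:8, 1)
        G <- sample(2:8, 1)
        lv <- matrix(sample(0:(G - 1), nr * nc, replace = TRUE), nr, nc)
        lv[matrix(runif(nr * nc) < 0.3, nr, nc)] <- NA   # masked-out pixels
        ths <- thetaSets[[sample(length(thetaSets), 1)]]
        sym <- sample(c(TRUE, FALSE), 1)
        P <- bruteGLCM(lv, G, thetas = ths, symmetric = sym)
        if (sum(P) == 0) {
            expect_error(computeGLCM(lv, nLevels = G, thetas = ths,
                                     symmetric = sym), "degenerate")
            next
        }
        g <- computeGLCM(lv, nLevels = G, thetas = ths, symmetric = sym)
        expect_identical(unname(pairCounts(g)), P)
        expect_equal(unname(glcmMatrix(g)), P / sum(P))
    }
})

test_that("degenerate GLCMs fail loudly instead of emitting NaN", {
    lv <- matrix(c(0L, NA, NA, 1L), 2, 2)   # no adjacent in-mask pair at 0deg
    expect_error(computeGLCM(lv, nLevels = 2, thetas = 0), "degenerate-GLCM")
    expect_error(computeGLCM(matrix(NA_integer_, 2, 2), nLevels = 2),
                 "degenerate")
})

test_that("feature values of degenerate and checkerboard textures match
           closed forms", {
    fc <- glcmFeatures(computeGLCM(matrix(3L, 4, 4), nLevels = 8))
    expect_equal(unname(fc[c("uniformity", "entropy", "dissimilarity",
                             "idn")]), c(1, 0, 0, 1), tolerance = 1e-15)
    expect_true(is.na(fc[["correlation"]]))

    cb <- outer(1:6, 1:6, function(r, c) as.integer((r + c) %% 2))
    f <- glcmFeatures(computeGLCM(cb, nLevels = 2, thetas = c(0, 90)))
    expect_equal(unname(f["uniformity"]), 0.5, tolerance = 1e-12)
    expect_equal(unname(f["entropy"]), log(0.5), tolerance = 1e-12)
    expect_equal(unname(f["dissimilarity"]), 1, tolerance = 1e-12)
    expect_equal(unname(f["idn"]), 0.8, tolerance = 1e-12)
    expect_equal(unname(f["correlation"]), -1, tolerance = 1e-12)
})

test_that("each statistic equals an independent double-sum oracle on random
           GLCMs", {
    set.seed(51)
    for (rep in 1:20) {
        G <- sample(2:12, 1)
        M <- matrix(rexp(G * G), G, G)
        M <- M + t(M)             # symmetric random co-occurrence mass
        M[runif(G * G) < 0.3] <- 0
        if (sum(M) == 0) next
        C <- M / sum(M)
        g <- new("GLCM", cooc = C, counts = M, delta = 1L,
                 thetas = c(0, 45, 90, 135), symmetric = FALSE)
        expect_equal(glcmFeatures(g), bruteFeatures(C), tolerance = 1e-12)
    }
})

test_that("entropy and uniformity respect their analytic bounds", {
    set.seed(61)
    for (rep in 1:25) {
        G <- sample(2:8, 1)
        lv <- matrix(sample(0:(G - 1), 49, replace = TRUE), 7, 7)
        f <- glcmFeatures(computeGLCM(lv, nLevels = G))
        nzc <- sum(glcmMatrix(computeGLCM(lv, nLevels = G)) > 0)
        expect_gte(f[["uniformity"]], 1 / nzc)
        expect_lte(f[["uniformity"]], 1)
        expect_lte(f[["entropy"]], 0)
        expect_gte(f[["entropy"]], -2 * log(G))
        expect_gte(f[["dissimilarity"]], 0)
        expect_lte(f[["dissimilarity"]], G - 1)
        expect_gte(f[["idn"]], 0)
        expect_lte(f[["idn"]], 1)
        if (!is.na(f[["correlation"]])) {
            expect_gte(f[["correlation"]], -1 - 1e-12)
            expect_lte(f[["correlation"]], 1 + 1e-12)
        }
    }
})

test_that("dissimilarity is zero iff all mass is diagonal and is transpose
           invariant for symmetric GLCMs", {
    g <- computeGLCM(matrix(rep(0:1, each = 8), 4, 4), nLevels = 2)
    f <- glcmFeatures(g)
    offDiag <- sum(glcmMatrix(g)) - sum(diag(glcmMatrix(g)))
    expect_identical(f[["dissimilarity"]] == 0, offDiag == 0)
    set.seed(71)
    lv <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
    f1 <- glcmFeatures(computeGLCM(lv, nLevels = 4))
    f2 <- glcmFeatures(computeGLCM(t(lv), nLevels = 4))
    expect_equal(f1[["dissimilarity"]], f2[["dissimilarity"]],
                 tolerance = 1e-12)
})

test_that("features ignore pixels outside the ROI anywhere in the bounding
           box (mask exclusion contract)", {
    set.seed(81)
    core <- matrix(sample(0:5, 25, replace = TRUE), 5, 5)
    g0 <- computeGLCM(core, nLevels = 6)
    # embed in a larger bounding box filled with extreme out-of-mask levels
    big <- matrix(NA_integer_, 9, 9)
    big[3:7, 3:7] <- core
    garbage <- big
    garbage[is.na(big)] <- 5L
    mk <- !is.na(big)
    g1 <- computeGLCM(garbage, mask = mk, nLevels = 6)
    expect_identical(pairCounts(g1), pairCounts(g0))
    expect_equal(glcmFeatures(g1), glcmFeatures(g0), tolerance = 1e-15)
})

test_that("end-to-end extraction: constant tumor, analytic mean, noise
           monotonicity", {
    # constant tumor HU -> degenerate texture regardless of G
    ph <- generatePhantom(smallPhantomSpec(seed = 3, tumorSD = 0))
    for (G in c(8L, 64L)) {
        fv <- extractFeatures(ph$volume, ph$tumorMask,
                              config = quantizationConfig(G),
                              id = "const") |> suppressWarnings()
        expect_equal(fv$dissimilarity, 0)
        expect_equal(fv$idn, 1)
        expect_true(is.na(fv$correlation))
        expect_equal(fv$mean_intensity, 57, tolerance = 1e-9)
    }
    # mean intensity equals the direct mean of in-mask HU on the slice
    ph2 <- generatePhantom(smallPhantomSpec(seed = 9))
    fv2 <- extractFeatures(ph2$volume, ph2$tumorMask)
    cs <- largestCrossSection(ph2$tumorMask, spacing(ph2$volume))
    direct <- mean(voxels(ph2$volume)[cs$slice, , ][
        maskArray(ph2$tumorMask)[cs$slice, , ]])
    expect_equal(fv2$mean_intensity, direct, tolerance = 1e-9)
    expect_equal(fv2$size_mm2, cs$area)

    # more noise -> strictly greater dissimilarity, seed by seed
    wins <- 0L
    for (s in 1:20) {
        phLo <- generatePhantom(smallPhantomSpec(seed = s, tumorSD = 5))
        phHi <- generatePhantom(smallPhantomSpec(seed = s, tumorSD = 20))
        lo <- extractFeatures(phLo$volume, phLo$tumorMask)
        hi <- extractFeatures(phHi$volume, phHi$tumorMask)
        if (hi$dissimilarity > lo$dissimilarity) wins <- wins + 1L
    }
    expect_identical(wins, 20L)
})

test_that("extraction errors carry the subject and ROI identity", {
    vox <- array(-500, dim = c(1, 3, 3))   # everything below the HU window
    vol <- CTVolume(vox)
    m <- ROIMask(array(TRUE, dim = dim(vox)), "tumor")
    expect_error(extractFeatures(vol, m, id = "sub-007"),
                 "sub-007/tumor")
})
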