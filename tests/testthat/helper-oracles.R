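# Independent oracles used across the suite. These re-derive expected
# values by brute force / direct enumeration and must stay independent of
# the package's implementation paths.

# Naive GLCM by explicit pair enumeration: for every pixel and every
# orientation, walk to the displaced pixel and count the (level, level)
# pair if both ends are in-mask.
bruteGLCM <- function(levels, G, delta = 1L, thetas = c(0, 45, 90, 135),
                      symmetric = TRUE) {
    offs <- list("0" = c(0, delta), "45" = c(-delta, delta),
                 "90" = c(-delta, 0), "135" = c(-delta, -delta))
    P <- matrix(0, G, G)
    nr <- nrow(levels); nc <- ncol(levels)
    for (th in thetas) {
        o <- offs[[as.character(th)]]
        for (r in seq_len(nr)) for (cc in seq_len(nc)) {
            r2 <- r + o[1]; c2 <- cc + o[2]
            if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
            a <- levels[r, cc]; b <- levels[r2, c2]
            if (is.na(a) || is.na(b)) next
            P[a + 1, b + 1] <- P[a + 1, b + 1] + 1
        }
    }
    if (symmetric) P <- P + t(P)
    P
}

# Texture statistics by direct double summation over all (i, j) cells.
bruteFeatures <- function(C) {
    G <- nrow(C)
    uni <- 0; ent <- 0; dis <- 0; idn <- 0
    for (i in 1:G) for (j in 1:G) {
        c_ <- C[i, j]
        uni <- uni + c_^2
        if (c_ > 0) ent <- ent + c_ * log(c_)
        dis <- dis + c_ * abs(i - j)
        idn <- idn + c_ / (1 + abs(i - j)^2 / G^2)
    }
    px <- rowSums(C); py <- colSums(C)
    lev <- 0:(G - 1)
    mux <- sum(lev * px); muy <- sum(lev * py)
    sx <- sqrt(sum((lev - mux)^2 * px)); sy <- sqrt(sum((lev - muy)^2 * py))
    cor_ <- if (sx * sy == 0) NA_real_ else {
        s <- 0
        for (i in 1:G) for (j in 1:G)
            s <- s + (i - 1 - mux) * (j - 1 - muy) * C[i, j]
        s / (sx * sy)
    }
    c(uniformity = uni, entropy = ent, dissimilarity = dis,
      correlation = cor_, idn = idn)
}

# Breslow partial log-likelihood for a single covariate, coded directly
# from its definition (sum over distinct death times).
breslowLogLik <- function(beta, x, time, event) {
    dt <- sort(unique(time[event == 1]))
    ll <- 0
    for (t in dt) {
        dead <- which(time == t & event == 1)
        risk <- which(time >= t)
        ll <- ll + beta * sum(x[dead]) -
            length(dead) * log(sum(exp(beta * x[risk])))
    }
    ll
}

# Two-sided Mann-Whitney p by label permutation (resampling).
permMWp <- function(x, y, B = 20000L) {
    nx <- length(x); n <- nx + length(y)
    pool <- c(x, y)
    obs <- sum(rank(pool)[seq_len(nx)]) - nx * (nx + 1) / 2
    mid <- nx * (n - nx) / 2
    dev <- abs(obs - mid)
    hits <- 0L
    for (b in seq_len(B)) {
        idx <- sample.int(n, nx)
        u <- sum(rank(pool)[idx]) - nx * (nx + 1) / 2
        if (abs(u - mid) >= dev - 1e-9) hits <- hits + 1L
    }
    hits / B
}

# Small, fast phantom/cohort specs used wherever many replicates are run.
smallPhantomSpec <- function(seed = 1L, ...) {
    phantomSpec(dim = c(3L, 24L, 24L), tumorRadii = c(6, 8),
                normalRadii = c(5, 6), seed = seed, ...)
}
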