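#' @include AllClasses.R AllGenerics.R
NULL

.FEATURE_NAMES <- c("uniformity", "entropy", "dissimilarity", "correlation",
                    "idn")

#' Quantize a 2D HU slice to grey levels
#'
#' Equal-width quantization: level = floor(G * (HU - lo) / (hi - lo)),
#' clamped to G-1 at HU = hi. Out-of-mask pixels carry the sentinel
#' \code{NA}. In-mask HU values must already lie inside [lo, hi]
#' (guaranteed when the slice went through [applyHUFilter()] with the same
#' bounds).
#'
#' @param slice 2D numeric matrix of HU values.
#' @param mask 2D logical matrix, same shape.
#' @param config a [QuantizationConfig-class].
#' @return Integer matrix of levels in 0..G-1, NA outside the mask.
#' @examples
#' s <- matrix(c(1, 9), 1, 2)
#' quantizeSlice(s, matrix(TRUE, 1, 2), quantizationConfig(2, lo = 0, hi = 10))
#' @export
quantizeSlice <- function(slice, mask, config = quantizationConfig()) {
    stopifnot(is.matrix(slice), is.matrix(mask),
              identical(dim(slice), dim(mask)), is(config, "QuantizationConfig"))
    if (!any(mask))
        stop("empty-ROI error: no in-mask pixels to quantize")
    hu <- slice[mask]
    if (any(hu < config@lo | hu > config@hi))
        stop("quantization contract violated: in-mask HU outside [",
             config@lo, ", ", config@hi, "]; apply the HU filter first")
    G <- config@nLevels
    lev <- floor(G * (slice - config@lo) / (config@hi - config@lo))
    lev[lev >= G] <- G - 1L   # HU exactly at hi maps into the top bin
    out <- matrix(NA_integer_, nrow(slice), ncol(slice))
    out[mask] <- as.integer(lev[mask])
    out
}

# Row/column displacement for one orientation (degrees) at distance delta.
# Row index grows downward, so 45 degrees pairs a pixel with its upper-right
# neighbour; for symmetric GLCMs the choice of direction along each
# orientation is immaterial.
.offsetFor <- function(theta, delta) {
    switch(as.character(theta),
           "0"   = c(0L, delta),
           "45"  = c(-delta, delta),
           "90"  = c(-delta, 0L),
           "135" = c(-delta, -delta),
           stop("unsupported orientation: ", theta,
                " (must be one of 0, 45, 90, 135)"))
}

#' Compute a masked grey-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized grey levels between pixel pairs at
#' interpixel distance \code{delta} along each requested orientation. A pair
#' is counted only if both pixels are in-mask (non-sentinel): pixels of the
#' ROI bounding box that fall outside the ROI never contribute. Counts are
#' pooled over orientations into one matrix; with \code{symmetric = TRUE}
#' each pair is recorded in both (i, j) and (j, i). C is the count matrix
#' normalized to sum 1.
#'
#' @param levels integer matrix of levels 0..G-1 with NA outside the mask,
#'   as produced by [quantizeSlice()].
#' @param mask optional 2D logical matrix; defaults to \code{!is.na(levels)}.
#' @param nLevels number of grey levels G; defaults to \code{max(levels) + 1}.
#' @param delta interpixel distance in pixels (default 1: adjacent pixels).
#' @param thetas orientations in degrees, any subset of c(0, 45, 90, 135);
#'   default all four (rotation-robust pooling).
#' @param symmetric count each pair in both orders (default TRUE).
#' @return A [GLCM-class].
#' @examples
#' lv <- matrix(c(0L, 0L, 1L, 1L), 2, 2)  # columns of constant level
#' g <- computeGLCM(lv, nLevels = 2, thetas = 0)
#' glcmMatrix(g)   # C[1,2] = C[2,1] = 0.5
#' @export
computeGLCM <- function(levels, mask = NULL, nLevels = NULL, delta = 1L,
                        thetas = c(0, 45, 90, 135), symmetric = TRUE) {
    stopifnot(is.matrix(levels))
    if (!is.null(mask)) {
        stopifnot(identical(dim(mask), dim(levels)))
        levels[!mask] <- NA_integer_
    }
    if (is.null(nLevels)) {
        if (all(is.na(levels)))
            stop("degenerate-GLCM error: no in-mask pixels")
        nLevels <- max(levels, na.rm = TRUE) + 1L
    }
    G <- as.integer(nLevels)
    delta <- as.integer(delta)
    stopifnot(G >= 1L, delta >= 1L, length(thetas) >= 1L)
    if (any(!is.na(levels) & (levels < 0L | levels >= G)))
        stop("levels must lie in 0..G-1")
    nr <- nrow(levels); nc <- ncol(levels)
    counts <- numeric(G * G)
    for (th in thetas) {
        off <- .offsetFor(th, delta)
        dr <- off[1]; dc <- off[2]
        r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
        c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
        if (r1 > r2 || c1 > c2) next
        a <- levels[r1:r2, c1:c2, drop = FALSE]
        b <- levels[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
        ok <- !is.na(a) & !is.na(b)
        if (!any(ok)) next
        idx <- a[ok] * G + b[ok] + 1L
        counts <- counts + tabulate(idx, nbins = G * G)
    }
    P <- matrix(counts, G, G, byrow = TRUE)  # row = level i, col = level j
    if (symmetric) P <- P + t(P)
    tot <- sum(P)
    if (tot == 0)
        stop("degenerate-GLCM error: no admissible in-mask pixel pairs at ",
             "delta = ", delta)
    dimnames(P) <- list(0:(G - 1L), 0:(G - 1L))
    new("GLCM", cooc = P / tot, counts = P, delta = delta,
        thetas = as.numeric(thetas), symmetric = isTRUE(symmetric))
}

#' Texture statistics of a GLCM
#'
#' Computes the five co-occurrence statistics from the normalized matrix C
#' with levels indexed i, j (all sums over all (i, j) pairs):
#' \describe{
#'   \item{uniformity}{sum C_ij^2 (energy); 1 iff a single nonzero cell.}
#'   \item{entropy}{sum C_ij log C_ij, natural log, 0 log 0 = 0. Note the
#'     sign: as defined here entropy is non-positive (many texture texts
#'     negate it; this package does not).}
#'   \item{dissimilarity}{sum C_ij |i - j|.}
#'   \item{correlation}{sum (i - mu_x)(j - mu_y) C_ij / (sigma_x sigma_y),
#'     with marginal means/SDs of the level index; \code{NA} (undefined)
#'     when sigma_x * sigma_y = 0, e.g. for a constant image.}
#'   \item{idn}{inverse difference normalized,
#'     sum C_ij / (1 + |i - j|^2 / G^2). (This denominator is the one
#'     usually called inverse difference *moment* normalized; the package
#'     keeps the short name "idn" for the statistic as defined here.)}
#' }
#'
#' @param glcm a [GLCM-class].
#' @return Named numeric vector with elements uniformity, entropy,
#'   dissimilarity, correlation, idn. correlation is NA when undefined.
#' @examples
#' lv <- matrix(0L, 3, 3)
#' f <- glcmFeatures(computeGLCM(lv, nLevels = 4))
#' f[["uniformity"]]  # 1: constant image
#' @export
glcmFeatures <- function(glcm) {
    stopifnot(is(glcm, "GLCM"))
    C <- glcmMatrix(glcm)
    G <- nrow(C)
    lev <- 0:(G - 1L)
    I <- matrix(lev, G, G)        # row index level
    J <- t(I)                     # column index level
    absD <- abs(I - J)
    uniformity <- sum(C^2)
    nz <- C > 0
    entropy <- sum(C[nz] * log(C[nz]))
    dissimilarity <- sum(C * absD)
    idn <- sum(C / (1 + absD^2 / G^2))
    px <- rowSums(C); py <- colSums(C)
    mux <- sum(lev * px); muy <- sum(lev * py)
    sx <- sqrt(sum((lev - mux)^2 * px))
    sy <- sqrt(sum((lev - muy)^2 * py))
    correlation <- if (sx * sy == 0) NA_real_ else
        sum((I - mux) * (J - muy) * C) / (sx * sy)
    c(uniformity = uniformity, entropy = entropy,
      dissimilarity = dissimilarity, correlation = correlation, idn = idn)
}

#' Extract the texture feature vector of one ROI
#'
#' Runs the full per-ROI measurement: HU-filter the mask, locate the
#' largest cross-section, quantize that slice, build the masked symmetric
#' GLCM at the given offset, and compute the five texture statistics plus
#' the mean HU of the filtered in-mask pixels on that slice and the
#' cross-sectional area in mm^2.
#'
#' @param volume a [CTVolume-class].
#' @param mask an [ROIMask-class] congruent with \code{volume}.
#' @param filter an [HUFilter-class] (default [-10, 500] HU).
#' @param config a [QuantizationConfig-class] (default G = 64 over the
#'   filter range).
#' @param delta,thetas,symmetric GLCM parameters, see [computeGLCM()].
#' @param id optional subject identifier carried into error messages.
#' @return One-row data.frame with columns slice_index, n_pixels, size_mm2,
#'   mean_intensity, uniformity, entropy, dissimilarity, correlation, idn.
#' @seealso [computeGLCM()], [glcmFeatures()], [largestCrossSection()]
#' @export
extractFeatures <- function(volume, mask, filter = huFilter(),
                            config = quantizationConfig(lo = filter@lo,
                                                        hi = filter@hi),
                            delta = 1L, thetas = c(0, 45, 90, 135),
                            symmetric = TRUE, id = NULL) {
    who <- paste0(if (!is.null(id)) paste0(id, "/"), roiRole(mask))
    fmask <- applyHUFilter(volume, mask, filter)
    if (!any(maskArray(fmask)))
        stop("extraction error [", who,
             "]: mask empty after HU filtering")
    cs <- largestCrossSection(fmask, spacing(volume))
    sl <- voxels(volume)[cs$slice, , , drop = TRUE]
    mk <- maskArray(fmask)[cs$slice, , , drop = TRUE]
    lv <- quantizeSlice(sl, mk, config)
    g <- tryCatch(
        computeGLCM(lv, nLevels = config@nLevels, delta = delta,
                    thetas = thetas, symmetric = symmetric),
        error = function(e) stop("extraction error [", who, "]: ",
                                 conditionMessage(e), call. = FALSE))
    f <- glcmFeatures(g)
    if (is.na(f[["correlation"]]))
        warning("correlation undefined (zero marginal variance) for ", who,
                "; recorded as NA", call. = FALSE)
    data.frame(slice_index = cs$slice, n_pixels = cs$nPixels,
               size_mm2 = cs$area, mean_intensity = mean(sl[mk]),
               uniformity = f[["uniformity"]], entropy = f[["entropy"]],
               dissimilarity = f[["dissimilarity"]],
               correlation = f[["correlation"]], idn = f[["idn"]])
}
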