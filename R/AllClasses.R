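#' @import methods
NULL

#' CTVolume: a 3D CT image grid in Hounsfield units
#'
#' Container for a 3D scalar grid of CT numbers (HU) with physical voxel
#' spacing. The first array index is always the slice (z) axis; rows and
#' columns of each slice are the y and x axes. \code{\link{readVolume}}
#' normalizes NIfTI input to this convention.
#'
#' @slot voxels 3D numeric array of HU values, indexed [slice, y, x].
#' @slot spacing numeric length-3 vector (dz, dy, dx) in millimetres.
#' @seealso [CTVolume()], [readVolume()], [ROIMask-class]
#' @export
setClass("CTVolume", representation(voxels = "array", spacing = "numeric"))

setValidity("CTVolume", function(object) {
    d <- dim(object@voxels)
    if (length(d) != 3L)
        return("voxels must be a 3D array [slice, y, x]")
    if (any(d < 1L))
        return("voxel grid must be non-empty")
    if (!all(is.finite(object@voxels)))
        return("HU values must all be finite")
    if (length(object@spacing) != 3L || !all(is.finite(object@spacing)) ||
        any(object@spacing <= 0))
        return("spacing must be three positive finite values (dz, dy, dx) in mm")
    TRUE
})

#' Construct a CTVolume
#'
#' @param voxels 3D numeric array of HU values, indexed [slice, y, x].
#' @param spacing numeric (dz, dy, dx) voxel spacing in mm.
#' @return A [CTVolume-class] object.
#' @examples
#' vol <- CTVolume(array(0, dim = c(2, 4, 4)), spacing = c(5, 0.625, 0.625))
#' spacing(vol)
#' @export
CTVolume <- function(voxels, spacing = c(1, 1, 1)) {
    storage.mode(voxels) <- "double"
    new("CTVolume", voxels = voxels, spacing = as.numeric(spacing))
}

#' ROIMask: a binary region-of-interest mask
#'
#' A logical 3D grid congruent with a companion \linkS4class{CTVolume},
#' labelled by the tissue role it delineates (tumor or normal pancreas).
#' Congruence with a specific volume is checked by the operations that pair
#' the two (e.g. \code{\link{applyHUFilter}}).
#'
#' @slot mask logical 3D array, TRUE inside the region of interest.
#' @slot role character, "tumor" or "normal".
#' @seealso [ROIMask()], [applyHUFilter()], [largestCrossSection()]
#' @export
setClass("ROIMask", representation(mask = "array", role = "character"))

setValidity("ROIMask", function(object) {
    if (length(dim(object@mask)) != 3L)
        return("mask must be a 3D array")
    if (!is.logical(object@mask))
        return("mask must be logical")
    if (any(is.na(object@mask)))
        return("mask must not contain NA")
    if (length(object@role) != 1L || !object@role %in% c("tumor", "normal"))
        return("role must be 'tumor' or 'normal'")
    TRUE
})

#' Construct an ROIMask
#'
#' Any nonzero / TRUE entry is treated as in-mask (tolerant ingestion of
#' 0/1-coded masks).
#'
#' @param mask 3D array (logical or numeric 0/1-coded), indexed [slice, y, x].
#' @param role tissue role of the region, "tumor" or "normal".
#' @return An [ROIMask-class] object.
#' @examples
#' m <- array(0, dim = c(1, 3, 3)); m[1, 2, 2] <- 1
#' ROIMask(m, "tumor")
#' @export
ROIMask <- function(mask, role = c("tumor", "normal")) {
    role <- match.arg(role)
    if (!is.logical(mask)) {
        d <- dim(mask)
        mask <- array(as.logical(mask != 0), dim = d)
    }
    new("ROIMask", mask = mask, role = role)
}

#' HUFilter: Hounsfield-unit admissibility window
#'
#' Voxels with HU strictly below \code{lo} or strictly above \code{hi} are
#' removed from analysis; the bounds themselves survive. The defaults
#' (-10, 500) exclude fat (HU < -10) and metal/stent artefacts (HU > 500),
#' both of which otherwise contaminate pancreatic texture measurements.
#'
#' @slot lo numeric lower HU bound (inclusive), default -10.
#' @slot hi numeric upper HU bound (inclusive), default 500.
#' @seealso [huFilter()], [applyHUFilter()]
#' @export
setClass("HUFilter", representation(lo = "numeric", hi = "numeric"))

setValidity("HUFilter", function(object) {
    if (length(object@lo) != 1L || length(object@hi) != 1L ||
        !is.finite(object@lo) || !is.finite(object@hi))
        return("lo and hi must be single finite values")
    if (object@lo >= object@hi)
        return("lo must be < hi")
    TRUE
})

#' Construct an HUFilter
#' @param lo inclusive lower HU bound.
#' @param hi inclusive upper HU bound.
#' @return An [HUFilter-class] object.
#' @export
huFilter <- function(lo = -10, hi = 500) new("HUFilter", lo = lo, hi = hi)

#' QuantizationConfig: grey-level quantization of HU values
#'
#' Equal-width binning of the HU range [lo, hi] into G grey levels
#' 0..G-1. By default the range is tied to the HU admissibility window
#' so every admissible voxel maps to a level.
#'
#' @slot nLevels integer G, number of grey levels (>= 2), default 64.
#' @slot lo numeric lower HU bound mapped to level 0.
#' @slot hi numeric upper HU bound mapped to level G-1.
#' @seealso [quantizationConfig()], [quantizeSlice()]
#' @export
setClass("QuantizationConfig",
         representation(nLevels = "integer", lo = "numeric", hi = "numeric"))

setValidity("QuantizationConfig", function(object) {
    if (length(object@nLevels) != 1L || is.na(object@nLevels) ||
        object@nLevels < 2L)
        return("nLevels (G) must be a single integer >= 2")
    if (length(object@lo) != 1L || length(object@hi) != 1L ||
        !is.finite(object@lo) || !is.finite(object@hi) ||
        object@lo >= object@hi)
        return("lo must be < hi and both finite")
    TRUE
})

#' Construct a QuantizationConfig
#' @param nLevels number of grey levels G (>= 2).
#' @param lo HU mapped to level 0.
#' @param hi HU mapped to level G-1.
#' @return A [QuantizationConfig-class] object.
#' @export
quantizationConfig <- function(nLevels = 64L, lo = -10, hi = 500)
    new("QuantizationConfig", nLevels = as.integer(nLevels), lo = lo, hi = hi)

#' GLCM: grey-level co-occurrence matrix
#'
#' A G x G matrix whose (i, j) entry is the probability that a pixel of
#' quantized level i-1 has a neighbour of level j-1 at interpixel distance
#' delta along one of the requested orientations, restricted to pixel pairs
#' that both lie inside the region of interest. C = P / sum(P) where P holds
#' the raw pair counts; when symmetric each ordered pair contributes to both
#' (i, j) and (j, i).
#'
#' @slot cooc G x G numeric matrix C of co-occurrence probabilities (sums
#'   to 1); retrieve with [glcmMatrix()].
#' @slot counts G x G numeric matrix P of raw pair counts; retrieve with
#'   [pairCounts()].
#' @slot delta integer interpixel distance in pixels.
#' @slot thetas numeric orientations in degrees (subset of 0, 45, 90, 135).
#' @slot symmetric logical, whether pairs were counted in both directions.
#' @seealso [computeGLCM()], [glcmFeatures()]
#' @export
setClass("GLCM",
         representation(cooc = "matrix", counts = "matrix",
                        delta = "integer", thetas = "numeric",
                        symmetric = "logical"))

setValidity("GLCM", function(object) {
    if (nrow(object@cooc) != ncol(object@cooc))
        return("C must be square")
    if (!identical(dim(object@cooc), dim(object@counts)))
        return("C and P must have identical dimensions")
    if (any(object@cooc < 0))
        return("co-occurrence probabilities must be non-negative")
    if (abs(sum(object@cooc) - 1) > 1e-8)
        return("C must be normalized to sum 1")
    if (isTRUE(object@symmetric) &&
        max(abs(object@cooc - t(object@cooc))) > 0)
        return("symmetric GLCM must satisfy C == t(C) exactly")
    if (length(object@delta) != 1L || object@delta < 1L)
        return("delta must be a positive integer")
    TRUE
})

#' CoxFit: univariate Cox proportional-hazards fit
#'
#' @slot beta numeric log-hazard coefficient per unit covariate.
#' @slot se numeric standard error from the observed information.
#' @slot wald numeric Wald statistic (beta/se)^2.
#' @slot p numeric two-sided p-value from chi-square(1).
#' @slot n integer number of subjects used.
#' @slot nEvents integer number of observed events.
#' @seealso [coxUnivariate()], [waldStatistic()]
#' @export
setClass("CoxFit",
         representation(beta = "numeric", se = "numeric", wald = "numeric",
                        p = "numeric", n = "integer", nEvents = "integer"))

setValidity("CoxFit", function(object) {
    if (object@se <= 0) return("se must be > 0")
    if (abs(object@wald - (object@beta / object@se)^2) >
        1e-8 * max(1, object@wald))
        return("wald must equal (beta/se)^2")
    if (object@p <= 0 || object@p > 1) return("p must lie in (0, 1]")
    TRUE
})

#' ROCResult: receiver-operating-characteristic analysis of one feature
#'
#' The reported AUC is oriented to be >= 0.5 (the direction slot records
#' whether larger or smaller feature values predict the positive class);
#' rawAuc is the unoriented positives-vs-negatives rank AUC, which satisfies
#' rawAuc = U / (n1 * n0) with the Mann-Whitney U of positives vs negatives.
#'
#' @slot auc numeric oriented area under the curve, in [0.5, 1].
#' @slot rawAuc numeric unoriented AUC, in [0, 1].
#' @slot threshold numeric Youden-optimal operating threshold (feature units).
#' @slot sensitivity numeric sensitivity at the threshold.
#' @slot specificity numeric specificity at the threshold.
#' @slot ciLower,ciUpper numeric Hanley-McNeil 95\% interval for the AUC.
#' @slot p numeric two-sided p for AUC != 0.5 (Mann-Whitney test).
#' @slot direction character ">=" if feature >= threshold predicts positive,
#'   "<=" otherwise.
#' @seealso [rocAnalysis()]
#' @export
setClass("ROCResult",
         representation(auc = "numeric", rawAuc = "numeric",
                        threshold = "numeric", sensitivity = "numeric",
                        specificity = "numeric", ciLower = "numeric",
                        ciUpper = "numeric", p = "numeric",
                        direction = "character"))

setValidity("ROCResult", function(object) {
    if (object@sensitivity < 0 || object@sensitivity > 1 ||
        object@specificity < 0 || object@specificity > 1)
        return("sensitivity and specificity must lie in [0, 1]")
    if (object@ciLower > object@auc + 1e-12 ||
        object@ciUpper < object@auc - 1e-12)
        return("ci95 must bracket the AUC")
    if (!object@direction %in% c(">=", "<="))
        return("direction must be '>=' or '<='")
    TRUE
})
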