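#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' \code{voxels} and \code{spacing} for \linkS4class{CTVolume},
#' \code{maskArray} and \code{roiRole} for \linkS4class{ROIMask},
#' \code{glcmMatrix}, \code{pairCounts} and \code{nLevels} for
#' \linkS4class{GLCM}, and \code{pValue} for the statistical result classes.
#'
#' @param object an object of the documented class.
#' @return The slot value (array, numeric vector, matrix or scalar).
#' @name accessors
#' @aliases voxels spacing maskArray roiRole glcmMatrix pairCounts nLevels
#'   pValue
#' @examples
#' vol <- CTVolume(array(0, dim = c(1, 2, 2)))
#' dim(voxels(vol))
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(object) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(object) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(object) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("roiRole", function(object) standardGeneric("roiRole"))

#' @rdname accessors
#' @export
setGeneric("glcmMatrix", function(object) standardGeneric("glcmMatrix"))

#' @rdname accessors
#' @export
setGeneric("pairCounts", function(object) standardGeneric("pairCounts"))

#' @rdname accessors
#' @export
setGeneric("nLevels", function(object) standardGeneric("nLevels"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname accessors
setMethod("voxels", "CTVolume", function(object) object@voxels)

#' @rdname accessors
setMethod("spacing", "CTVolume", function(object) object@spacing)

#' @rdname accessors
setMethod("maskArray", "ROIMask", function(object) object@mask)

#' @rdname accessors
setMethod("roiRole", "ROIMask", function(object) object@role)

#' @rdname accessors
setMethod("glcmMatrix", "GLCM", function(object) object@cooc)

#' @rdname accessors
setMethod("pairCounts", "GLCM", function(object) object@counts)

#' @rdname accessors
setMethod("nLevels", "GLCM", function(object) nrow(object@cooc))

#' @rdname accessors
setMethod("nLevels", "QuantizationConfig", function(object) object@nLevels)

#' @rdname accessors
setMethod("pValue", "CoxFit", function(object) object@p)

#' @rdname accessors
setMethod("pValue", "ROCResult", function(object) object@p)

#' @describeIn CoxFit-class the fitted log-hazard coefficient.
#' @param object a CoxFit.
#' @export
setMethod("coef", "CoxFit", function(object) object@beta)

#' CoxFit and ROCResult component accessors
#'
#' @param object a \linkS4class{CoxFit} or \linkS4class{ROCResult}.
#' @return A numeric scalar (or named numeric for \code{youdenPoint}).
#' @name fit-accessors
#' @aliases seCoef waldStat auc youdenPoint
NULL

#' @rdname fit-accessors
#' @export
setGeneric("seCoef", function(object) standardGeneric("seCoef"))

#' @rdname fit-accessors
#' @export
setGeneric("waldStat", function(object) standardGeneric("waldStat"))

#' @rdname fit-accessors
#' @export
setGeneric("auc", function(object) standardGeneric("auc"))

#' @rdname fit-accessors
#' @export
setGeneric("youdenPoint", function(object) standardGeneric("youdenPoint"))

#' @rdname fit-accessors
setMethod("seCoef", "CoxFit", function(object) object@se)

#' @rdname fit-accessors
setMethod("waldStat", "CoxFit", function(object) object@wald)

#' @rdname fit-accessors
setMethod("auc", "ROCResult", function(object) object@auc)

#' @rdname fit-accessors
setMethod("youdenPoint", "ROCResult", function(object)
    c(threshold = object@threshold, sensitivity = object@sensitivity,
      specificity = object@specificity))

setMethod("show", "CTVolume", function(object) {
    d <- dim(object@voxels)
    cat(sprintf("CTVolume: %d slices of %d x %d voxels\n", d[1], d[2], d[3]))
    cat(sprintf("  spacing (dz, dy, dx): %.3f x %.3f x %.3f mm\n",
                object@spacing[1], object@spacing[2], object@spacing[3]))
    cat(sprintf("  HU range: [%.1f, %.1f]\n",
                min(object@voxels), max(object@voxels)))
})

setMethod("show", "ROIMask", function(object) {
    d <- dim(object@mask)
    cat(sprintf("ROIMask (%s): %d slices of %d x %d, %d in-mask voxels\n",
                object@role, d[1], d[2], d[3], sum(object@mask)))
})

setMethod("show", "GLCM", function(object) {
    cat(sprintf(
        "GLCM: %d grey levels, delta = %d px, orientations {%s}%s\n",
        nrow(object@cooc), object@delta,
        paste(object@thetas, collapse = ", "),
        if (object@symmetric) ", symmetric" else ""))
    cat(sprintf("  %d pixel pairs, %d nonzero cells\n",
                as.integer(sum(object@counts) / (1 + object@symmetric)),
                sum(object@cooc > 0)))
})

setMethod("show", "CoxFit", function(object) {
    cat("Univariate Cox proportional-hazards fit\n")
    cat(sprintf("  B = %.4g  SE = %.4g  Wald = %.3g  p = %.4g\n",
                object@beta, object@se, object@wald, object@p))
    cat(sprintf("  %d subjects, %d events\n", object@n, object@nEvents))
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROC analysis: AUC = %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
                object@auc, object@ciLower, object@ciUpper, object@p))
    cat(sprintf(
        "  Youden threshold (feature %s %g): sensitivity %.3f, specificity %.3f\n",
        object@direction, object@threshold, object@sensitivity,
        object@specificity))
})
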