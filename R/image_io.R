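#' @include AllClasses.R AllGenerics.R
NULL

#' Read a CT volume from NIfTI
#'
#' Reads a 3D NIfTI image and normalizes it to the package convention:
#' the slice axis becomes the first array index (NIfTI stores x fastest,
#' so the on-disk (x, y, z) grid is transposed to (z, y, x)) and voxel
#' spacing is taken from the header pixdim.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return A [CTVolume-class].
#' @seealso [writeVolume()], [readMask()]
#' @export
readVolume <- function(path) {
    if (!file.exists(path))
        stop("volume file not found: ", path)
    img <- RNifti::readNifti(path)
    arr <- as.array(img)
    if (length(dim(arr)) != 3L)
        stop("format error: expected a 3D payload, got ",
             length(dim(arr)), "D in ", path)
    pd <- RNifti::pixdim(img)
    if (length(pd) < 3L || any(!is.finite(pd[1:3])) || any(pd[1:3] <= 0))
        stop("format error: non-positive voxel spacing in header of ", path)
    CTVolume(aperm(arr, c(3L, 2L, 1L)), spacing = rev(pd[1:3]))
}

#' Write a CT volume to NIfTI
#'
#' @param volume a [CTVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(volume, path) {
    stopifnot(is(volume, "CTVolume"))
    img <- RNifti::asNifti(aperm(voxels(volume), c(3L, 2L, 1L)))
    RNifti::pixdim(img) <- rev(spacing(volume))
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Read a binary ROI mask from NIfTI
#'
#' Any nonzero voxel is treated as in-mask. Axis and spacing conventions
#' match [readVolume()].
#'
#' @param path path to a .nii or .nii.gz mask file.
#' @param role tissue role, "tumor" or "normal".
#' @return An [ROIMask-class].
#' @export
readMask <- function(path, role = c("tumor", "normal")) {
    role <- match.arg(role)
    if (!file.exists(path))
        stop("mask file not found: ", path)
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) != 3L)
        stop("format error: expected a 3D mask, got ",
             length(dim(arr)), "D in ", path)
    ROIMask(aperm(arr, c(3L, 2L, 1L)), role = role)
}

#' Write a binary ROI mask to NIfTI
#'
#' @param mask an [ROIMask-class].
#' @param path output path.
#' @param spacing voxel spacing (dz, dy, dx) in mm written to the header.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path, spacing = c(1, 1, 1)) {
    stopifnot(is(mask, "ROIMask"))
    arr <- aperm(array(as.integer(maskArray(mask)), dim = dim(maskArray(mask))),
                 c(3L, 2L, 1L))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rev(spacing)
    RNifti::writeNifti(img, path)
    invisible(path)
}

#' Restrict an ROI mask to HU-admissible voxels
#'
#' Returns a new mask containing exactly the in-mask voxels whose HU value
#' lies within the admissibility window (bounds inclusive: voxels strictly
#' below \code{lo} or strictly above \code{hi} are removed). The input mask
#' is not modified. Idempotent, and the result is always a subset of the
#' input mask.
#'
#' @param volume a [CTVolume-class].
#' @param mask an [ROIMask-class] congruent with \code{volume}.
#' @param filter an [HUFilter-class]; default window is [-10, 500] HU.
#' @return An [ROIMask-class] with the same role.
#' @examples
#' vol <- CTVolume(array(c(-50, 30, 600, 0), dim = c(1, 2, 2)))
#' m <- ROIMask(array(c(TRUE, TRUE, TRUE, FALSE), dim = c(1, 2, 2)), "tumor")
#' sum(maskArray(applyHUFilter(vol, m, huFilter())))  # only HU = 30 survives
#' @export
applyHUFilter <- function(volume, mask, filter = huFilter()) {
    stopifnot(is(volume, "CTVolume"), is(mask, "ROIMask"),
              is(filter, "HUFilter"))
    if (!identical(dim(voxels(volume)), dim(maskArray(mask))))
        stop("alignment error: mask shape ",
             paste(dim(maskArray(mask)), collapse = "x"),
             " does not match volume shape ",
             paste(dim(voxels(volume)), collapse = "x"))
    v <- voxels(volume)
    keep <- maskArray(mask) & (v >= filter@lo) & (v <= filter@hi)
    new("ROIMask", mask = keep, role = roiRole(mask))
}

#' Locate the largest cross-section of a mask
#'
#' Finds the slice with the most in-mask pixels (features are measured on
#' the largest tumor cross-section). Ties are broken in favour of the
#' lowest slice index.
#'
#' @param mask an [ROIMask-class].
#' @param spacing in-plane pixel spacing: either (dy, dx) in mm, or a
#'   length-3 (dz, dy, dx) vector from which the last two are used.
#' @return A list with \code{slice} (integer index), \code{area} (mm^2) and
#'   \code{nPixels} (in-mask pixel count on that slice).
#' @examples
#' m <- array(FALSE, dim = c(3, 4, 4)); m[2, 1:2, 1:2] <- TRUE
#' largestCrossSection(ROIMask(m, "tumor"), spacing = c(0.5, 0.5))
#' @export
largestCrossSection <- function(mask, spacing = c(1, 1)) {
    stopifnot(is(mask, "ROIMask"))
    if (length(spacing) == 3L) spacing <- spacing[2:3]
    stopifnot(length(spacing) == 2L, all(spacing > 0))
    counts <- apply(maskArray(mask), 1L, sum)
    if (max(counts) == 0L)
        stop("empty-ROI error: mask '", roiRole(mask), "' has no in-mask voxels")
    idx <- which.max(counts)  # which.max returns the first maximum
    list(slice = as.integer(idx),
         area = counts[idx] * spacing[1] * spacing[2],
         nPixels = as.integer(counts[idx]))
}
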