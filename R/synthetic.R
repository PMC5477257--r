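#' @include AllClasses.R AllGenerics.R texture.R image_io.R
NULL

#' Specification of a synthetic CT phantom
#'
#' Describes one phantom volume: an elliptical "tumor" region (darker,
#' default mean 57 HU as typical of hypoenhancing pancreatic tumor on the
#' portal venous phase) and an elliptical "normal pancreas" region
#' (brighter, default mean 71 HU), both carrying spatially correlated
#' Gaussian texture on a fat-like background (-100 HU) that the HU
#' admissibility filter would exclude. In-plane ellipse semi-axes shrink
#' away from the central slice like an ellipsoid, so the largest
#' cross-section is always the central slice.
#'
#' @param dim grid size (nSlices, ny, nx).
#' @param spacing voxel spacing (dz, dy, dx) in mm; defaults mimic an
#'   abdominal CT reconstruction (5 mm slices, 0.625 mm in-plane).
#' @param tumorMean,normalMean region mean HU (defaults 57 and 71).
#' @param tumorSD,normalSD texture noise SD in HU before smoothing-induced
#'   correlation (defaults 12 and 8).
#' @param corLength texture correlation length ell in pixels (moving-average
#'   half-width; 0 = white noise). Default 1.
#' @param tumorRadii,normalRadii central-slice in-plane semi-axes (ry, rx)
#'   in pixels.
#' @param seed integer RNG seed; the phantom is deterministic given the seed.
#' @return A classed list of the above (class "PhantomSpec").
#' @seealso [generatePhantom()], [cohortSpec()]
#' @export
phantomSpec <- function(dim = c(5L, 48L, 48L),
                        spacing = c(5, 0.625, 0.625),
                        tumorMean = 57, normalMean = 71,
                        tumorSD = 12, normalSD = 8,
                        corLength = 1L,
                        tumorRadii = c(11, 14), normalRadii = c(8, 10),
                        seed = 1L) {
    stopifnot(length(dim) == 3L, all(dim >= 1L), all(spacing > 0),
              tumorSD >= 0, normalSD >= 0, corLength >= 0,
              all(tumorRadii >= 1), all(normalRadii >= 1))
    huf <- huFilter()
    if (tumorMean < huf@lo || tumorMean > huf@hi ||
        normalMean < huf@lo || normalMean > huf@hi)
        stop("region means must lie within the HU admissibility window")
    structure(list(dim = as.integer(dim), spacing = as.numeric(spacing),
                   tumorMean = tumorMean, normalMean = normalMean,
                   tumorSD = tumorSD, normalSD = normalSD,
                   corLength = as.integer(corLength),
                   tumorRadii = tumorRadii, normalRadii = normalRadii,
                   seed = as.integer(seed)),
              class = "PhantomSpec")
}

# Elliptical mask on an ny x nx grid, semi-axes (ry, rx) scaled by `scale`.
.ellipseMask <- function(ny, nx, cy, cx, ry, rx, scale = 1) {
    if (scale <= 0) return(matrix(FALSE, ny, nx))
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    ((yy - cy) / (ry * scale))^2 + ((xx - cx) / (rx * scale))^2 <= 1
}

# Spatially correlated unit-variance noise field: white noise smoothed by a
# separable moving average of half-width ell (circular edges keep the field
# stationary), rescaled by the theoretical variance reduction (2*ell+1)^2.
.correlatedNoise <- function(ny, nx, ell) {
    z <- matrix(stats::rnorm(ny * nx), ny, nx)
    if (ell == 0L) return(z)
    w <- rep(1 / (2 * ell + 1), 2 * ell + 1)
    sm <- apply(z, 2L, function(col)
        as.numeric(stats::filter(col, w, circular = TRUE)))
    sm <- t(apply(sm, 1L, function(row)
        as.numeric(stats::filter(row, w, circular = TRUE))))
    sm * (2 * ell + 1)
}

#' Generate a synthetic CT phantom with tumor and normal ROIs
#'
#' Renders the phantom described by a [phantomSpec()]: region means plus
#' spatially correlated Gaussian texture (white noise smoothed by a
#' moving average of half-width \code{corLength} and rescaled to the target
#' SD). In-region HU values are clipped into the admissibility window
#' [-10, 500] so downstream quantization always sees admissible values;
#' the number of clipped voxels is returned. Deterministic given the seed.
#'
#' @param spec a [phantomSpec()].
#' @return List with \code{volume} ([CTVolume-class]), \code{tumorMask} and
#'   \code{normalMask} ([ROIMask-class]), and \code{nClipped}.
#' @examples
#' ph <- generatePhantom(phantomSpec(seed = 7))
#' ph$volume
#' @export
generatePhantom <- function(spec) {
    stopifnot(inherits(spec, "PhantomSpec"))
    nz <- spec$dim[1]; ny <- spec$dim[2]; nx <- spec$dim[3]
    mid <- (nz + 1) / 2
    tMask <- array(FALSE, spec$dim); nMask <- array(FALSE, spec$dim)
    vol <- array(-100, spec$dim)   # fat-like background, outside HU window
    huf <- huFilter()
    set.seed(spec$seed)
    nClipped <- 0L
    for (z in seq_len(nz)) {
        # ellipsoid-like falloff of the in-plane radius away from the middle
        scale <- sqrt(pmax(0, 1 - ((z - mid) / (nz / 2 + 0.5))^2))
        tm <- .ellipseMask(ny, nx, cy = ny / 2, cx = nx * 0.3,
                           spec$tumorRadii[1], spec$tumorRadii[2], scale)
        nm <- .ellipseMask(ny, nx, cy = ny / 2, cx = nx * 0.72,
                           spec$normalRadii[1], spec$normalRadii[2], scale)
        nm <- nm & !tm   # normal tissue never overlaps the tumor
        sl <- matrix(-100, ny, nx)
        if (any(tm) || any(nm)) {
            noise <- .correlatedNoise(ny, nx, spec$corLength)
            sl[tm] <- spec$tumorMean + spec$tumorSD * noise[tm]
            sl[nm] <- spec$normalMean + spec$normalSD * noise[nm]
            inroi <- tm | nm
            lo <- sl[inroi] < huf@lo; hi <- sl[inroi] > huf@hi
            nClipped <- nClipped + sum(lo) + sum(hi)
            sl[inroi] <- pmin(pmax(sl[inroi], huf@lo), huf@hi)
        }
        vol[z, , ] <- sl
        tMask[z, , ] <- tm
        nMask[z, , ] <- nm
    }
    if (!any(tMask))
        stop("tumor region empty for the given geometry")
    list(volume = CTVolume(vol, spec$spacing),
         tumorMask = ROIMask(tMask, "tumor"),
         normalMask = ROIMask(nMask, "normal"),
         nClipped = nClipped)
}

#' Specification of a synthetic survival cohort
#'
#' Defines the statistical structure linking texture to outcome: per-subject
#' tumor texture heterogeneity (noise SD drawn uniformly from
#' \code{sdRange}) drives the chosen feature, and survival times follow a
#' proportional-hazards model whose log-hazard is linear in the
#' cohort-standardized driven feature:
#' T ~ Exponential(lambda0 * exp(beta * z)), censored administratively at a
#' Uniform(0, censorMax) time. Defaults emulate a resected-PDAC cohort:
#' n = 30, baseline hazard 1/31 per month (mean survival about 31 months)
#' and a follow-up window of 72 months.
#'
#' @param n number of subjects (>= 2), default 30.
#' @param beta log-hazard per SD of the driven feature, default 0.8.
#' @param lambda0 baseline hazard per month, default 1/31.
#' @param censorMax administrative censoring window in months (may be Inf
#'   for no censoring), default 72.
#' @param drivenFeature feature whose standardized value enters the hazard,
#'   default "dissimilarity".
#' @param sdRange range of per-subject tumor noise SD in HU, default (6, 18).
#' @param seed master seed reproducing the whole cohort.
#' @return A classed list (class "CohortSpec").
#' @seealso [generateCohort()]
#' @export
cohortSpec <- function(n = 30L, beta = 0.8, lambda0 = 1 / 31,
                       censorMax = 72, drivenFeature = "dissimilarity",
                       sdRange = c(6, 18), seed = 1L) {
    stopifnot(n >= 2L, lambda0 > 0, censorMax > 0,
              length(sdRange) == 2L, sdRange[1] <= sdRange[2],
              drivenFeature %in% c(.FEATURE_NAMES, "mean_intensity",
                                   "size_mm2"))
    structure(list(n = as.integer(n), beta = beta, lambda0 = lambda0,
                   censorMax = censorMax, drivenFeature = drivenFeature,
                   sdRange = as.numeric(sdRange), seed = as.integer(seed)),
              class = "CohortSpec")
}

#' Generate a synthetic cohort of phantoms with linked survival
#'
#' For each subject: draw a tumor texture noise SD, render a phantom
#' ([generatePhantom()]) with a subject seed derived from the master seed,
#' extract features through the texture module, then draw a survival time
#' from the proportional-hazards model of [cohortSpec()] applied to the
#' cohort-standardized driven feature. Fully deterministic given the master
#' seed. Optionally writes the volumes, masks, manifest and survival table
#' in the formats [runPipeline()] reads.
#'
#' @param pspec a [phantomSpec()] used as the template (its tumorSD and
#'   seed are overridden per subject).
#' @param cspec a [cohortSpec()].
#' @param writeDir if non-NULL, directory where NIfTI volumes/masks plus
#'   \code{manifest.csv} and \code{survival.csv} are written.
#' @param roles which ROI roles to extract features for; the pair by
#'   default, or just "tumor" for survival-only studies.
#' @return List with \code{cohort} (one row per subject: subject_id, tumor
#'   features, z_driven, time_months, event), \code{features} (long table,
#'   one row per subject x role), \code{manifest} and \code{survivalFile}
#'   (paths, NULL unless written).
#' @examples
#' cohort <- generateCohort(phantomSpec(dim = c(3L, 32L, 32L),
#'                                      tumorRadii = c(8, 10),
#'                                      normalRadii = c(6, 7)),
#'                          cohortSpec(n = 6, seed = 2))
#' cohort$cohort[, c("subject_id", "dissimilarity", "time_months", "event")]
#' @export
generateCohort <- function(pspec, cspec, writeDir = NULL,
                           roles = c("tumor", "normal")) {
    stopifnot(inherits(pspec, "PhantomSpec"), inherits(cspec, "CohortSpec"))
    roles <- match.arg(roles, several.ok = TRUE)
    if (!"tumor" %in% roles)
        stop("the tumor role is required (the driven feature is a tumor feature)")
    n <- cspec$n
    set.seed(cspec$seed)
    subSeeds <- sample.int(.Machine$integer.max - 1L, n)
    sds <- stats::runif(n, cspec$sdRange[1], cspec$sdRange[2])
    # per-subject tumor size jitter (+/- 30% on the in-plane radii) so the
    # cross-sectional size covariate varies across the cohort
    radScale <- stats::runif(n, 0.7, 1.3)
    ids <- sprintf("sub-%03d", seq_len(n))
    if (!is.null(writeDir) && !dir.exists(writeDir))
        dir.create(writeDir, recursive = TRUE)
    featRows <- vector("list", n * length(roles))
    manifest <- NULL
    k <- 0L
    for (i in seq_len(n)) {
        ps <- pspec
        ps$tumorSD <- sds[i]
        ps$tumorRadii <- pspec$tumorRadii * radScale[i]
        ps$seed <- subSeeds[i]
        ph <- generatePhantom(ps)
        masks <- list(tumor = ph$tumorMask, normal = ph$normalMask)
        for (role in roles) {
            fv <- extractFeatures(ph$volume, masks[[role]], id = ids[i])
            k <- k + 1L
            featRows[[k]] <- cbind(data.frame(subject_id = ids[i],
                                              role = role), fv)
        }
        if (!is.null(writeDir)) {
            vp <- file.path(writeDir, paste0(ids[i], "_ct.nii.gz"))
            tp <- file.path(writeDir, paste0(ids[i], "_tumor.nii.gz"))
            np <- file.path(writeDir, paste0(ids[i], "_normal.nii.gz"))
            writeVolume(ph$volume, vp)
            writeMask(ph$tumorMask, tp, spacing = pspec$spacing)
            writeMask(ph$normalMask, np, spacing = pspec$spacing)
            manifest <- rbind(manifest, data.frame(
                subject_id = ids[i], volume = vp, tumor_mask = tp,
                normal_mask = np))
        }
    }
    features <- do.call(rbind, featRows)
    tumorFeat <- features[features$role == "tumor", ]
    x <- tumorFeat[[cspec$drivenFeature]]
    if (stats::sd(x) == 0)
        stop("driven feature is constant across the cohort; widen sdRange")
    z <- as.numeric(scale(x))
    ttrue <- stats::rexp(n, rate = cspec$lambda0 * exp(cspec$beta * z))
    cens <- if (is.infinite(cspec$censorMax)) rep(Inf, n)
            else stats::runif(n, 0, cspec$censorMax)
    time <- pmin(ttrue, cens)
    event <- as.integer(ttrue <= cens)
    if (sum(event) < 2L)
        stop("fewer than 2 events generated; enlarge censorMax or n and regenerate")
    surv <- data.frame(subject_id = ids, time_months = time, event = event)
    cohort <- cbind(tumorFeat[, setdiff(names(tumorFeat), "role")],
                    z_driven = z,
                    time_months = time, event = event)
    rownames(cohort) <- NULL
    manifestFile <- survivalFile <- NULL
    if (!is.null(writeDir)) {
        manifestFile <- file.path(writeDir, "manifest.csv")
        survivalFile <- file.path(writeDir, "survival.csv")
        utils::write.csv(manifest, manifestFile, row.names = FALSE)
        utils::write.csv(surv, survivalFile, row.names = FALSE)
    }
    list(cohort = cohort, features = features, survival = surv,
         manifest = manifestFile, survivalFile = survivalFile)
}
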