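#' @include AllClasses.R AllGenerics.R texture.R survstats.R
NULL

.TABLE_FEATURES <- c("uniformity", "entropy", "dissimilarity", "correlation",
                     "idn", "size_mm2", "mean_intensity")

#' Exclude early post-operative deaths from a cohort
#'
#' Removes subjects whose death (event = 1) occurred before \code{minMonths}
#' months, because very early deaths reflect post-operative complications
#' rather than tumor biology. Subjects censored before the cut-off are
#' retained.
#'
#' @param records data.frame with columns time_months and event.
#' @param minMonths exclusion horizon in months (default 3).
#' @return The filtered data.frame; the number of removed subjects is
#'   attached as attribute \code{"nExcluded"}.
#' @examples
#' d <- data.frame(time_months = c(2, 2, 5), event = c(1, 0, 1))
#' filterCohort(d)  # the early death is dropped, the early censor kept
#' @export
filterCohort <- function(records, minMonths = 3) {
    stopifnot(is.data.frame(records),
              all(c("time_months", "event") %in% names(records)))
    drop <- records$event == 1 & records$time_months < minMonths
    out <- records[!drop, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "nExcluded") <- sum(drop)
    out
}

#' Pipeline configuration
#'
#' Bundles everything one analysis run needs: the input manifest (per
#' subject: volume path, tumor mask path, normal mask path), the survival
#' table, the HU admissibility window, the quantization and GLCM settings,
#' the ROC outcome rule and the output directory.
#'
#' @param manifest data.frame (or CSV path) with columns subject_id,
#'   volume, tumor_mask, normal_mask.
#' @param survival data.frame (or CSV path) with columns subject_id,
#'   time_months, event.
#' @param outDir output directory for reports and figures.
#' @param filter an [HUFilter-class].
#' @param quantization a [QuantizationConfig-class].
#' @param delta,thetas,symmetric GLCM settings, see [computeGLCM()].
#' @param rocRule "median" (positive class = survival >= cohort median) or
#'   "horizon" (survival >= \code{rocHorizon} months).
#' @param rocHorizon months, used when \code{rocRule = "horizon"}.
#' @param ties Cox tie handling, "breslow" or "efron".
#' @param minMonths early-death exclusion horizon ([filterCohort()]).
#' @param alpha significance level used to select features for KM figures.
#' @param makePlots write KM/histogram PNGs (default TRUE).
#' @return A classed list (class "PipelineConfig").
#' @seealso [runPipeline()], [readPipelineConfig()]
#' @export
pipelineConfig <- function(manifest, survival, outDir,
                           filter = huFilter(),
                           quantization = quantizationConfig(
                               lo = filter@lo, hi = filter@hi),
                           delta = 1L, thetas = c(0, 45, 90, 135),
                           symmetric = TRUE,
                           rocRule = c("median", "horizon"),
                           rocHorizon = 24,
                           ties = c("breslow", "efron"),
                           minMonths = 3, alpha = 0.05, makePlots = TRUE) {
    if (is.character(manifest)) manifest <- utils::read.csv(manifest)
    if (is.character(survival)) survival <- utils::read.csv(survival)
    stopifnot(is.data.frame(manifest),
              all(c("subject_id", "volume", "tumor_mask", "normal_mask")
                  %in% names(manifest)),
              is.data.frame(survival),
              all(c("subject_id", "time_months", "event")
                  %in% names(survival)))
    structure(list(manifest = manifest, survival = survival,
                   outDir = outDir, filter = filter,
                   quantization = quantization, delta = as.integer(delta),
                   thetas = thetas, symmetric = symmetric,
                   rocRule = match.arg(rocRule), rocHorizon = rocHorizon,
                   ties = match.arg(ties), minMonths = minMonths,
                   alpha = alpha, makePlots = isTRUE(makePlots)),
              class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; \code{manifest} and
#' \code{survival} are paths to CSV files, \code{hu_lo}/\code{hu_hi} set
#' the admissibility window and \code{n_levels} the grey levels.
#'
#' @param path YAML file path.
#' @return A [pipelineConfig()] object.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    filter <- huFilter(lo = y$hu_lo %||% -10, hi = y$hu_hi %||% 500)
    pipelineConfig(manifest = y$manifest, survival = y$survival,
                   outDir = y$out_dir %||% ".",
                   filter = filter,
                   quantization = quantizationConfig(
                       nLevels = y$n_levels %||% 64L,
                       lo = filter@lo, hi = filter@hi),
                   delta = y$delta %||% 1L,
                   thetas = y$thetas %||% c(0, 45, 90, 135),
                   symmetric = y$symmetric %||% TRUE,
                   rocRule = y$roc_rule %||% "median",
                   rocHorizon = y$roc_horizon %||% 24,
                   ties = y$ties %||% "breslow",
                   minMonths = y$min_months %||% 3,
                   alpha = y$alpha %||% 0.05,
                   makePlots = y$make_plots %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.logLine <- function(log, ...) c(log, paste0(...))

# median (IQR) as the reports print it
.medIqr <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Run the full texture-survival analysis
#'
#' End-to-end orchestration over a cohort: apply the early-death exclusion,
#' extract tumor and normal feature vectors per subject (per-subject
#' failures are logged and the subject dropped), then emit the three report
#' tables -- tumor-vs-normal rank-sum comparison, univariate Cox regression
#' of overall survival on each tumor feature, and ROC analysis of each
#' feature against the dichotomized outcome -- plus Kaplan-Meier and
#' histogram figures for features significantly associated with survival.
#' All CSV outputs are deterministic functions of the inputs, so a rerun
#' with the same config is byte-identical.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with elements \code{features}, \code{table3}
#'   (comparison), \code{table4} (Cox), \code{table5} (ROC), \code{log}
#'   (character vector, also written to run_log.txt) and \code{outDir}.
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    if (!dir.exists(config$outDir))
        dir.create(config$outDir, recursive = TRUE)
    log <- character()

    surv <- filterCohort(config$survival, config$minMonths)
    log <- .logLine(log, "excluded ", attr(surv, "nExcluded"),
                    " early death(s) (< ", config$minMonths, " months)")
    man <- config$manifest[config$manifest$subject_id %in% surv$subject_id, ]
    if (nrow(man) < 2L)
        stop("pipeline precondition failed: fewer than 2 subjects after ",
             "the early-death exclusion (", nrow(man), " left)")

    rows <- list()
    for (i in seq_len(nrow(man))) {
        sid <- man$subject_id[i]
        res <- tryCatch({
            vol <- readVolume(man$volume[i])
            lapply(c(tumor = "tumor", normal = "normal"), function(role) {
                m <- readMask(man[[paste0(role, "_mask")]][i], role = role)
                cbind(data.frame(subject_id = sid, role = role),
                      extractFeatures(vol, m, filter = config$filter,
                                      config = config$quantization,
                                      delta = config$delta,
                                      thetas = config$thetas,
                                      symmetric = config$symmetric,
                                      id = sid))
            })
        }, error = function(e) e)
        if (inherits(res, "error")) {
            log <- .logLine(log, "dropped subject ", sid, ": ",
                            conditionMessage(res))
        } else rows[[length(rows) + 1L]] <- do.call(rbind, res)
    }
    if (length(rows) < 2L)
        stop("pipeline failed: fewer than 2 subjects with usable features")
    features <- do.call(rbind, rows)
    rownames(features) <- NULL
    log <- .logLine(log, length(rows), " subject(s) analyzed")

    tumor <- features[features$role == "tumor", ]
    normal <- features[features$role == "normal", ]
    tumor <- merge(tumor, surv, by = "subject_id", sort = TRUE)

    # -- comparison table: tumor vs normal per texture feature + intensity
    cmpFeatures <- c(.FEATURE_NAMES, "mean_intensity")
    table3 <- do.call(rbind, lapply(cmpFeatures, function(f) {
        tx <- tumor[[f]]; nx <- normal[[f]]
        tx <- tx[!is.na(tx)]; nx <- nx[!is.na(nx)]
        mt <- .medIqr(tx); mn <- .medIqr(nx)
        p <- if (length(tx) && length(nx)) mannWhitney(tx, nx)$p else NA_real_
        data.frame(feature = f,
                   tumor_median = mt["median"], tumor_q1 = mt["q1"],
                   tumor_q3 = mt["q3"],
                   normal_median = mn["median"], normal_q1 = mn["q1"],
                   normal_q3 = mn["q3"], p_value = p)
    }))
    rownames(table3) <- NULL

    # -- Cox table: B / SE / Wald / p per tumor covariate
    table4 <- do.call(rbind, lapply(.TABLE_FEATURES, function(f) {
        x <- tumor[[f]]
        nMissing <- sum(is.na(x))
        fit <- tryCatch(
            coxUnivariate(x, tumor$time_months, tumor$event,
                          ties = config$ties),
            error = function(e) e)
        if (inherits(fit, "error")) {
            log <<- .logLine(log, "Cox fit failed for ", f, ": ",
                             conditionMessage(fit))
            return(data.frame(feature = f, n_missing = nMissing,
                              b = NA_real_, se = NA_real_, wald = NA_real_,
                              p_value = NA_real_))
        }
        if (nMissing > 0)
            log <<- .logLine(log, f, ": ", nMissing,
                             " subject(s) dropped pairwise (undefined feature)")
        data.frame(feature = f, n_missing = nMissing, b = coef(fit),
                   se = seCoef(fit), wald = waldStat(fit),
                   p_value = pValue(fit))
    }))
    rownames(table4) <- NULL

    # -- ROC table against the dichotomized outcome
    outcome <- if (config$rocRule == "median")
        dichotomizeSurvival(tumor$time_months)
    else as.integer(tumor$time_months >= config$rocHorizon)
    table5 <- do.call(rbind, lapply(.TABLE_FEATURES, function(f) {
        x <- tumor[[f]]
        r <- tryCatch(rocAnalysis(x, outcome), error = function(e) e)
        if (inherits(r, "error")) {
            log <<- .logLine(log, "ROC failed for ", f, ": ",
                             conditionMessage(r))
            return(data.frame(feature = f, sensitivity = NA_real_,
                              specificity = NA_real_, auc = NA_real_,
                              threshold = NA_real_, ci_lower = NA_real_,
                              ci_upper = NA_real_, direction = NA_character_,
                              p_value = NA_real_))
        }
        yp <- youdenPoint(r)
        data.frame(feature = f, sensitivity = yp[["sensitivity"]],
                   specificity = yp[["specificity"]], auc = auc(r),
                   threshold = yp[["threshold"]],
                   ci_lower = r@ciLower, ci_upper = r@ciUpper,
                   direction = r@direction, p_value = pValue(r))
    }))
    rownames(table5) <- NULL

    # -- figures for survival-associated features
    sig <- table4$feature[!is.na(table4$p_value) &
                          table4$p_value < config$alpha]
    if (config$makePlots) {
        for (f in sig) {
            x <- tumor[[f]]
            ok <- !is.na(x)
            ks <- tryCatch(
                medianSplitKM(x[ok], tumor$time_months[ok], tumor$event[ok]),
                error = function(e) NULL)
            if (is.null(ks)) next
            grDevices::png(file.path(config$outDir, paste0("km_", f, ".png")),
                           width = 720, height = 560)
            fit <- survival::survfit(
                survival::Surv(tumor$time_months[ok], tumor$event[ok]) ~
                    ks$group)
            graphics::plot(fit, col = c("steelblue", "firebrick"), lwd = 2,
                           xlab = "Months", ylab = "Cumulative survival",
                           main = paste0(f, ": median split (log-rank p = ",
                                         signif(ks$p, 3), ")"))
            graphics::legend("topright", bty = "n", lwd = 2,
                             col = c("steelblue", "firebrick"),
                             legend = paste(c("low", "high"), f))
            grDevices::dev.off()
            grDevices::png(file.path(config$outDir,
                                     paste0("hist_", f, ".png")),
                           width = 720, height = 560)
            graphics::hist(x[ok], breaks = "FD", col = "grey80",
                           xlab = f, main = paste("Distribution of", f))
            grDevices::dev.off()
        }
        log <- .logLine(log, "figures written for: ",
                        if (length(sig)) paste(sig, collapse = ", ")
                        else "(none)")
    }

    utils::write.csv(features, file.path(config$outDir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(table3, file.path(config$outDir,
                                       "table3_comparison.csv"),
                     row.names = FALSE)
    utils::write.csv(table4, file.path(config$outDir, "table4_cox.csv"),
                     row.names = FALSE)
    utils::write.csv(table5, file.path(config$outDir, "table5_roc.csv"),
                     row.names = FALSE)
    log <- .logLine(log,
                    "note: p-values are raw (no multiplicity adjustment ",
                    "across the ", length(.TABLE_FEATURES), " covariates)")
    writeLines(log, file.path(config$outDir, "run_log.txt"))
    invisible(list(features = features, table3 = table3, table4 = table4,
                   table5 = table5, log = log, outDir = config$outDir))
}
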