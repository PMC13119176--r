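#' Run the full augmentation pipeline
#'
#' Orchestrates the end-to-end distribution-reconstruction run: dataset
#' statistics, donor-bank extraction, category-aware copy-paste with
#' environment simulation, teacher accept-reject screening, writing the
#' output dataset (originals plus kept augmented samples, in YOLO layout),
#' and a before/after report. The input dataset is never mutated; the run
#' is a pure function of (input, configuration, seed), so identical calls
#' produce byte-identical label files and report JSON.
#'
#' The "after" statistics in the report are recomputed by re-reading the
#' written output dataset, so the report always describes what is actually
#' on disk.
#'
#' @param input dataset root directory or a \linkS4class{DetectionDataset}
#'   read from one.
#' @param outputRoot destination directory (must differ from the input
#'   root; created if missing).
#' @param policy an \linkS4class{AugPolicy}.
#' @param profile an \linkS4class{EnvProfile} or \code{NULL} to skip
#'   environment simulation.
#' @param teacher a \linkS4class{TeacherModel} or \code{NULL} to skip
#'   screening (all samples kept).
#' @param screenCfg a \linkS4class{ScreeningConfig}.
#' @param seed global seed; fanned out to independent per-stage streams.
#' @param n0,bins report parameters (see \code{\link{distributionReport}}).
#' @param verbose emit per-stage progress messages.
#' @return list with \code{outputRoot}, \code{before} and \code{after}
#'   \linkS4class{DistributionReport}s, \code{planned} distribution,
#'   \code{screening} summary, \code{nAugmented}, \code{nKept},
#'   \code{provenance} data.frame, and the paths of the written report
#'   files.
#' @export
runPipeline <- function(input, outputRoot, policy, profile = envProfile(),
                        teacher = NULL, screenCfg = screeningConfig(),
                        seed = 1L, n0 = 200L, bins = 10L, verbose = TRUE) {
    say <- function(...) if (verbose) message("[pipeline] ", ...)
    ds <- if (is.character(input)) readDataset(input) else input
    stopifnot(is(ds, "DetectionDataset"))
    if (is.character(input) &&
        normalizePath(input, mustWork = FALSE) ==
        normalizePath(outputRoot, mustWork = FALSE))
        stop("outputRoot must differ from the input root")
    say("computing input statistics over ", nItems(ds), " image(s)")
    before <- distributionReport(ds, n0 = n0, bins = bins)
    def <- classDeficits(before@distribution, policy@targetCount)
    say(sum(def > 0), " deficit class(es), ", sum(def), " paste(s) needed")

    dir.create(file.path(outputRoot, "images"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(outputRoot, "labels"), recursive = TRUE,
               showWarnings = FALSE)
    say("copying ", nItems(ds), " original item(s)")
    writeDataset(ds, outputRoot, overwrite = TRUE)

    kept <- 0L; total <- 0L
    reasonTab <- c(low_confidence = 0L, poor_localization = 0L,
                   class_mismatch = 0L, over_occluded = 0L)
    provRows <- list()
    sink <- function(sample, screen) {
        total <<- total + 1L
        if (!is.null(screen) && !screen@accepted) {
            bad <- screen@verdicts$reason[screen@verdicts$reason != "ok"]
            reasonTab[bad[1]] <<- reasonTab[bad[1]] + 1L
            say("sample ", total, " rejected (", bad[1], ")")
            return(invisible(NULL))
        }
        kept <<- kept + 1L
        stem <- sprintf("aug_%05d", kept)
        writeImageFile(sample@image,
                       file.path(outputRoot, "images", paste0(stem, ".png")))
        ann <- sample@annotations
        writeLines(vapply(seq_len(nrow(ann)), function(j)
            formatLabelLine(ann[j, ]), ""),
            file.path(outputRoot, "labels", paste0(stem, ".txt")))
        pv <- sample@provenance
        pv$stem <- stem
        provRows[[length(provRows) + 1L]] <<- pv
        invisible(NULL)
    }
    bank <- NULL
    if (sum(def) > 0) {
        say("extracting donor instances for deficit classes")
        inst <- extractInstances(ds, classes = which(def > 0L) - 1L,
                                 alphaMode = if (policy@blendMode == "hard")
                                     "hard" else "feathered")
        bank <- buildBank(inst, classNames(ds))
        say("bank: ", sum(bankCounts(bank)), " donor instance(s)")
        plan <- planAndAugment(ds, bank, policy, profile = profile,
                               teacher = teacher, screenCfg = screenCfg,
                               seed = seed, sink = sink)
    } else {
        plan <- list(planned = before@distribution,
                     pastes = setNames(integer(length(def)), names(def)),
                     failures = 0L)
    }
    say(kept, " of ", total, " augmented sample(s) kept")

    outDs <- readDataset(outputRoot)
    after <- distributionReport(outDs, n0 = n0, bins = bins)
    provenance <- if (length(provRows)) do.call(rbind, provRows) else
        data.frame()
    screening <- c(as.list(reasonTab), n_kept = kept,
                   n_rejected = total - kept)
    report <- list(
        before = reportToList(before), after = reportToList(after),
        delta = compareReports(before, after), screening = screening,
        planned_counts = as.list(counts(plan$planned)),
        paste_failures = plan$failures, seed = seed)
    reportPath <- file.path(outputRoot, "report.json")
    jsonlite::write_json(report, reportPath, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
    mdPath <- file.path(outputRoot, "report.md")
    writeLines(c("# Augmentation report", "", "## Before",
                 reportToMarkdown(before), "", "## After",
                 reportToMarkdown(after)), mdPath)
    provPath <- file.path(outputRoot, "provenance.json")
    jsonlite::write_json(provenance, provPath, auto_unbox = TRUE,
                         digits = NA)
    list(outputRoot = outputRoot, before = before, after = after,
         planned = plan$planned, screening = screening,
         nAugmented = total, nKept = kept, provenance = provenance,
         reportPath = reportPath, markdownPath = mdPath,
         provenancePath = provPath)
}

#' Read a pipeline configuration file
#'
#' YAML mirror of the programmatic interface: top-level keys \code{input},
#' \code{output}, \code{seed}, and optional blocks \code{policy} (fields of
#' \code{\link{augPolicy}}), \code{env} (fields of \code{\link{envProfile}};
#' \code{env: none} disables the stage), \code{screening} (fields of
#' \code{\link{screeningConfig}}), \code{teacher} (\code{kind: oracle} plus
#' \code{\link{oracleTeacher}} fields, or \code{kind: none}) and
#' \code{report} (\code{n0}, \code{bins}).
#'
#' @param path YAML file.
#' @return list of resolved pipeline arguments, ready for
#'   \code{do.call(runPipeline, ...)}.
#' @export
readPipelineConfig <- function(path) {
    y <- yaml::read_yaml(path)
    if (is.null(y$input) || is.null(y$output))
        stop("config must name 'input' and 'output' roots")
    pol <- y$policy
    if (is.null(pol$targetCount))
        stop("config policy must set targetCount")
    policy <- augPolicy(
        targetCount = unlist(pol$targetCount),
        scaleJitter = if (is.null(pol$scaleJitter)) c(0.5, 2) else
            unlist(pol$scaleJitter),
        maxPastePerImage = if (is.null(pol$maxPastePerImage)) 3L else
            pol$maxPastePerImage,
        maxOverlapIoU = if (is.null(pol$maxOverlapIoU)) 0.1 else
            pol$maxOverlapIoU,
        blendMode = if (is.null(pol$blendMode)) "feathered" else
            pol$blendMode,
        onReject = if (is.null(pol$onReject)) "drop" else pol$onReject)
    profile <- if (identical(y$env, "none")) NULL else {
        e <- if (is.list(y$env)) y$env else list()
        do.call(envProfile, e[names(e) %in% names(formals(envProfile))])
    }
    sc <- if (is.list(y$screening)) y$screening else list()
    screenCfg <- do.call(screeningConfig,
                         sc[names(sc) %in% names(formals(screeningConfig))])
    teacher <- NULL
    if (is.list(y$teacher) && identical(y$teacher$kind, "oracle")) {
        tp <- y$teacher
        teacher <- oracleTeacher(
            detectionProb = if (is.null(tp$detectionProb)) 1 else
                tp$detectionProb,
            confBase = if (is.null(tp$confBase)) 1 else tp$confBase,
            confSd = if (is.null(tp$confSd)) 0 else tp$confSd,
            locNoise = if (is.null(tp$locNoise)) 0 else tp$locNoise)
    }
    rep_ <- if (is.list(y$report)) y$report else list()
    list(input = y$input, outputRoot = y$output, policy = policy,
         profile = profile, teacher = teacher, screenCfg = screenCfg,
         seed = if (is.null(y$seed)) 1L else as.integer(y$seed),
         n0 = if (is.null(rep_$n0)) 200L else as.integer(rep_$n0),
         bins = if (is.null(rep_$bins)) 10L else as.integer(rep_$bins))
}
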