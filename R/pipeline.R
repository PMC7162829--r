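# Config-driven end-to-end orchestration:
# simulate/load -> preprocess -> chemometrics -> differential -> enrichment.

.configDefaults <- function() list(
    simulate = list(preset = NULL, noise_sd = NULL, jitter_sd_ppm = NULL,
                    dilution_log_sd = NULL, n_per_class = NULL),
    input = list(spectra = NULL, metadata = NULL),
    preprocess = list(keep_min = 0.8, keep_max = 10.0,
                      drop = list(c(4.7, 5.2)), pqn = TRUE, align = TRUE,
                      max_shift_ppm = 0.02, min_segment_points = 30L,
                      stop_corr = 0.98, log_offset = "noise-floor"),
    analysis = list(mmc_components = NULL, qda_gamma = 0.5, ridge = 1e-6,
                    loo = TRUE, pca_components = 2L),
    comparisons = "auto",
    reference = "WT",
    fdr_level = 0.1,
    tol_ppm = 0.01,
    enrichment = list(pathways = NULL, background = NULL),
    seed = 1L,
    outdir = "nmrmetab_run")

# unknown keys are errors, not warnings: silent typos corrupt analyses
.mergeConfig <- function(user, defaults, path = "") {
    if (is.null(user)) return(defaults)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
        stop("unknown config key(s)", if (nzchar(path)) paste0(" in ", path),
             ": ", paste(unknown, collapse = ", "))
    overridden <- character(0)
    for (nm in names(user)) {
        if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
            nm %in% c("simulate", "input", "preprocess", "analysis",
                      "enrichment")) {
            sub <- .mergeConfig(user[[nm]], defaults[[nm]], nm)
            overridden <- c(overridden,
                            paste0(nm, ".", attr(sub, "overridden")))
            attr(sub, "overridden") <- NULL
            defaults[[nm]] <- sub
        } else {
            defaults[[nm]] <- user[[nm]]
            overridden <- c(overridden, nm)
        }
    }
    attr(defaults, "overridden") <- overridden
    defaults
}

#' Build and validate a pipeline configuration
#'
#' Exactly one of a `simulate` block (with a packaged `preset` name) or an
#' `input` block (paths to a spectrum matrix and metadata table) must be
#' given. All other keys have defaults; unknown keys are errors.
#'
#' @param ... Named configuration entries (see [runPipeline()]).
#' @return Validated configuration list with attribute `"overridden"`
#'   naming the keys the caller set.
#' @export
pipelineConfig <- function(...) {
    user <- list(...)
    cfg <- .mergeConfig(user, .configDefaults())
    hasSim <- !is.null(cfg$simulate$preset)
    hasInput <- !is.null(cfg$input$spectra) || !is.null(cfg$input$metadata)
    if (hasSim && hasInput)
        stop("config must contain either a simulate preset or input paths, not both")
    if (!hasSim && !hasInput)
        stop("config needs a simulate preset or input paths")
    if (hasInput && (is.null(cfg$input$spectra) || is.null(cfg$input$metadata)))
        stop("input block needs both 'spectra' and 'metadata' paths")
    if (!is.numeric(cfg$fdr_level) || cfg$fdr_level <= 0 || cfg$fdr_level >= 1)
        stop("fdr_level must lie in (0, 1)")
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys follow [pipelineConfig()].
#' @return Validated configuration list.
#' @export
readPipelineConfig <- function(path) {
    do.call(pipelineConfig, yaml::read_yaml(path))
}

.stageLog <- function(stage, ...) {
    message(sprintf("[nmrmetab] %s | %s", stage,
                    paste(..., collapse = " ")))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or loading), preprocessing
#' (exclusion, PQN, alignment, log transform), PCA + MMC + leave-one-out
#' cross-validated classification, per-comparison differential analysis
#' (ANOVA/BH/pFDR, fold changes, metabolite calls), and metabolite-set
#' over-representation analysis. All tables are written under `outdir`
#' together with a manifest (parameter echo with default-vs-overridden
#' status, per-file checksums). Identical config and seed give identical
#' output checksums.
#'
#' @param config A configuration from [pipelineConfig()] /
#'   [readPipelineConfig()].
#' @param outdir,seed Optional overrides of the config values.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL) {
    overridden <- attr(config, "overridden")
    if (!is.null(outdir)) config$outdir <- outdir
    if (!is.null(seed)) config$seed <- seed
    out <- config$outdir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    stage <- "setup"
    runStage <- function(name, fn) {
        stage <<- name
        t0 <- proc.time()[["elapsed"]]
        res <- tryCatch(fn(), error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
        .stageLog(name, sprintf("elapsed=%.2fs", proc.time()[["elapsed"]] - t0))
        res
    }

    # --- data ------------------------------------------------------------
    truth <- NULL
    set <- runStage("data", function() {
        if (!is.null(config$simulate$preset)) {
            ov <- list()
            if (!is.null(config$simulate$noise_sd))
                ov$noiseSd <- config$simulate$noise_sd
            if (!is.null(config$simulate$jitter_sd_ppm))
                ov$jitterSdPpm <- config$simulate$jitter_sd_ppm
            if (!is.null(config$simulate$dilution_log_sd))
                ov$dilutionLogSd <- config$simulate$dilution_log_sd
            if (!is.null(config$simulate$n_per_class))
                ov$nPerClass <- config$simulate$n_per_class
            design <- do.call(presetDesign, c(
                list(name = config$simulate$preset,
                     seed = stageSeed(config$seed, "simulate")), ov))
            sim <- simulateDataset(design)
            truth <<- sim$truth
            writeSpectrumSet(sim$set, file.path(out, "spectra.csv"),
                             file.path(out, "metadata.csv"))
            jsonlite::write_json(
                list(dilution_factors = as.list(truth@dilutionFactors),
                     effects = as.data.frame(truth@effects)),
                file.path(out, "ground_truth.json"), digits = NA)
            files <<- c(files, file.path(out, c("spectra.csv",
                                                "metadata.csv",
                                                "ground_truth.json")))
            sim$set
        } else {
            readSpectrumSet(config$input$spectra, config$input$metadata)
        }
    })

    # --- preprocess -------------------------------------------------------
    pp <- runStage("preprocess", function() {
        p <- config$preprocess
        res <- preprocessSpectra(set, keepMin = p$keep_min,
                                 keepMax = p$keep_max, drop = p$drop,
                                 pqn = p$pqn, align = p$align,
                                 maxShiftPpm = p$max_shift_ppm,
                                 minSegmentPoints = p$min_segment_points,
                                 stopCorr = p$stop_corr,
                                 logOffset = p$log_offset)
        writeSpectrumSet(res$set, file.path(out, "processed_spectra.csv"),
                         file.path(out, "processed_metadata.csv"))
        rep <- res$report
        jsonlite::write_json(list(
            excluded_regions = rep@excludedRegions,
            keep_range = rep@keepRange,
            dilution_factors = as.list(rep@dilutionFactors),
            reference_sample_id = rep@referenceSampleId,
            log_offset = rep@logOffset,
            stage_order = rep@stageOrder,
            shifts = lapply(rep@shiftMap, function(d) as.list(d))),
            file.path(out, "preprocess_report.json"), digits = NA,
            auto_unbox = TRUE)
        files <<- c(files, file.path(out, c("processed_spectra.csv",
                                            "processed_metadata.csv",
                                            "preprocess_report.json")))
        res
    })
    logSet <- pp$set
    labels <- colData(logSet)$genotype

    # --- chemometrics -----------------------------------------------------
    cv <- runStage("chemometrics", function() {
        a <- config$analysis
        kPca <- min(a$pca_components, ncol(logSet) - 1L)
        pca <- pcaFit(logSet, k = kPca)
        utils::write.table(
            data.frame(sample_id = rownames(pca@scores),
                       genotype = labels, pca@scores,
                       check.names = FALSE),
            file.path(out, "pca_scores.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
        mmc <- mmcFit(logSet, k = a$mmc_components)
        utils::write.table(
            data.frame(sample_id = rownames(mmc@scores),
                       genotype = labels, mmc@scores,
                       check.names = FALSE),
            file.path(out, "mmc_scores.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
        files <<- c(files, file.path(out, c("pca_scores.tsv",
                                            "mmc_scores.tsv")))
        if (!isTRUE(a$loo)) return(NULL)
        cv <- looCv(logSet, k = a$mmc_components, regGamma = a$qda_gamma,
                    ridge = a$ridge)
        jsonlite::write_json(list(
            correct_rate = cv@correctRate,
            predictions = cv@predictions,
            confusion = as.data.frame(cv@confusion)),
            file.path(out, "cv_result.json"), digits = NA,
            auto_unbox = TRUE)
        files <<- c(files, file.path(out, "cv_result.json"))
        cv
    })

    # --- differential -----------------------------------------------------
    diffs <- runStage("differential", function() {
        pairs <- config$comparisons
        if (identical(pairs, "auto")) {
            ref <- config$reference
            if (!ref %in% labels)
                stop("reference genotype '", ref, "' not present")
            pairs <- lapply(setdiff(sort(unique(labels)), ref),
                            function(g) c(g, ref))
        }
        res <- lapply(pairs, function(pr) {
            dr <- differentialAnalysis(logSet, pp$unlogged, pr,
                                       fdrLevel = config$fdr_level,
                                       tolPpm = config$tol_ppm)
            prefix <- paste0(pr[1], "_vs_", pr[2], "_")
            files <<- c(files,
                        writeDifferentialTables(dr, logSet, out, prefix))
            dr
        })
        # Table-1-style direction summary across comparisons
        allMets <- metaboliteNames(defaultPeakLibrary())
        summ <- data.frame(metabolite = allMets)
        for (dr in res) {
            col <- setNames(rep("-", length(allMets)), allMets)
            mc <- metaboliteCalls(dr)
            col[mc$name] <- ifelse(mc$direction == "up", "up", "down")
            summ[[paste(dr@comparison, collapse = "_vs_")]] <- col
        }
        p1 <- file.path(out, "table1_summary.tsv")
        utils::write.table(summ, p1, sep = "\t", row.names = FALSE,
                           quote = FALSE)
        files <<- c(files, p1)
        res
    })

    # --- enrichment -------------------------------------------------------
    runStage("enrichment", function() {
        pw <- if (is.null(config$enrichment$pathways))
            defaultPathwayLibrary()
        else readPathwayLibrary(config$enrichment$pathways)
        bg <- if (is.null(config$enrichment$background))
            unname(hmdbIds(defaultPeakLibrary()))
        else readLines(config$enrichment$background)
        for (dr in diffs) {
            sig <- unique(metaboliteCalls(dr)$hmdb)
            er <- ora(sig, bg, pw)
            p <- file.path(out, paste0(paste(dr@comparison,
                                             collapse = "_vs_"),
                                       "_enrichment.tsv"))
            utils::write.table(er, p, sep = "\t", row.names = FALSE,
                               quote = FALSE)
            files <<- c(files, p)
        }
        NULL
    })

    # --- manifest ---------------------------------------------------------
    files <- unique(files)
    manifest <- list(
        package = "nmrmetab",
        version = as.character(utils::packageVersion("nmrmetab")),
        seed = config$seed,
        parameters = config,
        overridden_parameters = if (length(overridden)) overridden
                                else character(0),
        outputs = lapply(files, function(f)
            list(file = basename(f),
                 md5 = unname(tools::md5sum(f)))))
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    invisible(manifest)
}
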