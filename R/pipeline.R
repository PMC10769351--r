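#' Build a pipeline run configuration
#'
#' Assembles the resolved configuration for [runPipeline()]: the run mode,
#' input/output paths, the geometry block (pixel size, profile length and
#' width, smoothing and peak windows, minimum ROI area) and the statistics
#' block (reference condition, alpha levels). Every run writes a resolved
#' copy of this configuration alongside its outputs.
#'
#' @param mode one of \code{"simulate"}, \code{"quantify-confocal"},
#'   \code{"quantify-sted"}, \code{"quantify-soma"}, \code{"stats"},
#'   \code{"full-demo"}.
#' @param outputDir directory for stage outputs (created if needed).
#' @param imagePath,annotationPath inputs for the quantify modes.
#' @param seed integer seed controlling every stochastic stage.
#' @param geometry named list; defaults: \code{profile_length_nm = 1000},
#'   \code{profile_width_nm = 200}, \code{smoothing_window_px = 5},
#'   \code{peak_window_nm = 200}, \code{min_roi_area_um2 = 0.05},
#'   \code{n_transverse = 15}.
#' @param stats named list; defaults: \code{reference = "cTKO"},
#'   \code{alpha = c(0.05, 0.01, 0.001)}.
#' @param simulate named list forwarded to [synthConfig()] for the
#'   simulate/full-demo modes, plus \code{conditions}: a named numeric
#'   vector of protein-of-interest amplitudes per condition and
#'   \code{n_per_condition} synapses per condition.
#' @param blind logical: scramble condition labels in intermediate tables,
#'   unscrambled only in the final statistics report.
#' @return classed list \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(mode = "full-demo", outputDir = "presynquant-run",
                           imagePath = NULL, annotationPath = NULL,
                           seed = 1L, geometry = list(), stats = list(),
                           simulate = list(), blind = FALSE) {
    modes <- c("simulate", "quantify-confocal", "quantify-sted",
               "quantify-soma", "stats", "full-demo")
    if (!mode %in% modes)
        stop("unknown mode '", mode, "'; expected one of: ",
             paste(modes, collapse = ", "))
    geo <- utils::modifyList(list(
        profile_length_nm = 1000, profile_width_nm = 200,
        smoothing_window_px = 5L, peak_window_nm = 200,
        min_roi_area_um2 = 0.05, n_transverse = 15L), geometry)
    st <- utils::modifyList(list(
        reference = "cTKO", alpha = c(0.05, 0.01, 0.001)), stats)
    sim <- utils::modifyList(list(
        conditions = c(ctrl = 100, rescue = 100, cTKO = 0),
        n_per_condition = 30L, n_per_field = 10L,
        field_size_px = c(512L, 512L)), simulate)
    if (any(unlist(geo[c("profile_length_nm", "profile_width_nm",
                         "peak_window_nm", "min_roi_area_um2")]) <= 0))
        stop("geometry parameters must be positive")
    if (mode %in% c("quantify-confocal", "quantify-sted", "quantify-soma") &&
        is.null(imagePath))
        stop("mode '", mode, "' requires imagePath")
    structure(list(mode = mode, outputDir = outputDir,
                   imagePath = imagePath, annotationPath = annotationPath,
                   seed = as.integer(seed), geometry = geo, stats = st,
                   simulate = sim, blind = blind),
              class = "pipelineConfig")
}

#' Read or write a pipeline configuration as YAML
#'
#' Named vectors (e.g. \code{simulate$conditions}) are stored as YAML
#' maps so their names survive the round trip.
#'
#' @param path YAML file whose top-level keys mirror the
#'   [pipelineConfig()] arguments.
#' @return \code{readRunConfig}: classed list \code{"pipelineConfig"}.
#' @export
readRunConfig <- function(path) {
    v <- yaml::read_yaml(path)
    v$simulate <- lapply(v$simulate, function(x)
        if (is.list(x)) unlist(x) else x)
    do.call(pipelineConfig, v)
}

#' @rdname readRunConfig
#' @param config a \code{"pipelineConfig"}.
#' @export
writeRunConfig <- function(config, path) {
    asMaps <- function(x) {
        if (is.list(x)) lapply(x, asMaps)
        else if (!is.null(names(x)) && length(x) > 1L) as.list(x)
        else x
    }
    yaml::write_yaml(asMaps(unclass(config)), path)
    invisible(path)
}

scrambleMap <- function(labels, seed) {
    # deterministic label-scrambling for blind analysis
    set.seed(seed + 7919L)
    code <- sprintf("blind_%02d", sample(seq_along(labels)))
    stats::setNames(code, labels)
}

simulateCondition <- function(cond, amp, simCfg, geo, seed) {
    nFields <- ceiling(simCfg$n_per_condition / simCfg$n_per_field)
    peaks <- NULL; profiles <- list(); excluded <- 0L
    got <- 0L
    for (f in seq_len(nFields)) {
        nHere <- min(simCfg$n_per_field, simCfg$n_per_condition - got)
        if (nHere <= 0L) break
        args <- simCfg[setdiff(names(simCfg),
                               c("conditions", "n_per_condition",
                                 "n_per_field", "field_size_px"))]
        args$imageSizePx <- simCfg$field_size_px
        args$nSynapses <- nHere
        args$rngSeed <- seed + 1000L * match(cond, names(simCfg$conditions)) + f
        cfg <- do.call(synthConfig, args)
        cfg@channelAmplitudes[["poi"]] <- amp
        fld <- generateSynapseField(cfg)
        lps <- extractProfiles(fld$image, annotationsFromTruth(fld$truth),
                               lengthNm = geo$profile_length_nm,
                               widthNm = geo$profile_width_nm,
                               nTransverse = geo$n_transverse)
        lps <- alignProfiles(lps, window = geo$smoothing_window_px)
        excluded <- excluded + nrow(lps@excluded)
        if (nSynapses(lps) > 0L) {
            sm <- summarizeProfiles(lps, windowNm = geo$peak_window_nm)
            pk <- peakTable(sm)
            pk$id <- pk$id + got
            pk$condition <- cond
            peaks <- rbind(peaks, pk)
            profiles[[f]] <- profileTable(sm)
        }
        got <- got + nHere
    }
    list(peaks = peaks, excluded = excluded)
}

#' Run the quantification pipeline
#'
#' Orchestrates simulate / segment / profile / summarize / stats stages
#' with stable output filenames, a resolved-config copy and a JSON run
#' manifest (seed, config hash, synapse and ROI counts, exclusions).
#' \code{full-demo} simulates one synthetic condition per entry of
#' \code{simulate$conditions} (named protein-of-interest amplitudes),
#' quantifies window peak intensities per synapse, and compares conditions
#' with Kruskal-Wallis plus Dunn's post hoc against the configured
#' reference. Identical configuration and seed reproduce every output
#' byte; input files are never modified.
#'
#' @param config a \code{"pipelineConfig"} (see [pipelineConfig()]) or a
#'   path to a YAML file for [readRunConfig()].
#' @return invisibly, a list with the manifest and the main stage results.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- readRunConfig(config)
    stopifnot(inherits(config, "pipelineConfig"))
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outputDir, f)
    writeRunConfig(config, out("resolved-config.yaml"))
    cfgHash <- unname(tools::md5sum(out("resolved-config.yaml")))
    geo <- config$geometry
    manifest <- list(mode = config$mode, seed = config$seed,
                     config_md5 = cfgHash)
    results <- list()

    if (config$mode %in% c("simulate", "full-demo")) {
        sim <- config$simulate
        conds <- sim$conditions
        blindMap <- if (config$blind) scrambleMap(names(conds), config$seed)
                    else stats::setNames(names(conds), names(conds))
        allPeaks <- NULL; exclTotal <- 0L
        for (cond in names(conds)) {
            res <- simulateCondition(cond, conds[[cond]], sim, geo,
                                     config$seed)
            exclTotal <- exclTotal + res$excluded
            if (!is.null(res$peaks)) {
                res$peaks$condition <- unname(blindMap[res$peaks$condition])
                allPeaks <- rbind(allPeaks, res$peaks)
            }
        }
        manifest$n_synapses_analyzed <- if (is.null(allPeaks)) 0L
                                        else nrow(allPeaks)
        manifest$n_synapses_excluded <- exclTotal
        if (is.null(allPeaks)) {
            warning("no valid side-view synapses; writing empty summary")
            utils::write.csv(
                data.frame(id = integer(0), poi_peak = numeric(0),
                           psd_peak = numeric(0), condition = character(0)),
                out("peaks.csv"), row.names = FALSE)
        } else {
            utils::write.csv(allPeaks, out("peaks.csv"), row.names = FALSE)
            results$peaks <- allPeaks
            if (config$mode == "full-demo") {
                unblind <- stats::setNames(names(blindMap), blindMap)
                allPeaks$condition <- unname(unblind[allPeaks$condition])
                sr <- kruskalDunn(
                    data.frame(value = allPeaks$poi_peak,
                               condition = allPeaks$condition),
                    reference = config$stats$reference)
                writeStatReport(sr, out("stats-report.txt"))
                utils::write.csv(comparisons(sr), out("stats-comparisons.csv"),
                                 row.names = FALSE)
                results$stats <- sr
            }
        }
    } else if (config$mode == "quantify-sted") {
        image <- readImageTiff(config$imagePath)
        ann <- if (is.null(config$annotationPath))
            detectSideView(image) else readAnnotations(config$annotationPath)
        lps <- extractProfiles(image, ann,
                               lengthNm = geo$profile_length_nm,
                               widthNm = geo$profile_width_nm,
                               nTransverse = geo$n_transverse)
        lps <- alignProfiles(lps, window = geo$smoothing_window_px)
        manifest$n_synapses_analyzed <- nSynapses(lps)
        manifest$n_synapses_excluded <- nrow(lps@excluded)
        manifest$exclusion_reasons <- as.list(table(lps@excluded$reason))
        utils::write.csv(lps@excluded, out("excluded-synapses.csv"),
                         row.names = FALSE)
        if (nSynapses(lps) == 0L) {
            warning("no valid side-view synapses; writing empty summary")
            utils::write.csv(data.frame(), out("peaks.csv"),
                             row.names = FALSE)
        } else {
            sm <- summarizeProfiles(lps, windowNm = geo$peak_window_nm)
            utils::write.csv(peakTable(sm), out("peaks.csv"),
                             row.names = FALSE)
            utils::write.csv(profileTable(sm), out("mean-profiles.csv"),
                             row.names = FALSE)
            results$summary <- sm
        }
    } else if (config$mode == "quantify-confocal") {
        image <- readImageTiff(config$imagePath)
        rois <- segmentSynapsin(image, minAreaUm2 = geo$min_roi_area_um2,
                                imageId = basename(config$imagePath))
        for (ch in setdiff(channelNames(image), "synapsin"))
            rois <- roiMeanLevels(image, rois, ch)
        manifest$n_rois <- roiCount(rois)
        writeRoiTable(rois, out("rois.csv"))
        utils::write.csv(
            data.frame(channel = names(imageSummary(rois)),
                       image_mean = as.numeric(imageSummary(rois))),
            out("image-summary.csv"), row.names = FALSE)
        results$rois <- rois
    } else if (config$mode == "quantify-soma") {
        stop("quantify-soma requires explicit masks; use somaDonutMean() ",
             "with makeDiscMask() or imported masks")
    } else if (config$mode == "stats") {
        tab <- utils::read.csv(config$annotationPath)
        sr <- kruskalDunn(tab, reference = config$stats$reference)
        writeStatReport(sr, out("stats-report.txt"))
        results$stats <- sr
    }

    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(list(manifest = manifest, results = results))
}
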