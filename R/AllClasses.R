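#' @import methods
NULL

#' Multichannel fluorescence image
#'
#' Container for a single 2-D field of view with one or more named channels,
#' a physical pixel size in nanometres, and a per-channel modality tag
#' (\code{"confocal"} or \code{"STED"}). The modality tag travels with the
#' image so that profile extraction can refuse to treat a confocal channel
#' as super-resolved.
#'
#' @slot data numeric array of dimension (rows, cols, channels).
#' @slot channels character vector of unique channel names, one per slice.
#' @slot modality character vector parallel to \code{channels}.
#' @slot pixelSizeNm positive scalar, physical edge length of one pixel (nm).
#'
#' @seealso [MultiChannelImage()] for the constructor, [getChannel()],
#'   [channelNames()], [pixelSize()], [modality()].
#' @exportClass MultiChannelImage
setClass("MultiChannelImage",
    representation(
        data = "array",
        channels = "character",
        modality = "character",
        pixelSizeNm = "numeric"
    )
)

setValidity("MultiChannelImage", function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3L)
        msg <- c(msg, "data must be a 3-D array (rows, cols, channels)")
    else {
        if (d[3] != length(object@channels))
            msg <- c(msg, "number of channel names must match dim(data)[3]")
        if (length(object@modality) != length(object@channels))
            msg <- c(msg, "one modality tag per channel required")
    }
    if (anyDuplicated(object@channels))
        msg <- c(msg, "channel names must be unique")
    if (length(object@pixelSizeNm) != 1L || !is.finite(object@pixelSizeNm) ||
        object@pixelSizeNm <= 0)
        msg <- c(msg, "pixelSizeNm must be a single positive number")
    if (!all(object@modality %in% c("confocal", "STED")))
        msg <- c(msg, "modality must be 'confocal' or 'STED'")
    if (length(msg)) msg else TRUE
})

#' Synthetic-field generator configuration
#'
#' Parameters of the synthetic imaging model: field geometry, synapse
#' geometry (PSD-95 bar, synapsin cloud, protein-of-interest bar and its
#' signed trans-synaptic offset), per-channel peak amplitudes and PSF
#' widths, noise model, and the random seed. Negative \code{cavOffsetNm}
#' places the protein-of-interest bar on the presynaptic side of PSD-95.
#'
#' @slot imageSizePx integer pair (rows, cols).
#' @slot pixelSizeNm positive scalar (nm); 14.194 for synapse fields,
#'   90.2 for soma fields by convention.
#' @slot nSynapses number of synapses (or somata in soma mode) to place.
#' @slot psdBarLengthNm,psdBarThicknessNm PSD-95 bar dimensions (nm); the
#'   bar is elongated perpendicular to the trans-synaptic axis.
#' @slot cloudRadiusNm Gaussian sigma of the synapsin vesicle-cloud density.
#' @slot cavOffsetNm signed displacement (nm) of the protein-of-interest bar
#'   centre from the PSD-95 bar centre along the trans-synaptic axis.
#' @slot channelAmplitudes named nonnegative numeric, pre-PSF peak density
#'   per channel (photon scale).
#' @slot psfFwhmNm named positive numeric, Gaussian PSF FWHM per channel.
#' @slot backgroundLevel nonnegative scalar added after PSF blurring.
#' @slot gaussianReadNoiseSd nonnegative scalar, detector read noise SD.
#' @slot poissonNoise logical, Poisson-resample the blurred signal.
#' @slot somaMode logical, generate somatic fields instead of synapse fields.
#' @slot faceOnPsd logical, render PSD-95 as a round blob (face-view synapse)
#'   instead of an elongated bar; used to exercise side-view rejection.
#' @slot somaRadiusNm,nucleusRadiusNm soma-mode disc radii (nm).
#' @slot rngSeed integer seed consumed at the start of each generator call.
#'
#' @seealso [synthConfig()] for the validated constructor with defaults.
#' @exportClass SynthConfig
setClass("SynthConfig",
    representation(
        imageSizePx = "integer",
        pixelSizeNm = "numeric",
        nSynapses = "integer",
        psdBarLengthNm = "numeric",
        psdBarThicknessNm = "numeric",
        cloudRadiusNm = "numeric",
        cavOffsetNm = "numeric",
        channelAmplitudes = "numeric",
        psfFwhmNm = "numeric",
        backgroundLevel = "numeric",
        gaussianReadNoiseSd = "numeric",
        poissonNoise = "logical",
        somaMode = "logical",
        faceOnPsd = "logical",
        somaRadiusNm = "numeric",
        nucleusRadiusNm = "numeric",
        rngSeed = "integer"
    )
)

setValidity("SynthConfig", function(object) {
    msg <- character()
    if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 8L))
        msg <- c(msg, "imageSizePx must be two integers >= 8")
    if (object@pixelSizeNm <= 0)
        msg <- c(msg, "pixelSizeNm must be positive")
    if (object@nSynapses < 0L)
        msg <- c(msg, "nSynapses must be nonnegative")
    if (any(object@psfFwhmNm <= 0))
        msg <- c(msg, "all PSF FWHMs must be positive")
    if (any(object@channelAmplitudes < 0))
        msg <- c(msg, "channel amplitudes must be nonnegative")
    if (is.null(names(object@channelAmplitudes)) ||
        is.null(names(object@psfFwhmNm)))
        msg <- c(msg, "channelAmplitudes and psfFwhmNm must be named")
    else if (!setequal(names(object@channelAmplitudes),
                       names(object@psfFwhmNm)))
        msg <- c(msg, "channelAmplitudes and psfFwhmNm must name the same channels")
    if (object@backgroundLevel < 0 || object@gaussianReadNoiseSd < 0)
        msg <- c(msg, "background and read-noise SD must be nonnegative")
    if (object@somaMode && object@nucleusRadiusNm >= object@somaRadiusNm)
        msg <- c(msg, "nucleusRadiusNm must be smaller than somaRadiusNm")
    if (length(msg)) msg else TRUE
})

#' Generator-side ground truth
#'
#' One record per generated object (synapse or soma) together with an echo
#' of the generating configuration and seed; the oracle against which
#' downstream recovery is tested.
#'
#' @slot objects data.frame; for synapse fields: \code{id, x_nm, y_nm,
#'   axis_dx, axis_dy, offset_nm} plus one \code{amp_<channel>} column per
#'   channel. For soma fields: \code{id, x_nm, y_nm, soma_radius_nm,
#'   nucleus_radius_nm, ha_amplitude, true_donut_mean}.
#' @slot config the generating [SynthConfig-class].
#' @slot seed integer seed actually used.
#' @exportClass GroundTruth
setClass("GroundTruth",
    representation(
        objects = "data.frame",
        config = "SynthConfig",
        seed = "integer"
    )
)

#' Per-synapse trans-synaptic line profiles
#'
#' Intensity profiles sampled along the annotation axis (one sample per
#' pixel, averaged over the transverse ROI width) for every channel, plus
#' the smoothed PSD-95 trace, the PSD-95 peak index and aligned positions
#' once [alignProfiles()] has run. Synapses excluded during extraction or
#' alignment are logged with a reason.
#'
#' @slot positionsNm common raw sampling axis, nm relative to the
#'   annotation centre (strictly increasing, constant step = pixel size).
#' @slot profiles list (one per synapse) of numeric matrices
#'   (samples x channels) of raw intensities.
#' @slot smoothedPsd list of numeric vectors (rolling-average PSD-95), or
#'   empty before [smoothPsd()].
#' @slot peakIndex integer vector, argmax of smoothed PSD-95 per synapse
#'   (NA before alignment).
#' @slot channels,psdChannel,poiChannel channel bookkeeping.
#' @slot pixelSizeNm sampling step (nm).
#' @slot annotations data.frame of the retained [synapse annotations]
#'   (id, x_nm, y_nm, axis_dx, axis_dy, provenance).
#' @slot excluded data.frame (id, reason) of synapses dropped.
#' @exportClass LineProfileSet
setClass("LineProfileSet",
    representation(
        positionsNm = "numeric",
        profiles = "list",
        smoothedPsd = "list",
        peakIndex = "integer",
        channels = "character",
        psdChannel = "character",
        poiChannel = "character",
        pixelSizeNm = "numeric",
        annotations = "data.frame",
        excluded = "data.frame"
    )
)

setValidity("LineProfileSet", function(object) {
    msg <- character()
    p <- object@positionsNm
    if (length(p) > 1L) {
        st <- diff(p)
        if (any(st <= 0) || diff(range(st)) > 1e-6)
            msg <- c(msg, "positionsNm must be strictly increasing with constant step")
    }
    if (length(object@profiles) != nrow(object@annotations))
        msg <- c(msg, "one profile matrix per retained annotation required")
    if (length(object@smoothedPsd) &&
        length(object@smoothedPsd) != length(object@profiles))
        msg <- c(msg, "smoothedPsd must be empty or parallel to profiles")
    if (length(msg)) msg else TRUE
})

#' Condition-level profile summary
#'
#' Mean aligned profile with SEM per channel on the common aligned grid,
#' and per-synapse peak intensities extracted within the window around the
#' PSD-95 peak (protein of interest from the raw trace, PSD-95 from the
#' smoothed trace).
#'
#' @slot gridNm aligned positions (nm; zero at the PSD-95 peak).
#' @slot meanProfile,semProfile numeric matrices (positions x channels);
#'   SEM is NA where fewer than two synapses contribute.
#' @slot nContributing integer matrix of synapse counts per grid position.
#' @slot peaks data.frame (id, poi_peak, psd_peak).
#' @slot windowNm full width (nm) of the peak-extraction window.
#' @slot channels character.
#' @exportClass ProfileSummary
setClass("ProfileSummary",
    representation(
        gridNm = "numeric",
        meanProfile = "matrix",
        semProfile = "matrix",
        nContributing = "matrix",
        peaks = "data.frame",
        windowNm = "numeric",
        channels = "character"
    )
)

#' Segmentation ROI table
#'
#' Labelled connected components of a thresholded mask channel with areas
#' and (after [roiMeanLevels()]) per-channel mean intensities, plus the
#' per-image summary defined as the unweighted mean of per-ROI means.
#'
#' @slot rois data.frame (label, pixel_count, area_um2, centroid_x_nm,
#'   centroid_y_nm, then mean_<channel> columns).
#' @slot labelMatrix integer matrix of ROI labels (0 = background).
#' @slot imageId character identifier.
#' @slot pixelSizeNm numeric.
#' @slot imageSummary named numeric, per-image average of per-ROI means
#'   (NA_real_ with a flag when the table is empty).
#' @exportClass RoiTable
setClass("RoiTable",
    representation(
        rois = "data.frame",
        labelMatrix = "matrix",
        imageId = "character",
        pixelSizeNm = "numeric",
        imageSummary = "numeric"
    )
)

setValidity("RoiTable", function(object) {
    msg <- character()
    if (nrow(object@rois)) {
        if (anyDuplicated(object@rois$label))
            msg <- c(msg, "ROI labels must be unique")
        lab <- sort(unique(object@labelMatrix[object@labelMatrix > 0L]))
        if (!identical(as.integer(sort(object@rois$label)), as.integer(lab)))
            msg <- c(msg, "label matrix and ROI table disagree")
    }
    if (length(msg)) msg else TRUE
})

#' Group-comparison result
#'
#' A global test (Kruskal-Wallis, Friedman, repeated-measures ANOVA or
#' Wilcoxon signed-rank) with control-referenced post-hoc comparisons,
#' multiplicity-adjusted p-values and significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @slot test name of the analysis.
#' @slot statistic,df,pValue global test statistic(s), degrees of freedom
#'   and p-value(s) (named vectors for ANOVA with several effects).
#' @slot comparisons data.frame (comparison, n_1, n_2, estimate, p_raw,
#'   p_adj, stars); empty when no post-hoc applies.
#' @slot reference the reference condition label.
#' @slot nPerGroup named integer vector of group sizes.
#' @slot note character, degenerate-case flags.
#' @exportClass StatResult
setClass("StatResult",
    representation(
        test = "character",
        statistic = "numeric",
        df = "numeric",
        pValue = "numeric",
        comparisons = "data.frame",
        reference = "character",
        nPerGroup = "integer",
        note = "character"
    )
)
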