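#' @rdname MultiChannelImage
#' @param x a \linkS4class{MultiChannelImage}.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname MultiChannelImage
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname MultiChannelImage
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname MultiChannelImage
#' @param channel channel name.
#' @export
setGeneric("getChannel", function(x, channel) standardGeneric("getChannel"))

#' Number of synapses (or cells) represented by an object
#' @param x a \linkS4class{LineProfileSet}, \linkS4class{GroundTruth} or
#'   \linkS4class{ProfileSummary}.
#' @return integer count.
#' @export
setGeneric("nSynapses", function(x) standardGeneric("nSynapses"))

#' @rdname smoothPsd
#' @export
setGeneric("smoothPsd", function(x, window = 5L) standardGeneric("smoothPsd"))

#' @rdname alignProfiles
#' @export
setGeneric("alignProfiles", function(x, ...) standardGeneric("alignProfiles"))

#' Profile accessors
#' @param x a \linkS4class{LineProfileSet}.
#' @return \code{profileMatrices}: list of samples-by-channels matrices;
#'   \code{profilePositions}: raw sampling axis (nm);
#'   \code{smoothedPsdTraces}: list of smoothed PSD-95 vectors;
#'   \code{excludedSynapses}: data.frame (id, reason).
#' @name LineProfileSet-accessors
#' @export
setGeneric("profileMatrices", function(x) standardGeneric("profileMatrices"))

#' @rdname LineProfileSet-accessors
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))

#' @rdname LineProfileSet-accessors
#' @export
setGeneric("smoothedPsdTraces", function(x) standardGeneric("smoothedPsdTraces"))

#' @rdname LineProfileSet-accessors
#' @export
setGeneric("excludedSynapses", function(x) standardGeneric("excludedSynapses"))

#' Aligned sample positions per synapse
#' @param x a \linkS4class{LineProfileSet} after [alignProfiles()].
#' @return list of numeric vectors (nm, zero at the PSD-95 peak).
#' @export
setGeneric("alignedPositions", function(x) standardGeneric("alignedPositions"))

#' ROI accessors
#' @param x a \linkS4class{RoiTable}.
#' @return \code{roiTable}: the per-ROI data.frame; \code{roiCount}: integer;
#'   \code{imageSummary}: named numeric of per-image averages of per-ROI
#'   means.
#' @name RoiTable-accessors
#' @export
setGeneric("roiTable", function(x) standardGeneric("roiTable"))

#' @rdname RoiTable-accessors
#' @export
setGeneric("roiCount", function(x) standardGeneric("roiCount"))

#' @rdname RoiTable-accessors
#' @export
setGeneric("imageSummary", function(x) standardGeneric("imageSummary"))

#' Ground-truth accessors
#' @param x a \linkS4class{GroundTruth}.
#' @return \code{groundTruthTable}: the per-object data.frame.
#' @export
setGeneric("groundTruthTable", function(x) standardGeneric("groundTruthTable"))

#' Post-hoc comparison table of a test result
#' @param x a \linkS4class{StatResult}.
#' @return data.frame of control-referenced comparisons.
#' @export
setGeneric("comparisons", function(x) standardGeneric("comparisons"))
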