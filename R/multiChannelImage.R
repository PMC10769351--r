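#' Construct a multichannel image
#'
#' @param data numeric array (rows, cols, channels) or a list of equally
#'   sized matrices.
#' @param channels character vector of channel names.
#' @param modality character, \code{"confocal"} or \code{"STED"}, recycled
#'   to one tag per channel.
#' @param pixelSizeNm physical pixel size in nanometres.
#' @return a \linkS4class{MultiChannelImage}.
#' @examples
#' img <- MultiChannelImage(list(a = matrix(0, 8, 8)), pixelSizeNm = 90.2)
#' channelNames(img)
#' @export
MultiChannelImage <- function(data, channels = NULL,
                              modality = "confocal", pixelSizeNm) {
    if (is.list(data)) {
        if (is.null(channels)) channels <- names(data)
        data <- array(unlist(data, use.names = FALSE),
                      dim = c(dim(data[[1]]), length(data)))
    }
    if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
    if (is.null(channels))
        channels <- paste0("ch", seq_len(dim(data)[3]))
    modality <- rep_len(modality, length(channels))
    new("MultiChannelImage", data = data, channels = channels,
        modality = modality, pixelSizeNm = pixelSizeNm)
}

#' @rdname MultiChannelImage
#' @export
setMethod("channelNames", "MultiChannelImage", function(x) x@channels)

#' @rdname MultiChannelImage
#' @export
setMethod("pixelSize", "MultiChannelImage", function(x) x@pixelSizeNm)

#' @rdname MultiChannelImage
#' @export
setMethod("modality", "MultiChannelImage",
    function(x) stats::setNames(x@modality, x@channels))

#' @rdname MultiChannelImage
#' @export
setMethod("getChannel", "MultiChannelImage", function(x, channel) {
    i <- match(channel, x@channels)
    if (is.na(i))
        stop("unknown channel '", channel, "'; available: ",
             paste(x@channels, collapse = ", "))
    x@data[, , i]
})

#' @rdname MultiChannelImage
#' @export
setMethod("dim", "MultiChannelImage", function(x) dim(x@data))

setMethod("show", "MultiChannelImage", function(object) {
    d <- dim(object@data)
    cat("MultiChannelImage:", d[1], "x", d[2], "px,",
        sprintf("%.3f nm/px", object@pixelSizeNm), "\n")
    cat("  channels:",
        paste0(object@channels, " (", object@modality, ")",
               collapse = ", "), "\n")
    invisible(NULL)
})

#' Write / read a multichannel image as multi-page TIFF
#'
#' One 32-bit float page per channel; intensities are stored scaled to
#' [0, 1] with the scale factor kept in the metadata. Channel names,
#' modality tags, pixel size and the intensity scale live in a JSON
#' sidecar (\code{<path>.meta.json}) written next to the TIFF, so a round
#' trip restores the object including physical units.
#'
#' @param x a \linkS4class{MultiChannelImage}.
#' @param path file path.
#' @return \code{writeImageTiff}: invisibly, the path.
#'   \code{readImageTiff}: a \linkS4class{MultiChannelImage}.
#' @export
writeImageTiff <- function(x, path) {
    stopifnot(is(x, "MultiChannelImage"))
    lo <- min(x@data); hi <- max(x@data)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_along(x@channels),
                    function(i) (x@data[, , i] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
    jsonlite::write_json(
        list(channels = x@channels, modality = x@modality,
             pixel_size_nm = x@pixelSizeNm,
             intensity_offset = lo, intensity_scale = scale),
        paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeImageTiff
#' @export
readImageTiff <- function(path) {
    metaPath <- paste0(path, ".meta.json")
    if (!file.exists(metaPath))
        stop("missing metadata sidecar '", metaPath,
             "' written by writeImageTiff()")
    meta <- jsonlite::fromJSON(metaPath)
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(unlist(pages, use.names = FALSE),
                 dim = c(dim(pages[[1]]), length(pages)))
    arr <- arr * meta$intensity_scale + meta$intensity_offset
    MultiChannelImage(arr, channels = meta$channels,
                      modality = meta$modality,
                      pixelSizeNm = meta$pixel_size_nm)
}

#' Read / write side-view synapse annotations
#'
#' Plain comma-separated exchange format: columns \code{id, x_nm, y_nm,
#' axis_dx, axis_dy, provenance}. The axis is normalized on read; its
#' positive sense points from the presynaptic toward the postsynaptic side.
#'
#' @param ann annotation data.frame.
#' @param path file path.
#' @return \code{readAnnotations}: validated data.frame.
#' @export
writeAnnotations <- function(ann, path) {
    utils::write.csv(ann, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeAnnotations
#' @export
readAnnotations <- function(path) {
    ann <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("id", "x_nm", "y_nm", "axis_dx", "axis_dy")
    if (!all(need %in% names(ann)))
        stop("annotation table must contain columns: ",
             paste(need, collapse = ", "))
    if (is.null(ann$provenance)) ann$provenance <- "manual"
    nrm <- sqrt(ann$axis_dx^2 + ann$axis_dy^2)
    if (any(nrm == 0)) stop("annotation with zero-length axis vector")
    ann$axis_dx <- ann$axis_dx / nrm
    ann$axis_dy <- ann$axis_dy / nrm
    ann
}
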