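#' Otsu threshold
#'
#' Threshold maximizing the between-class variance of the intensity
#' histogram. For integer-valued 8-bit data every level 0..255 is a
#' candidate split; otherwise the range is divided into \code{levels}
#' equal bins. On ties the smallest threshold is returned, so the result
#' is deterministic. The returned scalar sits strictly between the last
#' level of the lower class and the first level of the upper class; the
#' foreground mask is \code{x > otsuThreshold(x)}.
#'
#' @param x numeric vector or matrix of intensities.
#' @param levels number of histogram bins for non-8-bit data.
#' @return threshold scalar.
#' @examples
#' otsuThreshold(c(rep(0, 50), rep(100, 50)))
#' @export
otsuThreshold <- function(x, levels = 256L) {
    v <- as.numeric(x)
    v <- v[is.finite(v)]
    if (!length(v)) stop("no finite intensities")
    rng <- range(v)
    if (rng[1] == rng[2])
        stop("degenerate input: image is constant, no Otsu threshold exists")
    eightBit <- all(v == round(v)) && rng[1] >= 0 && rng[2] <= 255
    if (eightBit) {
        counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
        mids <- 0:255
        K <- 256L
    } else {
        edges <- seq(rng[1], rng[2], length.out = levels + 1L)
        bin <- findInterval(v, edges, rightmost.closed = TRUE,
                            all.inside = TRUE)
        counts <- tabulate(bin, nbins = levels)
        mids <- (edges[-1] + edges[-(levels + 1L)]) / 2
        K <- as.integer(levels)
    }
    n <- sum(counts)
    w0 <- cumsum(counts)[-K]
    m0 <- cumsum(counts * mids)[-K]
    w1 <- n - w0
    mu <- sum(counts * mids)
    # between-class variance for split after bin k (classes <=k vs >k)
    num <- (mu * w0 / n - m0)^2
    sb <- ifelse(w0 == 0 | w1 == 0, -Inf, num / (w0 / n * w1 / n)) / n^2
    k <- which.max(sb)          # ties -> smallest index
    if (eightBit) k - 1 + 0.5 else edges[k + 1L]
}

## 8-connected component labelling by iterative minimum-label propagation.
## Returns an integer matrix with labels 1..k (0 = background).
labelComponents8 <- function(mask) {
    stopifnot(is.matrix(mask))
    nr <- nrow(mask); nc <- ncol(mask)
    lab <- matrix(Inf, nr, nc)
    lab[mask] <- seq_len(sum(mask))
    shift <- function(m, dr, dc) {
        out <- matrix(Inf, nr, nc)
        rs <- seq_len(nr) - dr; cs <- seq_len(nc) - dc
        okR <- rs >= 1 & rs <= nr; okC <- cs >= 1 & cs <= nc
        out[okR, okC] <- m[rs[okR], cs[okC]]
        out
    }
    repeat {
        new <- lab
        for (dr in -1:1) for (dc in -1:1) {
            if (dr == 0 && dc == 0) next
            new <- pmin(new, shift(lab, dr, dc))
        }
        new[!mask] <- Inf
        if (identical(new, lab)) break
        lab <- new
    }
    lab[!mask] <- 0
    u <- sort(unique(lab[lab > 0]))
    out <- matrix(0L, nr, nc)
    out[mask] <- match(lab[mask], u)
    out
}

#' Segment the synapsin channel into ROIs
#'
#' Otsu-thresholds the mask channel, labels 8-connected components and
#' discards those below the minimum area (kept if
#' \code{pixel_count * pixel_size^2 >= minAreaUm2}; the pixel-count cutoff
#' is the smallest integer satisfying this, e.g. 249 px at 14.194 nm and
#' 7 px at 90.2 nm for 0.05 um^2). Quantification is always on raw
#' intensities.
#'
#' @param image a \linkS4class{MultiChannelImage}.
#' @param maskChannel channel defining the masks (default "synapsin").
#' @param minAreaUm2 minimum ROI area in um^2.
#' @param imageId identifier stored in the result.
#' @return a \linkS4class{RoiTable} (means not yet attached; see
#'   [roiMeanLevels()]).
#' @export
segmentSynapsin <- function(image, maskChannel = "synapsin",
                            minAreaUm2 = 0.05, imageId = "image") {
    ch <- getChannel(image, maskChannel)
    ps <- pixelSize(image)
    thr <- otsuThreshold(ch)
    mask <- ch > thr
    lab <- labelComponents8(mask)
    cutoffPx <- minAreaPixelCount(minAreaUm2, ps)
    k <- max(lab)
    keep <- integer(0)
    if (k > 0) {
        cnt <- tabulate(lab[lab > 0], nbins = k)
        keep <- which(cnt >= cutoffPx)
    }
    out <- matrix(0L, nrow(lab), ncol(lab))
    rois <- data.frame(label = integer(0), pixel_count = integer(0),
                       area_um2 = numeric(0), centroid_x_nm = numeric(0),
                       centroid_y_nm = numeric(0))
    if (length(keep)) {
        for (j in seq_along(keep)) out[lab == keep[j]] <- j
        idx <- which(out > 0, arr.ind = TRUE)
        l <- out[out > 0]
        cnt <- tabulate(l, nbins = length(keep))
        cx <- tapply((idx[, "col"] - 0.5) * ps, l, mean)
        cy <- tapply((idx[, "row"] - 0.5) * ps, l, mean)
        rois <- data.frame(label = seq_along(keep), pixel_count = cnt,
                           area_um2 = cnt * ps^2 / 1e6,
                           centroid_x_nm = as.numeric(cx),
                           centroid_y_nm = as.numeric(cy))
    }
    new("RoiTable", rois = rois, labelMatrix = out, imageId = imageId,
        pixelSizeNm = ps,
        imageSummary = stats::setNames(numeric(0), character(0)))
}

#' Smallest pixel count satisfying an area cutoff
#'
#' @param minAreaUm2 area threshold (um^2).
#' @param pixelSizeNm pixel size (nm).
#' @return integer pixel count: the smallest n with
#'   \code{n * pixelSizeNm^2 >= minAreaUm2 * 1e6}.
#' @examples
#' minAreaPixelCount(0.05, 90.2)    # 7
#' minAreaPixelCount(0.05, 14.194)  # 249
#' @export
minAreaPixelCount <- function(minAreaUm2, pixelSizeNm) {
    as.integer(ceiling(round(minAreaUm2 * 1e6 / pixelSizeNm^2, 9)))
}

#' Attach per-ROI mean intensities of a target channel
#'
#' Adds a \code{mean_<channel>} column with the mean raw intensity of the
#' target channel over each ROI's pixels, and sets the per-image summary
#' to the unweighted mean of per-ROI means (each synapse ROI counts once,
#' regardless of size; not the pooled-pixel mean).
#'
#' @param image the same-shaped \linkS4class{MultiChannelImage}.
#' @param rois a \linkS4class{RoiTable} from [segmentSynapsin()].
#' @param targetChannel channel to quantify.
#' @return the augmented \linkS4class{RoiTable}. With an empty ROI table
#'   the image summary is \code{NA} and a warning flags it.
#' @export
roiMeanLevels <- function(image, rois, targetChannel) {
    stopifnot(is(rois, "RoiTable"))
    ch <- getChannel(image, targetChannel)
    if (!identical(dim(ch), dim(rois@labelMatrix)))
        stop("ROI table was derived from a different image shape")
    col <- paste0("mean_", targetChannel)
    if (!nrow(rois@rois)) {
        warning("empty RoiTable: image summary undefined for '",
                targetChannel, "'")
        rois@rois[[col]] <- numeric(0)
        rois@imageSummary[col] <- NA_real_
        return(rois)
    }
    l <- rois@labelMatrix[rois@labelMatrix > 0]
    v <- ch[rois@labelMatrix > 0]
    # tapply orders by sorted label, which is already 1..k
    m <- as.numeric(tapply(v, factor(l, levels = rois@rois$label), mean))
    rois@rois[[col]] <- m
    rois@imageSummary[col] <- mean(m)
    rois
}

#' Donut-shaped somatic ROI mean
#'
#' Mean raw intensity of the target channel over the donut region (outer
#' somatic mask minus nuclear mask); the nuclear mask is intersected with
#' the outer mask first.
#'
#' @param image a \linkS4class{MultiChannelImage}.
#' @param outerMask,nuclearMask logical matrices of image shape.
#' @param targetChannel channel to quantify.
#' @param cellId identifier.
#' @return data.frame (cell_id, n_pixels, mean).
#' @export
somaDonutMean <- function(image, outerMask, nuclearMask, targetChannel,
                          cellId = 1L) {
    ch <- getChannel(image, targetChannel)
    if (!identical(dim(outerMask), dim(ch)) ||
        !identical(dim(nuclearMask), dim(ch)))
        stop("masks must match the image shape")
    donut <- outerMask & !(nuclearMask & outerMask)
    if (!any(donut))
        stop("empty donut ROI for cell ", cellId,
             ": nuclear mask covers the whole somatic mask")
    data.frame(cell_id = cellId, n_pixels = sum(donut),
               mean = mean(ch[donut]))
}

#' @rdname RoiTable-accessors
#' @export
setMethod("roiTable", "RoiTable", function(x) x@rois)

#' @rdname RoiTable-accessors
#' @export
setMethod("roiCount", "RoiTable", function(x) nrow(x@rois))

#' @rdname RoiTable-accessors
#' @export
setMethod("imageSummary", "RoiTable", function(x) x@imageSummary)

setMethod("show", "RoiTable", function(object) {
    cat("RoiTable '", object@imageId, "': ", nrow(object@rois),
        " ROIs at ", sprintf("%.3f", object@pixelSizeNm), " nm/px\n",
        sep = "")
    if (length(object@imageSummary)) {
        cat("  image summary (mean of per-ROI means):\n")
        for (nm in names(object@imageSummary))
            cat("   ", nm, "=", signif(object@imageSummary[[nm]], 6), "\n")
    }
    invisible(NULL)
})

#' Write an ROI table to CSV
#' @param x a \linkS4class{RoiTable}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeRoiTable <- function(x, path) {
    stopifnot(is(x, "RoiTable"))
    utils::write.csv(x@rois, path, row.names = FALSE)
    invisible(path)
}

#' Mask import/export as single-page TIFF
#' @param mask logical matrix.
#' @param path file path.
#' @return \code{readMaskTiff}: logical matrix.
#' @export
writeMaskTiff <- function(mask, path) {
    tiff::writeTIFF(mask * 1, path, bits.per.sample = 8L)
    invisible(path)
}

#' @rdname writeMaskTiff
#' @export
readMaskTiff <- function(path) {
    tiff::readTIFF(path) > 0.5
}
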