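#' Configure the synthetic-imaging generator
#'
#' Builds a validated \linkS4class{SynthConfig}. Defaults emulate the
#' acquisition settings of the quantified experiments: 14.194 nm pixels,
#' a ~60 nm FWHM STED PSF for the PSD-95 and protein-of-interest channels
#' and a ~250 nm FWHM confocal PSF for synapsin. Geometry defaults (bar
#' 400 x 80 nm, vesicle-cloud sigma 200 nm, protein bar offset -50 nm,
#' i.e. on the presynaptic side) are stated assumptions chosen to look
#' like typical cultured-neuron side-view synapses; no measured cloud or
#' bar size is being reproduced.
#'
#' @param imageSizePx integer pair (rows, cols).
#' @param pixelSizeNm pixel edge (nm).
#' @param nSynapses number of synapses (somata in soma mode).
#' @param psdBarLengthNm,psdBarThicknessNm PSD-95 bar size (nm).
#' @param cloudRadiusNm synapsin cloud Gaussian sigma (nm).
#' @param cavOffsetNm signed protein-of-interest offset from the PSD-95 bar
#'   centre along the trans-synaptic axis (nm; negative = presynaptic).
#' @param channelAmplitudes named pre-PSF peak densities (photon scale).
#' @param psfFwhmNm named Gaussian PSF FWHMs (nm).
#' @param backgroundLevel,gaussianReadNoiseSd,poissonNoise noise model.
#' @param somaMode,somaRadiusNm,nucleusRadiusNm somatic-field settings.
#' @param faceOnPsd render round (face-view) PSD-95 blobs instead of bars.
#' @param rngSeed integer seed.
#' @return a \linkS4class{SynthConfig}.
#' @examples
#' cfg <- synthConfig(nSynapses = 2L, rngSeed = 7L)
#' @export
synthConfig <- function(imageSizePx = c(512L, 512L),
                        pixelSizeNm = 14.194,
                        nSynapses = 10L,
                        psdBarLengthNm = 400,
                        psdBarThicknessNm = 80,
                        cloudRadiusNm = 200,
                        cavOffsetNm = -50,
                        channelAmplitudes = c(synapsin = 80, psd95 = 120,
                                              poi = 100),
                        psfFwhmNm = c(synapsin = 250, psd95 = 60, poi = 60),
                        backgroundLevel = 5,
                        gaussianReadNoiseSd = 2,
                        poissonNoise = TRUE,
                        somaMode = FALSE,
                        faceOnPsd = FALSE,
                        somaRadiusNm = 6000,
                        nucleusRadiusNm = 3200,
                        rngSeed = 1L) {
    if (somaMode && missing(channelAmplitudes)) {
        channelAmplitudes <- c(neun = 60, nucleus = 80, ha = 100)
        if (missing(psfFwhmNm))
            psfFwhmNm <- c(neun = 250, nucleus = 250, ha = 250)
        if (missing(pixelSizeNm)) pixelSizeNm <- 90.2
    }
    new("SynthConfig",
        imageSizePx = as.integer(imageSizePx),
        pixelSizeNm = pixelSizeNm,
        nSynapses = as.integer(nSynapses),
        psdBarLengthNm = psdBarLengthNm,
        psdBarThicknessNm = psdBarThicknessNm,
        cloudRadiusNm = cloudRadiusNm,
        cavOffsetNm = cavOffsetNm,
        channelAmplitudes = channelAmplitudes,
        psfFwhmNm = psfFwhmNm,
        backgroundLevel = backgroundLevel,
        gaussianReadNoiseSd = gaussianReadNoiseSd,
        poissonNoise = poissonNoise,
        somaMode = somaMode,
        faceOnPsd = faceOnPsd,
        somaRadiusNm = somaRadiusNm,
        nucleusRadiusNm = nucleusRadiusNm,
        rngSeed = as.integer(rngSeed))
}

## fwhm -> gaussian sigma
fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

## 1-D boxcar of half-width h convolved with a unit-integral Gaussian of
## sigma s, evaluated at t: pnorm((t+h)/s) - pnorm((t-h)/s). s -> 0 gives
## back the indicator.
blurredBox <- function(t, h, s) {
    if (s <= 0) return(as.numeric(abs(t) <= h))
    stats::pnorm((t + h) / s) - stats::pnorm((t - h) / s)
}

## pixel-centre coordinates (nm): pixel (r, c) centre at ((c-.5)ps, (r-.5)ps)
pixelCentres <- function(n, ps) (seq_len(n) - 0.5) * ps

## Add a rectangular bar (length L along 'ebar', thickness T along 'axis'),
## amplitude A pre-blur, convolved with a Gaussian PSF of sigma s, into a
## local window of 'img'. The post-PSF field separates into two blurred
## boxcars in the bar frame, so the render is exact (no grid aliasing).
addBlurredBar <- function(img, ps, cx, cy, axis, A, L, T, s) {
    if (A == 0) return(img)
    e <- c(-axis[2], axis[1])                       # bar long direction
    pad <- 4 * s
    hx <- abs(e[1]) * (L / 2 + pad) + abs(axis[1]) * (T / 2 + pad)
    hy <- abs(e[2]) * (L / 2 + pad) + abs(axis[2]) * (T / 2 + pad)
    nr <- nrow(img); nc <- ncol(img)
    c0 <- max(1L, floor((cx - hx) / ps + 0.5)); c1 <- min(nc, ceiling((cx + hx) / ps + 0.5))
    r0 <- max(1L, floor((cy - hy) / ps + 0.5)); r1 <- min(nr, ceiling((cy + hy) / ps + 0.5))
    if (c0 > c1 || r0 > r1) return(img)
    xs <- pixelCentres(nc, ps)[c0:c1] - cx
    ys <- pixelCentres(nr, ps)[r0:r1] - cy
    u <- outer(ys * e[2], xs * e[1], "+")           # along bar length
    v <- outer(ys * axis[2], xs * axis[1], "+")     # along thickness
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] +
        A * blurredBox(u, L / 2, s) * blurredBox(v, T / 2, s)
    img
}

## Isotropic Gaussian cloud (peak A, sigma sc) convolved with PSF sigma s:
## peak scales by sc^2/(sc^2+s^2), width adds in quadrature.
addBlurredCloud <- function(img, ps, cx, cy, A, sc, s) {
    if (A == 0) return(img)
    st2 <- sc^2 + s^2
    Aeff <- A * sc^2 / st2
    rad <- 5 * sqrt(st2)
    nr <- nrow(img); nc <- ncol(img)
    c0 <- max(1L, floor((cx - rad) / ps + 0.5)); c1 <- min(nc, ceiling((cx + rad) / ps + 0.5))
    r0 <- max(1L, floor((cy - rad) / ps + 0.5)); r1 <- min(nr, ceiling((cy + rad) / ps + 0.5))
    if (c0 > c1 || r0 > r1) return(img)
    xs <- pixelCentres(nc, ps)[c0:c1] - cx
    ys <- pixelCentres(nr, ps)[r0:r1] - cy
    g <- Aeff * outer(exp(-ys^2 / (2 * st2)), exp(-xs^2 / (2 * st2)))
    img[r0:r1, c0:c1] <- img[r0:r1, c0:c1] + g
    img
}

## Hard-edged filled disc sampled at pixel centres (soma mode; optics are
## negligible at the somatic scale so no PSF is applied).
addDisc <- function(img, ps, cx, cy, A, radius) {
    if (A == 0) return(img)
    nr <- nrow(img); nc <- ncol(img)
    xs <- pixelCentres(nc, ps) - cx
    ys <- pixelCentres(nr, ps) - cy
    img + A * (outer(ys^2, xs^2, "+") <= radius^2)
}

## Rejection-sample non-overlapping centres with a border margin.
## minSepNm guards the 1000 x 200 nm profile rectangles (bounding-circle
## radius sqrt(500^2 + 100^2) ~ 510 nm each).
placeCentres <- function(n, sizeNm, marginNm, minSepNm, maxTries) {
    xs <- numeric(0); ys <- numeric(0)
    lowX <- marginNm; highX <- sizeNm[2] - marginNm
    lowY <- marginNm; highY <- sizeNm[1] - marginNm
    if (n > 0L && (highX <= lowX || highY <= lowY))
        stop("field too small for the requested geometry: usable area ",
             "is empty after a ", round(marginNm), " nm border margin")
    tries <- 0L
    while (length(xs) < n) {
        if (tries >= maxTries) {
            dens <- n / prod(sizeNm) * 1e6
            stop(sprintf(
                "could not place %d synapses without ROI overlap after %d tries (requested density %.2f per um^2); use a larger field or fewer synapses",
                n, maxTries, dens))
        }
        tries <- tries + 1L
        x <- stats::runif(1, lowX, highX)
        y <- stats::runif(1, lowY, highY)
        if (!length(xs) || all((xs - x)^2 + (ys - y)^2 >= minSepNm^2)) {
            xs <- c(xs, x); ys <- c(ys, y)
        }
    }
    list(x = xs, y = ys)
}

## Noiseless per-channel render (background included) for given placement.
renderSynapseChannels <- function(config, x, y, ax, ay) {
    chans <- names(config@channelAmplitudes)
    ps <- config@pixelSizeNm
    dims <- config@imageSizePx
    amps <- config@channelAmplitudes
    sig <- fwhmToSigma(config@psfFwhmNm)
    L <- config@psdBarLengthNm; T <- config@psdBarThicknessNm
    n <- length(x)
    out <- lapply(chans, function(ch) {
        img <- matrix(0, dims[1], dims[2])
        for (i in seq_len(n)) {
            a <- c(ax[i], ay[i])
            if (ch == "synapsin") {
                # cloud centre sits one cloud sigma on the presynaptic side
                img <- addBlurredCloud(img, ps,
                    x[i] - config@cloudRadiusNm * a[1],
                    y[i] - config@cloudRadiusNm * a[2],
                    amps[ch], config@cloudRadiusNm, sig[ch])
            } else if (ch == "psd95") {
                if (config@faceOnPsd)
                    img <- addBlurredCloud(img, ps, x[i], y[i],
                                           amps[ch], L / 4, sig[ch])
                else
                    img <- addBlurredBar(img, ps, x[i], y[i], a,
                                         amps[ch], L, T, sig[ch])
            } else if (ch == "poi") {
                off <- config@cavOffsetNm
                img <- addBlurredBar(img, ps,
                                     x[i] + off * a[1],
                                     y[i] + off * a[2],
                                     a, amps[ch], L, T, sig[ch])
            }
            # any further named channels stay background-only
        }
        img + config@backgroundLevel
    })
    names(out) <- chans
    out
}

applyNoiseModel <- function(imgs, config) {
    lapply(imgs, function(img) {
        if (config@poissonNoise)
            img <- matrix(stats::rpois(length(img), img),
                          nrow(img), ncol(img))
        if (config@gaussianReadNoiseSd > 0)
            img <- img + matrix(
                stats::rnorm(length(img), 0, config@gaussianReadNoiseSd),
                nrow(img), ncol(img))
        img
    })
}

synapseFieldFromPlacement <- function(config, x, y, ax, ay) {
    chans <- names(config@channelAmplitudes)
    noisy <- applyNoiseModel(renderSynapseChannels(config, x, y, ax, ay),
                             config)
    modal <- ifelse(chans == "synapsin", "confocal", "STED")
    image <- MultiChannelImage(noisy, channels = chans, modality = modal,
                               pixelSizeNm = config@pixelSizeNm)
    n <- length(x)
    objects <- data.frame(
        id = seq_len(n), x_nm = x, y_nm = y, axis_dx = ax, axis_dy = ay,
        offset_nm = rep(config@cavOffsetNm, n))
    for (ch in chans)
        objects[[paste0("amp_", ch)]] <-
            rep(config@channelAmplitudes[[ch]], n)
    if (n == 0L) objects <- objects[0, , drop = FALSE]
    truth <- new("GroundTruth", objects = objects, config = config,
                 seed = config@rngSeed)
    list(image = image, truth = truth)
}

#' Render a synapse field at prescribed positions
#'
#' Like [generateSynapseField()] but with caller-supplied synapse centres
#' and orientations instead of random placement (noise still follows the
#' config and its seed). Useful for controlled geometry, e.g. rendering
#' the same synapse at two orientations.
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param centersNm numeric matrix or data.frame with columns x, y (nm).
#' @param thetaRad orientation angle per synapse (radians; the
#'   trans-synaptic axis is (cos, sin)).
#' @return list(image, truth) as in [generateSynapseField()].
#' @export
renderSynapseField <- function(config, centersNm, thetaRad) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    centersNm <- as.matrix(centersNm)
    set.seed(config@rngSeed)
    synapseFieldFromPlacement(config, centersNm[, 1], centersNm[, 2],
                              cos(thetaRad), sin(thetaRad))
}

#' Generate a synthetic synapse field with ground truth
#'
#' Renders a multichannel field of side-view synapses: a diffuse synapsin
#' cloud (confocal channel), an elongated PSD-95 bar tangent to the cloud
#' edge (STED), and a protein-of-interest bar parallel to PSD-95 and
#' displaced by \code{cavOffsetNm} along the trans-synaptic axis (STED).
#' Each channel is the exact closed form of the scene density convolved
#' with its Gaussian PSF, plus background, then optional Poisson
#' resampling and Gaussian read noise. Identical config and seed give
#' byte-identical output.
#'
#' @param config a \linkS4class{SynthConfig} (with \code{somaMode = FALSE}).
#' @return list with elements \code{image} (\linkS4class{MultiChannelImage})
#'   and \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' f <- generateSynapseField(synthConfig(nSynapses = 1L, rngSeed = 3L))
#' nSynapses(f$truth)
#' @export
generateSynapseField <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    if (config@somaMode)
        stop("config has somaMode set; use generateSomaField()")
    chans <- names(config@channelAmplitudes)
    need <- c("synapsin", "psd95", "poi")
    if (!all(need %in% chans))
        stop("synapse fields need channels named: ",
             paste(need, collapse = ", "))
    ps <- config@pixelSizeNm
    dims <- config@imageSizePx
    sizeNm <- dims * ps
    set.seed(config@rngSeed)

    margin <- sqrt(500^2 + 100^2) + 2 * ps +
        max(fwhmToSigma(config@psfFwhmNm))
    pos <- placeCentres(config@nSynapses, sizeNm, margin,
                        minSepNm = 1100,
                        maxTries = 400L * max(1L, config@nSynapses))
    n <- config@nSynapses
    theta <- if (n > 0L) stats::runif(n, 0, 2 * pi) else numeric(0)
    synapseFieldFromPlacement(config, pos$x, pos$y, cos(theta), sin(theta))
}

#' Generate a synthetic somatic field with ground truth
#'
#' Renders NeuN-like filled somata, nested nuclear discs and an HA-like
#' channel that is constant within each soma, so the true donut-ROI mean
#' of every cell is known exactly. Per-cell HA amplitudes are drawn
#' uniformly in [0.5, 1.5] times the configured \code{ha} amplitude.
#'
#' @param config a \linkS4class{SynthConfig} with \code{somaMode = TRUE};
#'   channels must include \code{neun}, \code{nucleus} and \code{ha}.
#' @return list with \code{image} and \code{truth} as in
#'   [generateSynapseField()].
#' @export
generateSomaField <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    validObject(config)
    if (!config@somaMode)
        stop("config lacks somaMode; use generateSynapseField()")
    chans <- names(config@channelAmplitudes)
    need <- c("neun", "nucleus", "ha")
    if (!all(need %in% chans))
        stop("soma fields need channels named: ", paste(need, collapse = ", "))
    ps <- config@pixelSizeNm
    dims <- config@imageSizePx
    sizeNm <- dims * ps
    set.seed(config@rngSeed)

    n <- config@nSynapses
    R <- config@somaRadiusNm; rN <- config@nucleusRadiusNm
    pos <- placeCentres(n, sizeNm, marginNm = R + 2 * ps,
                        minSepNm = 2 * R + 4 * ps,
                        maxTries = 400L * max(1L, n))
    amps <- config@channelAmplitudes
    haAmp <- if (n > 0L) amps[["ha"]] * stats::runif(n, 0.5, 1.5) else numeric(0)

    imgs <- list(
        neun = matrix(0, dims[1], dims[2]),
        nucleus = matrix(0, dims[1], dims[2]),
        ha = matrix(0, dims[1], dims[2]))
    for (i in seq_len(n)) {
        imgs$neun <- addDisc(imgs$neun, ps, pos$x[i], pos$y[i],
                             amps[["neun"]], R)
        imgs$nucleus <- addDisc(imgs$nucleus, ps, pos$x[i], pos$y[i],
                                amps[["nucleus"]], rN)
        imgs$ha <- addDisc(imgs$ha, ps, pos$x[i], pos$y[i], haAmp[i], R)
    }
    imgs <- lapply(imgs, function(img) {
        img <- img + config@backgroundLevel
        if (config@poissonNoise)
            img <- matrix(stats::rpois(length(img), img),
                          nrow(img), ncol(img))
        if (config@gaussianReadNoiseSd > 0)
            img <- img + matrix(
                stats::rnorm(length(img), 0, config@gaussianReadNoiseSd),
                nrow(img), ncol(img))
        img
    })
    image <- MultiChannelImage(imgs, channels = names(imgs),
                               modality = "confocal", pixelSizeNm = ps)
    objects <- data.frame(
        id = seq_len(n), x_nm = pos$x, y_nm = pos$y,
        soma_radius_nm = rep(R, n), nucleus_radius_nm = rep(rN, n),
        ha_amplitude = haAmp,
        true_donut_mean = haAmp + config@backgroundLevel)
    if (n == 0L) objects <- objects[0, , drop = FALSE]
    truth <- new("GroundTruth", objects = objects, config = config,
                 seed = config@rngSeed)
    list(image = image, truth = truth)
}

#' @rdname groundTruthTable
#' @export
setMethod("groundTruthTable", "GroundTruth", function(x) x@objects)

#' @rdname nSynapses
#' @export
setMethod("nSynapses", "GroundTruth", function(x) nrow(x@objects))

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:", nrow(object@objects),
        if (object@config@somaMode) "somata" else "synapses",
        "(seed", object@seed, ")\n")
    invisible(NULL)
})

#' Ground-truth synapse annotations
#'
#' Converts a synapse-field \linkS4class{GroundTruth} into the annotation
#' table consumed by [extractProfiles()], with provenance
#' \code{"ground_truth"}.
#'
#' @param truth a \linkS4class{GroundTruth} from [generateSynapseField()].
#' @return data.frame (id, x_nm, y_nm, axis_dx, axis_dy, provenance).
#' @export
annotationsFromTruth <- function(truth) {
    stopifnot(is(truth, "GroundTruth"))
    o <- truth@objects
    data.frame(id = o$id, x_nm = o$x_nm, y_nm = o$y_nm,
               axis_dx = o$axis_dx, axis_dy = o$axis_dy,
               provenance = rep("ground_truth", nrow(o)))
}

#' Circular pixel mask
#'
#' Disc membership of pixel centres; used to build somatic and nuclear
#' masks from ground-truth disc parameters (and handy for manual ROIs).
#'
#' @param dims integer pair (rows, cols).
#' @param centerNm numeric pair (x, y) in nm.
#' @param radiusNm disc radius (nm).
#' @param pixelSizeNm pixel size (nm).
#' @return logical matrix.
#' @export
makeDiscMask <- function(dims, centerNm, radiusNm, pixelSizeNm) {
    xs <- pixelCentres(dims[2], pixelSizeNm) - centerNm[1]
    ys <- pixelCentres(dims[1], pixelSizeNm) - centerNm[2]
    outer(ys^2, xs^2, "+") <= radiusNm^2
}

#' Write generator configuration as YAML
#'
#' @param config a \linkS4class{SynthConfig}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSynthConfig <- function(config, path) {
    sl <- slotNames(config)
    vals <- lapply(sl, function(s) {
        v <- slot(config, s)
        if (!is.null(names(v))) as.list(v) else v
    })
    names(vals) <- sl
    yaml::write_yaml(vals, path)
    invisible(path)
}

#' @rdname writeSynthConfig
#' @export
readSynthConfig <- function(path) {
    vals <- yaml::read_yaml(path)
    do.call(synthConfig, list(
        imageSizePx = as.integer(unlist(vals$imageSizePx)),
        pixelSizeNm = vals$pixelSizeNm,
        nSynapses = vals$nSynapses,
        psdBarLengthNm = vals$psdBarLengthNm,
        psdBarThicknessNm = vals$psdBarThicknessNm,
        cloudRadiusNm = vals$cloudRadiusNm,
        cavOffsetNm = vals$cavOffsetNm,
        channelAmplitudes = unlist(vals$channelAmplitudes),
        psfFwhmNm = unlist(vals$psfFwhmNm),
        backgroundLevel = vals$backgroundLevel,
        gaussianReadNoiseSd = vals$gaussianReadNoiseSd,
        poissonNoise = vals$poissonNoise,
        somaMode = vals$somaMode,
        faceOnPsd = vals$faceOnPsd,
        somaRadiusNm = vals$somaRadiusNm,
        nucleusRadiusNm = vals$nucleusRadiusNm,
        rngSeed = vals$rngSeed))
}
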