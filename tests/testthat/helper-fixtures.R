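# Shared fixtures and independent oracles for the test suite.

# Noiseless single-synapse config on a small field.
quietConfig <- function(..., imageSizePx = c(256L, 256L), nSynapses = 1L,
                        seed = 1L) {
    synthConfig(imageSizePx = imageSizePx, nSynapses = nSynapses,
                poissonNoise = FALSE, gaussianReadNoiseSd = 0,
                rngSeed = seed, ...)
}

# Brute-force Otsu oracle for 8-bit integer data: explicit loop over the
# 256 candidate splits (class1 = values <= t), between-class variance via
# plain means. Returns the smallest maximizing candidate t.
bruteOtsu8bit <- function(x) {
    x <- as.numeric(x)
    best <- -Inf; bestT <- NA_integer_
    n <- length(x)
    for (t in 0:255) {
        lo <- x[x <= t]; hi <- x[x > t]
        if (!length(lo) || !length(hi)) next
        w0 <- length(lo) / n; w1 <- length(hi) / n
        sb <- w0 * w1 * (mean(lo) - mean(hi))^2
        if (sb > best + 1e-12) { best <- sb; bestT <- t }
    }
    bestT
}

# Brute-force centred rolling mean (interior points only).
bruteRollInterior <- function(x, w) {
    h <- (w - 1) %/% 2
    sapply((h + 1):(length(x) - h), function(i) mean(x[(i - h):(i + h)]))
}

# Shift a matrix by whole pixels, padding with its corner value.
shiftMatrix <- function(m, dr, dc) {
    out <- matrix(m[1, 1], nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
        m[seq_len(nrow(m) - dr), seq_len(ncol(m) - dc)]
    out
}

# Rotate a matrix by 90 degrees; new[r, c] = old[c, ncol + 1 - r].
rotateMatrix90 <- function(m) t(m[, rev(seq_len(ncol(m)))])

# Apply shiftMatrix / rotateMatrix90 to every channel of an image.
shiftImage <- function(img, dr, dc) {
    arr <- img@data
    out <- array(0, dim(arr))
    for (k in seq_len(dim(arr)[3])) out[, , k] <- shiftMatrix(arr[, , k], dr, dc)
    MultiChannelImage(out, channelNames(img), img@modality, pixelSize(img))
}

rotateImage90 <- function(img) {
    arr <- img@data
    out <- array(0, c(dim(arr)[2], dim(arr)[1], dim(arr)[3]))
    for (k in seq_len(dim(arr)[3])) out[, , k] <- rotateMatrix90(arr[, , k])
    MultiChannelImage(out, channelNames(img), img@modality, pixelSize(img))
}

# Map an annotation through the rotateMatrix90 coordinate change.
rotateAnnotation90 <- function(ann, img) {
    ncNm <- dim(img)[2] * pixelSize(img)
    out <- ann
    out$x_nm <- ann$y_nm
    out$y_nm <- ncNm - ann$x_nm
    out$axis_dx <- ann$axis_dy
    out$axis_dy <- -ann$axis_dx
    out
}

# Recovered protein-peak position (nm, aligned axis) per synapse.
recoveredOffsets <- function(lps) {
    ap <- alignedPositions(lps)
    pm <- profileMatrices(lps)
    vapply(seq_len(nSynapses(lps)), function(i)
        ap[[i]][which.max(pm[[i]][, "poi"])], numeric(1))
}
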