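test_that("profiles of a constant image are constant", {
    arr <- array(3.5, c(128, 128, 3))
    img <- MultiChannelImage(arr, c("synapsin", "psd95", "poi"),
                             c("confocal", "STED", "STED"), 14.194)
    ann <- data.frame(id = 1L, x_nm = 64 * 14.194, y_nm = 64 * 14.194,
                      axis_dx = cos(0.7), axis_dy = sin(0.7),
                      provenance = "manual")
    lps <- extractProfiles(img, ann)
    expect_equal(nSynapses(lps), 1L)
    expect_true(all(abs(profileMatrices(lps)[[1]] - 3.5) < 1e-12))
    expect_equal(length(profilePositions(lps)), 71L)
    expect_equal(diff(profilePositions(lps))[1], 14.194)
})

test_that("profile sample count follows the pixel size", {
    # ~1000 nm at one sample per pixel, odd count: 71 samples at 14.194 nm
    arr <- array(1.0, c(128, 128, 2))
    img <- MultiChannelImage(arr, c("psd95", "poi"), "STED", 20)
    ann <- data.frame(id = 1L, x_nm = 1280, y_nm = 1280, axis_dx = 1,
                      axis_dy = 0, provenance = "manual")
    lps <- extractProfiles(img, ann)
    expect_equal(length(profilePositions(lps)), 2 * floor(1000 / 40) + 1)
})

test_that("clipped rectangles are excluded with a reason", {
    cfg <- quietConfig(imageSizePx = c(128L, 128L), nSynapses = 0L)
    f <- generateSynapseField(cfg)
    ann <- data.frame(id = c(1L, 2L),
                      x_nm = c(64, 5) * 14.194, y_nm = c(64, 5) * 14.194,
                      axis_dx = 1, axis_dy = 0, provenance = "manual")
    lps <- extractProfiles(f$image, ann)
    expect_equal(nSynapses(lps), 1L)
    expect_equal(excludedSynapses(lps)$id, 2L)
    expect_match(excludedSynapses(lps)$reason, "clipped")
})

test_that("confocal channels are refused as profile channels", {
    arr <- array(1.0, c(64, 64, 2))
    img <- MultiChannelImage(arr, c("psd95", "poi"),
                             c("confocal", "STED"), 14.194)
    ann <- data.frame(id = 1L, x_nm = 450, y_nm = 450, axis_dx = 1,
                      axis_dy = 0, provenance = "manual")
    expect_error(extractProfiles(img, ann), "STED")
})

test_that("rolling average matches the brute-force oracle", {
    expect_equal(rollingMean(c(0, 0, 5, 0, 0), 5)[3], 1)
    x <- rep(2.5, 20)
    expect_equal(rollingMean(x, 5), x)
    set.seed(8)
    y <- rnorm(50)
    sm <- rollingMean(y, 5)
    expect_equal(sm[3:48], bruteRollInterior(y, 5))
    sm7 <- rollingMean(y, 7)
    expect_equal(sm7[4:47], bruteRollInterior(y, 7))
    # shrinking boundary window
    expect_equal(sm[1], mean(y[1:3]))
    expect_equal(sm[50], mean(y[48:50]))
    expect_error(rollingMean(y, 4), "odd")
    expect_error(rollingMean(y[1:3], 5), "exceeds")
})

test_that("alignment places the smoothed PSD-95 maximum at zero", {
    cfg <- quietConfig(seed = 3L)
    f <- generateSynapseField(cfg)
    lps <- alignProfiles(extractProfiles(f$image, annotationsFromTruth(f$truth)))
    ap <- alignedPositions(lps)
    sm <- smoothedPsdTraces(lps)
    for (i in seq_len(nSynapses(lps)))
        expect_identical(ap[[i]][which.max(sm[[i]])], 0)
})

test_that("ties in the smoothed trace resolve to the lowest index", {
    prof <- matrix(0, 71, 2, dimnames = list(NULL, c("psd95", "poi")))
    prof[c(30, 40), "psd95"] <- 10   # symmetric double peak
    lps <- new("LineProfileSet",
               positionsNm = (-35:35) * 14.194,
               profiles = list(prof), smoothedPsd = list(),
               peakIndex = NA_integer_, channels = c("psd95", "poi"),
               psdChannel = "psd95", poiChannel = "poi",
               pixelSizeNm = 14.194,
               annotations = data.frame(id = 1L, x_nm = 0, y_nm = 0,
                                        axis_dx = 1, axis_dy = 0,
                                        provenance = "manual"),
               excluded = data.frame(id = integer(0),
                                     reason = character(0)))
    al <- alignProfiles(lps, window = 1L)
    expect_identical(al@peakIndex, 30L)
    al2 <- alignProfiles(lps, window = 1L)
    expect_identical(al2@peakIndex, al@peakIndex)
})

test_that("flat PSD-95 traces are excluded at alignment", {
    prof <- matrix(1, 71, 2, dimnames = list(NULL, c("psd95", "poi")))
    lps <- new("LineProfileSet",
               positionsNm = (-35:35) * 14.194,
               profiles = list(prof), smoothedPsd = list(),
               peakIndex = NA_integer_, channels = c("psd95", "poi"),
               psdChannel = "psd95", poiChannel = "poi",
               pixelSizeNm = 14.194,
               annotations = data.frame(id = 7L, x_nm = 0, y_nm = 0,
                                        axis_dx = 1, axis_dy = 0,
                                        provenance = "manual"),
               excluded = data.frame(id = integer(0),
                                     reason = character(0)))
    al <- alignProfiles(lps)
    expect_equal(nSynapses(al), 0L)
    expect_match(excludedSynapses(al)$reason, "flat")
})

test_that("whole-pixel translation and 90-degree rotation commute exactly", {
    # dyadic pixel size and width keep every coordinate exactly
    # representable, so grid-aligned equivariance is bitwise
    cfg <- quietConfig(pixelSizeNm = 16, seed = 2L)
    ctr <- matrix(c(128.5, 130.5) * 16, 1)
    f <- renderSynapseField(cfg, ctr, 0)
    ann <- annotationsFromTruth(f$truth)
    p0 <- extractProfiles(f$image, ann, widthNm = 224)

    img2 <- shiftImage(f$image, 7, 5)
    ann2 <- ann
    ann2$x_nm <- ann$x_nm + 5 * 16
    ann2$y_nm <- ann$y_nm + 7 * 16
    p2 <- extractProfiles(img2, ann2, widthNm = 224)
    expect_identical(profileMatrices(p0), profileMatrices(p2))

    img3 <- rotateImage90(f$image)
    ann3 <- rotateAnnotation90(ann, f$image)
    p3 <- extractProfiles(img3, ann3, widthNm = 224)
    expect_identical(profileMatrices(p0), profileMatrices(p3))

    # aligned profiles inherit the bit-identity
    a0 <- alignProfiles(p0); a3 <- alignProfiles(p3)
    expect_identical(a0@peakIndex, a3@peakIndex)
    expect_identical(smoothedPsdTraces(a0), smoothedPsdTraces(a3))
})

test_that("arbitrary rotations change profiles by less than 1 percent", {
    cfg <- quietConfig(seed = 2L)
    ctr <- matrix(c(128.37, 130.81) * 14.194, 1)
    f0 <- renderSynapseField(cfg, ctr, 0)
    p0 <- extractProfiles(f0$image, annotationsFromTruth(f0$truth))
    m0 <- profileMatrices(p0)[[1]]
    for (th in c(0.3, 0.9, 1.7, 2.6)) {
        fx <- renderSynapseField(cfg, ctr, th)
        px <- extractProfiles(fx$image, annotationsFromTruth(fx$truth))
        mx <- profileMatrices(px)[[1]]
        for (ch in c("psd95", "poi", "synapsin")) {
            rel <- max(abs(mx[, ch] - m0[, ch])) / max(abs(m0[, ch]))
            expect_lt(rel, 0.01)
        }
    }
})

test_that("translation of the scene leaves aligned profiles unchanged", {
    cfg <- quietConfig(seed = 2L)
    f1 <- renderSynapseField(cfg, matrix(c(120.3, 121.9) * 14.194, 1), 0.8)
    f2 <- renderSynapseField(cfg,
                             matrix(c(130.3, 131.9) * 14.194, 1), 0.8)
    a1 <- alignProfiles(extractProfiles(f1$image,
                                        annotationsFromTruth(f1$truth)))
    a2 <- alignProfiles(extractProfiles(f2$image,
                                        annotationsFromTruth(f2$truth)))
    expect_identical(a1@peakIndex, a2@peakIndex)
    expect_equal(profileMatrices(a1)[[1]], profileMatrices(a2)[[1]],
                 tolerance = 1e-9)
})

test_that("summaries average aligned profiles and window the peaks", {
    cfg <- quietConfig(nSynapses = 4L, seed = 17L)
    f <- generateSynapseField(cfg)
    lps <- alignProfiles(extractProfiles(f$image,
                                         annotationsFromTruth(f$truth)))
    sm <- summarizeProfiles(lps)
    # peak window at 14.194 nm/px: 15 samples, +/-7 around zero
    inWin <- abs(sm@gridNm) <= 100 + 1e-9
    expect_equal(sum(inWin), 15L)
    expect_equal(range(sm@gridNm[inWin] / 14.194), c(-7, 7))
    # SEM defined only where >= 2 synapses contribute
    expect_true(all(is.na(sm@semProfile[sm@nContributing < 2])))
    expect_true(all(!is.na(sm@semProfile[sm@nContributing >= 2])))

    # single synapse: mean profile equals the profile, SEM undefined
    one <- alignProfiles(extractProfiles(
        f$image, annotationsFromTruth(f$truth)[1, , drop = FALSE]))
    sm1 <- summarizeProfiles(one)
    expect_true(all(is.na(sm1@semProfile)))
    prof <- profileMatrices(one)[[1]]
    prof[, "psd95"] <- smoothedPsdTraces(one)[[1]]
    expect_equal(unname(sm1@meanProfile), unname(prof))
    expect_error(summarizeProfiles(
        alignProfiles(extractProfiles(f$image,
                      annotationsFromTruth(f$truth)[0, , drop = FALSE]))),
        "no synapses")
})

test_that("peak of the mean profile never exceeds the mean of peaks", {
    for (seed in c(1L, 5L, 9L)) {
        cfg <- synthConfig(imageSizePx = c(512L, 512L), nSynapses = 8L,
                           rngSeed = seed)
        f <- generateSynapseField(cfg)
        lps <- alignProfiles(extractProfiles(f$image,
                                             annotationsFromTruth(f$truth)))
        sm <- summarizeProfiles(lps)
        inWin <- abs(sm@gridNm) <= sm@windowNm / 2 + 1e-9
        maxOfMean <- max(sm@meanProfile[inWin, "poi"])
        meanOfMax <- mean(peakTable(sm)$poi_peak)
        expect_lte(maxOfMean, meanOfMax + 1e-12)
    }
})

test_that("noiseless offset recovery is within one sample step", {
    cfg <- quietConfig(imageSizePx = c(512L, 512L), nSynapses = 6L,
                       cavOffsetNm = -50, seed = 23L)
    f <- generateSynapseField(cfg)
    lps <- alignProfiles(extractProfiles(f$image,
                                         annotationsFromTruth(f$truth)))
    rec <- recoveredOffsets(lps)
    expect_true(all(abs(rec - (-50)) <= 14.194 + 1e-9))
})

test_that("window peak intensity increases with generator amplitude", {
    amps <- c(25, 50, 100, 150)
    med <- vapply(amps, function(a) {
        cfg <- synthConfig(imageSizePx = c(512L, 512L), nSynapses = 10L,
                           channelAmplitudes = c(synapsin = 80, psd95 = 120,
                                                 poi = a),
                           rngSeed = 51L)
        f <- generateSynapseField(cfg)
        lps <- alignProfiles(extractProfiles(f$image,
                                             annotationsFromTruth(f$truth)))
        mean(peakTable(summarizeProfiles(lps))$poi_peak)
    }, numeric(1))
    expect_true(all(diff(med) > 0))
    # slope vs the noiseless unit response, after background offset
    unit <- quietConfig(channelAmplitudes = c(synapsin = 80, psd95 = 120,
                                              poi = 1),
                        backgroundLevel = 0, seed = 51L)
    fu <- renderSynapseField(unit, matrix(c(128.32, 128.71) * 14.194, 1),
                             0.6)
    lu <- alignProfiles(extractProfiles(fu$image,
                                        annotationsFromTruth(fu$truth)))
    unitPeak <- peakTable(summarizeProfiles(lu))$poi_peak
    slope <- stats::coef(stats::lm(med ~ amps))[["amps"]]
    expect_lt(abs(slope - unitPeak) / unitPeak, 0.1)
})

test_that("the detector finds side-view synapses and rejects face-on ones", {
    cfg <- quietConfig(imageSizePx = c(512L, 512L), nSynapses = 5L,
                       seed = 11L)
    f <- generateSynapseField(cfg)
    ann <- detectSideView(f$image)
    tr <- groundTruthTable(f$truth)
    expect_equal(nrow(ann), 5L)
    for (i in seq_len(nrow(tr))) {
        d <- sqrt((ann$x_nm - tr$x_nm[i])^2 + (ann$y_nm - tr$y_nm[i])^2)
        j <- which.min(d)
        expect_lt(d[j], 100)
        cosang <- ann$axis_dx[j] * tr$axis_dx[i] +
            ann$axis_dy[j] * tr$axis_dy[i]
        expect_gt(cosang, cos(15 * pi / 180))  # axis and sign agree
    }
    # empty field (noise only, so Otsu still has two levels):
    # empty annotation list, not an error
    expect_equal(nrow(detectSideView(generateSynapseField(
        synthConfig(imageSizePx = c(256L, 256L), nSynapses = 0L,
                    rngSeed = 3L))$image)), 0L)
    # face-on synapses (round PSD-95 blobs) are rejected
    fc <- generateSynapseField(quietConfig(imageSizePx = c(512L, 512L),
                                           nSynapses = 5L, seed = 11L,
                                           faceOnPsd = TRUE))
    expect_equal(nrow(detectSideView(fc$image)), 0L)
})
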