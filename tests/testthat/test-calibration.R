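makeBundle <- function(raw, white, dark, wl = NULL) {
    if (is.null(wl)) wl <- seq(500, by = 10, length.out = dim(raw)[3])
    new("RawCubeBundle", raw = raw, white = white, dark = dark,
        wavelengths = wl)
}

test_that("reflectance calibration identities hold", {
    d <- c(3L, 4L, 2L)
    white <- c(4000, 3000)
    dark <- c(100, 80)
    whiteCube <- array(rep(white, each = 12), dim = d)
    darkCube <- array(rep(dark, each = 12), dim = d)
    # raw == white -> 1 everywhere; raw == dark -> 0; midpoint -> 0.5
    expect_equal(calibrateCube(makeBundle(whiteCube, white, dark))@reflectance,
                 array(1, dim = d))
    expect_equal(calibrateCube(makeBundle(darkCube, white, dark))@reflectance,
                 array(0, dim = d))
    mid <- (whiteCube + darkCube) / 2
    expect_equal(calibrateCube(makeBundle(mid, white, dark))@reflectance,
                 array(0.5, dim = d))
    # full-frame references broadcast identically
    expect_equal(calibrateCube(makeBundle(mid, whiteCube, darkCube))@reflectance,
                 array(0.5, dim = d))
})

test_that("calibration is invariant to affine rescaling of the counts", {
    set.seed(4)
    d <- c(3L, 3L, 4L)
    raw <- array(runif(prod(d), 500, 3500), dim = d)
    white <- runif(d[3], 3800, 4000)
    dark <- runif(d[3], 50, 120)
    base <- calibrateCube(makeBundle(raw, white, dark))@reflectance
    a <- 3.7; cc <- 211
    scaled <- calibrateCube(makeBundle(a * raw + cc, a * white + cc,
                                       a * dark + cc))@reflectance
    expect_equal(scaled, base, tolerance = 1e-12)
})

test_that("zero calibration denominators are masked, not propagated", {
    d <- c(2L, 2L, 2L)
    raw <- array(200, dim = d)
    white <- array(400, dim = d)
    dark <- array(100, dim = d)
    white[1, 1, 1] <- 100  # white == dark at one pixel-band
    suppressMessages(cube <- calibrateCube(makeBundle(raw, white, dark)))
    expect_true(cube@mask[1, 1, 1])
    expect_true(is.na(cube@reflectance[1, 1, 1]))
    expect_false(anyNA(cube@reflectance[, , 2]))
    # masked pixels are excluded from ROI means
    rois <- data.frame(sample_id = "s1", center_x = 0.5, center_y = 0.5,
                       semi_x = 1.5, semi_y = 1.5, rotation = 0)
    sp <- extractROIMeans(cube, rois)
    expect_equal(unname(spectraMatrix(sp)[1, ]), c(1 / 3, 1 / 3))
    # an all-reference cube cannot be calibrated
    expect_error(calibrateCube(makeBundle(raw, array(100, d), array(100, d))),
                 "calibration failure")
})

test_that("ROI means are exact on constant and two-pixel regions", {
    cube <- constantCube(0.5)
    rois <- data.frame(sample_id = "s1", center_x = 2, center_y = 1.5,
                       semi_x = 1.8, semi_y = 1.2, rotation = 0)
    expect_true(all(spectraMatrix(extractROIMeans(cube, rois)) == 0.5))
    # two pixels with band values 0.2 and 0.4 average to 0.3
    cube2 <- constantCube(0, H = 1L, W = 4L, B = 1L)
    cube2@reflectance[1, 1, 1] <- 0.2
    cube2@reflectance[1, 2, 1] <- 0.4
    roi2 <- data.frame(sample_id = "s2", center_x = 0.5, center_y = 0,
                       semi_x = 0.6, semi_y = 0.5, rotation = 0)
    expect_equal(unname(spectraMatrix(extractROIMeans(cube2, roi2))[1, 1]), 0.3)
    # an ellipse that covers no pixel center errors with the sample name
    roiEmpty <- data.frame(sample_id = "ghost", center_x = 1.5, center_y = 1.5,
                           semi_x = 0.3, semi_y = 0.3, rotation = 0)
    expect_error(extractROIMeans(constantCube(1), roiEmpty), "ghost")
})

test_that("ellipse pixel membership approximates the continuous area", {
    m <- vigorspec:::.ellipseMask(40, 40, 20, 20, 3, 2, 0)
    # brute-force oracle: count integer centers inside (x/3)^2 + (y/2)^2 <= 1
    cnt <- 0L
    for (x in -4:4) for (y in -3:3)
        if ((x / 3)^2 + (y / 2)^2 <= 1) cnt <- cnt + 1L
    expect_identical(sum(m), cnt)
    expect_lt(abs(sum(m) - pi * 3 * 2) / (pi * 3 * 2), 0.15)
    # rotating a circle changes nothing; rotating the ellipse 90 deg swaps axes
    expect_identical(vigorspec:::.ellipseMask(40, 40, 20, 20, 3, 2, 90),
                     vigorspec:::.ellipseMask(40, 40, 20, 20, 2, 3, 0))
})

test_that("ROI mean is linear in the cube values", {
    set.seed(8)
    cube <- constantCube(0, H = 10L, W = 10L, B = 3L)
    cube@reflectance <- array(runif(300), dim = c(10, 10, 3))
    rois <- data.frame(sample_id = "s1", center_x = 4, center_y = 4,
                       semi_x = 3, semi_y = 2, rotation = 15)
    m1 <- spectraMatrix(extractROIMeans(cube, rois))
    cube2 <- cube
    cube2@reflectance <- 2 * cube@reflectance + 0.1
    m2 <- spectraMatrix(extractROIMeans(cube2, rois))
    expect_equal(m2, 2 * m1 + 0.1, tolerance = 1e-12)
})

test_that("band windowing keeps the closed interval and is idempotent", {
    ds <- SeedSpectra(matrix(runif(8), 2), wavelengths = c(10, 20, 30, 40))
    expect_equal(wavelengths(windowBands(ds, 15, 35)), c(20, 30))
    expect_equal(wavelengths(windowBands(ds, 10, 40)), c(10, 20, 30, 40))
    expect_equal(wavelengths(windowBands(ds, 20, 20)), 20)
    w1 <- windowBands(ds, 15, 35)
    expect_equal(spectraMatrix(windowBands(w1, 15, 35)), spectraMatrix(w1))
    expect_error(windowBands(ds, 41, 45), "empty window")
    # the default window on the 256-band instrument grid
    full <- SeedSpectra(matrix(runif(2 * 256), 2),
                        wavelengths = makeWavelengthGrid(256, 386.7, 1016.7))
    win <- windowBands(full)
    expect_true(all(wavelengths(win) >= 430.1 & wavelengths(win) <= 971.5))
    expect_gt(nrow(win), 200)
})

test_that("cube round-trip recovers the simulated spectra", {
    cfg <- noiselessLinearConfig(seed = 21, nSeeds = 6L, nBands = 25L)
    cr <- simulateCube(cfg)
    suppressMessages(cube <- calibrateCube(cr$bundle))
    got <- spectraMatrix(extractROIMeans(cube, cr$rois))
    want <- spectraMatrix(simulateSpectra(cfg))
    expect_lt(max(abs(got - want)), 1e-6)
})
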