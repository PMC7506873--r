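asSpectra <- function(X) SeedSpectra(X, wavelengths = seq(500,
    by = 10, length.out = ncol(X)))

test_that("band-trait correlation matches hand-computed Pearson values", {
    expect_equal(bandTraitCorrelation(asSpectra(cbind(1:3)), c(2, 4, 6))@scores,
                 1, tolerance = 1e-12)
    expect_equal(bandTraitCorrelation(asSpectra(cbind(1:3)), c(3, 2, 1))@scores,
                 -1, tolerance = 1e-12)
    expect_equal(bandTraitCorrelation(asSpectra(cbind(1:4)),
                                      c(1, 3, 2, 4))@scores,
                 0.8, tolerance = 1e-12)
    expect_error(bandTraitCorrelation(asSpectra(cbind(1:2)), c(1, 2)),
                 "at least 3")
    expect_error(bandTraitCorrelation(asSpectra(cbind(1:4)), rep(2, 4)),
                 "degenerate target")
    expect_warning(
        sc <- bandTraitCorrelation(asSpectra(cbind(1:4, rep(1, 4))),
                                   c(1, 3, 2, 4)),
        "zero-variance")
    expect_equal(sc@scores[2], 0)
})

test_that("correlation scores are invariant to affine rescaling", {
    set.seed(2)
    X <- matrix(rnorm(60), 12, 5)
    y <- rnorm(12)
    base <- bandTraitCorrelation(asSpectra(X), y)@scores
    X2 <- X
    X2[, 3] <- -2.5 * X[, 3] + 7
    flipped <- bandTraitCorrelation(asSpectra(X2), y)@scores
    expect_equal(flipped[3], -base[3], tolerance = 1e-12)
    expect_equal(flipped[-3], base[-3], tolerance = 1e-12)
    expect_equal(bandTraitCorrelation(asSpectra(X), 4 * y + 2)@scores, base,
                 tolerance = 1e-12)
})

test_that("correlation ranking keeps the largest |score| with stable ties", {
    mk <- function(s) new("BandScores", bandIndices = seq_along(s),
                          wavelengths = 500 + 10 * seq_along(s), scores = s,
                          trait = "root_length")
    expect_equal(selectedBands(hccSelect(mk(c(0.9, -0.95, 0.1)), k = 2)),
                 c(2L, 1L))
    expect_equal(selectedBands(hccSelect(mk(c(0.5, 0.5, -0.5)), k = 2)),
                 c(1L, 2L))
    all3 <- hccSelect(mk(c(0.2, -0.6, 0.4)), k = 3)
    expect_equal(selectedBands(all3), c(2L, 3L, 1L))
    expect_equal(selectedBands(hccSelect(mk(c(0.2, -0.6, 0.4)), k = 10)),
                 c(2L, 3L, 1L))
})

test_that("ranking is nested: top-k is a subset of top-(k+1)", {
    set.seed(3)
    ds <- tinySpectra(n = 15, p = 9, seed = 3)
    y <- rnorm(15)
    sc <- bandTraitCorrelation(ds, y)
    for (k in 1:8)
        expect_true(all(selectedBands(hccSelect(sc, k)) %in%
                        selectedBands(hccSelect(sc, k + 1L))))
})

test_that("SPA follows the projection geometry on a hand example", {
    X <- cbind(a = c(2, 0), b = c(0, 1), c = c(2, 0))
    ds <- asSpectra(X)
    expect_equal(selectedBands(spaSelect(ds, m = 1, start = 1)), 1L)
    # after selecting column a, c projects to zero and b keeps norm 1
    expect_equal(selectedBands(spaSelect(ds, m = 2, start = 1)), c(1L, 2L))
})

test_that("SPA agrees with an explicit least-squares projection oracle", {
    for (seed in 1:4) {
        set.seed(seed)
        p <- sample(4:6, 1)
        X <- matrix(rnorm(8 * p), 8, p)
        ds <- asSpectra(X)
        for (s in seq_len(p)) {
            m <- p - 1L
            expect_equal(selectedBands(spaSelect(ds, m = m, start = s)),
                         spaOracleChain(X, s, m),
                         info = sprintf("seed %d start %d", seed, s))
        }
    }
})

test_that("SPA-selected columns are linearly independent", {
    set.seed(9)
    X <- matrix(rnorm(20 * 10), 20, 10)
    X[, 7] <- X[, 1] * 2  # an exact duplicate direction
    sel <- selectedBands(spaSelect(asSpectra(X), m = 6, start = 1))
    expect_equal(qr(X[, sel])$rank, length(sel))
    expect_false(all(c(1L, 7L) %in% sel))
})

test_that("automatic SPA start requires y and respects the size grid", {
    ds <- tinySpectra(n = 20, p = 8, seed = 5)
    y <- rowSums(spectraMatrix(ds)[, c(2, 6)]) + rnorm(20, 0, 0.05)
    expect_error(spaSelect(ds, m = 3, start = "auto"), "required")
    expect_error(spaSelect(ds, m = 50, start = 1), "invalid config")
    res <- spaSelect(ds, m = c(2, 3, 4), start = "auto", y = y)
    expect_true(length(selectedBands(res)) %in% c(2, 3, 4))
    expect_true(is.finite(res@diagnostics$looRmse))
})

test_that("GA is deterministic, monotone under elitism, and benefits from seeding", {
    ds <- tinySpectra(n = 30, p = 12, seed = 6)
    y <- drop(spectraMatrix(ds)[, c(3, 9)] %*% c(1, -1)) + rnorm(30, 0, 0.02)
    g1 <- gaSelect(ds, y, kMax = 4, generations = 10, popSize = 12, rngSeed = 7)
    g2 <- gaSelect(ds, y, kMax = 4, generations = 10, popSize = 12, rngSeed = 7)
    expect_identical(selectedBands(g1), selectedBands(g2))
    expect_identical(g1@diagnostics$trajectory, g2@diagnostics$trajectory)
    # best-ever fitness never decreases
    expect_true(all(diff(g1@diagnostics$trajectory) >= 0))
    # seeding the true mask into the population: elitism keeps its fitness
    truth <- rep(FALSE, 12); truth[c(3, 9)] <- TRUE
    g3 <- gaSelect(ds, y, kMax = 4, generations = 10, popSize = 12,
                   rngSeed = 7, initPop = matrix(truth, nrow = 1))
    f0 <- vigorspec:::.gaFitness(spectraMatrix(ds), y, truth, 4L)
    expect_gte(g3@diagnostics$fitness, f0)
})

test_that("all three selectors put a lone noiseless signal band first", {
    cfg <- sharpSignalConfig(seed = 13, bands = 30L, effects = 50)
    st <- simulateStudy(cfg)
    ds <- spectra(st)
    y <- traitVector(ds, "root_length")
    expect_equal(selectedBands(hccSelect(bandTraitCorrelation(ds, y), 1))[1],
                 30L)
    expect_equal(selectedBands(spaSelect(ds, m = 1, start = "auto", y = y)),
                 30L)
    ga <- gaSelect(ds, y, kMax = 3, generations = 25, popSize = 20,
                   rngSeed = 17)
    expect_true(30L %in% selectedBands(ga))
})
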