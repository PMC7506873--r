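# Small in-code fixtures shared across the suite.

tinySpectra <- function(n = 10L, p = 6L, seed = 1L, traits = NULL) {
    set.seed(seed)
    X <- matrix(runif(n * p, 0.2, 0.8), n, p)
    SeedSpectra(X, wavelengths = seq(500, 500 + 10 * (p - 1), by = 10),
                traits = traits)
}

# Noiseless linear-link study: traits exactly linear in the spectra.
# Informative bands scale with the grid so small fixtures stay valid.
noiselessLinearConfig <- function(seed = 1L, nSeeds = 40L, nBands = 30L) {
    at <- function(f) max(1L, min(nBands, as.integer(round(f * nBands))))
    simulationConfig(
        nSeeds = nSeeds, nBands = nBands,
        wavelengthStart = 400, wavelengthEnd = 900,
        spectralNoiseSd = 0, albedoSd = 0.05, slopeSd = 0.02,
        amplitudeSd = 0.1, bumpWidth = 2,
        traits = list(
            root_length = traitSpec(bands = c(at(0.27), at(0.67)),
                                    effects = c(40, 35),
                                    link = "linear", noiseSd = 0,
                                    intercept = 10),
            seedling_length = traitSpec(bands = c(at(0.17), at(0.83)),
                                        effects = c(30, 25), link = "linear",
                                        noiseSd = 0, intercept = 20)),
        rngSeed = seed)
}

# Sharp, well-separated informative bands with no shared baseline variation:
# the construction under which band-trait correlation is maximal exactly at
# the informative bands.
sharpSignalConfig <- function(seed = 1L, bands = c(15L, 30L, 45L),
                              effects = c(50, 45, 55), noiseSd = 0) {
    simulationConfig(
        nSeeds = 300L, nBands = 60L, wavelengthStart = 400,
        wavelengthEnd = 900, spectralNoiseSd = 0.03, albedoSd = 0,
        slopeSd = 0, amplitudeSd = 0.1, bumpWidth = 0.6,
        traits = list(root_length = traitSpec(bands = bands,
            effects = effects, link = "linear", noiseSd = noiseSd,
            intercept = 60)),
        rngSeed = seed)
}

# n = 200 linear-link recovery conditions: 3 informative bands among 50,
# trait noise set for a 5:1 signal-to-noise variance ratio.
recoveryStudy <- function(seed, snr = 5) {
    cfg <- simulationConfig(
        nSeeds = 200L, nBands = 50L, wavelengthStart = 430, wavelengthEnd = 970,
        spectralNoiseSd = 0.02, albedoSd = 0.03, slopeSd = 0.02,
        amplitudeSd = 0.1, bumpWidth = 0.6,
        traits = list(root_length = traitSpec(bands = c(10L, 25L, 40L),
            effects = c(60, -50, 55), link = "linear", noiseSd = 0,
            intercept = 60)),
        rngSeed = seed)
    y0 <- simulateTraits(simulateSpectra(cfg), cfg)$root_length
    cfg$traits$root_length$noiseSd <- sd(y0) / sqrt(snr)
    simulateStudy(cfg)
}

# Uniform small cube with per-band references.
constantCube <- function(value, H = 4L, W = 5L, B = 3L) {
    new("ReflectanceCube",
        reflectance = array(value, dim = c(H, W, B)),
        wavelengths = seq(500, by = 10, length.out = B),
        mask = array(FALSE, dim = c(H, W, B)))
}

# Fast pipeline configuration for grid-structure tests.
smallPipeline <- function(masterSeed = 1L, dataset = NULL, simulation = NULL,
                          qMax = 5L) {
    if (is.null(dataset) && is.null(simulation)) {
        simulation <- noiselessLinearConfig()
        simulation$traits$root_length$noiseSd <- 2
        simulation$traits$seedling_length$noiseSd <- 3
    }
    pipelineConfig(simulation = simulation, dataset = dataset,
                   windowLow = 400, windowHigh = 900, nTrain = 30L,
                   hccK = 15L, spaSizes = c(3L, 5L), gaKMax = 8L,
                   gaGenerations = 15L, gaPopSize = 16L, qMax = qMax,
                   masterSeed = masterSeed)
}

# Independent SPA oracle: greedy chain where each step projects every
# remaining column on the orthogonal complement of the selected set via an
# explicit least-squares fit (lm.fit), not the package's recursive update.
spaOracleChain <- function(X, start, m) {
    sel <- start
    while (length(sel) < m) {
        rest <- setdiff(seq_len(ncol(X)), sel)
        norms <- vapply(rest, function(j) {
            r <- stats::lm.fit(X[, sel, drop = FALSE], X[, j])$residuals
            sum(r^2)
        }, numeric(1))
        sel <- c(sel, rest[which.max(norms)])
    }
    sel
}
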