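#' Evenly spaced wavelength grid
#'
#' The instrument grid is modelled as uniform between the stated endpoints;
#' real pushbroom cameras have slightly irregular spacing, but the exact grid
#' is rarely published, and a uniform grid keeps fixtures reproducible.
#'
#' @param nBands number of bands (>= 2).
#' @param startNm,endNm first and last band centers in nm, start < end.
#' @return strictly increasing numeric vector of length \code{nBands} whose
#'   first and last elements equal the stated endpoints.
#' @examples
#' makeWavelengthGrid(3, 0, 10)  # 0 5 10
#' @export
makeWavelengthGrid <- function(nBands, startNm, endNm) {
    nBands <- .assertCount(nBands, "nBands", min = 2L)
    if (!is.finite(startNm) || !is.finite(endNm) || startNm >= endNm)
        stop("invalid config: 'startNm' must be strictly less than 'endNm'")
    seq(startNm, endNm, length.out = nBands)
}

#' Specification of one simulated germination trait
#'
#' Each trait is driven by the spectrum values at a sparse set of informative
#' bands through a linear predictor t_i = sum_b effect_b * x_ib.  With
#' \code{link = "linear"} the trait is \code{intercept + t + eps}; with
#' \code{link = "nonlinear"} it is a scaled logistic of the standardized
#' predictor, \code{intercept + scale * plogis(gain * (z(t) - center)) + eps},
#' a smooth monotone saturating response.  A nonzero \code{center} places the
#' logistic midpoint off the population mean, so the population sits on the
#' curved shoulder of the saturation rather than its locally-linear middle —
#' the regime in which vigorous seeds plateau while weak seeds spread out.
#' Noise is Gaussian with sd \code{noiseSd} and traits are truncated at zero
#' (lengths are nonnegative).
#'
#' @param bands integer indices (1-based, on the full simulated grid) of the
#'   informative bands.
#' @param effects numeric effect size per informative band (trait units per
#'   reflectance unit).
#' @param link "linear" or "nonlinear".
#' @param noiseSd trait-unit noise standard deviation (>= 0).
#' @param intercept baseline trait value (trait units, default 0).
#' @param scale,gain logistic-link amplitude (trait units) and steepness
#'   (per standardized-predictor unit); ignored for the linear link.
#' @param center logistic midpoint in standardized-predictor units (default
#'   0, the symmetric case); ignored for the linear link.
#' @return a list with class checked by \code{\link{simulationConfig}}.
#' @export
traitSpec <- function(bands, effects, link = c("linear", "nonlinear"),
                      noiseSd = 0, intercept = 0, scale = 50, gain = 3,
                      center = 0) {
    link <- match.arg(link)
    list(bands = as.integer(bands), effects = as.numeric(effects),
         link = link, noiseSd = noiseSd, intercept = intercept,
         scale = scale, gain = gain, center = center)
}

#' Configuration of a synthetic seed-vigor study
#'
#' Describes the simulated instrument (band count, wavelength range), the
#' population of seeds (smooth reflectance baselines with seed-to-seed
#' albedo/slope variation), the informative-band structure linking spectra
#' to traits, and the cube-fixture geometry.
#'
#' @param nSeeds number of seeds.
#' @param nBands number of spectral bands (>= 2).
#' @param wavelengthStart,wavelengthEnd grid endpoints in nm.
#' @param traits named list of \code{\link{traitSpec}} entries (default
#'   names: \code{root_length}, \code{seedling_length}).
#' @param spectralNoiseSd per-band iid measurement noise on reflectance.
#' @param albedoSd sd of the per-seed flat reflectance offset.
#' @param slopeSd sd of the per-seed spectral slope component.
#' @param amplitudeSd sd of the per-seed amplitude of each informative-band
#'   perturbation (reflectance units); these amplitudes are the latent
#'   variables that drive the traits.
#' @param bumpWidth width (in bands, Gaussian sd) of each informative-band
#'   perturbation.
#' @param cubeHeight,cubeWidth cube fixture dimensions in pixels (optional;
#'   derived from the seed layout when NULL).
#' @param rngSeed integer seed; identical configurations yield bit-identical
#'   studies.
#' @return validated configuration list.
#' @export
simulationConfig <- function(nSeeds, nBands,
                             wavelengthStart = 386.7, wavelengthEnd = 1016.7,
                             traits = NULL,
                             spectralNoiseSd = 0.002, albedoSd = 0.12,
                             slopeSd = 0.05, amplitudeSd = 0.10,
                             bumpWidth = 12,
                             cubeHeight = NULL, cubeWidth = NULL,
                             rngSeed = 1L) {
    nSeeds <- .assertCount(nSeeds, "nSeeds")
    nBands <- .assertCount(nBands, "nBands", min = 2L)
    if (wavelengthStart >= wavelengthEnd)
        stop("invalid config: wavelengthStart must be < wavelengthEnd")
    if (is.null(traits))
        traits <- list(root_length = traitSpec(bands = max(1L, nBands %/% 2L),
                                               effects = 50, noiseSd = 1))
    if (is.null(names(traits)) || any(!nzchar(names(traits))))
        stop("invalid config: 'traits' must be a named list")
    for (nm in names(traits)) {
        tr <- traits[[nm]]
        if (length(tr$bands) != length(tr$effects))
            stop(sprintf("invalid config: trait '%s' needs one effect per informative band", nm))
        if (any(tr$bands < 1L) || any(tr$bands > nBands))
            stop(sprintf("invalid config: trait '%s' has informative bands outside 1..%d",
                         nm, nBands))
        if (tr$noiseSd < 0)
            stop(sprintf("invalid config: trait '%s' has negative noiseSd", nm))
    }
    if (spectralNoiseSd < 0 || albedoSd < 0 || slopeSd < 0 || amplitudeSd < 0)
        stop("invalid config: spread parameters must be nonnegative")
    structure(list(nSeeds = nSeeds, nBands = nBands,
                   wavelengthStart = wavelengthStart,
                   wavelengthEnd = wavelengthEnd, traits = traits,
                   spectralNoiseSd = spectralNoiseSd, albedoSd = albedoSd,
                   slopeSd = slopeSd, amplitudeSd = amplitudeSd,
                   bumpWidth = bumpWidth, cubeHeight = cubeHeight,
                   cubeWidth = cubeWidth, rngSeed = as.integer(rngSeed)),
              class = "vigorspec_config")
}

# Band index nearest a target wavelength on a config's grid.
.bandAt <- function(config, nm) {
    wl <- makeWavelengthGrid(config$nBands, config$wavelengthStart,
                             config$wavelengthEnd)
    which.min(abs(wl - nm))
}

#' Default synthetic study configuration
#'
#' The stock conditions used throughout the package's examples and checks:
#' 89 seeds imaged over 256 bands spanning 386.7-1016.7 nm, two germination
#' traits through a saturating (logistic) link, with root length tied to
#' mid/high-wavelength bands at larger effect sizes and seedling length tied
#' to low-wavelength bands at smaller effect sizes and higher noise, so the
#' band-correlation profile is trait-specific and root length is the easier
#' target.
#'
#' @param rngSeed integer seed.
#' @param link link function for both traits ("nonlinear" default).
#' @return a configuration list (see \code{\link{simulationConfig}}).
#' @export
defaultStudyConfig <- function(rngSeed = 1L, link = "nonlinear") {
    cfg <- simulationConfig(nSeeds = 89L, nBands = 256L,
                            wavelengthStart = 386.7, wavelengthEnd = 1016.7,
                            albedoSd = 0.18, amplitudeSd = 0.16,
                            rngSeed = rngSeed)
    root <- traitSpec(bands = vapply(c(705, 810, 900), function(nm)
                          .bandAt(cfg, nm), integer(1L)),
                      effects = c(55, -45, 50), link = link,
                      noiseSd = 5, intercept = 15, scale = 60, gain = 3,
                      center = 0.75)
    seedling <- traitSpec(bands = vapply(c(470, 520, 560), function(nm)
                              .bandAt(cfg, nm), integer(1L)),
                          effects = c(22, -18, 20), link = link,
                          noiseSd = 20, intercept = 40, scale = 45, gain = 3,
                          center = 0.7)
    cfg$traits <- list(root_length = root, seedling_length = seedling)
    cfg
}

#' Simulate per-seed reflectance spectra
#'
#' Each seed's spectrum is a smooth baseline (a shared seed-like reflectance
#' shape plus per-seed albedo, slope and curvature deviations) with Gaussian
#' band-localized perturbations at every informative band; the per-seed
#' perturbation amplitudes are the latent variables that later drive the
#' traits.  Values are clipped to the physical reflectance range [0, 1].
#' Deterministic given the configuration (including its seed).
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a \linkS4class{SeedSpectra} (no traits attached).
#' @export
simulateSpectra <- function(config) {
    stopifnot(inherits(config, "vigorspec_config"))
    n <- config$nSeeds
    p <- config$nBands
    wl <- makeWavelengthGrid(p, config$wavelengthStart, config$wavelengthEnd)
    u <- (wl - wl[1L]) / (wl[p] - wl[1L])
    .withSeed(.subSeed(config$rngSeed, 1L), {
        # shared baseline: reflectance rising through the VNIR with a broad
        # water-absorption dip near 980 nm
        shape <- 0.30 + 0.34 * u - 0.08 * exp(-((wl - 980)^2) / (2 * 30^2))
        X <- matrix(shape, n, p, byrow = TRUE)
        X <- X + stats::rnorm(n, 0, config$albedoSd)          # flat albedo
        X <- X + outer(stats::rnorm(n, 0, config$slopeSd), u - 0.5)
        X <- X + outer(stats::rnorm(n, 0, config$slopeSd / 2),
                       (u - 0.5)^2 - 1 / 12)
        idx <- seq_len(p)
        for (tr in config$traits) {
            for (b in tr$bands) {
                bump <- exp(-0.5 * ((idx - b) / config$bumpWidth)^2)
                X <- X + outer(stats::rnorm(n, 0, config$amplitudeSd), bump)
            }
        }
        if (config$spectralNoiseSd > 0)
            X <- X + matrix(stats::rnorm(n * p, 0, config$spectralNoiseSd), n, p)
        X <- pmin(pmax(X, 0), 1)
        SeedSpectra(X, wavelengths = wl,
                    sampleIds = sprintf("seed%03d", seq_len(n)))
    })
}

#' Simulate germination traits from spectra
#'
#' Applies each trait's link to its linear predictor over the informative
#' bands (see \code{\link{traitSpec}}), adds Gaussian noise, and truncates at
#' zero.  Truncation events are counted in the \code{"truncated"} attribute.
#'
#' @param spectra a \linkS4class{SeedSpectra} generated from \code{config}.
#' @param config the matching \code{\link{simulationConfig}}.
#' @return data.frame of traits, one row per seed, rownames = sample ids.
#' @export
simulateTraits <- function(spectra, config) {
    stopifnot(inherits(config, "vigorspec_config"))
    X <- spectraMatrix(spectra)
    if (ncol(X) != config$nBands)
        stop("shape error: spectra band count does not match the configuration")
    if (nrow(X) != config$nSeeds)
        stop("shape error: spectra seed count does not match the configuration")
    out <- list()
    truncated <- integer(0)
    for (k in seq_along(config$traits)) {
        nm <- names(config$traits)[k]
        tr <- config$traits[[k]]
        t <- drop(X[, tr$bands, drop = FALSE] %*% tr$effects)
        mu <- if (tr$link == "linear") {
            tr$intercept + t
        } else {
            s <- stats::sd(t)
            z <- if (is.finite(s) && s > 0) (t - mean(t)) / s else rep(0, length(t))
            tr$intercept + tr$scale * stats::plogis(tr$gain * (z - tr$center))
        }
        y <- .withSeed(.subSeed(config$rngSeed, 100L + k),
                       mu + stats::rnorm(length(mu), 0, tr$noiseSd))
        ntrunc <- sum(y < 0)
        if (ntrunc > 0)
            message(sprintf("simulateTraits: %d '%s' values truncated at 0",
                            ntrunc, nm))
        truncated[nm] <- ntrunc
        out[[nm]] <- pmax(y, 0)
    }
    res <- data.frame(out, row.names = rownames(X))
    attr(res, "truncated") <- truncated
    res
}

# Lay seeds out on a rectangular tray of elliptical ROIs.
.defaultRoiGrid <- function(nSeeds, cell = 14L, semiX = 4, semiY = 3) {
    ncols <- ceiling(sqrt(nSeeds))
    nrows <- ceiling(nSeeds / ncols)
    i <- seq_len(nSeeds) - 1L
    data.frame(
        sample_id = sprintf("seed%03d", seq_len(nSeeds)),
        center_x = (i %% ncols) * cell + cell / 2,
        center_y = (i %/% ncols) * cell + cell / 2,
        semi_x = semiX, semi_y = semiY,
        rotation = 0, part = "whole",
        stringsAsFactors = FALSE)
}

#' Simulate a raw hypercube fixture
#'
#' Builds a raw-counts cube whose white/dark calibration followed by ROI
#' averaging reproduces \code{\link{simulateSpectra}} exactly: every pixel of
#' seed i carries seed i's reflectance spectrum, the background carries a
#' distinct dim baseline, and the per-band white/dark reference counts mimic
#' a plate scan and a lens-capped exposure.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @param rois ROI table (see \code{\link{.defaultRoiGrid}} layout: columns
#'   sample_id, center_x, center_y, semi_x, semi_y, rotation, part), one row
#'   per seed, ellipses disjoint and inside the cube.  Default: a grid tray.
#' @return list with elements \code{bundle} (\linkS4class{RawCubeBundle})
#'   and \code{rois} (the ROI table used).
#' @export
simulateCube <- function(config, rois = NULL) {
    stopifnot(inherits(config, "vigorspec_config"))
    spectra <- simulateSpectra(config)
    X <- spectraMatrix(spectra)
    n <- nrow(X)
    p <- ncol(X)
    if (is.null(rois)) rois <- .defaultRoiGrid(n)
    if (nrow(rois) != n)
        stop("invalid fixture: need one ROI per seed")
    H <- config$cubeHeight %||% as.integer(max(rois$center_y + rois$semi_y) + 7)
    W <- config$cubeWidth %||% as.integer(max(rois$center_x + rois$semi_x) + 7)
    wl <- wavelengths(spectra)
    u <- (wl - wl[1L]) / (wl[p] - wl[1L])
    background <- 0.12 + 0.04 * u
    refl <- array(rep(background, each = H * W), dim = c(H, W, p))
    claimed <- matrix(FALSE, H, W)
    for (i in seq_len(n)) {
        m <- .ellipseMask(H, W, rois$center_x[i], rois$center_y[i],
                          rois$semi_x[i], rois$semi_y[i], rois$rotation[i])
        if (!any(m))
            stop(sprintf("invalid fixture: empty ROI for sample '%s'",
                         rois$sample_id[i]))
        if (any(m & claimed))
            stop("invalid fixture: overlapping ROIs")
        if (any(m[c(1L, H), ]) || any(m[, c(1L, W)]))
            stop("invalid fixture: ROI touches the cube boundary")
        claimed <- claimed | m
        idx <- which(m)
        for (b in seq_len(p)) refl[idx + (b - 1L) * H * W] <- X[i, b]
    }
    white <- 3200 + 600 * u
    dark <- 90 + 15 * u
    raw <- array(0, dim = c(H, W, p))
    for (b in seq_len(p))
        raw[, , b] <- dark[b] + refl[, , b] * (white[b] - dark[b])
    bundle <- new("RawCubeBundle", raw = raw, white = white, dark = dark,
                  wavelengths = wl)
    list(bundle = bundle, rois = rois)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete synthetic study
#'
#' Runs \code{\link{simulateSpectra}} and \code{\link{simulateTraits}} under
#' the configuration's seed and, optionally, builds the raw-cube fixture
#' whose calibration round-trips to the same spectra.
#'
#' @param config a \code{\link{simulationConfig}} (default:
#'   \code{\link{defaultStudyConfig}()}).
#' @param cube logical; also build the raw cube and ROI table?
#' @return a \linkS4class{SyntheticStudy}.
#' @examples
#' study <- simulateStudy(defaultStudyConfig(rngSeed = 7))
#' germinationTraits(spectra(study))[1:3, ]
#' @export
simulateStudy <- function(config = defaultStudyConfig(), cube = FALSE) {
    sp <- simulateSpectra(config)
    tr <- simulateTraits(sp, config)
    ss <- SeedSpectra(spectraMatrix(sp), wavelengths = wavelengths(sp),
                      sampleIds = sampleIds(sp), traits = tr)
    cb <- NULL
    rois <- NULL
    if (cube) {
        cr <- simulateCube(config)
        cb <- cr$bundle
        rois <- cr$rois
    }
    new("SyntheticStudy", spectra = ss, truth = unclass(config),
        cube = cb, rois = rois)
}

#' @describeIn simulateStudy accessor for the spectra (with traits).
#' @param study a \linkS4class{SyntheticStudy}.
#' @export
spectra <- function(study) study@spectra

#' @describeIn simulateStudy accessor for the generating truth.
#' @export
studyTruth <- function(study) study@truth

setMethod("show", "SyntheticStudy", function(object) {
    cat(sprintf("SyntheticStudy: %d seeds, %d bands; traits: %s; cube: %s\n",
                ncol(object@spectra), nrow(object@spectra),
                paste(names(object@truth$traits), collapse = ", "),
                if (is.null(object@cube)) "absent" else "present"))
})
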