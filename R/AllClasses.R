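#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

setClassUnion("NumericOrArray", c("numeric", "matrix", "array"))
setClassUnion("OptionalDataFrame", c("data.frame", "NULL"))

#' Per-seed mean reflectance spectra
#'
#' A \linkS4class{SummarizedExperiment} whose rows are spectral bands and
#' whose columns are seeds.  The single assay \code{"reflectance"} holds the
#' per-seed mean reflectance, \code{rowData} carries the wavelength grid in
#' nanometres, and \code{colData} optionally carries germination traits
#' (root length, seedling length) for the same seeds.
#'
#' @export
setClass("SeedSpectra", contains = "SummarizedExperiment")

setValidity("SeedSpectra", function(object) {
    msg <- character()
    if (!"reflectance" %in% assayNames(object))
        msg <- c(msg, "assay 'reflectance' is required")
    wl <- rowData(object)$wavelength
    if (is.null(wl))
        msg <- c(msg, "rowData must contain a 'wavelength' column")
    else {
        if (anyNA(wl)) msg <- c(msg, "wavelengths must not contain NA")
        if (length(wl) > 1L && any(diff(wl) <= 0))
            msg <- c(msg, "wavelengths must be strictly increasing")
    }
    if (length(assayNames(object)) && anyNA(assay(object, 1L)))
        msg <- c(msg, "reflectance matrix must not contain NA")
    if (length(msg)) msg else TRUE
})

#' Raw hypercube with white/dark reference frames
#'
#' Holds an uncalibrated hyperspectral cube of sensor counts
#' (height x width x bands) together with the white-plate and dark-current
#' reference measurements and the wavelength grid.  References may be either
#' per-band scalars (length-B numeric, a plate-scan average) or full
#' H x W x B arrays; both broadcast during calibration.
#'
#' @slot raw numeric array, H x W x B raw counts.
#' @slot white per-band numeric vector or H x W x B array of white counts.
#' @slot dark per-band numeric vector or H x W x B array of dark counts.
#' @slot wavelengths numeric, strictly increasing, length B (nm).
#'
#' @export
setClass("RawCubeBundle",
    representation(raw = "array", white = "NumericOrArray",
                   dark = "NumericOrArray", wavelengths = "numeric"))

setValidity("RawCubeBundle", function(object) {
    msg <- character()
    d <- dim(object@raw)
    if (length(d) != 3L)
        msg <- c(msg, "raw cube must be a 3-D array (H x W x B)")
    else {
        if (length(object@wavelengths) != d[3L])
            msg <- c(msg, "wavelength vector must have one entry per band")
        for (nm in c("white", "dark")) {
            ref <- slot(object, nm)
            ok <- (is.null(dim(ref)) && length(ref) == d[3L]) ||
                  (length(dim(ref)) == 3L && all(dim(ref) == d))
            if (!ok)
                msg <- c(msg, sprintf(
                    "'%s' must be a length-B vector or an array matching the cube", nm))
        }
    }
    if (length(object@wavelengths) > 1L && any(diff(object@wavelengths) <= 0))
        msg <- c(msg, "wavelengths must be strictly increasing")
    if (length(msg)) msg else TRUE
})

#' Calibrated reflectance cube
#'
#' Relative reflectance per pixel and band, as produced by
#' \code{\link{calibrateCube}}.  Pixels where the white and dark references
#' coincide (zero calibration denominator) are recorded in \code{mask} and
#' set to \code{NA} in \code{reflectance}; they are excluded from ROI means.
#' Values outside [0, 1] (e.g. specular highlights) are retained.
#'
#' @slot reflectance numeric H x W x B array.
#' @slot wavelengths numeric, length B (nm).
#' @slot mask logical H x W x B array, TRUE where calibration was undefined.
#'
#' @export
setClass("ReflectanceCube",
    representation(reflectance = "array", wavelengths = "numeric",
                   mask = "array"))

#' Per-band correlation scores against one trait
#'
#' @slot bandIndices integer indices into the source dataset's bands.
#' @slot wavelengths numeric wavelengths (nm) of those bands.
#' @slot scores numeric Pearson correlation per band, in [-1, 1].
#' @slot trait name of the trait the scores were computed against.
#'
#' @export
setClass("BandScores",
    representation(bandIndices = "integer", wavelengths = "numeric",
                   scores = "numeric", trait = "character"))

setValidity("BandScores", function(object) {
    msg <- character()
    if (length(object@scores) != length(object@bandIndices))
        msg <- c(msg, "one score per band is required")
    if (any(abs(object@scores) > 1 + 1e-12, na.rm = TRUE))
        msg <- c(msg, "correlation scores must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Result of a wavelength-selection method
#'
#' Ordered band indices chosen by one of the selection strategies, together
#' with per-band scores where the method defines them (correlation ranking)
#' and method-specific diagnostics (GA fitness trajectory, SPA start column).
#'
#' @slot method one of "none", "hcc", "spa", "ga".
#' @slot selected integer, ordered band indices into the source dataset.
#' @slot k integer, number of bands requested.
#' @slot trait name of the trait that drove the selection ("" if none).
#' @slot wavelengths numeric, wavelengths (nm) of the selected bands.
#' @slot scores numeric, per-band score over all source bands (may be empty).
#' @slot diagnostics list of method-specific extras.
#'
#' @export
setClass("SelectionResult",
    representation(method = "character", selected = "integer", k = "integer",
                   trait = "character", wavelengths = "numeric",
                   scores = "numeric", diagnostics = "list"))

setValidity("SelectionResult", function(object) {
    msg <- character()
    if (anyDuplicated(object@selected))
        msg <- c(msg, "selected band indices must be unique")
    if (length(object@selected) > object@k)
        msg <- c(msg, "more bands selected than requested")
    if (any(object@selected < 1L))
        msg <- c(msg, "band indices must be positive")
    if (length(msg)) msg else TRUE
})

#' Train/test partition of a spectral dataset
#'
#' @slot trainIds,testIds disjoint character vectors of sample identifiers
#'   whose union covers the dataset.
#' @slot method "kennard_stone" or "given".
#'
#' @export
setClass("TrainTestSplit",
    representation(trainIds = "character", testIds = "character",
                   method = "character"))

setValidity("TrainTestSplit", function(object) {
    if (length(intersect(object@trainIds, object@testIds)))
        "train and test sets must be disjoint" else TRUE
})

#' Fitted spectra-to-trait regression models
#'
#' Virtual parent of the three regression models.  All models center the
#' spectra and the trait by their training means; coefficients of the linear
#' models (PCR, PLS) are mapped back to band space.
#'
#' @slot trait name of the modelled trait.
#' @slot q integer, number of components / latent variables used.
#' @slot xMean numeric, training column means of the spectra.
#' @slot yMean numeric(1), training mean of the trait.
#' @slot bandWavelengths numeric, wavelengths (nm) of the modelled bands.
#'
#' @export
setClass("SpectralModel",
    representation("VIRTUAL", trait = "character", q = "integer",
                   xMean = "numeric", yMean = "numeric",
                   bandWavelengths = "numeric"))

#' @describeIn SpectralModel principal component regression: least squares on
#'   the first q principal-component scores of the centered spectra.
#' @export
setClass("PCRModel", contains = "SpectralModel",
    representation(rotation = "matrix", coefficients = "numeric"))

#' @describeIn SpectralModel partial least squares (univariate NIPALS).
#' @export
setClass("PLSModel", contains = "SpectralModel",
    representation(weights = "matrix", loadings = "matrix",
                   coefficients = "numeric"))

#' @describeIn SpectralModel kernel principal component regression with the
#'   Gaussian kernel k(x, y) = exp(-||x - y||^2 / sigma) (sigma divides the
#'   squared distance directly).  Training spectra are retained for
#'   prediction-time cross-kernels.
#' @export
setClass("KPCRModel", contains = "SpectralModel",
    representation(Xtrain = "matrix", sigma = "numeric", kernel = "character",
                   eigvec = "matrix", eigval = "numeric", beta = "numeric",
                   kColMeans = "numeric", kGrandMean = "numeric"))

#' Synthetic seed-vigor study with known ground truth
#'
#' Bundles everything the generator produced: per-seed spectra with traits in
#' \code{colData}, the generating configuration (the truth), and optionally a
#' raw cube plus the elliptical ROI table that reproduces the spectra after
#' calibration.
#'
#' @export
setClass("SyntheticStudy",
    representation(spectra = "SeedSpectra", truth = "list",
                   cube = "ANY", rois = "OptionalDataFrame"))
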