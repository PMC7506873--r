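#' Construct a SeedSpectra object
#'
#' @param X numeric matrix of mean reflectance, one row per seed and one
#'   column per band (the orientation statistics are run in; it is stored
#'   transposed, bands x seeds, following the assay convention).
#' @param wavelengths numeric vector of band centers in nm, strictly
#'   increasing, one per column of \code{X}.
#' @param sampleIds character vector of seed identifiers; defaults to the
#'   row names of \code{X} or \code{seed001, seed002, ...}.
#' @param traits optional data.frame of germination traits (e.g. columns
#'   \code{root_length}, \code{seedling_length}), one row per seed.
#'
#' @return A \linkS4class{SeedSpectra} object.
#' @examples
#' X <- matrix(runif(12), nrow = 3)
#' ss <- SeedSpectra(X, wavelengths = c(500, 600, 700, 800))
#' spectraMatrix(ss)
#' @export
SeedSpectra <- function(X, wavelengths, sampleIds = NULL, traits = NULL) {
    X <- as.matrix(X)
    if (ncol(X) != length(wavelengths))
        stop("'X' must have one column per wavelength")
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(X))) rownames(X)
                     else sprintf("seed%03d", seq_len(nrow(X)))
    if (length(sampleIds) != nrow(X))
        stop("'sampleIds' must have one entry per row of 'X'")
    cd <- if (is.null(traits)) DataFrame(row.names = sampleIds)
          else {
              if (nrow(traits) != nrow(X))
                  stop("'traits' must have one row per seed")
              DataFrame(traits, row.names = sampleIds)
          }
    assaym <- t(X)
    dimnames(assaym) <- list(sprintf("%.1f", wavelengths), sampleIds)
    se <- SummarizedExperiment(
        assays = list(reflectance = assaym),
        rowData = DataFrame(wavelength = as.numeric(wavelengths)),
        colData = cd)
    new("SeedSpectra", se)
}

#' @describeIn SeedSpectra wavelength grid (nm).
#' @export
setMethod("wavelengths", "SeedSpectra",
    function(x) rowData(x)$wavelength)

#' @describeIn SeedSpectra reflectance as a seeds x bands matrix (the
#'   orientation used by the selection and regression functions).
#' @export
setMethod("spectraMatrix", "SeedSpectra",
    function(x) t(assay(x, "reflectance")))

#' @describeIn SeedSpectra seed identifiers.
#' @export
setMethod("sampleIds", "SeedSpectra", function(x) colnames(x))

#' @describeIn SeedSpectra germination traits stored alongside the spectra
#'   (data.frame, possibly with zero columns).
#' @export
setMethod("germinationTraits", "SeedSpectra",
    function(x) as.data.frame(colData(x)))

setMethod("show", "SeedSpectra", function(object) {
    wl <- wavelengths(object)
    cat(sprintf("SeedSpectra: %d seeds x %d bands (%.1f-%.1f nm)\n",
                ncol(object), nrow(object),
                if (length(wl)) min(wl) else NA, if (length(wl)) max(wl) else NA))
    tr <- colnames(colData(object))
    if (length(tr)) cat("traits:", paste(tr, collapse = ", "), "\n")
})

#' Extract one trait vector aligned with the spectra
#'
#' @param ds a \linkS4class{SeedSpectra} with traits in \code{colData}.
#' @param trait trait column name.
#' @return named numeric vector, one entry per seed.
#' @export
traitVector <- function(ds, trait) {
    tab <- germinationTraits(ds)
    if (!trait %in% colnames(tab))
        stop(sprintf("trait '%s' not present (have: %s)", trait,
                     paste(colnames(tab), collapse = ", ")))
    y <- tab[[trait]]
    names(y) <- rownames(tab)
    y
}

#' Restrict spectra to a closed wavelength window
#'
#' Keeps exactly the bands whose wavelength lies in \code{[lowNm, highNm]}
#' (closed interval), preserving order.  The default window drops the noisy
#' edges of a visible/near-infrared instrument range.
#'
#' @param ds a \linkS4class{SeedSpectra}.
#' @param lowNm,highNm window bounds in nm, \code{lowNm < highNm} (equality
#'   allowed to pick a single band).
#' @return a \linkS4class{SeedSpectra} with the retained bands.
#' @examples
#' X <- matrix(runif(8), nrow = 2)
#' ss <- SeedSpectra(X, wavelengths = c(10, 20, 30, 40))
#' wavelengths(windowBands(ss, 15, 35))  # 20, 30
#' @export
windowBands <- function(ds, lowNm = 430.1, highNm = 971.5) {
    if (lowNm > highNm) stop("'lowNm' must not exceed 'highNm'")
    wl <- wavelengths(ds)
    keep <- wl >= lowNm & wl <= highNm
    if (!any(keep))
        stop(sprintf("empty window: no wavelength in [%g, %g] nm", lowNm, highNm))
    ds[keep, ]
}
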