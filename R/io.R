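#' Write / read per-seed spectra as CSV
#'
#' Plain-text interchange format: one row per seed, a \code{sample_id}
#' column, then one column per band headed by the wavelength in nm printed
#' with one decimal, plus any trait columns after the bands.
#'
#' @param ds a \linkS4class{SeedSpectra}.
#' @param path CSV file path.
#' @return \code{path} (write) or a \linkS4class{SeedSpectra} (read).
#' @export
writeSpectraCSV <- function(ds, path) {
    X <- spectraMatrix(ds)
    df <- data.frame(sample_id = sampleIds(ds), X, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df) <- c("sample_id", sprintf("%.1f", wavelengths(ds)))
    tr <- germinationTraits(ds)
    if (ncol(tr)) df <- cbind(df, tr)
    utils::write.csv(df, path, row.names = FALSE)
    invisible(path)
}

#' @rdname writeSpectraCSV
#' @export
readSpectraCSV <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    isBand <- grepl("^[0-9]+(\\.[0-9]+)?$", colnames(df))
    X <- as.matrix(df[, isBand, drop = FALSE])
    traits <- df[, !isBand & colnames(df) != "sample_id", drop = FALSE]
    SeedSpectra(X, wavelengths = as.numeric(colnames(df)[isBand]),
                sampleIds = df$sample_id,
                traits = if (ncol(traits)) traits else NULL)
}

#' Write a synthetic study to a fixture directory
#'
#' Text-plus-TIFF layout: \code{spectra.csv} (spectra and traits),
#' \code{study.json} (wavelengths, ROI ellipses, generator truth, and the
#' white/dark reference vectors and count scale for the cube), and, when a
#' cube is present, \code{cube.tif} with one 32-bit float page per band,
#' counts divided by \code{count_scale} to fit the [0, 1] TIFF range.
#'
#' @param study a \linkS4class{SyntheticStudy}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeStudy <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeSpectraCSV(study@spectra, file.path(dir, "spectra.csv"))
    meta <- list(wavelengths = wavelengths(study@spectra),
                 truth = study@truth, rois = study@rois)
    if (!is.null(study@cube)) {
        cb <- study@cube
        scale <- max(cb@raw, cb@white, cb@dark)
        meta$cube <- list(count_scale = scale, white = as.numeric(cb@white),
                          dark = as.numeric(cb@dark), dim = dim(cb@raw))
        pages <- lapply(seq_len(dim(cb@raw)[3L]),
                        function(b) cb@raw[, , b] / scale)
        tiff::writeTIFF(pages, file.path(dir, "cube.tif"),
                        bits.per.sample = 32L)
    }
    jsonlite::write_json(meta, file.path(dir, "study.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    invisible(dir)
}

#' Read a synthetic study fixture directory
#'
#' @param dir directory written by \code{\link{writeStudy}}.
#' @return a \linkS4class{SyntheticStudy} (cube present when it was written;
#'   raw counts restored via the stored count scale, exact up to 32-bit
#'   float precision).
#' @export
readStudy <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "study.json"),
                                simplifyVector = TRUE)
    sp <- readSpectraCSV(file.path(dir, "spectra.csv"))
    cube <- NULL
    if (!is.null(meta$cube) && file.exists(file.path(dir, "cube.tif"))) {
        pages <- tiff::readTIFF(file.path(dir, "cube.tif"), all = TRUE)
        d <- as.integer(meta$cube$dim)
        raw <- array(0, dim = d)
        for (b in seq_len(d[3L])) raw[, , b] <- pages[[b]] * meta$cube$count_scale
        cube <- new("RawCubeBundle", raw = raw,
                    white = as.numeric(meta$cube$white),
                    dark = as.numeric(meta$cube$dark),
                    wavelengths = as.numeric(meta$wavelengths))
    }
    rois <- if (!is.null(meta$rois)) as.data.frame(meta$rois) else NULL
    truth <- meta$truth
    new("SyntheticStudy", spectra = sp,
        truth = if (is.null(truth)) list() else truth,
        cube = cube, rois = rois)
}
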