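# Pixel-center-in-ellipse membership.  Pixel (row i, col j), 1-based in R,
# has center (x, y) = (j - 1, i - 1): x runs along columns, y along rows,
# 0-based, matching the ROI table convention.
.ellipseMask <- function(H, W, cx, cy, a, b, rotationDeg = 0) {
    if (a <= 0 || b <= 0) stop("ellipse semi-axes must be positive")
    x <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) - cx
    y <- matrix(seq_len(H) - 1, H, W) - cy
    th <- rotationDeg * pi / 180
    xr <- cos(th) * x + sin(th) * y
    yr <- -sin(th) * x + cos(th) * y
    (xr / a)^2 + (yr / b)^2 <= 1
}

#' White/dark reflectance calibration of a raw hypercube
#'
#' Converts raw sensor counts to relative reflectance,
#' \deqn{I = (I_{raw} - I_{dark}) / (I_{white} - I_{dark}),}
#' elementwise per pixel and band.  White and dark references may be
#' per-band scalars (plate-scan averages) or full cubes; both broadcast.
#' Pixels where the white and dark counts coincide have no defined
#' reflectance: they are set to \code{NA}, flagged in the result's
#' \code{mask}, and excluded from downstream ROI means.  Values outside
#' [0, 1] (specular highlights, dark shadows) are kept, not clipped.
#'
#' @param bundle a \linkS4class{RawCubeBundle}.
#' @return a \linkS4class{ReflectanceCube}.
#' @examples
#' raw <- array(c(1, 2), dim = c(1, 1, 2))
#' b <- new("RawCubeBundle", raw = raw, white = c(2, 4), dark = c(0, 0),
#'          wavelengths = c(500, 600))
#' calibrateCube(b)@reflectance  # 0.5 at both bands
#' @export
setMethod("calibrateCube", "RawCubeBundle", function(bundle, ...) {
    d <- dim(bundle@raw)
    H <- d[1L]; W <- d[2L]; B <- d[3L]
    expand <- function(ref) {
        if (is.null(dim(ref)) || length(dim(ref)) < 3L)
            array(rep(as.numeric(ref), each = H * W), dim = d)
        else ref
    }
    white <- expand(bundle@white)
    dark <- expand(bundle@dark)
    denom <- white - dark
    mask <- denom == 0
    if (all(mask))
        stop("calibration failure: white and dark references coincide everywhere")
    refl <- (bundle@raw - dark) / denom
    refl[mask] <- NA_real_
    nOut <- sum(refl < 0 | refl > 1, na.rm = TRUE)
    if (nOut > 0)
        message(sprintf("calibrateCube: %d pixel-band reflectance values outside [0, 1] (kept)",
                        nOut))
    if (any(mask))
        message(sprintf("calibrateCube: %d pixel-band values masked (zero calibration denominator)",
                        sum(mask)))
    new("ReflectanceCube", reflectance = refl,
        wavelengths = bundle@wavelengths, mask = mask)
})

setMethod("show", "ReflectanceCube", function(object) {
    d <- dim(object@reflectance)
    cat(sprintf("ReflectanceCube: %d x %d pixels, %d bands (%.1f-%.1f nm), %d masked values\n",
                d[1L], d[2L], d[3L], min(object@wavelengths),
                max(object@wavelengths), sum(object@mask)))
})

#' Extract per-seed mean spectra from elliptical ROIs
#'
#' For each ROI, averages the reflectance of the pixels whose centers fall
#' inside the ellipse, band by band.  Masked (uncalibratable) pixels are
#' excluded from the average; an ROI whose pixels are all masked at some
#' band is an error, as is an ROI containing no pixel at all.
#'
#' @param cube a \linkS4class{ReflectanceCube}.
#' @param rois data.frame with columns \code{sample_id}, \code{center_x},
#'   \code{center_y}, \code{semi_x}, \code{semi_y}, \code{rotation} (degrees)
#'   and optionally \code{part}; coordinates are 0-based pixel centers,
#'   x = column, y = row.
#' @return a \linkS4class{SeedSpectra}, one row per ROI in table order.
#' @export
extractROIMeans <- function(cube, rois) {
    need <- c("sample_id", "center_x", "center_y", "semi_x", "semi_y")
    if (!all(need %in% colnames(rois)))
        stop("ROI table must have columns: ", paste(need, collapse = ", "))
    if (is.null(rois$rotation)) rois$rotation <- 0
    d <- dim(cube@reflectance)
    H <- d[1L]; W <- d[2L]; B <- d[3L]
    X <- matrix(NA_real_, nrow(rois), B)
    for (i in seq_len(nrow(rois))) {
        m <- .ellipseMask(H, W, rois$center_x[i], rois$center_y[i],
                          rois$semi_x[i], rois$semi_y[i], rois$rotation[i])
        if (!any(m))
            stop(sprintf("empty ROI: no pixel center inside the ellipse of sample '%s'",
                         rois$sample_id[i]))
        idx <- which(m)
        for (b in seq_len(B)) {
            v <- cube@reflectance[idx + (b - 1L) * H * W]
            v <- v[!is.na(v)]
            if (!length(v))
                stop(sprintf("empty ROI: all pixels of sample '%s' masked at band %d",
                             rois$sample_id[i], b))
            X[i, b] <- mean(v)
        }
    }
    SeedSpectra(X, wavelengths = cube@wavelengths,
                sampleIds = as.character(rois$sample_id))
}
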