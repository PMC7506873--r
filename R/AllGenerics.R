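#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @export
setGeneric("spectraMatrix", function(x) standardGeneric("spectraMatrix"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("germinationTraits", function(x) standardGeneric("germinationTraits"))

#' @export
setGeneric("selectedBands", function(x) standardGeneric("selectedBands"))

#' @export
setGeneric("calibrateCube", function(bundle, ...) standardGeneric("calibrateCube"))
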