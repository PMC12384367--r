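#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))

#' @export
setGeneric("cropWindow", function(x, window) standardGeneric("cropWindow"))

#' @export
setGeneric("varianceContribution",
           function(x) standardGeneric("varianceContribution"))

#' @export
setGeneric("explainedFraction",
           function(x) standardGeneric("explainedFraction"))

#' @export
setGeneric("pcaScores", function(x) standardGeneric("pcaScores"))

#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' @export
setGeneric("predictConcentration",
           function(object, spectra, ...) standardGeneric("predictConcentration"))

#' @export
setGeneric("evaluateModel",
           function(object, spectra, ...) standardGeneric("evaluateModel"))

#' @export
setGeneric("rSquared", function(x) standardGeneric("rSquared"))

#' @export
setGeneric("lod", function(x) standardGeneric("lod"))
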