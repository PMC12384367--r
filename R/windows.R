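#' Create a spectral window
#'
#' @param low,high window bounds in cm^-1, low < high.
#' @return a [SpectralWindow-class].
#' @examples
#' spectralWindow(500, 600)
#' @export
spectralWindow <- function(low, high)
  methods::new("SpectralWindow", low = as.numeric(low), high = as.numeric(high))

#' The four default analysis windows
#'
#' Windows 350-405, 410-490, 500-600 and 1190-1250 cm^-1, chosen around the
#' characteristic bands of the pyrene / R6G system; the 500-600 cm^-1 window
#' contains the 586 cm^-1 pyrene band used for quantitation.
#'
#' @return list of four [SpectralWindow-class] objects.
#' @export
defaultWindows <- function()
  list(spectralWindow(350, 405), spectralWindow(410, 490),
       spectralWindow(500, 600), spectralWindow(1190, 1250))

setMethod("show", "SpectralWindow", function(object)
  cat(sprintf("SpectralWindow %g-%g cm-1\n", object@low, object@high)))

windowLabel <- function(window) sprintf("%g-%g", window@low, window@high)

#' @describeIn cropWindow restrict a SpectraSet to one window (both endpoints
#'   inclusive; wavenumbers are physical values, not indices).
#' @param x a [SpectraSet-class].
#' @param window a [SpectralWindow-class].
#' @export
setMethod("cropWindow", signature("SpectraSet", "SpectralWindow"),
  function(x, window) {
    keep <- wavenumbers(x) >= window@low & wavenumbers(x) <= window@high
    if (!any(keep))
      stop("window ", windowLabel(window), " cm-1 has no overlap with the grid")
    x[keep, ]
  })
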