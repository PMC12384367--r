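#' Concentration scaling for the sigmoid output layer
#'
#' The network's sigmoid output lives in (0, 1); concentrations spanning four
#' decades are mapped linearly in log10(c) onto (margin, 1 - margin):
#' forward(c) = margin + (1 - 2 margin) * (log10 c - log10 cMin) /
#' (log10 cMax - log10 cMin). The inverse is exact.
#'
#' @param cMin,cMax calibrated range, ppm (> 0).
#' @param margin fraction in (0, 0.5), default 0.05; keeps targets off the
#'   sigmoid asymptotes.
#' @return `concentrationScaler`: a [ConcentrationScaler-class].
#' @examples
#' sc <- concentrationScaler(0.01, 70)
#' scaleConcentration(0.01, sc)                      # 0.05 (the margin)
#' unscaleConcentration(scaleConcentration(5, sc), sc)  # 5
#' @export
concentrationScaler <- function(cMin, cMax, margin = 0.05)
  methods::new("ConcentrationScaler", cMin = as.numeric(cMin),
               cMax = as.numeric(cMax), margin = as.numeric(margin))

#' @rdname concentrationScaler
#' @param c concentration(s), ppm, > 0. Values outside \[cMin, cMax\] are
#'   clipped with a warning.
#' @param scaler a [ConcentrationScaler-class].
#' @export
scaleConcentration <- function(c, scaler) {
  if (any(is.na(c)) || any(c <= 0))
    stop("concentrations must be > 0 to be log-scaled")
  if (any(c < scaler@cMin) || any(c > scaler@cMax)) {
    warning("concentration(s) outside [", scaler@cMin, ", ", scaler@cMax,
            "] ppm clipped before scaling")
    c <- pmin(pmax(c, scaler@cMin), scaler@cMax)
  }
  m <- scaler@margin
  m + (1 - 2 * m) * (log10(c) - log10(scaler@cMin)) /
    (log10(scaler@cMax) - log10(scaler@cMin))
}

#' @rdname concentrationScaler
#' @param y scaled value(s) in (0, 1).
#' @export
unscaleConcentration <- function(y, scaler) {
  m <- scaler@margin
  10^(log10(scaler@cMin) + (y - m) / (1 - 2 * m) *
        (log10(scaler@cMax) - log10(scaler@cMin)))
}

setMethod("show", "ConcentrationScaler", function(object)
  cat(sprintf("ConcentrationScaler: [%g, %g] ppm -> [%g, %g] (log10 axis)\n",
              object@cMin, object@cMax, object@margin, 1 - object@margin)))
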