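#' Prediction-quality report
#'
#' `regressionReport()` compares predicted against true concentrations:
#' R^2 = 1 - SS_res/SS_tot on the raw ppm axis, the same statistic on the
#' log10 axis (`rSquaredLog`, the axis a four-decade calibration is judged
#' on and the one the model natively predicts), RMSE in ppm, and the
#' least-squares line of log10(predicted) on log10(true).
#' `evaluateModel()` predicts on a labelled test set first.
#'
#' @param yTrue,yPred concentration vectors, ppm.
#' @param model label recorded in the report.
#' @return a [RegressionReport-class].
#' @examples
#' regressionReport(c(1, 2, 3), c(1, 2, 4))  # R^2 = 0.5 on the ppm axis
#' @export
regressionReport <- function(yTrue, yPred, model = "model") {
  if (length(yTrue) == 0L) stop("empty test set")
  if (length(yTrue) != length(yPred))
    stop("yTrue and yPred must have equal length")
  if (var(yTrue) == 0)
    stop("constant yTrue: R^2 is undefined")
  ssRes <- sum((yPred - yTrue)^2)
  ssTot <- sum((yTrue - mean(yTrue))^2)
  r2 <- 1 - ssRes / ssTot
  rmse <- sqrt(mean((yPred - yTrue)^2))
  if (all(yTrue > 0) && all(yPred > 0)) {
    lt <- log10(yTrue); lp <- log10(yPred)
    r2log <- 1 - sum((lp - lt)^2) / sum((lt - mean(lt))^2)
    line <- coef(lm(lp ~ lt))
    slope <- unname(line[2]); intercept <- unname(line[1])
  } else {
    r2log <- NA_real_; slope <- NA_real_; intercept <- NA_real_
  }
  methods::new("RegressionReport", yTrue = as.numeric(yTrue),
               yPred = as.numeric(yPred), rSquared = r2, rSquaredLog = r2log,
               rmse = rmse, fitLineSlope = slope,
               fitLineIntercept = intercept, model = model)
}

#' @rdname regressionReport
#' @param object a fitted [PcaBpModel-class] or [PlsrModel-class].
#' @param spectra labelled test [SpectraSet-class] (non-empty).
#' @param ... unused.
#' @export
setMethod("evaluateModel", "ANY", function(object, spectra, ...) {
  yTrue <- concentrations(spectra)
  if (length(yTrue) == 0L) stop("empty test set")
  if (anyNA(yTrue)) stop("test spectra must have known concentrations")
  yPred <- predictConcentration(object, spectra)
  regressionReport(yTrue, yPred, model = class(object))
})

#' @describeIn regressionReport raw-ppm-axis R^2 accessor.
#' @param x a RegressionReport.
#' @export
setMethod("rSquared", "RegressionReport", function(x) x@rSquared)

setMethod("show", "RegressionReport", function(object) {
  cat(sprintf("RegressionReport [%s], n = %d\n",
              object@model, length(object@yTrue)))
  cat(sprintf("  R^2 (log10 axis) = %.4f | R^2 (ppm axis) = %.4f | RMSE = %.3g ppm\n",
              object@rSquaredLog, object@rSquared, object@rmse))
  cat(sprintf("  prediction line (log10): y = %.3f x + %.3f\n",
              object@fitLineSlope, object@fitLineIntercept))
})

reportAsList <- function(report)
  list(model = report@model,
       r_squared_ppm = report@rSquared,
       r_squared_log10 = report@rSquaredLog,
       rmse_ppm = report@rmse,
       fit_line_slope = report@fitLineSlope,
       fit_line_intercept = report@fitLineIntercept,
       y_true_ppm = report@yTrue,
       y_pred_ppm = report@yPred)
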