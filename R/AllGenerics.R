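#' @rdname ThzSpectra-accessors
#' @export
setGeneric("frequencyGrid", function(x) standardGeneric("frequencyGrid"))

#' @rdname ThzSpectra-accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname ThzSpectra-accessors
#' @export
setGeneric("kappaMatrix", function(x) standardGeneric("kappaMatrix"))

#' @rdname mscCorrect
#' @export
setGeneric("mscCorrect", function(x, reference = NULL, ...)
  standardGeneric("mscCorrect"))

#' @rdname mscCorrect
#' @export
setGeneric("mscGains", function(object) standardGeneric("mscGains"))

#' @rdname mscCorrect
#' @export
setGeneric("mscOffsets", function(object) standardGeneric("mscOffsets"))

#' @rdname mscCorrect
#' @export
setGeneric("corrected", function(object) standardGeneric("corrected"))

#' @rdname pcaFit
#' @export
setGeneric("pcaFit", function(x, q = 2L, ...) standardGeneric("pcaFit"))

#' @rdname pcaFit
#' @export
setGeneric("pcaProject", function(model, x, ...) standardGeneric("pcaProject"))

#' @rdname pcaFit
#' @export
setGeneric("explainedVariance", function(model) standardGeneric("explainedVariance"))

#' @rdname annTrain
#' @export
setGeneric("annTrain", function(x, targets, config, ...) standardGeneric("annTrain"))

#' @rdname annPredict
#' @export
setGeneric("annPredict", function(model, x, ...) standardGeneric("annPredict"))

#' @rdname minSeparatingLines
#' @export
setGeneric("separabilityIndex", function(object) standardGeneric("separabilityIndex"))

#' Accessors for ThzSpectra
#'
#' `frequencyGrid()` returns the shared frequency grid in THz,
#' `classLabels()` the integer class labels and `kappaMatrix()` the
#' samples-by-frequencies extinction matrix (the transpose of the internal
#' assay, i.e. the orientation used by PCA and the network).
#'
#' @param x a [ThzSpectra-class] object.
#' @return numeric vector, integer vector, or numeric matrix respectively.
#' @name ThzSpectra-accessors
NULL

#' @rdname ThzSpectra-accessors
#' @export
setMethod("frequencyGrid", "ThzSpectra", function(x)
  as.numeric(rowData(x)$frequency_THz))

#' @rdname ThzSpectra-accessors
#' @export
setMethod("classLabels", "ThzSpectra", function(x)
  stats::setNames(as.integer(colData(x)$label), colnames(x)))

#' @rdname ThzSpectra-accessors
#' @export
setMethod("kappaMatrix", "ThzSpectra", function(x) t(assay(x, "kappa")))

setMethod("show", "ThzSpectra", function(object) {
  f <- frequencyGrid(object)
  lab <- classLabels(object)
  cat("ThzSpectra:", ncol(object), "spectra on", nrow(object),
      sprintf("frequencies [%.4g, %.4g] THz\n", min(f), max(f)))
  if (length(lab)) {
    tab <- table(lab, useNA = "ifany")
    cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
})

setMethod("show", "MSCResult", function(object) {
  cat("MSCResult:", ncol(object@corrected), "corrected spectra\n")
  cat(sprintf("  gains  a_i: [%.4g, %.4g]\n", min(object@gains), max(object@gains)))
  cat(sprintf("  offsets b_i: [%.4g, %.4g]\n", min(object@offsets), max(object@offsets)))
  if (length(object@uncorrected))
    cat("  uncorrected (a_i = 0):", paste(object@uncorrected, collapse = ", "), "\n")
})

setMethod("show", "PCAModel", function(object) {
  r <- object@explainedVarianceRatio
  cat("PCAModel:", ncol(object@loadings), "components,",
      "explained variance:", paste(sprintf("%.3f", head(r, 4)), collapse = " "),
      if (length(r) > 4) "...\n" else "\n")
})

setMethod("show", "SeparabilityResult", function(object) {
  cat(sprintf("SeparabilityResult pair (%d, %d): s = %s, index = %s [%s]\n",
              object@classPair[1], object@classPair[2],
              ifelse(is.na(object@s), "NA", object@s),
              ifelse(is.na(object@index), "NA", format(object@index)),
              if (object@exact) "exact" else "upper bound"))
})

setMethod("show", "ThzAnnModel", function(object) {
  cat(sprintf("ThzAnnModel: %d-%d-1 network, %d epochs, final MSE %.4g (stop: %s)\n",
              ncol(object@W1), nrow(object@W1), length(object@history),
              tail(object@history, 1), object@stopReason))
})

#' @rdname mscCorrect
#' @export
setMethod("mscGains", "MSCResult", function(object) object@gains)

#' @rdname mscCorrect
#' @export
setMethod("mscOffsets", "MSCResult", function(object) object@offsets)

#' @rdname mscCorrect
#' @export
setMethod("corrected", "MSCResult", function(object) object@corrected)

#' @rdname minSeparatingLines
#' @export
setMethod("separabilityIndex", "SeparabilityResult", function(object) object@index)
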