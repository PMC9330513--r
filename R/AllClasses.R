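#' ThzSpectra: labelled extinction curves on a shared frequency grid
#'
#' `ThzSpectra` extends [SummarizedExperiment::SummarizedExperiment] and is the
#' pipeline's central container.  The single assay `"kappa"` stores
#' dimensionless extinction coefficients with frequencies as rows and samples
#' as columns; `rowData()$frequency_THz` holds the grid and
#' `colData()$label` the class labels (integers, `NA` for unknown).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [ThzSpectra()] for construction, [frequencyGrid()],
#'   [classLabels()], [kappaMatrix()] for access.
#' @export
setClass("ThzSpectra", contains = "SummarizedExperiment")

.validThzSpectra <- function(object) {
  msg <- character()
  if (!"kappa" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'kappa' is missing")
  f <- rowData(object)$frequency_THz
  if (is.null(f)) {
    msg <- c(msg, "rowData()$frequency_THz is missing")
  } else {
    if (is.unsorted(f, strictly = TRUE))
      msg <- c(msg, "frequency grid must be strictly increasing")
    if (length(f) > 2) {
      d <- diff(f)
      if (max(d) - min(d) > 1e-12)
        msg <- c(msg, "frequency grid must be uniformly spaced (within 1e-12 THz)")
    }
  }
  if (is.null(colData(object)$label))
    msg <- c(msg, "colData()$label is missing")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be unique")
  k <- assay(object, "kappa")
  if (length(k) && !all(is.finite(k)))
    msg <- c(msg, "kappa values must be finite")
  if (length(msg)) msg else TRUE
}
setValidity("ThzSpectra", .validThzSpectra)

#' Construct a ThzSpectra object
#'
#' @param kappa numeric matrix of extinction coefficients, frequencies in rows
#'   and samples in columns (a samples-by-frequencies matrix is transposed
#'   automatically when unambiguous via `samplesInRows`).
#' @param frequencies numeric vector of frequencies in THz, strictly
#'   increasing and uniformly spaced; length must match `nrow(kappa)`.
#' @param labels integer class labels, one per sample (`NA` allowed).
#' @param sampleIds character sample identifiers; defaults to `s1, s2, ...`.
#' @param samplesInRows set `TRUE` when `kappa` has samples in rows.
#' @return A [ThzSpectra-class] object.
#' @examples
#' grid <- makeFrequencyGrid(0.5, 0.9, 11)
#' x <- ThzSpectra(matrix(runif(22), nrow = 11), grid, labels = c(1L, 2L))
#' frequencyGrid(x)
#' @export
ThzSpectra <- function(kappa, frequencies, labels,
                       sampleIds = NULL, samplesInRows = FALSE) {
  kappa <- as.matrix(kappa)
  if (samplesInRows) kappa <- t(kappa)
  if (nrow(kappa) != length(frequencies))
    stop("nrow(kappa) must equal length(frequencies)")
  n <- ncol(kappa)
  if (length(labels) != n)
    stop("need one label per sample")
  if (is.null(sampleIds)) sampleIds <- paste0("s", seq_len(n))
  colnames(kappa) <- sampleIds
  se <- SummarizedExperiment(
    assays = list(kappa = kappa),
    rowData = DataFrame(frequency_THz = as.numeric(frequencies)),
    colData = DataFrame(label = as.integer(labels), row.names = sampleIds)
  )
  new("ThzSpectra", se)
}

#' Multivariate scattering correction result
#'
#' Holds the corrected dataset together with the reference curve (the
#' arithmetic mean of the fitted set) and the per-sample least-squares gain
#' \eqn{a_i} and offset \eqn{b_i}, so that
#' `corrected_i = (raw_i - b_i) / a_i`.
#'
#' @slot corrected [ThzSpectra-class] of corrected curves.
#' @slot reference numeric mean curve the regressions were fitted against.
#' @slot gains,offsets named numeric vectors of per-sample \eqn{a_i}, \eqn{b_i}.
#' @slot uncorrected character ids of samples left uncorrected because their
#'   fitted gain was zero (flagged with a warning at fit time).
#' @export
setClass("MSCResult",
  representation(corrected = "ThzSpectra", reference = "numeric",
                 gains = "numeric", offsets = "numeric",
                 uncorrected = "character"))

setValidity("MSCResult", function(object) {
  n <- ncol(object@corrected)
  if (length(object@gains) != n || length(object@offsets) != n)
    return("need one gain and one offset per sample")
  if (any(object@gains[!names(object@gains) %in% object@uncorrected] == 0))
    return("corrected samples must have nonzero gains")
  TRUE
})

#' Principal component model of a spectral matrix
#'
#' @slot center numeric per-frequency mean removed before rotation.
#' @slot loadings p-by-q orthonormal matrix of eigenvectors (columns), sign
#'   fixed so the largest-magnitude entry of each loading is positive.
#' @slot eigenvalues covariance eigenvalues for the retained components.
#' @slot explainedVarianceRatio fractions of total variance, non-increasing.
#' @export
setClass("PCAModel",
  representation(center = "numeric", loadings = "matrix",
                 eigenvalues = "numeric", explainedVarianceRatio = "numeric"))

setValidity("PCAModel", function(object) {
  q <- ncol(object@loadings)
  G <- crossprod(object@loadings)
  if (max(abs(G - diag(q))) > 1e-10)
    return("loadings must be orthonormal")
  r <- object@explainedVarianceRatio
  if (any(r < -1e-12 | r > 1 + 1e-12) || is.unsorted(rev(r)) || sum(r) > 1 + 1e-8)
    return("explained variance ratios must be in [0,1], non-increasing, sum <= 1")
  TRUE
})

#' Fisher scatter matrices for a two-group comparison
#'
#' Within-class scatter \eqn{S_w} and between-class scatter \eqn{S_b} as the
#' plain (unnormalized) sums of outer products, plus the two group means.
#'
#' @slot Sw,Sb symmetric positive semi-definite p-by-p matrices.
#' @slot mu0,mu1 group mean vectors.
#' @export
setClass("ScatterMatrices",
  representation(Sw = "matrix", Sb = "matrix", mu0 = "numeric", mu1 = "numeric"))

setValidity("ScatterMatrices", function(object) {
  sym <- function(M) max(abs(M - t(M))) <= 1e-8 * (1 + max(abs(M)))
  if (!sym(object@Sw) || !sym(object@Sb))
    return("scatter matrices must be symmetric")
  TRUE
})

#' Linear-separability search result for one class pair
#'
#' `s` is the number of straight lines found whose arrangement classifies the
#' 2-D points with zero error (an upper bound unless `exact`), and
#' `index = 1/s` is the separability index.  `witnessLines` holds the lines as
#' `list(normal = c(wx, wy), offset = c)` meaning the line `w . x = c`.
#'
#' @slot classPair integer vector of the two class labels compared.
#' @slot s integer minimum line count found (`NA` when none within `sMax`).
#' @slot exact `TRUE` when the search was exhaustive up to `s`.
#' @slot index numeric `1/s` (`NA` when `s` is).
#' @slot witnessLines list of witness lines.
#' @export
setClass("SeparabilityResult",
  representation(classPair = "integer", s = "integer", exact = "logical",
                 index = "numeric", witnessLines = "list"))

setValidity("SeparabilityResult", function(object) {
  if (!is.na(object@s)) {
    if (object@s < 1L) return("s must be >= 1")
    if (abs(object@index - 1 / object@s) > 1e-12)
      return("index must equal 1/s")
  }
  TRUE
})

#' A trained three-layer feedforward network
#'
#' Input layer of size p (one node per frequency), tansig hidden layer, single
#' ReLU output regressed on the numeric class targets 1/2/3.
#'
#' @slot W1,b1 hidden-layer weights (hidden x p) and biases.
#' @slot W2,b2 output weights (1 x hidden) and bias.
#' @slot history per-epoch training mean squared error.
#' @slot stopReason one of `"gradient"`, `"mse_goal"`, `"max_epochs"`.
#' @slot config the [trainConfig()] list used.
#' @export
setClass("ThzAnnModel",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 history = "numeric", stopReason = "character", config = "list"))

setValidity("ThzAnnModel", function(object) {
  if (nrow(object@W1) != length(object@b1)) return("W1/b1 shape mismatch")
  if (ncol(object@W2) != nrow(object@W1)) return("W2/W1 shape mismatch")
  if (nrow(object@W2) != 1L || length(object@b2) != 1L)
    return("single output unit expected")
  if (!all(is.finite(object@W1)) || !all(is.finite(object@W2)) ||
      !all(is.finite(object@b1)) || !all(is.finite(object@b2)))
    return("parameters must be finite")
  TRUE
})
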