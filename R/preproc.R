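#' Amplitude spectrum of a time-domain trace
#'
#' Magnitudes of the discrete Fourier transform at the non-negative
#' frequencies, with the frequency axis in THz derived from the (uniform)
#' time step in ps.
#'
#' @param trace `data.frame(time_ps, amplitude)` with a uniform time axis and
#'   at least 8 samples.
#' @return `data.frame(frequency_THz, amplitude)` covering DC to Nyquist.
#' @export
amplitudeSpectrum <- function(trace) {
  tms <- trace$time_ps
  x <- trace$amplitude
  if (length(x) < 8) stop("need at least 8 samples")
  dt <- diff(tms)
  if (max(dt) - min(dt) > 1e-9 * max(abs(dt)))
    stop("time axis must be uniform")
  N <- length(x)
  mags <- Mod(fft(x))
  half <- seq_len(N %/% 2 + 1)
  data.frame(frequency_THz = (half - 1) / (N * dt[1]),
             amplitude = mags[half])
}

#' Extinction coefficient from the amplitude transmission ratio
#'
#' Thin-slab transmission relation
#' \deqn{\kappa = \frac{c}{\omega d}\,
#'   \ln\!\frac{4 n(\omega)}{\rho(\omega)\,(1+n(\omega))^2}}
#' with \eqn{\rho} the sample-to-reference amplitude ratio, \eqn{n} the real
#' refractive index, \eqn{d} the slab thickness in meters and \eqn{\omega}
#' the angular frequency in rad/s.  \eqn{\kappa = 0} exactly at the lossless
#' Fresnel point \eqn{\rho = 4n/(1+n)^2}, and \eqn{\kappa \ge 0} whenever
#' \eqn{\rho} does not exceed it.
#'
#' @param rho amplitude transmission ratio(s), > 0.
#' @param n real refractive index, >= 1 (scalar or per-frequency).
#' @param d thickness in meters, > 0.
#' @param omega angular frequency in rad/s, > 0 (vectorized).
#' @return Dimensionless extinction coefficient(s).
#' @examples
#' extinctionCoefficient(4 * 1.5 / 2.5^2, n = 1.5, d = 1e-3,
#'                       omega = 2 * pi * 0.6e12)   # exactly 0
#' @export
extinctionCoefficient <- function(rho, n = 1.5, d, omega) {
  if (any(rho <= 0)) stop("rho must be positive")
  if (any(n < 1)) stop("refractive index must be >= 1")
  if (any(d <= 0) || any(omega <= 0)) stop("need d > 0 and omega > 0")
  cLight <- 299792458
  cLight / (omega * d) * log(4 * n / (rho * (1 + n)^2))
}

#' Window a spectral curve onto an analysis grid
#'
#' Linear interpolation of a source curve onto the (usually 91-point) analysis
#' grid.  The source range must cover the grid; applying the operation twice
#' is the same as applying it once.
#'
#' @param frequencies source frequency axis in THz.
#' @param values source curve values.
#' @param grid target grid from [makeFrequencyGrid()].
#' @return Numeric vector of `length(grid)` values.
#' @export
windowToBand <- function(frequencies, values, grid = makeFrequencyGrid()) {
  if (min(grid) < min(frequencies) || max(grid) > max(frequencies))
    stop("grid lies outside the source frequency range")
  approx(frequencies, values, xout = grid)$y
}

#' Extinction curve from a reference/sample trace pair
#'
#' Full time-domain extraction: FFT amplitude spectra of both traces, the
#' sample/reference amplitude ratio, the thin-slab extinction relation, and
#' windowing onto the analysis grid.
#'
#' @param reference,sample time-domain traces (`data.frame(time_ps, amplitude)`).
#' @param n real refractive index (default 1.5).
#' @param d slab thickness in meters (default 1 mm).
#' @param grid analysis grid in THz.
#' @return Numeric extinction values on `grid`.
#' @seealso [sampleTimeDomainPair()] for the synthesis inverse.
#' @export
extinctionFromTraces <- function(reference, sample, n = 1.5, d = 1e-3,
                                 grid = makeFrequencyGrid()) {
  ar <- amplitudeSpectrum(reference)
  as_ <- amplitudeSpectrum(sample)
  keep <- ar$frequency_THz >= min(grid) - 0.05 &
          ar$frequency_THz <= max(grid) + 0.05 & ar$amplitude > 0
  rho <- as_$amplitude[keep] / ar$amplitude[keep]
  kap <- extinctionCoefficient(rho, n = n, d = d,
                               omega = 2 * pi * ar$frequency_THz[keep] * 1e12)
  windowToBand(ar$frequency_THz[keep], kap, grid)
}

.mscFitOne <- function(kappa, reference) {
  vr <- reference - mean(reference)
  a <- sum(vr * (kappa - mean(kappa))) / sum(vr^2)
  b <- mean(kappa) - a * mean(reference)
  c(a = a, b = b)
}

#' Multivariate scattering correction
#'
#' Each curve is modelled as an affine image of a common reference curve
#' (by default the arithmetic mean of the set): ordinary least squares of
#' \eqn{\kappa_i} on the reference gives a per-sample gain \eqn{a_i} and
#' offset \eqn{b_i}, and the corrected curve is
#' \eqn{\kappa_i^{MSC} = (\kappa_i - b_i)/a_i}.
#'
#' When correcting held-out data (a test set) pass the training-set mean as
#' `reference` so no information leaks from the test samples.
#'
#' @param x a [ThzSpectra-class] or a samples-by-frequencies numeric matrix.
#' @param reference optional reference curve; defaults to the mean curve of
#'   `x` itself.  Must not be constant.
#' @param ... unused.
#' @return An [MSCResult-class]; see [corrected()], [mscGains()],
#'   [mscOffsets()].
#' @examples
#' cfg <- syntheticConfig(nPerClass = 4, seed = 2)
#' ds <- sampleExtinctionDataset(makeClassProfiles(cfg), cfg)
#' res <- mscCorrect(ds)
#' range(mscGains(res))
#' @name mscCorrect
NULL

#' @rdname mscCorrect
#' @export
setMethod("mscCorrect", "ThzSpectra", function(x, reference = NULL, ...) {
  X <- kappaMatrix(x)        # samples x p
  if (nrow(X) < 2 && is.null(reference))
    stop("need at least 2 spectra to form a reference")
  if (is.null(reference)) reference <- colMeans(X)
  if (sd(reference) == 0)
    stop("degenerate input: reference curve is constant")
  n <- nrow(X)
  gains <- numeric(n); offsets <- numeric(n)
  uncorrected <- character()
  Xc <- X
  for (i in seq_len(n)) {
    ab <- .mscFitOne(X[i, ], reference)
    gains[i] <- ab["a"]; offsets[i] <- ab["b"]
    if (ab["a"] == 0) {
      uncorrected <- c(uncorrected, rownames(X)[i])
    } else {
      Xc[i, ] <- (X[i, ] - ab["b"]) / ab["a"]
    }
  }
  if (length(uncorrected))
    warning("fitted gain a_i = 0; passed through uncorrected: ",
            paste(uncorrected, collapse = ", "))
  names(gains) <- names(offsets) <- rownames(X)
  out <- ThzSpectra(t(Xc), frequencyGrid(x), classLabels(x),
                    sampleIds = colnames(x))
  new("MSCResult", corrected = out, reference = as.numeric(reference),
      gains = gains, offsets = offsets, uncorrected = uncorrected)
})

#' @rdname mscCorrect
#' @export
setMethod("mscCorrect", "matrix", function(x, reference = NULL, ...) {
  p <- ncol(x)
  grid <- seq(0, 1, length.out = p)
  obj <- ThzSpectra(t(x), grid, labels = rep(NA_integer_, nrow(x)),
                    sampleIds = rownames(x))
  mscCorrect(obj, reference = reference)
})

#' Per-sample MSC coefficients as a table
#'
#' @param object an [MSCResult-class].
#' @return `data.frame(sample_id, a_i, b_i)`.
#' @export
mscCoefficients <- function(object) {
  stopifnot(is(object, "MSCResult"))
  data.frame(sample_id = names(mscGains(object)),
             a_i = unname(mscGains(object)),
             b_i = unname(mscOffsets(object)))
}
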