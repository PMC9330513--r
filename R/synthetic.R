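#' Construct a uniform frequency grid
#'
#' @param fMin,fMax band limits in THz; `fMax > fMin`.
#' @param nPoints number of grid points (`>= 2`).
#' @return Strictly increasing, uniformly spaced numeric vector with first
#'   element `fMin` and last `fMax`.  The default is the 91-point analysis
#'   band from 0.5 to 0.9 THz.
#' @examples
#' g <- makeFrequencyGrid()
#' length(g)      # 91
#' diff(g)[1]     # 0.4/90 THz
#' @export
makeFrequencyGrid <- function(fMin = 0.5, fMax = 0.9, nPoints = 91L) {
  if (!is.numeric(fMin) || !is.numeric(fMax) || fMax <= fMin)
    stop("need fMax > fMin")
  if (nPoints < 2) stop("need nPoints >= 2")
  seq(fMin, fMax, length.out = as.integer(nPoints))
}

#' Configuration for the synthetic extinction-spectrum generator
#'
#' The generator emulates the structure of featureless (peak-free) extinction
#' curves of three gelatin classes: a shared smooth base curve, a small
#' class-specific deviation that survives multivariate scattering correction,
#' and a per-sample scatter model
#' \deqn{\kappa_i = a_i (\mu_g + \delta_g) + b_i + \varepsilon_i}
#' with gain \eqn{a_i \sim N(1, gainSd)} truncated positive, offset
#' \eqn{b_i \sim N(0, offsetSd)} and i.i.d. per-frequency noise
#' \eqn{\varepsilon_i \sim N(0, noiseSd)}.
#'
#' The default scatter magnitudes are calibrated so that the scatter dominates
#' the raw data (first principal component above ~96% explained variance and
#' overlapping class pairs in the raw 2-PC plane) while the class deviations
#' remain cleanly recoverable after correction.
#'
#' @param nPerClass samples per class (default 90).
#' @param nClasses number of classes (default 3).
#' @param grid frequency grid from [makeFrequencyGrid()].
#' @param gainSd,offsetSd,noiseSd scatter-model standard deviations (all >= 0).
#' @param classSignalScale magnitude of the class deviation curves relative to
#'   unit-norm deviation directions; 0 makes classes indistinguishable.
#' @param seed integer; fully determines the generated data.
#' @return A classed list of settings.
#' @export
syntheticConfig <- function(nPerClass = 90L, nClasses = 3L,
                            grid = makeFrequencyGrid(),
                            gainSd = 0.15, offsetSd = 0.05, noiseSd = 0.005,
                            classSignalScale = 0.1, seed = 1L) {
  stopifnot(nPerClass >= 0, nClasses >= 1,
            gainSd >= 0, offsetSd >= 0, noiseSd >= 0, classSignalScale >= 0)
  structure(list(nPerClass = as.integer(nPerClass),
                 nClasses = as.integer(nClasses),
                 grid = grid, gainSd = gainSd, offsetSd = offsetSd,
                 noiseSd = noiseSd, classSignalScale = classSignalScale,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Deviation directions orthogonal to span{base, 1}: curvature from (f-fc)^2
# and skew from (f-fc)^3.  Orthogonality guarantees MSC cannot erase them.
.deviationBasis <- function(base, f) {
  fc <- mean(range(f))
  span <- qr.Q(qr(cbind(base, rep(1, length(f)))))
  proj <- function(v) drop(v - span %*% crossprod(span, v))
  u1 <- proj((f - fc)^2)
  u1 <- u1 / sqrt(sum(u1^2))
  u2 <- proj((f - fc)^3)
  u2 <- u2 - u1 * sum(u1 * u2)
  u2 <- u2 / sqrt(sum(u2^2))
  cbind(u1, u2)
}

# Class coordinates in the (u1, u2) deviation plane; rows sum to zero so the
# dataset mean curve stays close to the base curve.  The three-class layout is
# the calibrated default; other class counts fall back to a zero-mean polygon.
.classCoords <- function(nClasses) {
  if (nClasses == 3L)
    return(rbind(c(-1, -0.2), c(0, 0.4), c(1, -0.2)))
  if (nClasses == 1L) return(rbind(c(1, 0)))
  ang <- 2 * pi * (seq_len(nClasses) - 1) / nClasses
  cbind(cos(ang), sin(ang))
}

#' Generate class extinction profiles
#'
#' Builds one profile per class: a shared smooth, monotone, peak-free base
#' curve (quadratic in frequency) plus a class-specific deviation curve lying
#' orthogonal to `span{base, 1}`, so ordinary scattering correction preserves
#' the class signal.  Deterministic given the config.
#'
#' @param config a [syntheticConfig()].
#' @return List of profiles, each `list(label, meanCurve, deviationCurve)` on
#'   `config$grid`.
#' @examples
#' pr <- makeClassProfiles(syntheticConfig())
#' length(pr)                    # 3
#' @export
makeClassProfiles <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  f <- config$grid
  base <- 0.55 + 1.6 * (f - f[1]) + 0.9 * (f - f[1])^2
  U <- .deviationBasis(base, f)
  coords <- .classCoords(config$nClasses) * config$classSignalScale
  if (config$classSignalScale == 0)
    warning("classSignalScale = 0: classes are indistinguishable by design")
  lapply(seq_len(config$nClasses), function(g) {
    list(label = g,
         meanCurve = base,
         deviationCurve = drop(U %*% coords[g, ]))
  })
}

#' Sample a labelled synthetic extinction dataset
#'
#' Draws `nPerClass` spectra per class under the scatter model
#' `kappa_i = a_i (mean_g + deviation_g) + b_i + noise`, with the gain
#' truncated positive.  Bit-reproducible from `config$seed`.
#'
#' @param profiles output of [makeClassProfiles()] (on `config$grid`).
#' @param config the matching [syntheticConfig()].
#' @return A [ThzSpectra-class] with `nClasses * nPerClass` samples.
#' @examples
#' cfg <- syntheticConfig(nPerClass = 5, seed = 7)
#' ds <- sampleExtinctionDataset(makeClassProfiles(cfg), cfg)
#' table(classLabels(ds))
#' @export
sampleExtinctionDataset <- function(profiles, config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  p <- length(config$grid)
  for (pr in profiles)
    if (length(pr$meanCurve) != p || length(pr$deviationCurve) != p)
      stop("profiles are not on the config grid")
  n <- config$nPerClass * config$nClasses
  labels <- rep(seq_len(config$nClasses), each = config$nPerClass)
  kappa <- matrix(0, nrow = p, ncol = n)
  set.seed(config$seed)
  for (i in seq_len(n)) {
    pr <- profiles[[labels[i]]]
    a <- rnorm(1, 1, config$gainSd)
    while (a <= 0) a <- rnorm(1, 1, config$gainSd)
    b <- rnorm(1, 0, config$offsetSd)
    eps <- rnorm(p, 0, config$noiseSd)
    kappa[, i] <- a * (pr$meanCurve + pr$deviationCurve) + b + eps
  }
  ThzSpectra(kappa, config$grid, labels,
             sampleIds = sprintf("s%03d", seq_len(n)))
}

#' Synthesize a reference/sample time-domain pulse pair
#'
#' Emits a single-cycle terahertz pulse (Gaussian-derivative shape, width
#' about 1 ps, peak amplitude about 2000 detector units) and the corresponding
#' transmitted pulse for one class: the reference spectrum is multiplied per
#' frequency by the amplitude transmission
#' \deqn{\rho(\omega) = \frac{4n}{(1+n)^2} e^{-\kappa \omega d / c},}
#' the inverse of the thin-slab extinction relation, and transformed back to
#' the time domain.  Feeding the pair through [extinctionFromTraces()]
#' recovers the class extinction curve on the analysis grid.
#'
#' @param config a [syntheticConfig()]; supplies the grid and class profiles.
#' @param classLabel class whose extinction curve modulates the sample pulse.
#' @param profiles optional profiles (defaults to `makeClassProfiles(config)`).
#' @param n real refractive index of the slab (constant, default 1.5).
#' @param d slab thickness in meters (default 1 mm).
#' @param nTime,dt time axis: `nTime` points spaced `dt` ps.
#' @return `list(reference, sample)`, each a `data.frame(time_ps, amplitude)`,
#'   with the `n` and `d` used attached as attributes.
#' @export
sampleTimeDomainPair <- function(config, classLabel, profiles = NULL,
                                 n = 1.5, d = 1e-3,
                                 nTime = 2048L, dt = 0.05) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(profiles)) profiles <- suppressWarnings(makeClassProfiles(config))
  if (classLabel < 1 || classLabel > length(profiles))
    stop("classLabel out of range")
  pr <- profiles[[classLabel]]
  tms <- (seq_len(nTime) - 1) * dt
  t0 <- 25
  sigma <- 0.35
  shape <- -(tms - t0) / sigma * exp(-(tms - t0)^2 / (2 * sigma^2))
  refAmp <- 2000 / exp(-0.5) * shape

  freqs <- (seq_len(nTime) - 1) / (nTime * dt)        # THz (dt in ps)
  halfIdx <- seq_len(nTime %/% 2 + 1)
  fPos <- freqs[halfIdx]
  kcurve <- pr$meanCurve + pr$deviationCurve
  # constant extension outside the band keeps rho smooth and positive
  kap <- approx(config$grid, kcurve, xout = fPos, rule = 2)$y
  omega <- 2 * pi * fPos * 1e12
  cLight <- 299792458
  rho <- 4 * n / (1 + n)^2 * exp(-kap * omega * d / cLight)

  R <- fft(refAmp)
  Hpos <- rho
  H <- numeric(nTime)
  H[halfIdx] <- Hpos
  if (nTime %% 2 == 0) {
    H[(nTime %/% 2 + 2):nTime] <- rev(Hpos[2:(nTime %/% 2)])
  } else {
    H[(nTime %/% 2 + 2):nTime] <- rev(Hpos[2:(nTime %/% 2 + 1)])
  }
  sampAmp <- Re(fft(R * H, inverse = TRUE)) / nTime

  mk <- function(a, kind) {
    out <- data.frame(time_ps = tms, amplitude = a)
    attr(out, "kind") <- kind
    out
  }
  out <- list(reference = mk(refAmp, "reference"), sample = mk(sampAmp, "sample"))
  attr(out, "n") <- n
  attr(out, "d") <- d
  out
}
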