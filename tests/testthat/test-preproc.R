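test_that("amplitude spectrum localizes tones and satisfies Parseval", {
  dt <- 0.05
  tm <- (0:2047) * dt
  tone <- data.frame(time_ps = tm, amplitude = cos(2 * pi * 0.6 * tm))
  sp <- amplitudeSpectrum(tone)
  expect_equal(sp$frequency_THz[which.max(sp$amplitude)], 0.6,
               tolerance = 1 / (2048 * dt))

  zero <- data.frame(time_ps = tm, amplitude = rep(0, 2048))
  expect_true(all(amplitudeSpectrum(zero)$amplitude == 0))

  set.seed(5)
  x <- rnorm(2048)
  sp <- amplitudeSpectrum(data.frame(time_ps = tm, amplitude = x))
  # Parseval over the full spectrum reconstructed from non-negative bins
  m2 <- sp$amplitude^2
  full <- m2[1] + 2 * sum(m2[2:(length(m2) - 1)]) + m2[length(m2)]
  expect_equal(sum(x^2), full / 2048)

  expect_error(amplitudeSpectrum(data.frame(time_ps = cumsum(runif(64)),
                                            amplitude = rnorm(64))), "uniform")
  expect_error(amplitudeSpectrum(tone[1:4, ]), "8 samples")
})

test_that("extinction coefficient follows the thin-slab relation", {
  omega <- 2 * pi * 0.6e12
  # lossless Fresnel point
  expect_equal(extinctionCoefficient(4 * 1.5 / 2.5^2, n = 1.5, d = 1e-3,
                                     omega = omega), 0)
  # rho = fresnel * exp(-1) gives exactly c/(omega d)
  rho <- 4 * 1.5 / 2.5^2 * exp(-1)
  expect_equal(extinctionCoefficient(rho, n = 1.5, d = 1e-3, omega = omega),
               299792458 / (omega * 1e-3))
  expect_equal(299792458 / (omega * 1e-3), 0.0796, tolerance = 1e-3)
  # monotone decreasing in rho; non-negative below the Fresnel point
  rhos <- seq(0.1, 0.96, length.out = 20)
  ks <- extinctionCoefficient(rhos, n = 1.5, d = 1e-3, omega = omega)
  expect_true(all(diff(ks) < 0))
  expect_true(all(ks >= 0))
  expect_error(extinctionCoefficient(-0.1, n = 1.5, d = 1e-3, omega = omega),
               "positive")
})

test_that("band windowing interpolates linearly and is a projection", {
  grid <- makeFrequencyGrid(0.5, 0.9, 91)
  # identity on curves already sampled on the grid
  v <- sin(grid * 7)
  expect_equal(windowToBand(grid, v, grid), v)
  # exact on linear curves
  src <- seq(0.3, 1.1, by = 0.007)
  expect_equal(windowToBand(src, 2 * src, grid), 2 * grid)
  # projection: twice == once
  w1 <- windowToBand(src, src^2, grid)
  expect_equal(windowToBand(grid, w1, grid), w1)
  expect_error(windowToBand(seq(0.6, 0.9, 0.01), 1:31, grid), "outside")
})

test_that("MSC recovers affine families and reduces pointwise deviation", {
  grid <- makeFrequencyGrid(0.5, 0.9, 21)
  mu <- 0.5 + grid^2

  # identical spectra: self-regression gives a_i = 1, b_i = 0
  X <- matrix(mu, 6, 21, byrow = TRUE)
  res <- mscCorrect(X)
  expect_equal(unname(mscGains(res)), rep(1, 6))
  expect_equal(unname(mscOffsets(res)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(kappaMatrix(corrected(res))), X)

  # exact affine family collapses to zero within-set variance
  set.seed(8)
  alpha <- runif(8, 0.5, 2)
  beta <- rnorm(8)
  Xa <- t(vapply(1:8, function(i) alpha[i] * mu + beta[i], numeric(21)))
  resA <- mscCorrect(Xa)
  K <- kappaMatrix(corrected(resA))
  expect_lt(max(apply(K, 2, sd)), 1e-10)
  # fitted coefficients match the generating ones up to the common affine map
  # of the mean curve: corrected curves equal a shared affine image of mu
  expect_lt(max(abs(sweep(K, 2, K[1, ]))), 1e-10)

  # synthetic scatter: pointwise sd strictly smaller after correction at
  # every frequency
  ds <- tinyDataset(nPerClass = 20, seed = 4)
  raw <- kappaMatrix(ds)
  cor <- kappaMatrix(corrected(mscCorrect(ds)))
  expect_true(all(apply(cor, 2, sd) < apply(raw, 2, sd)))

  # idempotence under the stored-reference convention: a second pass against
  # the first pass's reference is the identity (second-pass a_i = 1, b_i = 0)
  first <- mscCorrect(ds)
  second <- mscCorrect(corrected(first), reference = first@reference)
  expect_lt(max(abs(kappaMatrix(corrected(second)) - cor)) /
              max(abs(cor)), 1e-8)
  expect_equal(unname(mscGains(second)), rep(1, 60), tolerance = 1e-10)
  expect_equal(unname(mscOffsets(second)), rep(0, 60), tolerance = 1e-10)

  # degenerate reference
  expect_error(mscCorrect(matrix(1, 4, 10)), "constant")
})

test_that("MSC with a training reference corrects held-out curves consistently", {
  ds <- tinyDataset(nPerClass = 12, seed = 9)
  X <- kappaMatrix(ds)
  ref <- colMeans(X[1:18, ])
  resTr <- mscCorrect(X[1:18, ], reference = ref)
  resTe <- mscCorrect(X[19:36, ], reference = ref)
  expect_equal(resTe@reference, as.numeric(ref))
  # corrected held-out curves are near the profile curves, not the raw ones
  expect_lt(max(apply(kappaMatrix(corrected(resTe)), 2, sd)),
            max(apply(X[19:36, ], 2, sd)))
})
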