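test_that("PCA matches hand eigendecompositions and conventions", {
  # rank-1 data: PC1 explains everything
  X <- cbind(0:2, rep(0, 3))
  m <- pcaFit(X, q = 2)
  expect_equal(explainedVariance(m), c(1, 0))
  expect_equal(abs(m@loadings[, 1]), c(1, 0))

  # hand eigendecomposition: points on the diagonal
  X2 <- rbind(c(1, 1), c(-1, -1), c(2, 2), c(-2, -2))
  m2 <- pcaFit(X2, q = 2)
  expect_equal(m2@loadings[, 1], c(1, 1) / sqrt(2))
  expect_equal(explainedVariance(m2)[1], 1)

  # orthonormal loadings, ratios sum to 1 at full rank
  set.seed(2)
  X3 <- matrix(rnorm(60), 12, 5)
  m3 <- pcaFit(X3, q = 5)
  expect_equal(crossprod(m3@loadings), diag(5), tolerance = 1e-10)
  expect_equal(sum(explainedVariance(m3)), 1)
  expect_false(is.unsorted(rev(explainedVariance(m3))))
  # sign convention: largest-magnitude entry positive
  for (j in 1:5) expect_gt(m3@loadings[which.max(abs(m3@loadings[, j])), j], 0)
})

test_that("PCA projection satisfies the usual identities", {
  set.seed(3)
  X <- matrix(rnorm(80), 16, 5)
  m <- pcaFit(X, q = 5)
  Y <- pcaProject(m, X)
  # score variances equal the eigenvalues
  expect_equal(apply(Y, 2, var), m@eigenvalues, tolerance = 1e-10)
  # projecting the mean gives the origin
  expect_equal(drop(pcaProject(m, colMeans(X))), rep(0, 5), tolerance = 1e-10)
  # full-rank reconstruction
  Xhat <- sweep(Y %*% t(m@loadings), 2, -m@center)
  expect_lt(max(abs(Xhat - X)), 1e-8)
  expect_error(pcaProject(m, matrix(0, 2, 4)), "mismatch")
  # fit on one subset, project another: shared axes
  sc <- pcaScores2D(m, X[1:4, ], labels = rep(1L, 4))
  expect_equal(as.matrix(sc[, c("pc1", "pc2")]), Y[1:4, 1:2],
               ignore_attr = TRUE)
})

test_that("scatter matrices match hand arithmetic", {
  X0 <- rbind(c(0, 0), c(2, 0))
  X1 <- rbind(c(0, 2), c(2, 2))
  S <- scatterMatrices(rbind(X0, X1), c(0, 0, 1, 1))
  expect_equal(S@mu0, c(1, 0))
  expect_equal(S@mu1, c(1, 2))
  expect_equal(S@Sw, rbind(c(4, 0), c(0, 0)))
  expect_equal(S@Sb, rbind(c(0, 0), c(0, 4)))

  # equal means: zero between-class scatter
  Se <- scatterMatrices(rbind(c(0, 0), c(2, 2), c(1, 1), c(1, 1)),
                        c(0, 0, 1, 1))
  expect_equal(Se@Sb, matrix(0, 2, 2))
  # singleton groups: zero within-class scatter
  Ss <- scatterMatrices(rbind(c(0, 0), c(1, 3)), c(0, 1))
  expect_equal(Ss@Sw, matrix(0, 2, 2))
  expect_error(scatterMatrices(rbind(c(0, 0)), c(0)), "two groups")
})

test_that("Rayleigh quotient is scale-invariant with a degenerate branch", {
  S <- scatterMatrices(rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2)),
                       c(0, 0, 1, 1))
  w <- c(0.3, 1.1)
  expect_equal(rayleighQuotient(2 * w, S), rayleighQuotient(w, S))
  # degenerate denominator along (0, 1)
  expect_warning(J <- rayleighQuotient(c(0, 1), S), "degenerate")
  expect_identical(J, Inf)
  # ridge regularization: J -> 4 / eps
  eps <- 1e-6
  Sr <- new("ScatterMatrices", Sw = S@Sw + rbind(c(0, 0), c(0, eps)),
            Sb = S@Sb, mu0 = S@mu0, mu1 = S@mu1)
  expect_equal(rayleighQuotient(c(0, 1), Sr), 4 / eps)
  # equal means: J = 0 everywhere
  Se <- scatterMatrices(rbind(c(0, 0), c(2, 2), c(1, 1), c(1, 1)),
                        c(0, 0, 1, 1))
  expect_equal(rayleighQuotient(c(1, 2), Se), 0)
  expect_error(rayleighQuotient(c(0, 0), S), "nonzero")
})

test_that("Fisher direction maximizes J and equals the top generalized eigenvalue", {
  set.seed(7)
  X <- rbind(matrix(rnorm(40, sd = c(1, 3)), 20, 2, byrow = TRUE),
             matrix(rnorm(40, sd = c(1, 3)), 20, 2, byrow = TRUE) + c(3, 1))
  lab <- rep(0:1, each = 20)
  S <- scatterMatrices(X, lab)
  w <- fisherDirection(S)
  Jw <- rayleighQuotient(w, S)
  # beats 1000 random directions
  ang <- runif(1000, 0, pi)
  Jr <- vapply(seq_along(ang), function(i)
    rayleighQuotient(c(cos(ang[i]), sin(ang[i])), S), numeric(1))
  expect_true(all(Jw >= Jr - 1e-12))
  # equals the top generalized eigenvalue of (Sb, Sw)
  lambda <- max(Re(eigen(solve(S@Sw) %*% S@Sb)$values))
  expect_equal(Jw, lambda, tolerance = 1e-8)
  # label swap flips the direction
  S2 <- scatterMatrices(X, 1 - lab)
  expect_equal(fisherDirection(S2), -w, tolerance = 1e-10)
  # isotropic within-class scatter: direction parallel to the mean difference
  Si <- new("ScatterMatrices", Sw = diag(2), Sb = S@Sb, mu0 = c(0, 0),
            mu1 = c(3, 1))
  expect_equal(abs(sum(fisherDirection(Si) *
                         c(-3, -1) / sqrt(10))), 1, tolerance = 1e-12)
})

test_that("linear separability decisions match the enumeration oracle", {
  # two tight distant clusters: separable
  set.seed(11)
  A <- matrix(rnorm(20, sd = 0.5), 10, 2)
  B <- matrix(rnorm(20, sd = 0.5), 10, 2) + 10
  r <- isLinearlySeparable(rbind(A, B), rep(1:2, each = 10))
  expect_true(r$separable)
  # the witness actually separates
  sA <- A %*% r$witness$normal - r$witness$offset
  sB <- B %*% r$witness$normal - r$witness$offset
  expect_true(all(sA < 0) && all(sB > 0))

  # XOR corners: not separable
  xor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  expect_false(isLinearlySeparable(xor, c(1, 1, 2, 2))$separable)

  # single distinct points: separable; duplicated cross-labelled point: not
  expect_true(isLinearlySeparable(rbind(c(0, 0), c(1, 0)), 1:2)$separable)
  expect_false(isLinearlySeparable(rbind(c(1, 1), c(1, 1), c(3, 3)),
                                   c(1, 2, 2))$separable)

  # randomized equivalence with the candidate-line enumeration oracle
  set.seed(19)
  agree <- vapply(1:200, function(k) {
    n <- sample(3:8, 1)
    m <- sample(3:8, 1)
    shift <- runif(1, 0, 3)
    pts <- rbind(matrix(rnorm(2 * n), n, 2),
                 matrix(rnorm(2 * m), m, 2) + shift)
    lab <- rep(1:2, c(n, m))
    isLinearlySeparable(pts, lab)$separable == enumSeparable(pts, lab)
  }, logical(1))
  expect_true(all(agree))
})

test_that("minimum separating lines: exact small cases and index bookkeeping", {
  xor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  res <- minSeparatingLines(xor, c(1, 1, 2, 2))
  expect_equal(res@s, 2L)
  expect_equal(separabilityIndex(res), 0.5)
  expect_true(res@exact)
  expect_true(enumTwoLines(xor, c(1, 1, 2, 2)))   # oracle agrees two suffice
  # witness lines reclassify the input without error
  pred <- classifyWithLines(xor, c(1, 1, 2, 2), res@witnessLines)
  expect_equal(pred, c(1L, 1L, 2L, 2L))

  # separable pair: s = 1
  two <- rbind(c(0, 0), c(0, 1), c(5, 0), c(5, 1))
  r1 <- minSeparatingLines(two, c(1, 1, 2, 2))
  expect_equal(r1@s, 1L)
  expect_equal(separabilityIndex(r1), 1)

  # three collinear clusters A | B | A need two lines
  set.seed(23)
  tri <- rbind(matrix(c(rnorm(8, 0, 0.1), rnorm(8, 0, 0.1)), 8, 2),
               matrix(c(rnorm(8, 5, 0.1), rnorm(8, 0, 0.1)), 8, 2),
               matrix(c(rnorm(8, 10, 0.1), rnorm(8, 0, 0.1)), 8, 2))
  lab <- rep(c(1, 2, 1), each = 8)
  r2 <- minSeparatingLines(tri, lab)
  expect_equal(r2@s, 2L)
  expect_true(r2@exact)
  expect_equal(classifyWithLines(tri, lab, r2@witnessLines), lab)

  # s-budget consistency: a larger budget never yields a larger s
  r3 <- minSeparatingLines(tri, lab, sMax = 3)
  expect_lte(r3@s, r2@s + 0L)
  # budget too small: undefined s with empty witness
  r4 <- minSeparatingLines(xor, c(1, 1, 2, 2), sMax = 1)
  expect_true(is.na(r4@s))
  expect_true(is.na(separabilityIndex(r4)))
})

test_that("minSeparatingLines agrees with isLinearlySeparable at s = 1", {
  set.seed(29)
  agree <- vapply(1:100, function(k) {
    n <- sample(4:10, 1)
    shift <- runif(1, 0, 4)
    pts <- rbind(matrix(rnorm(2 * n), n, 2),
                 matrix(rnorm(2 * n), n, 2) + shift)
    lab <- rep(1:2, each = n)
    res <- minSeparatingLines(pts, lab, sMax = 2)
    (res@s == 1L && !is.na(res@s)) == isLinearlySeparable(pts, lab)$separable
  }, logical(1))
  expect_true(all(agree))
})

test_that("multiclass separability covers all pairs", {
  set.seed(31)
  sc <- data.frame(
    label = rep(1:3, each = 10),
    pc1 = rnorm(30) + rep(c(0, 8, 16), each = 10),
    pc2 = rnorm(30))
  res <- multiclassSeparability(sc)
  expect_length(res, 3)
  expect_true(all(vapply(res, separabilityIndex, numeric(1)) == 1))
  expect_length(multiclassSeparability(sc[sc$label < 3, ]), 1)
  expect_length(multiclassSeparability(sc[sc$label == 1, ]), 0)
})
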