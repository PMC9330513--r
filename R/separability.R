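#' Principal component analysis of a spectral matrix
#'
#' Column means are removed, the covariance eigenvectors are sorted by
#' descending eigenvalue, and the explained-variance ratio of component k is
#' its eigenvalue over the eigenvalue total.  The sign of each loading is
#' fixed so its largest-magnitude entry is positive.
#'
#' @param x samples-by-features numeric matrix, or a [ThzSpectra-class].
#' @param q number of components to retain (`<= ncol(x)`).
#' @param ... unused.
#' @return A [PCAModel-class].
#' @name pcaFit
NULL

#' @rdname pcaFit
#' @export
setMethod("pcaFit", "matrix", function(x, q = 2L, ...) {
  if (nrow(x) < 2) stop("need at least 2 samples")
  q <- as.integer(q)
  if (q > ncol(x)) stop("q must not exceed the feature dimension")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  k <- min(q, ncol(pc$rotation))
  L <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(L)))
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  ratioQ <- numeric(q)
  ratioQ[seq_len(k)] <- ratio[seq_len(k)]
  evQ <- numeric(q)
  evQ[seq_len(k)] <- ev[seq_len(k)]
  if (k < q) {
    # rank-deficient request: trailing components carry zero variance
    warning("requested more components than the data rank; trailing ratios are 0")
    extra <- matrix(0, nrow = ncol(x), ncol = q - k)
    L <- cbind(L, extra)
  }
  new("PCAModel", center = unname(pc$center), loadings = unname(L),
      eigenvalues = evQ, explainedVarianceRatio = ratioQ)
})

#' @rdname pcaFit
#' @export
setMethod("pcaFit", "ThzSpectra", function(x, q = 2L, ...)
  pcaFit(kappaMatrix(x), q = q))

#' @rdname pcaFit
#' @export
setMethod("explainedVariance", "PCAModel", function(model)
  model@explainedVarianceRatio)

#' @rdname pcaFit
#' @param model a fitted [PCAModel-class].
#' @export
setMethod("pcaProject", "PCAModel", function(model, x, ...) {
  if (is(x, "ThzSpectra")) x <- kappaMatrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(model@center)) stop("feature dimension mismatch")
  sweep(x, 2, model@center) %*% model@loadings
})

#' First-two-component scores with labels
#'
#' Convenience wrapper: project onto the first two principal components and
#' return a labelled score table (the 2-D feature space used by the
#' separability index).
#'
#' @param model a [PCAModel-class] with at least two components.
#' @param x a [ThzSpectra-class] or matrix with labels supplied separately.
#' @param labels labels when `x` is a matrix.
#' @return `data.frame(sample_id, label, pc1, pc2)`.
#' @export
pcaScores2D <- function(model, x, labels = NULL) {
  if (is(x, "ThzSpectra")) {
    labels <- as.integer(classLabels(x))
    ids <- colnames(x)
  } else ids <- rownames(x) %||% paste0("s", seq_len(nrow(x)))
  sc <- pcaProject(model, x)
  if (ncol(sc) < 2) stop("need at least two components")
  data.frame(sample_id = ids, label = labels, pc1 = sc[, 1], pc2 = sc[, 2],
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher scatter matrices
#'
#' Unnormalized within-class and between-class scatter for two groups:
#' \deqn{S_w = \sum_{x \in X_0}(x-\mu_0)(x-\mu_0)^T +
#'             \sum_{x \in X_1}(x-\mu_1)(x-\mu_1)^T, \quad
#'       S_b = (\mu_0-\mu_1)(\mu_0-\mu_1)^T.}
#'
#' @param points numeric matrix, one row per observation.
#' @param labels two-level grouping vector; the first level (in sorted order)
#'   is group 0.
#' @return A [ScatterMatrices-class].
#' @export
scatterMatrices <- function(points, labels) {
  points <- as.matrix(points)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly two groups")
  X0 <- points[labels == lev[1], , drop = FALSE]
  X1 <- points[labels == lev[2], , drop = FALSE]
  if (!nrow(X0) || !nrow(X1)) stop("both groups must be non-empty")
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  Sw <- crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))
  db <- mu0 - mu1
  new("ScatterMatrices", Sw = unname(Sw), Sb = unname(tcrossprod(db)),
      mu0 = unname(mu0), mu1 = unname(mu1))
}

#' Generalized Rayleigh quotient
#'
#' `J(w) = (w' Sb w) / (w' Sw w)`, the between- over within-class scatter
#' along direction `w`; invariant to rescaling of `w`.  When the denominator
#' vanishes the quotient is degenerate: `Inf` is returned (with a warning)
#' if the numerator is positive, `NaN` otherwise.
#'
#' @param w nonzero direction vector.
#' @param S a [ScatterMatrices-class].
#' @return Scalar `J >= 0`.
#' @export
rayleighQuotient <- function(w, S) {
  stopifnot(is(S, "ScatterMatrices"))
  if (all(w == 0)) stop("w must be nonzero")
  num <- drop(crossprod(w, S@Sb %*% w))
  den <- drop(crossprod(w, S@Sw %*% w))
  if (den == 0) {
    warning("w' Sw w = 0: degenerate Rayleigh quotient")
    return(if (num > 0) Inf else NaN)
  }
  num / den
}

#' Fisher discriminant direction
#'
#' The direction maximizing the generalized Rayleigh quotient,
#' `w = Sw^{-1} (mu0 - mu1)` (unit norm).  A ridge `eps * trace(Sw) * I`
#' with `eps = 1e-8` is added when `Sw` is singular.
#'
#' @param S a [ScatterMatrices-class] with distinct group means.
#' @return Unit-norm numeric vector.
#' @export
fisherDirection <- function(S) {
  stopifnot(is(S, "ScatterMatrices"))
  db <- S@mu0 - S@mu1
  if (all(db == 0)) stop("group means are identical: no Fisher direction")
  Sw <- S@Sw
  w <- tryCatch(solve(Sw, db), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) {
    ridge <- 1e-8 * max(sum(diag(Sw)), 1)
    w <- solve(Sw + diag(ridge, nrow(Sw)), db)
  }
  w / sqrt(sum(w^2))
}

# ---- linear separability geometry ------------------------------------------

# Closest point of segment [p, q] to the origin.
.closestOnSegment <- function(p, q) {
  d <- q - p
  L2 <- sum(d^2)
  t <- if (L2 == 0) 0 else max(0, min(1, -sum(p * d) / L2))
  p + t * d
}

#' Exact linear-separability test for two labelled point sets in 2-D
#'
#' Decides whether some straight line puts all points of one class strictly
#' on one side and all points of the other class strictly on the opposite
#' side.  The decision uses the geometric dual of the feasibility problem:
#' the sets are strictly separable if and only if the origin lies outside the
#' closed convex hull of the pairwise difference set `{a - b}`.  A duplicated
#' point carrying both labels therefore makes the sets inseparable with no
#' special casing.
#'
#' @param points n-by-2 numeric matrix.
#' @param labels two-level grouping vector.
#' @return `list(separable, witness)`; the witness (when separable) is
#'   `list(normal, offset, sideOfFirst)` describing the line
#'   `normal . x = offset` with the first class on the side
#'   `sign(normal . x - offset) == sideOfFirst`.
#' @export
isLinearlySeparable <- function(points, labels) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly two classes")
  A <- points[labels == lev[1], , drop = FALSE]
  B <- points[labels == lev[2], , drop = FALSE]
  if (!nrow(A) || !nrow(B)) stop("both classes must be non-empty")
  # pairwise differences a - b
  D <- cbind(rep(A[, 1], times = nrow(B)) - rep(B[, 1], each = nrow(A)),
             rep(A[, 2], times = nrow(B)) - rep(B[, 2], each = nrow(A)))
  diam <- max(abs(D))
  tol <- 1e-12 * max(diam, 1)
  if (diam <= tol)                      # all differences ~ 0
    return(list(separable = FALSE, witness = NULL))
  h <- chull(D)
  P <- D[h, , drop = FALSE]
  inHull <- if (nrow(P) <= 2) {
    p <- P[1, ]; q <- P[nrow(P), ]
    sum(.closestOnSegment(p, q)^2) <= (tol)^2
  } else {
    nv <- nrow(P)
    nxt <- c(2:nv, 1)
    cr <- P[, 1] * P[nxt, 2] - P[, 2] * P[nxt, 1]   # cross(P_i, P_{i+1})
    crTol <- tol * diam
    !(any(cr > crTol) && any(cr < -crTol))          # mixed signs => outside
  }
  if (inHull) return(list(separable = FALSE, witness = NULL))
  # witness: w = -c/|c| for c the closest hull point to the origin
  nv <- nrow(P)
  best <- NULL; bestD <- Inf
  for (i in seq_len(nv)) {
    cpt <- .closestOnSegment(P[i, ], P[i %% nv + 1, ])
    d2 <- sum(cpt^2)
    if (d2 < bestD) { bestD <- d2; best <- cpt }
  }
  w <- -best / sqrt(sum(best^2))
  sA <- drop(A %*% w); sB <- drop(B %*% w)
  offset <- (max(sA) + min(sB)) / 2
  list(separable = TRUE,
       witness = list(normal = w, offset = offset, sideOfFirst = -1))
}

# Candidate lines through all point pairs, offset +-eps along the normal.
# Returns a K x 3 matrix (wx, wy, c) for lines w.x = c.
.candidateLines <- function(points, eps = NULL, maxPairs = Inf, seed = 1L) {
  n <- nrow(points)
  pairs <- utils::combn(n, 2)
  if (ncol(pairs) > maxPairs) {
    set.seed(seed)
    pairs <- pairs[, sample.int(ncol(pairs), maxPairs), drop = FALSE]
  }
  p <- points[pairs[1, ], , drop = FALSE]
  q <- points[pairs[2, ], , drop = FALSE]
  d <- q - p
  len <- sqrt(rowSums(d^2))
  keep <- len > 0
  p <- p[keep, , drop = FALSE]; d <- d[keep, , drop = FALSE]; len <- len[keep]
  w <- cbind(-d[, 2], d[, 1]) / len
  c0 <- rowSums(w * p)
  if (is.null(eps)) {
    diam <- max(apply(points, 2, function(v) diff(range(v))))
    eps <- 1e-6 * max(diam, 1)
  }
  rbind(cbind(w, c0 + eps), cbind(w, c0 - eps))
}

# Exhaustive two-line search over candidate pairs via class-wise Gram
# matrices of side indicators; exact for the perturbed candidate set.
.twoLinesExact <- function(points, y01, cand) {
  S <- (cand[, 1:2] %*% t(points) > cand[, 3])        # K x n logical
  A <- S[, y01 == 0, drop = FALSE] * 1
  B <- S[, y01 == 1, drop = FALSE] * 1
  r0 <- rowSums(A); r1 <- rowSums(B)
  n0 <- ncol(A); n1 <- ncol(B)
  M0 <- tcrossprod(A)                                  # (i,j): class0 in TT cell
  M1 <- tcrossprod(B)
  # cell counts for pair (i, j):
  #   TT = M[i,j]; TF = r[i] - M[i,j]; FT = r[j] - M[i,j]; FF = n - r[i] - r[j] + M[i,j]
  Ri <- matrix(r0, nrow(M0), ncol(M0))
  Rj <- t(Ri)
  Si <- matrix(r1, nrow(M1), ncol(M1))
  Sj <- t(Si)
  impure <- (M0 * M1 > 0) |
            ((Ri - M0) * (Si - M1) > 0) |
            ((Rj - M0) * (Sj - M1) > 0) |
            ((n0 - Ri - Rj + M0) * (n1 - Si - Sj + M1) > 0)
  diag(impure) <- TRUE                                 # a pair needs 2 distinct lines
  ok <- which(!impure, arr.ind = TRUE)
  if (!nrow(ok)) return(NULL)
  ok[1, ]
}

# Greedy refinement: repeatedly add the candidate line that most reduces the
# number of points sitting in mixed-class cells.
.greedyLines <- function(points, y01, cand, sMax) {
  n <- nrow(points)
  S <- (cand[, 1:2] %*% t(points) > cand[, 3])
  cellId <- rep(1L, n)
  impurity <- function(cells) {
    sum(vapply(split(y01, cells), function(v) {
      tb <- tabulate(v + 1L, 2L)
      sum(tb) - max(tb)
    }, numeric(1)))
  }
  chosen <- integer(0)
  for (k in seq_len(sMax)) {
    cur <- impurity(cellId)
    if (cur == 0) break
    best <- NA_integer_; bestImp <- cur
    for (j in seq_len(nrow(S))) {
      imp <- impurity(paste0(cellId, S[j, ]))
      if (imp < bestImp) { bestImp <- imp; best <- j }
    }
    if (is.na(best)) break                              # no line helps
    chosen <- c(chosen, best)
    cellId <- as.integer(factor(paste0(cellId, S[best, ])))
  }
  list(lines = chosen, pure = impurity(cellId) == 0)
}

#' Minimum number of separating lines and the separability index
#'
#' Finds the smallest number `s <= sMax` of straight lines whose arrangement
#' partitions the plane into cells each containing points of only one class,
#' and reports the linear-separability index `1/s`.  `s = 1` is decided
#' exactly by [isLinearlySeparable()].  `s = 2` is decided exactly — over the
#' canonical candidate set of lines through point pairs perturbed by
#' `+-eps` along their normals — when the instance has at most `nExact`
#' points; larger instances, and `s > 2`, use a seeded deterministic
#' subsample of candidates with greedy cell splitting, giving an upper bound
#' flagged `exact = FALSE`.
#'
#' @param points n-by-2 numeric matrix.
#' @param labels two-level grouping vector.
#' @param sMax largest line count to try (default 5).
#' @param nExact largest instance size for the exhaustive two-line search
#'   (default 40; the search is quartic in n).
#' @param maxCandidates candidate-line budget for the greedy stage.
#' @param seed seed for the deterministic subsampling.
#' @return A [SeparabilityResult-class].  When no arrangement with at most
#'   `sMax` lines is found, `s` and `index` are `NA` (the index is then known
#'   to be below `1/sMax`).
#' @examples
#' xor <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
#' minSeparatingLines(xor, c(1, 1, 2, 2))   # s = 2, index 0.5
#' @export
minSeparatingLines <- function(points, labels, sMax = 5L, nExact = 40L,
                               maxCandidates = 400L, seed = 1L) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, sMax >= 1)
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("need exactly two classes")
  y01 <- as.integer(labels == lev[2])
  pair <- as.integer(lev)

  one <- isLinearlySeparable(points, labels)
  if (one$separable)
    return(new("SeparabilityResult", classPair = pair, s = 1L, exact = TRUE,
               index = 1, witnessLines = list(one$witness)))
  if (sMax == 1L)
    return(new("SeparabilityResult", classPair = pair, s = NA_integer_,
               exact = TRUE, index = NA_real_, witnessLines = list()))

  asLines <- function(cand, idx)
    lapply(idx, function(j) list(normal = cand[j, 1:2], offset = cand[j, 3]))

  n <- nrow(points)
  if (n <= nExact) {
    cand <- .candidateLines(points)
    hit <- .twoLinesExact(points, y01, cand)
    if (!is.null(hit))
      return(new("SeparabilityResult", classPair = pair, s = 2L, exact = TRUE,
                 index = 0.5, witnessLines = asLines(cand, hit)))
    if (sMax == 2L)
      return(new("SeparabilityResult", classPair = pair, s = NA_integer_,
                 exact = TRUE, index = NA_real_, witnessLines = list()))
  }
  cand <- .candidateLines(points, maxPairs = maxCandidates, seed = seed)
  g <- .greedyLines(points, y01, cand, sMax)
  if (g$pure && length(g$lines) <= sMax)
    return(new("SeparabilityResult", classPair = pair,
               s = as.integer(length(g$lines)), exact = FALSE,
               index = 1 / length(g$lines),
               witnessLines = asLines(cand, g$lines)))
  new("SeparabilityResult", classPair = pair, s = NA_integer_, exact = FALSE,
      index = NA_real_, witnessLines = list())
}

#' Pairwise separability over all class pairs
#'
#' Applies [minSeparatingLines()] to every unordered pair of classes present
#' in a 2-D score table.
#'
#' @param scores `data.frame(label, pc1, pc2)` as from [pcaScores2D()].
#' @param sMax,... passed to [minSeparatingLines()].
#' @return List of [SeparabilityResult-class], one per pair (empty when fewer
#'   than two classes are present).
#' @export
multiclassSeparability <- function(scores, sMax = 5L, ...) {
  classes <- sort(unique(scores$label))
  if (length(classes) < 2) return(list())
  pairs <- utils::combn(classes, 2)
  lapply(seq_len(ncol(pairs)), function(k) {
    g <- pairs[, k]
    keep <- scores$label %in% g
    minSeparatingLines(cbind(scores$pc1, scores$pc2)[keep, , drop = FALSE],
                       scores$label[keep], sMax = sMax, ...)
  })
}

#' Classify 2-D points by an arrangement of lines
#'
#' Assigns each training point to its arrangement cell (the pattern of line
#' sides), labels every cell by its training majority class, and classifies
#' query points by their cell.  Used to verify that witness lines reclassify
#' the input with zero errors.
#'
#' @param points n-by-2 training points with `labels`.
#' @param labels training labels.
#' @param lines list of `list(normal, offset)` as in
#'   [SeparabilityResult-class].
#' @param newPoints points to classify (default: the training points).
#' @return Predicted labels (`NA` for cells never seen in training).
#' @export
classifyWithLines <- function(points, labels, lines, newPoints = points) {
  points <- as.matrix(points); newPoints <- as.matrix(newPoints)
  sides <- function(P) {
    vapply(lines, function(L) drop(P %*% L$normal) > L$offset, logical(nrow(P)))
  }
  key <- function(M) apply(matrix(M, ncol = length(lines)), 1, paste, collapse = "")
  cellTrain <- key(sides(points))
  maj <- vapply(split(labels, cellTrain), function(v)
    as.integer(names(sort(table(v), decreasing = TRUE))[1]), integer(1))
  pred <- maj[key(sides(newPoints))]
  unname(pred)
}
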