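# Shared fixtures and independent oracles (kept separate from the package
# implementation paths they check).

tinyConfig <- function(nPerClass = 6L, seed = 1L, ...)
  syntheticConfig(nPerClass = nPerClass, seed = seed, ...)

tinyDataset <- function(nPerClass = 6L, seed = 1L, ...) {
  cfg <- tinyConfig(nPerClass, seed, ...)
  sampleExtinctionDataset(makeClassProfiles(cfg), cfg)
}

# Oracle: strict linear separability by enumerating candidate lines through
# every point pair, perturbed +-eps along the normal.  Independent of the
# convex-hull dual used by isLinearlySeparable().
enumSeparable <- function(points, labels) {
  lev <- sort(unique(labels))
  A <- points[labels == lev[1], , drop = FALSE]
  B <- points[labels == lev[2], , drop = FALSE]
  n <- nrow(points)
  diam <- max(apply(points, 2, function(v) diff(range(v))), 1e-9)
  eps <- 1e-7 * diam
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- points[j, ] - points[i, ]
    if (all(d == 0)) next
    w <- c(-d[2], d[1]) / sqrt(sum(d^2))
    c0 <- sum(w * points[i, ])
    for (cc in c(c0 + eps, c0 - eps)) {
      sA <- A %*% w - cc
      sB <- B %*% w - cc
      if ((all(sA < 0) && all(sB > 0)) || (all(sA > 0) && all(sB < 0)))
        return(TRUE)
    }
  }
  FALSE
}

# Oracle: exhaustive two-line search by brute-force double loop over the
# perturbed candidate set, checking purity of all four arrangement cells.
enumTwoLines <- function(points, labels) {
  lev <- sort(unique(labels))
  y <- as.integer(labels == lev[2])
  n <- nrow(points)
  diam <- max(apply(points, 2, function(v) diff(range(v))), 1e-9)
  eps <- 1e-7 * diam
  cand <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- points[j, ] - points[i, ]
    if (all(d == 0)) next
    w <- c(-d[2], d[1]) / sqrt(sum(d^2))
    c0 <- sum(w * points[i, ])
    cand[[length(cand) + 1]] <- c(w, c0 + eps)
    cand[[length(cand) + 1]] <- c(w, c0 - eps)
  }
  sides <- vapply(cand, function(L) points %*% L[1:2] > L[3], logical(n))
  K <- length(cand)
  for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    cell <- paste0(sides[, a], sides[, b])
    pure <- all(vapply(split(y, cell),
                       function(v) length(unique(v)) == 1, logical(1)))
    if (pure) return(TRUE)
  }
  FALSE
}

# Oracle: finite-difference gradient of the batch MSE through the forward
# pass only (central differences).
fdGradient <- function(params, X, targets, h = 1e-6) {
  lossAt <- function(p) {
    y <- annForward(p, X)
    mean((y - targets)^2)
  }
  out <- params
  for (nm in c("W1", "b1", "W2", "b2")) {
    g <- params[[nm]]
    for (k in seq_along(g)) {
      pp <- params; pp[[nm]][k] <- pp[[nm]][k] + h
      pm <- params; pm[[nm]][k] <- pm[[nm]][k] - h
      g[k] <- (lossAt(pp) - lossAt(pm)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}
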