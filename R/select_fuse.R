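# MRCEV feature selection — L1-penalised multinomial logistic regression
# whose coefficient magnitudes rank features — and CSID fusion of the
# selected vectors (plain concatenation by default, with an optional
# convolutional sparse-coding mode).

#' Rectify a feature matrix to nonnegative values
#'
#' Elementwise `max(0, x)`; the selection stage consumes only positive
#' activations. Idempotent.
#'
#' @param x numeric matrix/vector or a [FeatureSet-class].
#' @return same type as the input with negatives zeroed.
#' @export
positiveActivate <- function(x) {
  if (is(x, "FeatureSet")) {
    x@values <- pmax(x@values, 0)
    return(x)
  }
  pmax(x, 0)
}

#' Fit the MRCEV selection model
#'
#' Minimises the multinomial negative log-likelihood plus an L1 penalty
#' ("entropy variance" term) on the feature coefficients,
#' `T = R_psi + reg * sum(|coef|)`, by proximal gradient descent with a
#' fixed step 1/L (L from the curvature bound of the softmax likelihood,
#' with a halving safeguard so the objective never increases). The
#' intercept is unpenalised. Coefficients start at zero, so the fit is
#' deterministic; the seed only controls row shuffling.
#'
#' @param x numeric n x d feature matrix (or [FeatureSet-class]).
#' @param y labels (factor/character), ignored when `x` is a FeatureSet.
#' @param regWeight L1 multiplier (default 0.01).
#' @param maxIter iteration cap (default 300).
#' @param tol objective-change convergence tolerance (default 1e-8).
#' @param seed integer seed.
#' @return a [MrcevModel-class].
#' @export
mrcevFit <- function(x, y = NULL, regWeight = 0.01, maxIter = 300L,
                     tol = 1e-8, seed = 1L) {
  if (is(x, "FeatureSet")) {
    y <- sampleLabels(x)
    x <- featureValues(x)
  }
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  y <- factor(y)
  if (all(levels(y) %in% c("normal", "DR")))
    y <- factor(y, levels = c("normal", "DR"))
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  lev <- levels(y)
  K <- nlevels(y)
  n <- nrow(x); d <- ncol(x)
  ord <- withSeed(seed, sample.int(n))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  Xa <- cbind(1, x)
  smax <- svd(Xa, nu = 0, nv = 0)$d[1]
  L <- 0.5 * smax^2 + 1e-8
  B <- matrix(0, d, K)
  b0 <- numeric(K)
  objective <- function(B, b0) {
    Z <- sweep(x %*% B, 2, b0, "+")
    P <- softmaxRows(Z)
    nll <- -sum(log(rowSums(P * Y) + 1e-300))
    list(obj = nll + regWeight * sum(abs(B)), nll = nll, P = P)
  }
  cur <- objective(B, b0)
  trace <- cur$obj
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    resid <- cur$P - Y
    gB <- crossprod(x, resid)
    g0 <- colSums(resid)
    step <- 1 / L
    repeat {
      Bn <- softThreshold(B - step * gB, step * regWeight)
      b0n <- b0 - step * g0
      nxt <- objective(Bn, b0n)
      if (nxt$obj <= cur$obj + 1e-12 || step < 1e-14 / L) break
      step <- step / 2
    }
    delta <- cur$obj - nxt$obj
    B <- Bn; b0 <- b0n; cur <- nxt
    trace <- c(trace, cur$obj)
    if (abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!is.finite(cur$obj)) stop("non-finite objective")
  inv <- integer(n); inv[ord] <- seq_len(n)  # posteriors in input row order
  new("MrcevModel", coef = B, intercept = b0, regWeight = regWeight,
      classLevels = lev, probs = cur$P[inv, , drop = FALSE], nll = cur$nll,
      l1Norm = sum(abs(B)), objective = cur$obj, objTrace = trace,
      converged = converged)
}

#' Select the top-k features from a fitted MRCEV model
#'
#' Features are ranked by the maximum over classes of the absolute
#' coefficient; only nonzero-score features are eligible (so the result may
#' hold fewer than `k`). Ties break toward the lower index; indices are
#' returned sorted ascending.
#'
#' @param model a [MrcevModel-class].
#' @param k requested number of features.
#' @return a [SelectionResult-class].
#' @export
mrcevSelect <- function(model, k) {
  if (k <= 0) stop("k must be positive")
  scores <- apply(abs(coef(model)), 1, max)
  nz <- which(scores > 0)
  if (!length(nz)) {
    warning("all coefficients are zero: empty selection")
    return(new("SelectionResult", selected = integer(0),
               scores = scores, k = as.integer(k)))
  }
  ranked <- nz[order(-scores[nz], nz)]
  sel <- sort(head(ranked, min(k, length(nz))))
  new("SelectionResult", selected = as.integer(sel), scores = scores,
      k = as.integer(k))
}

# --- convolutional sparse coding helpers (1-D, causal truncation) --------

cscRecon <- function(h, z) {
  m <- ncol(z)
  r <- numeric(m)
  for (a in seq_len(nrow(h))) {
    full <- convolve(z[a, ], rev(h[a, ]), type = "open")
    r <- r + full[seq_len(m)]
  }
  r
}

# adjoint of cscRecon in z: correlation of the residual with each atom
cscAdjoint <- function(h, res) {
  m <- length(res)
  q <- ncol(h)
  out <- matrix(0, nrow(h), m)
  for (a in seq_len(nrow(h))) {
    full <- convolve(c(res, numeric(q - 1)), h[a, ], type = "open")
    out[a, ] <- full[q:(q + m - 1)]
  }
  out
}

cscPowerL <- function(h, m, iters = 12L) {
  z <- matrix(1 / sqrt(nrow(h) * m), nrow(h), m)
  for (i in seq_len(iters)) {
    w <- cscAdjoint(h, cscRecon(h, z))
    nz <- sqrt(sum(w^2))
    if (nz < 1e-12) return(1)
    z <- w / nz
  }
  sqrt(sum(cscAdjoint(h, cscRecon(h, z))^2)) * 1.02 + 1e-9
}

cscFitOne <- function(xvec, lambda, atoms, atomLen, istaIters, alternations,
                      seed) {
  m <- length(xvec)
  h <- withSeed(seed, matrix(rnorm(atoms * atomLen), atoms, atomLen))
  h <- h / sqrt(rowSums(h^2))
  z <- matrix(0, atoms, m)
  objOf <- function(h, z) {
    res <- xvec - cscRecon(h, z)
    0.5 * sum(res^2) + lambda * sum(abs(z))
  }
  trace <- objOf(h, z)
  for (al in seq_len(alternations)) {
    Lz <- cscPowerL(h, m)
    for (it in seq_len(istaIters)) {
      res <- cscRecon(h, z) - xvec
      g <- cscAdjoint(h, res)
      step <- 1 / Lz
      repeat {
        zn <- softThreshold(z - step * g, step * lambda)
        if (objOf(h, zn) <= tail(trace, 1) + 1e-12 || step < 1e-12 / Lz) break
        step <- step / 2
      }
      z <- zn
      trace <- c(trace, objOf(h, z))
    }
    if (al < alternations && any(z != 0)) {
      # one safeguarded gradient step on the dictionary
      res <- cscRecon(h, z) - xvec
      gh <- matrix(0, atoms, atomLen)
      for (a in seq_len(atoms)) {
        full <- convolve(c(res, numeric(m - 1)), z[a, ], type = "open")
        gh[a, ] <- full[m:(m + atomLen - 1)]
      }
      step <- 1 / max(sum(z^2), 1)
      repeat {
        hn <- h - step * gh
        if (objOf(hn, z) <= tail(trace, 1) + 1e-12 || step < 1e-12) break
        step <- step / 2
      }
      h <- hn
      trace <- c(trace, objOf(h, z))
    }
  }
  res <- xvec - cscRecon(h, z)
  list(h = h, z = z, recon = cscRecon(h, z), residual = 0.5 * sum(res^2),
       trace = trace)
}

#' Fuse two selected feature vectors (CSID)
#'
#' `mode = "concat"` (default) concatenates the two vectors losslessly.
#' `mode = "sparse"` learns a small 1-D convolutional dictionary per source
#' (8 atoms of length 16, seeded init), computes sparse codes by iterative
#' shrinkage (objective `0.5 ||x - sum_a h_a * z_a||^2 + lambda ||z||_1`,
#' non-increasing by construction), fuses the reconstructed sources by
#' elementwise maximum (the shorter padded with zeros), and appends the
#' flattened codes.
#'
#' @param vecA,vecB numeric feature vectors.
#' @param lambda sparsity weight (default 0.01; must be nonnegative).
#' @param mode "concat" or "sparse".
#' @param atoms dictionary size per source (default 8).
#' @param atomLen atom length (default 16).
#' @param istaIters shrinkage iterations per alternation (default 30).
#' @param alternations code/dictionary alternations (default 3).
#' @param sourceTags character tags of the two inputs.
#' @param seed integer seed for dictionary init.
#' @return a [FusedVector-class].
#' @export
csidFuse <- function(vecA, vecB, lambda = 0.01,
                     mode = c("concat", "sparse"), atoms = 8L, atomLen = 16L,
                     istaIters = 30L, alternations = 3L,
                     sourceTags = c("fc6", "fc7"), seed = 1L) {
  mode <- match.arg(mode)
  if (lambda < 0) stop("lambda must be nonnegative")
  stopifnot(all(is.finite(vecA)), all(is.finite(vecB)))
  if (mode == "concat") {
    return(new("FusedVector", values = c(vecA, vecB), sources = sourceTags,
               lambda = lambda, mode = "concat", residual = NA_real_,
               objTrace = numeric(0), codes = list()))
  }
  fa <- cscFitOne(vecA, lambda, atoms, atomLen, istaIters, alternations,
                  deriveSeed(seed, 1L))
  fb <- cscFitOne(vecB, lambda, atoms, atomLen, istaIters, alternations,
                  deriveSeed(seed, 2L))
  m <- max(length(vecA), length(vecB))
  padTo <- function(v, m) c(v, numeric(m - length(v)))
  fused <- pmax(padTo(fa$recon, m), padTo(fb$recon, m))
  nTr <- min(length(fa$trace), length(fb$trace))
  new("FusedVector",
      values = c(fused, as.numeric(fa$z), as.numeric(fb$z)),
      sources = sourceTags, lambda = lambda, mode = "sparse",
      residual = fa$residual + fb$residual,
      objTrace = fa$trace[seq_len(nTr)] + fb$trace[seq_len(nTr)],
      codes = list(fa$z, fb$z))
}
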