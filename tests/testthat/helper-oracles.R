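# Independent oracles used across test files. Each recomputes its quantity
# by a route different from the package implementation.

# Convolution by explicit nested loops (zero padding, square kernel).
convOracle <- function(x, W, b, k, s, p) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; C <- d[3]; N <- d[4]
  Ho <- (H + 2 * p - k) %/% s + 1
  Wo <- (Wd + 2 * p - k) %/% s + 1
  F <- ncol(W)
  xp <- array(0, c(H + 2 * p, Wd + 2 * p, C, N))
  xp[(p + 1):(p + H), (p + 1):(p + Wd), , ] <- x
  y <- array(0, c(Ho, Wo, F, N))
  for (n in 1:N) for (f in 1:F) for (oh in 1:Ho) for (ow in 1:Wo) {
    acc <- b[f]
    for (c in 1:C) for (kh in 1:k) for (kw in 1:k) {
      acc <- acc + W[kh + k * (kw - 1) + k * k * (c - 1), f] *
        xp[(oh - 1) * s + kh, (ow - 1) * s + kw, c, n]
    }
    y[oh, ow, f, n] <- acc
  }
  y
}

# Otsu by exhaustive enumeration: recompute class means from scratch at
# every candidate cut; first maximum; threshold = upper edge of that bin.
otsuOracle <- function(v, levels = 256L) {
  h <- tabulate(pmin(floor(as.numeric(v) * levels) + 1L, levels), levels)
  mids <- (seq_len(levels) - 0.5) / levels
  best <- -Inf; bt <- NA_integer_
  for (t in seq_len(levels - 1L)) {
    w0 <- sum(h[1:t]); w1 <- sum(h) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(mids[1:t] * h[1:t]) / w0
    mu1 <- sum(mids[(t + 1):levels] * h[(t + 1):levels]) / w1
    vb <- w0 * w1 * (mu0 - mu1)^2
    if (vb > best) { best <- vb; bt <- t }
  }
  bt / levels
}

# AUC as the Mann-Whitney U statistic over all positive/negative pairs
# (ties counted 1/2).
aucOracle <- function(scores, truth) {
  sp <- scores[truth == "DR"]; sn <- scores[truth == "normal"]
  tot <- 0
  for (a in sp) tot <- tot + sum(a > sn) + 0.5 * sum(a == sn)
  tot / (length(sp) * length(sn))
}

# 8-connected component count by plain R flood fill.
componentCountOracle <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cnt <- 0L
  for (j in seq_len(ncol(mask))) for (i in seq_len(nrow(mask))) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cnt <- cnt + 1L
    stack <- list(c(i, j)); lab[i, j] <- cnt
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        ni <- v[1] + di; nj <- v[2] + dj
        if (ni >= 1 && ni <= nrow(mask) && nj >= 1 && nj <= ncol(mask) &&
            mask[ni, nj] != 0 && lab[ni, nj] == 0) {
          lab[ni, nj] <- cnt
          stack[[length(stack) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  cnt
}

# Unpenalised multinomial logistic fit by plain full-batch gradient descent
# with a fixed small step, run to tight tolerance.
multinomOracle <- function(x, y, maxIter = 20000L, lr = NULL, tol = 1e-10) {
  y <- factor(y)
  K <- nlevels(y); n <- nrow(x)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), as.integer(y))] <- 1
  Xa <- cbind(1, x)
  if (is.null(lr)) lr <- 1 / (0.5 * svd(Xa, nu = 0, nv = 0)$d[1]^2)
  B <- matrix(0, ncol(Xa), K)
  obj <- function(B) {
    Z <- Xa %*% B
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    -sum(log(rowSums(P * Y) + 1e-300))
  }
  prev <- obj(B)
  for (it in seq_len(maxIter)) {
    Z <- Xa %*% B
    Z <- Z - apply(Z, 1, max)
    P <- exp(Z) / rowSums(exp(Z))
    B <- B - lr * crossprod(Xa, P - Y)
    if (it %% 100 == 0) {
      cur <- obj(B)
      if (abs(prev - cur) < tol) break
      prev <- cur
    }
  }
  list(B = B, obj = obj(B))
}

# Moore-Penrose least squares via SVD pseudo-inverse.
pinvSolve <- function(H, U) {
  sv <- svd(H)
  keep <- sv$d > max(dim(H)) * .Machine$double.eps * sv$d[1]
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) %*% U / sv$d[keep])
}
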