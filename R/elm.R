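# Extreme learning machine: random fixed hidden layer with sigmoid
# activation, output weights solved in closed form by ridge-stabilised
# least squares.

#' Train an extreme learning machine
#'
#' Input weights and offsets are drawn uniform [-1, 1] from the seed; the
#' hidden matrix is `H = sigmoid(X W' + offsets)`; output weights solve the
#' penalised least-squares problem in closed form,
#' `Y = (H'H + (1/x) I)^-1 H' U` with one-hot labels U. Larger penalty `x`
#' means weaker regularisation (the penalty multiplies the training-error
#' term of the stabilised objective).
#'
#' @param x numeric n x d feature matrix (rows = samples).
#' @param y labels (factor/character, levels normal/DR or any 2+ classes).
#' @param hiddenSize number of hidden units V (default 500).
#' @param penalty penalty parameter x (default 1), must be positive.
#' @param seed integer seed for the random hidden layer.
#' @return an [ElmModel-class].
#' @export
elmTrain <- function(x, y, hiddenSize = 500L, penalty = 1.0, seed = 1L) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("features must be finite")
  if (nrow(x) < 2L) stop("need at least 2 samples")
  y <- factor(y)
  if (all(levels(y) %in% c("normal", "DR")))
    y <- factor(y, levels = c("normal", "DR"))
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("both classes must be present")
  if (penalty <= 0) stop("penalty must be positive")
  V <- as.integer(hiddenSize)
  d <- ncol(x)
  wb <- withSeed(seed, list(W = matrix(runif(V * d, -1, 1), V, d),
                            b = runif(V, -1, 1)))
  H <- elmHidden(wb$W, wb$b, x)
  U <- matrix(0, nrow(x), nlevels(y))
  U[cbind(seq_len(nrow(x)), as.integer(y))] <- 1
  A <- crossprod(H) + diag(1 / penalty, V)
  Y <- solve(A, crossprod(H, U))
  new("ElmModel", inputWeights = wb$W, offsets = wb$b, outputWeights = Y,
      penalty = penalty, hiddenSize = V, seed = as.integer(seed),
      classLevels = levels(y))
}

elmHidden <- function(W, b, x) {
  S <- x %*% t(W)
  S <- sweep(S, 2, b, "+")
  1 / (1 + exp(-S))
}

#' Predict class scores with an ELM
#'
#' Scores are `sigmoid(X W' + offsets) Y`; the predicted class is the
#' argmax with ties broken toward the lower class index; `positiveScore`
#' is the DR-class score used for ROC thresholding.
#'
#' @param model an [ElmModel-class].
#' @param x numeric feature matrix with the model's input dimension.
#' @return list of class `elm_scores` with `scores` (n x K matrix),
#'   `predicted` (factor) and `positiveScore` (numeric).
#' @export
elmPredict <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(model@inputWeights))
    stop(sprintf("feature dimension %d does not match model dimension %d",
                 ncol(x), ncol(model@inputWeights)))
  H <- elmHidden(model@inputWeights, model@offsets, x)
  scores <- H %*% model@outputWeights
  colnames(scores) <- model@classLevels
  pred <- model@classLevels[max.col(scores, ties.method = "first")]
  pos <- if ("DR" %in% model@classLevels) scores[, "DR"] else scores[, 2]
  structure(list(scores = scores,
                 predicted = factor(pred, levels = model@classLevels),
                 positiveScore = as.numeric(pos)),
            class = "elm_scores")
}
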