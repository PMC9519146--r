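#' @include utils.R
NULL

## Linear discriminant classifier with a shared within-class covariance
## regularised by Ledoit-Wolf shrinkage toward the scaled identity
## mu * I, mu = tr(S)/p. The analytic shrinkage intensity is the
## Ledoit-Wolf (2004) optimum computed from the pooled class-centred data.

## X: rows already centred (class means removed); returns list(alpha, mu).
.ledoitWolf <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  delta2 <- sum((S - diag(mu, p))^2) / p
  if (delta2 == 0) return(list(alpha = 0, mu = mu, S = S))
  normS2 <- sum(S^2)
  beta2bar <- (sum(rowSums(Xc^2)^2) - n * normS2) / (n^2 * p)
  beta2 <- min(beta2bar, delta2)
  list(alpha = beta2 / delta2, mu = mu, S = S)
}

#' Fit a shrinkage-regularised linear discriminant
#'
#' Multiclass linear discriminant with a single shared covariance matrix
#' estimated from the pooled class-centred training rows. With
#' `shrinkage = "auto"` the covariance is shrunk toward the scaled identity
#' with the analytic Ledoit-Wolf optimal intensity; a numeric value in
#' \[0, 1\] fixes the intensity (0 = plain sample covariance). Class priors
#' are the empirical class frequencies. Per-class probabilities are the
#' softmax of the linear discriminant scores.
#'
#' @param X numeric matrix, samples x features.
#' @param y integer class labels in `1..K`.
#' @param classes the full expected class set (default `1:max(y)`); a class
#'   absent from `y` is an error naming the class.
#' @param shrinkage "auto" or a fixed intensity in \[0, 1\].
#' @return an object of class `"shrinkageDiscriminant"` with elements
#'   `W` (features x K score weights), `b` (K intercepts), `classes`,
#'   `alpha` (shrinkage used).
#' @seealso [predictDiscriminant()]
#' @export
fitDiscriminant <- function(X, y, classes = seq_len(max(y)),
                            shrinkage = "auto") {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) .stopf("X rows and y length differ")
  missing <- setdiff(classes, unique(y))
  if (length(missing) > 0)
    .stopf("class %s absent from the training data", missing[1])
  if (length(classes) < 2) .stopf("need at least 2 classes")
  K <- length(classes)
  p <- ncol(X)
  n <- nrow(X)
  means <- matrix(0, K, p)
  priors <- numeric(K)
  Xc <- X
  for (k in seq_len(K)) {
    rows <- y == classes[k]
    priors[k] <- mean(rows)
    means[k, ] <- colMeans(X[rows, , drop = FALSE])
    Xc[rows, ] <- sweep(X[rows, , drop = FALSE], 2, means[k, ])
  }
  if (identical(shrinkage, "auto")) {
    lw <- .ledoitWolf(Xc)
    alpha <- lw$alpha
    Sigma <- (1 - alpha) * lw$S + diag(alpha * lw$mu, p)
  } else {
    alpha <- as.numeric(shrinkage)
    if (alpha < 0 || alpha > 1) .stopf("shrinkage must lie in [0, 1]")
    S <- crossprod(Xc) / n
    mu <- sum(diag(S)) / p
    Sigma <- (1 - alpha) * S + diag(alpha * mu, p)
  }
  W <- solve(Sigma, t(means))            # p x K
  b <- -0.5 * colSums(t(means) * W) + log(priors)
  structure(list(W = W, b = b, classes = classes, alpha = alpha),
            class = "shrinkageDiscriminant")
}

#' Predict class probabilities from a fitted discriminant
#'
#' @param model a `"shrinkageDiscriminant"` from [fitDiscriminant()].
#' @param X numeric matrix, samples x features.
#' @return matrix (samples x K) of per-class probabilities (softmax of the
#'   discriminant scores); rows sum to 1.
#' @export
predictDiscriminant <- function(model, X) {
  stopifnot(inherits(model, "shrinkageDiscriminant"))
  X <- as.matrix(X)
  scores <- sweep(X %*% model$W, 2, model$b, "+")
  m <- apply(scores, 1, max)
  e <- exp(scores - m)
  probs <- e / rowSums(e)
  colnames(probs) <- model$classes
  probs
}
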