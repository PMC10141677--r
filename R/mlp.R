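#' Two-hidden-layer perceptron regressor
#'
#' A fully-connected network with two hidden layers of `hidden` rectified
#' linear units each and a linear output, trained by full-batch Adam on
#' the mean squared error. Inputs and the target are standardized by the
#' training statistics stored in the fitted object, so predictions are on
#' the original scale. Training is deterministic given `(X, y, seed)`:
#' the seed drives only the weight initialization (He-scaled normal) and
#' is restored via a local RNG scope.
#'
#' @param X numeric matrix of training inputs (rows = samples).
#' @param y numeric target vector.
#' @param seed integer seed for weight initialization.
#' @param hidden units per hidden layer.
#' @param epochs full-batch Adam steps.
#' @param lr Adam learning rate.
#' @param l2 L2 weight-decay coefficient on the weights (not biases);
#'   with a dozen-to-few-dozen training samples the network has far more
#'   parameters than data, so a small ridge penalty controls variance.
#' @return an object of class `mlp`, for [predict.mlp()].
#' @export
mlp_fit <- function(X, y, seed = 1L, hidden = c(10L, 10L), epochs = 600L,
                    lr = 0.02, l2 = 0.03) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in regressor inputs")
  }
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  x_scale[!is.finite(x_scale) | x_scale == 0] <- 1
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale == 0) y_scale <- 1
  Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
  ys <- (y - y_center) / y_scale
  d <- ncol(Xs)
  sizes <- c(d, hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L],
                                  sd = sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  nl <- length(W)
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(Xs)
  for (t in seq_len(epochs)) {
    # forward
    A <- vector("list", nl + 1L)
    A[[1L]] <- Xs
    for (l in seq_len(nl)) {
      Z <- A[[l]] %*% W[[l]] + matrix(b[[l]], n, length(b[[l]]), byrow = TRUE)
      A[[l + 1L]] <- if (l < nl) pmax(Z, 0) else Z
    }
    # backward (MSE)
    delta <- 2 * (A[[nl + 1L]] - ys) / n
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(A[[l]], delta) + l2 * W[[l]]
      gb <- colSums(delta)
      if (l > 1L) {
        delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
      }
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      cb1 <- 1 - beta1^t
      cb2 <- 1 - beta2^t
      W[[l]] <- W[[l]] - lr * (mW[[l]] / cb1) / (sqrt(vW[[l]] / cb2) + eps)
      b[[l]] <- b[[l]] - lr * (mb[[l]] / cb1) / (sqrt(vb[[l]] / cb2) + eps)
    }
  }
  structure(
    list(W = W, b = b, x_center = x_center, x_scale = x_scale,
         y_center = y_center, y_scale = y_scale, hidden = hidden,
         epochs = epochs, lr = lr, l2 = l2, seed = seed),
    class = "mlp"
  )
}

#' Predict from a fitted perceptron
#'
#' @param object an [mlp_fit()] object.
#' @param newdata numeric matrix (or vector for one sample).
#' @param ... unused.
#' @return numeric predictions on the original target scale.
#' @export
predict.mlp <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  A <- Xs
  nl <- length(object$W)
  for (l in seq_len(nl)) {
    Z <- A %*% object$W[[l]] +
      matrix(object$b[[l]], nrow(A), length(object$b[[l]]), byrow = TRUE)
    A <- if (l < nl) pmax(Z, 0) else Z
  }
  as.vector(A) * object$y_scale + object$y_center
}
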