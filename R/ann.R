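# Single-hidden-layer feed-forward network (tanh hidden units, softmax
# output, cross-entropy loss) trained full-batch by scaled conjugate
# gradient (Moller 1993, Neural Networks 6:525-533). SCG is Hessian-free
# (O(weights) memory), line-search free, and deterministic given the
# initial weights, which makes runs reproducible from a single seed.

ann_unpack <- function(theta, d, h, c) {
  i <- 0L
  W1 <- matrix(theta[(i + 1):(i + d * h)], d, h); i <- i + d * h
  b1 <- theta[(i + 1):(i + h)]; i <- i + h
  W2 <- matrix(theta[(i + 1):(i + h * c)], h, c); i <- i + h * c
  b2 <- theta[(i + 1):(i + c)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

# loss and gradient of the cross-entropy in one pass
ann_fg <- function(theta, X, Yi, d, h, c, decay) {
  n <- nrow(X)
  p <- ann_unpack(theta, d, h, c)
  A <- tanh(X %*% p$W1 + rep(p$b1, each = n))
  Z <- A %*% p$W2 + rep(p$b2, each = n)
  zmax <- Z[cbind(seq_len(n), max.col(Z, ties.method = "first"))]
  LS <- Z - zmax - log(rowSums(exp(Z - zmax)))
  f <- -mean(LS[cbind(seq_len(n), Yi)]) + 0.5 * decay * sum(theta^2)
  P <- exp(LS)
  P[cbind(seq_len(n), Yi)] <- P[cbind(seq_len(n), Yi)] - 1
  P <- P / n
  D1 <- (P %*% t(p$W2)) * (1 - A^2)
  g <- c(
    crossprod(X, D1), colSums(D1),
    crossprod(A, P), colSums(P)
  ) + decay * theta
  list(f = f, g = g)
}

scg_minimize <- function(theta, fg, maxit = 200, tol = 1e-6) {
  sigma0 <- 1e-4
  lambda <- 1e-6
  lambdabar <- 0
  cur <- fg(theta)
  r <- -cur$g
  p <- r
  success <- TRUE
  nparam <- length(theta)
  loss <- cur$f
  k_since_restart <- 0L
  delta <- 1
  for (k in seq_len(maxit)) {
    p2 <- sum(p^2)
    if (p2 < .Machine$double.eps) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      s <- (fg(theta + sigma * p)$g - cur$g) / sigma
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambdabar) * p2
    if (delta <= 0) {
      lambdabar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambdabar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    cand_theta <- theta + alpha * p
    cand <- fg(cand_theta)
    Delta <- 2 * delta * (cur$f - cand$f) / mu^2
    if (is.finite(Delta) && Delta >= 0) {
      theta <- cand_theta
      r_new <- -cand$g
      cur <- cand
      lambdabar <- 0
      success <- TRUE
      k_since_restart <- k_since_restart + 1L
      if (k_since_restart >= nparam) {
        p <- r_new
        k_since_restart <- 0L
      } else {
        beta <- (sum(r_new^2) - sum(r_new * r)) / mu
        p <- r_new + beta * p
      }
      r <- r_new
      if (Delta >= 0.75) lambda <- lambda / 4
      loss <- c(loss, cur$f)
      if (sqrt(sum(r^2)) < tol) break
    } else {
      lambdabar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25) {
      lambda <- lambda + delta * (1 - max(Delta, 0)) / p2
      if (!is.finite(lambda) || lambda > 1e20) break
    }
  }
  list(theta = theta, loss_history = loss, iterations = length(loss) - 1L)
}

#' Train the feed-forward classifier by scaled conjugate gradient
#'
#' Fits a one-hidden-layer network (tanh hidden activation, softmax output,
#' cross-entropy loss, full-batch SCG) on standardized features. The z-score
#' standardization is fit on the supplied (training) data only and stored in
#' the model, so test folds are never looked at. Deterministic under a fixed
#' seed.
#'
#' @param x Feature matrix or data frame (numeric columns only).
#' @param y Labels: factor (its level set defines the output layer, 8 classes
#'   for the full arrhythmia task) or character.
#' @param n_hidden Hidden-layer width.
#' @param seed Integer seed for the weight initialization.
#' @param maxit Maximum SCG iterations (default 200, no early stopping other
#'   than gradient-norm convergence).
#' @param decay Optional L2 penalty on the weights (default 0).
#' @param tol Gradient-norm convergence tolerance.
#' @return An object of class `ecg_ann`.
#' @export
train_ann <- function(x, y, n_hidden, seed, maxit = 200, decay = 0, tol = 1e-6) {
  X <- as.matrix(x)
  if (!is.numeric(X) || anyNA(X) || any(!is.finite(X))) {
    abort("Features must be finite numeric values (no NA/NaN/Inf).")
  }
  y <- if (is.factor(y)) y else factor(y)
  if (length(unique(as.integer(y))) < 2) {
    abort("Training data must contain at least 2 distinct classes.")
  }
  if (nrow(X) != length(y)) abort("`x` and `y` lengths differ.")
  assert_scalar_number(n_hidden, "n_hidden")
  if (n_hidden < 1) abort("`n_hidden` must be at least 1.")
  n_hidden <- as.integer(n_hidden)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
  d <- ncol(Xs)
  cls <- levels(y)
  c <- length(cls)
  Yi <- as.integer(y)
  theta0 <- with_seed(derive_seed(seed, "ann_init"), {
    c(
      rnorm(d * n_hidden, 0, 1 / sqrt(d)),
      numeric(n_hidden),
      rnorm(n_hidden * c, 0, 1 / sqrt(n_hidden)),
      numeric(c)
    )
  })
  fit <- scg_minimize(
    theta0,
    function(th) ann_fg(th, Xs, Yi, d, n_hidden, c, decay),
    maxit = maxit, tol = tol
  )
  structure(
    list(
      params = ann_unpack(fit$theta, d, n_hidden, c),
      n_inputs = d, n_hidden = n_hidden, classes = cls,
      center = center, scale = scale, seed = as.integer(seed),
      loss_history = fit$loss_history,
      epochs_run = fit$iterations,
      final_loss = fit$loss_history[length(fit$loss_history)]
    ),
    class = "ecg_ann"
  )
}

#' Predict heartbeat classes
#'
#' Deterministic argmax over the softmax output activations.
#'
#' @param object A fitted [train_ann()] model.
#' @param newdata Feature matrix or data frame with `n_inputs` columns.
#' @param type `"class"` (default) for labels, `"prob"` for the softmax
#'   matrix.
#' @param ... Unused.
#' @return Factor of predicted labels (levels = the model's class set) or a
#'   probability matrix.
#' @export
predict.ecg_ann <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_inputs) {
    abort(sprintf(
      "Feature dimension %d does not match model inputs %d.",
      ncol(X), object$n_inputs
    ))
  }
  n <- nrow(X)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  p <- object$params
  A <- tanh(Xs %*% p$W1 + rep(p$b1, each = n))
  Z <- A %*% p$W2 + rep(p$b2, each = n)
  if (type == "prob") {
    P <- exp(Z - apply(Z, 1, max))
    P <- P / rowSums(P)
    colnames(P) <- object$classes
    return(P)
  }
  factor(object$classes[max.col(Z, ties.method = "first")], levels = object$classes)
}

#' @export
print.ecg_ann <- function(x, ...) {
  cat(sprintf(
    "<ecg_ann> %d-%d-%d network, %d SCG iterations, final loss %.4g\n",
    x$n_inputs, x$n_hidden, length(x$classes), x$epochs_run, x$final_loss
  ))
  invisible(x)
}

#' @rdname train_ann
#' @param x A fitted `ecg_ann` model.
#' @param ... Unused.
#' @export
glance.ecg_ann <- function(x, ...) {
  tibble(
    n_inputs = x$n_inputs, n_hidden = x$n_hidden,
    n_classes = length(x$classes),
    n_parameters = x$n_inputs * x$n_hidden + x$n_hidden +
      x$n_hidden * length(x$classes) + length(x$classes),
    iterations = x$epochs_run, final_loss = x$final_loss
  )
}

#' @rdname train_ann
#' @export
tidy.ecg_ann <- function(x, ...) {
  p <- x$params
  bind_rows(
    tibble(layer = "hidden", weight = as.vector(p$W1),
           from = rep(seq_len(nrow(p$W1)), ncol(p$W1)),
           to = rep(seq_len(ncol(p$W1)), each = nrow(p$W1))),
    tibble(layer = "hidden_bias", weight = p$b1, from = NA_integer_,
           to = seq_along(p$b1)),
    tibble(layer = "output", weight = as.vector(p$W2),
           from = rep(seq_len(nrow(p$W2)), ncol(p$W2)),
           to = rep(seq_len(ncol(p$W2)), each = nrow(p$W2))),
    tibble(layer = "output_bias", weight = p$b2, from = NA_integer_,
           to = seq_along(p$b2))
  )
}
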