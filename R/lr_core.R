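# From-scratch minibatch logistic regression: numerically stable sigmoid,
# least-squares polynomial sigmoid (the only link evaluable under encrypted
# arithmetic), BCE, ridge gradient, Nesterov accelerated gradient. The
# encrypted trainer mirrors this arithmetic operation-for-operation, so
# every formulation choice here (lookahead NAG, unpenalized intercept,
# zero initialization, per-epoch seeded shuffle) is shared.

#' Training configuration
#'
#' @param learning_rate step size (> 0).
#' @param batch_size minibatch size (>= 1); the last partial batch is kept.
#' @param momentum Nesterov momentum coefficient in [0, 1).
#' @param epochs number of passes over the data.
#' @param l2_lambda ridge penalty on the coefficients (intercept
#'   unpenalized).
#' @param sigmoid_mode `"exact"` or `"poly"` (polynomial approximation;
#'   required for encrypted training).
#' @param poly_degree odd degree of the polynomial sigmoid.
#' @param seed seed driving the per-epoch batch shuffle.
#' @param early_stopping stop when validation BCE fails to improve for 3
#'   consecutive epochs (plaintext only; encrypted runs cannot inspect the
#'   loss without decryption).
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, batch_size = 64,
                         momentum = 0.9, epochs = 20, l2_lambda = 0.01,
                         sigmoid_mode = c("exact", "poly"),
                         poly_degree = 3, seed = 1L,
                         early_stopping = FALSE) {
  sigmoid_mode <- match.arg(sigmoid_mode)
  stopifnot(learning_rate > 0, batch_size >= 1,
            momentum >= 0, momentum < 1, l2_lambda >= 0, epochs >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 momentum = momentum, epochs = as.integer(epochs),
                 l2_lambda = l2_lambda, sigmoid_mode = sigmoid_mode,
                 poly_degree = as.integer(poly_degree),
                 seed = as.integer(seed),
                 early_stopping = isTRUE(early_stopping)),
            class = "train_config")
}

#' Model weights
#' @param beta coefficient vector.
#' @param intercept scalar log-odds offset.
#' @param columns optional column schema the coefficients refer to.
#' @return list of class `model_weights`.
#' @export
model_weights <- function(beta, intercept, columns = names(beta)) {
  stopifnot(all(is.finite(beta)), is.finite(intercept))
  structure(list(beta = as.numeric(beta), intercept = as.numeric(intercept),
                 columns = columns), class = "model_weights")
}

#' @export
print.model_weights <- function(x, ...) {
  cat(sprintf("<model_weights> p=%d intercept=%.4g\n",
              length(x$beta), x$intercept))
  invisible(x)
}

#' Serialize model weights (with column schema) to/from JSON
#' @param weights a `model_weights` object.
#' @param path optional file path.
#' @export
weights_to_json <- function(weights, path = NULL) {
  js <- jsonlite::toJSON(unclass(weights), digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @rdname weights_to_json
#' @param json JSON string (ignored when `path` given).
#' @export
weights_from_json <- function(path = NULL, json = NULL) {
  x <- jsonlite::fromJSON(if (!is.null(path)) path else json)
  model_weights(unlist(x$beta), x$intercept, unlist(x$columns))
}

#' Numerically stable logistic sigmoid
#' @param z numeric vector.
#' @return 1 / (1 + exp(-z)), stable for large |z|.
#' @export
sigmoid <- function(z) {
  out <- numeric(length(z))
  pos <- !is.na(z) & z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out[is.na(z)] <- NA_real_
  out
}

#' Least-squares polynomial approximation of the sigmoid
#'
#' Fits an odd-degree polynomial to the sigmoid on a dense uniform grid
#' over `interval` by least squares, and records the achieved maximum
#' absolute error on a fine reference grid. This is the link used whenever
#' the model must be evaluated under encrypted arithmetic.
#'
#' @param degree odd polynomial degree (>= 1).
#' @param interval fit interval, `lo < 0 < hi` (default c(-8, 8)).
#' @param grid_size number of fit-grid points.
#' @return `poly_sigmoid`: list with `degree`, `coef` (ascending powers),
#'   `interval`, `max_abs_error`.
#' @export
fit_poly_sigmoid <- function(degree = 3, interval = c(-8, 8),
                             grid_size = 1001) {
  stopifnot(degree >= 1, degree %% 2 == 1,
            interval[1] < 0, interval[2] > 0)
  z <- seq(interval[1], interval[2], length.out = grid_size)
  V <- outer(z, 0:degree, `^`)
  cf <- qr.solve(V, sigmoid(z))
  zf <- seq(interval[1], interval[2], length.out = 20001)
  err <- max(abs(eval_poly(cf, zf) - sigmoid(zf)))
  structure(list(degree = as.integer(degree), coef = as.numeric(cf),
                 interval = as.numeric(interval), max_abs_error = err),
            class = "poly_sigmoid")
}

# Horner evaluation; coef in ascending powers.
eval_poly <- function(coef, z) {
  out <- rep(coef[length(coef)], length(z))
  for (k in rev(seq_len(length(coef) - 1L))) {
    out <- out * z + coef[k]
  }
  out
}

#' Evaluate a fitted polynomial sigmoid
#' @param poly a `poly_sigmoid`.
#' @param z numeric vector.
#' @export
eval_poly_sigmoid <- function(poly, z) eval_poly(poly$coef, z)

link_function <- function(sigmoid_mode, poly) {
  if (sigmoid_mode == "exact") return(sigmoid)
  if (is.null(poly)) stop("poly sigmoid mode needs a fitted poly_sigmoid",
                          call. = FALSE)
  function(z) eval_poly(poly$coef, z)
}

#' Mean binary cross-entropy
#' @param y 0/1 labels.
#' @param p predicted probabilities (clipped to [1e-12, 1 - 1e-12]).
#' @export
bce <- function(y, p) {
  if (length(y) != length(p)) stop("length mismatch", call. = FALSE)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Ridge-penalized BCE gradient
#'
#' Returns the gradient of mean BCE plus `lambda/2 * ||beta||^2` at the
#' given weights: `t(X) (p - y) / m + lambda * beta` for the coefficients
#' and `mean(p - y)` for the (unpenalized) intercept, with `p` from the
#' active sigmoid mode.
#'
#' @param weights a `model_weights`.
#' @param X batch matrix (m x p).
#' @param y batch labels.
#' @param lambda ridge penalty.
#' @param sigmoid_mode `"exact"` or `"poly"`.
#' @param poly fitted `poly_sigmoid` when mode is `"poly"`.
#' @return list with `beta` gradient vector and `intercept` gradient.
#' @export
lr_gradient <- function(weights, X, y, lambda = 0,
                        sigmoid_mode = "exact", poly = NULL) {
  link <- link_function(sigmoid_mode, poly)
  m <- nrow(X)
  r <- link(drop(X %*% weights$beta) + weights$intercept) - y
  list(beta = drop(crossprod(X, r)) / m + lambda * weights$beta,
       intercept = sum(r) / m)
}

#' One Nesterov accelerated gradient step
#'
#' Lookahead formulation: the gradient is evaluated at
#' `weights + momentum * velocity`; then
#' `velocity <- momentum * velocity - lr * g` and
#' `weights <- weights + velocity`. With `momentum = 0` this is a plain
#' SGD step.
#'
#' @param state list with `weights` (`model_weights`) and `velocity`
#'   (list `beta`, `intercept`).
#' @param X,y minibatch.
#' @param config a `train_config`.
#' @param poly fitted `poly_sigmoid` for poly mode.
#' @return updated state.
#' @export
nag_step <- function(state, X, y, config, poly = NULL) {
  mu <- config$momentum; lr <- config$learning_rate
  look <- model_weights(state$weights$beta + mu * state$velocity$beta,
                        state$weights$intercept + mu * state$velocity$intercept,
                        state$weights$columns)
  g <- lr_gradient(look, X, y, config$l2_lambda,
                   config$sigmoid_mode, poly)
  v_beta <- mu * state$velocity$beta - lr * g$beta
  v_int <- mu * state$velocity$intercept - lr * g$intercept
  list(weights = model_weights(state$weights$beta + v_beta,
                               state$weights$intercept + v_int,
                               state$weights$columns),
       velocity = list(beta = v_beta, intercept = v_int))
}

#' Train logistic regression on plaintext data
#'
#' Zero-initialized minibatch NAG with ridge penalty; deterministic given
#' `config$seed`. Rows are shuffled once into fixed minibatch blocks and
#' each epoch visits the blocks in a fresh seeded order -- the same
#' schedule the encrypted trainer uses (block membership cannot be
#' re-permuted inside ciphertexts), so the two trainers are exact
#' arithmetic mirrors. With `validation` supplied and
#' `early_stopping = TRUE`, training stops after 3 epochs without
#' validation-BCE improvement.
#'
#' @param X design matrix (n x p, no missing values).
#' @param y 0/1 outcome vector.
#' @param config a `train_config`.
#' @param validation optional list with `X`, `y` for the loss trace /
#'   early stopping.
#' @param poly optional fitted `poly_sigmoid`; fitted on the fly from
#'   `config$poly_degree` when mode is `"poly"` and none is given.
#' @param schedule_label label seeding the row shuffle; a parity run must
#'   pass the label used by [pack_dataset()].
#' @return list with `weights` (`model_weights`) and `trace` (data.frame
#'   `epoch`, `train_bce`, `val_bce`).
#' @export
train_plaintext <- function(X, y, config, validation = NULL, poly = NULL,
                            schedule_label = "plain") {
  stopifnot(!anyNA(X), nrow(X) == length(y))
  if (config$sigmoid_mode == "poly" && is.null(poly)) {
    poly <- fit_poly_sigmoid(config$poly_degree)
  }
  link <- if (config$sigmoid_mode == "exact") sigmoid else
    function(z) eval_poly(poly$coef, z)
  p_dim <- ncol(X)
  cols <- colnames(X)
  w <- numeric(p_dim); b <- 0
  vw <- numeric(p_dim); vb <- 0
  mu <- config$momentum; lr <- config$learning_rate
  lam <- config$l2_lambda
  trace <- data.frame(epoch = integer(), train_bce = numeric(),
                      val_bce = numeric())
  best_val <- Inf; stall <- 0L
  groups <- make_block_groups(nrow(X), config$batch_size, config$seed,
                              schedule_label)
  for (epoch in seq_len(config$epochs)) {
    ord <- epoch_block_order(length(groups), epoch, config$seed)
    for (g in ord) {
      rows <- groups[[g]]
      Xb <- X[rows, , drop = FALSE]; yb <- y[rows]
      m <- length(rows)
      lw <- w + mu * vw; lb <- b + mu * vb
      r <- link(drop(Xb %*% lw) + lb) - yb
      gw <- drop(crossprod(Xb, r)) / m + lam * lw
      gb <- sum(r) / m
      vw <- mu * vw - lr * gw
      vb <- mu * vb - lr * gb
      w <- w + vw
      b <- b + vb
      if (!all(is.finite(w)) || !is.finite(b)) {
        stop(sprintf("non-finite weights at epoch %d; reduce the learning ",
                     epoch), "rate or check the data", call. = FALSE)
      }
    }
    tr_bce <- bce(y, link(drop(X %*% w) + b))
    va_bce <- if (!is.null(validation)) {
      bce(validation$y, link(drop(validation$X %*% w) + b))
    } else NA_real_
    trace <- rbind(trace, data.frame(epoch = epoch, train_bce = tr_bce,
                                     val_bce = va_bce))
    if (!is.finite(tr_bce)) {
      stop("non-finite training loss; aborting", call. = FALSE)
    }
    if (config$early_stopping && !is.null(validation)) {
      if (va_bce < best_val - 1e-12) {
        best_val <- va_bce; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= 3L) break
      }
    }
  }
  list(weights = model_weights(stats::setNames(w, cols), b, cols),
       trace = trace)
}

#' Predicted probabilities and hard classifications
#'
#' @param weights a `model_weights`.
#' @param X design matrix with the training column schema.
#' @param sigmoid_mode `"exact"` (default) or `"poly"`.
#' @param poly fitted `poly_sigmoid` for poly mode.
#' @return probability vector.
#' @export
predict_proba <- function(weights, X, sigmoid_mode = "exact", poly = NULL) {
  if (ncol(X) != length(weights$beta)) {
    stop("column schema mismatch between weights and X", call. = FALSE)
  }
  if (!is.null(colnames(X)) && !is.null(weights$columns) &&
      !identical(colnames(X), weights$columns)) {
    stop("column schema mismatch between weights and X", call. = FALSE)
  }
  link <- link_function(sigmoid_mode, poly)
  link(drop(X %*% weights$beta) + weights$intercept)
}

#' @rdname predict_proba
#' @param p probability vector.
#' @param threshold decision threshold; ties classify as 1.
#' @export
classify <- function(p, threshold = 0.5) as.integer(p >= threshold)

#' Per-feature odds ratios
#' @param weights a `model_weights`.
#' @return `exp(beta)` named per coefficient.
#' @export
odds_ratios <- function(weights) {
  stats::setNames(exp(weights$beta), weights$columns)
}

#' Exact Shapley attributions for a linear log-odds model
#'
#' For a logistic model the log-odds are linear in the features, so the
#' Shapley value of feature j for sample i is
#' `phi_ij = beta_j * (x_ij - background_mean_j)` exactly (attribution on
#' the log-odds scale). Completeness:
#' `sum_j phi_ij + (beta . means + intercept) = logit(p_i)`.
#'
#' @param weights a `model_weights`.
#' @param X design matrix.
#' @param background_means per-feature background means.
#' @return n x p attribution matrix.
#' @export
linear_shap <- function(weights, X, background_means) {
  if (length(background_means) != length(weights$beta)) {
    stop("background_means must have one entry per feature", call. = FALSE)
  }
  phi <- sweep(X, 2, background_means, "-")
  sweep(phi, 2, weights$beta, "*")
}
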