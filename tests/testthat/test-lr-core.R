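# Plaintext trainer: links, losses, gradients, NAG, training dynamics,
# interpretability helpers.

test_that("sigmoid is exact, symmetric and stable", {
  expect_identical(sigmoid(0), 0.5)
  expect_equal(sigmoid(1), 0.7310585786, tolerance = 1e-10)
  for (z in c(1, 5, 50)) {
    expect_equal(sigmoid(-z), 1 - sigmoid(z), tolerance = 1e-12)
  }
  expect_equal(sigmoid(c(-800, 800)), c(0, 1))
  expect_false(anyNA(sigmoid(c(-1e6, 1e6))))
})

test_that("polynomial sigmoid matches the frozen least-squares oracle", {
  ps <- fit_poly_sigmoid(3)
  expect_equal(eval_poly_sigmoid(ps, 0), 0.5, tolerance = 1e-6)
  # dense-grid brute-force value computed once and frozen
  expect_equal(ps$max_abs_error, 0.1131885, tolerance = 1e-6)
  ps7 <- fit_poly_sigmoid(7)
  expect_equal(eval_poly_sigmoid(ps7, 0), 0.5, tolerance = 1e-6)
  expect_lt(ps7$max_abs_error, ps$max_abs_error)
  expect_error(fit_poly_sigmoid(2), "%%")
  # odd symmetry about (0, 0.5) within the fit tolerance
  z <- seq(-6, 6, by = 0.25)
  expect_lt(max(abs(eval_poly_sigmoid(ps, z) +
                      eval_poly_sigmoid(ps, -z) - 1)), 1e-10)
})

test_that("bce handles closed forms and clipping", {
  expect_equal(bce(1, 1), 0, tolerance = 1e-10)
  expect_equal(bce(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_true(is.finite(bce(1, 0)))
  expect_error(bce(c(1, 0), 0.5), "length mismatch")
})

test_that("gradient matches hand arithmetic, finite differences and glm stationarity", {
  w0 <- model_weights(0, 0)
  g <- lr_gradient(w0, matrix(1, 1, 1), 1, lambda = 0)
  expect_equal(g$beta, -0.5)
  expect_equal(g$intercept, -0.5)

  # central-difference oracle on random small problems
  set.seed(42)
  for (rep in 1:5) {
    n <- 20; p <- 3; lam <- 0.05
    X <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.4)
    w <- model_weights(rnorm(p, sd = 0.5), rnorm(1, sd = 0.5))
    f <- function(v) {
      bce(y, sigmoid(drop(X %*% v[1:p]) + v[p + 1])) +
        lam / 2 * sum(v[1:p]^2)
    }
    v0 <- c(w$beta, w$intercept)
    num <- vapply(seq_len(p + 1), function(j) {
      h <- 1e-6; e <- numeric(p + 1); e[j] <- h
      (f(v0 + e) - f(v0 - e)) / (2 * h)
    }, 0)
    g <- lr_gradient(w, X, y, lambda = lam)
    expect_equal(c(g$beta, g$intercept), num, tolerance = 1e-6)
  }

  # gradient vanishes at the glm optimum
  set.seed(7)
  X <- matrix(rnorm(200 * 2), 200, 2)
  y <- rbinom(200, 1, plogis(X[, 1]))
  co <- glm.fit(cbind(X, 1), y, family = binomial())$coefficients
  g <- lr_gradient(model_weights(co[1:2], co[3]), X, y, lambda = 0)
  expect_lt(max(abs(c(g$beta, g$intercept))), 1e-6)
})

test_that("nag_step reduces to SGD at mu = 0 and decays velocity on flat loss", {
  set.seed(1)
  X <- matrix(rnorm(10 * 2), 10, 2)
  y <- rbinom(10, 1, 0.5)
  cfg <- train_config(momentum = 0, l2_lambda = 0, learning_rate = 0.1)
  st <- list(weights = model_weights(c(0.3, -0.2), 0.1),
             velocity = list(beta = c(0, 0), intercept = 0))
  out <- nag_step(st, X, y, cfg)
  g <- lr_gradient(st$weights, X, y, 0)
  expect_equal(out$weights$beta, st$weights$beta - 0.1 * g$beta)
  expect_equal(out$weights$intercept,
               st$weights$intercept - 0.1 * g$intercept)

  # zero gradient everywhere (X = 0, y = 0.5, flat intercept): the
  # coefficient velocity decays geometrically by mu
  cfg2 <- train_config(momentum = 0.9, l2_lambda = 0)
  st2 <- list(weights = model_weights(c(0, 0), 0),
              velocity = list(beta = c(1, -2), intercept = 0))
  out2 <- nag_step(st2, matrix(0, 4, 2), rep(0.5, 4), cfg2)
  expect_equal(out2$velocity$beta, 0.9 * c(1, -2))
  expect_equal(out2$velocity$intercept, 0)
  out3 <- nag_step(out2, matrix(0, 4, 2), rep(0.5, 4), cfg2)
  expect_equal(out3$velocity$beta, 0.81 * c(1, -2))
})

test_that("train_plaintext is deterministic with sane dynamics", {
  sets <- h_site_sets(h_profile(), 800, seed = 31)
  cfg0 <- train_config(epochs = 0)
  f0 <- train_plaintext(sets$train$X, sets$train$y, cfg0)
  expect_true(all(f0$weights$beta == 0) && f0$weights$intercept == 0)

  cfg <- train_config(epochs = 3, seed = 5)
  f1 <- train_plaintext(sets$train$X, sets$train$y, cfg)
  f2 <- train_plaintext(sets$train$X, sets$train$y, cfg)
  expect_identical(f1$weights, f2$weights)
  expect_identical(nrow(f1$trace), 3L)

  # epoch-mean loss is non-increasing (stochastic jitter tolerance)
  cfg2 <- train_config(epochs = 10, seed = 5, l2_lambda = 0)
  f3 <- train_plaintext(sets$train$X, sets$train$y, cfg2)
  expect_true(all(diff(f3$trace$train_bce) <= 1e-3))

  # early stopping halts on a stalled validation loss
  cfgES <- train_config(epochs = 300, learning_rate = 0.05, seed = 5,
                        early_stopping = TRUE)
  fes <- train_plaintext(sets$train$X, sets$train$y, cfgES,
                         validation = sets$val)
  expect_lt(nrow(fes$trace), 300L)
})

test_that("ridge penalty shrinks the coefficient norm monotonically", {
  sets <- h_site_sets(h_profile(), 1000, seed = 33)
  norms <- vapply(c(0, 0.01, 0.1, 1), function(l) {
    cfg <- train_config(epochs = 15, l2_lambda = l, seed = 4)
    f <- train_plaintext(sets$train$X, sets$train$y, cfg)
    sqrt(sum(f$weights$beta^2))
  }, 0)
  expect_true(all(diff(norms) <= 0))
})

test_that("poly-mode weights stay within the frozen propagation bound of exact mode", {
  sets <- h_site_sets(h_profile(), 1500, seed = 7)
  fe <- train_plaintext(sets$train$X, sets$train$y,
                        train_config(epochs = 3, seed = 4))
  fp <- train_plaintext(sets$train$X, sets$train$y,
                        train_config(epochs = 3, sigmoid_mode = "poly",
                                     seed = 4))
  d <- max(abs(c(fe$weights$beta - fp$weights$beta,
                 fe$weights$intercept - fp$weights$intercept)))
  # first measurement: 0.171 with poly max error 0.113; frozen at 10x
  expect_lt(d, 10 * fit_poly_sigmoid(3)$max_abs_error)
})

test_that("prediction, classification and odds ratios behave", {
  w0 <- model_weights(c(0, 0), 0, c("a", "b"))
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  p <- predict_proba(w0, X)
  expect_true(all(p == 0.5))
  expect_true(all(classify(p) == 1L))

  w <- model_weights(1, 0, "a")
  expect_equal(predict_proba(w, matrix(1, 1, 1, dimnames = list(NULL, "a"))),
               0.7310585786, tolerance = 1e-9)
  # monotonicity in a positive-coefficient feature
  xs <- matrix(seq(-3, 3, by = 0.5), ncol = 1, dimnames = list(NULL, "a"))
  expect_true(all(diff(predict_proba(w, xs)) > 0))
  expect_error(predict_proba(w, X), "schema mismatch")

  expect_equal(unname(odds_ratios(model_weights(c(0, log(2)), 0))),
               c(1, 2))
})

test_that("linear SHAP satisfies completeness and the closed-form ranking", {
  set.seed(9)
  X <- matrix(rnorm(50 * 4), 50, 4)
  X[, 3] <- X[, 3] * 3          # inflate one feature's spread
  w <- model_weights(c(0.5, -1, 0.4, 0), 0.3)
  mu <- colMeans(X)
  phi <- linear_shap(w, X, mu)
  expect_equal(dim(phi), c(50, 4))
  expect_true(all(abs(linear_shap(w, matrix(mu, 1), mu)) < 1e-12))
  logit_p <- drop(X %*% w$beta) + w$intercept
  expect_equal(rowSums(phi) + drop(mu %*% w$beta) + w$intercept, logit_p)
  imp <- colMeans(abs(phi))
  ref <- abs(w$beta) * apply(X, 2, function(v) mean(abs(v - mean(v))))
  expect_identical(order(imp), order(ref))
})

test_that("model weights serialize to JSON with schema intact", {
  w <- model_weights(c(a = 0.5, b = -1), 0.25, c("a", "b"))
  f <- tempfile(fileext = ".json")
  weights_to_json(w, f)
  w2 <- weights_from_json(f)
  expect_equal(w2$beta, unname(w$beta))
  expect_equal(w2$intercept, w$intercept)
  expect_identical(w2$columns, c("a", "b"))
})
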