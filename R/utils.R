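# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. All stochastic
#' operations in the package route their seeds through this helper so that
#' generation is a pure function of its (data, seed) arguments and never
#' perturbs the user's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a master seed and a stream label, staying below
# 2^31. Cheap string hash (polynomial, mod a prime < 2^31).
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(as.character(label))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Multivariate normal draws via Cholesky (consumes the active RNG stream).
rmvn_chol <- function(n, mu, sigma) {
  p <- length(mu)
  L <- chol(sigma)  # upper triangular, sigma = t(L) %*% L
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% L, 2, mu, "+")
}

stopifnot_prob_vector <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-12) {
    stop(what, " must be a probability vector summing to 1", call. = FALSE)
  }
  invisible(TRUE)
}
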