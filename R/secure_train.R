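# Encrypted logistic regression training. The trainer touches only the
# public HE op surface plus the audited refresh; arithmetic (lookahead NAG,
# polynomial sigmoid, ridge with unpenalized intercept, batch scheduling)
# mirrors lr_core operation-for-operation, which is what makes
# ciphertext/plaintext parity a testable property rather than a claim.
#
# Packing layout: rows are permuted once by a seeded shuffle, grouped into
# fixed minibatch blocks of `batch_size` rows; each block stores one
# ciphertext per design column (plus a 0/1 intercept/validity column that
# doubles as the padding mask) and one for the outcome, all with the block's
# rows in the slots. Per epoch, the *visiting order of blocks* is
# re-shuffled by seed; block membership is frozen at encryption time since
# ciphertext rows cannot be re-permuted. The plaintext trainer uses the
# identical schedule (see `make_block_groups` / `epoch_block_order`).

make_block_groups <- function(n, batch_size, seed, label) {
  perm <- with_seed(derive_seed(seed, paste0("shuffle-", label)),
                    sample.int(n))
  starts <- seq(1L, n, by = batch_size)
  lapply(starts, function(s) perm[s:min(s + batch_size - 1L, n)])
}

epoch_block_order <- function(n_groups, epoch, seed) {
  with_seed(derive_seed(seed, paste0("epoch-", epoch)),
            sample.int(n_groups))
}

#' Pack a design matrix into encrypted minibatch blocks
#'
#' @param design a `design_matrix` (see [one_hot_encode()]).
#' @param pk public key.
#' @param config a `train_config`; its `seed` and `batch_size` fix the
#'   (deterministic) packing layout. `batch_size` must be a power of two
#'   so slot-rotation reductions work.
#' @param label schedule label for the row shuffle (defaults to the first
#'   site in the design); merged plaintext mirrors must reuse it.
#' @return `packed_matrix`.
#' @export
pack_dataset <- function(design, pk, config, label = design$site[1]) {
  X <- design$X; y <- design$y
  n <- nrow(X); p <- ncol(X)
  bs <- config$batch_size
  if (bitwAnd(bs, bs - 1L) != 0) {
    stop("batch_size must be a power of two for slot reductions",
         call. = FALSE)
  }
  ctx <- pk$context
  if (bs > ctx$slot_count) stop("batch exceeds slot capacity",
                                call. = FALSE)
  groups <- make_block_groups(n, bs, config$seed, label)
  blocks <- lapply(groups, function(rows) {
    m <- length(rows)
    pad <- bs - m
    cols <- lapply(seq_len(p), function(j) {
      he_encrypt(c(X[rows, j], rep(0, pad)), pk)
    })
    names(cols) <- colnames(X)
    list(cols = cols,
         mask = he_encrypt(c(rep(1, m), rep(0, pad)), pk),  # intercept col
         y = he_encrypt(c(y[rows], rep(0, pad)), pk),
         m = m, label = label)
  })
  structure(list(blocks = blocks, n = n, p = p,
                 columns = colnames(X), batch_size = bs,
                 sites = unique(design$site), labels = label,
                 key_id = pk$key_id, pk = pk, seed = config$seed),
            class = "packed_matrix")
}

#' @export
print.packed_matrix <- function(x, ...) {
  cat(sprintf("<packed_matrix> n=%d p=%d blocks=%d sites=%s\n",
              x$n, x$p, length(x$blocks), paste(x$sites, collapse = "+")))
  invisible(x)
}

#' Merge encrypted datasets from several sites
#'
#' Concatenates packed blocks without any decryption (the context's audit
#' counters are untouched). Schemas, batch size, and keypair must match.
#'
#' @param packs list of `packed_matrix` objects.
#' @return merged `packed_matrix`.
#' @export
merge_encrypted <- function(packs) {
  stopifnot(length(packs) >= 1)
  ref <- packs[[1]]
  for (pk2 in packs[-1]) {
    if (!identical(pk2$columns, ref$columns)) stop("schema mismatch",
                                                   call. = FALSE)
    if (!identical(pk2$key_id, ref$key_id)) stop("key mismatch",
                                                 call. = FALSE)
    if (pk2$batch_size != ref$batch_size) stop("batch size mismatch",
                                               call. = FALSE)
  }
  structure(list(blocks = do.call(c, lapply(packs, `[[`, "blocks")),
                 n = as.integer(sum(vapply(packs, `[[`, 0, "n"))),
                 p = ref$p, columns = ref$columns,
                 batch_size = ref$batch_size,
                 sites = unique(unlist(lapply(packs, `[[`, "sites"))),
                 labels = unlist(lapply(packs, `[[`, "labels")),
                 key_id = ref$key_id, pk = ref$pk, seed = ref$seed),
            class = "packed_matrix")
}

#' Decrypt and unpack a packed matrix (for verification only)
#' @param pack a `packed_matrix`.
#' @param sk secret key.
#' @return list with `X`, `y` reconstructed in packed row order.
#' @export
unpack_dataset <- function(pack, sk) {
  Xs <- lapply(pack$blocks, function(b) {
    m <- b$m
    cbind(sapply(b$cols, function(ct) he_decrypt(ct, sk)[seq_len(m)]))
  })
  ys <- lapply(pack$blocks, function(b) he_decrypt(b$y, sk)[seq_len(b$m)])
  X <- do.call(rbind, Xs)
  colnames(X) <- pack$columns
  list(X = X, y = unlist(ys))
}

# Per-iteration multiplicative depth of the encrypted NAG update for a
# degree-d polynomial link; with the level-6 default context the degree-3
# update exactly exhausts the budget, hence refresh once per iteration.
iteration_depth <- function(degree) {
  # lookahead mul_plain(1) -> z mul(1) -> powers (ceil(log-free chain):
  # z^k needs k-1 sequential muls) -> coeff mul_plain(1) -> gradient mul(1)
  3L + (degree - 1L) + 1L
}

#' Train logistic regression on ciphertext
#'
#' Runs the identical NAG / polynomial-sigmoid / ridge update sequence as
#' [train_plaintext()] with the same seed-driven batch schedule, entirely
#' through the public HE op surface. Weights and velocity are held as
#' broadcast ciphertexts (one per coefficient plus intercept) and refreshed
#' at the end of every iteration, the simplest schedule that keeps the
#' level budget ahead of one iteration's multiplicative depth. Epochs are
#' fixed: the loss cannot be inspected without decryption, so there is no
#' encrypted early stopping.
#'
#' @param pack a `packed_matrix`.
#' @param config a `train_config` with `sigmoid_mode = "poly"`.
#' @param authority a `refresh_authority` for the pack's keypair.
#' @param poly optional pre-fitted `poly_sigmoid`.
#' @return `encrypted_weights`; attribute `run_log` records iterations,
#'   refresh count and the minimum level reached.
#' @export
train_encrypted <- function(pack, config, authority, poly = NULL) {
  if (config$sigmoid_mode != "poly") {
    stop("encrypted training requires sigmoid_mode = 'poly' (the exact ",
         "sigmoid is not ciphertext-evaluable)", call. = FALSE)
  }
  if (is.null(poly)) poly <- fit_poly_sigmoid(config$poly_degree)
  ctx <- pack$pk$context
  if (ctx$levels < iteration_depth(poly$degree)) {
    stop(sprintf("level budget %d below the per-iteration depth %d",
                 ctx$levels, iteration_depth(poly$degree)), call. = FALSE)
  }
  pk <- pack$pk
  p <- pack$p
  bs <- pack$batch_size
  mu <- config$momentum; lr <- config$learning_rate
  lam <- config$l2_lambda
  cf <- poly$coef  # ascending powers, degree d

  zeros <- rep(0, bs)
  w <- lapply(seq_len(p + 1L), function(j) he_encrypt(zeros, pk))
  v <- lapply(seq_len(p + 1L), function(j) he_encrypt(zeros, pk))

  iterations <- 0L
  min_level <- ctx$levels
  refresh0 <- ctx$audit$refresh_calls
  n_groups <- length(pack$blocks)

  for (epoch in seq_len(config$epochs)) {
    ord <- epoch_block_order(n_groups, epoch, config$seed)
    for (g in ord) {
      blk <- pack$blocks[[g]]
      m <- blk$m
      sc <- lr / m

      # lookahead point w + mu * v (per coefficient, broadcast slots)
      look <- lapply(seq_len(p + 1L), function(j) {
        he_add(w[[j]], he_mul_plain(v[[j]], mu))
      })

      # linear predictor over the block's slots; the mask column is the
      # intercept feature (1 on real rows, 0 on padding)
      z <- he_mul(look[[p + 1L]], blk$mask)
      for (j in seq_len(p)) {
        z <- he_add(z, he_mul(look[[j]], blk$cols[[j]]))
      }

      # residual scaled by lr/m:  (poly(z) - y) * lr / m .
      # Polynomial coefficients are folded with lr/m so the whole residual
      # costs one level past the power chain; the constant term touches
      # padded slots too, but every feature column (incl. the mask) is zero
      # there, so padded rows contribute nothing to the gradient.
      zpow <- z
      r <- he_add_plain(he_mul_plain(z, cf[2] * sc), cf[1] * sc)
      if (poly$degree >= 2) {
        for (k in 2:poly$degree) {
          zpow <- he_mul(zpow, z)
          r <- he_add(r, he_mul_plain(zpow, cf[k + 1] * sc))
        }
      }
      r <- he_sub(r, he_mul_plain(blk$y, sc))

      # gradient per coefficient: slot-sum of col_j * r, broadcast
      for (j in seq_len(p + 1L)) {
        colj <- if (j <= p) blk$cols[[j]] else blk$mask
        gj <- he_reduce_sum(he_mul(colj, r))
        vj <- he_sub(he_mul_plain(v[[j]], mu), gj)
        if (j <= p && lam > 0) {
          # ridge term lr*lambda evaluated at the lookahead point, exactly
          # as the plaintext gradient does; the intercept stays unpenalized
          vj <- he_sub(vj, he_mul_plain(look[[j]], lr * lam))
        }
        wj <- he_add(w[[j]], vj)
        min_level <- min(min_level, wj$level, vj$level)
        # refresh whenever the remaining budget cannot fund another
        # iteration (with the default parameters: always)
        if (wj$level < iteration_depth(poly$degree)) {
          wj <- he_refresh(wj, authority)
        }
        if (vj$level < iteration_depth(poly$degree)) {
          vj <- he_refresh(vj, authority)
        }
        w[[j]] <- wj
        v[[j]] <- vj
      }
      iterations <- iterations + 1L
    }
  }

  out <- structure(list(cts = w, columns = pack$columns,
                        key_id = pack$key_id, poly = poly),
                   class = "encrypted_weights")
  attr(out, "run_log") <- list(
    iterations = iterations,
    refresh_calls = ctx$audit$refresh_calls - refresh0,
    min_level = min_level,
    predicted_refresh = iterations * 2L * (p + 1L))
  out
}

#' @export
print.encrypted_weights <- function(x, ...) {
  cat(sprintf("<encrypted_weights> p=%d (+intercept), key=%s\n",
              length(x$cts) - 1L, x$key_id))
  invisible(x)
}

#' Decrypt trained encrypted weights into plaintext model weights
#'
#' @param enc an `encrypted_weights`.
#' @param sk matching secret key.
#' @return `model_weights` in the lr_core schema.
#' @export
decrypt_weights <- function(enc, sk) {
  if (!identical(sk$key_id, enc$key_id)) stop("key mismatch", call. = FALSE)
  vals <- vapply(enc$cts, function(ct) he_decrypt(ct, sk)[1], 0)
  p <- length(vals) - 1L
  model_weights(stats::setNames(vals[seq_len(p)], enc$columns),
                vals[p + 1L], enc$columns)
}

#' Plaintext mirror of encrypted training on a packed layout
#'
#' Trains with exactly the block schedule the encrypted trainer uses for
#' the given (design, label) list -- the independent plaintext arm of the
#' parity and merge-equivariance checks.
#'
#' @param designs list of `design_matrix` objects.
#' @param labels schedule labels, one per design (must match the labels
#'   used at packing).
#' @param config a `train_config` (`sigmoid_mode = "poly"` for parity).
#' @param poly optional pre-fitted `poly_sigmoid`.
#' @return list with `weights` and `trace` (as [train_plaintext()]).
#' @export
train_plaintext_mirror <- function(designs, labels, config, poly = NULL) {
  if (config$sigmoid_mode == "poly" && is.null(poly)) {
    poly <- fit_poly_sigmoid(config$poly_degree)
  }
  link <- if (config$sigmoid_mode == "exact") sigmoid else
    function(z) eval_poly(poly$coef, z)
  groups <- list(); Xs <- list(); ys <- list(); off <- 0L
  for (i in seq_along(designs)) {
    d <- designs[[i]]
    gi <- make_block_groups(nrow(d$X), config$batch_size, config$seed,
                            labels[[i]])
    groups <- c(groups, lapply(gi, function(g) g + off))
    Xs[[i]] <- d$X; ys[[i]] <- d$y
    off <- off + nrow(d$X)
  }
  X <- do.call(rbind, Xs); y <- unlist(ys)
  p_dim <- ncol(X)
  w <- numeric(p_dim); b <- 0; vw <- numeric(p_dim); vb <- 0
  mu <- config$momentum; lr <- config$learning_rate
  lam <- config$l2_lambda
  trace <- data.frame(epoch = integer(), train_bce = numeric(),
                      val_bce = numeric())
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
      vw <- mu * vw - lr * gw; vb <- mu * vb - lr * gb
      w <- w + vw; b <- b + vb
    }
    trace <- rbind(trace, data.frame(
      epoch = epoch, train_bce = bce(y, link(drop(X %*% w) + b)),
      val_bce = NA_real_))
  }
  list(weights = model_weights(stats::setNames(w, colnames(X)), b,
                               colnames(X)),
       trace = trace)
}
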