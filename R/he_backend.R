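# CKKS-style leveled homomorphic arithmetic: an abstract contract (slot
# vectors, scale, level budget, per-operation noise model, audited refresh)
# plus a toy reference backend. The backend models the *computation* of
# approximate HE faithfully -- slotwise arithmetic with injected noise,
# levels consumed by multiplication, refresh restoring the budget -- but is
# not a cryptosystem: payloads are held opaquely in memory and "security"
# is an API contract (the secret key is only usable through decryption and
# the refresh authority), which is what the training-loop audit tests.

#' Create an HE context
#'
#' @param ring_dim ring dimension N (power of two); slot count is N/2.
#' @param scale encoding scale Delta (default 2^40). The toy backend does
#'   not carry scaled integers; `scale` fixes the noise floor: every noisy
#'   operation injects zero-mean Gaussian error with sd `sigma = 64/scale`.
#' @param levels level budget L; each (plain or ciphertext) multiplication
#'   consumes one level, additions and rotations none.
#' @return `he_context` with fields `ring_dim`, `slot_count`, `scale`,
#'   `levels`, `sigma`, `eps_enc` (frozen encryption error bound,
#'   `64 * sigma`), `modulus_chain` (descriptive string) and an `audit`
#'   environment counting decrypt and refresh calls.
#' @export
he_context <- function(ring_dim = 2^13, scale = 2^40, levels = 6) {
  if (ring_dim < 2 || bitwAnd(ring_dim, ring_dim - 1L) != 0) {
    stop("ring_dim must be a power of two", call. = FALSE)
  }
  stopifnot(levels >= 1, scale > 1)
  sigma <- 64 / scale
  audit <- new.env(parent = emptyenv())
  audit$decrypt_calls <- 0L
  audit$refresh_calls <- 0L
  structure(list(
    ring_dim = as.integer(ring_dim),
    slot_count = as.integer(ring_dim / 2),
    scale = scale,
    levels = as.integer(levels),
    sigma = sigma,
    eps_enc = 64 * sigma,
    modulus_chain = sprintf("q0 * Delta^%d (Delta = 2^%.0f)",
                            levels, log2(scale)),
    audit = audit
  ), class = "he_context")
}

#' @export
print.he_context <- function(x, ...) {
  cat(sprintf("<he_context> N=%d slots=%d Delta=2^%.0f L=%d eps_enc=%.2e\n",
              x$ring_dim, x$slot_count, log2(x$scale), x$levels, x$eps_enc))
  invisible(x)
}

#' Generate a keypair bound to a context
#'
#' Deterministic given `seed`. The returned object carries the public key
#' (with relinearization / rotation key placeholders) and the secret key;
#' the secret key is consumed only by [he_decrypt()] and
#' [refresh_authority()].
#'
#' @param context an `he_context`.
#' @param seed integer seed.
#' @return `he_keypair` with elements `pk` and `sk`.
#' @export
keygen <- function(context, seed) {
  if (!inherits(context, "he_context")) stop("invalid context",
                                             call. = FALSE)
  material <- with_seed(seed, stats::runif(8))
  key_id <- paste0("k", derive_seed(seed, paste(material, collapse = ",")))
  pk <- structure(list(key_id = key_id, material = material,
                       relin_key = "opaque", rotation_keys = "opaque",
                       context = context), class = "he_public_key")
  sk <- structure(list(key_id = key_id, context = context),
                  class = "he_secret_key")
  structure(list(pk = pk, sk = sk), class = "he_keypair")
}

new_ct <- function(payload, level, context, key_id, nbound) {
  structure(list(payload = payload, level = as.integer(level),
                 scale = context$scale, slot_len = length(payload),
                 key_id = key_id, context = context, nbound = nbound),
            class = "ciphertext_vector")
}

#' @export
print.ciphertext_vector <- function(x, ...) {
  cat(sprintf("<ciphertext_vector> slots=%d level=%d/%d noise<=%.2e\n",
              x$slot_len, x$level, x$context$levels, x$nbound))
  invisible(x)
}

#' Encrypt a real slot vector
#'
#' Randomized: fresh encryption noise (sd `sigma`) is drawn from the active
#' RNG stream, so encrypting the same vector twice yields different
#' ciphertexts. Roundtrip error is bounded by the context's `eps_enc`.
#'
#' @param v numeric vector, length <= slot count.
#' @param pk public key from [keygen()].
#' @return `ciphertext_vector` at full level.
#' @export
he_encrypt <- function(v, pk) {
  ctx <- pk$context
  if (length(v) > ctx$slot_count) stop("vector exceeds slot count",
                                       call. = FALSE)
  payload <- v + stats::rnorm(length(v), 0, ctx$sigma)
  new_ct(payload, ctx$levels, ctx, pk$key_id, 8 * ctx$sigma)
}

#' Decrypt a ciphertext
#'
#' Decryption with the wrong secret key returns deterministic garbage (far
#' outside `eps_enc`) rather than the payload. Every call increments the
#' context's decrypt audit counter, which the encrypted-training privacy
#' audit inspects.
#'
#' @param ct a `ciphertext_vector`.
#' @param sk secret key.
#' @return numeric slot vector.
#' @export
he_decrypt <- function(ct, sk) {
  ctx <- ct$context
  ctx$audit$decrypt_calls <- ctx$audit$decrypt_calls + 1L
  if (!identical(sk$key_id, ct$key_id)) {
    garbage <- with_seed(derive_seed(1, paste0(sk$key_id, ct$key_id)),
                         stats::rnorm(ct$slot_len, 0, 1e6))
    return(ct$payload + garbage)
  }
  ct$payload
}

check_compatible <- function(a, b) {
  if (!identical(a$key_id, b$key_id)) stop("key mismatch", call. = FALSE)
  if (a$slot_len != b$slot_len) stop("slot length mismatch", call. = FALSE)
  if (a$scale != b$scale) stop("scale mismatch", call. = FALSE)
  invisible(TRUE)
}

# Additions are exact in the toy backend (CKKS addition adds no fresh
# noise); operands are aligned down to the lower level.
#' Homomorphic slotwise operations
#'
#' `he_add`/`he_sub` combine two ciphertexts (level aligned to the lower
#' operand); `he_add_plain`/`he_mul_plain` apply a plaintext vector or
#' scalar; `he_mul` is multiply + relinearize + rescale and, like
#' `he_mul_plain`, consumes one level; `he_rotate` cyclically shifts slots
#' left by `k` (rotation-key switch, no level cost); `he_neg` negates.
#' Multiplying at level 0 raises a level-exhaustion error.
#'
#' @param a,b,ct `ciphertext_vector`s.
#' @param v plaintext numeric vector (or scalar, recycled).
#' @param k rotation offset.
#' @return `ciphertext_vector`.
#' @export
he_add <- function(a, b) {
  check_compatible(a, b)
  new_ct(a$payload + b$payload, min(a$level, b$level), a$context,
         a$key_id, a$nbound + b$nbound)
}

#' @rdname he_add
#' @export
he_sub <- function(a, b) {
  check_compatible(a, b)
  new_ct(a$payload - b$payload, min(a$level, b$level), a$context,
         a$key_id, a$nbound + b$nbound)
}

#' @rdname he_add
#' @export
he_neg <- function(ct) {
  new_ct(-ct$payload, ct$level, ct$context, ct$key_id, ct$nbound)
}

#' @rdname he_add
#' @export
he_add_plain <- function(ct, v) {
  new_ct(ct$payload + v, ct$level, ct$context, ct$key_id, ct$nbound)
}

#' @rdname he_add
#' @export
he_mul_plain <- function(ct, v) {
  if (ct$level < 1L) stop("level exhausted: refresh required",
                          call. = FALSE)
  ctx <- ct$context
  payload <- ct$payload * v + stats::rnorm(ct$slot_len, 0, ctx$sigma)
  new_ct(payload, ct$level - 1L, ctx, ct$key_id,
         ct$nbound * max(abs(v), 1e-300) + 8 * ctx$sigma)
}

#' @rdname he_add
#' @export
he_mul <- function(a, b) {
  check_compatible(a, b)
  lvl <- min(a$level, b$level)
  if (lvl < 1L) stop("level exhausted: refresh required", call. = FALSE)
  ctx <- a$context
  payload <- a$payload * b$payload + stats::rnorm(a$slot_len, 0, ctx$sigma)
  nb <- a$nbound * max(abs(b$payload)) + b$nbound * max(abs(a$payload)) +
    a$nbound * b$nbound + 8 * ctx$sigma
  new_ct(payload, lvl - 1L, ctx, a$key_id, nb)
}

#' @rdname he_add
#' @export
he_rotate <- function(ct, k) {
  n <- ct$slot_len
  k <- ((k %% n) + n) %% n
  payload <- if (k == 0) ct$payload else
    c(ct$payload[(k + 1):n], ct$payload[seq_len(k)])
  payload <- payload + stats::rnorm(n, 0, ct$context$sigma)
  new_ct(payload, ct$level, ct$context, ct$key_id,
         ct$nbound + 8 * ct$context$sigma)
}

# Sum across all slots, result broadcast to every slot. Requires a
# power-of-two slot length.
he_reduce_sum <- function(ct) {
  n <- ct$slot_len
  if (bitwAnd(n, n - 1L) != 0) {
    stop("reduce requires power-of-two slot length", call. = FALSE)
  }
  k <- 1L
  while (k < n) {
    ct <- he_add(ct, he_rotate(ct, k))
    k <- k * 2L
  }
  ct
}

#' Create a refresh authority
#'
#' The refresh authority is the stand-in for CKKS bootstrapping: the only
#' component besides final decryption allowed to touch the secret key. Its
#' [he_refresh()] restores a ciphertext's full level budget
#' (decrypt-and-re-encrypt internally) and increments the context's
#' refresh audit counter.
#'
#' @param keypair an `he_keypair`.
#' @return `refresh_authority` bound to the keypair.
#' @export
refresh_authority <- function(keypair) {
  sk <- keypair$sk   # held in this closure only
  pk <- keypair$pk
  auth <- function(ct) {
    if (!identical(ct$key_id, sk$key_id)) {
      stop("refresh authority not authorized for this ciphertext",
           call. = FALSE)
    }
    ctx <- ct$context
    ctx$audit$refresh_calls <- ctx$audit$refresh_calls + 1L
    payload <- ct$payload + stats::rnorm(ct$slot_len, 0, ctx$sigma)
    new_ct(payload, ctx$levels, ctx, ct$key_id, ct$nbound + 8 * ctx$sigma)
  }
  structure(list(refresh_fn = auth, key_id = keypair$pk$key_id),
            class = "refresh_authority")
}

#' Refresh a ciphertext's level budget
#' @param ct `ciphertext_vector`.
#' @param authority a `refresh_authority` for the matching keypair.
#' @return refreshed `ciphertext_vector` at full level.
#' @export
he_refresh <- function(ct, authority) {
  if (!inherits(authority, "refresh_authority")) {
    stop("unauthorized refresh", call. = FALSE)
  }
  authority$refresh_fn(ct)
}

#' Audit counters for a context
#' @param context an `he_context`.
#' @return list with `decrypt_calls` and `refresh_calls`.
#' @export
he_audit <- function(context) {
  list(decrypt_calls = context$audit$decrypt_calls,
       refresh_calls = context$audit$refresh_calls)
}
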