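# Encrypted training: packing, merging, arithmetic parity with the
# plaintext mirror, and the privacy audit.

toy_design <- function(n, p = 3, seed = 1, site = "T") {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("x", seq_len(p))))
  y <- rbinom(n, 1, plogis(X[, 1] - 0.5))
  h_design(X, y, site)
}

test_that("packing round-trips and pads the final block", {
  ctx <- h_toy_context()
  keys <- keygen(ctx, 1)
  d <- toy_design(100, seed = 2)
  cfg <- train_config(batch_size = 64, seed = 3, sigmoid_mode = "poly")
  pack <- pack_dataset(d, keys$pk, cfg)
  expect_identical(length(pack$blocks), 2L)
  expect_identical(pack$blocks[[2]]$m, 36L)
  expect_identical(names(pack$blocks[[1]]$cols), colnames(d$X))

  up <- unpack_dataset(pack, keys$sk)
  perm <- unlist(securelogit:::make_block_groups(100, 64, 3, "T"))
  expect_lt(max(abs(up$X - d$X[perm, ])), 1e-8)
  expect_lt(max(abs(up$y - d$y[perm])), 1e-8)

  expect_error(pack_dataset(d, keys$pk,
                            train_config(batch_size = 48)), "power of two")
})

test_that("merge_encrypted concatenates without decryption", {
  ctx <- h_toy_context()
  keys <- keygen(ctx, 4)
  cfg <- train_config(batch_size = 32, seed = 5, sigmoid_mode = "poly")
  pa <- pack_dataset(toy_design(96, seed = 6, site = "A"), keys$pk, cfg)
  pb <- pack_dataset(toy_design(80, seed = 7, site = "B"), keys$pk, cfg)
  aud0 <- he_audit(ctx)
  merged <- merge_encrypted(list(pa, pb))
  aud1 <- he_audit(ctx)
  expect_identical(merged$n, 176L)
  expect_identical(aud0, aud1)  # no privileged ops during merge

  upm <- unpack_dataset(merged, keys$sk)
  upa <- unpack_dataset(pa, keys$sk)
  upb <- unpack_dataset(pb, keys$sk)
  expect_lt(max(abs(upm$X - rbind(upa$X, upb$X))), 1e-8)

  keys2 <- keygen(ctx, 99)
  pc <- pack_dataset(toy_design(32, seed = 8), keys2$pk, cfg)
  expect_error(merge_encrypted(list(pa, pc)), "key mismatch")
})

test_that("one encrypted NAG iteration matches the lr_core oracle within 1e-4", {
  ctx <- h_toy_context()
  keys <- keygen(ctx, 10)
  auth <- refresh_authority(keys)
  X <- matrix(c(1, -0.5, 0.25, 2), 2, 2,
              dimnames = list(NULL, c("x1", "x2")))
  y <- c(1, 0)
  d <- h_design(X, y)
  cfg <- train_config(batch_size = 2, epochs = 1, sigmoid_mode = "poly",
                      seed = 11)
  poly <- fit_poly_sigmoid(3)
  pack <- pack_dataset(d, keys$pk, cfg)
  enc <- train_encrypted(pack, cfg, auth, poly = poly)
  dec <- decrypt_weights(enc, keys$sk)

  st <- list(weights = model_weights(c(0, 0), 0, colnames(X)),
             velocity = list(beta = c(0, 0), intercept = 0))
  oracle <- nag_step(st, X, y, cfg, poly = poly)$weights
  expect_lt(max(abs(c(dec$beta - oracle$beta,
                      dec$intercept - oracle$intercept))), 1e-4)
})

test_that("zero-epoch encrypted training decrypts to zero weights with schema", {
  ctx <- h_toy_context()
  keys <- keygen(ctx, 12)
  auth <- refresh_authority(keys)
  d <- toy_design(40, seed = 13)
  cfg <- train_config(batch_size = 32, epochs = 0, sigmoid_mode = "poly")
  enc <- train_encrypted(pack_dataset(d, keys$pk, cfg), cfg, auth)
  dec <- decrypt_weights(enc, keys$sk)
  expect_lt(max(abs(c(dec$beta, dec$intercept))), ctx$eps_enc)
  expect_identical(dec$columns, colnames(d$X))
  other <- keygen(ctx, 14)
  expect_error(decrypt_weights(enc, other$sk), "key mismatch")
})

test_that("encrypted training requires the polynomial link", {
  ctx <- h_toy_context()
  keys <- keygen(ctx, 15)
  auth <- refresh_authority(keys)
  d <- toy_design(32, seed = 16)
  cfgp <- train_config(batch_size = 32, sigmoid_mode = "poly")
  pack <- pack_dataset(d, keys$pk, cfgp)
  expect_error(train_encrypted(pack, train_config(batch_size = 32), auth),
               "poly")
  shallow <- he_context(2^7, 2^40, levels = 3)
  kshallow <- keygen(shallow, 1)
  packs <- pack_dataset(d, kshallow$pk, cfgp)
  expect_error(train_encrypted(packs, cfgp, refresh_authority(kshallow)),
               "level budget")
})

test_that("privacy audit: no decryption during training, refreshes as predicted", {
  ctx <- h_toy_context()
  keys <- keygen(ctx, 17)
  auth <- refresh_authority(keys)
  d <- toy_design(100, seed = 18)
  cfg <- train_config(batch_size = 64, epochs = 2, sigmoid_mode = "poly",
                      seed = 19)
  pack <- pack_dataset(d, keys$pk, cfg)
  aud0 <- he_audit(ctx)
  enc <- train_encrypted(pack, cfg, auth)
  aud1 <- he_audit(ctx)
  expect_identical(aud1$decrypt_calls, aud0$decrypt_calls)
  log <- attr(enc, "run_log")
  expect_identical(log$iterations, 4L)  # 2 blocks x 2 epochs
  expect_identical(log$refresh_calls, log$predicted_refresh)
  expect_identical(aud1$refresh_calls - aud0$refresh_calls,
                   log$refresh_calls)
})

test_that("merge-equivariance: encrypted merged training equals the plaintext mirror", {
  ctx <- h_toy_context()
  keys <- keygen(ctx, 20)
  auth <- refresh_authority(keys)
  dA <- toy_design(96, seed = 21, site = "A")
  dB <- toy_design(80, seed = 22, site = "B")
  cfg <- train_config(batch_size = 32, epochs = 2, sigmoid_mode = "poly",
                      seed = 23)
  poly <- fit_poly_sigmoid(3)
  merged <- merge_encrypted(list(
    pack_dataset(dA, keys$pk, cfg, label = "A"),
    pack_dataset(dB, keys$pk, cfg, label = "B")))
  enc <- train_encrypted(merged, cfg, auth, poly = poly)
  dec <- decrypt_weights(enc, keys$sk)
  mirror <- train_plaintext_mirror(list(dA, dB), list("A", "B"), cfg,
                                   poly = poly)
  expect_lt(max(abs(c(dec$beta - mirror$weights$beta,
                      dec$intercept - mirror$weights$intercept))), 1e-6)
})

test_that("single-site encrypted training matches train_plaintext bit-nearly", {
  ctx <- he_context(2^13, 2^40, 6)
  keys <- keygen(ctx, 24)
  auth <- refresh_authority(keys)
  sets <- h_site_sets(h_profile(), 300, seed = 25)
  Xtr <- sets$train$X; ytr <- sets$train$y
  cfg <- train_config(epochs = 2, sigmoid_mode = "poly", seed = 26)
  poly <- fit_poly_sigmoid(3)
  plain <- train_plaintext(Xtr, ytr, cfg, poly = poly,
                           schedule_label = "X")
  pack <- pack_dataset(h_design(Xtr, ytr, "X"), keys$pk, cfg, label = "X")
  dec <- decrypt_weights(train_encrypted(pack, cfg, auth, poly = poly),
                         keys$sk)
  # frozen regression bound: first measurement was ~1e-7
  expect_lt(max(abs(c(dec$beta - plain$weights$beta,
                      dec$intercept - plain$weights$intercept))), 1e-6)
})
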