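# Experiment drivers: the cross-site validation matrix, the incremental
# model-adaptation curves, and the ciphertext/plaintext parity study.

#' Experiment configuration
#'
#' @param profiles named list of `hospital_profile`s (default: the three
#'   built-in profiles via [default_profiles()]).
#' @param n_per_site cohort size drawn per site (scaled-down default; the
#'   real institutions are 1-2 orders of magnitude larger).
#' @param train a `train_config`. Single-site rows train in plaintext with
#'   the exact sigmoid; merged rows train under encryption and force
#'   `sigmoid_mode = "poly"`.
#' @param he list of [he_context()] parameters.
#' @param B bootstrap replicates per matrix cell / curve point.
#' @param schedule model-adaptation host-size schedule, strictly
#'   increasing from 0.
#' @param seed master seed; every derived stream hangs off it.
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @param trainer_mode `"encrypted"` (merged models trained on ciphertext)
#'   or `"plaintext_mirror"` (same block schedule without HE; for fast
#'   property checks -- parity ties the two together).
#' @param n_parity,parity_epochs size and epochs of the parity study.
#' @return `experiment_config` list with a deterministic `config_hash`.
#' @export
experiment_config <- function(profiles = NULL, n_per_site = 4000,
                              train = train_config(epochs = 3),
                              he = list(ring_dim = 2^13, scale = 2^40,
                                        levels = 6),
                              B = 20,
                              schedule = c(0, 1000, 3000, 6000, 10000,
                                           15000, 20000),
                              seed = 1L, out_dir = NULL,
                              trainer_mode = c("encrypted",
                                               "plaintext_mirror"),
                              n_parity = 2000, parity_epochs = 3) {
  trainer_mode <- match.arg(trainer_mode)
  if (is.null(profiles)) profiles <- default_profiles()
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, `[[`, "", "site_id")
  }
  stopifnot(all(diff(schedule) > 0), schedule[1] == 0)
  cfg <- list(profiles = profiles, n_per_site = n_per_site, train = train,
              he = he, B = B, schedule = schedule, seed = as.integer(seed),
              out_dir = out_dir, trainer_mode = trainer_mode,
              n_parity = n_parity, parity_epochs = parity_epochs)
  hash_src <- jsonlite::toJSON(list(
    sites = names(profiles), n_per_site = n_per_site,
    train = unclass(train), he = he, B = B, schedule = schedule,
    seed = seed, trainer_mode = trainer_mode, n_parity = n_parity,
    parity_epochs = parity_epochs), auto_unbox = TRUE, digits = NA)
  cfg$config_hash <- sprintf("%08x", derive_seed(7, hash_src))
  class(cfg) <- "experiment_config"
  cfg
}

# Simulate, inject missingness, impute, standardize per site (each
# hospital on its own full data, before any encryption), encode, and split
# 6:2:2 site-locally.
prepare_sites <- function(config) {
  out <- list()
  for (s in names(config$profiles)) {
    prof <- config$profiles[[s]]
    cohort <- sample_cohort(prof, config$n_per_site,
                            derive_seed(config$seed, paste0("cohort-", s)))
    cohort <- inject_missingness(cohort, prof$miss_rates,
                                 derive_seed(config$seed,
                                             paste0("miss-", s)))
    prep <- prepare_design(cohort)
    spl <- split_622(nrow(cohort),
                     derive_seed(config$seed, paste0("split-", s)))
    d <- prep$design
    take <- function(idx) list(X = d$X[idx, , drop = FALSE], y = d$y[idx])
    out[[s]] <- list(design = d, params = prep$params, split = spl,
                     train = take(spl$train), val = take(spl$val),
                     test = take(spl$test))
  }
  out
}

site_combos <- function(sites) {
  combos <- as.list(sites)
  for (k in 2:length(sites)) {
    cmb <- utils::combn(sites, k, simplify = FALSE)
    combos <- c(combos, cmb)
  }
  combos
}

make_merged_trainer <- function(config, keys, authority, poly, label) {
  cfg <- config$train
  cfg$sigmoid_mode <- "poly"
  if (config$trainer_mode == "plaintext_mirror") {
    function(X, y, rs) {
      cfg$seed <- rs
      design <- list(X = X, y = y, site = label)
      train_plaintext_mirror(list(design), list(label), cfg,
                             poly = poly)$weights
    }
  } else {
    function(X, y, rs) {
      cfg$seed <- rs
      design <- structure(list(X = X, y = y, site = rep(label, nrow(X)),
                               columns = colnames(X)),
                          class = "design_matrix")
      with_seed(derive_seed(rs, "he-noise"), {
        pack <- pack_dataset(design, keys$pk, cfg, label = label)
        enc <- train_encrypted(pack, cfg, authority, poly = poly)
        decrypt_weights(enc, keys$sk)
      })
    }
  }
}

#' Cross-site validation matrix
#'
#' Trains every site combination -- single sites in plaintext, multi-site
#' merges on ciphertext -- and bootstrap-evaluates each model on every
#' site's fixed test partition (AUROC and AUPRC with 95% CIs). With three
#' sites this is the 7-row x 3-column validation matrix.
#'
#' @param config an `experiment_config`.
#' @return `cross_site_matrix`: list with `table` (tidy data.frame:
#'   train_combo, test_site, metric, mean, lo, hi, B, seed) and `sites`.
#'   Written to `out_dir/cross_site_matrix.csv` when configured.
#' @export
run_cross_site_matrix <- function(config) {
  sites <- names(config$profiles)
  if (length(sites) < 2) stop("need at least 2 sites", call. = FALSE)
  prep <- prepare_sites(config)
  test_sets <- lapply(prep, `[[`, "test")
  poly <- fit_poly_sigmoid(config$train$poly_degree)
  ctx <- do.call(he_context, config$he)
  keys <- keygen(ctx, derive_seed(config$seed, "keys"))
  auth <- refresh_authority(keys)

  rows <- list()
  for (combo in site_combos(sites)) {
    label <- paste(combo, collapse = "+")
    train_set <- list(
      X = do.call(rbind, lapply(combo, function(s) prep[[s]]$train$X)),
      y = unlist(lapply(combo, function(s) prep[[s]]$train$y)))
    trainer <- if (length(combo) == 1L) {
      cfg <- config$train
      cfg$sigmoid_mode <- "exact"
      function(X, y, rs) {
        cfg$seed <- rs
        train_plaintext(X, y, cfg, schedule_label = label)$weights
      }
    } else {
      make_merged_trainer(config, keys, auth, poly, label)
    }
    br <- bootstrap_evaluate(trainer, train_set, test_sets, B = config$B,
                             seed = derive_seed(config$seed,
                                                paste0("combo-", label)))
    ci <- br$ci
    ci$train_combo <- label
    ci$regime <- if (length(combo) == 1L) "single (plaintext)" else
      "merged (ciphertext)"
    rows[[label]] <- ci
  }
  tab <- do.call(rbind, rows)
  tab <- data.frame(train_combo = tab$train_combo, regime = tab$regime,
                    test_site = tab$test_set, metric = tab$metric,
                    mean = tab$mean, ci_lo = tab$lo, ci_hi = tab$hi,
                    B = config$B, seed = config$seed,
                    row.names = NULL)
  out <- structure(list(table = tab, sites = sites,
                        config_hash = config$config_hash),
                   class = "cross_site_matrix")
  write_artifact(config, tab, "cross_site_matrix.csv")
  out
}

#' Model-adaptation curve
#'
#' The donor site contributes its full (encrypted) training partition; the
#' host contributes nested prefixes of a seeded shuffle of its own
#' training rows, one prefix per schedule size (so subsets are comparable
#' across sizes). Each merged model is bootstrap-evaluated on the host's
#' fixed test partition.
#'
#' @param config an `experiment_config`; `config$schedule` gives the host
#'   data sizes (starting at 0 = donor-only baseline).
#' @param donor,host site names.
#' @return `adaptation_curve`: list with `curve` (data.frame size,
#'   replicate, auroc, auprc), `summary` (size, metric, mean, lo, hi),
#'   `donor`, `host`.
#' @export
run_adaptation <- function(config, donor, host) {
  prep <- prepare_sites(config)
  stopifnot(donor %in% names(prep), host %in% names(prep))
  host_train <- prep[[host]]$train
  n_host <- nrow(host_train$X)
  if (max(config$schedule) > n_host) {
    stop(sprintf("schedule max %d exceeds host training rows %d",
                 max(config$schedule), n_host), call. = FALSE)
  }
  host_order <- with_seed(derive_seed(config$seed, "adapt-host-order"),
                          sample.int(n_host))
  poly <- fit_poly_sigmoid(config$train$poly_degree)
  ctx <- do.call(he_context, config$he)
  keys <- keygen(ctx, derive_seed(config$seed, "keys"))
  auth <- refresh_authority(keys)
  test_sets <- list(host = prep[[host]]$test)

  curve <- list(); summ <- list()
  for (s in config$schedule) {
    rows_host <- host_order[seq_len(s)]
    train_set <- list(
      X = rbind(prep[[donor]]$train$X,
                host_train$X[rows_host, , drop = FALSE]),
      y = c(prep[[donor]]$train$y, host_train$y[rows_host]))
    label <- sprintf("%s+%s@%d", donor, host, s)
    trainer <- make_merged_trainer(config, keys, auth, poly, label)
    br <- bootstrap_evaluate(trainer, train_set, test_sets, B = config$B,
                             seed = derive_seed(config$seed,
                                                paste0("adapt-", s)))
    res <- br$results
    res$size <- s
    curve[[as.character(s)]] <- res[, c("size", "replicate",
                                        "auroc", "auprc")]
    ci <- br$ci
    ci$size <- s
    summ[[as.character(s)]] <- ci
  }
  curve <- do.call(rbind, c(curve, make.row.names = FALSE))
  summ <- do.call(rbind, c(summ, make.row.names = FALSE))
  summ <- data.frame(size = summ$size, metric = summ$metric,
                     mean = summ$mean, lo = summ$lo, hi = summ$hi)
  out <- structure(list(curve = curve, summary = summ,
                        donor = donor, host = host,
                        config_hash = config$config_hash),
                   class = "adaptation_curve")
  write_artifact(config, curve,
                 sprintf("adaptation_%s_to_%s.csv", donor, host))
  out
}

#' Ciphertext/plaintext parity study
#'
#' Trains one model twice with identical seeds, batch schedule and
#' polynomial sigmoid -- once in plaintext, once entirely on ciphertext --
#' then scores the same held-out test partition with both decrypted weight
#' vectors and reports the absolute prediction differences. Under exact
#' mirroring the only sources of discrepancy are the HE noise model and
#' level/refresh arithmetic.
#'
#' @param config an `experiment_config` (`n_parity` rows from the first
#'   profile, `parity_epochs` epochs).
#' @return `parity_report`: mean/min/max absolute prediction difference,
#'   max absolute weight difference, `n_compared`, context parameters.
#' @export
run_parity <- function(config) {
  site <- names(config$profiles)[1]
  prof <- config$profiles[[site]]
  cohort <- sample_cohort(prof, config$n_parity,
                          derive_seed(config$seed, "parity-cohort"))
  cohort <- inject_missingness(cohort, prof$miss_rates,
                               derive_seed(config$seed, "parity-miss"))
  prep <- prepare_design(cohort)
  spl <- split_622(nrow(cohort), derive_seed(config$seed, "parity-split"))
  d <- prep$design
  Xtr <- d$X[spl$train, , drop = FALSE]; ytr <- d$y[spl$train]
  Xte <- d$X[spl$test, , drop = FALSE]; yte <- d$y[spl$test]

  cfg <- config$train
  cfg$sigmoid_mode <- "poly"
  cfg$epochs <- config$parity_epochs
  poly <- fit_poly_sigmoid(cfg$poly_degree)

  plain <- train_plaintext(Xtr, ytr, cfg, poly = poly,
                           schedule_label = site)

  ctx <- do.call(he_context, config$he)
  keys <- keygen(ctx, derive_seed(config$seed, "keys"))
  auth <- refresh_authority(keys)
  design_tr <- structure(list(X = Xtr, y = ytr,
                              site = rep(site, nrow(Xtr)),
                              columns = colnames(Xtr)),
                         class = "design_matrix")
  enc_w <- with_seed(derive_seed(config$seed, "he-noise"), {
    pack <- pack_dataset(design_tr, keys$pk, cfg, label = site)
    train_encrypted(pack, cfg, auth, poly = poly)
  })
  dec <- decrypt_weights(enc_w, keys$sk)

  p_plain <- predict_proba(plain$weights, Xte)
  p_enc <- predict_proba(dec, Xte)
  ad <- abs(p_plain - p_enc)
  out <- structure(list(
    mean_abs_diff = mean(ad), min_abs_diff = min(ad),
    max_abs_diff = max(ad), n_compared = length(ad),
    weight_max_abs_diff = max(abs(c(plain$weights$beta - dec$beta,
                                    plain$weights$intercept -
                                      dec$intercept))),
    he = config$he, run_log = attr(enc_w, "run_log"),
    config_hash = config$config_hash, seed = config$seed),
    class = "parity_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      out[c("mean_abs_diff", "min_abs_diff", "max_abs_diff", "n_compared",
            "weight_max_abs_diff", "he", "config_hash", "seed")],
      file.path(config$out_dir, "parity_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.parity_report <- function(x, ...) {
  cat(sprintf(paste0("<parity_report> n=%d  mean|diff|=%.3e  ",
                     "min|diff|=%.3e  max|diff|=%.3e\n"),
              x$n_compared, x$mean_abs_diff, x$min_abs_diff,
              x$max_abs_diff))
  invisible(x)
}

write_artifact <- function(config, df, filename) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, filename)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- sub("\\.csv$", ".meta.json", path)
  jsonlite::write_json(list(config_hash = config$config_hash,
                            seed = config$seed,
                            created = "deterministic"),
                       meta, auto_unbox = TRUE)
  invisible(path)
}
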