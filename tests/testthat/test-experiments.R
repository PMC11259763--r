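# Experiment drivers and the CLI.

h_three_sites <- function(tau = 0) {
  base <- h_beta(c(age = 2.0, alb = -1.6, emergency = 1.6, cr = 0.8))
  mk <- function(id, seed) {
    h_profile(id, beta = if (tau > 0) {
      perturb_coefficients(base, tau, seed)
    } else base)
  }
  list(A = mk("A", 1), S = mk("S", 2), E = mk("E", 3))
}

test_that("cross-site matrix has the full combinatorial layout (encrypted)", {
  cfg <- experiment_config(
    profiles = h_three_sites(), n_per_site = 800, B = 2,
    train = train_config(epochs = 4, learning_rate = 0.05,
                         l2_lambda = 0.001, seed = 4), seed = 5,
    he = list(ring_dim = 2^7, scale = 2^40, levels = 6))
  res <- run_cross_site_matrix(cfg)
  tab <- res$table
  expect_identical(nrow(tab), 7L * 3L * 2L)
  expect_identical(length(unique(tab$train_combo)), 7L)
  expect_setequal(unique(tab$test_site), c("A", "S", "E"))
  expect_setequal(unique(tab$regime),
                  c("single (plaintext)", "merged (ciphertext)"))
  expect_true(all(tab$ci_lo <= tab$mean + 1e-12))
  expect_true(all(tab$mean <= tab$ci_hi + 1e-12))
  # every own-site single model clears the noise floor
  for (s in c("A", "S", "E")) {
    own <- tab[tab$train_combo == s & tab$test_site == s &
                 tab$metric == "auroc", ]
    expect_gt(own$mean, 0.6)
  }
})

test_that("homogeneous pooling never hurts foreign-site transfer", {
  cfg <- experiment_config(
    profiles = h_three_sites(tau = 0), n_per_site = 1500, B = 3,
    train = train_config(epochs = 3, seed = 6), seed = 7,
    trainer_mode = "plaintext_mirror")
  tab <- run_cross_site_matrix(cfg)$table
  au <- tab[tab$metric == "auroc", ]
  grab <- function(combo, site) au$mean[au$train_combo == combo &
                                          au$test_site == site]
  # merged model at least matches the single foreign model, within the
  # bootstrap CI slack
  for (site in c("A", "E")) {
    foreign <- setdiff(c("A", "E"), site)
    merged <- grab("A+S+E", site)
    single_foreign <- grab(foreign, site)
    sub <- au[au$train_combo == foreign & au$test_site == site, ]
    width <- sub$ci_hi - sub$ci_lo
    expect_gte(merged, single_foreign - max(width, 0.05))
  }
})

test_that("adaptation curves cover the schedule and validate inputs", {
  profs <- h_three_sites(tau = 0)[c("A", "E")]
  cfg <- experiment_config(
    profiles = profs, n_per_site = 600, B = 2,
    train = train_config(epochs = 2, seed = 8),
    schedule = c(0, 100, 300), seed = 9,
    trainer_mode = "plaintext_mirror")
  ad <- run_adaptation(cfg, "A", "E")
  expect_setequal(unique(ad$curve$size), c(0, 100, 300))
  expect_identical(nrow(ad$curve), 3L * 2L)
  expect_true(all(ad$summary$lo <= ad$summary$mean + 1e-12))

  bad <- experiment_config(profiles = profs, n_per_site = 600,
                           schedule = c(0, 100000), seed = 9)
  expect_error(run_adaptation(bad, "A", "E"), "exceeds host")
})

test_that("experiment configs validate the schedule and hash deterministically", {
  profs <- h_three_sites()[c("A", "E")]
  expect_error(experiment_config(profiles = profs, schedule = c(0, 5, 5)),
               "diff")
  expect_error(experiment_config(profiles = profs, schedule = c(10, 20)))
  c1 <- experiment_config(profiles = profs, seed = 3)
  c2 <- experiment_config(profiles = profs, seed = 3)
  c3 <- experiment_config(profiles = profs, seed = 4)
  expect_identical(c1$config_hash, c2$config_hash)
  expect_false(identical(c1$config_hash, c3$config_hash))
})

test_that("parity report is ordered, deterministic, and degrades with coarser scale", {
  prof <- list(X = h_profile())
  mk <- function(scale) {
    cfg <- experiment_config(profiles = prof, n_parity = 300,
                             parity_epochs = 2, seed = 11,
                             train = train_config(seed = 11),
                             he = list(ring_dim = 2^13, scale = scale,
                                       levels = 6))
    run_parity(cfg)
  }
  r40 <- mk(2^40)
  expect_lte(r40$min_abs_diff, r40$mean_abs_diff)
  expect_lte(r40$mean_abs_diff, r40$max_abs_diff)
  expect_identical(r40$run_log$refresh_calls,
                   r40$run_log$predicted_refresh)
  r40b <- mk(2^40)
  expect_identical(r40$mean_abs_diff, r40b$mean_abs_diff)

  # precision ladder: smaller scale -> coarser arithmetic -> larger drift
  r28 <- mk(2^28)
  r16 <- mk(2^16)
  expect_lt(r40$mean_abs_diff, r28$mean_abs_diff)
  expect_lt(r28$mean_abs_diff, r16$mean_abs_diff)
})

test_that("cross-site outputs are byte-identical across reruns", {
  profs <- h_three_sites()[c("A", "E")]
  run_once <- function(dir) {
    cfg <- experiment_config(profiles = profs, n_per_site = 800, B = 2,
                             train = train_config(epochs = 1, seed = 12),
                             seed = 13, out_dir = dir,
                             trainer_mode = "plaintext_mirror")
    run_cross_site_matrix(cfg)
    unname(tools::md5sum(file.path(dir, "cross_site_matrix.csv")))
  }
  d1 <- tempfile(); d2 <- tempfile()
  expect_identical(run_once(d1), run_once(d2))
})

test_that("cli subcommands run end to end", {
  td <- tempfile(); dir.create(td)
  old <- setwd(td); on.exit(setwd(old))

  out <- file.path(td, "cohort.csv")
  expect_identical(
    suppressMessages(cli(c("simulate", "--sites", "2", "--n", "150",
                           "--seed", "7", "-o", out))), 0L)
  tab <- read_cohort_csv(out)
  expect_identical(nrow(tab), 300L)
  expect_setequal(unique(tab$site), c("A", "S"))

  expect_identical(
    suppressMessages(cli(c("preprocess", "--in", out,
                           "--out-prefix", "prep"))), 0L)
  expect_true(file.exists("prep_design.csv"))
  expect_true(file.exists("prep_params.json"))
  des <- utils::read.csv("prep_design.csv", check.names = FALSE)
  expect_identical(nrow(des), 300L)

  expect_identical(suppressMessages(cli(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(cli(character())), 2L)
})
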