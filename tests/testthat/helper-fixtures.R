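# Desk-scale test fixtures, built in code. The default profiles keep the
# realistic 0.2-0.4% mortality prevalence; experiment-level tests that fit
# models on a few thousand rows use these elevated-prevalence (4%) test
# profiles instead, so training partitions contain more than a handful of
# events.

h_cont_names <- c("age", "bmi", "wbc", "hb", "plt", "na", "k", "bun",
                  "cr", "alb", "got", "gpt", "glu", "pt_inr", "aptt")
h_lab_names <- setdiff(h_cont_names, c("age", "bmi"))

h_cont_specs <- function() {
  means <- c(age = 60, bmi = 24, wbc = 7, hb = 13, plt = 240, na = 140,
             k = 4.2, bun = 15, cr = 1, alb = 4, got = 25, gpt = 23,
             glu = 110, pt_inr = 1, aptt = 30)
  sds <- c(age = 15, bmi = 4, wbc = 2.5, hb = 1.8, plt = 70, na = 2.5,
           k = 0.4, bun = 7, cr = 0.6, alb = 0.5, got = 20, gpt = 20,
           glu = 35, pt_inr = 0.1, aptt = 4)
  floors <- c(age = 18, bmi = 10)
  lower <- pmax(means - 5 * sds,
                ifelse(names(means) %in% names(floors),
                       floors[names(means)], 0.01))
  data.frame(name = names(means), mean = unname(means), sd = unname(sds),
             lower = unname(lower), upper = unname(means + 5 * sds),
             stringsAsFactors = FALSE)
}

h_lab_corr <- function(r_within = 0.75, r_between = 0.05) {
  blocks <- list(c("wbc", "hb", "plt"), c("na", "k", "bun", "cr"),
                 c("alb", "got", "gpt"), c("pt_inr", "aptt"), "glu")
  k <- length(h_lab_names)
  m <- matrix(r_between, k, k, dimnames = list(h_lab_names, h_lab_names))
  for (blk in blocks) m[blk, blk] <- r_within
  diag(m) <- 1
  m
}

# beta: zero everywhere except a few strong, documented predictors
h_beta <- function(overrides = c(age = 1.2, alb = -1.0, emergency = 1.2)) {
  b <- stats::setNames(numeric(length(design_columns())), design_columns())
  b[names(overrides)] <- overrides
  b
}

h_profile <- function(site_id = "X", beta = h_beta(), prevalence = 0.04,
                      miss_rates = c(bmi = 0.05, alb = 0.02),
                      tau = 0, calib_seed = 42, calibrate_n = 20000) {
  prof <- hospital_profile(
    site_id = site_id, n_default = 5000,
    cont_specs = h_cont_specs(), sex_p = 0.55,
    surgery_probs = c(general = 0.35, otolaryngologic = 0.1,
                      urologic = 0.1, orthopedic = 0.15,
                      gynecologic = 0.15, plastic = 0.05, other = 0.1),
    anesthesia_probs = c(general = 0.8, neuraxial = 0.1, mac = 0.05,
                         regional = 0.03, other = 0.02),
    emergency_p = 0.06, lab_corr = h_lab_corr(), beta = beta,
    target_prevalence = prevalence, miss_rates = miss_rates,
    heterogeneity_tau = tau)
  prof$intercept <- calibrate_intercept(prof, prevalence,
                                        n_mc = calibrate_n,
                                        seed = calib_seed)
  prof
}

# Very strong signal (generative AUROC > 0.95) for metric sanity checks.
h_profile_strong <- function(site_id = "X") {
  h_profile(site_id,
            beta = h_beta(c(age = 2.8, alb = -2.2, emergency = 2.0,
                            cr = 1.2, glu = 0.8)))
}

# Pure-noise site: no predictor carries signal.
h_profile_noise <- function(site_id = "N") {
  h_profile(site_id, beta = h_beta(numeric(0)))
}

# Preprocessed train/val/test sets for one profile.
h_site_sets <- function(profile, n, seed) {
  cohort <- sample_cohort(profile, n, seed)
  d <- prepare_design(cohort)$design
  spl <- split_622(n, seed + 1L)
  take <- function(idx) list(X = d$X[idx, , drop = FALSE], y = d$y[idx])
  list(design = d, train = take(spl$train), val = take(spl$val),
       test = take(spl$test))
}

# Bare design_matrix from raw pieces (for toy secure-training fixtures).
h_design <- function(X, y, site = "T") {
  structure(list(X = X, y = y, site = rep(site, nrow(X)),
                 columns = colnames(X)), class = "design_matrix")
}

h_toy_context <- function(levels = 6) he_context(2^7, 2^40, levels)
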