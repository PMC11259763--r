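# Hospital generative profiles: everything needed to simulate one site's
# perioperative cohort (feature distributions, lab-panel correlation,
# site-level logistic coefficients, outcome prevalence, MCAR missingness).

#' Construct a hospital profile
#'
#' A `hospital_profile` bundles the generative parameters for one synthetic
#' site: truncated-normal specs for the continuous features, category
#' probabilities, a lab-panel correlation matrix, logistic coefficients on
#' the standardized/encoded scale, an intercept, a target outcome prevalence
#' and per-feature missingness rates.
#'
#' @param site_id short site label.
#' @param n_default default cohort size for this site.
#' @param cont_specs data.frame with columns `name`, `mean`, `sd`, `lower`,
#'   `upper` covering every continuous feature in [design_columns()].
#' @param sex_p probability that a patient is female.
#' @param surgery_probs named probabilities over the 7 surgery categories.
#' @param anesthesia_probs named probabilities over the 5 anesthesia
#'   categories.
#' @param emergency_p probability of emergency surgery.
#' @param lab_corr 13x13 correlation matrix over the laboratory features,
#'   rows/columns in the order of the lab schema.
#' @param beta named coefficient vector over [design_columns()] (log-odds
#'   per standardized unit / per indicator).
#' @param intercept log-odds offset; if `NA` it must be calibrated before
#'   sampling (see [calibrate_intercept()]).
#' @param target_prevalence outcome probability in (0, 0.05].
#' @param miss_rates named per-feature MCAR probabilities, each in [0, 0.10].
#' @param heterogeneity_tau sd of the site-level Gaussian coefficient
#'   perturbation used when deriving site betas from a shared base.
#' @return object of class `hospital_profile`.
#' @export
hospital_profile <- function(site_id, n_default, cont_specs, sex_p,
                             surgery_probs, anesthesia_probs, emergency_p,
                             lab_corr, beta, intercept = NA_real_,
                             target_prevalence, miss_rates,
                             heterogeneity_tau = 0) {
  prof <- structure(list(
    site_id = as.character(site_id),
    n_default = as.integer(n_default),
    cont_specs = cont_specs,
    sex_p = sex_p,
    surgery_probs = surgery_probs,
    anesthesia_probs = anesthesia_probs,
    emergency_p = emergency_p,
    lab_corr = lab_corr,
    beta = beta,
    intercept = intercept,
    target_prevalence = target_prevalence,
    miss_rates = miss_rates,
    heterogeneity_tau = heterogeneity_tau
  ), class = "hospital_profile")
  validate_profile(prof)
  prof
}

#' @export
print.hospital_profile <- function(x, ...) {
  cat(sprintf(
    "<hospital_profile '%s'>  n_default=%d  prevalence=%.4g  tau=%.3g\n",
    x$site_id, x$n_default, x$target_prevalence, x$heterogeneity_tau))
  invisible(x)
}

validate_profile <- function(p) {
  stopifnot(inherits(p, "hospital_profile"))
  if (!setequal(p$cont_specs$name, sl_continuous)) {
    stop("cont_specs must cover exactly the continuous schema features",
         call. = FALSE)
  }
  if (any(p$cont_specs$sd <= 0)) stop("continuous sds must be positive",
                                      call. = FALSE)
  stopifnot_prob_vector(p$surgery_probs, "surgery_probs")
  stopifnot_prob_vector(p$anesthesia_probs, "anesthesia_probs")
  if (!setequal(names(p$surgery_probs), sl_surgery_levels) ||
      !setequal(names(p$anesthesia_probs), sl_anesthesia_levels)) {
    stop("category probability names must match the schema levels",
         call. = FALSE)
  }
  lc <- p$lab_corr
  if (!isTRUE(all.equal(lc, t(lc), tolerance = 1e-10)) ||
      any(abs(diag(lc) - 1) > 1e-10)) {
    stop("lab_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(lc, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("lab_corr must be positive semi-definite",
                            call. = FALSE)
  if (any(p$miss_rates < 0 | p$miss_rates > 0.10)) {
    stop("miss_rates must lie in [0, 0.10]", call. = FALSE)
  }
  if (!(p$target_prevalence > 0 && p$target_prevalence <= 0.05)) {
    stop("target_prevalence must lie in (0, 0.05]", call. = FALSE)
  }
  if (!setequal(names(p$beta), design_columns())) {
    stop("beta must be named over design_columns()", call. = FALSE)
  }
  invisible(TRUE)
}

# Block-exchangeable lab correlation: r_within inside each collection panel,
# r_between across panels.
default_lab_corr <- function(r_within = 0.75, r_between = 0.05) {
  k <- length(sl_labs)
  m <- matrix(r_between, k, k, dimnames = list(sl_labs, sl_labs))
  for (blk in sl_lab_blocks) {
    m[blk, blk] <- r_within
  }
  diag(m) <- 1
  m
}

# Shared base coefficients on the standardized/encoded scale. Package
# defaults chosen so discrimination is driven by a few strong predictors
# (age, albumin, emergency surgery) with plausible smaller effects elsewhere;
# these are modelling defaults, not estimates from any real cohort.
default_base_beta <- function() {
  b <- c(age = 0.90, bmi = -0.10,
         wbc = 0.25, hb = -0.20, plt = -0.10, na = -0.10, k = 0.05,
         bun = 0.20, cr = 0.35, alb = -0.70, got = 0.10, gpt = 0.05,
         glu = 0.15, pt_inr = 0.30, aptt = 0.10,
         sex = -0.10, emergency = 1.00,
         surgery_general = 0.20, surgery_otolaryngologic = -0.20,
         surgery_urologic = -0.10, surgery_orthopedic = 0.00,
         surgery_gynecologic = -0.30, surgery_plastic = -0.20,
         surgery_other = 0.10,
         anesthesia_general = 0.10, anesthesia_neuraxial = -0.10,
         anesthesia_mac = -0.20, anesthesia_regional = -0.10,
         anesthesia_other = 0.00)
  b[design_columns()]
}

make_cont_specs <- function(means, sds) {
  floors <- c(age = 18, bmi = 10)
  lower <- pmax(means - 5 * sds,
                ifelse(names(means) %in% names(floors),
                       floors[names(means)], 0.01))
  data.frame(name = names(means), mean = unname(means), sd = unname(sds),
             lower = unname(lower), upper = unname(means + 5 * sds),
             stringsAsFactors = FALSE)
}

renorm_probs <- function(named_pct, levels_all) {
  p <- named_pct / 100
  s <- sum(p)
  out <- stats::setNames(numeric(length(levels_all)), levels_all)
  if (s >= 1) {
    # Printed percentages exceed 100; treat them as relative weights over
    # mutually exclusive categories and leave nothing for "other".
    out[names(p)] <- p / s
  } else {
    out[names(p)] <- p
    out["other"] <- 1 - s
  }
  out
}

#' Default three-hospital profiles
#'
#' Returns generative profiles for three synthetic institutions, labelled
#' "A", "S" and "E", whose marginal feature distributions (continuous
#' means/SDs, category frequencies, emergency rates) and 30-day mortality
#' prevalences follow the published summary table of a three-hospital
#' perioperative cohort (two large tertiary centers and one mid-size
#' center). Site coefficient vectors are a shared base perturbed per site
#' with sd `tau`, and intercepts are Monte-Carlo calibrated so that
#' simulated prevalence matches each site's target.
#'
#' @param tau heterogeneity sd applied to the shared base coefficients.
#' @param calibrate_n Monte-Carlo sample size for intercept calibration.
#' @return named list of three `hospital_profile` objects (`A`, `S`, `E`).
#' @export
default_profiles <- function(tau = 0.3, calibrate_n = 50000) {
  tbl <- list(
    S = list(
      n = 46956L,
      means = c(age = 55.9, bmi = 24.6, wbc = 6.6, hb = 13.1, plt = 239.8,
                na = 140.2, k = 4.2, bun = 15.5, cr = 1.0, alb = 4.2,
                got = 24.4, gpt = 23.4, glu = 110.8, pt_inr = 1.0,
                aptt = 31.6),
      sds = c(age = 16.1, bmi = 3.9, wbc = 3.0, hb = 1.8, plt = 73.5,
              na = 2.7, k = 0.4, bun = 8.1, cr = 1.1, alb = 0.5,
              got = 36.7, gpt = 32.5, glu = 30.5, pt_inr = 0.1,
              aptt = 4.6),
      sex_p = 0.559, emergency_p = 0.074,
      surgery = c(general = 28.7, otolaryngologic = 9.7, urologic = 10.1,
                  orthopedic = 14.3, gynecologic = 14.5, plastic = 4.0),
      anesthesia = c(general = 76.8, neuraxial = 16.5, mac = 12.3,
                     regional = 0.1),
      deaths = 156L
    ),
    A = list(
      n = 162184L,
      means = c(age = 54.2, bmi = 24.2, wbc = 6.7, hb = 12.8, plt = 247.1,
                na = 139.8, k = 4.3, bun = 14.8, cr = 0.9, alb = 3.8,
                got = 25.0, gpt = 22.7, glu = 113.3, pt_inr = 1.0,
                aptt = 27.0),
      sds = c(age = 15.9, bmi = 3.7, wbc = 2.4, hb = 1.9, plt = 72.7,
              na = 2.4, k = 0.3, bun = 6.8, cr = 0.7, alb = 0.5,
              got = 33.7, gpt = 32.3, glu = 36.9, pt_inr = 0.1,
              aptt = 3.3),
      sex_p = 0.582, emergency_p = 0.055,
      surgery = c(general = 36.4, otolaryngologic = 10.8, urologic = 12.7,
                  orthopedic = 14.7, gynecologic = 19.5, plastic = 1.4),
      anesthesia = c(general = 92.2, neuraxial = 7.0, mac = 0.0,
                     regional = 0.8),
      deaths = 306L
    ),
    E = list(
      n = 131867L,
      means = c(age = 48.5, bmi = 23.8, wbc = 7.5, hb = 13.1, plt = 245.6,
                na = 140.7, k = 4.2, bun = 13.7, cr = 0.9, alb = 4.1,
                got = 26.5, gpt = 25.1, glu = 198.3, pt_inr = 1.0,
                aptt = 26.9),
      sds = c(age = 17.1, bmi = 3.8, wbc = 3.9, hb = 1.9, plt = 72.0,
              na = 3.0, k = 0.4, bun = 6.9, cr = 0.7, alb = 0.6,
              got = 95.0, gpt = 50.9, glu = 243.9, pt_inr = 0.4,
              aptt = 5.4),
      sex_p = 0.601, emergency_p = 0.032,
      surgery = c(general = 30.8, otolaryngologic = 10.8, urologic = 6.9,
                  orthopedic = 17.8, gynecologic = 20.1, plastic = 7.4),
      anesthesia = c(general = 76.0, neuraxial = 8.1, mac = 3.8,
                     regional = 0.4),
      deaths = 316L
    )
  )

  # Mid-size center shows the largest missingness (BMI, anesthesia type,
  # glucose); large centers only sparse lab gaps. All rates MCAR, within
  # the observed 0-7.63% band.
  miss_common <- stats::setNames(rep(0.01, length(sl_labs)), sl_labs)
  miss <- list(
    S = c(bmi = 0.015, miss_common),
    A = c(bmi = 0.010, miss_common),
    E = c(bmi = 0.0763, anesthesia_type = 0.05, glu = 0.04,
          miss_common[setdiff(sl_labs, "glu")])
  )

  base_beta <- default_base_beta()
  out <- list()
  for (sid in c("A", "S", "E")) {
    d <- tbl[[sid]]
    beta <- perturb_coefficients(base_beta, tau,
                                 seed = derive_seed(991, paste0("beta-", sid)))
    prof <- hospital_profile(
      site_id = sid, n_default = d$n,
      cont_specs = make_cont_specs(d$means, d$sds),
      sex_p = d$sex_p,
      surgery_probs = renorm_probs(d$surgery, sl_surgery_levels),
      anesthesia_probs = renorm_probs(d$anesthesia, sl_anesthesia_levels),
      emergency_p = d$emergency_p,
      lab_corr = default_lab_corr(),
      beta = beta,
      target_prevalence = d$deaths / d$n,
      miss_rates = miss[[sid]],
      heterogeneity_tau = tau
    )
    prof$intercept <- calibrate_intercept(
      prof, prof$target_prevalence, n_mc = calibrate_n,
      seed = derive_seed(991, paste0("calib-", sid)))
    out[[sid]] <- prof
  }
  out
}

#' Perturb a coefficient vector with site-level heterogeneity
#'
#' Adds independent zero-mean Gaussian noise of sd `tau` to every
#' coordinate, modelling how predictor effects differ across institutions.
#'
#' @param base_beta numeric coefficient vector.
#' @param tau non-negative perturbation sd; `0` returns `base_beta`
#'   unchanged.
#' @param seed integer seed.
#' @return perturbed vector with the same names.
#' @export
perturb_coefficients <- function(base_beta, tau, seed) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0) {
    stop("tau must be a single non-negative number", call. = FALSE)
  }
  if (tau == 0) return(base_beta)
  base_beta + with_seed(seed, stats::rnorm(length(base_beta), 0, tau))
}

#' Calibrate a profile's intercept to a target outcome prevalence
#'
#' Bisects on the intercept so that the Monte-Carlo mean of
#' `plogis(intercept + beta . x)` over simulated standardized feature
#' vectors matches `target_prevalence` (the mean is monotone increasing in
#' the intercept). When `beta` is identically zero the closed form
#' `qlogis(target_prevalence)` is returned.
#'
#' @param profile a `hospital_profile` (its `intercept` is ignored).
#' @param target_prevalence desired outcome probability in (0, 1).
#' @param n_mc Monte-Carlo sample size.
#' @param seed integer seed for the feature draws.
#' @return calibrated intercept (scalar).
#' @export
calibrate_intercept <- function(profile, target_prevalence,
                                n_mc = 50000, seed = 1L) {
  if (!(target_prevalence > 0 && target_prevalence < 1)) {
    stop("target_prevalence must lie in (0, 1)", call. = FALSE)
  }
  if (all(profile$beta == 0)) return(stats::qlogis(target_prevalence))
  X <- with_seed(seed, sample_encoded_features(profile, n_mc)$X)
  eta <- drop(X %*% profile$beta)
  prev_at <- function(b0) mean(stats::plogis(b0 + eta))
  lo <- -40; hi <- 10
  for (i in seq_len(100)) {
    mid <- (lo + hi) / 2
    if (prev_at(mid) < target_prevalence) lo <- mid else hi <- mid
    if (hi - lo < 1e-10) break
  }
  b0 <- (lo + hi) / 2
  rel <- abs(prev_at(b0) - target_prevalence) / target_prevalence
  if (rel > 0.10) {
    stop("intercept calibration failed to reach the target prevalence; ",
         "profile is likely misspecified", call. = FALSE)
  }
  b0
}

#' Serialize / deserialize a hospital profile as JSON
#'
#' @param profile a `hospital_profile`.
#' @param path file path; `profile_to_json` returns the JSON string
#'   invisibly and writes to `path` when given.
#' @return `profile_from_json` returns a `hospital_profile`.
#' @export
profile_to_json <- function(profile, path = NULL) {
  x <- unclass(profile)
  # named vectors serialize as JSON objects, not bare arrays
  for (f in c("surgery_probs", "anesthesia_probs", "beta", "miss_rates")) {
    x[[f]] <- as.list(x[[f]])
  }
  x$lab_corr <- as.data.frame(x$lab_corr)
  js <- jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' @rdname profile_to_json
#' @param json JSON string (ignored when `path` given).
#' @export
profile_from_json <- function(path = NULL, json = NULL) {
  x <- jsonlite::fromJSON(if (!is.null(path)) path else json)
  lc <- as.matrix(x$lab_corr)
  dimnames(lc) <- list(sl_labs, sl_labs)
  hospital_profile(
    site_id = x$site_id, n_default = x$n_default,
    cont_specs = as.data.frame(x$cont_specs),
    sex_p = x$sex_p,
    surgery_probs = unlist(x$surgery_probs),
    anesthesia_probs = unlist(x$anesthesia_probs),
    emergency_p = x$emergency_p, lab_corr = lc,
    beta = unlist(x$beta), intercept = x$intercept,
    target_prevalence = x$target_prevalence,
    miss_rates = unlist(x$miss_rates),
    heterogeneity_tau = x$heterogeneity_tau
  )
}
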