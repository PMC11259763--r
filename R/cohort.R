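# Cohort simulation: feature draws, outcome labels, MCAR missingness, CSV IO.

# Draw n patients' features from a profile. Consumes the active RNG stream
# (callers wrap in with_seed). Returns the raw-scale table (without outcome)
# and the standardized/encoded design matrix used by the generative
# logistic model. Continuous draws are clipped at the spec'd truncation
# bounds (mean +/- 5 sd, physiologic floors).
sample_encoded_features <- function(profile, n) {
  cs <- profile$cont_specs
  rownames(cs) <- cs$name

  # age / BMI: independent truncated (clipped) normals
  demo <- sapply(c("age", "bmi"), function(f) {
    pmin(pmax(stats::rnorm(n, cs[f, "mean"], cs[f, "sd"]),
              cs[f, "lower"]), cs[f, "upper"])
  })

  # labs: multivariate normal with the panel-block correlation, then clip
  mu <- cs[sl_labs, "mean"]
  sd <- cs[sl_labs, "sd"]
  sigma <- diag(sd) %*% profile$lab_corr %*% diag(sd)
  labs <- rmvn_chol(n, mu, sigma)
  colnames(labs) <- sl_labs
  for (f in sl_labs) {
    labs[, f] <- pmin(pmax(labs[, f], cs[f, "lower"]), cs[f, "upper"])
  }

  sex <- stats::rbinom(n, 1L, profile$sex_p)
  emergency <- stats::rbinom(n, 1L, profile$emergency_p)
  surgery <- sample(sl_surgery_levels, n, replace = TRUE,
                    prob = profile$surgery_probs[sl_surgery_levels])
  anesthesia <- sample(sl_anesthesia_levels, n, replace = TRUE,
                       prob = profile$anesthesia_probs[sl_anesthesia_levels])

  raw <- data.frame(age = demo[, "age"], sex = ifelse(sex == 1, "F", "M"),
                    bmi = demo[, "bmi"], labs,
                    surgery_type = surgery, anesthesia_type = anesthesia,
                    emergency = emergency, stringsAsFactors = FALSE,
                    check.names = FALSE)

  # generative encoding: z-score continuous by profile parameters,
  # binaries and one-hot indicators as 0/1
  X <- matrix(0, n, length(design_columns()),
              dimnames = list(NULL, design_columns()))
  for (f in sl_continuous) {
    v <- if (f %in% c("age", "bmi")) demo[, f] else labs[, f]
    X[, f] <- (v - cs[f, "mean"]) / cs[f, "sd"]
  }
  X[, "sex"] <- sex
  X[, "emergency"] <- emergency
  for (lv in sl_surgery_levels) {
    X[, paste0("surgery_", lv)] <- as.numeric(surgery == lv)
  }
  for (lv in sl_anesthesia_levels) {
    X[, paste0("anesthesia_", lv)] <- as.numeric(anesthesia == lv)
  }
  list(raw = raw, X = X)
}

#' Sample a synthetic cohort from a hospital profile
#'
#' Draws `n` patients: laboratory panels from a truncated multivariate
#' normal with the profile's block correlation, demographics and categories
#' from their marginal distributions, and a binary 30-day mortality outcome
#' from the site's logistic model applied to the standardized encoding.
#' Deterministic given `seed`; the returned table has no missing cells
#' (apply [inject_missingness()] afterwards).
#'
#' @param profile a `hospital_profile` with a calibrated intercept.
#' @param n number of patients (>= 1).
#' @param seed integer seed.
#' @return data.frame in the fixed cohort column order (see
#'   [cohort_columns()]), with `outcome` in \{0,1\} and `site` set to the
#'   profile's `site_id`.
#' @export
sample_cohort <- function(profile, n, seed) {
  stopifnot(n >= 1)
  validate_profile(profile)
  if (is.na(profile$intercept)) {
    stop("profile intercept is NA; calibrate it first", call. = FALSE)
  }
  with_seed(seed, {
    feats <- sample_encoded_features(profile, n)
    p <- stats::plogis(profile$intercept + drop(feats$X %*% profile$beta))
    outcome <- stats::rbinom(n, 1L, p)
    tab <- feats$raw
    tab$outcome <- outcome
    tab$site <- profile$site_id
    tab[, sl_cohort_columns]
  })
}

#' Fixed cohort column order
#' @return character vector of the 21 cohort columns.
#' @export
cohort_columns <- function() sl_cohort_columns

#' Inject missing-completely-at-random cells into a cohort
#'
#' Each eligible cell is independently set to `NA` with its feature's rate.
#' `outcome` and `site` are never eligible.
#'
#' @param table cohort data.frame.
#' @param miss_rates named per-feature probabilities in [0, 1]; features
#'   absent from the vector keep rate 0.
#' @param seed integer seed.
#' @return the table with `NA` cells injected.
#' @export
inject_missingness <- function(table, miss_rates, seed) {
  bad <- intersect(names(miss_rates), c("outcome", "site"))
  if (length(bad)) stop("outcome/site are not eligible for missingness",
                        call. = FALSE)
  if (any(miss_rates < 0 | miss_rates > 1)) {
    stop("miss_rates must lie in [0, 1]", call. = FALSE)
  }
  unknown <- setdiff(names(miss_rates), sl_feature_columns)
  if (length(unknown)) stop("unknown features in miss_rates: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  n <- nrow(table)
  with_seed(seed, {
    for (f in names(miss_rates)) {
      r <- miss_rates[[f]]
      if (r > 0) table[[f]][stats::runif(n) < r] <- NA
    }
    table
  })
}

#' Read / write cohorts in the package CSV dialect
#'
#' One row per patient, header row, UTF-8, empty string for missing cells,
#' fixed column order.
#'
#' @param table cohort data.frame.
#' @param path file path.
#' @export
write_cohort_csv <- function(table, path) {
  utils::write.csv(table[, sl_cohort_columns], path, row.names = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @return `read_cohort_csv` returns the cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  cls <- stats::setNames(rep("numeric", length(sl_cohort_columns)),
                         sl_cohort_columns)
  cls[c("sex", "surgery_type", "anesthesia_type", "site")] <- "character"
  cls[c("emergency", "outcome")] <- "integer"
  tab <- utils::read.csv(path, colClasses = cls, na.strings = "",
                         fileEncoding = "UTF-8")
  if (!identical(names(tab), sl_cohort_columns)) {
    stop("CSV columns do not match the cohort schema", call. = FALSE)
  }
  if (anyNA(tab$outcome)) stop("outcome must be non-missing", call. = FALSE)
  tab
}
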