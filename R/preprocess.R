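# Preprocessing: per-site median imputation, per-site standardization
# (performed at each hospital before any encryption), one-hot encoding,
# 6:2:2 splitting, missingness diagnostics.

is_categorical_col <- function(f) {
  f %in% c("sex", "surgery_type", "anesthesia_type", "emergency")
}

#' Impute missing cells with per-site medians / modes
#'
#' Continuous cells get the per-site median of observed values; categorical
#' cells the per-site modal category. The output contains no missing cells.
#'
#' @param table cohort data.frame (possibly with `NA` cells).
#' @return imputed cohort data.frame.
#' @export
impute_median <- function(table) {
  for (s in unique(table$site)) {
    idx <- which(table$site == s)
    for (f in sl_feature_columns) {
      v <- table[[f]][idx]
      if (!anyNA(v)) next
      obs <- v[!is.na(v)]
      if (length(obs) == 0L) {
        stop(sprintf("feature '%s' fully missing at site '%s'", f, s),
             call. = FALSE)
      }
      fill <- if (is_categorical_col(f)) {
        tt <- table(obs)
        names(tt)[which.max(tt)]  # ties: first level in table order
      } else {
        stats::median(obs)
      }
      if (is.numeric(v)) fill <- as.numeric(fill)
      v[is.na(v)] <- fill
      table[[f]][idx] <- v
    }
  }
  table
}

#' Standardize continuous features within each site
#'
#' Each continuous value x at site s becomes (x - mean_s) / sd_s. In
#' training mode (`params = NULL`) the per-site means/sds are computed from
#' the observed data and returned; in scoring mode the supplied parameters
#' are reused verbatim (never recomputed), which is the train/test leakage
#' guard.
#'
#' @param table imputed cohort data.frame.
#' @param params optional `standardization_params` from a previous call.
#' @return list with elements `table` (standardized) and `params`.
#' @export
standardize_per_site <- function(table, params = NULL) {
  compute <- is.null(params)
  if (compute) {
    params <- list()
    for (s in unique(table$site)) {
      idx <- table$site == s
      params[[s]] <- lapply(stats::setNames(nm = sl_continuous), function(f) {
        m <- mean(table[[f]][idx]); sd <- stats::sd(table[[f]][idx])
        if (!is.finite(sd) || sd <= 0) {
          stop(sprintf("zero within-site sd for '%s' at site '%s'", f, s),
               call. = FALSE)
        }
        c(mean = m, sd = sd)
      })
    }
    class(params) <- "standardization_params"
  }
  for (s in unique(table$site)) {
    if (is.null(params[[s]])) {
      stop("no standardization parameters for site ", s, call. = FALSE)
    }
    idx <- table$site == s
    for (f in sl_continuous) {
      pr <- params[[s]][[f]]
      table[[f]][idx] <- (table[[f]][idx] - pr[["mean"]]) / pr[["sd"]]
    }
  }
  list(table = table, params = params)
}

#' Serialize standardization parameters to JSON
#' @param params a `standardization_params` object.
#' @param path optional file path.
#' @export
standardization_params_to_json <- function(params, path = NULL) {
  js <- jsonlite::toJSON(unclass(params), digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' One-hot encode a (imputed, standardized) cohort into a design matrix
#'
#' Categorical variables expand to full indicator groups (no reference
#' level dropped; the ridge penalty absorbs the redundancy), binary
#' features become single 0/1 columns, continuous features pass through.
#'
#' @param table imputed/standardized cohort data.frame.
#' @return `design_matrix`: list with `X` (n x 29 numeric matrix in
#'   [design_columns()] order), `y` outcome vector, `site` vector.
#' @export
one_hot_encode <- function(table) {
  bad_s <- setdiff(unique(table$surgery_type), sl_surgery_levels)
  bad_a <- setdiff(unique(table$anesthesia_type), sl_anesthesia_levels)
  bad_x <- setdiff(unique(table$sex), c("F", "M"))
  if (length(c(bad_s, bad_a, bad_x))) {
    stop("unseen category label(s): ",
         paste(c(bad_s, bad_a, bad_x), collapse = ", "), call. = FALSE)
  }
  n <- nrow(table)
  X <- matrix(0, n, length(design_columns()),
              dimnames = list(NULL, design_columns()))
  for (f in sl_continuous) X[, f] <- table[[f]]
  X[, "sex"] <- as.numeric(table$sex == "F")
  X[, "emergency"] <- as.numeric(table$emergency)
  for (lv in sl_surgery_levels) {
    X[, paste0("surgery_", lv)] <- as.numeric(table$surgery_type == lv)
  }
  for (lv in sl_anesthesia_levels) {
    X[, paste0("anesthesia_", lv)] <- as.numeric(table$anesthesia_type == lv)
  }
  if (anyNA(X)) stop("design matrix contains missing values; impute first",
                     call. = FALSE)
  structure(list(X = X, y = as.integer(table$outcome),
                 site = table$site, columns = design_columns()),
            class = "design_matrix")
}

#' Split n rows 6:2:2 into train / validation / test
#'
#' Validation and test sizes are `round(0.2 n)` (half-up), training is the
#' remainder; assignment is a seeded uniform shuffle, unstratified.
#'
#' @param n number of rows (>= 5).
#' @param seed integer seed.
#' @return list of disjoint index vectors `train`, `val`, `test` covering
#'   `1:n`.
#' @export
split_622 <- function(n, seed) {
  stopifnot(n >= 5)
  n_val <- floor(0.2 * n + 0.5)
  n_test <- n_val
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n - n_val - n_test)]),
       val = sort(perm[(n - n_val - n_test + 1):(n - n_test)]),
       test = sort(perm[(n - n_test + 1):n]))
}

#' Missingness diagnostics
#'
#' Per-feature missing rates, pairwise Pearson correlation of the
#' missingness indicator vectors, pairwise correlation of observed
#' continuous values, and the pairs whose absolute correlation reaches the
#' 0.7 flagging threshold (the signature of collectively-ordered panels).
#'
#' @param table cohort data.frame (with `NA` cells).
#' @param threshold absolute-correlation flag threshold (default 0.7).
#' @return list with `miss_rates`, `miss_corr`, `value_corr`,
#'   `flagged_missing` and `flagged_values` (data.frames of feature pairs).
#' @export
missingness_diagnostics <- function(table, threshold = 0.7) {
  feats <- sl_feature_columns
  ind <- sapply(feats, function(f) as.numeric(is.na(table[[f]])))
  miss_rates <- colMeans(ind)
  miss_corr <- suppressWarnings(stats::cor(ind))
  miss_corr[!is.finite(miss_corr)] <- NA_real_
  vals <- as.matrix(table[, sl_continuous])
  value_corr <- suppressWarnings(
    stats::cor(vals, use = "pairwise.complete.obs"))
  flag_pairs <- function(m) {
    out <- data.frame(a = character(), b = character(), r = numeric())
    nm <- colnames(m)
    for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
      r <- m[i, j]
      if (!is.na(r) && abs(r) >= threshold) {
        out <- rbind(out, data.frame(a = nm[i], b = nm[j], r = r))
      }
    }
    out
  }
  list(miss_rates = miss_rates, miss_corr = miss_corr,
       value_corr = value_corr,
       flagged_missing = flag_pairs(miss_corr),
       flagged_values = flag_pairs(value_corr))
}

#' Full preprocessing pipeline for one cohort
#'
#' impute -> standardize (per site) -> encode, optionally reusing
#' standardization parameters (scoring mode).
#'
#' @param table cohort data.frame.
#' @param params optional `standardization_params`.
#' @return list `design` (a `design_matrix`) and `params`.
#' @export
prepare_design <- function(table, params = NULL) {
  tab <- impute_median(table)
  st <- standardize_per_site(tab, params)
  list(design = one_hot_encode(st$table), params = st$params)
}
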