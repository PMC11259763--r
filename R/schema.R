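# Fixed cohort schema: 19 predictors (3 demographic, 13 preoperative labs,
# surgery type, anesthesia type, emergency flag) plus outcome and site label.

sl_continuous <- c("age", "bmi",
                   "wbc", "hb", "plt", "na", "k", "bun", "cr",
                   "alb", "got", "gpt", "glu", "pt_inr", "aptt")

sl_labs <- c("wbc", "hb", "plt", "na", "k", "bun", "cr",
             "alb", "got", "gpt", "glu", "pt_inr", "aptt")

# Panels drawn together in routine preoperative workups; within-panel lab
# values are strongly correlated (|r| >= 0.7 block structure).
sl_lab_blocks <- list(
  cbc   = c("wbc", "hb", "plt"),
  chem  = c("na", "k", "bun", "cr"),
  liver = c("alb", "got", "gpt"),
  coag  = c("pt_inr", "aptt"),
  gluc  = "glu"
)

sl_surgery_levels <- c("general", "otolaryngologic", "urologic",
                       "orthopedic", "gynecologic", "plastic", "other")

sl_anesthesia_levels <- c("general", "neuraxial", "mac", "regional", "other")

sl_binary <- c("sex", "emergency")  # sex coded 1 = female

sl_feature_columns <- c(sl_continuous, "sex", "surgery_type",
                        "anesthesia_type", "emergency")

sl_cohort_columns <- c("age", "sex", "bmi", sl_labs,
                       "surgery_type", "anesthesia_type", "emergency",
                       "outcome", "site")

#' Encoded design-matrix column names
#'
#' Order of columns in a model-ready design matrix: 15 standardized
#' continuous features, two 0/1 binary features, then full one-hot groups
#' for surgery type (7 levels) and anesthesia type (5 levels); p = 29.
#' No reference level is dropped; the ridge penalty absorbs the redundancy.
#'
#' @return character vector of length 29.
#' @export
design_columns <- function() {
  c(sl_continuous, "sex", "emergency",
    paste0("surgery_", sl_surgery_levels),
    paste0("anesthesia_", sl_anesthesia_levels))
}
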