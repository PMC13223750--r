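## fixtures built in code at test time

# 10 samples x 5 metabolites with constructed missingness:
#   M1 fully observed, M2 8/10 observed (inclusive boundary),
#   M3 7/10 (dropped at 0.8), M4 9/10, M5 fully observed constant-ish
toy_metabolites <- function() {
  m <- matrix(rep(c(2, 4, 8, 1, 5, 3, 6, 7, 9, 10), 5), nrow = 10,
              dimnames = list(paste0("S", 1:10), paste0("M", 1:5)))
  m[, 2] <- c(2, 4, NA, 1, 5, 3, 6, NA, 9, 10)
  m[, 3] <- c(2, NA, NA, 1, 5, NA, 6, 7, 9, 10)
  m[, 4] <- c(2, 4, 8, NA, 5, 3, 6, 7, 9, 10)
  m
}

# 3-sample KP concentration fixture with hand-computable ratios
toy_kp_concentrations <- function() {
  mets <- c("Trp", "Kyn", "KA", "Anth", "3OHKyn", "Xanth", "3OHAnth",
            "PA", "QA")
  m <- matrix(1, nrow = 3, ncol = length(mets),
              dimnames = list(paste0("S", 1:3), mets))
  m[2, ] <- c(4, 2, 1, 1, 1, 1, 0.5, 3, 1.5)   # hand-worked row
  m[3, "Kyn"] <- NA                              # missing component
  m
}

# small cohort with fully observed activity for direct response planting
small_cohort <- function(n_patients = 50, weeks = c(0, 2, 6, 14),
                         seed = 1, ...) {
  cfg <- synthetic_config(n_patients = n_patients, weeks = weeks,
                          frac_activity_missing = 0, seed = seed, ...)
  generate_cohort(cfg)
}

# plant a longitudinal response on a cohort: slope on standardized
# activity + random patient intercept + residual noise
plant_response <- function(cohort, slope = 0, icpt_sd = 1, resid_sd = 1,
                           group_delta = 0) {
  act <- standardize_activity(cohort)$activity_std
  pats <- unique(cohort$patient_id)
  u <- rnorm(length(pats), 0, icpt_sd)[match(cohort$patient_id, pats)]
  delta <- if (group_delta != 0) group_delta * cohort$remitter else 0
  slope * act + u + delta + rnorm(nrow(cohort), 0, resid_sd)
}
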