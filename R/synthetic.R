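#' Configuration for the synthetic longitudinal IBD cohort generator
#'
#' Bundles and validates all knobs of the generator. Defaults emulate the
#' structure of a longitudinal advanced-therapy IBD cohort: two diagnoses
#' (UC scored on the total Mayo scale 0-12, CD on the Harvey-Bradshaw Index
#' 0-16), visits at 0/2/6/14/52 weeks, a logarithmic decline of disease
#' activity in remitters, serum KP metabolites coupled to activity (Kyn:Trp
#' rising, QA accumulating when QPRT is suppressed), left-censoring of
#' below-LOD concentrations, and mucosal expression in which IDO1 increases
#' and QPRT decreases with activity.
#'
#' @param n_patients number of patients (>= 2).
#' @param frac_remitters fraction of patients whose activity declines
#'   logarithmically to remission.
#' @param frac_uc fraction with ulcerative colitis (rest Crohn's disease).
#' @param weeks strictly increasing visit weeks containing 0.
#' @param beta_ido1 planted slope of log-IDO1 TPM per SD of standardized
#'   activity (> 0 for inflammation-induced IDO1).
#' @param beta_qprt planted slope of log-QPRT TPM per SD of standardized
#'   activity (<= 0 for suppression).
#' @param qa_coupling strength linking QA accumulation to
#'   activity * |beta_qprt|; the planted log-QA slope is
#'   `qa_coupling * abs(beta_qprt)`.
#' @param noise_sd_expr lognormal residual sd of expression.
#' @param noise_sd_met lognormal residual sd of metabolite concentrations.
#' @param noise_sd_act additive sd of visit-level activity-score noise.
#' @param lod_quantile fraction in `[0,1)`: per metabolite, concentrations
#'   below this quantile of the marginal distribution are censored
#'   (platform-wide limit of detection semantics).
#' @param frac_activity_missing fraction of non-baseline visits whose
#'   activity score is unobserved (to exercise log-decline imputation).
#' @param seed integer; a fixed seed gives byte-identical output.
#' @return a `synthetic_config` list.
#' @export
#' @examples
#' cfg <- synthetic_config(n_patients = 10, seed = 1)
#' cohort <- generate_cohort(cfg)
synthetic_config <- function(n_patients = 60,
                             frac_remitters = 0.5,
                             frac_uc = 0.5,
                             weeks = c(0, 2, 6, 14, 52),
                             beta_ido1 = 0.15,
                             beta_qprt = -0.15,
                             qa_coupling = 2,
                             noise_sd_expr = 0.3,
                             noise_sd_met = 0.25,
                             noise_sd_act = 0.6,
                             lod_quantile = 0.03,
                             frac_activity_missing = 0.1,
                             seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients < 2 || n_patients != round(n_patients))
    stop_field("n_patients", "must be an integer >= 2")
  check_fraction(frac_remitters, "frac_remitters")
  check_fraction(frac_uc, "frac_uc")
  check_fraction(frac_activity_missing, "frac_activity_missing")
  check_fraction(lod_quantile, "lod_quantile", allow_one = FALSE)
  if (!is.numeric(weeks) || length(weeks) < 2L || anyNA(weeks) ||
      any(diff(weeks) <= 0) || weeks[1] != 0)
    stop_field("weeks", "must be strictly increasing and start at week 0")
  check_number(beta_ido1, "beta_ido1")
  check_number(beta_qprt, "beta_qprt")
  if (beta_qprt > 0)
    stop_field("beta_qprt", "must be <= 0 (QPRT suppression)")
  check_number(qa_coupling, "qa_coupling")
  for (f in c("noise_sd_expr", "noise_sd_met", "noise_sd_act")) {
    v <- get(f)
    check_number(v, f)
    if (v < 0) stop_field(f, "must be >= 0")
  }
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop_field("seed", "must be a single integer")
  structure(list(
    n_patients = as.integer(n_patients), frac_remitters = frac_remitters,
    frac_uc = frac_uc, weeks = as.numeric(weeks), beta_ido1 = beta_ido1,
    beta_qprt = beta_qprt, qa_coupling = qa_coupling,
    noise_sd_expr = noise_sd_expr, noise_sd_met = noise_sd_met,
    noise_sd_act = noise_sd_act, lod_quantile = lod_quantile,
    frac_activity_missing = frac_activity_missing,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

activity_scale_max <- function(diagnosis) ifelse(diagnosis == "UC", 12, 16)

#' Generate a synthetic longitudinal cohort table
#'
#' One row per patient-visit. Remitters follow
#' `activity(t) = a_i - b_i * log(1 + week)` with `b_i > 0`, clipped to the
#' scale range (total Mayo 0-12 for UC, HBI 0-16 for CD); non-remitters
#' have `b_i = 0`, i.e. fluctuate around their baseline. A fraction of
#' non-baseline activity scores is masked unobserved
#' (`observed_activity = FALSE`, `activity = NA`) to exercise
#' [impute_activity_log_decline()]; the latent score used to couple
#' metabolome/expression generation is kept in `activity_true`.
#'
#' @param config a [synthetic_config()].
#' @return a `data.frame` with columns `sample_id`, `patient_id`,
#'   `diagnosis` (UC/CD), `sex` (0/1), `age`, `bmi`, `week`, `activity`,
#'   `activity_true`, `observed_activity`, `remitter`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be created by synthetic_config()", call. = FALSE)
  with_seed(config$seed, {
    n <- config$n_patients
    pid <- sprintf("P%03d", seq_len(n))
    n_uc <- round(config$frac_uc * n)
    diagnosis <- sample(c(rep("UC", n_uc), rep("CD", n - n_uc)))
    n_rem <- round(config$frac_remitters * n)
    remitter <- sample(c(rep(TRUE, n_rem), rep(FALSE, n - n_rem)))
    sex <- rbinom(n, 1L, 0.5)
    age <- pmin(pmax(round(rnorm(n, 38, 12)), 18), 80)
    bmi <- round(pmin(pmax(rnorm(n, 25, 4), 16), 45), 1)
    smax <- activity_scale_max(diagnosis)
    # active disease at inclusion: upper half of each scale
    a0 <- runif(n, 0.5 * smax, 0.9 * smax)
    wmax <- max(config$weeks)
    # remitters decline towards a residual score of 0..2 by the last visit
    b <- ifelse(remitter, (a0 - runif(n, 0, 2)) / log(1 + wmax), 0)

    k <- length(config$weeks)
    idx <- rep(seq_len(n), each = k)
    week <- rep(config$weeks, times = n)
    mu <- a0[idx] - b[idx] * log(1 + week)
    act <- mu + rnorm(n * k, 0, config$noise_sd_act)
    act <- pmin(pmax(act, 0), smax[idx])

    observed <- rep(TRUE, n * k)
    nonbase <- which(week > 0)
    n_miss <- round(config$frac_activity_missing * length(nonbase))
    if (n_miss > 0) observed[sample(nonbase, n_miss)] <- FALSE

    data.frame(
      sample_id = paste0(pid[idx], "_W", week),
      patient_id = pid[idx],
      diagnosis = diagnosis[idx],
      sex = sex[idx],
      age = age[idx],
      bmi = bmi[idx],
      week = week,
      activity = ifelse(observed, act, NA_real_),
      activity_true = act,
      observed_activity = observed,
      remitter = remitter[idx],
      stringsAsFactors = FALSE
    )
  })
}

#' Standardize disease-activity scores across UC and CD
#'
#' HBI (CD) and total Mayo (UC) live on different scales; before pooling
#' both diagnoses in one mixed model the score is z-scored within
#' diagnosis. Adds an `activity_std` column (from `activity`, after any
#' imputation) and, when present, `activity_true_std`.
#'
#' @param cohort a cohort `data.frame` (see [generate_cohort()]).
#' @return the cohort with standardized activity columns appended.
#' @export
standardize_activity <- function(cohort) {
  zscore_by <- function(x, g) {
    for (lev in unique(g)) {
      i <- g == lev
      mu <- mean(x[i], na.rm = TRUE)
      s <- sd(x[i], na.rm = TRUE)
      x[i] <- if (is.na(s) || s == 0) 0 else (x[i] - mu) / s
    }
    x
  }
  cohort$activity_std <- zscore_by(cohort$activity, cohort$diagnosis)
  if ("activity_true" %in% names(cohort))
    cohort$activity_true_std <-
      zscore_by(cohort$activity_true, cohort$diagnosis)
  cohort
}

# serum KP panel: baseline concentration (uM) and planted log-slope per SD
# of standardized activity. Trp falls and Kyn rises with inflammation
# (Kyn:Trp up); PA is deliberately uncoupled; QA's slope is supplied at
# generation time as qa_coupling * |beta_qprt|.
kp_metabolite_profiles <- function() {
  data.frame(
    metabolite = c("Trp", "Kyn", "KA", "Anth", "3OHKyn", "Xanth",
                   "3OHAnth", "PA", "QA", "5OHTrp", "Sero", "NAM"),
    base = c(60, 2, 0.05, 0.02, 0.04, 0.02, 0.01, 0.08, 0.5,
             0.01, 0.5, 0.3),
    slope = c(-0.10, 0.15, 0.05, 0.05, 0.08, 0.03, 0.05, 0, NA,
              0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# mucosal KP gene panel: baseline TPM; only IDO1/QPRT get planted slopes
kp_gene_profiles <- function() {
  data.frame(
    gene = c("IDO1", "IDO2", "TDO2", "KYAT1", "AADAT", "KYNU", "KMO",
             "HAAO", "ACMSD", "QPRT", "NMNAT1", "NADSYN1", "TPH1",
             "TPH2", "DDC", "NAMPT"),
    base = c(30, 0.5, 5, 20, 8, 15, 6, 10, 2, 40, 12, 9, 1, 0.2, 4, 50),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic serum metabolome coupled to disease activity
#'
#' Concentrations are lognormal around a pathway-coupled log-mean: per
#' metabolite, `log(conc) = log(base) + slope * activity_std + u_patient +
#' eps`, with Trp declining and Kyn (hence Kyn:Trp) rising with activity,
#' and the planted log-QA slope equal to
#' `qa_coupling * abs(beta_qprt)` (QA accumulates when QPRT is
#' suppressed). Values below the per-metabolite `lod_quantile` of the
#' marginal distribution are masked missing (left-censoring).
#'
#' @param cohort a cohort `data.frame` from [generate_cohort()].
#' @param config the [synthetic_config()] used to build the cohort.
#' @return samples x metabolites numeric matrix (uM) with `NA` for
#'   censored cells.
#' @export
generate_metabolome <- function(cohort, config) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  prof <- kp_metabolite_profiles()
  prof$slope[prof$metabolite == "QA"] <-
    config$qa_coupling * abs(config$beta_qprt)
  act <- standardize_activity(cohort)$activity_true_std
  with_seed(config$seed + 1L, {
    n <- nrow(cohort)
    upat <- rnorm(length(unique(cohort$patient_id)), 0, 0.15)
    names(upat) <- unique(cohort$patient_id)
    m <- sapply(seq_len(nrow(prof)), function(j) {
      mu <- log(prof$base[j]) + prof$slope[j] * act +
        upat[cohort$patient_id]
      exp(mu + rnorm(n, 0, config$noise_sd_met))
    })
    dimnames(m) <- list(cohort$sample_id, prof$metabolite)
    if (config$lod_quantile > 0) {
      for (j in seq_len(ncol(m))) {
        lod <- quantile(m[, j], config$lod_quantile, names = FALSE)
        m[m[, j] < lod, j] <- NA_real_
      }
    }
    m
  })
}

#' Generate synthetic mucosal expression with planted IDO1/QPRT effects
#'
#' Per gene, `log(TPM) = log(base) + beta_g * activity_std + u_patient +
#' eps`: `beta_g` is `beta_ido1` for IDO1 (rising with inflammation),
#' `beta_qprt` for QPRT (suppressed), and 0 for every other KP gene.
#'
#' @inheritParams generate_metabolome
#' @return samples x genes numeric TPM matrix (all values > 0).
#' @export
generate_expression <- function(cohort, config) {
  if (nrow(cohort) == 0L) stop("cohort is empty", call. = FALSE)
  prof <- kp_gene_profiles()
  beta <- setNames(numeric(nrow(prof)), prof$gene)
  beta["IDO1"] <- config$beta_ido1
  beta["QPRT"] <- config$beta_qprt
  act <- standardize_activity(cohort)$activity_true_std
  with_seed(config$seed + 2L, {
    n <- nrow(cohort)
    upat <- rnorm(length(unique(cohort$patient_id)), 0, 0.15)
    names(upat) <- unique(cohort$patient_id)
    m <- sapply(seq_len(nrow(prof)), function(j) {
      mu <- log(prof$base[j]) + beta[prof$gene[j]] * act +
        upat[cohort$patient_id]
      exp(mu + rnorm(n, 0, config$noise_sd_expr))
    })
    dimnames(m) <- list(cohort$sample_id, prof$gene)
    m
  })
}
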