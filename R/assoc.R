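#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: with `m` p-values sorted ascending, the adjusted value of
#' the i-th is `min_{j >= i} p_(j) * m / j`, capped at 1, returned in the
#' input order. `NA` entries are ignored (and returned as `NA`) without
#' counting towards `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  out <- rep(NA_real_, length(p))
  x <- p[ok]
  m <- length(x)
  if (m == 0L) return(out)
  o <- order(x)
  adj <- rev(cummin(rev(x[o] * m / seq_len(m))))
  adj <- pmin(adj, 1)
  res <- numeric(m)
  res[o] <- adj
  out[ok] <- res
  out
}

#' Impute missing disease-activity scores by logarithmic decline
#'
#' Clinical activity under effective therapy declines roughly
#' logarithmically, so per patient the observed visits are fit by least
#' squares to `score = a + b * log(1 + week)` and unobserved visits are
#' filled with the fitted value, clipped to the scale range (total Mayo
#' 0-12 for UC, HBI 0-16 for CD). Patients with a single observed visit
#' carry that value forward/backward. Observed scores are never altered.
#'
#' @param cohort cohort `data.frame` with `patient_id`, `week`,
#'   `diagnosis` and `activity` (`NA` = unobserved).
#' @return the cohort with `activity` completed and `observed_activity`
#'   marking which values were measured.
#' @export
impute_activity_log_decline <- function(cohort) {
  obs <- !is.na(cohort$activity)
  none <- tapply(obs, cohort$patient_id, sum) == 0L
  if (any(none))
    stop("patient(s) with no observed activity score: ",
         paste(names(none)[none], collapse = ", "), call. = FALSE)
  cohort$observed_activity <- obs
  smax <- activity_scale_max(cohort$diagnosis)
  for (pid in unique(cohort$patient_id)) {
    i <- which(cohort$patient_id == pid)
    oi <- i[obs[i]]
    mi <- i[!obs[i]]
    if (length(mi) == 0L) next
    if (length(oi) == 1L) {
      fitted <- rep(cohort$activity[oi], length(mi))
    } else {
      fit <- lm(activity ~ log1p(week), data = cohort[oi, ])
      fitted <- predict(fit, newdata = cohort[mi, , drop = FALSE])
    }
    cohort$activity[mi] <- pmin(pmax(fitted, 0), smax[mi])
  }
  cohort
}

lmm_control <- function() {
  lme4::lmerControl(calc.derivs = FALSE,
                    check.conv.grad = "ignore",
                    check.conv.singular = "ignore",
                    check.conv.hess = "ignore")
}

# fit one random-intercept model, returning the fixed-effect table or NULL
fit_one_lmm <- function(formula, data) {
  fit <- tryCatch(
    suppressWarnings(suppressMessages(
      lme4::lmer(formula, data = data, REML = TRUE,
                 control = lmm_control()))),
    error = function(e) NULL)
  fit
}

lmm_fixef_table <- function(fit) {
  co <- summary(fit)$coefficients
  data.frame(term = rownames(co), estimate = co[, "Estimate"],
             se = co[, "Std. Error"], t = co[, "t value"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mixed-model association of responses with disease activity
#'
#' For every response column, fits the longitudinal random-intercept
#' model `y ~ sex * predictor (+ covariates) + (1 | patient)` by REML and
#' reports estimate, SE, t and a Wald-normal p per fixed-effect term,
#' with Benjamini-Hochberg adjustment across responses within each term
#' family. The predictor is the pooled, per-diagnosis standardized
#' activity score (`predictor = "activity"`; run
#' [impute_activity_log_decline()] first if scores are missing) or any
#' aligned numeric vector, e.g. the serum Kyn:Trp ratio. `diagnosis` is
#' included as covariate only when UC and CD are pooled. Non-convergence
#' yields a `NaN`-flagged row, never an aborted batch.
#'
#' @param responses samples x responses numeric matrix, rows aligned to
#'   `cohort` (matching `sample_id` row names).
#' @param cohort cohort `data.frame`.
#' @param predictor `"activity"` or a numeric vector aligned to rows.
#' @param predictor_name label used in the output `term` column.
#' @param covariates any of `"age"`, `"bmi"`, `"diagnosis"`.
#' @return `data.frame` with columns `response`, `term`, `estimate`,
#'   `se`, `t`, `p`, `p_adj`, `n_obs`, `converged`.
#' @export
fit_activity_lmm <- function(responses, cohort, predictor = "activity",
                             predictor_name = NULL,
                             covariates = c("age", "bmi", "diagnosis")) {
  if (is.vector(responses)) responses <- cbind(response = responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("response_", seq_len(ncol(responses)))
  if (nrow(responses) != nrow(cohort))
    stop("responses and cohort have different numbers of rows",
         call. = FALSE)
  if (!is.null(rownames(responses)) && "sample_id" %in% names(cohort) &&
      !identical(rownames(responses), cohort$sample_id))
    stop("response row names do not match cohort sample_id", call. = FALSE)
  if (identical(predictor, "activity")) {
    if (anyNA(cohort$activity))
      stop("cohort has missing activity scores; run ",
           "impute_activity_log_decline() first", call. = FALSE)
    pred <- standardize_activity(cohort)$activity_std
    if (is.null(predictor_name)) predictor_name <- "activity"
  } else {
    if (!is.numeric(predictor) || length(predictor) != nrow(cohort))
      stop("predictor must be 'activity' or a numeric vector aligned ",
           "to the cohort", call. = FALSE)
    pred <- predictor
    if (is.null(predictor_name)) predictor_name <- "predictor"
  }
  covariates <- if (length(covariates))
    match.arg(covariates, c("age", "bmi", "diagnosis"), several.ok = TRUE)
  else character(0)
  if (length(unique(cohort$diagnosis)) < 2L)
    covariates <- setdiff(covariates, "diagnosis")
  n_pat_multi <- sum(table(cohort$patient_id) >= 2L)
  if (length(unique(cohort$patient_id)) < 2L || n_pat_multi < 2L)
    stop("need >= 2 patients with >= 2 visits", call. = FALSE)

  # center sex so the predictor main effect is the sex-averaged slope
  # (with treatment coding it would be the slope in the sex=0 stratum)
  base <- data.frame(sex = cohort$sex - mean(cohort$sex), pred = pred,
                     patient_id = cohort$patient_id,
                     stringsAsFactors = FALSE)
  for (cv in covariates) base[[cv]] <- cohort[[cv]]
  rhs <- paste(c("sex * pred", covariates, "(1 | patient_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste("y ~", rhs))

  rename_terms <- function(tm) {
    tm <- sub("^pred$", predictor_name, tm)
    tm <- sub("^sex:pred$", paste0("sex:", predictor_name), tm)
    sub("^diagnosisUC$", "diagnosis", tm)
  }
  res <- lapply(colnames(responses), function(rn) {
    d <- base
    d$y <- responses[, rn]
    keep <- complete.cases(d)
    d <- d[keep, , drop = FALSE]
    fit <- if (sum(keep) >= 4L) fit_one_lmm(form, d) else NULL
    if (is.null(fit)) {
      terms <- rename_terms(c("(Intercept)", "sex", "pred", covariates,
                              "sex:pred"))
      return(data.frame(response = rn, term = terms, estimate = NaN,
                        se = NaN, t = NaN, p = NaN, n_obs = sum(keep),
                        converged = FALSE, stringsAsFactors = FALSE))
    }
    tab <- lmm_fixef_table(fit)
    tab$term <- rename_terms(tab$term)
    data.frame(response = rn, tab,
               p = 2 * pnorm(-abs(tab$t)),
               n_obs = nrow(d), converged = TRUE,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_adj <- NA_real_
  for (tm in unique(res$term)) {
    i <- res$term == tm
    res$p_adj[i] <- bh_adjust(res$p[i])
  }
  res[c("response", "term", "estimate", "se", "t", "p", "p_adj",
        "n_obs", "converged")]
}

#' Remitter vs non-remitter contrasts at each visit
#'
#' Fits `y ~ remitter * factor(week) + (1 | patient)` and reports the
#' remission minus non-remission group difference, its SE and Wald-normal
#' p at every scheduled week, BH-adjusted across weeks. Remission labels
#' follow endoscopic semantics (eMayo < 2 for UC, SES-CD < 3 for CD) and
#' are constant within patient. A week observed in only one group gets a
#' `NaN`-flagged row.
#'
#' @param response numeric vector aligned to cohort rows.
#' @param cohort cohort `data.frame` with `week` and `patient_id`.
#' @param remission logical per-row remission labels; defaults to
#'   `cohort$remitter`.
#' @return `data.frame` with columns `week`, `estimate`, `se`, `p`,
#'   `p_adj`, `n_obs`.
#' @export
timepoint_contrasts <- function(response, cohort, remission = NULL) {
  if (is.null(remission)) remission <- cohort$remitter
  if (length(response) != nrow(cohort) ||
      length(remission) != nrow(cohort))
    stop("response/remission must align with cohort rows", call. = FALSE)
  weeks <- sort(unique(cohort$week))
  d <- data.frame(y = response, rem = as.numeric(remission),
                  weekf = factor(cohort$week, levels = weeks),
                  patient_id = cohort$patient_id,
                  stringsAsFactors = FALSE)
  d <- d[complete.cases(d), , drop = FALSE]
  both_groups <- vapply(weeks, function(w) {
    g <- d$rem[d$weekf == w]
    length(unique(g)) == 2L
  }, logical(1))
  fit <- fit_one_lmm(y ~ rem * weekf + (1 | patient_id), d)
  out <- data.frame(week = weeks, estimate = NaN, se = NaN, p = NaN,
                    n_obs = as.vector(table(d$weekf)[as.character(weeks)]))
  if (!is.null(fit)) {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    for (k in seq_along(weeks)) {
      if (!both_groups[k]) next
      wanted <- "rem"
      if (k > 1L) wanted <- c(wanted, paste0("rem:weekf", weeks[k]))
      if (!all(wanted %in% names(beta))) next  # dropped (rank deficient)
      cv <- setNames(numeric(length(beta)), names(beta))
      cv[wanted] <- 1
      est <- sum(cv * beta)
      se <- sqrt(drop(t(cv) %*% V %*% cv))
      out$estimate[k] <- est
      out$se[k] <- se
      out$p[k] <- 2 * pnorm(-abs(est / se))
    }
  }
  out$p_adj <- bh_adjust(ifelse(is.nan(out$p), NA, out$p))
  out
}

#' Spearman correlations with FDR across features
#'
#' Per feature, Spearman's rho computed as the Pearson correlation of
#' mid-ranks (average ranks on ties) on pairwise-complete observations,
#' p from the t approximation with n - 2 degrees of freedom, and BH
#' adjustment across features. Features with fewer than 3 complete pairs
#' are `NaN`-flagged.
#'
#' @param features samples x features numeric matrix (or vector).
#' @param target numeric vector aligned to rows.
#' @return `data.frame` with columns `feature`, `rho`, `p`, `p_adj`, `n`.
#' @export
spearman_with_fdr <- function(features, target) {
  if (is.vector(features)) features <- cbind(feature = features)
  if (nrow(features) != length(target))
    stop("features and target have different lengths", call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("feature_", seq_len(ncol(features)))
  rows <- lapply(colnames(features), function(fn) {
    x <- features[, fn]
    ok <- !is.na(x) & !is.na(target)
    n <- sum(ok)
    if (n < 3L)
      return(data.frame(feature = fn, rho = NaN, p = NaN, n = n))
    rx <- rank(x[ok])
    ry <- rank(target[ok])
    rho <- stats::cor(rx, ry)
    p <- if (abs(rho) >= 1) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), df = n - 2)
    }
    data.frame(feature = fn, rho = rho, p = p, n = n)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(ifelse(is.nan(out$p), NA, out$p))
  out[c("feature", "rho", "p", "p_adj", "n")]
}
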