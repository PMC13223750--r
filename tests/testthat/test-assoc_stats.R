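test_that("BH step-up matches the cumulative-minimum formula", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)                 # single p unchanged
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # property: agrees with stats::p.adjust, order-preserving, >= raw
  set.seed(18)
  for (i in 1:20) {
    p <- runif(sample(2:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, stats::p.adjust(p, method = "BH"))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  # NA entries pass through without counting towards m
  p <- c(0.01, NA, 0.02)
  expect_equal(bh_adjust(p), c(0.02, NA, 0.02))
})

test_that("log-decline imputation is exact on two-point trajectories", {
  co <- data.frame(
    sample_id = paste0("P1_W", c(0, 2, 14)), patient_id = "P1",
    diagnosis = "CD", week = c(0, 2, 14),
    activity = c(10, NA, 10 - 2 * log(15)))
  out <- impute_activity_log_decline(co)
  expect_equal(out$activity[2], 10 - 2 * log(3), tolerance = 1e-9)
  expect_identical(out$activity[c(1, 3)], co$activity[c(1, 3)])
  expect_identical(out$observed_activity, c(TRUE, FALSE, TRUE))
  # constant scores -> constant imputation
  co$activity <- c(5, NA, 5)
  expect_equal(impute_activity_log_decline(co)$activity, c(5, 5, 5))
  # fully observed -> identity
  co$activity <- c(5, 4, 3)
  expect_equal(impute_activity_log_decline(co)$activity, c(5, 4, 3))
  # single observed visit carried; fitted values clipped to scale
  co$activity <- c(12, NA, NA)
  expect_equal(impute_activity_log_decline(co)$activity, c(12, 12, 12))
  co$activity <- c(16, 6, NA)          # steep decline would go negative
  expect_gte(min(impute_activity_log_decline(co)$activity), 0)
  co$activity <- c(NA, NA, NA)
  expect_error(impute_activity_log_decline(co), "P1")
})

test_that("LMM recovers a planted activity slope within 2 SE", {
  co <- small_cohort(n_patients = 50, seed = 19)
  set.seed(19)
  y <- plant_response(co, slope = 0.5, icpt_sd = 1, resid_sd = 0.1)
  a <- fit_activity_lmm(y, co, covariates = character())
  act <- a[a$term == "activity", ]
  expect_true(act$converged)
  expect_lt(abs(act$estimate - 0.5), 2 * act$se)
  expect_equal(act$t, act$estimate / act$se, tolerance = 1e-9)
  expect_true(all(a$p >= 0 & a$p <= 1, na.rm = TRUE))
  expect_true(all(a$p_adj >= a$p, na.rm = TRUE))
})

test_that("LMM reduces to OLS when between-patient variance is zero", {
  co <- small_cohort(n_patients = 30, seed = 20)
  set.seed(20)
  y <- plant_response(co, slope = 0.3, icpt_sd = 0, resid_sd = 0.5)
  a <- fit_activity_lmm(y, co, covariates = character())
  ols <- oracle_ols_fixef(y, co)
  got <- setNames(a$estimate, a$term)
  expect_equal(got[["(Intercept)"]], ols[["(Intercept)"]],
               tolerance = 1e-3)
  expect_equal(got[["activity"]], ols[["pred"]], tolerance = 1e-3)
  expect_equal(got[["sex"]], ols[["sex"]], tolerance = 1e-3)
  expect_equal(got[["sex:activity"]], ols[["sex:pred"]],
               tolerance = 1e-3)
})

test_that("batch fitting survives degenerate response columns", {
  co <- small_cohort(n_patients = 20, seed = 21)
  set.seed(21)
  resp <- cbind(good = plant_response(co, slope = 0.4),
                dead = rep(NA_real_, nrow(co)))
  rownames(resp) <- co$sample_id
  a <- fit_activity_lmm(resp, co)
  expect_true(all(a$converged[a$response == "good"]))
  expect_true(all(!a$converged[a$response == "dead"]))
  expect_true(all(is.nan(a$estimate[a$response == "dead"])))
  # a Kyn:Trp-style numeric predictor works the same way
  kt <- plant_response(co, slope = 0.2)
  a2 <- fit_activity_lmm(resp[, "good"], co, predictor = kt,
                         predictor_name = "Kyn:Trp")
  expect_true("Kyn:Trp" %in% a2$term)
  expect_true("sex:Kyn:Trp" %in% a2$term)
})

test_that("fit_activity_lmm rejects misaligned input", {
  co <- small_cohort(n_patients = 10, seed = 22)
  y <- rnorm(nrow(co))
  expect_error(fit_activity_lmm(y[-1], co), "rows")
  co_na <- co
  co_na$activity[2] <- NA
  expect_error(fit_activity_lmm(y, co_na), "impute_activity_log_decline")
  expect_error(fit_activity_lmm(y, co, predictor = 1:3), "aligned")
})

test_that("timepoint contrasts recover a planted group difference", {
  co <- small_cohort(n_patients = 60, seed = 23)
  set.seed(23)
  y <- plant_response(co, icpt_sd = 0.3, resid_sd = 0.3, group_delta = 1)
  ct <- timepoint_contrasts(y, co)
  expect_equal(ct$week, c(0, 2, 6, 14))
  expect_true(all(abs(ct$estimate - 1) < 0.2))
  expect_true(all(ct$p_adj < 0.05))
  # identical groups: estimates ~ 0
  y0 <- plant_response(co, icpt_sd = 0.3, resid_sd = 0.3)
  ct0 <- timepoint_contrasts(y0, co)
  expect_true(all(abs(ct0$estimate) < 0.3))
})

test_that("a week observed in a single group is NaN-flagged", {
  co <- small_cohort(n_patients = 20, seed = 24)
  set.seed(24)
  y <- plant_response(co, group_delta = 1)
  # drop all non-remitter rows at week 14
  drop <- co$week == 14 & !co$remitter
  y[drop] <- NA
  ct <- timepoint_contrasts(y, co)
  expect_true(is.nan(ct$estimate[ct$week == 14]))
  expect_false(anyNA(ct$estimate[ct$week != 14]))
})

test_that("permuted remission labels destroy the planted contrast", {
  hits <- vapply(1:30, function(s) {
    co <- small_cohort(n_patients = 30, seed = 400 + s)
    set.seed(400 + s)
    y <- plant_response(co, icpt_sd = 0.3, resid_sd = 0.3,
                        group_delta = 1)
    pats <- unique(co$patient_id)
    perm <- setNames(sample(tapply(co$remitter, co$patient_id, `[`, 1)),
                     pats)
    ct <- timepoint_contrasts(y, co, remission = perm[co$patient_id])
    mean(ct$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_lt(mean(hits), 0.2)
})

test_that("Spearman with FDR matches the mid-rank Pearson oracle", {
  out <- spearman_with_fdr(cbind(x = c(1, 2, 3)), c(1, 2, 3))
  expect_equal(out$rho, 1)
  out <- spearman_with_fdr(cbind(x = c(1, 2, 3)), c(3, 2, 1))
  expect_equal(out$rho, -1)
  # ties: equals Pearson on explicitly computed mid-ranks
  set.seed(25)
  x <- sample(1:5, 40, replace = TRUE)
  y <- x + sample(0:2, 40, replace = TRUE)
  out <- spearman_with_fdr(cbind(a = x), y)
  expect_equal(out$rho, oracle_spearman(x, y))
  expect_equal(out$p,
               cor.test(x, y, method = "spearman", exact = FALSE)$p.value,
               tolerance = 1e-12)
  # pairwise-complete + minimum pair count
  f <- cbind(ok = c(1, 2, 3, 4, NA), few = c(1, NA, NA, NA, 2))
  out <- spearman_with_fdr(f, c(2, 3, 4, 5, 6))
  expect_equal(out$n, c(4, 2))
  expect_true(is.nan(out$rho[2]))
  expect_false(is.na(out$p_adj[1]))
})
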