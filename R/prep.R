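#' Missingness filter for targeted metabolomics (80% rule)
#'
#' Concentrations below the limits of quantitation/detection enter the
#' matrix as `NA`. Metabolites with at least `min_nonmissing` non-missing
#' values across samples are retained; the boundary is inclusive (a
#' metabolite observed in exactly 80% of samples is kept). Samples and
#' retained values are unchanged.
#'
#' @param m samples x metabolites numeric matrix, `NA` = missing.
#' @param min_nonmissing required non-missing fraction, in (0, 1].
#' @return the matrix restricted to retained metabolites.
#' @export
apply_eighty_percent_rule <- function(m, min_nonmissing = 0.8) {
  check_matrix(m, "metabolite matrix")
  if (!is.numeric(min_nonmissing) || length(min_nonmissing) != 1L ||
      is.na(min_nonmissing) || min_nonmissing <= 0 || min_nonmissing > 1)
    stop("min_nonmissing must be in (0, 1]", call. = FALSE)
  frac <- colMeans(!is.na(m))
  m[, frac >= min_nonmissing, drop = FALSE]
}

#' Half-minimum imputation of left-censored values
#'
#' Each missing cell of metabolite `j` is set to half of metabolite `j`'s
#' minimum observed value (the standard stand-in for below-LOD
#' concentrations). Observed cells are unchanged; the result has no
#' missing cells. Apply [apply_eighty_percent_rule()] first so no
#' metabolite is entirely missing.
#'
#' @param m samples x metabolites numeric matrix, `NA` = missing.
#' @return the matrix with all `NA` cells imputed.
#' @export
impute_half_minimum <- function(m) {
  check_matrix(m, "metabolite matrix")
  all_missing <- colSums(!is.na(m)) == 0L
  if (any(all_missing))
    stop("metabolite(s) with no observed values: ",
         paste(colnames(m)[all_missing], collapse = ", "),
         "; filter with apply_eighty_percent_rule() first", call. = FALSE)
  for (j in seq_len(ncol(m))) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- 0.5 * min(m[!miss, j])
  }
  m
}

#' Log10 transform and autoscale a metabolite matrix
#'
#' Per metabolite, values become `(log10(x) - mean) / sd` with the sample
#' standard deviation (n-1 denominator), so every column has mean 0 and
#' unit sd. Run after imputation: all values must be strictly positive.
#'
#' @param m samples x metabolites numeric matrix, no missing values.
#' @return the transformed matrix.
#' @export
log10_autoscale <- function(m) {
  check_matrix(m, "metabolite matrix")
  if (anyNA(m))
    stop("matrix contains missing values; impute first", call. = FALSE)
  if (any(m <= 0))
    stop("log10 transform requires strictly positive values", call. = FALSE)
  lg <- log10(m)
  sds <- apply(lg, 2L, sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-variance metabolite(s): ",
         paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
  scale(lg, center = TRUE, scale = sds)[, , drop = FALSE]
}

ratio_definitions <- function() {
  sum_ido <- c("3OHAnth", "3OHKyn", "KA", "Kyn", "PA", "QA", "Xanth")
  list(
    "Kyn:Trp"    = list(num = "Kyn", den = "Trp"),
    "PA:QA"      = list(num = "PA",  den = "QA"),
    "QA:Trp"     = list(num = "QA",  den = "Trp"),
    "QA:sumIDO"  = list(num = "QA",  den = sum_ido),
    "QA:3OHAnth" = list(num = "QA",  den = "3OHAnth")
  )
}

#' Kynurenine-pathway ratio panel
#'
#' Computes the five diagnostic ratios on raw concentrations (never on
#' log/scaled values): `Kyn:Trp` (IDO1-driven KP activation), `PA:QA`,
#' `QA:Trp` (overall QA synthesis relative to the Trp pool),
#' `QA:sumIDO` = QA / (3OHAnth + 3OHKyn + KA + Kyn + PA + QA + Xanth)
#' (relative QA accumulation among IDO-downstream metabolites), and
#' `QA:3OHAnth`. A missing component propagates `NA` for that sample's
#' ratio, so by default ratios are computed before imputation to avoid
#' imputation-driven artifacts.
#'
#' @param m samples x metabolites numeric matrix of raw concentrations.
#' @return samples x 5 matrix of dimensionless ratios.
#' @export
compute_ratio_panel <- function(m) {
  check_matrix(m, "metabolite matrix")
  defs <- ratio_definitions()
  needed <- unique(unlist(lapply(defs, function(d) c(d$num, d$den))))
  absent <- setdiff(needed, colnames(m))
  if (length(absent))
    stop("missing metabolite column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  out <- sapply(defs, function(d) {
    den <- if (length(d$den) == 1L) m[, d$den]
           else rowSums(m[, d$den, drop = FALSE])  # NA propagates
    m[, d$num] / den
  })
  out <- matrix(out, nrow = nrow(m),
                dimnames = list(rownames(m), names(defs)))
  out
}
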