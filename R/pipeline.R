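`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flag bottleneck reactions from activity associations
#'
#' A bottleneck is a catalysed reaction whose activity score falls
#' significantly with disease activity (negative estimate, BH-adjusted
#' p < `alpha`) while lying downstream — by directed substrate-to-product
#' reachability — of at least one reaction whose score rises
#' significantly. Spontaneous (GPR-less) reactions conduct reachability
#' but are never flagged. This decision rule formalizes reading the sign
#' pattern off the fitted pathway map and is an artifact-defined
#' criterion, not a published one.
#'
#' @param assoc `data.frame` from [fit_activity_lmm()] on a RAS matrix
#'   (the `response` column must hold reaction ids).
#' @param model the `pathway_model` the RAS matrix was computed from.
#' @param alpha BH-adjusted significance threshold.
#' @param term which term's estimates to read (default `"activity"`).
#' @return character vector of flagged reaction ids (model order).
#' @export
flag_bottlenecks <- function(assoc, model, alpha = 0.05,
                             term = "activity") {
  validate_pathway_model(model)
  a <- assoc[assoc$term == term, , drop = FALSE]
  ids <- vapply(model$reactions, `[[`, "", "id")
  unknown <- setdiff(unique(a$response), ids)
  if (length(unknown))
    stop("association results for unknown reaction id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  has_gpr <- ids[!vapply(model$reactions,
                         function(rx) is.null(rx[["gpr"]]), logical(1))]
  sig <- a[is.finite(a$p_adj) & a$p_adj < alpha, , drop = FALSE]
  pos <- sig$response[sig$estimate > 0]
  neg <- intersect(sig$response[sig$estimate < 0], has_gpr)
  if (length(pos) == 0L || length(neg) == 0L) return(character(0))
  down_of_pos <- unique(unlist(lapply(pos, downstream_reactions,
                                      model = model)))
  ids[ids %in% intersect(neg, down_of_pos)]
}

default_run_config <- function() {
  list(
    mode = "simulate",
    seed = 1L,
    synthetic = list(),
    paths = list(),
    options = list(or_mode = "sum",
                   covariates = c("age", "bmi", "diagnosis"),
                   alpha = 0.05, n_perm = 1000L,
                   min_nonmissing = 0.8, ratio_on = "raw"),
    outdir = NULL,
    verbosity = 1L
  )
}

resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON path",
                             call. = FALSE)
  base <- default_run_config()
  out <- utils::modifyList(base, config)
  out$mode <- match.arg(out$mode, c("simulate", "load"))
  if (out$mode == "load") {
    need <- c("cohort_tsv", "metabolome_tsv", "expression_tsv")
    missing <- setdiff(need, names(out$paths))
    if (length(missing))
      stop("mode 'load' requires paths: ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  out$seed <- as.integer(out$seed)
  out
}

log_stage <- function(config, ...) {
  if ((config$verbosity %||% 1L) > 0L)
    message("[kpnad] ", sprintf(...))
}

#' Run the full bottleneck-detection pipeline
#'
#' Executes, in fixed order: simulate-or-load inputs; activity-score
#' imputation (logarithmic decline); metabolomics preprocessing (80%
#' rule, ratio panel on raw concentrations, half-minimum imputation,
#' log10 + autoscale); reaction activity scores over the packaged (or
#' supplied) Trp-degradation model; mixed-model association of RAS,
#' scaled metabolites, ratios and log-TPM expression with standardized
#' disease activity; remitter timepoint contrasts for the ratio panel;
#' GSEA on any supplied gene sets that intersect the expression panel;
#' and bottleneck flagging. All intermediate tables are written to
#' `outdir` when one is configured; output is byte-identical under a
#' fixed seed.
#'
#' @param config a config list or path to a JSON config. Fields:
#'   `mode` ("simulate"/"load"), `seed`, `synthetic` (arguments to
#'   [synthetic_config()]), `paths` (`cohort_tsv`, `metabolome_tsv`,
#'   `expression_tsv`, optional `model_json`, `gmt`), `options`
#'   (`or_mode`, `covariates`, `alpha`, `n_perm`, `min_nonmissing`,
#'   `ratio_on`), `outdir`, `verbosity`.
#' @return a `bottleneck_report` list: `flagged`, `reactions` (activity
#'   effects per reaction), `metabolites`, `ratios`, `contrasts`,
#'   `enrichment`, `counts`, `provenance`.
#' @export
run_pipeline <- function(config) {
  config <- resolve_run_config(config)
  opt <- config$options

  if (config$mode == "simulate") {
    syn <- config$synthetic
    syn$seed <- config$seed
    scfg <- do.call(synthetic_config, syn)
    log_stage(config, "simulate: %d patients, %d visits",
              scfg$n_patients, length(scfg$weeks))
    cohort <- generate_cohort(scfg)
    met <- generate_metabolome(cohort, scfg)
    expr <- generate_expression(cohort, scfg)
  } else {
    cohort <- read_cohort_tsv(config$paths$cohort_tsv)
    met <- read_matrix_tsv(config$paths$metabolome_tsv)
    expr <- read_matrix_tsv(config$paths$expression_tsv)
  }
  model <- if (!is.null(config$paths$model_json))
    read_pathway_model(config$paths$model_json) else load_trp_subnetwork()

  cohort <- impute_activity_log_decline(cohort)
  log_stage(config, "cohort: %d samples / %d patients (%d imputed scores)",
            nrow(cohort), length(unique(cohort$patient_id)),
            sum(!cohort$observed_activity))

  filtered <- apply_eighty_percent_rule(met, opt$min_nonmissing)
  log_stage(config, "80%% rule: %d/%d metabolites retained",
            ncol(filtered), ncol(met))
  ratio_source <- if (identical(opt$ratio_on, "imputed"))
    impute_half_minimum(filtered) else filtered
  ratios <- compute_ratio_panel(ratio_source)
  imputed <- impute_half_minimum(filtered)
  scaled <- log10_autoscale(imputed)

  ras <- compute_ras_matrix(model, expr, or_mode = opt$or_mode)
  scorable <- colnames(ras)[!apply(ras, 2, function(x) all(is.nan(x)))]
  log_stage(config, "RAS: %d/%d reactions scorable",
            length(scorable), ncol(ras))

  covs <- opt$covariates
  assoc_ras <- fit_activity_lmm(ras[, scorable, drop = FALSE], cohort,
                                covariates = covs)
  assoc_met <- fit_activity_lmm(scaled, cohort, covariates = covs)
  assoc_ratio <- fit_activity_lmm(ratios, cohort, covariates = covs)
  assoc_expr <- fit_activity_lmm(log(expr), cohort, covariates = covs)
  log_stage(config, "LMM: %d/%d expression fits converged",
            sum(assoc_expr$converged), nrow(assoc_expr))

  contrasts <- NULL
  if ("remitter" %in% names(cohort) &&
      length(unique(cohort$remitter)) == 2L) {
    contrasts <- do.call(rbind, lapply(colnames(ratios), function(rn) {
      ct <- timepoint_contrasts(ratios[, rn], cohort)
      cbind(response = rn, ct)
    }))
  }

  enrichment <- NULL
  ranking <- tryCatch(suppressMessages(make_ranking(assoc_expr)),
                      error = function(e) NULL)
  sets <- if (!is.null(config$paths$gmt)) read_gmt(config$paths$gmt)
          else builtin_gene_sets()
  if (!is.null(ranking)) {
    usable <- Filter(function(s)
      length(intersect(s$genes, names(ranking))) > 0 &&
      length(intersect(s$genes, names(ranking))) < length(ranking), sets)
    if (length(usable)) {
      enrichment <- do.call(rbind, lapply(usable, function(s) {
        r <- gsea_es(ranking, s, n_perm = opt$n_perm,
                     seed = config$seed + 101L)
        data.frame(set = r$set, es = r$es, p = r$p, size = r$size,
                   direction = r$direction, stringsAsFactors = FALSE)
      }))
      enrichment$p_adj <- bh_adjust(enrichment$p)
    } else {
      log_stage(config,
                "enrichment skipped: no gene set overlaps the panel")
    }
  }

  flagged <- flag_bottlenecks(assoc_ras, model, alpha = opt$alpha)
  log_stage(config, "bottleneck flags: %s",
            if (length(flagged)) paste(flagged, collapse = ", ")
            else "(none)")

  act_ras <- assoc_ras[assoc_ras$term == "activity", , drop = FALSE]
  report <- structure(list(
    flagged = flagged,
    reactions = act_ras,
    metabolites = assoc_met[assoc_met$term == "activity", , drop = FALSE],
    ratios = assoc_ratio[assoc_ratio$term == "activity", , drop = FALSE],
    contrasts = contrasts,
    enrichment = enrichment,
    counts = list(
      n_samples = nrow(cohort),
      n_patients = length(unique(cohort$patient_id)),
      metabolites_retained = ncol(filtered),
      metabolites_dropped = ncol(met) - ncol(filtered),
      reactions_scorable = length(scorable),
      imputed_activity_scores = sum(!cohort$observed_activity),
      nonconverged_fits = sum(!assoc_ras$converged)
    ),
    # outdir is excluded from the provenance echo so the report is
    # byte-identical wherever the run is materialized
    provenance = list(config = config[setdiff(names(config), "outdir")],
                      seed = config$seed,
                      package_version = as.character(packageVersion("kpnad")))
  ), class = "bottleneck_report")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$outdir, f)
    write_cohort_tsv(cohort, out("cohort.tsv"))
    write_matrix_tsv(met, out("metabolome_raw.tsv"))
    write_matrix_tsv(imputed, out("metabolome_imputed.tsv"))
    write_matrix_tsv(scaled, out("metabolome_scaled.tsv"))
    write_matrix_tsv(ratios, out("ratios.tsv"))
    write_matrix_tsv(expr, out("expression.tsv"))
    write_matrix_tsv(ras, out("ras.tsv"))
    write_df_tsv(assoc_ras, out("assoc_ras.tsv"))
    write_df_tsv(assoc_met, out("assoc_metabolites.tsv"))
    write_df_tsv(assoc_ratio, out("assoc_ratios.tsv"))
    write_df_tsv(assoc_expr, out("assoc_expression.tsv"))
    if (!is.null(contrasts)) write_df_tsv(contrasts, out("contrasts.tsv"))
    if (!is.null(enrichment))
      write_df_tsv(enrichment, out("enrichment.tsv"))
    write_pathway_model(model, out("pathway_model.json"))
    jsonlite::write_json(unclass(report), out("report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)
  }
  report
}

#' @export
print.bottleneck_report <- function(x, ...) {
  cat("<bottleneck_report>\n")
  cat("  flagged bottleneck reaction(s): ",
      if (length(x$flagged)) paste(x$flagged, collapse = ", ")
      else "(none)", "\n", sep = "")
  cat(sprintf("  %d samples / %d patients; %d scorable reactions\n",
              x$counts$n_samples, x$counts$n_patients,
              x$counts$reactions_scorable))
  invisible(x)
}

#' Read / write the longitudinal sample sheet
#'
#' One row per patient-visit with covariates, activity scores and
#' remission labels; empty activity cells are unobserved scores.
#'
#' @param cohort cohort `data.frame`.
#' @param path file path.
#' @return `read_cohort_tsv()` a cohort `data.frame`.
#' @export
write_cohort_tsv <- function(cohort, path) {
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "")
  need <- c("sample_id", "patient_id", "diagnosis", "week", "activity")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sample sheet lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df[c("patient_id", "week")]))
    stop("duplicate (patient_id, week) rows in sample sheet",
         call. = FALSE)
  if ("remitter" %in% names(df)) df$remitter <- as.logical(df$remitter)
  if ("observed_activity" %in% names(df))
    df$observed_activity <- as.logical(df$observed_activity)
  df
}
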