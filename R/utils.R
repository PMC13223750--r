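## internal helpers shared across modules

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid field '%s': %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x > 1 || (!allow_one && x == 1))
    stop_field(field, sprintf("must be a fraction in [0,%s]",
                              if (allow_one) "1" else "1)"))
  invisible(x)
}

check_number <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a finite number")
  invisible(x)
}

# samples x features numeric matrix with mandatory dimnames
check_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m))
    stop(sprintf("%s must be a numeric matrix", what), call. = FALSE)
  if (nrow(m) == 0L || ncol(m) == 0L)
    stop(sprintf("%s is empty", what), call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop(sprintf("%s needs sample row names and feature column names", what),
         call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop(sprintf("%s has duplicated feature names", what), call. = FALSE)
  invisible(m)
}

#' Read / write sample-by-feature TSV matrices
#'
#' Matrices are stored with samples as rows, a leading `sample_id` column,
#' and one column per metabolite/gene/reaction. Empty cells are missing
#' values (left-censored metabolite measurements).
#'
#' @param path file path.
#' @param m numeric matrix with sample row names and feature column names.
#' @return `read_matrix_tsv()` a numeric matrix; `write_matrix_tsv()` the
#'   path, invisibly.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("expected a 'sample_id' column in ", path, call. = FALSE)
  m <- as.matrix(df[setdiff(names(df), "sample_id")])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$sample_id)
  m
}

#' @rdname read_matrix_tsv
#' @export
write_matrix_tsv <- function(m, path) {
  check_matrix(m)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

write_df_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
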