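## gene-protein-reaction boolean rules: parsing and evaluation
##
## Grammar (recon3D style, "and"/"or" case-insensitive):
##   expr   := term  ( "or"  term  )*
##   term   := factor( "and" factor)*
##   factor := "(" expr ")" | gene
## n-ary nodes: "A or B or C" parses to a single OR with three children.

gpr_leaf <- function(gene) structure(list(op = "gene", gene = gene),
                                     class = "gpr_expr")
gpr_node <- function(op, children) {
  if (length(children) == 1L) return(children[[1L]])
  structure(list(op = op, children = children), class = "gpr_expr")
}

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1L]]
  if (m[1L] == -1L) return(data.frame(tok = character(), pos = integer()))
  data.frame(tok = regmatches(text, list(m))[[1L]], pos = as.integer(m),
             stringsAsFactors = FALSE)
}

gpr_error <- function(msg, pos) {
  stop(sprintf("GPR parse error at position %d: %s", pos, msg),
       call. = FALSE)
}

#' Parse a gene-protein-reaction rule
#'
#' Parses recon3D-style boolean rules ("and" = enzyme complex, "or" =
#' isozymes; case-insensitive; parentheses honored) into an expression
#' tree. `format()`/`as.character()` on the result give a canonical
#' round-trippable string.
#'
#' @param text nonempty rule string, e.g. `"IDO1 or IDO2 or TDO2"`.
#' @return a `gpr_expr` tree (leaves are gene symbols, internal nodes
#'   AND/OR with >= 2 children).
#' @export
#' @examples
#' parse_gpr("G1 and (G2 or G3)")
parse_gpr <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) ||
      !nzchar(trimws(text)))
    stop("GPR rule must be a nonempty string", call. = FALSE)
  toks <- gpr_tokenize(text)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$tok[i] else NA_character_
  pos <- function() if (i <= n) toks$pos[i] else nchar(text) + 1L

  parse_expr <- function() {
    children <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      i <<- i + 1L
      children <- c(children, list(parse_term()))
    }
    gpr_node("or", children)
  }
  parse_term <- function() {
    children <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      i <<- i + 1L
      children <- c(children, list(parse_factor()))
    }
    gpr_node("and", children)
  }
  parse_factor <- function() {
    tk <- peek()
    if (is.na(tk)) gpr_error("unexpected end of rule", pos())
    if (tk == "(") {
      i <<- i + 1L
      e <- parse_expr()
      if (is.na(peek()) || peek() != ")")
        gpr_error("unbalanced parentheses", pos())
      i <<- i + 1L
      return(e)
    }
    if (tk == ")") gpr_error("unexpected ')'", pos())
    if (tolower(tk) %in% c("and", "or"))
      gpr_error(sprintf("dangling operator '%s'", tk), pos())
    i <<- i + 1L
    gpr_leaf(tk)
  }

  e <- parse_expr()
  if (!is.na(peek()))
    gpr_error(sprintf("unexpected token '%s'", peek()), pos())
  e
}

#' @export
format.gpr_expr <- function(x, ...) {
  if (x$op == "gene") return(x$gene)
  parts <- vapply(x$children, function(ch) {
    s <- format(ch)
    if (ch$op != "gene") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", x$op, " "))
}

#' @export
as.character.gpr_expr <- function(x, ...) format(x)

#' @export
print.gpr_expr <- function(x, ...) {
  cat("<GPR> ", format(x), "\n", sep = "")
  invisible(x)
}

gpr_genes <- function(gpr) {
  if (gpr$op == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}

#' Reaction activity score of one GPR rule
#'
#' Evaluates a rule against gene expression (TPM): a leaf scores its
#' gene's TPM; an AND node (enzyme complex) the minimum of its children
#' (limiting subunit); an OR node (isozymes) the sum of its children
#' (`or_mode = "sum"`, capacities add) or their maximum
#' (`or_mode = "max"`). Genes absent from `expr` (or `NA`) contribute 0
#' to OR and are skipped in AND; a node all of whose children are
#' unmeasured scores `NaN` ("no evidence", distinct from silent).
#'
#' @param gpr a `gpr_expr` from [parse_gpr()].
#' @param expr named numeric vector of nonnegative TPM values.
#' @param or_mode `"sum"` (default) or `"max"`.
#' @return a nonnegative score, or `NaN` if no leaf is measured.
#' @export
reaction_activity_score <- function(gpr, expr, or_mode = c("sum", "max")) {
  or_mode <- match.arg(or_mode)
  if (!inherits(gpr, "gpr_expr"))
    stop("gpr must be a gpr_expr", call. = FALSE)
  ev <- function(node) {
    if (node$op == "gene") {
      v <- expr[node$gene]
      if (is.null(v) || length(v) == 0L || is.na(v)) return(NaN)
      return(unname(v))
    }
    vals <- vapply(node$children, ev, numeric(1))
    meas <- vals[!is.nan(vals)]
    if (length(meas) == 0L) return(NaN)
    if (node$op == "and") min(meas)
    else if (or_mode == "sum") sum(meas) else max(meas)
  }
  ev(gpr)
}

#' Reaction activity scores for a whole expression matrix
#'
#' Applies [reaction_activity_score()] per reaction and sample: one
#' nonnegative score per (sample, reaction), with `NaN` columns for
#' reactions that have no GPR (spontaneous) or no measured gene. With
#' `or_mode = "sum"` scores are 1-homogeneous in expression and monotone
#' in every gene.
#'
#' @param model a `pathway_model` (see [load_trp_subnetwork()]).
#' @param expr samples x genes nonnegative TPM matrix.
#' @inheritParams reaction_activity_score
#' @return samples x reactions RAS matrix.
#' @export
compute_ras_matrix <- function(model, expr, or_mode = c("sum", "max")) {
  or_mode <- match.arg(or_mode)
  if (!inherits(model, "pathway_model"))
    stop("model must be a pathway_model", call. = FALSE)
  if (length(model$reactions) == 0L)
    stop("pathway model has no reactions", call. = FALSE)
  check_matrix(expr, "expression matrix")
  if (any(expr < 0, na.rm = TRUE))
    stop("expression matrix must be nonnegative", call. = FALSE)
  # evaluate each tree on column vectors; measuredness is per gene, so
  # AND-skip / OR-zero semantics reduce to dropping unmeasured leaves
  ev <- function(node) {
    if (node$op == "gene") {
      if (!node$gene %in% colnames(expr)) return(NULL)
      v <- expr[, node$gene]
      if (all(is.na(v))) return(NULL)
      return(v)
    }
    vals <- Filter(Negate(is.null), lapply(node$children, ev))
    if (length(vals) == 0L) return(NULL)
    if (node$op == "and") do.call(pmin, vals)
    else if (or_mode == "sum") Reduce(`+`, vals)
    else do.call(pmax, vals)
  }
  out <- sapply(model$reactions, function(rx) {
    if (is.null(rx[["gpr"]])) return(rep(NaN, nrow(expr)))
    v <- ev(rx[["gpr"]])
    if (is.null(v)) rep(NaN, nrow(expr)) else v
  })
  out <- matrix(out, nrow = nrow(expr),
                dimnames = list(rownames(expr),
                                vapply(model$reactions, `[[`, "", "id")))
  out
}
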