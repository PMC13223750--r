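## independent oracles; these deliberately avoid the code paths they check

# autoscale oracle: direct per-column recomputation
oracle_autoscale <- function(m) {
  lg <- log10(m)
  sweep(sweep(lg, 2, colMeans(lg)), 2, apply(lg, 2, sd), "/")
}

# random GPR rule string with at most `max_leaves` leaves
random_gpr_string <- function(max_leaves = 6, genes = LETTERS[1:8]) {
  build <- function(n) {
    if (n == 1L) return(sample(genes, 1))
    k <- sample.int(n - 1L, 1)
    op <- sample(c("and", "or"), 1)
    sprintf("(%s %s %s)", build(k), op, build(n - k))
  }
  build(sample.int(max_leaves, 1))
}

# table-driven bottom-up GPR evaluator: flattens the tree into a post-order
# node table, then fills a value column iteratively (no recursion in the
# evaluation step), with min/sum semantics and NaN = unmeasured
oracle_gpr_eval <- function(gpr, expr, or_mode = "sum") {
  nodes <- list()
  flatten <- function(node) {
    if (node$op == "gene") {
      nodes[[length(nodes) + 1L]] <<- list(op = "gene", gene = node$gene,
                                           children = integer())
    } else {
      idx <- vapply(node$children, flatten, integer(1))
      nodes[[length(nodes) + 1L]] <<- list(op = node$op, gene = NA,
                                           children = idx)
    }
    length(nodes)
  }
  flatten(gpr)
  val <- rep(NA_real_, length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    if (nd$op == "gene") {
      v <- expr[nd$gene]
      val[i] <- if (length(v) == 0L || is.na(v)) NaN else unname(v)
    } else {
      ch <- val[nd$children]
      ch <- ch[!is.nan(ch)]
      val[i] <- if (length(ch) == 0L) NaN
                else if (nd$op == "and") min(ch)
                else if (or_mode == "sum") sum(ch)
                else max(ch)
    }
  }
  val[length(nodes)]
}

# brute-force weighted running-sum enrichment score (explicit loop)
oracle_es <- function(ranking, set_genes) {
  genes <- names(sort(ranking, decreasing = TRUE))
  s <- abs(ranking[genes])
  nh <- sum(genes %in% set_genes)
  nm <- length(genes) - nh
  denom <- sum(s[genes %in% set_genes])
  running <- 0
  best <- 0
  for (g in genes) {
    if (g %in% set_genes) running <- running + s[[g]] / denom
    else running <- running - 1 / nm
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# exhaustive hypergeometric upper tail for small universes: enumerate all
# draws of size n and count those overlapping the set by >= k
oracle_hyper_enum <- function(k, universe, set_genes, n_draw) {
  draws <- utils::combn(universe, n_draw, simplify = FALSE)
  mean(vapply(draws, function(d)
    sum(d %in% set_genes) >= k, logical(1)))
}

# Spearman oracle: explicit mid-ranks then Pearson
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stats::cor(rank(x[ok], ties.method = "average"),
             rank(y[ok], ties.method = "average"))
}

# OLS oracle for the mixed model at zero between-patient variance
oracle_ols_fixef <- function(y, cohort, covariates = character()) {
  d <- data.frame(y = y, sex = cohort$sex - mean(cohort$sex),
                  pred = standardize_activity(cohort)$activity_std)
  for (cv in covariates) d[[cv]] <- cohort[[cv]]
  rhs <- paste(c("sex * pred", covariates), collapse = " + ")
  coef(lm(stats::as.formula(paste("y ~", rhs)), data = d))
}
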