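#' Gene sets: construction, GMT input/output, built-ins
#'
#' `gene_set()` builds a validated set (unique, nonempty symbols).
#' `read_gmt()`/`write_gmt()` handle the tab-separated GMT format
#' (name, description, symbols...); duplicated symbols within a line are
#' deduplicated with a warning. `builtin_gene_sets()` returns the
#' interferon-gamma response signature used to score mucosal cytokine
#' tone (IFITM1, MX1, OAS3, IFIT1, IFI44L, IFI16); TNF and IL23
#' signatures are published externally and must be supplied by the user
#' as a GMT file, never hard-coded here.
#'
#' @param name set name.
#' @param genes character vector of gene symbols.
#' @param description optional description (stored in GMT column 2).
#' @param path GMT file path.
#' @param sets list of `gene_set` objects.
#' @return `gene_set()` a `gene_set`; `read_gmt()`/`builtin_gene_sets()`
#'   a named list of `gene_set`s.
#' @export
gene_set <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (!nzchar(name)) stop("gene set needs a name", call. = FALSE)
  if (length(genes) == 0L || any(!nzchar(genes)))
    stop("gene set '", name, "' needs nonempty gene symbols",
         call. = FALSE)
  if (anyDuplicated(genes)) {
    warning("gene set '", name, "': duplicated symbols deduplicated",
            call. = FALSE)
    genes <- unique(genes)
  }
  structure(list(name = name, genes = genes, description = description),
            class = "gene_set")
}

#' @rdname gene_set
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 40), call. = FALSE)
    gene_set(f[1L], f[-(1:2)], description = f[2L])
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' @rdname gene_set
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$name, s$description, s$genes), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname gene_set
#' @export
builtin_gene_sets <- function() {
  list(IFNG = gene_set(
    "IFNG",
    c("IFITM1", "MX1", "OAS3", "IFIT1", "IFI44L", "IFI16"),
    description = "interferon-gamma response signature"
  ))
}

#' Gene-level ranking statistic from mixed-model results
#'
#' The GSEA ranking statistic per gene is the sum of the activity (or
#' Kyn:Trp) main-effect t-value and the sex-interaction t-value from
#' [fit_activity_lmm()]. Genes with `NaN` in either term are excluded
#' and counted in a message.
#'
#' @param assoc result `data.frame` from [fit_activity_lmm()].
#' @param main_term name of the main-effect term (default `"activity"`).
#' @param interaction_term name of the interaction term (default
#'   `paste0("sex:", main_term)`).
#' @return named numeric vector, one rank statistic per gene.
#' @export
make_ranking <- function(assoc, main_term = "activity",
                         interaction_term = paste0("sex:", main_term)) {
  if (is.null(assoc) || nrow(assoc) == 0L)
    stop("empty association results", call. = FALSE)
  tm <- assoc[assoc$term == main_term, c("response", "t")]
  ti <- assoc[assoc$term == interaction_term, c("response", "t")]
  if (nrow(tm) == 0L || nrow(ti) == 0L)
    stop("terms '", main_term, "' / '", interaction_term,
         "' not found in association results", call. = FALSE)
  merged <- merge(tm, ti, by = "response", suffixes = c("_main", "_int"))
  stat <- merged$t_main + merged$t_int
  bad <- !is.finite(stat)
  if (any(bad))
    message(sum(bad), " gene(s) excluded from ranking (NaN t-values)")
  setNames(stat[!bad], merged$response[!bad])
}

# weighted Kolmogorov-Smirnov running-sum enrichment score; `stat_sorted`
# is |statistic| ordered decreasing, `hit` a logical vector of the same
# length marking set members
running_sum_es <- function(stat_sorted, hit) {
  n <- length(stat_sorted)
  nh <- sum(hit)
  denom_hit <- sum(stat_sorted[hit])
  delta <- rep(-1 / (n - nh), n)
  delta[hit] <- if (denom_hit > 0) stat_sorted[hit] / denom_hit
                else 1 / nh
  rs <- cumsum(delta)
  rs[which.max(abs(rs))]
}

#' Permutation GSEA enrichment score
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment score (weight
#' exponent 1 on the absolute ranking statistic) for one gene set against
#' a precomputed ranking (see [make_ranking()]). The null is gene-label
#' permutation: set labels are redrawn `n_perm` times and
#' `p = (1 + #[|ES*| >= |ES|]) / (n_perm + 1)`, so p is floored at
#' `1/(n_perm + 1)`. Deterministic under a fixed seed.
#'
#' @param ranking named numeric vector of gene-level statistics.
#' @param set a [gene_set()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @return list with `set`, `es` (in `[-1, 1]`), `p`, `n_perm`, `size`
#'   (genes in both set and ranking), `direction` (+1/-1).
#' @export
gsea_es <- function(ranking, set, n_perm = 1000L, seed = 1L) {
  if (is.null(names(ranking)) || length(ranking) < 2L)
    stop("ranking must be a named vector of >= 2 genes", call. = FALSE)
  if (n_perm < 100L) stop("n_perm must be >= 100", call. = FALSE)
  genes <- names(ranking)
  members <- intersect(set$genes, genes)
  if (length(members) == 0L)
    stop("gene set '", set$name, "' is disjoint from the ranking",
         call. = FALSE)
  if (length(members) == length(genes))
    stop("gene set '", set$name, "' covers the whole ranking",
         call. = FALSE)
  o <- order(ranking, decreasing = TRUE)
  s <- abs(ranking[o])
  hit <- names(ranking)[o] %in% members
  es <- running_sum_es(s, hit)
  nh <- length(members)
  n <- length(genes)
  with_seed(seed, {
    perm <- vapply(seq_len(n_perm), function(b) {
      h <- logical(n)
      h[sample.int(n, nh)] <- TRUE
      running_sum_es(s, h)
    }, numeric(1))
    p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
  })
  list(set = set$name, es = es, p = p, n_perm = n_perm, size = nh,
       direction = sign(es))
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a hit list and a gene set, drawing `|hits|` genes from the
#' universe without replacement.
#'
#' @param hits character vector of selected genes (subset of universe).
#' @param universe character vector of all assayed genes.
#' @param set a [gene_set()]; intersected with the universe.
#' @return the p-value `P(X >= overlap)`.
#' @export
hypergeom_overrepresentation <- function(hits, universe, set) {
  hits <- unique(hits)
  universe <- unique(universe)
  if (!all(hits %in% universe))
    stop("hits must be a subset of the universe", call. = FALSE)
  K <- length(intersect(set$genes, universe))
  k <- length(intersect(hits, set$genes))
  phyper(k - 1, K, length(universe) - K, length(hits),
         lower.tail = FALSE)
}

#' Rank-based single-sample gene-set score
#'
#' All measured genes of one sample are ranked ascending (mid-ranks on
#' ties); the score is the centered mean rank of the set genes,
#' normalized so the maximum attainable value (set genes occupy the top
#' ranks) is +0.5 and the minimum is -0.5:
#' `score = (mean_rank_set - (n + 1) / 2) / (n - |S|)`. The score
#' depends on expression only through ranks, hence is invariant under
#' any strictly monotone transform.
#'
#' @param expr_sample named numeric vector of one sample's expression
#'   (`NA` = not measured).
#' @param set a [gene_set()].
#' @return score in `[-0.5, 0.5]`, or `NaN` if no set gene is measured.
#' @export
single_sample_score <- function(expr_sample, set) {
  x <- expr_sample[!is.na(expr_sample)]
  members <- intersect(set$genes, names(x))
  if (length(members) == 0L) return(NaN)
  n <- length(x)
  ns <- length(members)
  if (n == ns) return(0)
  r <- rank(x, ties.method = "average")
  (mean(r[members]) - (n + 1) / 2) / (n - ns)
}
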