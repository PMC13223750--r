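#' Construct and validate a pathway model
#'
#' A `pathway_model` holds reactions (id, display name, substrate and
#' product metabolite ids, optional GPR rule) plus the declared metabolite
#' list. Every metabolite referenced by a reaction must be declared; ids
#' must be unique.
#'
#' @param name model name.
#' @param reactions list of reactions; each a list with `id`, `name`,
#'   `substrates`, `products`, and `gpr` (a rule string or `NULL` for
#'   spontaneous reactions).
#' @param metabolites `data.frame` with columns `id`, `name`.
#' @return a validated `pathway_model`.
#' @export
pathway_model <- function(name, reactions, metabolites) {
  rxns <- lapply(reactions, function(rx) {
    rx$gpr_string <- if (is.null(rx[["gpr"]])) NA_character_
                     else if (inherits(rx$gpr, "gpr_expr")) format(rx$gpr)
                     else as.character(rx$gpr)
    rx$gpr <- if (is.na(rx$gpr_string)) NULL else parse_gpr(rx$gpr_string)
    rx
  })
  model <- structure(list(name = name, reactions = rxns,
                          metabolites = metabolites),
                     class = "pathway_model")
  validate_pathway_model(model)
  model
}

#' @rdname pathway_model
#' @param model a `pathway_model`.
#' @export
validate_pathway_model <- function(model) {
  if (!inherits(model, "pathway_model"))
    stop("not a pathway_model", call. = FALSE)
  ids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate reaction ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(model$metabolites$id))
    stop("duplicate metabolite ids", call. = FALSE)
  for (rx in model$reactions) {
    if (length(rx$substrates) == 0L || length(rx$products) == 0L)
      stop("reaction ", rx$id, " needs substrates and products",
           call. = FALSE)
    undeclared <- setdiff(c(rx$substrates, rx$products),
                          model$metabolites$id)
    if (length(undeclared))
      stop("reaction ", rx$id, " references undeclared metabolite(s): ",
           paste(undeclared, collapse = ", "), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("<pathway_model> %s: %d reactions, %d metabolites\n",
              x$name, length(x$reactions), nrow(x$metabolites)))
  for (rx in x$reactions)
    cat(sprintf("  %-6s %s -> %s  [%s]\n", rx$id,
                paste(rx$substrates, collapse = "+"),
                paste(rx$products, collapse = "+"),
                if (is.null(rx[["gpr"]])) "spontaneous" else rx$gpr_string))
  invisible(x)
}

#' Packaged tryptophan-degradation subnetwork
#'
#' A canonical reconstruction of the kynurenine pathway (KP) plus the
#' serotonin branch and the salvage entry into NAD+. The only reaction id
#' anchored to the full-genome reconstruction is `R24a`, the committed
#' step of de novo NAD+ synthesis (QA -> NAMN, catalysed by QPRT); the
#' remaining ids are fixture-local. The spontaneous ring opening
#' 3OHAnth -> ACMS and the spontaneous cyclisation ACMS -> QA carry no
#' GPR and therefore no reaction activity score.
#'
#' @return a `pathway_model` with reactions over metabolites
#'   Trp, Kyn, KA, Anth, 3OHKyn, Xanth, 3OHAnth, ACMS, PA, QA, NAMN,
#'   NAD, 5OHTrp, Sero, NAM.
#' @export
load_trp_subnetwork <- function() {
  mets <- data.frame(
    id = c("Trp", "Kyn", "KA", "Anth", "3OHKyn", "Xanth", "3OHAnth",
           "ACMS", "PA", "QA", "NAMN", "NAD", "5OHTrp", "Sero", "NAM"),
    name = c("tryptophan", "kynurenine", "kynurenic acid",
             "anthranilic acid", "3-hydroxy-kynurenine",
             "xanthurenic acid", "3-hydroxy-anthranilic acid",
             "2-amino-3-carboxymuconate semialdehyde", "picolinic acid",
             "quinolinic acid", "nicotinic acid mononucleotide", "NAD+",
             "5-hydroxy-tryptophan", "serotonin", "nicotinamide"),
    stringsAsFactors = FALSE
  )
  rxns <- list(
    list(id = "R01", name = "Trp -> Kyn (lumped dioxygenase/formamidase)",
         substrates = "Trp", products = "Kyn",
         gpr = "IDO1 or IDO2 or TDO2"),
    list(id = "R02", name = "Kyn -> KA",
         substrates = "Kyn", products = "KA", gpr = "KYAT1 or AADAT"),
    list(id = "R03", name = "Kyn -> Anth",
         substrates = "Kyn", products = "Anth", gpr = "KYNU"),
    list(id = "R04", name = "Kyn -> 3OHKyn",
         substrates = "Kyn", products = "3OHKyn", gpr = "KMO"),
    list(id = "R05", name = "3OHKyn -> Xanth",
         substrates = "3OHKyn", products = "Xanth",
         gpr = "KYAT1 or AADAT"),
    list(id = "R06", name = "3OHKyn -> 3OHAnth",
         substrates = "3OHKyn", products = "3OHAnth", gpr = "KYNU"),
    list(id = "R07", name = "3OHAnth -> ACMS",
         substrates = "3OHAnth", products = "ACMS", gpr = "HAAO"),
    list(id = "R08", name = "ACMS -> QA (spontaneous cyclisation)",
         substrates = "ACMS", products = "QA", gpr = NULL),
    list(id = "R09", name = "ACMS -> PA",
         substrates = "ACMS", products = "PA", gpr = "ACMSD"),
    list(id = "R24a", name = "QA -> NAMN (committed de novo NAD+ step)",
         substrates = "QA", products = "NAMN", gpr = "QPRT"),
    list(id = "R10", name = "NAMN -> NAD (lumped adenylyl/amidation)",
         substrates = "NAMN", products = "NAD",
         gpr = "NMNAT1 and NADSYN1"),
    list(id = "R11", name = "Trp -> 5OHTrp",
         substrates = "Trp", products = "5OHTrp", gpr = "TPH1 or TPH2"),
    list(id = "R12", name = "5OHTrp -> Sero",
         substrates = "5OHTrp", products = "Sero", gpr = "DDC"),
    list(id = "R13", name = "NAM -> NAD (salvage entry, lumped)",
         substrates = "NAM", products = "NAD", gpr = "NAMPT and NMNAT1")
  )
  pathway_model("trp_degradation", rxns, mets)
}

#' Serialize / deserialize a pathway model as JSON
#'
#' @param model a `pathway_model`.
#' @param path file path.
#' @return `read_pathway_model()` a validated `pathway_model`;
#'   `write_pathway_model()` the path, invisibly.
#' @export
write_pathway_model <- function(model, path) {
  validate_pathway_model(model)
  obj <- list(
    name = model$name,
    reactions = lapply(model$reactions, function(rx)
      list(id = rx$id, name = rx$name, substrates = as.list(rx$substrates),
           products = as.list(rx$products),
           gpr = if (is.null(rx[["gpr"]])) NULL else rx$gpr_string)),
    metabolites = model$metabolites
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pathway_model
#' @export
read_pathway_model <- function(path) {
  obj <- jsonlite::read_json(path)
  rxns <- lapply(obj$reactions, function(rx)
    list(id = rx$id, name = rx$name,
         substrates = unlist(rx$substrates),
         products = unlist(rx$products),
         gpr = rx$gpr))
  mets <- data.frame(
    id = vapply(obj$metabolites, `[[`, "", "id"),
    name = vapply(obj$metabolites, `[[`, "", "name"),
    stringsAsFactors = FALSE
  )
  pathway_model(obj$name, rxns, mets)
}

# reaction ids reachable downstream of `from` (exclusive) via directed
# product -> substrate chains; spontaneous reactions conduct reachability
downstream_reactions <- function(model, from) {
  ids <- vapply(model$reactions, `[[`, "", "id")
  prods <- lapply(model$reactions, `[[`, "products")
  subs <- lapply(model$reactions, `[[`, "substrates")
  succ <- lapply(seq_along(ids), function(i)
    ids[vapply(subs, function(s) length(intersect(prods[[i]], s)) > 0,
               logical(1))])
  names(succ) <- ids
  seen <- character()
  frontier <- succ[[from]]
  while (length(frontier)) {
    new <- setdiff(frontier, seen)
    seen <- c(seen, new)
    frontier <- unique(unlist(succ[new]))
  }
  setdiff(seen, from)
}
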