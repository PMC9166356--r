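# Gene-protein-reaction (GPR) boolean trees.
#
# A GPR is a nested list with a `kind` field: "GENE" leaves carry `gene_id`;
# "AND"/"OR" nodes carry `children` (>= 2). AND encodes a multi-subunit
# complex (all genes required), OR encodes isoenzymes (any gene suffices).

#' Construct GPR tree nodes
#'
#' `gpr_gene()` makes a leaf; `gpr_and()`/`gpr_or()` combine two or more
#' subtrees (complex / isoenzyme semantics respectively).
#'
#' @param gene_id gene identifier for a leaf node.
#' @param ... two or more GPR subtrees.
#' @return a GPR tree (nested list of class `gpr`).
#' @export
gpr_gene <- function(gene_id) {
  stopifnot(is.character(gene_id), length(gene_id) == 1, nzchar(gene_id))
  structure(list(kind = "GENE", gene_id = gene_id), class = "gpr")
}

#' @rdname gpr_gene
#' @export
gpr_and <- function(...) .gpr_node("AND", list(...))

#' @rdname gpr_gene
#' @export
gpr_or <- function(...) .gpr_node("OR", list(...))

.gpr_node <- function(kind, children) {
  if (length(children) < 2) stop(kind, " node requires at least 2 children")
  stopifnot(all(vapply(children, inherits, logical(1), "gpr")))
  structure(list(kind = kind, children = children), class = "gpr")
}

#' Parse a GPR rule string
#'
#' Accepts the conventional textual form, e.g. `"(g1 and g2) or g3"`.
#' `and`/`or` are case-insensitive; parentheses group; `or` binds loosest.
#'
#' @param text rule string; `NA`/empty string yields `NULL` (no GPR).
#' @return a `gpr` tree or `NULL`.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(NULL)
  }
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()\\s]+", text, perl = TRUE))[[1]]
  env <- new.env()
  env$toks <- toks; env$pos <- 1L
  peek <- function() if (env$pos <= length(env$toks)) env$toks[env$pos] else NA
  take <- function() { t <- peek(); env$pos <- env$pos + 1L; t }
  parse_or <- function() {
    parts <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) %in% c("or", "|")) {
      take(); parts <- c(parts, list(parse_and()))
    }
    if (length(parts) == 1) parts[[1]] else .gpr_node("OR", parts)
  }
  parse_and <- function() {
    parts <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) %in% c("and", "&")) {
      take(); parts <- c(parts, list(parse_atom()))
    }
    if (length(parts) == 1) parts[[1]] else .gpr_node("AND", parts)
  }
  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR rule: ", text)
    if (t == "(") {
      node <- parse_or()
      if (!identical(take(), ")")) stop("unbalanced parentheses in GPR: ", text)
      return(node)
    }
    if (t == ")") stop("unexpected ')' in GPR: ", text)
    gpr_gene(t)
  }
  node <- parse_or()
  if (!is.na(peek())) stop("trailing tokens in GPR: ", text)
  node
}

#' Serialize a GPR tree to its textual rule
#'
#' @param gpr a `gpr` tree or `NULL`.
#' @return a rule string (`""` for `NULL`).
#' @export
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  rec <- function(node, parent_kind) {
    if (node$kind == "GENE") return(node$gene_id)
    op <- if (node$kind == "AND") " and " else " or "
    s <- paste(vapply(node$children, rec, character(1), node$kind), collapse = op)
    # parenthesize when nested under a different operator
    if (!is.na(parent_kind) && parent_kind != node$kind) paste0("(", s, ")") else s
  }
  rec(gpr, NA_character_)
}

#' Evaluate a GPR tree against a set of inactive genes
#'
#' Returns whether the reaction retains a functional enzyme: a GENE leaf is
#' TRUE iff the gene is not inactive; AND requires all children, OR any.
#' A `NULL` GPR (no gene association) always evaluates TRUE.
#'
#' @param gpr a `gpr` tree or `NULL`.
#' @param inactive_genes character vector of disabled gene ids.
#' @return logical scalar.
#' @export
eval_gpr <- function(gpr, inactive_genes = character(0)) {
  if (is.null(gpr)) return(TRUE)
  switch(gpr$kind,
    GENE = !(gpr$gene_id %in% inactive_genes),
    AND  = all(vapply(gpr$children, eval_gpr, logical(1), inactive_genes)),
    OR   = any(vapply(gpr$children, eval_gpr, logical(1), inactive_genes)),
    stop("unknown GPR node kind: ", gpr$kind)
  )
}

#' List the genes referenced by a GPR tree
#'
#' @param gpr a `gpr` tree or `NULL`.
#' @return character vector of unique gene ids (empty for `NULL`).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character(0))
  if (gpr$kind == "GENE") return(gpr$gene_id)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}
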