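# In-silico gene-deletion phenotyping.
#
# A gene deletion disables every reaction whose GPR evaluates false with the
# gene (plus any already-inactive genes) switched off, then re-solves the
# growth problem. A gene is essential when the knockout growth rate falls
# below 0.05 /h; genes retaining >= 0.05 /h but at most 85% of wild-type
# growth are growth-limiting.

.disabled_reactions <- function(model, inactive) {
  with_gpr <- names(model$gpr)
  with_gpr[!vapply(model$gpr, eval_gpr, logical(1), inactive)]
}

.knockout_model <- function(model, genes) {
  inactive <- union(model$inactive_genes, genes)
  for (rid in .disabled_reactions(model, inactive)) {
    model <- set_bounds(model, rid, lb = 0, ub = 0)
  }
  model
}

#' Simulate a single gene deletion
#'
#' Disables the reactions left without a functional enzyme, re-runs
#' parsimonious FBA, and classifies the gene by the knockout growth rate and
#' the importance ratio (knockout growth / wild-type growth).
#'
#' @param model a `metabolic_model`.
#' @param gene gene id to delete.
#' @param essential_threshold knockout growth rate (/h) below which the gene
#'   is essential.
#' @param limiting_fraction importance at or below which a viable knockout is
#'   growth-limiting.
#' @param wt_growth optional precomputed wild-type growth rate.
#' @return list with `gene`, `disabled_reactions`, `ko_growth`, `importance`,
#'   `call` (`"essential"`, `"growth_limiting"`, `"non_essential"`).
#' @export
single_gene_deletion <- function(model, gene, essential_threshold = 0.05,
                                 limiting_fraction = 0.85, wt_growth = NULL) {
  if (!gene %in% model$genes) stop("gene not in model: ", gene)
  if (is.null(wt_growth)) {
    wt <- fba(flux_problem(model))
    if (wt$status != "optimal") stop("wild-type FBA failed: ", wt$status)
    wt_growth <- wt$objective
  }
  inactive <- union(model$inactive_genes, gene)
  disabled <- .disabled_reactions(model, inactive)
  already <- .disabled_reactions(model, model$inactive_genes)
  disabled <- setdiff(disabled, already)
  ko <- pfba(flux_problem(.knockout_model(model, gene)))
  ko_growth <- if (ko$status == "optimal") ko$objective else 0
  importance <- ko_growth / wt_growth
  call <- if (ko_growth < essential_threshold) {
    "essential"
  } else if (importance <= limiting_fraction) {
    "growth_limiting"
  } else {
    "non_essential"
  }
  list(gene = gene, disabled_reactions = disabled, ko_growth = ko_growth,
       importance = importance, call = call)
}

#' Scan all genes for deletion phenotypes
#'
#' @inheritParams single_gene_deletion
#' @param genes genes to scan (default: all model genes not already inactive).
#' @return data.frame with columns `gene`, `ko_growth`, `importance`, `call`.
#' @export
gene_deletion_scan <- function(model, genes = NULL, essential_threshold = 0.05,
                               limiting_fraction = 0.85) {
  if (is.null(genes)) genes <- setdiff(model$genes, model$inactive_genes)
  wt <- fba(flux_problem(model))
  if (wt$status != "optimal") stop("wild-type FBA failed: ", wt$status)
  rows <- lapply(genes, function(g) {
    r <- single_gene_deletion(model, g, essential_threshold, limiting_fraction,
                              wt_growth = wt$objective)
    data.frame(gene = g, ko_growth = r$ko_growth, importance = r$importance,
               call = r$call, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Genes whose loss limits but does not abolish growth
#'
#' @inheritParams gene_deletion_scan
#' @return character vector of growth-limiting gene ids.
#' @export
growth_limiting_screen <- function(model, genes = NULL,
                                   essential_threshold = 0.05,
                                   limiting_fraction = 0.85) {
  scan <- gene_deletion_scan(model, genes, essential_threshold, limiting_fraction)
  scan$gene[scan$call == "growth_limiting"]
}

#' Reactions essential for growth
#'
#' A reaction is essential when forcing its flux to zero drops the optimal
#' growth rate below `essential_threshold`.
#'
#' @param model a `metabolic_model`.
#' @param essential_threshold growth-rate cut-off (/h).
#' @return character vector of reaction ids.
#' @export
essential_reactions <- function(model, essential_threshold = 0.05) {
  Filter(function(rid) {
    ko <- fba(flux_problem(model, bounds = stats::setNames(list(c(0, 0)), rid)))
    ko$status != "optimal" || ko$objective < essential_threshold
  }, model$reactions$id)
}

#' Deactivate lowly expressed isoenzymes
#'
#' For every reaction that is essential in the unconstrained model and has an
#' OR-type (isoenzyme) GPR, keeps the most expressed isoenzyme gene and marks
#' any isoenzyme expressed at least `fold`-fold lower as inactive. The
#' returned model can be re-used for essentiality calls, where the silent
#' partner no longer rescues the expressed gene.
#'
#' @param model a `metabolic_model`.
#' @param expression named numeric vector of RPKM values per gene.
#' @param fold expression ratio at or beyond which an isoenzyme is silenced.
#' @param essential_threshold growth-rate cut-off defining an essential
#'   reaction (flux forced to zero).
#' @return list with `model` (with updated `inactive_genes`) and
#'   `deactivated` (character vector).
#' @export
deactivate_lowly_expressed_isoenzymes <- function(model, expression, fold = 5,
                                                  essential_threshold = 0.05) {
  wt <- fba(flux_problem(model))
  if (wt$status != "optimal") stop("wild-type FBA failed: ", wt$status)
  deactivated <- character(0)
  or_rxns <- names(model$gpr)[vapply(model$gpr, function(g) g$kind == "OR",
                                     logical(1))]
  for (rid in or_rxns) {
    ko <- fba(flux_problem(model, bounds = stats::setNames(list(c(0, 0)), rid)))
    ko_growth <- if (ko$status == "optimal") ko$objective else 0
    if (ko_growth >= essential_threshold) next  # reaction not essential
    iso <- gpr_genes(model$gpr[[rid]])
    expr <- expression[iso]
    if (anyNA(expr)) {
      warning("missing expression for isoenzyme(s) of ", rid, ": ",
              paste(iso[is.na(expr)], collapse = ", "), "; skipped")
      iso <- iso[!is.na(expr)]; expr <- expr[!is.na(expr)]
      if (length(iso) < 2) next
    }
    top <- max(expr)
    silent <- iso[expr <= top / fold & iso != iso[which.max(expr)]]
    deactivated <- union(deactivated, silent)
  }
  model$inactive_genes <- union(model$inactive_genes, deactivated)
  list(model = model, deactivated = deactivated)
}

#' Compare predicted and observed essentiality calls
#'
#' Builds the confusion matrix over the shared gene universe (genes
#' unclassified on either side are excluded) and reports accuracy, precision
#' and recall with "essential" as the positive class.
#'
#' @param predicted,observed named character vectors with values
#'   `"essential"` / `"non_essential"` (any other value is treated as
#'   unclassified and dropped).
#' @return list with `confusion` (TP, FN, FP, TN), `accuracy`, `precision`,
#'   `recall` (a metric with zero denominator is `NA`).
#' @export
compare_essentiality <- function(predicted, observed) {
  keep_p <- names(predicted)[predicted %in% c("essential", "non_essential")]
  keep_o <- names(observed)[observed %in% c("essential", "non_essential")]
  common <- intersect(keep_p, keep_o)
  if (length(common) == 0) stop("no genes classified on both sides")
  p <- predicted[common] == "essential"
  o <- observed[common] == "essential"
  conf <- c(TP = sum(p & o), FN = sum(!p & o), FP = sum(p & !o), TN = sum(!p & !o))
  metrics_from_confusion(conf)
}

#' Accuracy, precision and recall from a confusion matrix
#'
#' `accuracy = (TP+TN)/(TP+FN+FP+TN)`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)`.
#'
#' @param confusion named numeric vector with entries TP, FN, FP, TN.
#' @return list with `confusion`, `accuracy`, `precision`, `recall`.
#' @export
metrics_from_confusion <- function(confusion) {
  tp <- confusion[["TP"]]; fn <- confusion[["FN"]]
  fp <- confusion[["FP"]]; tn <- confusion[["TN"]]
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  list(confusion = c(TP = tp, FN = fn, FP = fp, TN = tn),
       accuracy = safe_div(tp + tn, tp + fn + fp + tn),
       precision = safe_div(tp, tp + fp),
       recall = safe_div(tp, tp + fn))
}
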