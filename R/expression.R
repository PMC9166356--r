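# Expression-to-reaction mapping, iMAT category thresholds, the iMAT MILP
# for condition-specific models, and growth-rate estimation from biomass
# curves.

#' Map gene expression onto reactions through the GPR logic
#'
#' Recursive over the GPR tree: an OR node (isoenzymes) sums its children,
#' an AND node (complex) takes the minimum, a leaf reads the gene's RPKM.
#' Genes missing from the profile contribute 0 with a warning. Reactions
#' without a GPR receive `NA` (they default to the moderate category).
#'
#' @param model a `metabolic_model`.
#' @param profile data.frame with a `gene_id` column and one `rpkm_<label>`
#'   column per condition, or a named numeric vector of RPKM values.
#' @param condition condition label selecting the `rpkm_<condition>` column
#'   (ignored when `profile` is already a vector).
#' @return named numeric vector of reaction expression values (NA where no
#'   GPR).
#' @export
map_expression_to_reactions <- function(model, profile, condition = NULL) {
  if (is.data.frame(profile)) {
    col <- paste0("rpkm_", condition)
    if (!col %in% names(profile)) stop("profile lacks column ", col)
    rpkm <- stats::setNames(profile[[col]], profile$gene_id)
  } else {
    rpkm <- profile
  }
  needed <- unique(unlist(lapply(model$gpr, gpr_genes)))
  missing <- setdiff(needed, names(rpkm))
  if (length(missing) > 0) {
    warning("no expression for gene(s): ", paste(missing, collapse = ", "),
            "; treated as 0")
    rpkm[missing] <- 0
  }
  eval_expr <- function(node) {
    switch(node$kind,
      GENE = unname(rpkm[node$gene_id]),
      OR   = sum(vapply(node$children, eval_expr, numeric(1))),
      AND  = min(vapply(node$children, eval_expr, numeric(1)))
    )
  }
  out <- stats::setNames(rep(NA_real_, nrow(model$reactions)),
                         model$reactions$id)
  for (rid in names(model$gpr)) out[rid] <- eval_expr(model$gpr[[rid]])
  out
}

#' Weight reaction expression by fold change
#'
#' For the condition of interest, multiplies the absolute reaction expression
#' by its fold change relative to a reference condition (with a pseudocount
#' to guard against zeros), so reactions with high absolute expression and/or
#' high fold change are up-weighted.
#'
#' @param rx_expr_base reaction expression in the condition of interest.
#' @param rx_expr_reference reaction expression in the reference condition.
#' @param pseudocount added to numerator and denominator of the fold change.
#' @return named numeric vector of weighted expression values.
#' @export
weight_condition_expression <- function(rx_expr_base, rx_expr_reference,
                                        pseudocount = 1) {
  common <- intersect(names(rx_expr_base), names(rx_expr_reference))
  fc <- (rx_expr_base[common] + pseudocount) /
    (rx_expr_reference[common] + pseudocount)
  rx_expr_base[common] * fc
}

#' Derive iMAT expression-category thresholds
#'
#' The high cut-off is the 95th percentile of the reaction expression
#' distribution. The low cut-off is the minimal expression among reactions
#' essential in the model, after excluding outliers below
#' `Q1 - 1.5 IQR` of the essential-reaction distribution — this guarantees
#' essential reactions are not penalized as lowly expressed.
#'
#' @param rx_expr named numeric reaction expression vector (NA entries are
#'   ignored).
#' @param model_essential_reactions reaction ids essential in the model.
#' @param high_pct percentile for the high cut.
#' @return list with `low_cut` and `high_cut`.
#' @export
derive_imat_thresholds <- function(rx_expr, model_essential_reactions,
                                   high_pct = 0.95) {
  vals <- rx_expr[!is.na(rx_expr)]
  high_cut <- unname(stats::quantile(vals, high_pct, type = 7))
  ess <- rx_expr[intersect(model_essential_reactions, names(vals))]
  ess <- ess[!is.na(ess)]
  if (length(ess) == 0) stop("empty essential reaction set")
  q <- stats::quantile(ess, c(0.25, 0.75), type = 7)
  lo_fence <- q[[1]] - 1.5 * (q[[2]] - q[[1]])
  kept <- ess[ess >= lo_fence]
  list(low_cut = min(kept), high_cut = high_cut)
}

#' Assign iMAT categories to reactions
#'
#' `value <= low_cut` is low, `value >= high_cut` high, otherwise moderate.
#' Reactions without expression (no GPR) are moderate.
#'
#' @param rx_expr named numeric reaction expression vector.
#' @param low_cut,high_cut category thresholds.
#' @return named character vector (`"low"`, `"moderate"`, `"high"`).
#' @export
assign_imat_categories <- function(rx_expr, low_cut, high_cut) {
  cat <- ifelse(is.na(rx_expr), "moderate",
                ifelse(rx_expr <= low_cut, "low",
                       ifelse(rx_expr >= high_cut, "high", "moderate")))
  stats::setNames(cat, names(rx_expr))
}

#' Build a condition-specific model with iMAT
#'
#' Solves the iMAT mixed-integer program: maximize the number of active
#' (|v| >= epsilon) reactions in the high category plus inactive
#' (|v| < epsilon) reactions in the low category, subject to steady state,
#' bounds, a minimum growth rate, and nutrient caps. Suppressed low
#' reactions (indicator satisfied) have their bounds clamped to
#' (-epsilon, epsilon) in the returned model.
#'
#' @param model a `metabolic_model`.
#' @param categories named character vector from [assign_imat_categories()].
#' @param epsilon activity threshold flux (mmol/gDCW/h).
#' @param growth_rate minimum growth rate to impose (/h).
#' @param nutrient_caps named list of `c(lb, ub)` bound overrides (e.g. a
#'   fixed substrate uptake or a nitrogen cap).
#' @return list of class `condition_specific_model` with fields `model` (the
#'   clamped model), `active` (high reactions active), `suppressed` (low
#'   reactions held near zero), `objective` (iMAT score), `fluxes` (the MILP
#'   flux vector), `growth_rate`, `epsilon`.
#' @export
imat <- function(model, categories, epsilon = 0.1, growth_rate = 0,
                 nutrient_caps = list()) {
  N <- stoichiometric_matrix(model)
  n <- ncol(N)
  rids <- colnames(N)
  lb <- stats::setNames(model$reactions$lower_bound, rids)
  ub <- stats::setNames(model$reactions$upper_bound, rids)
  for (rid in names(nutrient_caps)) {
    lb[rid] <- nutrient_caps[[rid]][1]; ub[rid] <- nutrient_caps[[rid]][2]
  }
  lb[model$biomass_reaction_id] <- max(lb[model$biomass_reaction_id], growth_rate)
  if (lb[model$biomass_reaction_id] > ub[model$biomass_reaction_id]) {
    stop("infeasible iMAT setup: growth constraint exceeds the biomass ",
         "upper bound")
  }
  high <- names(categories)[categories == "high"]
  low <- names(categories)[categories == "low"]
  high <- intersect(high, rids); low <- intersect(low, rids)

  # variables: v (n) | yhf, yhr per high reaction | yl per low reaction
  nh <- length(high); nl <- length(low)
  nv <- n + 2 * nh + nl
  iv <- function(rid) match(rid, rids)
  A <- matrix(0, 0, nv); dir <- character(0); rhs <- numeric(0)
  add_row <- function(idx, coef, d, r) {
    row <- numeric(nv); row[idx] <- coef
    A <<- rbind(A, row); dir <<- c(dir, d); rhs <<- c(rhs, r)
  }
  A <- cbind(N, matrix(0, nrow(N), 2 * nh + nl))
  dir <- rep("=", nrow(N)); rhs <- rep(0, nrow(N))
  for (k in seq_along(high)) {
    i <- iv(high[k]); yf <- n + k; yr <- n + nh + k
    # yf = 1 -> v_i >= epsilon ; yr = 1 -> v_i <= -epsilon
    add_row(c(i, yf), c(1, -(epsilon - lb[i])), ">=", lb[i])
    add_row(c(i, yr), c(1, (epsilon + ub[i])), "<=", ub[i])
    add_row(c(yf, yr), c(1, 1), "<=", 1)
  }
  for (k in seq_along(low)) {
    i <- iv(low[k]); y <- n + 2 * nh + k
    # y = 1 -> -epsilon <= v_i <= epsilon
    add_row(c(i, y), c(1, ub[i] - epsilon), "<=", ub[i])
    add_row(c(i, y), c(1, lb[i] + epsilon), ">=", lb[i])
  }
  obj <- c(rep(0, n), rep(1, 2 * nh + nl))
  lbv <- c(lb, rep(0, 2 * nh + nl))
  ubv <- c(ub, rep(1, 2 * nh + nl))
  sol <- solve_milp(obj, A, dir, rhs, lbv, ubv,
                    int_idx = n + seq_len(2 * nh + nl), sense = "max")
  if (sol$status != "optimal") {
    stop("iMAT MILP infeasible under the growth and nutrient constraints")
  }
  v <- stats::setNames(sol$x[seq_len(n)], rids)
  yh <- if (nh > 0) sol$x[n + seq_len(nh)] + sol$x[n + nh + seq_len(nh)] else numeric(0)
  yl <- if (nl > 0) sol$x[n + 2 * nh + seq_len(nl)] else numeric(0)
  active <- high[yh > 0.5]
  suppressed <- low[yl > 0.5]
  out <- model
  for (rid in names(nutrient_caps)) {
    out <- set_bounds(out, rid, lb = nutrient_caps[[rid]][1],
                      ub = nutrient_caps[[rid]][2])
  }
  out <- set_bounds(out, model$biomass_reaction_id,
                    lb = lb[[model$biomass_reaction_id]])
  for (rid in suppressed) {
    out <- set_bounds(out, rid, lb = max(lb[[rid]], -epsilon),
                      ub = min(ub[[rid]], epsilon))
  }
  structure(list(model = out, active = active, suppressed = suppressed,
                 objective = round(sol$objective), fluxes = v,
                 growth_rate = growth_rate, epsilon = epsilon),
            class = "condition_specific_model")
}

#' Save a condition-specific model in the package JSON schema
#'
#' Writes the clamped model with an annotation block recording how it was
#' derived (iMAT score, active and suppressed sets, epsilon, growth
#' constraint), so a reloaded model documents its provenance.
#'
#' @param csm a `condition_specific_model`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_condition_model <- function(csm, path) {
  stopifnot(inherits(csm, "condition_specific_model"))
  write_model_json(csm$model, path)
  raw <- jsonlite::read_json(path)
  raw$annotation <- list(
    derivation = "imat_condition_specific",
    imat_objective = csm$objective,
    active = as.list(csm$active),
    suppressed = as.list(csm$suppressed),
    epsilon = csm$epsilon,
    growth_rate = csm$growth_rate)
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.condition_specific_model <- function(x, ...) {
  cat("condition_specific_model: iMAT score", x$objective, "\n")
  cat("  active high reactions:", paste(x$active, collapse = ", "), "\n")
  cat("  suppressed low reactions:", paste(x$suppressed, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate a growth rate from a biomass time series
#'
#' Logistic mode fits `X(t) = K / (1 + ((K - X0)/X0) exp(-r t))` by
#' nonlinear least squares and returns the exponential-phase rate constant
#' `r`. Linear mode (for a linear-accumulation phase such as nitrogen
#' depletion) fits a straight line and returns slope divided by mean biomass
#' as the specific rate.
#'
#' @param time numeric vector of times (h).
#' @param biomass numeric vector of biomass concentrations (gDCW/L).
#' @param mode `"logistic"` or `"linear"`.
#' @return estimated specific growth rate (/h).
#' @export
estimate_growth_rate <- function(time, biomass, mode = c("logistic", "linear")) {
  mode <- match.arg(mode)
  if (length(time) < 4) stop("need at least 4 time points")
  if (mode == "linear") {
    fit <- stats::lm(biomass ~ time)
    return(unname(stats::coef(fit)[2]) / mean(biomass))
  }
  if (stats::sd(biomass) < 1e-12) return(0)
  K0 <- max(biomass) * 1.05
  X00 <- max(min(biomass[biomass > 0], na.rm = TRUE), 1e-6)
  r0 <- {
    pos <- biomass > 0
    if (sum(pos) >= 2) {
      max(stats::coef(stats::lm(log(biomass[pos]) ~ time[pos]))[2], 0.01)
    } else 0.1
  }
  fit <- try(minpack.lm::nlsLM(
    biomass ~ K / (1 + ((K - X0) / X0) * exp(-r * time)),
    start = list(K = K0, X0 = X00, r = r0),
    lower = c(K = 1e-9, X0 = 1e-9, r = 0),
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("logistic fit did not converge: ", attr(fit, "condition")$message)
  }
  unname(stats::coef(fit)[["r"]])
}
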