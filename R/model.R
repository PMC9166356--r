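# Metabolic model container and validation checks.
#
# A `metabolic_model` is an S3 list with:
#   metabolites : data.frame(id, name, compartment, is_external)
#   formulas    : named list of named integer vectors (element -> count)
#   reactions   : data.frame(id, lower_bound, upper_bound, subsystem)
#   stoich      : named list (reaction id -> named numeric, metabolite -> coeff;
#                 negative = consumed, positive = produced)
#   gpr         : named list (reaction id -> gpr tree or NULL)
#   genes       : character
#   biomass_reaction_id, atpm_reaction_id : reaction ids
#   gam, ngam   : maintenance parameters (mmol ATP/gDCW, mmol/gDCW/h)
#   inactive_genes : genes switched off (e.g. silent isoenzymes)
#   transporter_override : optional explicit transporter id list
#
# Transport reactions follow the "_tx" id suffix convention and are written
# in the import direction: positive flux brings the metabolite in, and the
# upper bound is the allowed uptake rate. External metabolites carry the
# "x_" id prefix.

#' Construct a metabolic model
#'
#' Assembles and link-checks a model from its parts. Every stoichiometry key
#' must resolve to a metabolite, every GPR leaf to a gene, and the biomass
#' and ATP-maintenance ids to reactions.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (`cytosol`, `periplasm` or `external`), `is_external`.
#' @param formulas named list of named numeric vectors, element -> atom count.
#' @param reactions data.frame with columns `id`, `lower_bound`, `upper_bound`,
#'   and optionally `subsystem`.
#' @param stoich named list: reaction id -> named numeric coefficient vector.
#' @param gpr named list: reaction id -> `gpr` tree (entries may be absent).
#' @param genes character vector of gene ids.
#' @param biomass_reaction_id,atpm_reaction_id designated reaction ids.
#' @param gam,ngam growth-associated (mmol ATP/gDCW) and non-growth-associated
#'   (mmol/gDCW/h) maintenance values.
#' @param transporter_override optional character vector overriding the
#'   `_tx`-suffix transporter convention.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, formulas, reactions, stoich, gpr,
                            genes, biomass_reaction_id, atpm_reaction_id,
                            gam = NA_real_, ngam = NA_real_,
                            transporter_override = NULL) {
  stopifnot(!anyDuplicated(metabolites$id), !anyDuplicated(reactions$id))
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (any(reactions$lower_bound > reactions$upper_bound)) {
    bad <- reactions$id[reactions$lower_bound > reactions$upper_bound]
    stop("lower_bound > upper_bound for reaction(s): ", paste(bad, collapse = ", "))
  }
  stoich <- stoich[reactions$id]
  names(stoich) <- reactions$id
  for (rid in reactions$id) {
    s <- stoich[[rid]]
    if (is.null(s) || length(s) == 0) stop("empty stoichiometry for reaction ", rid)
    missing_met <- setdiff(names(s), metabolites$id)
    if (length(missing_met) > 0) {
      stop("reaction ", rid, " references undefined metabolite(s): ",
           paste(missing_met, collapse = ", "))
    }
  }
  gpr <- gpr[intersect(names(gpr), reactions$id)]
  for (rid in names(gpr)) {
    missing_gene <- setdiff(gpr_genes(gpr[[rid]]), genes)
    if (length(missing_gene) > 0) {
      stop("GPR of reaction ", rid, " references undefined gene(s): ",
           paste(missing_gene, collapse = ", "))
    }
  }
  for (mid in names(formulas)) {
    f <- formulas[[mid]]
    if (any(f < 0)) stop("negative atom count in formula of ", mid)
  }
  if (!biomass_reaction_id %in% reactions$id) {
    stop("biomass reaction id does not resolve: ", biomass_reaction_id)
  }
  if (!atpm_reaction_id %in% reactions$id) {
    stop("ATPM reaction id does not resolve: ", atpm_reaction_id)
  }
  structure(list(
    metabolites = metabolites, formulas = formulas, reactions = reactions,
    stoich = stoich, gpr = gpr, genes = genes,
    biomass_reaction_id = biomass_reaction_id,
    atpm_reaction_id = atpm_reaction_id,
    gam = gam, ngam = ngam,
    inactive_genes = character(0),
    transporter_override = transporter_override
  ), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("metabolic_model:", nrow(x$metabolites), "metabolites,",
      nrow(x$reactions), "reactions,", length(x$genes), "genes\n")
  cat("  biomass:", x$biomass_reaction_id, " ATPM:", x$atpm_reaction_id, "\n")
  if (length(x$inactive_genes) > 0) {
    cat("  inactive genes:", paste(x$inactive_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Transporter reaction ids
#'
#' Transporters are identified by the `_tx` id suffix, unless the model
#' carries an explicit override list.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
transporter_ids <- function(model) {
  if (!is.null(model$transporter_override)) return(model$transporter_override)
  grep("_tx$", model$reactions$id, value = TRUE)
}

#' Set flux bounds on a reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to modify.
#' @param lb,ub new bounds (either may be `NULL` to keep the current value).
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("unknown reaction: ", reaction_id)
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  model
}

# ---------------------------------------------------------------------------
# JSON I/O

#' Read / write a metabolic model in the package JSON schema
#'
#' The schema is a single JSON object with fields `metabolites` (array of
#' \{id, name, formula, compartment, is_external\}), `reactions` (array of
#' \{id, stoichiometry, lower_bound, upper_bound, gpr, subsystem\} with `gpr`
#' a textual rule such as `"(g1 and g2) or g3"`), `genes`, `biomass_reaction`,
#' `atpm_reaction`, `gam`, `ngam`. Coefficients are signed decimals; bounds
#' are in mmol/gDCW/h. Unknown top-level fields are ignored with a warning.
#'
#' @param path file path.
#' @param format only `"json"` is supported.
#' @return `read_model_json()` returns a `metabolic_model`;
#'   `write_model_json()` returns `path` invisibly.
#' @export
read_model_json <- function(path, format = "json") {
  stopifnot(identical(format, "json"))
  if (!file.exists(path)) stop("model file not found: ", path)
  raw <- jsonlite::read_json(path)
  known <- c("id", "metabolites", "reactions", "genes", "biomass_reaction",
             "atpm_reaction", "gam", "ngam", "annotation")
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    warning("ignoring unknown model field(s): ", paste(extra, collapse = ", "))
  }
  req <- c("metabolites", "reactions", "genes", "biomass_reaction", "atpm_reaction")
  miss <- setdiff(req, names(raw))
  if (length(miss) > 0) stop("model JSON missing field(s): ", paste(miss, collapse = ", "))

  mets <- do.call(rbind, lapply(raw$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite record without id")
    data.frame(id = m$id, name = m$name %||% m$id,
               compartment = m$compartment %||% "cytosol",
               is_external = isTRUE(m$is_external), stringsAsFactors = FALSE)
  }))
  formulas <- stats::setNames(lapply(raw$metabolites, function(m) {
    if (is.null(m$formula)) return(NULL)
    unlist(m$formula)
  }), mets$id)
  formulas <- formulas[!vapply(formulas, is.null, logical(1))]

  rxn <- do.call(rbind, lapply(raw$reactions, function(r) {
    if (is.null(r$id)) stop("reaction record without id")
    if (is.null(r$stoichiometry) || length(r$stoichiometry) == 0) {
      stop("reaction ", r$id, " has empty stoichiometry")
    }
    data.frame(id = r$id,
               lower_bound = r$lower_bound %||% -1000,
               upper_bound = r$upper_bound %||% 1000,
               subsystem = r$subsystem %||% "", stringsAsFactors = FALSE)
  }))
  stoich <- stats::setNames(lapply(raw$reactions, function(r) unlist(r$stoichiometry)),
                            rxn$id)
  gpr <- stats::setNames(lapply(raw$reactions, function(r) parse_gpr(r$gpr)), rxn$id)
  gpr <- gpr[!vapply(gpr, is.null, logical(1))]

  metabolic_model(
    metabolites = mets, formulas = formulas, reactions = rxn, stoich = stoich,
    gpr = gpr, genes = unlist(raw$genes),
    biomass_reaction_id = raw$biomass_reaction,
    atpm_reaction_id = raw$atpm_reaction,
    gam = raw$gam %||% NA_real_, ngam = raw$ngam %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_model_json
#' @param model a `metabolic_model`.
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment,
                is_external = m$is_external)
    f <- model$formulas[[m$id]]
    if (!is.null(f)) out$formula <- as.list(f)
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    out <- list(id = r$id, stoichiometry = as.list(model$stoich[[r$id]]),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                subsystem = r$subsystem)
    g <- model$gpr[[r$id]]
    if (!is.null(g)) out$gpr <- deparse_gpr(g)
    out
  })
  obj <- list(metabolites = mets, reactions = rxns, genes = as.list(model$genes),
              biomass_reaction = model$biomass_reaction_id,
              atpm_reaction = model$atpm_reaction_id,
              gam = model$gam, ngam = model$ngam)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Stoichiometric matrix and validation checks

#' Build the stoichiometric matrix
#'
#' Entry (i, j) is the coefficient of metabolite i in reaction j. External
#' metabolites (the `x_` pool outside the cell) are excluded from the balanced
#' row set by default, so that `N v = 0` expresses steady state over internal
#' metabolites only.
#'
#' @param model a `metabolic_model`.
#' @param drop_external exclude external metabolites from the rows.
#' @return numeric matrix with metabolite ids as rownames and reaction ids as
#'   colnames.
#' @export
stoichiometric_matrix <- function(model, drop_external = TRUE) {
  mets <- model$metabolites
  if (drop_external) mets <- mets[!mets$is_external, , drop = FALSE]
  N <- matrix(0, nrow(mets), nrow(model$reactions),
              dimnames = list(mets$id, model$reactions$id))
  for (rid in model$reactions$id) {
    s <- model$stoich[[rid]]
    keep <- intersect(names(s), mets$id)
    N[keep, rid] <- s[keep]
  }
  N
}

#' Check elemental balance of internal reactions
#'
#' Sums `coefficient x atom count` per element for every reaction other than
#' transporters, the biomass reaction and the ATP-maintenance reaction.
#' A balanced model returns a zero-row data frame.
#'
#' @param model a `metabolic_model`.
#' @param elements elements to check.
#' @param tol absolute imbalance below which a reaction counts as balanced.
#' @return data.frame with columns `reaction_id`, `element`, `imbalance`.
#' @export
check_atom_balance <- function(model,
                               elements = c("C", "H", "N", "O", "P", "S"),
                               tol = 1e-6) {
  skip <- c(transporter_ids(model), model$biomass_reaction_id,
            model$atpm_reaction_id)
  check_rxns <- setdiff(model$reactions$id, skip)
  external <- model$metabolites$id[model$metabolites$is_external]
  rows <- list()
  for (rid in check_rxns) {
    s <- model$stoich[[rid]]
    mets <- setdiff(names(s), external)
    nofor <- mets[!mets %in% names(model$formulas)]
    if (length(nofor) > 0) {
      stop("missing formula for metabolite(s) in reaction ", rid, ": ",
           paste(nofor, collapse = ", "))
    }
    for (el in elements) {
      net <- sum(vapply(mets, function(m) {
        f <- model$formulas[[m]]
        s[[m]] * (if (el %in% names(f)) f[[el]] else 0)
      }, numeric(1)))
      if (abs(net) > tol) {
        rows[[length(rows) + 1L]] <- data.frame(
          reaction_id = rid, element = el, imbalance = net,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(reaction_id = character(0), element = character(0),
                      imbalance = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Find unconserved metabolites
#'
#' A metabolite is conserved when it can carry a strictly positive weight in
#' some conservation relation `m' N_internal = 0` (molecular weights are one
#' such relation for a mass-balanced network). The set of metabolites that
#' cannot is found with a linear program that maximizes the number of
#' metabolites whose weight can reach 1, over the internal (non-transport,
#' non-biomass) reactions. An empty set certifies stoichiometric consistency.
#'
#' @param model a `metabolic_model`.
#' @param tol threshold below 1 at which a weight indicator counts as failed.
#' @return character vector of unconserved metabolite ids (possibly empty).
#' @export
find_unconserved_metabolites <- function(model, tol = 1e-6) {
  internal_rxns <- setdiff(model$reactions$id,
                           c(transporter_ids(model), model$biomass_reaction_id))
  if (length(internal_rxns) == 0) return(character(0))
  N <- stoichiometric_matrix(model, drop_external = TRUE)
  N <- N[, internal_rxns, drop = FALSE]
  use <- rownames(N)[rowSums(N != 0) > 0]
  if (length(use) == 0) return(character(0))
  N <- N[use, , drop = FALSE]
  nm <- length(use)
  # variables: m (weights, [0, cap]) then z (indicators, [0, 1])
  # constraints: N' m = 0 ; m - z >= 0 ; maximize sum(z)
  A_eq <- cbind(t(N), matrix(0, ncol(N), nm))
  A_ge <- cbind(diag(nm), -diag(nm))
  A <- rbind(A_eq, A_ge)
  dir <- c(rep("=", nrow(A_eq)), rep(">=", nm))
  rhs <- rep(0, nrow(A))
  obj <- c(rep(0, nm), rep(1, nm))
  sol <- solve_lp(obj, A, dir, rhs,
                  lb = rep(0, 2 * nm), ub = c(rep(1e4, nm), rep(1, nm)))
  if (sol$status != "optimal") stop("conservation LP failed: ", sol$status)
  z <- sol$x[nm + seq_len(nm)]
  use[z < 1 - tol]
}

#' Check for erroneous energy-generating cycles
#'
#' Maximizes flux through the ATP-maintenance reaction while all transporter
#' uptakes are closed (no carbon or energy source enters the cell). Any
#' positive optimum reveals a thermodynamically impossible internal cycle
#' that generates ATP from nothing.
#'
#' @param model a `metabolic_model`.
#' @param tol flux below which the result counts as zero.
#' @return list with `flux` (max ATPM flux; 0 when the closed problem is
#'   infeasible) and `status`.
#' @export
check_energy_cycles <- function(model, tol = 1e-6) {
  for (rid in transporter_ids(model)) {
    s <- model$stoich[[rid]]
    ext <- names(s)[startsWith(names(s), "x_")]
    imports_forward <- length(ext) == 0 || any(s[ext] < 0)
    if (imports_forward) {
      model <- set_bounds(model, rid, ub = 0)
      i <- match(rid, model$reactions$id)
      if (model$reactions$lower_bound[i] > 0) model <- set_bounds(model, rid, lb = 0)
    } else {
      model <- set_bounds(model, rid, lb = 0)
    }
  }
  # ATPM lower bound (NGAM) must be released for the closed test
  model <- set_bounds(model, model$atpm_reaction_id, lb = 0)
  obj <- stats::setNames(1, model$atpm_reaction_id)
  sol <- fba(flux_problem(model, objective = obj))
  if (sol$status != "optimal") return(list(flux = 0, status = sol$status))
  flux <- if (abs(sol$objective) < tol) 0 else sol$objective
  list(flux = flux, status = "optimal")
}

#' Run all theoretical-validation checks
#'
#' Combines the elemental-balance check, the unconserved-metabolite scan and
#' the closed-uptake energy-cycle test into a single report.
#'
#' @param model a `metabolic_model`.
#' @param tol numeric tolerance shared by the three checks.
#' @return list of class `validation_report` with fields
#'   `imbalanced_reactions`, `unconserved_metabolites`, `energy_cycle_flux`,
#'   `passed`.
#' @export
validate_model <- function(model, tol = 1e-6) {
  imb <- check_atom_balance(model, tol = tol)
  unc <- find_unconserved_metabolites(model, tol = tol)
  ec <- check_energy_cycles(model, tol = tol)
  structure(list(
    imbalanced_reactions = imb,
    unconserved_metabolites = unc,
    energy_cycle_flux = ec$flux,
    passed = nrow(imb) == 0 && length(unc) == 0 && abs(ec$flux) <= tol
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("validation_report:", if (x$passed) "PASSED" else "FAILED", "\n")
  cat("  imbalanced reactions:", nrow(x$imbalanced_reactions), "\n")
  cat("  unconserved metabolites:", length(x$unconserved_metabolites), "\n")
  cat("  energy-cycle ATPM flux:", format(x$energy_cycle_flux), "\n")
  invisible(x)
}

#' Write a validation report as TSV plus a readable log
#'
#' @param report a `validation_report`.
#' @param path output TSV path (imbalances); a `.log` sibling summarizes all
#'   three checks.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  utils::write.table(report$imbalanced_reactions, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log <- c(
    paste("validation passed:", report$passed),
    paste("imbalanced reactions:", nrow(report$imbalanced_reactions)),
    paste("unconserved metabolites:",
          paste(report$unconserved_metabolites, collapse = ", ")),
    paste("energy-cycle ATPM flux:", report$energy_cycle_flux)
  )
  writeLines(log, sub("\\.tsv$", ".log", path))
  invisible(path)
}
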