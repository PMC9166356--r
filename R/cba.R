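# Constraint-based analyses: FBA, parsimonious FBA, flux variability,
# carbon-source phenotype screening, biomass-precursor diagnostics, flux
# normalization/correlation, and the P/O ratio.

#' Define a flux problem
#'
#' Bundles a model with an objective, optional bound overrides and an
#' optimization sense. The default objective is the biomass reaction.
#'
#' @param model a `metabolic_model`.
#' @param objective named numeric vector of objective weights per reaction id;
#'   default puts weight 1 on the biomass reaction.
#' @param bounds named list of `c(lb, ub)` overrides per reaction id.
#' @param sense `"max"` or `"min"`.
#' @return object of class `flux_problem`.
#' @export
flux_problem <- function(model, objective = NULL, bounds = list(),
                         sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.null(objective)) {
    objective <- stats::setNames(1, model$biomass_reaction_id)
  }
  bad <- setdiff(names(objective), model$reactions$id)
  if (length(bad) > 0) stop("objective references unknown reaction(s): ",
                            paste(bad, collapse = ", "))
  bad <- setdiff(names(bounds), model$reactions$id)
  if (length(bad) > 0) stop("bound override for unknown reaction(s): ",
                            paste(bad, collapse = ", "))
  structure(list(model = model, objective = objective, bounds = bounds,
                 sense = sense), class = "flux_problem")
}

.problem_bounds <- function(problem) {
  rx <- problem$model$reactions
  lb <- stats::setNames(rx$lower_bound, rx$id)
  ub <- stats::setNames(rx$upper_bound, rx$id)
  for (rid in names(problem$bounds)) {
    lb[rid] <- problem$bounds[[rid]][1]
    ub[rid] <- problem$bounds[[rid]][2]
  }
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Solves `max c'v` subject to `N v = 0` and box bounds — the steady-state
#' linear program over the internal metabolite set.
#'
#' @param problem a [flux_problem()].
#' @return object of class `flux_solution`: list with `fluxes` (named vector),
#'   `objective`, `status` (`"optimal"`, `"infeasible"`, `"unbounded"`).
#' @export
fba <- function(problem) {
  stopifnot(inherits(problem, "flux_problem"))
  model <- problem$model
  N <- stoichiometric_matrix(model)
  b <- .problem_bounds(problem)
  obj <- stats::setNames(numeric(ncol(N)), colnames(N))
  obj[names(problem$objective)] <- problem$objective
  sol <- solve_lp(obj, N, rep("=", nrow(N)), rep(0, nrow(N)),
                  lb = b$lb, ub = b$ub, sense = problem$sense)
  fluxes <- if (sol$status == "optimal") {
    stats::setNames(sol$x, colnames(N))
  } else {
    stats::setNames(rep(NA_real_, ncol(N)), colnames(N))
  }
  structure(list(fluxes = fluxes, objective = sol$objective,
                 status = sol$status), class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("flux_solution:", x$status, " objective =", format(x$objective), "\n")
  invisible(x)
}

#' Parsimonious flux balance analysis
#'
#' First solves the FBA problem, then fixes the optimum `c'v = Z` and
#' minimizes the total absolute flux `sum |v|` by splitting each flux into
#' non-negative forward and backward components. The returned objective
#' equals the FBA optimum; `total_flux` carries the minimized sum.
#'
#' @param problem a [flux_problem()].
#' @return a `flux_solution` with an extra `total_flux` field.
#' @export
pfba <- function(problem) {
  base <- fba(problem)
  if (base$status != "optimal") return(base)
  model <- problem$model
  N <- stoichiometric_matrix(model)
  n <- ncol(N)
  b <- .problem_bounds(problem)
  obj_full <- stats::setNames(numeric(n), colnames(N))
  obj_full[names(problem$objective)] <- problem$objective

  # variables: v+ (n) then v- (n); v = v+ - v-
  A_ss <- cbind(N, -N)
  A_fix <- matrix(c(obj_full, -obj_full), nrow = 1)
  A <- rbind(A_ss, A_fix)
  dir <- c(rep("=", nrow(N)), "=")
  rhs <- c(rep(0, nrow(N)), base$objective)
  # enforce original bounds where the split alone is not enough
  pos_lb <- which(b$lb > 0)
  neg_ub <- which(b$ub < 0)
  for (i in pos_lb) {
    row <- numeric(2 * n); row[i] <- 1; row[n + i] <- -1
    A <- rbind(A, row); dir <- c(dir, ">="); rhs <- c(rhs, b$lb[i])
  }
  for (i in neg_ub) {
    row <- numeric(2 * n); row[i] <- 1; row[n + i] <- -1
    A <- rbind(A, row); dir <- c(dir, "<="); rhs <- c(rhs, b$ub[i])
  }
  lb2 <- c(rep(0, n), rep(0, n))
  ub2 <- c(pmax(b$ub, 0), pmax(-b$lb, 0))
  sol <- solve_lp(rep(1, 2 * n), A, dir, rhs, lb2, ub2, sense = "min")
  if (sol$status != "optimal") {
    # numerically brittle corner: fall back to the FBA vertex
    base$total_flux <- sum(abs(base$fluxes))
    return(base)
  }
  v <- sol$x[seq_len(n)] - sol$x[n + seq_len(n)]
  structure(list(fluxes = stats::setNames(v, colnames(N)),
                 objective = base$objective, status = "optimal",
                 total_flux = sol$objective), class = "flux_solution")
}

#' Flux variability analysis
#'
#' Computes the minimum and maximum attainable flux for each reaction while
#' the biomass flux is held at or above `growth_fraction` of its optimum.
#' With `growth_fraction = 0` (and open transporters) the `vmin = vmax = 0`
#' rows identify blocked reactions.
#'
#' @param model a `metabolic_model`.
#' @param growth_fraction fraction of the biomass optimum to retain, in
#'   `[0, 1]`.
#' @param reactions reaction ids to scan (default: all).
#' @param bounds optional bound overrides as in [flux_problem()].
#' @return object of class `fva_result`: list with `ranges` (data.frame
#'   `reaction_id`, `vmin`, `vmax`, `status`), `growth_fraction`, `optimum`.
#' @export
fva <- function(model, growth_fraction = 0.9, reactions = NULL, bounds = list()) {
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  wt <- fba(flux_problem(model, bounds = bounds))
  if (wt$status != "optimal") stop("biomass FBA not optimal: ", wt$status)
  bounds[[model$biomass_reaction_id]] <- c(
    growth_fraction * wt$objective,
    .problem_bounds(flux_problem(model, bounds = bounds))$ub[[model$biomass_reaction_id]]
  )
  if (is.null(reactions)) reactions <- model$reactions$id
  rows <- lapply(reactions, function(rid) {
    obj <- stats::setNames(1, rid)
    lo <- fba(flux_problem(model, objective = obj, bounds = bounds, sense = "min"))
    hi <- fba(flux_problem(model, objective = obj, bounds = bounds, sense = "max"))
    ok <- lo$status == "optimal" && hi$status == "optimal"
    data.frame(reaction_id = rid,
               vmin = if (ok) lo$objective else NA_real_,
               vmax = if (ok) hi$objective else NA_real_,
               status = if (ok) "optimal" else "failed",
               stringsAsFactors = FALSE)
  })
  structure(list(ranges = do.call(rbind, rows),
                 growth_fraction = growth_fraction, optimum = wt$objective),
            class = "fva_result")
}

#' Blocked reactions from an FVA result
#'
#' @param fva_result an [fva()] result.
#' @param tol flux magnitude below which a range endpoint counts as zero.
#' @return character vector of blocked reaction ids.
#' @export
blocked_reactions <- function(fva_result, tol = 1e-6) {
  r <- fva_result$ranges
  r$reaction_id[!is.na(r$vmin) & abs(r$vmin) < tol & abs(r$vmax) < tol]
}

# transported internal metabolite of a transporter (the non-"x_" species)
.transported_met <- function(model, rid) {
  s <- model$stoich[[rid]]
  ids <- names(s)[!startsWith(names(s), "x_")]
  if (length(ids) == 0) NA_character_ else ids[1]
}

.carbon_transporters <- function(model) {
  Filter(function(rid) {
    met <- .transported_met(model, rid)
    if (is.na(met)) return(FALSE)
    f <- model$formulas[[met]]
    !is.null(f) && "C" %in% names(f) && f[["C"]] > 0
  }, transporter_ids(model))
}

# open a transporter for import at `uptake`, regardless of written direction
.open_import <- function(model, rid, uptake) {
  s <- model$stoich[[rid]]
  met <- .transported_met(model, rid)
  if (s[[met]] > 0) set_bounds(model, rid, lb = 0, ub = uptake)
  else set_bounds(model, rid, lb = -uptake, ub = 0)
}

.close_import <- function(model, rid) {
  s <- model$stoich[[rid]]
  met <- .transported_met(model, rid)
  i <- match(rid, model$reactions$id)
  if (s[[met]] > 0) {
    set_bounds(model, rid, lb = min(model$reactions$lower_bound[i], 0), ub = 0)
  } else {
    set_bounds(model, rid, lb = 0,
               ub = max(model$reactions$upper_bound[i], 0))
  }
}

#' Apply a minimal-medium environment
#'
#' Closes every carbon uptake, then opens the chosen carbon source at the
#' given uptake rate. Non-carbon exchanges (sulfate, phosphate, ammonium,
#' oxygen, water, protons) keep their structural bounds, i.e. free uptake.
#'
#' @param model a `metabolic_model`.
#' @param carbon_source internal metabolite id of the carbon source, or `NULL`
#'   to close all carbon uptakes.
#' @param uptake maximal uptake rate (mmol/gDCW/h).
#' @return the constrained model.
#' @export
apply_minimal_medium <- function(model, carbon_source = NULL, uptake = 10) {
  for (rid in .carbon_transporters(model)) model <- .close_import(model, rid)
  if (!is.null(carbon_source)) {
    tx <- Filter(function(rid) identical(.transported_met(model, rid), carbon_source),
                 transporter_ids(model))
    if (length(tx) == 0) {
      model <- .add_transporter(model, carbon_source)
      tx <- paste0(carbon_source, "_tx")
    }
    model <- .open_import(model, tx[1], uptake)
  }
  model
}

.add_transporter <- function(model, met) {
  if (!met %in% model$metabolites$id) stop("unknown metabolite: ", met)
  ext <- paste0("x_", met)
  if (!ext %in% model$metabolites$id) {
    model$metabolites <- rbind(model$metabolites, data.frame(
      id = ext, name = ext, compartment = "external", is_external = TRUE,
      stringsAsFactors = FALSE))
  }
  rid <- paste0(met, "_tx")
  model$reactions <- rbind(model$reactions, data.frame(
    id = rid, lower_bound = 0, upper_bound = 0, subsystem = "transport",
    stringsAsFactors = FALSE))
  model$stoich[[rid]] <- stats::setNames(c(-1, 1), c(ext, met))
  model
}

#' Screen a carbon source for growth support
#'
#' Adds (or reuses) a transport reaction for the metabolite with uptake
#' allowed up to `uptake` mmol/gDCW/h, closes all other carbon uptakes, and
#' runs parsimonious FBA on the biomass objective. The substrate supports
#' growth when the predicted growth rate exceeds `growth_threshold`.
#'
#' @param model a `metabolic_model`.
#' @param metabolite_id internal metabolite id of the candidate substrate.
#' @param uptake allowed uptake rate (default 10 mmol/gDCW/h).
#' @param growth_threshold growth-rate cut-off (default 0.01 /h).
#' @return list with `call` (`"growth"`/`"no_growth"`) and `growth_rate`.
#' @export
screen_carbon_source <- function(model, metabolite_id, uptake = 10,
                                 growth_threshold = 0.01) {
  if (!metabolite_id %in% model$metabolites$id) {
    stop("unknown metabolite: ", metabolite_id)
  }
  m <- apply_minimal_medium(model, carbon_source = metabolite_id, uptake = uptake)
  sol <- pfba(flux_problem(m))
  mu <- if (sol$status == "optimal") sol$objective else 0
  list(call = if (mu > growth_threshold) "growth" else "no_growth",
       growth_rate = mu)
}

#' Score a phenotype screen against observations
#'
#' Compares predicted and observed growth/no-growth calls over a shared
#' substrate universe and reports the confusion matrix plus overall accuracy.
#'
#' @param predicted,observed named character vectors of `"growth"` /
#'   `"no_growth"` calls.
#' @return list with `confusion` (named counts TP/FN/FP/TN, growth as the
#'   positive class) and `accuracy`.
#' @export
score_phenotype_screen <- function(predicted, observed) {
  common <- intersect(names(predicted), names(observed))
  if (length(common) == 0) stop("no common substrates to score")
  p <- predicted[common] == "growth"
  o <- observed[common] == "growth"
  conf <- c(TP = sum(p & o), FN = sum(!p & o), FP = sum(p & !o), TN = sum(!p & !o))
  list(confusion = conf, accuracy = (conf[["TP"]] + conf[["TN"]]) / length(common))
}

#' Test producibility of each biomass precursor
#'
#' For every net-consumed metabolite of the biomass reaction (excluding
#' recycled cofactor moieties), adds an artificial consuming transport
#' reaction and maximizes it. For infeasible precursors the LP is re-run with
#' all reactions reversible: irreversible reactions then carrying negative
#' flux are directionality-curation candidates; precursors that stay
#' infeasible are true network gaps.
#'
#' @param model a `metabolic_model`.
#' @param exclude metabolite ids to skip (cofactor moieties recycled through
#'   the biomass reaction rather than synthesized de novo).
#' @param tol flux threshold for "producible".
#' @return data.frame with columns `metabolite_id`, `feasible`, `gap`, and a
#'   list-column `candidates` of reversibility-candidate reaction ids.
#' @export
test_biomass_precursors <- function(model,
                                    exclude = c("atp", "adp", "nad", "nadh",
                                                "nadp", "nadph", "coa", "h2o",
                                                "h", "pi"),
                                    tol = 1e-6) {
  s <- model$stoich[[model$biomass_reaction_id]]
  precursors <- setdiff(names(s)[s < 0], exclude)
  rows <- lapply(precursors, function(met) {
    m <- model
    drain <- paste0("drain_", met, "_tx")
    m$reactions <- rbind(m$reactions, data.frame(
      id = drain, lower_bound = 0, upper_bound = 1000, subsystem = "artificial",
      stringsAsFactors = FALSE))
    m$stoich[[drain]] <- stats::setNames(-1, met)
    sol <- fba(flux_problem(m, objective = stats::setNames(1, drain)))
    feasible <- sol$status == "optimal" && sol$objective > tol
    candidates <- character(0); gap <- FALSE
    if (!feasible) {
      irr <- m$reactions$id[m$reactions$lower_bound >= 0 & m$reactions$id != drain]
      m2 <- m
      keep_fwd <- m2$reactions$id %in% c(drain, m2$biomass_reaction_id)
      m2$reactions$lower_bound <- ifelse(
        keep_fwd, m2$reactions$lower_bound,
        pmin(m2$reactions$lower_bound, -1000))
      sol2 <- fba(flux_problem(m2, objective = stats::setNames(1, drain)))
      if (sol2$status == "optimal" && sol2$objective > tol) {
        neg <- names(sol2$fluxes)[sol2$fluxes < -tol]
        candidates <- intersect(neg, irr)
      } else {
        gap <- TRUE
      }
    }
    out <- data.frame(metabolite_id = met, feasible = feasible, gap = gap,
                      stringsAsFactors = FALSE)
    out$candidates <- list(candidates)
    out
  })
  do.call(rbind, rows)
}

#' Rescale a flux solution to a reference flux
#'
#' Scales every flux by `target / |v_ref|`, e.g. to express a solution per
#' unit of substrate uptake. Steady state is preserved by linearity.
#'
#' @param solution a `flux_solution`.
#' @param reference_reaction reaction id whose flux anchors the scale.
#' @param target desired flux value for the reference reaction.
#' @return the rescaled `flux_solution`.
#' @export
normalize_fluxes <- function(solution, reference_reaction, target = 1) {
  vref <- solution$fluxes[[reference_reaction]]
  if (is.null(vref) || is.na(vref)) stop("unknown reference reaction: ",
                                         reference_reaction)
  if (abs(vref) < 1e-12) stop("reference reaction carries zero flux")
  k <- target / abs(vref)
  solution$fluxes <- solution$fluxes * k
  solution$objective <- solution$objective * k
  solution
}

#' Pearson correlation between two flux vectors
#'
#' @param v1,v2 named numeric flux vectors.
#' @param reaction_subset optional reaction ids to compare (default: the
#'   common names); at least 3 are required.
#' @return list with `pearson_r` and `r_squared`.
#' @export
compare_flux_vectors <- function(v1, v2, reaction_subset = NULL) {
  if (is.null(reaction_subset)) reaction_subset <- intersect(names(v1), names(v2))
  if (length(reaction_subset) < 3) stop("need at least 3 common reactions")
  a <- v1[reaction_subset]; b <- v2[reaction_subset]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero-variance flux vector; correlation undefined")
  }
  r <- stats::cor(a, b, method = "pearson")
  list(pearson_r = r, r_squared = r^2)
}

#' P/O ratio of a flux solution
#'
#' ATP synthesized through the oxidative-phosphorylation reactions divided by
#' oxygen atoms consumed by them (2 atoms per O2).
#'
#' @param solution a `flux_solution`.
#' @param model a `metabolic_model`.
#' @param phosphorylation_reactions reaction ids of the oxidative
#'   phosphorylation machinery; by default, every reaction that consumes
#'   `o2` and produces `atp`.
#' @param o2_id,atp_id metabolite ids for oxygen and ATP.
#' @return the P/O ratio (numeric scalar).
#' @export
po_ratio <- function(solution, model, phosphorylation_reactions = NULL,
                     o2_id = "o2", atp_id = "atp") {
  if (is.null(phosphorylation_reactions)) {
    phosphorylation_reactions <- Filter(function(rid) {
      s <- model$stoich[[rid]]
      isTRUE(s[o2_id] < 0) && isTRUE(s[atp_id] > 0)
    }, model$reactions$id)
  }
  atp <- 0; o_atoms <- 0
  for (rid in phosphorylation_reactions) {
    s <- model$stoich[[rid]]
    v <- solution$fluxes[[rid]]
    if (isTRUE(s[atp_id] > 0)) atp <- atp + v * s[[atp_id]]
    if (isTRUE(s[o2_id] < 0)) o_atoms <- o_atoms + v * (-s[[o2_id]]) * 2
  }
  if (abs(o_atoms) < 1e-9) {
    stop("no oxygen consumed through the phosphorylation reactions; ",
         "P/O ratio undefined")
  }
  atp / o_atoms
}
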