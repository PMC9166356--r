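# End-to-end orchestration: validate -> essentiality vs TraDIS -> iMAT per
# condition -> flux sampling -> differential flux -> regulatory
# classification, with every stage's table written before the next begins.

#' Assemble a pipeline configuration
#'
#' Collects input paths, every module threshold, the seeds, and the output
#' directory. The defaults are the package's standard analysis settings: the
#' 0.05 /h essentiality and 0.85 growth-limiting cut-offs, the 5-fold
#' isoenzyme-silencing ratio, the 65th/75th percentile insertion-index
#' thresholds, the 95th percentile iMAT high cut, an iMAT activity epsilon
#' of 0.1 mmol/gDCW/h, a fixed substrate uptake of 2.1 mmol/gDCW/h, growth
#' rates of 0.2 /h (growth phase, f16) and 0.009 /h (nitrogen-depleted
#' phase, f26), and KS/FDR differential-flux settings alpha = 0.05,
#' FC cut = 1/3 (the exact-2-fold point, printed 0.33), expression
#' concordance cut = 1 log2 unit.
#'
#' @param model,expression,insertions,annotation,reference_essential input
#'   file paths (see the module readers for formats).
#' @param out_dir output directory.
#' @param conditions labels of the two expression conditions (reference
#'   first).
#' @param growth_rates named growth-rate constraints per condition (/h).
#' @param substrate_uptake fixed substrate uptake (mmol/gDCW/h) applied to
#'   the first carbon transporter.
#' @param essential_threshold,limiting_fraction,isoenzyme_fold,lower_pct,upper_pct,high_pct,epsilon,alpha,fc_cut,expr_cut
#'   module thresholds (see module documentation).
#' @param n_samples,thinning flux-sampling settings.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(model, expression, insertions, annotation,
                            reference_essential, out_dir,
                            conditions = c("f16", "f26"),
                            growth_rates = c(f16 = 0.2, f26 = 0.009),
                            substrate_uptake = 2.1,
                            essential_threshold = 0.05,
                            limiting_fraction = 0.85,
                            isoenzyme_fold = 5,
                            lower_pct = 0.65, upper_pct = 0.75,
                            high_pct = 0.95, epsilon = 0.1,
                            alpha = 0.05, fc_cut = 1 / 3, expr_cut = 1.0,
                            n_samples = 500, thinning = 10, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

.stage_tsv <- function(df, out_dir, name) {
  path <- file.path(out_dir, paste0(name, ".tsv"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: model loading and theoretical validation;
#' TraDIS insertion-index calling; in-silico essentiality (with
#' silent-isoenzyme deactivation) compared against the TraDIS calls; iMAT
#' condition-specific models for both conditions; duplicate flux sampling
#' with a convergence screen; differential-flux analysis; and regulatory
#' classification. Each stage writes its TSV before the next begins, and the
#' returned report aggregates the headline numbers.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(config[setdiff(names(config), "")],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  ref <- config$conditions[1]; alt <- config$conditions[2]

  # stage 1: model + validation
  model <- read_model_json(config$model)
  report_val <- validate_model(model)
  write_validation_report(report_val,
                          file.path(config$out_dir, "validation.tsv"))

  # stage 2: TraDIS calling
  ds <- read_insertion_tsv(config$insertions, config$annotation)
  reference <- readLines(config$reference_essential)
  trad <- tradis_call(ds, reference)
  .stage_tsv(trad$records, config$out_dir, "tradis_calls")

  # stage 3: essentiality with isoenzyme deactivation, vs TraDIS
  expr_tab <- utils::read.delim(config$expression, stringsAsFactors = FALSE)
  rpkm_ref <- stats::setNames(expr_tab[[paste0("rpkm_", ref)]],
                              expr_tab$gene_id)
  deact <- deactivate_lowly_expressed_isoenzymes(
    model, rpkm_ref, fold = config$isoenzyme_fold,
    essential_threshold = config$essential_threshold)
  scan <- gene_deletion_scan(deact$model,
                             genes = model$genes,
                             essential_threshold = config$essential_threshold,
                             limiting_fraction = config$limiting_fraction)
  .stage_tsv(scan, config$out_dir, "essentiality")
  predicted <- stats::setNames(
    ifelse(scan$call == "essential", "essential", "non_essential"), scan$gene)
  observed <- stats::setNames(trad$records$call, trad$records$gene_id)
  comparison <- compare_essentiality(predicted, observed)

  # stage 4: iMAT condition-specific models
  rx_ref <- map_expression_to_reactions(model, expr_tab, ref)
  rx_alt <- map_expression_to_reactions(model, expr_tab, alt)
  rx_alt_w <- weight_condition_expression(rx_alt, rx_ref)
  ess_rxns <- essential_reactions(model, config$essential_threshold)
  substrate_tx <- .carbon_transporters(model)[1]
  caps <- stats::setNames(
    list(c(config$substrate_uptake, config$substrate_uptake)), substrate_tx)
  csm <- list()
  for (cond in config$conditions) {
    rx_expr <- if (cond == ref) rx_ref else rx_alt_w
    cuts <- derive_imat_thresholds(rx_expr, ess_rxns, config$high_pct)
    cats <- assign_imat_categories(rx_expr, cuts$low_cut, cuts$high_cut)
    caps_cond <- caps
    if (cond == alt) {
      # nitrogen-depleted phase: cap nitrogen at the minimum required
      n_tx <- .nitrogen_transporter(model)
      if (!is.na(n_tx)) {
        need <- .minimal_uptake(model, n_tx, config$growth_rates[[cond]],
                                caps)
        caps_cond[[n_tx]] <- c(0, need)
      }
    }
    csm[[cond]] <- imat(model, cats, epsilon = config$epsilon,
                        growth_rate = config$growth_rates[[cond]],
                        nutrient_caps = caps_cond)
    .stage_tsv(data.frame(reaction_id = names(cats),
                          expression = unname(rx_expr[names(cats)]),
                          category = unname(cats),
                          stringsAsFactors = FALSE),
               config$out_dir, paste0("imat_categories_", cond))
  }

  # stage 5: duplicate sampling + convergence screen
  seeds <- config$seed * 100L + 1:4
  runs <- list(
    a1 = sample_fluxes(csm[[ref]], config$n_samples, config$thinning, seeds[1]),
    a2 = sample_fluxes(csm[[ref]], config$n_samples, config$thinning, seeds[2]),
    b1 = sample_fluxes(csm[[alt]], config$n_samples, config$thinning, seeds[3]),
    b2 = sample_fluxes(csm[[alt]], config$n_samples, config$thinning, seeds[4])
  )
  unstable <- union(check_convergence(runs$a1, runs$a2, config$alpha),
                    check_convergence(runs$b1, runs$b2, config$alpha))

  # stage 6: differential flux + regulation
  diff <- differential_flux(runs$a1, runs$b1, alpha = config$alpha,
                            fc_cut = config$fc_cut, exclude = unstable,
                            seed = config$seed)
  .stage_tsv(diff, config$out_dir, "differential_flux")
  lfc <- log2((rx_alt + 1) / (rx_ref + 1))
  regulation <- classify_regulation(diff, lfc, config$expr_cut)
  .stage_tsv(regulation, config$out_dir, "regulation")

  report <- structure(list(
    validation = list(passed = report_val$passed,
                      imbalanced = nrow(report_val$imbalanced_reactions),
                      unconserved = length(report_val$unconserved_metabolites),
                      energy_cycle_flux = report_val$energy_cycle_flux),
    tradis = as.list(table(trad$records$call)),
    tradis_thresholds = trad$thresholds[c("lower", "upper")],
    deactivated_isoenzymes = deact$deactivated,
    essentiality = comparison,
    imat = lapply(csm, function(x) list(objective = x$objective,
                                        active = x$active,
                                        suppressed = x$suppressed)),
    unstable_reactions = unstable,
    differential = as.list(table(diff$call)),
    regulation = as.list(table(regulation$class)),
    seed = config$seed
  ), class = "run_report")
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}

# first transporter importing a nitrogen-containing metabolite
.nitrogen_transporter <- function(model) {
  hits <- Filter(function(rid) {
    met <- .transported_met(model, rid)
    f <- model$formulas[[met]]
    !is.null(f) && "N" %in% names(f) && f[["N"]] > 0 &&
      !("C" %in% names(f) && f[["C"]] > 0)
  }, transporter_ids(model))
  if (length(hits) == 0) NA_character_ else hits[1]
}

# minimal uptake through `rid` compatible with the growth constraint
.minimal_uptake <- function(model, rid, growth_rate, caps) {
  bounds <- caps
  bounds[[model$biomass_reaction_id]] <- c(growth_rate, 1000)
  sol <- fba(flux_problem(model, objective = stats::setNames(1, rid),
                          bounds = bounds, sense = "min"))
  if (sol$status != "optimal") stop("cannot determine minimal uptake for ", rid)
  max(sol$objective, 0) * (1 + 1e-6)
}
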