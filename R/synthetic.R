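# Synthetic data generators: expression tables, transposon insertion
# libraries, biomass time series, and an independent-chain sampling
# benchmark. Each generator is seeded and returns its planted ground truth
# so recovery tests can score the pipeline end to end.

#' Default simulation configuration
#'
#' Collects the knobs of the synthetic generators: expression noise
#' (log-normal sigma in natural-log units), the silent-isoenzyme expression
#' ratio, insertion density (insertions per bp), the residual insertion rate
#' inside essential genes (fraction of the background density, modelling
#' cross-feeding survival of essential-gene mutants), gene layout, and the
#' number of genome-wide filler genes surrounding the model genes.
#'
#' @param seed integer seed.
#' @param sigma log-normal expression noise (sdlog).
#' @param base_meanlog,base_sdlog log-normal parameters of baseline RPKM.
#' @param silent_factor expression ratio partner/silent for planted silent
#'   isoenzymes.
#' @param insertion_density Poisson insertion density (insertions/bp).
#' @param contamination strictly-essential-gene insertion density as a
#'   fraction of `insertion_density` (cross-feeding survivors).
#' @param anchor_density reference-anchor-gene insertion density as a
#'   fraction of `insertion_density` (slow-death essential mutants that
#'   persist in the pooled library and anchor the thresholds).
#' @param gene_length_range gene length range (bp); lengths are drawn
#'   uniformly so insertion indexes are continuous.
#' @param gene_gap intergenic gap (bp).
#' @param n_genes total genes on the synthetic genome (model genes plus
#'   fillers).
#' @param n_essential planted strictly essential genes (model in-vivo
#'   essentials plus essential fillers), scored in recovery tests.
#' @param n_anchor reference anchor genes (also essential, separately
#'   modelled).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, sigma = 0.25, base_meanlog = log(200),
                       base_sdlog = 1, silent_factor = 10,
                       insertion_density = 0.2, contamination = 0.01,
                       anchor_density = 0.05,
                       gene_length_range = c(600L, 1400L), gene_gap = 200L,
                       n_genes = 500L, n_essential = 50L, n_anchor = 26L) {
  structure(list(seed = as.integer(seed), sigma = sigma,
                 base_meanlog = base_meanlog, base_sdlog = base_sdlog,
                 silent_factor = silent_factor,
                 insertion_density = insertion_density,
                 contamination = contamination,
                 anchor_density = anchor_density,
                 gene_length_range = as.integer(gene_length_range),
                 gene_gap = as.integer(gene_gap),
                 n_genes = as.integer(n_genes),
                 n_essential = as.integer(n_essential),
                 n_anchor = as.integer(n_anchor)), class = "sim_config")
}

#' Generate a two-condition expression table for the toy model
#'
#' Baseline RPKM per gene is log-normal; genes catalysing the reactions
#' planted as shifted under nitrogen limitation are multiplied by their fold
#' (up) or its inverse (down) in the f26 condition; planted silent
#' isoenzymes are drawn `silent_factor`-fold below their partner in both
#' conditions. `sigma = 0` reproduces the planted folds exactly.
#'
#' @param truth a `toy_truth` from [generate_toy_model()].
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `rpkm_f16`, `rpkm_f26`.
#' @export
generate_expression <- function(truth, config = sim_config()) {
  model <- truth$model
  genes <- model$genes
  .with_seed(config$seed + 1000L, {
    base <- stats::setNames(
      exp(stats::rnorm(length(genes), config$base_meanlog, config$base_sdlog)),
      genes)
    # silent isoenzymes sit far below their partner
    for (g in truth$silent_isoenzymes) {
      rid <- names(model$gpr)[vapply(model$gpr, function(t) g %in% gpr_genes(t),
                                     logical(1))][1]
      partner <- setdiff(gpr_genes(model$gpr[[rid]]), g)
      base[g] <- max(base[partner]) / config$silent_factor
    }
    fold16 <- stats::setNames(rep(1, length(genes)), genes)
    fold26 <- fold16
    sh <- truth$n_limited_shifted_reactions
    for (i in seq_len(nrow(sh))) {
      gs <- gpr_genes(model$gpr[[sh$reaction_id[i]]])
      gs <- setdiff(gs, truth$silent_isoenzymes)
      f <- if (sh$direction[i] == "up") sh$fold[i] else 1 / sh$fold[i]
      fold26[gs] <- f
    }
    noise <- function() exp(stats::rnorm(length(genes), 0, config$sigma))
    data.frame(gene_id = genes,
               rpkm_f16 = unname(base * fold16 * noise()),
               rpkm_f26 = unname(base * fold26 * noise()),
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic transposon insertion library
#'
#' Lays `n_genes` genes (the toy-model genes first, then filler genes) on a
#' linear genome with uniformly drawn gene lengths, fixed intergenic gaps and
#' alternating strands. Unique insertion sites are placed by a per-bp
#' Bernoulli process at `insertion_density` in non-essential genes and gaps,
#' at `contamination * insertion_density` in the strictly essential planted
#' genes (residual cross-feeding survivors), and at
#' `anchor_density * insertion_density` in the reference anchor genes —
#' essential genes whose mutants die slowly and therefore retain more
#' insertions in a pooled competitive library; their curated insertion
#' indexes anchor the 65th/75th-percentile classification thresholds, the
#' role a cross-species homolog-mapped essential set plays on real data.
#'
#' @param truth a `toy_truth` from [generate_toy_model()].
#' @param config a [sim_config()].
#' @return list with `dataset` (an `insertion_dataset`),
#'   `reference_essential` (the anchor gene ids), `essential_genes` (the
#'   strictly essential planted set scored by recovery tests; the model's
#'   in-vivo essential genes plus fillers), `annotations`.
#' @export
generate_tradis <- function(truth, config = sim_config()) {
  model_genes <- truth$model$genes
  n_fill <- config$n_genes - length(model_genes)
  if (n_fill < 0) stop("n_genes smaller than the number of model genes")
  fillers <- sprintf("tg%04d", seq_len(n_fill))
  genes <- c(model_genes, fillers)
  gap <- config$gene_gap
  n_ess_fill <- config$n_essential - length(truth$invivo_essential_genes)
  if (n_ess_fill < 0) stop("n_essential smaller than the model essential set")
  if (n_ess_fill + config$n_anchor > n_fill) stop("not enough filler genes")
  .with_seed(config$seed + 2000L, {
    L <- sample(config$gene_length_range[1]:config$gene_length_range[2],
                length(genes), replace = TRUE)
    start <- gap + 1L + c(0L, cumsum(L[-length(L)] + gap))
    ann <- data.frame(gene_id = genes, replicon = "chr1",
                      start = start, end = start + L - 1L,
                      strand = rep(c("+", "-"), length.out = length(genes)),
                      stringsAsFactors = FALSE)
    picked <- sample(fillers, n_ess_fill + config$n_anchor)
    ess_fillers <- picked[seq_len(n_ess_fill)]
    anchors <- sort(picked[n_ess_fill + seq_len(config$n_anchor)])
    essential <- c(truth$invivo_essential_genes, ess_fillers)
    genome_len <- max(ann$end) + gap
    dens <- rep(config$insertion_density, genome_len)
    for (i in which(ann$gene_id %in% essential)) {
      dens[ann$start[i]:ann$end[i]] <-
        config$insertion_density * config$contamination
    }
    for (i in which(ann$gene_id %in% anchors)) {
      dens[ann$start[i]:ann$end[i]] <-
        config$insertion_density * config$anchor_density
    }
    pos <- which(stats::runif(genome_len) < dens)
    ins <- data.frame(replicon = "chr1", position = pos,
                      count = rep(1, length(pos)), stringsAsFactors = FALSE)
    list(dataset = insertion_dataset(ins, ann, condition = "sob"),
         reference_essential = anchors,
         essential_genes = essential,
         annotations = ann)
  })
}

#' Generate biomass time series for the two growth phases
#'
#' A logistic curve for the growth phase and a straight line for the
#' nitrogen-depleted production phase, with multiplicative Gaussian noise.
#'
#' @param growth_rate exponential-phase rate constant (/h).
#' @param production_slope linear biomass accumulation slope
#'   (gDCW/L/h) in the depleted phase.
#' @param noise relative (fractional) Gaussian noise on each observation.
#' @param seed integer seed.
#' @param K,X0 logistic carrying capacity and inoculum (gDCW/L).
#' @param t_growth,t_production time grids (h) for the two phases.
#' @return list of two data.frames (`growth`, `production`) with columns
#'   `time`, `biomass`.
#' @export
generate_biomass_timeseries <- function(growth_rate = 0.2,
                                        production_slope = 0.05,
                                        noise = 0, seed = 1L,
                                        K = 5, X0 = 0.05,
                                        t_growth = seq(0, 40, by = 1),
                                        t_production = seq(0, 40, by = 1)) {
  stopifnot(growth_rate >= 0, production_slope >= 0)
  .with_seed(seed + 3000L, {
    xg <- if (growth_rate == 0) rep(X0, length(t_growth)) else
      K / (1 + ((K - X0) / X0) * exp(-growth_rate * t_growth))
    xp <- K + production_slope * t_production
    jitter <- function(x) x * (1 + stats::rnorm(length(x), 0, noise))
    list(growth = data.frame(time = t_growth, biomass = jitter(xg)),
         production = data.frame(time = t_production, biomass = jitter(xp)))
  })
}

#' Independent-chain benchmark model for flux sampling
#'
#' Builds a model of `n_chains` independent uptake/release chains
#' (`x_in_i -> s_i -> x_out_i`), whose flux polytope is an axis-aligned box:
#' chain i carries a uniform flux on `[0, caps[i]]`. Used to benchmark the
#' sampler against exact uniform moments and to plant mean shifts between
#' conditions by scaling a chain's cap.
#'
#' @param n_chains number of chains (2 reactions each).
#' @param caps numeric vector of per-chain uptake caps (recycled).
#' @return a `metabolic_model`. The designated biomass/ATPM ids point at the
#'   first release reaction purely to satisfy the container contract; they
#'   carry no biological meaning here.
#' @export
toy_sampling_model <- function(n_chains = 10, caps = 10) {
  caps <- rep_len(caps, n_chains)
  mets <- data.frame(id = character(0), name = character(0),
                     compartment = character(0), is_external = logical(0),
                     stringsAsFactors = FALSE)
  S <- list(); rxns <- NULL
  for (i in seq_len(n_chains)) {
    s <- sprintf("s%d", i)
    mets <- rbind(mets, data.frame(
      id = c(s, paste0("x_in", i), paste0("x_out", i)),
      name = c(s, paste0("x_in", i), paste0("x_out", i)),
      compartment = c("cytosol", "external", "external"),
      is_external = c(FALSE, TRUE, TRUE), stringsAsFactors = FALSE))
    up <- sprintf("upt%d_tx", i); rel <- sprintf("rel%d_tx", i)
    S[[up]] <- stats::setNames(c(-1, 1), c(paste0("x_in", i), s))
    S[[rel]] <- stats::setNames(c(-1, 1), c(s, paste0("x_out", i)))
    rxns <- rbind(rxns,
      data.frame(id = up, lower_bound = 0, upper_bound = caps[i],
                 subsystem = "chain", stringsAsFactors = FALSE),
      data.frame(id = rel, lower_bound = 0, upper_bound = 1000,
                 subsystem = "chain", stringsAsFactors = FALSE))
  }
  metabolic_model(metabolites = mets, formulas = list(), reactions = rxns,
                  stoich = S, gpr = list(), genes = character(0),
                  biomass_reaction_id = "rel1_tx", atpm_reaction_id = "rel1_tx")
}

#' Write every synthetic pipeline input to a directory
#'
#' Emits the toy model JSON, the two-condition expression TSV, the insertion
#' and annotation TSVs, the reference essential-gene list, and a truth
#' manifest JSON recording all planted ground truth.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed forwarded to all generators.
#' @param config optional [sim_config()] (its seed is overridden by `seed`).
#' @return invisibly, a named list of the file paths written.
#' @export
write_synthetic_inputs <- function(dir, seed = 1L, config = NULL) {
  if (is.null(config)) config <- sim_config(seed = seed)
  config$seed <- as.integer(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_toy_model(seed)
  expr <- generate_expression(truth, config)
  trad <- generate_tradis(truth, config)
  paths <- list(
    model = file.path(dir, "model.json"),
    expression = file.path(dir, "expression.tsv"),
    insertions = file.path(dir, "insertions.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    reference_essential = file.path(dir, "reference_essential.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_model_json(truth$model, paths$model)
  utils::write.table(expr, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(trad$dataset$insertions, paths$insertions, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(trad$annotations, paths$annotation, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(trad$reference_essential, paths$reference_essential)
  jsonlite::write_json(list(
    essential_genes = truth$essential_genes,
    invivo_essential_genes = truth$invivo_essential_genes,
    growth_limiting_genes = truth$growth_limiting_genes,
    silent_isoenzymes = truth$silent_isoenzymes,
    n_limited_shifted_reactions = truth$n_limited_shifted_reactions,
    by_product_truth = truth$by_product_truth,
    tradis_essential_genes = trad$essential_genes,
    seed = seed
  ), paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
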