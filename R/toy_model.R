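# Hand-audited toy metabolic network with recorded ground truth.
#
# The network emulates, at toy scale, the motifs of a PHB-producing
# chemolithoheterotroph growing on a sugar: a sugar uptake feeding an
# Entner-Doudoroff-like catabolic lump, pyruvate dehydrogenase and a TCA
# lump, two electron-transport-chain branches with distinct P/O ratios, an
# energy-coupled transhydrogenase, a nitrogen-requiring biomass reaction fed
# by an alanine-like precursor, a nitrogen-free NADPH-consuming PHB storage
# branch with secretion, and a PHB-degradation route that closes a
# transhydrogenase-like cycle. All species carry real elemental formulas so
# the network is exactly balanced for C, H, N, O, P and S.

.toy_formulas <- function() {
  list(
    fru   = c(C = 6,  H = 12, O = 6),
    pyr   = c(C = 3,  H = 4,  O = 3),
    ala   = c(C = 3,  H = 7,  N = 1, O = 2),
    nh4   = c(H = 4,  N = 1),
    so4   = c(O = 4,  S = 1),
    o2    = c(O = 2),
    co2   = c(C = 1,  O = 2),
    h2o   = c(H = 2,  O = 1),
    h     = c(H = 1),
    pi    = c(H = 3,  O = 4,  P = 1),
    ac    = c(C = 2,  H = 4,  O = 2),
    atp   = c(C = 10, H = 16, N = 5, O = 13, P = 3),
    adp   = c(C = 10, H = 15, N = 5, O = 10, P = 2),
    nad   = c(C = 21, H = 27, N = 7, O = 14, P = 2),
    nadh  = c(C = 21, H = 28, N = 7, O = 14, P = 2),
    nadp  = c(C = 21, H = 28, N = 7, O = 17, P = 3),
    nadph = c(C = 21, H = 29, N = 7, O = 17, P = 3),
    coa   = c(C = 21, H = 36, N = 7, O = 16, P = 3, S = 1),
    accoa = c(C = 23, H = 38, N = 7, O = 17, P = 3, S = 1),
    aacoa = c(C = 25, H = 40, N = 7, O = 18, P = 3, S = 1),
    hbcoa = c(C = 25, H = 42, N = 7, O = 18, P = 3, S = 1),
    phb   = c(C = 4,  H = 6,  O = 2),
    hb    = c(C = 4,  H = 8,  O = 3),
    aac   = c(C = 4,  H = 6,  O = 3)
  )
}

#' Build the toy benchmark model with its ground truth
#'
#' Constructs a 26-reaction, 24-gene metabolic model together with the
#' recorded truth used by the recovery tests: the planted essential and
#' growth-limiting gene sets, the silent isoenzymes, the reactions shifted
#' under nitrogen limitation, and the expected secreted by-product per
#' condition. The network itself is a fixed, hand-audited fixture; `seed`
#' only matters for the data layers generated on top of it (expression,
#' insertions), not for the network wiring.
#'
#' @param seed unused by the network itself; recorded in the truth object so
#'   downstream generators inherit it.
#' @return list of class `toy_truth` with fields `model`, `essential_genes`
#'   (in-silico essential at default medium), `invivo_essential_genes` (adds
#'   the isoenzyme whose partner is silent), `growth_limiting_genes`,
#'   `silent_isoenzymes`, `n_limited_shifted_reactions` (data.frame
#'   reaction_id, direction, fold), `by_product_truth`, and `seed`.
#' @export
generate_toy_model <- function(seed = 1L) {
  f <- .toy_formulas()
  internal <- names(f)
  ext <- c("x_fru", "x_o2", "x_nh4", "x_so4", "x_pi", "x_co2", "x_h2o",
           "x_h", "x_ac", "x_phb", "x_biomass")
  mets <- data.frame(
    id = c(internal, ext),
    name = c(internal, ext),
    compartment = c(rep("cytosol", length(internal)), rep("external", length(ext))),
    is_external = c(rep(FALSE, length(internal)), rep(TRUE, length(ext))),
    stringsAsFactors = FALSE
  )

  S <- list()
  rx <- function(id, stoich, lb, ub, subsystem) {
    S[[id]] <<- unlist(stoich)
    data.frame(id = id, lower_bound = lb, upper_bound = ub,
               subsystem = subsystem, stringsAsFactors = FALSE)
  }
  rxns <- rbind(
    # transport (import-positive orientation, "_tx" suffix)
    rx("fru_tx", c(x_fru = -1, fru = 1), 0, 10, "transport"),
    rx("o2_tx",  c(x_o2 = -1, o2 = 1), 0, 1000, "transport"),
    rx("nh4_tx", c(x_nh4 = -1, nh4 = 1), 0, 1000, "transport"),
    rx("so4_tx", c(x_so4 = -1, so4 = 1), 0, 1000, "transport"),
    rx("pi_tx",  c(x_pi = -1, pi = 1), 0, 1000, "transport"),
    rx("co2_tx", c(co2 = -1, x_co2 = 1), 0, 1000, "transport"),
    rx("h2o_tx", c(h2o = -1, x_h2o = 1), -1000, 1000, "transport"),
    rx("h_tx",   c(h = -1, x_h = 1), -1000, 1000, "transport"),
    rx("ac_tx",  c(ac = -1, x_ac = 1), 0, 1000, "transport"),
    rx("phb_tx", c(phb = -1, x_phb = 1), 0, 1000, "transport"),
    # catabolic backbone
    rx("ed", c(fru = -1, atp = -1, nad = -1, nadp = -1, h2o = -1,
               pyr = 2, adp = 1, pi = 1, nadh = 1, nadph = 1, h = 2),
       0, 1000, "catabolism"),
    rx("pdh", c(pyr = -1, coa = -1, nad = -1,
                accoa = 1, co2 = 1, nadh = 1, h = 1), 0, 1000, "catabolism"),
    rx("tca", c(accoa = -1, nad = -3, adp = -1, pi = -1, h2o = -2,
                co2 = 2, coa = 1, nadh = 3, atp = 1, h = 5), 0, 1000, "tca"),
    rx("ack", c(accoa = -1, adp = -1, pi = -1,
                ac = 1, coa = 1, atp = 1), 0, 1000, "overflow"),
    # electron transport: high and low P/O branches
    rx("etc_hi", c(nadh = -1, o2 = -0.5, adp = -2, pi = -2, h = -1,
                   nad = 1, h2o = 3, atp = 2), 0, 1000, "etc"),
    rx("etc_lo", c(nadh = -1, o2 = -0.5, adp = -1, pi = -1, h = -1,
                   nad = 1, h2o = 2, atp = 1), 0, 1000, "etc"),
    rx("thd", c(nadh = -1, nadp = -1, atp = -1, h2o = -1,
                nad = 1, nadph = 1, adp = 1, pi = 1), 0, 1000, "redox"),
    # nitrogen assimilation into the biomass precursor
    rx("alaS", c(pyr = -1, nh4 = -1, nadph = -1,
                 ala = 1, nadp = 1, h2o = 1), 0, 1000, "biosynthesis"),
    # PHB storage branch
    rx("phaA", c(accoa = -2, aacoa = 1, coa = 1), 0, 1000, "phb"),
    rx("phaB", c(aacoa = -1, nadph = -1, h = -1,
                 hbcoa = 1, nadp = 1), 0, 1000, "phb"),
    rx("phaC", c(hbcoa = -1, phb = 1, coa = 1), 0, 1000, "phb"),
    # PHB degradation closing a transhydrogenase-like cycle
    rx("phaZ", c(phb = -1, h2o = -1, hb = 1), 0, 1000, "phb"),
    rx("bdh",  c(hb = -1, nad = -1, aac = 1, nadh = 1, h = 1), 0, 1000, "phb"),
    rx("aacs", c(aac = -1, coa = -1, atp = -1,
                 aacoa = 1, adp = 1, pi = 1), 0, 1000, "phb"),
    # maintenance and growth
    rx("atpm", c(atp = -1, h2o = -1, adp = 1, pi = 1), 3, 1000, "maintenance"),
    rx("biomass", c(ala = -1.5, pyr = -0.5, so4 = -0.2, atp = -30.166,
                    nadph = -3, h2o = -30.166,
                    adp = 30.166, pi = 30.166, nadp = 3, x_biomass = 1),
       0, 1000, "biomass")
  )

  gpr <- list(
    fru_tx = parse_gpr("gFruT"),
    nh4_tx = parse_gpr("gNh4T"),
    so4_tx = parse_gpr("gSulT"),
    ac_tx  = parse_gpr("gAcT"),
    phb_tx = parse_gpr("gPhbT"),
    ed     = parse_gpr("gEd1 and gEd2 and gEd3"),
    pdh    = parse_gpr("gPdh1 or gPdh2"),
    tca    = parse_gpr("gTca1"),
    ack    = parse_gpr("gAck"),
    etc_hi = parse_gpr("gNuo1 and gNuo2"),
    etc_lo = parse_gpr("gCyd"),
    thd    = parse_gpr("gThd"),
    alaS   = parse_gpr("gAla1 or gAla2"),
    phaA   = parse_gpr("gPhaA"),
    phaB   = parse_gpr("gPhaB"),
    phaC   = parse_gpr("gPhaC1 or gPhaC2"),
    phaZ   = parse_gpr("gPhaZ"),
    bdh    = parse_gpr("gBdh"),
    aacs   = parse_gpr("gAacs")
  )
  genes <- sort(unique(unlist(lapply(gpr, gpr_genes))))

  model <- metabolic_model(
    metabolites = mets, formulas = f, reactions = rxns, stoich = S,
    gpr = gpr, genes = genes,
    biomass_reaction_id = "biomass", atpm_reaction_id = "atpm",
    gam = 30.166, ngam = 3
  )

  # nitrogen limitation pushes carbon into PHB synthesis and secretion while
  # overflow acetate production and the PHB degradation arm of the cycle are
  # repressed (storage conditions favour net accumulation)
  shifted <- data.frame(
    reaction_id = c("phaA", "phaB", "phaC", "phb_tx",
                    "ack", "ac_tx", "phaZ", "bdh", "aacs"),
    direction = c("up", "up", "up", "up",
                  "down", "down", "down", "down", "down"),
    fold = 4,
    stringsAsFactors = FALSE
  )

  structure(list(
    model = model,
    essential_genes = c("gFruT", "gNh4T", "gSulT", "gEd1", "gEd2", "gEd3"),
    invivo_essential_genes = c("gFruT", "gNh4T", "gSulT",
                               "gEd1", "gEd2", "gEd3", "gAla1"),
    growth_limiting_genes = c("gNuo1", "gNuo2", "gTca1", "gThd"),
    silent_isoenzymes = c("gAla2", "gPhaC2"),
    n_limited_shifted_reactions = shifted,
    by_product_truth = list(f16 = character(0), f26 = "x_phb"),
    seed = as.integer(seed)
  ), class = "toy_truth")
}
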