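# Small hand-built fixture models used across the tests.

# linear chain: x_A -> A -> B -> x_B, uptake capped at `cap`
chain_model <- function(cap = 10) {
  mets <- data.frame(
    id = c("A", "B", "x_A", "x_B"),
    name = c("A", "B", "x_A", "x_B"),
    compartment = c("cytosol", "cytosol", "external", "external"),
    is_external = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("A_tx", "conv", "B_tx"),
    lower_bound = c(0, 0, 0), upper_bound = c(cap, 1000, 1000),
    subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(A_tx = c(x_A = -1, A = 1), conv = c(A = -1, B = 1),
                 B_tx = c(B = -1, x_B = 1))
  metabolic_model(mets, list(), rxns, stoich, list(), character(0),
                  biomass_reaction_id = "B_tx", atpm_reaction_id = "B_tx")
}

# two parallel routes of unequal length:
# x_A -> A; A -> B (1 step); A -> M -> B (2 steps); B -> x_B
parallel_routes_model <- function(cap = 10) {
  mets <- data.frame(
    id = c("A", "B", "M", "x_A", "x_B"),
    name = c("A", "B", "M", "x_A", "x_B"),
    compartment = c(rep("cytosol", 3), "external", "external"),
    is_external = c(rep(FALSE, 3), TRUE, TRUE), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("A_tx", "short", "long1", "long2", "B_tx"),
    lower_bound = 0, upper_bound = c(cap, 1000, 1000, 1000, 1000),
    subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(A_tx = c(x_A = -1, A = 1), short = c(A = -1, B = 1),
                 long1 = c(A = -1, M = 1), long2 = c(M = -1, B = 1),
                 B_tx = c(B = -1, x_B = 1))
  metabolic_model(mets, list(), rxns, stoich, list(), character(0),
                  biomass_reaction_id = "B_tx", atpm_reaction_id = "B_tx")
}

# branched network with a capacity-limited and an uncapped route
branched_model <- function() {
  mets <- data.frame(
    id = c("A", "B", "C", "D", "x_A", "x_D"),
    name = c("A", "B", "C", "D", "x_A", "x_D"),
    compartment = c(rep("cytosol", 4), "external", "external"),
    is_external = c(rep(FALSE, 4), TRUE, TRUE), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("A_tx", "ab", "ac", "bd", "cd", "D_tx"),
    lower_bound = 0, upper_bound = c(10, 4, 1000, 1000, 3, 1000),
    subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(A_tx = c(x_A = -1, A = 1), ab = c(A = -1, B = 1),
                 ac = c(A = -1, C = 1), bd = c(B = -1, D = 1),
                 cd = c(C = -1, D = 1), D_tx = c(D = -1, x_D = 1))
  metabolic_model(mets, list(), rxns, stoich, list(), character(0),
                  biomass_reaction_id = "D_tx", atpm_reaction_id = "D_tx")
}

# glucose -> 2 lactate fixture with real formulas (balanced), plus a broken
# variant losing one lactate
glycolysis_fixture <- function(broken = FALSE) {
  f <- list(glc = c(C = 6, H = 12, O = 6), lac = c(C = 3, H = 6, O = 3))
  mets <- data.frame(
    id = c("glc", "lac", "x_glc", "x_lac"),
    name = c("glc", "lac", "x_glc", "x_lac"),
    compartment = c("cytosol", "cytosol", "external", "external"),
    is_external = c(FALSE, FALSE, TRUE, TRUE), stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("glc_tx", "ferm", "lac_tx"),
    lower_bound = 0, upper_bound = c(10, 1000, 1000),
    subsystem = "", stringsAsFactors = FALSE)
  stoich <- list(glc_tx = c(x_glc = -1, glc = 1),
                 ferm = c(glc = -1, lac = if (broken) 1 else 2),
                 lac_tx = c(lac = -1, x_lac = 1))
  metabolic_model(mets, f, rxns, stoich, list(), character(0),
                  biomass_reaction_id = "lac_tx", atpm_reaction_id = "lac_tx")
}
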