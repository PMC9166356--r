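# Model container, JSON I/O, stoichiometric matrix, validation checks.

test_that("JSON round trip preserves the model structure", {
  truth <- generate_toy_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(truth$model, path)
  m2 <- read_model_json(path)
  expect_identical(m2$metabolites$id, truth$model$metabolites$id)
  expect_identical(m2$reactions$id, truth$model$reactions$id)
  expect_equal(m2$reactions$lower_bound, truth$model$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, truth$model$reactions$upper_bound)
  for (rid in m2$reactions$id) {
    expect_equal(sort(names(m2$stoich[[rid]])),
                 sort(names(truth$model$stoich[[rid]])), info = rid)
    expect_equal(m2$stoich[[rid]][names(truth$model$stoich[[rid]])],
                 truth$model$stoich[[rid]], info = rid)
  }
  expect_identical(sort(m2$genes), sort(truth$model$genes))
  for (rid in names(truth$model$gpr)) {
    expect_identical(deparse_gpr(m2$gpr[[rid]]),
                     deparse_gpr(truth$model$gpr[[rid]]), info = rid)
  }
  expect_equal(m2$gam, truth$model$gam)
})

test_that("loader reports dangling references and missing fields by name", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    metabolites = list(list(id = "A", is_external = FALSE)),
    reactions = list(list(id = "r1", stoichiometry = list(Q = -1),
                          lower_bound = 0, upper_bound = 10)),
    genes = list(), biomass_reaction = "r1", atpm_reaction = "r1"
  ), path, auto_unbox = TRUE)
  expect_error(read_model_json(path), "Q")

  jsonlite::write_json(list(metabolites = list()), path, auto_unbox = TRUE)
  expect_error(read_model_json(path), "missing field")

  expect_error(read_model_json("does/not/exist.json"), "not found")
})

test_that("unknown top-level fields are ignored with a warning", {
  truth <- generate_toy_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(truth$model, path)
  raw <- jsonlite::read_json(path)
  raw$spurious <- "x"
  jsonlite::write_json(raw, path, auto_unbox = TRUE)
  expect_warning(read_model_json(path), "spurious")
})

test_that("stoichiometric matrix entries follow the coefficient convention", {
  m <- chain_model()
  N <- stoichiometric_matrix(m)
  expect_equal(unname(N["A", "conv"]), -1)
  expect_equal(unname(N["B", "conv"]), 1)
  expect_false("x_A" %in% rownames(N))

  # 2A -> B column
  m$stoich$conv <- c(A = -2, B = 1)
  N2 <- stoichiometric_matrix(m)
  expect_equal(unname(N2[c("A", "B"), "conv"]), c(-2, 1))

  # hand-constructed steady-state vector lies in the null space
  v <- c(A_tx = 5, conv = 5, B_tx = 5)
  expect_lt(max(abs(N %*% v[colnames(N)])), 1e-12)
})

test_that("atom balance accepts balanced and flags broken chemistry", {
  expect_equal(nrow(check_atom_balance(glycolysis_fixture())), 0)
  imb <- check_atom_balance(glycolysis_fixture(broken = TRUE))
  expect_setequal(imb$reaction_id, "ferm")
  expect_equal(imb$imbalance[imb$element == "C"], -3)
  expect_equal(imb$imbalance[imb$element == "H"], -6)
  expect_equal(imb$imbalance[imb$element == "O"], -3)

  # planted defect in the toy model is pinpointed
  truth <- generate_toy_model()
  m <- truth$model
  m$stoich$tca[["co2"]] <- 3
  imb2 <- check_atom_balance(m)
  expect_setequal(unique(imb2$reaction_id), "tca")

  # missing formula on a checked metabolite is diagnosed
  m2 <- glycolysis_fixture()
  m2$formulas$lac <- NULL
  expect_error(check_atom_balance(m2), "lac")
})

test_that("unconserved metabolites are detected and stable under rescaling", {
  # A <-> B conserved both ways (A_tx is transport; ab/ba are internal)
  mets <- data.frame(id = c("A", "B", "x_A"), name = c("A", "B", "x_A"),
                     compartment = c("cytosol", "cytosol", "external"),
                     is_external = c(FALSE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("A_tx", "ab", "ba"), lower_bound = 0,
                     upper_bound = 10, subsystem = "",
                     stringsAsFactors = FALSE)
  m <- metabolic_model(mets, list(), rxns,
                       list(A_tx = c(x_A = -1, A = 1),
                            ab = c(A = -1, B = 1), ba = c(B = -1, A = 1)),
                       list(), character(0), "A_tx", "A_tx")
  expect_identical(find_unconserved_metabolites(m), character(0))

  # A -> A + B nets to "B from nothing"; B flagged
  mc <- m
  mc$stoich$ab <- c(B = 1)
  flagged <- find_unconserved_metabolites(mc)
  expect_true("B" %in% flagged)

  # invariance: reaction reordering and positive column scaling
  truth <- generate_toy_model()
  base <- find_unconserved_metabolites(truth$model)
  perm <- truth$model
  ord <- rev(seq_len(nrow(perm$reactions)))
  perm$reactions <- perm$reactions[ord, ]
  perm$stoich <- perm$stoich[perm$reactions$id]
  expect_identical(sort(find_unconserved_metabolites(perm)), sort(base))
  scaled <- truth$model
  scaled$stoich$ed <- scaled$stoich$ed * 2.5
  expect_identical(sort(find_unconserved_metabolites(scaled)), sort(base))

  # a creation-from-nothing defect is flagged, and the flagged set agrees
  # with an independent per-metabolite oracle: metabolite i is conserved iff
  # max { m_i : N' m = 0, m >= 0 } > 0
  bad <- truth$model
  bad$stoich$phaC <- c(phb = 1, coa = 1)
  flagged_bad <- find_unconserved_metabolites(bad)
  expect_true(all(c("phb", "coa") %in% flagged_bad))
  oracle_unconserved <- function(model) {
    internal <- setdiff(model$reactions$id,
                        c(transporter_ids(model), model$biomass_reaction_id))
    N <- stoichiometric_matrix(model)[, internal, drop = FALSE]
    use <- rownames(N)[rowSums(N != 0) > 0]
    N <- N[use, , drop = FALSE]
    bad_ids <- character(0)
    for (i in seq_along(use)) {
      obj <- numeric(length(use)); obj[i] <- 1
      s <- solve_lp(obj, t(N), rep("=", ncol(N)), rep(0, ncol(N)),
                    lb = rep(0, length(use)), ub = rep(10, length(use)))
      if (s$objective < 1e-6) bad_ids <- c(bad_ids, use[i])
    }
    bad_ids
  }
  expect_setequal(flagged_bad, oracle_unconserved(bad))
  expect_setequal(base, oracle_unconserved(truth$model))
})

test_that("energy-cycle check is clean on the toy and catches a planted loop", {
  truth <- generate_toy_model()
  expect_equal(check_energy_cycles(truth$model)$flux, 0)

  # planted directionality error: a free ATP-regenerating reaction
  m <- truth$model
  m$reactions <- rbind(m$reactions, data.frame(
    id = "bad_atpase", lower_bound = 0, upper_bound = 1000, subsystem = "",
    stringsAsFactors = FALSE))
  m$stoich$bad_atpase <- c(adp = -1, pi = -1, atp = 1, h2o = 1)
  expect_gt(check_energy_cycles(m)$flux, 1)
})

test_that("the shipped toy model passes the full validation report", {
  rep <- validate_model(generate_toy_model()$model)
  expect_true(rep$passed)
  expect_equal(nrow(rep$imbalanced_reactions), 0)
  expect_length(rep$unconserved_metabolites, 0)
  expect_equal(rep$energy_cycle_flux, 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_validation_report(rep, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.tsv$", ".log", path)))
})
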