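# FBA, pFBA, FVA, screening, precursors, normalization, correlation, P/O.

test_that("FBA is bound-limited on a chain and handles edge objectives", {
  m <- chain_model(cap = 10)
  sol <- fba(flux_problem(m, objective = c(B_tx = 1)))
  expect_equal(sol$objective, 10)
  expect_equal(unname(sol$fluxes[c("A_tx", "conv", "B_tx")]), c(10, 10, 10))

  zero <- fba(flux_problem(m, objective = c(B_tx = 0)))
  expect_equal(zero$status, "optimal")
  expect_equal(zero$objective, 0)
})

test_that("FBA matches the vertex-enumeration oracle on the branched toy", {
  m <- branched_model()
  obj <- c(D_tx = 1)
  expect_equal(fba(flux_problem(m, objective = obj))$objective,
               oracle_fba(m, obj))
  # capacity structure: ab<=4 and cd<=3 cap D_tx at 7
  expect_equal(fba(flux_problem(m, objective = obj))$objective, 7)
})

test_that("pFBA keeps the FBA optimum and minimizes total flux", {
  m <- parallel_routes_model(cap = 10)
  obj <- c(B_tx = 1)
  p <- pfba(flux_problem(m, objective = obj))
  f <- fba(flux_problem(m, objective = obj))
  expect_equal(p$objective, f$objective, tolerance = 1e-6)
  # all flux goes down the one-step route
  expect_equal(unname(p$fluxes["short"]), 10, tolerance = 1e-6)
  expect_equal(unname(p$fluxes["long1"]), 0, tolerance = 1e-6)
  expect_equal(p$total_flux, oracle_pfba_total(m, obj), tolerance = 1e-6)

  # single-route model: pFBA flux vector equals the FBA one
  mc <- chain_model()
  expect_equal(pfba(flux_problem(mc, objective = c(B_tx = 1)))$fluxes,
               fba(flux_problem(mc, objective = c(B_tx = 1)))$fluxes,
               tolerance = 1e-8)
})

test_that("FVA ranges match vertex extremes and classify blocked reactions", {
  m <- branched_model()
  res <- fva(m, growth_fraction = 0)
  for (rid in m$reactions$id) {
    r <- res$ranges[res$ranges$reaction_id == rid, ]
    orc <- oracle_fva_range(m, rid)
    expect_equal(c(r$vmin, r$vmax), orc, tolerance = 1e-6, info = rid)
  }

  # dead-end reaction is blocked
  md <- m
  md$metabolites <- rbind(md$metabolites, data.frame(
    id = "E", name = "E", compartment = "cytosol", is_external = FALSE,
    stringsAsFactors = FALSE))
  md$reactions <- rbind(md$reactions, data.frame(
    id = "dead", lower_bound = 0, upper_bound = 10, subsystem = "",
    stringsAsFactors = FALSE))
  md$stoich$dead <- c(A = -1, E = 1)
  res2 <- fva(md, growth_fraction = 0)
  expect_identical(blocked_reactions(res2), "dead")

  # constrained FVA: growth >= 90% of optimum narrows ranges
  truth <- generate_toy_model()
  res90 <- fva(truth$model, growth_fraction = 0.9,
               reactions = c("biomass", "ack"))
  mu <- res90$optimum
  bio <- res90$ranges[res90$ranges$reaction_id == "biomass", ]
  expect_gte(bio$vmin, 0.9 * mu - 1e-6)
})

test_that("pFBA flux lies inside the FVA range for every reaction", {
  truth <- generate_toy_model()
  p <- pfba(flux_problem(truth$model))
  res <- fva(truth$model, growth_fraction = 1)
  for (i in seq_len(nrow(res$ranges))) {
    r <- res$ranges[i, ]
    expect_gte(p$fluxes[[r$reaction_id]], r$vmin - 1e-5)
    expect_lte(p$fluxes[[r$reaction_id]], r$vmax + 1e-5)
  }
})

test_that("carbon screen calls native and dead-end substrates correctly", {
  truth <- generate_toy_model()
  expect_identical(screen_carbon_source(truth$model, "fru")$call, "growth")
  # acetate has no catabolic route (ack is irreversible towards acetate)
  expect_identical(screen_carbon_source(truth$model, "ac")$call, "no_growth")
  # pyruvate gets an auto-added transporter and supports growth
  expect_identical(screen_carbon_source(truth$model, "pyr")$call, "growth")
  expect_error(screen_carbon_source(truth$model, "nope"), "unknown")
})

test_that("carbon screen is monotone in the uptake bound", {
  truth <- generate_toy_model()
  mus <- vapply(c(1, 5, 10, 20), function(u) {
    screen_carbon_source(truth$model, "fru", uptake = u)$growth_rate
  }, numeric(1))
  expect_true(all(diff(mus) >= -1e-8))
})

test_that("phenotype-screen scoring reproduces confusion arithmetic", {
  pred <- c(a = "growth", b = "growth", c = "no_growth", d = "no_growth")
  obs <- c(a = "growth", b = "no_growth", c = "growth", d = "no_growth")
  sc <- score_phenotype_screen(pred, obs)
  expect_equal(unname(sc$confusion), c(1, 1, 1, 1))
  expect_equal(sc$accuracy, 0.5)
})

test_that("biomass precursors: intact, flipped-direction, and gap cases", {
  truth <- generate_toy_model()
  res <- test_biomass_precursors(truth$model)
  expect_true(all(res$feasible))
  expect_setequal(res$metabolite_id, c("ala", "pyr", "so4"))

  # flip alaS backwards: ala becomes infeasible, alaS is the candidate
  m <- truth$model
  m$stoich$alaS <- -m$stoich$alaS
  res2 <- test_biomass_precursors(m)
  ala <- res2[res2$metabolite_id == "ala", ]
  expect_false(ala$feasible)
  expect_false(ala$gap)
  expect_true("alaS" %in% ala$candidates[[1]])

  # delete alaS entirely: a true gap
  m3 <- truth$model
  keep <- m3$reactions$id != "alaS"
  m3$reactions <- m3$reactions[keep, ]
  m3$stoich <- m3$stoich[m3$reactions$id]
  m3$gpr <- m3$gpr[setdiff(names(m3$gpr), "alaS")]
  res3 <- test_biomass_precursors(m3)
  expect_true(res3[res3$metabolite_id == "ala", "gap"])
})

test_that("flux normalization rescales linearly and preserves steady state", {
  truth <- generate_toy_model()
  sol <- pfba(flux_problem(truth$model))
  normed <- normalize_fluxes(sol, "fru_tx", target = 1)
  expect_equal(unname(normed$fluxes["fru_tx"]), 1)
  expect_equal(normed$fluxes, sol$fluxes / sol$fluxes[["fru_tx"]])
  N <- stoichiometric_matrix(truth$model)
  expect_lt(max(abs(N %*% normed$fluxes)), 1e-6)
  expect_equal(normalize_fluxes(sol, "fru_tx",
                                target = sol$fluxes[["fru_tx"]])$fluxes,
               sol$fluxes)
  zero <- sol; zero$fluxes["ack"] <- 0
  expect_error(normalize_fluxes(zero, "ack"), "zero")
})

test_that("flux-vector correlation matches direct computation", {
  v1 <- c(r1 = 1, r2 = 2, r3 = 3, r4 = 5)
  expect_equal(compare_flux_vectors(v1, v1)$pearson_r, 1)
  expect_equal(compare_flux_vectors(v1, -v1)$pearson_r, -1)
  expect_equal(compare_flux_vectors(v1, -v1)$r_squared, 1)
  v2 <- c(r1 = 2, r2 = 1, r3 = 4, r4 = 4)
  expect_equal(compare_flux_vectors(v1, v2)$pearson_r,
               cor(v1, v2))
  expect_error(compare_flux_vectors(v1, c(r1 = 1, r2 = 1, r3 = 1, r4 = 1)),
               "variance")
  expect_error(compare_flux_vectors(v1[1:2], v2[1:2]), "at least 3")
})

test_that("P/O ratio arithmetic on the two ETC branches", {
  truth <- generate_toy_model()
  sol <- pfba(flux_problem(truth$model))
  # high-efficiency branch alone: 2 ATP per O atom
  fake <- sol; fake$fluxes[] <- 0; fake$fluxes["etc_hi"] <- 7
  expect_equal(po_ratio(fake, truth$model), 2)
  fake$fluxes["etc_hi"] <- 0; fake$fluxes["etc_lo"] <- 3
  expect_equal(po_ratio(fake, truth$model), 1)
  # anaerobic: undefined
  fake$fluxes["etc_lo"] <- 0
  expect_error(po_ratio(fake, truth$model), "undefined")
})
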