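# Expression mapping, iMAT thresholds and MILP, growth-rate estimation.

test_that("GPR mapping rules: OR sums, AND takes the minimum, nesting works", {
  truth <- generate_toy_model()
  m <- truth$model
  rpkm <- stats::setNames(rep(10, length(m$genes)), m$genes)
  rpkm[c("gPdh1", "gPdh2")] <- c(100, 50)
  rpkm[c("gEd1", "gEd2", "gEd3")] <- c(100, 50, 75)
  rx <- map_expression_to_reactions(m, rpkm)
  expect_equal(unname(rx["pdh"]), 150)      # OR: sum of isoenzymes
  expect_equal(unname(rx["ed"]), 50)        # AND: min over the complex
  expect_true(is.na(rx["atpm"]))            # no GPR -> no value

  # nested OR(AND(g1,g2), g3) composes both rules
  nested <- parse_gpr("(gA and gB) or gC")
  m2 <- m
  m2$genes <- c(m2$genes, "gA", "gB", "gC")
  m2$gpr$atpm <- nested
  rx2 <- map_expression_to_reactions(
    m2, c(rpkm, gA = 100, gB = 50, gC = 30))
  expect_equal(unname(rx2["atpm"]), 80)

  # monotonicity: raising one gene never lowers any reaction value
  bumped <- rpkm; bumped["gPdh2"] <- bumped["gPdh2"] + 500
  rx3 <- map_expression_to_reactions(m, bumped)
  ok <- !is.na(rx) & !is.na(rx3)
  expect_true(all(rx3[ok] >= rx[ok] - 1e-12))

  # missing genes warn and count as zero
  expect_warning(rx4 <- map_expression_to_reactions(m, rpkm[-1]), "gAacs")
  expect_equal(unname(rx4["aacs"]), 0)
})

test_that("fold-change weighting multiplies and ranks shifted pathways up", {
  base <- c(r1 = 100, r2 = 50)
  ref <- c(r1 = 50, r2 = 50)
  w <- weight_condition_expression(base, ref)
  expect_equal(unname(w["r1"]), 100 * (101 / 51))
  expect_equal(unname(w["r2"]), 50)         # fold change 1: unchanged

  truth <- generate_toy_model()
  expr <- generate_expression(truth, sim_config(seed = 2))
  rx16 <- map_expression_to_reactions(truth$model, expr, "f16")
  rx26 <- map_expression_to_reactions(truth$model, expr, "f26")
  w26 <- weight_condition_expression(rx26, rx16)
  up <- truth$n_limited_shifted_reactions
  up <- up$reaction_id[up$direction == "up"]
  for (rid in up) {
    expect_gt(rank(w26)[rid], rank(rx26)[rid] - 1e-9)
  }
})

test_that("iMAT thresholds: 95th-percentile high cut and IQR-guarded low cut", {
  rx <- stats::setNames(as.numeric(1:100), paste0("r", 1:100))
  cuts <- derive_imat_thresholds(rx, paste0("r", c(10, 12, 15)))
  expect_equal(cuts$high_cut, 95.05)
  expect_equal(cuts$low_cut, 10)

  # an outlying essential value below Q1 - 1.5 IQR is excluded
  rx2 <- c(rx, out = 0.01)
  cuts2 <- derive_imat_thresholds(rx2, c("out", paste0("r", c(10, 12, 15, 14))))
  expect_equal(cuts2$low_cut, 10)
  expect_error(derive_imat_thresholds(rx, character(0)), "empty")
})

test_that("category assignment respects both cut-offs", {
  cats <- assign_imat_categories(c(a = 1, b = 50, c = 99, d = NA),
                                 low_cut = 5, high_cut = 95)
  expect_identical(unname(cats), c("low", "moderate", "high", "moderate"))
})

test_that("iMAT activates the high route and silences the low route", {
  # two parallel routes; expression discriminates them
  m <- parallel_routes_model(cap = 10)
  cats <- c(short = "low", long1 = "high")
  cs <- imat(m, cats, epsilon = 0.1, growth_rate = 0)
  expect_equal(cs$objective, 2)
  expect_true("long1" %in% cs$active)
  expect_true("short" %in% cs$suppressed)
  expect_gte(cs$fluxes[["long1"]], 0.1 - 1e-9)
  expect_lt(abs(cs$fluxes[["short"]]), 0.1 + 1e-9)

  # all-moderate categories: nothing to score
  cs2 <- imat(m, c(short = "moderate"), epsilon = 0.1)
  expect_equal(cs2$objective, 0)

  # infeasible growth demand names the constraint
  truth <- generate_toy_model()
  expect_error(imat(truth$model, c(ack = "low"), growth_rate = 100),
               "growth")
})

test_that("nitrogen-limited iMAT redirects carbon to storage, no by-products", {
  truth <- generate_toy_model()
  expr <- generate_expression(truth, sim_config(seed = 1))
  rx16 <- map_expression_to_reactions(truth$model, expr, "f16")
  rx26 <- weight_condition_expression(
    map_expression_to_reactions(truth$model, expr, "f26"), rx16)
  ess <- essential_reactions(truth$model)
  cuts <- derive_imat_thresholds(rx26, ess)
  cats <- assign_imat_categories(rx26, cuts$low_cut, cuts$high_cut)
  cs <- imat(truth$model, cats, epsilon = 0.1, growth_rate = 0.009,
             nutrient_caps = list(fru_tx = c(2.1, 2.1),
                                  nh4_tx = c(0, 0.014)))
  expect_gt(cs$fluxes[["phb_tx"]], 0.1)     # storage branch is the sink
  expect_lt(abs(cs$fluxes[["ac_tx"]]), 1e-6)  # no alternative by-product
  # embedded solution satisfies the base-model constraints
  N <- stoichiometric_matrix(truth$model)
  expect_lt(max(abs(N %*% cs$fluxes)), 1e-6)
  expect_true(all(cs$fluxes >= truth$model$reactions$lower_bound - 1e-6))
  expect_true(all(cs$fluxes <= truth$model$reactions$upper_bound + 1e-6))
  # iMAT objective is an integer within its structural range
  expect_true(cs$objective == round(cs$objective))
  expect_lte(cs$objective, sum(cats %in% c("high", "low")))
})

test_that("condition-specific models round-trip with provenance annotation", {
  m <- parallel_routes_model(cap = 10)
  cs <- imat(m, c(short = "low", long1 = "high"), epsilon = 0.1)
  path <- withr::local_tempfile(fileext = ".json")
  write_condition_model(cs, path)
  raw <- jsonlite::read_json(path)
  expect_identical(raw$annotation$derivation, "imat_condition_specific")
  expect_equal(raw$annotation$imat_objective, cs$objective)
  m2 <- read_model_json(path)
  # suppressed reaction bounds are clamped in the saved model
  i <- match("short", m2$reactions$id)
  expect_lte(m2$reactions$upper_bound[i], cs$epsilon)
})

test_that("growth-rate estimation recovers generated rates", {
  ts <- generate_biomass_timeseries(growth_rate = 0.2, noise = 0)
  est <- estimate_growth_rate(ts$growth$time, ts$growth$biomass, "logistic")
  expect_equal(est, 0.2, tolerance = 0.01)

  # constant biomass: rate 0 in both modes
  flat <- rep(1.7, 10)
  expect_equal(estimate_growth_rate(1:10, flat, "logistic"), 0)
  expect_equal(estimate_growth_rate(1:10, flat, "linear"), 0, tolerance = 1e-9)

  # linear mode: slope over mean biomass
  tt <- 0:9; bb <- 5 + 0.05 * tt
  expect_equal(estimate_growth_rate(tt, bb, "linear"), 0.05 / mean(bb))
  expect_error(estimate_growth_rate(1:3, c(1, 2, 3), "linear"), "4 time points")
})
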