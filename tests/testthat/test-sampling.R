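# Flux sampling, convergence screening, differential flux, regulation.

test_that("sampler reproduces uniform moments on a 1-D polytope", {
  m <- toy_sampling_model(n_chains = 1, caps = 10)
  ss <- sample_fluxes(m, n = 10000, thinning = 1, seed = 42)
  x <- ss$samples[, "upt1_tx"]
  se_mean <- sqrt(100 / 12 / 10000)
  expect_lt(abs(mean(x) - 5), 3 * se_mean)
  # variance of the sample variance for U(0,10): mu4 = 10^4/80
  se_var <- sqrt((10^4 / 80 - (100 / 12)^2 * (10000 - 3) / (10000 - 1)) / 10000)
  expect_lt(abs(var(x) - 100 / 12), 3 * se_var)
})

test_that("sampling is deterministic under a fixed seed", {
  m <- toy_sampling_model(n_chains = 3, caps = c(5, 10, 2))
  s1 <- sample_fluxes(m, n = 50, thinning = 2, seed = 7)
  s2 <- sample_fluxes(m, n = 50, thinning = 2, seed = 7)
  expect_identical(s1$samples, s2$samples)
  s3 <- sample_fluxes(m, n = 50, thinning = 2, seed = 8)
  expect_false(identical(s1$samples, s3$samples))
})

test_that("a point polytope is rejected", {
  m <- toy_sampling_model(n_chains = 1, caps = 10)
  expect_error(sample_fluxes(m, n = 10, bounds = list(upt1_tx = c(4, 4),
                                                      rel1_tx = c(4, 4))),
               "zero-volume")
})

test_that("every retained sample satisfies steady state and bounds", {
  truth <- generate_toy_model()
  ss <- sample_fluxes(truth$model, n = 100, thinning = 5, seed = 3)
  N <- stoichiometric_matrix(truth$model)
  expect_lt(max(abs(N %*% t(ss$samples))), 1e-6)
  lb <- truth$model$reactions$lower_bound
  ub <- truth$model$reactions$upper_bound
  for (i in seq_len(nrow(ss$samples))) {
    expect_true(all(ss$samples[i, ] >= lb - 1e-6))
    expect_true(all(ss$samples[i, ] <= ub + 1e-6))
  }
})

test_that("convergence screen: identical runs clean, null rarely flagged", {
  m <- toy_sampling_model(n_chains = 2, caps = 10)
  s1 <- sample_fluxes(m, n = 200, thinning = 3, seed = 1)
  expect_length(check_convergence(s1, s1), 0)
})

test_that("differential flux recovers a planted fold shift", {
  m_a <- toy_sampling_model(n_chains = 5, caps = 10)
  m_b <- toy_sampling_model(n_chains = 5, caps = c(40, rep(10, 4)))
  sa <- sample_fluxes(m_a, n = 600, thinning = 15, seed = 21)
  sb <- sample_fluxes(m_b, n = 600, thinning = 15, seed = 22)
  diff <- differential_flux(sa, sb)
  hit <- diff[diff$reaction_id %in% c("upt1_tx", "rel1_tx"), ]
  expect_true(all(hit$call == "up"))
  expect_true(all(hit$fc > 0.33))
  # BH adjustment: q >= p, monotone in p-rank
  expect_true(all(diff$q >= diff$p - 1e-12))
  ord <- order(diff$p)
  expect_true(all(diff(cummax(diff$q[ord])) >= -1e-12))
})

test_that("FC is antisymmetric under condition swap", {
  m <- toy_sampling_model(n_chains = 3, caps = c(4, 8, 16))
  sa <- sample_fluxes(m, n = 150, thinning = 5, seed = 5)
  sb <- sample_fluxes(m, n = 150, thinning = 5, seed = 6)
  d1 <- differential_flux(sa, sb)
  d2 <- differential_flux(sb, sa)
  expect_equal(d1$fc, -d2$fc[match(d1$reaction_id, d2$reaction_id)],
               tolerance = 1e-12)
  # the analytic statistic: 2:1 means give FC = 1/3
  expect_equal(flux_change(1, 2), 1 / 3)
  expect_equal(flux_change(2, 1), -1 / 3)
  expect_true(is.na(flux_change(1, -1)))
})

test_that("identical distributions are not called", {
  m <- toy_sampling_model(n_chains = 3, caps = 10)
  sa <- sample_fluxes(m, n = 300, thinning = 10, seed = 31)
  sb <- sample_fluxes(m, n = 300, thinning = 10, seed = 32)
  diff <- differential_flux(sa, sb)
  expect_true(all(diff$call == "unchanged"))
})

test_that("single-model reactions get bootstrap confidence intervals", {
  set.seed(2)
  # all-zero samples: CI [0,0], unchanged
  bs0 <- bootstrap_single_model(rep(0, 200), n_boot = 100, seed = 1)
  expect_equal(bs0$ci95, c(0, 0))
  expect_identical(bs0$call, "unchanged")

  # separated support: uniform on [5,10] excludes zero, called up
  bs1 <- bootstrap_single_model(runif(500, 5, 10), n_boot = 500, seed = 1)
  expect_identical(bs1$call, "up")
  expect_gt(bs1$ci95[1], 0)
  bs2 <- bootstrap_single_model(runif(500, -10, -5), n_boot = 500, seed = 1)
  expect_identical(bs2$call, "down")

  expect_error(bootstrap_single_model(1:10), ">= 100")

  # Monte-Carlo CI approximates the exact normal-approximation interval
  x <- rnorm(400, mean = 1, sd = 1)
  bs3 <- bootstrap_single_model(x, n_boot = 4000, seed = 3)
  expect_equal(bs3$ci95[1], mean(x) - 1.96 * sd(x) / 20, tolerance = 0.03)
  expect_equal(bs3$ci95[2], mean(x) + 1.96 * sd(x) / 20, tolerance = 0.03)

  # reactions absent from one condition are routed through the bootstrap
  m3 <- toy_sampling_model(n_chains = 2, caps = 10)
  sa <- sample_fluxes(m3, n = 150, thinning = 5, seed = 11)
  sb <- sample_fluxes(m3, n = 150, thinning = 5, seed = 12)
  sb$samples <- sb$samples[, 1:2]
  d <- differential_flux(sa, sb, n_boot = 300)
  extra <- d[d$reaction_id %in% c("upt2_tx", "rel2_tx"), ]
  expect_true(all(extra$call == "single_model"))
  expect_true(all(extra$ci_lo > 0))
})

test_that("sample sets persist as TSV with a settings manifest", {
  m <- toy_sampling_model(n_chains = 2, caps = 10)
  ss <- sample_fluxes(m, n = 20, thinning = 2, seed = 9)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_set(ss, path)
  back <- as.matrix(read.delim(path))
  expect_equal(unname(back), unname(ss$samples), tolerance = 1e-9)
  man <- jsonlite::read_json(paste0(path, ".manifest.json"))
  expect_equal(man$seed, 9)
  expect_equal(man$thinning, 2)
})

test_that("regulation classes follow concordance of flux and expression", {
  diff <- data.frame(reaction_id = c("r1", "r2", "r3", "r4"),
                     call = c("up", "up", "down", "up"),
                     stringsAsFactors = FALSE)
  lfc <- c(r1 = 2, r2 = 0.1, r3 = 2)
  expect_warning(reg <- classify_regulation(diff, lfc), "r4")
  expect_identical(reg$class[reg$reaction_id == "r1"], "transcriptional")
  expect_identical(reg$class[reg$reaction_id == "r2"], "post_translational")
  expect_identical(reg$class[reg$reaction_id == "r3"], "mixed")
  # only altered reactions are classified
  none <- classify_regulation(
    data.frame(reaction_id = "r1", call = "unchanged",
               stringsAsFactors = FALSE), lfc)
  expect_equal(nrow(none), 0)
})
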