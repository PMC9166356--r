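# Hit-and-run flux sampling and differential-flux statistics.
#
# The sampler is an artificial-centering hit-and-run (ACHR) chain over the
# flux polytope {v : N v = 0, lb <= v <= ub}. Warmup points are FVA-style
# vertices; directions are drawn as (stored point - running center), which
# adapts the proposal to the polytope's shape. Every move stays inside the
# null space of N, so each retained sample satisfies steady state to
# numerical precision.

# run code under a temporary RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Sample the flux polytope of a model
#'
#' Draws `n` flux vectors from the steady-state solution space with an
#' artificial-centering hit-and-run chain, retaining one point every
#' `thinning` steps after a warmup of FVA vertices. Reproducible for a fixed
#' seed.
#'
#' @param model a `metabolic_model` or `condition_specific_model`.
#' @param n number of samples to retain.
#' @param thinning chain steps per retained sample.
#' @param seed integer seed.
#' @param bounds optional bound overrides (named list of `c(lb, ub)`).
#' @return object of class `sample_set`: list with `samples` (n x reactions
#'   matrix), `condition`, `n_samples`, `thinning`, `seed`.
#' @export
sample_fluxes <- function(model, n = 10000, thinning = 1000, seed = 1L,
                          bounds = list()) {
  if (inherits(model, "condition_specific_model")) model <- model$model
  N <- stoichiometric_matrix(model)
  nr <- ncol(N)
  rids <- colnames(N)
  lb <- stats::setNames(model$reactions$lower_bound, rids)
  ub <- stats::setNames(model$reactions$upper_bound, rids)
  for (rid in names(bounds)) {
    lb[rid] <- bounds[[rid]][1]; ub[rid] <- bounds[[rid]][2]
  }

  # orthonormal null-space basis of N (directions must stay inside it)
  sv <- svd(N, nu = 0, nv = nr)
  rank <- sum(sv$d > max(dim(N)) * max(sv$d, 0) * 1e-12)
  if (rank >= nr) stop("zero-volume flux polytope: no degrees of freedom")
  Z <- sv$v[, (rank + 1):nr, drop = FALSE]

  # warmup vertices: per-reaction min/max LPs
  W <- list()
  for (rid in rids) {
    for (sense in c("max", "min")) {
      s <- fba(flux_problem(model, objective = stats::setNames(1, rid),
                            bounds = lapply(
                              stats::setNames(rids, rids),
                              function(r) c(lb[[r]], ub[[r]])),
                            sense = sense))
      if (s$status == "optimal") W[[length(W) + 1L]] <- s$fluxes
    }
  }
  if (length(W) == 0) stop("infeasible flux polytope")
  W <- do.call(rbind, W)
  spread <- apply(W, 2, function(x) diff(range(x)))
  if (max(spread) < 1e-9) {
    stop("zero-volume flux polytope: all fluxes are fixed")
  }

  center <- colMeans(W)
  x <- center
  n_stored <- nrow(W)
  samples <- matrix(NA_real_, n, nr, dimnames = list(NULL, rids))
  .with_seed(seed, {
    kept <- 0L
    step <- 0L
    while (kept < n) {
      step <- step + 1L
      p <- W[sample.int(nrow(W), 1L), ]
      d <- p - center
      d <- as.numeric(Z %*% crossprod(Z, d))   # stay exactly in null(N)
      nrm <- sqrt(sum(d^2))
      if (nrm < 1e-12) next
      d <- d / nrm
      act <- abs(d) > 1e-10
      alo <- (lb[act] - x[act]) / d[act]
      ahi <- (ub[act] - x[act]) / d[act]
      amin <- max(pmin(alo, ahi))
      amax <- min(pmax(alo, ahi))
      if (!is.finite(amin) || !is.finite(amax) || amax - amin < 1e-12) next
      x <- x + stats::runif(1, amin, amax) * d
      x <- pmin(pmax(x, lb), ub)
      # running artificial center over everything seen
      n_stored <- n_stored + 1L
      center <- center + (x - center) / n_stored
      if (step %% thinning == 0L) {
        kept <- kept + 1L
        samples[kept, ] <- x
      }
    }
  })
  structure(list(samples = samples, condition = "", n_samples = n,
                 thinning = thinning, seed = as.integer(seed)),
            class = "sample_set")
}

#' Write a sample set as TSV with a sidecar manifest
#'
#' The samples go to a plain TSV (one column per reaction); a
#' `<path>.manifest.json` sidecar records the sampling settings so a stored
#' matrix stays interpretable.
#'
#' @param sample_set a `sample_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_set <- function(sample_set, path) {
  stopifnot(inherits(sample_set, "sample_set"))
  utils::write.table(sample_set$samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(condition = sample_set$condition,
                            n_samples = sample_set$n_samples,
                            thinning = sample_set$thinning,
                            seed = sample_set$seed),
                       paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Flag reactions whose sampling has not converged
#'
#' Compares two independent sampling runs of the same model reaction by
#' reaction with a two-sample Kolmogorov-Smirnov test; reactions whose flux
#' distributions differ at level `alpha` are flagged unstable and should be
#' excluded from differential analysis.
#'
#' @param run1,run2 `sample_set` objects over the same reactions.
#' @param alpha significance level.
#' @return character vector of unstable reaction ids.
#' @export
check_convergence <- function(run1, run2, alpha = 0.05) {
  common <- intersect(colnames(run1$samples), colnames(run2$samples))
  p <- vapply(common, function(rid) {
    x <- run1$samples[, rid]; y <- run2$samples[, rid]
    if (stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12 &&
        abs(mean(x) - mean(y)) < 1e-9) return(1)
    suppressWarnings(stats::ks.test(x, y)$p.value)
  }, numeric(1))
  common[p < alpha]
}

#' Differential flux analysis between two conditions
#'
#' Per reaction sampled in both conditions: a two-sample KS test, a
#' Benjamini-Hochberg adjustment across all tested reactions, and the
#' normalized flux change `FC = (mean_b - mean_a) / (mean_b + mean_a)`.
#' A reaction is called up (higher in `b`) when `q < alpha` and
#' `FC > fc_cut`, down when `q < alpha` and `FC < -fc_cut`. Reactions whose
#' mean fluxes cancel (|sum| below `den_tol`) are marked unstable rather
#' than reported with a diverging FC. Reactions present in only one set are
#' routed to a bootstrap confidence interval on the mean
#' ([bootstrap_single_model()]) and called `single_model` up/down when zero
#' lies outside the 95% CI.
#'
#' @param a,b `sample_set` objects for the two conditions.
#' @param alpha significance level applied to the adjusted p-values.
#' @param fc_cut FC magnitude that must be strictly exceeded; the default
#'   1/3 (printed as 0.33) is the FC of an exact 2-fold change, so a
#'   reaction must change by more than 2-fold to be called.
#' @param exclude reaction ids to drop (e.g. from [check_convergence()]).
#' @param den_tol guard for a vanishing FC denominator.
#' @param n_boot,seed bootstrap settings for single-model reactions.
#' @return data.frame with columns `reaction_id`, `mean_a`, `mean_b`,
#'   `ks_stat`, `p`, `q`, `fc`, `call`, `ci_lo`, `ci_hi`.
#' @export
differential_flux <- function(a, b, alpha = 0.05, fc_cut = 1 / 3,
                              exclude = character(0), den_tol = 1e-9,
                              n_boot = 1000, seed = 1L) {
  ra <- setdiff(colnames(a$samples), exclude)
  rb <- setdiff(colnames(b$samples), exclude)
  common <- intersect(ra, rb)
  only_a <- setdiff(ra, rb); only_b <- setdiff(rb, ra)
  rows <- lapply(common, function(rid) {
    x <- a$samples[, rid]; y <- b$samples[, rid]
    identical_dist <- stats::sd(x) < 1e-12 && stats::sd(y) < 1e-12 &&
      abs(mean(x) - mean(y)) < 1e-9
    ks <- if (identical_dist) list(statistic = 0, p.value = 1) else
      suppressWarnings(stats::ks.test(x, y))
    data.frame(reaction_id = rid, mean_a = mean(x), mean_b = mean(y),
               ks_stat = unname(ks$statistic), p = ks$p.value,
               q = NA_real_, fc = NA_real_, call = NA_character_,
               ci_lo = NA_real_, ci_hi = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out) && nrow(out) > 0) {
    out$q <- stats::p.adjust(out$p, method = "BH")
    den <- out$mean_a + out$mean_b
    fc <- ifelse(abs(den) < den_tol, NA_real_, (out$mean_b - out$mean_a) / den)
    out$fc <- fc
    out$call <- ifelse(is.na(fc), "unstable",
                ifelse(out$q < alpha & fc > fc_cut, "up",
                ifelse(out$q < alpha & fc < -fc_cut, "down", "unchanged")))
  }
  single <- c(
    lapply(only_a, function(rid) list(rid = rid, s = a$samples[, rid], side = "a")),
    lapply(only_b, function(rid) list(rid = rid, s = b$samples[, rid], side = "b"))
  )
  srows <- lapply(single, function(e) {
    bs <- bootstrap_single_model(e$s, n_boot = n_boot, seed = seed)
    data.frame(reaction_id = e$rid,
               mean_a = if (e$side == "a") mean(e$s) else NA_real_,
               mean_b = if (e$side == "b") mean(e$s) else NA_real_,
               ks_stat = NA_real_, p = NA_real_, q = NA_real_, fc = NA_real_,
               call = if (bs$call == "unchanged") "unchanged" else "single_model",
               ci_lo = bs$ci95[1], ci_hi = bs$ci95[2], stringsAsFactors = FALSE)
  })
  rbind(out, do.call(rbind, srows))
}

#' Bootstrap confidence interval for a single-condition reaction
#'
#' Percentile bootstrap of the mean flux; the reaction is differentially
#' altered (up or down by the sign of its mean) when zero lies outside the
#' 95% confidence interval.
#'
#' @param samples numeric vector of sampled fluxes (>= 100).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `ci95` (length-2 vector) and `call`
#'   (`"up"`, `"down"`, `"unchanged"`).
#' @export
bootstrap_single_model <- function(samples, n_boot = 10000, seed = 1L,
                                   conf = 0.95) {
  if (length(samples) < 100) stop("need >= 100 samples for the bootstrap")
  if (max(abs(samples)) < 1e-12) {
    return(list(ci95 = c(0, 0), call = "unchanged"))
  }
  means <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(samples[sample.int(length(samples), replace = TRUE)])
    }, numeric(1))
  })
  ci <- unname(stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                               type = 7))
  call <- if (ci[1] > 0) "up" else if (ci[2] < 0) "down" else "unchanged"
  list(ci95 = ci, call = call)
}

#' Classify the regulatory level of differentially altered reactions
#'
#' Compares the direction of the flux change with the expression log2 fold
#' change of the catalysing genes: concordant changes (flux up with
#' expression up, or down with down) indicate transcriptional control; a
#' flux change without a matching expression change indicates
#' post-translational control; discordant signs are mixed.
#'
#' @param diff data.frame from [differential_flux()].
#' @param expression_log2fc named numeric vector of reaction-level expression
#'   log2 fold changes (condition b over condition a).
#' @param expr_cut minimal |log2 FC| treated as an expression change.
#' @return data.frame with columns `reaction_id`, `flux_direction`,
#'   `expression_log2fc`, `class`.
#' @export
classify_regulation <- function(diff, expression_log2fc, expr_cut = 1.0) {
  hits <- diff[diff$call %in% c("up", "down"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    rid <- hits$reaction_id[i]
    if (!rid %in% names(expression_log2fc) ||
        is.na(expression_log2fc[[rid]])) {
      warning("no expression fold change for reaction ", rid, "; skipped")
      return(NULL)
    }
    lfc <- expression_log2fc[[rid]]
    dirn <- hits$call[i]
    cls <- if (abs(lfc) < expr_cut) {
      "post_translational"
    } else if ((dirn == "up" && lfc >= expr_cut) ||
               (dirn == "down" && lfc <= -expr_cut)) {
      "transcriptional"
    } else {
      "mixed"
    }
    data.frame(reaction_id = rid, flux_direction = dirn,
               expression_log2fc = lfc, class = cls, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(reaction_id = character(0), flux_direction = character(0),
                      expression_log2fc = numeric(0), class = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}
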