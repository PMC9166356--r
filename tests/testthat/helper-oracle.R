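# Independent oracles used to cross-check the LP machinery.
#
# The vertex oracle enumerates all basic feasible solutions of
# {v : N v = 0, lb <= v <= ub} by fixing (n - rank(N)) variables at a bound
# and solving for the rest — brute force, valid for models with <= 8
# reactions.

enumerate_vertices <- function(model, bounds = list()) {
  N <- stoichiometric_matrix(model)
  rids <- colnames(N)
  lb <- stats::setNames(model$reactions$lower_bound, rids)
  ub <- stats::setNames(model$reactions$upper_bound, rids)
  for (rid in names(bounds)) {
    lb[rid] <- bounds[[rid]][1]; ub[rid] <- bounds[[rid]][2]
  }
  n <- length(rids)
  r <- qr(N)$rank
  k <- n - r
  verts <- list()
  push <- function(x) {
    for (v in verts) if (max(abs(v - x)) < 1e-6) return(invisible(NULL))
    verts[[length(verts) + 1L]] <<- x
  }
  fixsets <- if (k == 0) list(integer(0)) else combn(n, k, simplify = FALSE)
  for (fix in fixsets) {
    free <- setdiff(seq_len(n), fix)
    Nf <- N[, free, drop = FALSE]
    if (length(free) > 0 && qr(Nf)$rank < length(free)) next
    grid <- expand.grid(rep(list(1:2), length(fix)))
    if (nrow(grid) == 0) grid <- data.frame(row.names = 1)
    for (gi in seq_len(nrow(grid))) {
      xfix <- vapply(seq_along(fix), function(j) {
        if (grid[gi, j] == 1) lb[fix[j]] else ub[fix[j]]
      }, numeric(1))
      rhs <- if (length(fix) > 0) {
        -N[, fix, drop = FALSE] %*% xfix
      } else {
        matrix(0, nrow(N), 1)
      }
      xfree <- tryCatch(qr.solve(Nf, rhs), error = function(e) NULL)
      if (is.null(xfree)) next
      x <- numeric(n); x[fix] <- xfix; x[free] <- as.numeric(xfree)
      if (max(abs(N %*% x)) < 1e-7 &&
          all(x >= lb - 1e-7) && all(x <= ub + 1e-7)) {
        names(x) <- rids
        push(x)
      }
    }
  }
  do.call(rbind, verts)
}

oracle_fba <- function(model, objective, bounds = list(), sense = "max") {
  V <- enumerate_vertices(model, bounds)
  z <- as.numeric(V[, names(objective), drop = FALSE] %*% objective)
  if (sense == "max") max(z) else min(z)
}

oracle_fva_range <- function(model, rid, bounds = list()) {
  V <- enumerate_vertices(model, bounds)
  range(V[, rid])
}

oracle_pfba_total <- function(model, objective, bounds = list(), tol = 1e-6) {
  V <- enumerate_vertices(model, bounds)
  z <- as.numeric(V[, names(objective), drop = FALSE] %*% objective)
  zopt <- max(z)
  min(rowSums(abs(V[z >= zopt - tol, , drop = FALSE])))
}

# exhaustive truth-table evaluation of a GPR over all on/off gene states
oracle_gpr_agrees <- function(gpr) {
  genes <- gpr_genes(gpr)
  states <- expand.grid(rep(list(c(FALSE, TRUE)), length(genes)))
  for (i in seq_len(nrow(states))) {
    inactive <- genes[!unlist(states[i, ])]
    rec <- function(node) {
      if (node$kind == "GENE") return(!(node$gene_id %in% inactive))
      vals <- vapply(node$children, rec, logical(1))
      if (node$kind == "AND") all(vals) else any(vals)
    }
    if (rec(gpr) != eval_gpr(gpr, inactive)) return(FALSE)
  }
  TRUE
}

# random GPR tree with at most `max_leaves` leaves
random_gpr <- function(max_leaves = 4) {
  leaves <- sample(2:max_leaves, 1)
  ids <- paste0("g", seq_len(leaves))
  build <- function(pool) {
    if (length(pool) == 1) return(gpr_gene(pool))
    split <- sample(seq_len(length(pool) - 1), 1)
    op <- if (stats::runif(1) < 0.5) gpr_and else gpr_or
    op(build(pool[seq_len(split)]), build(pool[-seq_len(split)]))
  }
  build(ids)
}
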