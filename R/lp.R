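# Dense two-phase simplex for small linear programs.
#
# Solves  max/min  obj'x   s.t.  A x (dir) rhs,  lb <= x <= ub
# with dir entries in {"=", "<=", ">="}.  Designed for the problem sizes of
# small metabolic models (tens of reactions); all arithmetic is dense and
# Bland's rule is used throughout, trading speed for guaranteed termination.

#' Solve a linear program
#'
#' A self-contained dense two-phase simplex. Constraints are given as rows of
#' `A` with directions `dir` and right-hand sides `rhs`; variables are box
#' bounded. Infinite bounds are capped internally at a large finite value
#' (`cap`), which is safe for flux problems where structural bounds are
#' +-1000 by convention.
#'
#' @param obj numeric objective coefficient vector (length n).
#' @param A constraint matrix (m x n); may have zero rows.
#' @param dir character vector of constraint directions: `"="`, `"<="`, `">="`.
#' @param rhs numeric right-hand sides (length m).
#' @param lb,ub numeric lower/upper variable bounds (length n); may be infinite.
#' @param sense `"max"` or `"min"`.
#' @param cap finite stand-in for infinite bounds.
#' @param tol pivot/feasibility tolerance.
#' @return list with `x` (solution vector), `objective`, and `status`
#'   (`"optimal"`, `"infeasible"`, or `"unbounded"`).
#' @export
solve_lp <- function(obj, A, dir, rhs, lb, ub, sense = c("max", "min"),
                     cap = 1e6, tol = 1e-9) {
  sense <- match.arg(sense)
  n <- length(obj)
  if (is.null(dim(A))) A <- matrix(A, ncol = n)
  m <- nrow(A)
  stopifnot(length(dir) == m, length(rhs) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + 1e-12)) {
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "infeasible"))
  }

  # convert inequalities to equalities with non-negative slack columns
  ns <- sum(dir != "=")
  Afull <- cbind(A, matrix(0, m, ns))
  si <- 0L
  slack_lb <- numeric(0); slack_ub <- numeric(0)
  for (i in seq_len(m)) {
    if (dir[i] == "=") next
    si <- si + 1L
    Afull[i, n + si] <- if (dir[i] == "<=") 1 else -1
    slack_lb <- c(slack_lb, 0); slack_ub <- c(slack_ub, Inf)
  }
  cfull <- c(if (sense == "max") -obj else obj, rep(0, ns))  # internal: minimize
  lbf <- c(lb, slack_lb); ubf <- c(ub, slack_ub)
  lbf[lbf < -cap] <- -cap; ubf[ubf > cap] <- cap
  nf <- n + ns

  # shift x = lbf + y, 0 <= y <= r; bound rows y_j + t_j = r_j
  r <- ubf - lbf
  b2 <- rhs - as.numeric(Afull %*% lbf)
  nb <- nf                       # one bound row per variable (all r finite now)
  # tableau columns: y (nf) | t (nb) | artificials (m) | RHS
  M <- m + nb
  Tb <- matrix(0, M, nf + nb + m + 1)
  Tb[seq_len(m), seq_len(nf)] <- Afull
  Tb[seq_len(m), nf + nb + seq_len(m)] <- diag(m)
  Tb[seq_len(m), ncol(Tb)] <- b2
  # flip eq rows so RHS >= 0 (artificial keeps +1 after flip)
  for (i in seq_len(m)) {
    if (Tb[i, ncol(Tb)] < 0) {
      Tb[i, ] <- -Tb[i, ]
      Tb[i, nf + nb + i] <- 1
    }
  }
  for (j in seq_len(nb)) {
    Tb[m + j, j] <- 1
    Tb[m + j, nf + j] <- 1
    Tb[m + j, ncol(Tb)] <- r[j]
  }
  basis <- c(nf + nb + seq_len(m), nf + seq_len(nb))

  ncols <- nf + nb + m
  res1 <- .simplex_iterate(Tb, basis,
                           cost = c(rep(0, nf + nb), rep(1, m)),
                           allowed = rep(TRUE, ncols), tol = tol)
  Tb <- res1$T; basis <- res1$basis
  if (res1$objective > 1e-7) {
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "infeasible"))
  }
  # ban artificials from re-entering; pivot out any still basic
  allowed <- c(rep(TRUE, nf + nb), rep(FALSE, m))
  for (i in seq_len(M)) {
    if (basis[i] > nf + nb) {
      piv <- which(abs(Tb[i, seq_len(nf + nb)]) > tol)
      if (length(piv) > 0) {
        Tb <- .pivot(Tb, i, piv[1]); basis[i] <- piv[1]
      }
      # else: redundant row; harmless to leave (RHS ~ 0)
    }
  }
  res2 <- .simplex_iterate(Tb, basis,
                           cost = c(cfull, rep(0, nb), rep(0, m)),
                           allowed = allowed, tol = tol)
  if (res2$status == "unbounded") {
    return(list(x = rep(NA_real_, n), objective = NA_real_, status = "unbounded"))
  }
  y <- numeric(nf)
  for (i in seq_len(M)) if (res2$basis[i] <= nf) y[res2$basis[i]] <- res2$T[i, ncol(Tb)]
  x <- (lbf + y)[seq_len(n)]
  zval <- sum(obj * x)
  # report "unbounded" when the optimum is pinned to an artificial cap
  orig_inf <- c(ub > cap - 1, -lb > cap - 1)
  hit <- c(x > cap * 0.999, -x > cap * 0.999)
  status <- if (any(orig_inf & hit)) "unbounded" else "optimal"
  list(x = x, objective = zval, status = status)
}

.pivot <- function(Tb, prow, pcol) {
  Tb[prow, ] <- Tb[prow, ] / Tb[prow, pcol]
  colv <- Tb[, pcol]
  colv[prow] <- 0
  Tb <- Tb - outer(colv, Tb[prow, ])
  Tb[, pcol] <- 0
  Tb[prow, pcol] <- 1
  Tb
}

# Bland's-rule simplex on a tableau already feasible for `basis`,
# minimizing `cost` over columns where `allowed` is TRUE.
.simplex_iterate <- function(Tb, basis, cost, allowed, tol = 1e-9,
                             max_iter = 50000L) {
  M <- nrow(Tb); ncols <- ncol(Tb) - 1L
  # reduced-cost row: c - c_B' T
  cb <- cost[basis]
  red <- cost - as.numeric(crossprod(Tb[, seq_len(ncols), drop = FALSE], cb))
  zobj <- sum(cb * Tb[, ncols + 1L])
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_iter) stop("simplex iteration limit reached")
    cand <- which(allowed & red < -tol)
    if (length(cand) == 0) {
      return(list(T = Tb, basis = basis, objective = zobj, status = "optimal"))
    }
    j <- cand[1]                               # Bland: lowest index
    colj <- Tb[, j]
    pos <- which(colj > tol)
    if (length(pos) == 0) {
      return(list(T = Tb, basis = basis, objective = zobj, status = "unbounded"))
    }
    ratio <- Tb[pos, ncols + 1L] / colj[pos]
    best <- min(ratio)
    ties <- pos[ratio <= best + tol]
    i <- ties[which.min(basis[ties])]          # Bland tie-break
    Tb <- .pivot(Tb, i, j)
    basis[i] <- j
    cb <- cost[basis]
    red <- cost - as.numeric(crossprod(Tb[, seq_len(ncols), drop = FALSE], cb))
    zobj <- sum(cb * Tb[, ncols + 1L])
  }
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Wraps [solve_lp()] in a depth-first branch-and-bound over the variables in
#' `int_idx` (assumed integer, typically binary). Intended for the small
#' expression-integration MILPs arising from iMAT on toy-scale models.
#'
#' @inheritParams solve_lp
#' @param int_idx indices of integer-constrained variables.
#' @param int_tol integrality tolerance.
#' @return list with `x`, `objective`, `status`.
#' @export
solve_milp <- function(obj, A, dir, rhs, lb, ub, int_idx,
                       sense = c("max", "min"), int_tol = 1e-6, tol = 1e-9) {
  sense <- match.arg(sense)
  sgn <- if (sense == "max") 1 else -1
  best <- list(x = NULL, objective = -Inf)
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    rel <- solve_lp(obj, A, dir, rhs, node$lb, node$ub, sense = sense, tol = tol)
    if (rel$status != "optimal") next
    zrel <- sgn * rel$objective
    if (!is.null(best$x) && zrel <= sgn * best$objective + 1e-9) next
    frac <- abs(rel$x[int_idx] - round(rel$x[int_idx]))
    if (all(frac <= int_tol)) {
      if (is.null(best$x) || zrel > sgn * best$objective) {
        best <- list(x = rel$x, objective = rel$objective)
      }
      next
    }
    k <- int_idx[which.max(frac)]
    xv <- rel$x[k]
    lo <- node; lo$ub[k] <- floor(xv)
    hi <- node; hi$lb[k] <- ceiling(xv)
    stack <- c(stack, list(lo, hi))
  }
  if (is.null(best$x)) {
    return(list(x = NULL, objective = NA_real_, status = "infeasible"))
  }
  best$x[int_idx] <- round(best$x[int_idx])
  list(x = best$x, objective = best$objective, status = "optimal")
}
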