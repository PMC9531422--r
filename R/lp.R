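#' Solve a linear program with equality constraints and box bounds
#'
#' Minimises (or maximises) `obj %*% x` subject to `A %*% x = b` and
#' `lb <= x <= ub`.  This is the workhorse behind flux balance, flux
#' variability and thermodynamics-based flux analysis on the reduced
#' network; problems have at most a few hundred variables, for which the
#' package's dense bounded-variable simplex is adequate.  Infinite bounds
#' are clipped to `+/-1e6`.
#'
#' @param obj numeric objective vector.
#' @param A equality-constraint matrix (may have zero rows).
#' @param b right-hand side.
#' @param lb,ub variable bounds (recycled if scalar).
#' @param maximize maximise instead of minimise?
#' @return list with `status` ("optimal", "infeasible" or "iteration_limit"),
#'   `x` (solution or NULL) and `objval`.
#' @keywords internal
solve_lp <- function(obj, A, b, lb, ub, maximize = FALSE) {
  n <- length(obj)
  A <- matrix(as.numeric(A), ncol = n)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  stopifnot(length(b) == nrow(A), all(lb <= ub + 1e-12))
  lb <- pmax(lb, -1e6)
  ub <- pmin(ub, 1e6)
  res <- simplex_lp_cpp(obj, A, as.numeric(b), lb, ub, maximize)
  status <- c("optimal", "infeasible", "unbounded", "iteration_limit")[res$status + 1L]
  list(status = status, x = if (status == "optimal") as.numeric(res$x) else NULL,
       objval = if (status == "optimal") res$objval else NA_real_)
}

#' Solve a mixed-binary linear program by branch and bound
#'
#' Same problem form as [solve_lp()] plus integrality on the variables in
#' `bin_idx`, which must have bounds within \[0, 1\].  Used for the
#' direction binaries that couple flux signs to Gibbs-energy signs and for
#' the loop-law binaries of loopless flux variability analysis.  Depth-first
#' branch and bound on the most fractional binary.
#'
#' @inheritParams solve_lp
#' @param bin_idx integer indices of binary variables.
#' @param int_tol integrality tolerance.
#' @return as [solve_lp()]; `x` has integral binaries when optimal.
#' @keywords internal
solve_milp <- function(obj, A, b, lb, ub, bin_idx = integer(), maximize = FALSE,
                       int_tol = 1e-6, max_nodes = 20000L, warm = NULL) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  if (length(bin_idx) == 0L) return(solve_lp(obj, A, b, lb, ub, maximize))

  best <- list(status = "infeasible", x = NULL, objval = NA_real_)
  # warm start: fix the binaries at the suggested 0/1 pattern and solve the
  # resulting LP; a feasible result seeds the incumbent and prunes early
  if (!is.null(warm)) {
    wl <- lb; wu <- ub
    wl[bin_idx] <- wu[bin_idx] <- round(pmin(pmax(warm, 0), 1))
    wr <- solve_lp(obj, A, b, wl, wu, maximize)
    if (wr$status == "optimal")
      best <- list(status = "optimal", x = wr$x, objval = wr$objval)
  }
  # each node: bounds for the binaries (the rest are shared)
  stack <- list(list(lb = lb, ub = ub))
  nodes <- 0L
  sense <- if (maximize) 1 else -1  # larger sense*objval is better

  while (length(stack) > 0L && nodes < max_nodes) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    rel <- solve_lp(obj, A, b, node$lb, node$ub, maximize)
    if (rel$status != "optimal") next
    if (!is.na(best$objval) &&
        sense * rel$objval <= sense * best$objval + 1e-9) next  # bound prune
    frac <- abs(rel$x[bin_idx] - round(rel$x[bin_idx]))
    if (all(frac <= int_tol)) {
      if (is.na(best$objval) || sense * rel$objval > sense * best$objval) {
        xx <- rel$x
        xx[bin_idx] <- round(xx[bin_idx])
        best <- list(status = "optimal", x = xx, objval = rel$objval)
      }
      next
    }
    j <- bin_idx[which.max(frac)]
    up <- node; up$lb[j] <- 1
    dn <- node; dn$ub[j] <- 0
    # explore the branch closer to the relaxation value first
    if (rel$x[j] >= 0.5) stack <- c(stack, list(dn), list(up))
    else stack <- c(stack, list(up), list(dn))
  }
  if (nodes >= max_nodes && best$status != "optimal")
    return(list(status = "iteration_limit", x = NULL, objval = NA_real_))
  best
}
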