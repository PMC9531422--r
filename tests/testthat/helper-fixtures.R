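# Shared fixtures: small networks built in code, plus brute-force oracles.

# linear chain: uptake -> A -> B -> sink, all irreversible
chain_model <- function(dg0 = c(NA, -10, NA)) {
  mets <- tibble::tibble(
    id = c("A", "B", "X_e", "Y_e"), name = id,
    compartment = c("cytosol", "cytosol", "extracellular", "extracellular"),
    conc_lb = 1e-6, conc_ub = 1e-2,
    is_balanced = c(TRUE, TRUE, FALSE, FALSE),
    measured = c(TRUE, TRUE, FALSE, FALSE))
  eqs <- c(up = "X_e -> A", r1 = "A -> B", sink = "B -> Y_e")
  parsed <- lapply(eqs, parse_equation)
  rxns <- tibble::tibble(
    id = names(eqs), enzyme_label = names(eqs),
    stoich = lapply(parsed, `[[`, "stoich"),
    reversible = FALSE, lb = 0, ub = 10, dg0_prime = dg0,
    is_exchange = c(TRUE, FALSE, TRUE))
  network_model(mets, rxns, objective_id = "sink")
}

# two reactions forming an internal 2-cycle A <-> B
two_cycle_model <- function() {
  mets <- tibble::tibble(
    id = c("A", "B"), name = id, compartment = "cytosol",
    conc_lb = 1e-6, conc_ub = 1e-2, is_balanced = TRUE, measured = TRUE)
  rxns <- tibble::tibble(
    id = c("f", "g"), enzyme_label = c("f", "g"),
    stoich = list(c(A = -1, B = 1), c(B = -1, A = 1)),
    reversible = TRUE, lb = -10, ub = 10, dg0_prime = NA_real_,
    is_exchange = FALSE)
  network_model(mets, rxns, objective_id = "f")
}

# random small network with guaranteed-feasible mass balance
random_small_model <- function(n_met = 4, n_rxn = 6, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      S <- matrix(sample(c(-1, 0, 0, 1), n_met * n_rxn, replace = TRUE),
                  n_met, n_rxn)
      if (all(colSums(abs(S)) > 0) && all(rowSums(abs(S)) > 0)) break
    }
    S
  })
}

# rank by brute-force minor expansion (for small matrices only)
rank_by_minors <- function(S, tol = 1e-9) {
  for (k in rev(seq_len(min(dim(S))))) {
    ri <- utils::combn(nrow(S), k, simplify = FALSE)
    ci <- utils::combn(ncol(S), k, simplify = FALSE)
    for (r in ri) for (cc in ci)
      if (abs(det(S[r, cc, drop = FALSE])) > tol) return(k)
  }
  0L
}

# brute-force MILP by enumerating all binary patterns (oracle for solve_milp)
milp_by_enumeration <- function(obj, A, b, lb, ub, bin_idx, maximize) {
  best <- NULL
  patterns <- expand.grid(rep(list(0:1), length(bin_idx)))
  for (i in seq_len(nrow(patterns))) {
    l2 <- lb; u2 <- ub
    l2[bin_idx] <- u2[bin_idx] <- as.numeric(patterns[i, ])
    r <- fluxcontrol:::solve_lp(obj, A, b, l2, u2, maximize)
    if (r$status != "optimal") next
    if (is.null(best) ||
        (maximize && r$objval > best$objval) ||
        (!maximize && r$objval < best$objval)) best <- r
  }
  best
}

# steady state of a lin-log ground truth by brute-force ODE integration
ode_steady_state <- function(gt, enzyme_levels = NULL, t_end = 2000) {
  e <- gt$enzyme_levels
  if (!is.null(enzyme_levels)) e[names(enzyme_levels)] <- enzyme_levels
  ind <- gt$independent_ids
  S_R <- gt$reduced$S_R[ind, , drop = FALSE]
  rhs <- function(t, u, parms) {
    v <- e * gt$v_ref * (1 + as.numeric(gt$eps_true %*% u))
    list(as.numeric(S_R %*% v) / gt$c_ref)
  }
  out <- deSolve::ode(y = stats::setNames(rep(0, length(ind)), ind),
                      times = c(0, t_end), func = rhs, parms = NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12,
                      maxsteps = 1e6)
  u <- out[nrow(out), -1]
  list(u = u,
       fluxes = e * gt$v_ref * (1 + as.numeric(gt$eps_true %*% u)))
}
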