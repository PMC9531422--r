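# Loopless FVA, TFA optimisation, variability at the optimum, sampling.

test_that("a fully constrained chain pins every flux to the uptake", {
  m <- chain_model()
  fva <- loopless_fva(m, rate_constraints("up", 1, 0))
  expect_equal(fva$flux$min, rep(1, 3), tolerance = 1e-9)
  expect_equal(fva$flux$max, rep(1, 3), tolerance = 1e-9)
})

test_that("an internal two-cycle is forced to zero by the loop law", {
  m <- two_cycle_model()
  fva <- loopless_fva(m)
  expect_true(all(fva$flux$null))
})

test_that("bound-fixed reactions are flagged null", {
  m <- chain_model()
  m$reactions$ub[m$reactions$id == "r1"] <- 0
  fva <- loopless_fva(m)
  expect_true(fva$flux$null[fva$flux$reaction_id == "r1"])
})

test_that("solve_tfa reproduces the hand-balanced chain optimum", {
  m <- chain_model()
  prob <- tfa_problem(m, rate_constraints("up", 1, 0))
  sol <- solve_tfa(prob)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 1, tolerance = 1e-9)
  expect_lt(max(abs(m$S %*% sol$v)), 1e-6)
})

test_that("a thermodynamically uphill required reaction is infeasible", {
  # dG0 so large that no concentration in the box can make r1 run forward
  m <- chain_model(dg0 = c(NA, 80, NA))
  prob <- tfa_problem(m, rate_constraints("up", 1, 0))
  sol <- solve_tfa(prob)
  expect_equal(sol$status, "infeasible")
  expect_match(sol$hint, "rate|relax|conflict")
})

test_that("zero-width rate boxes at zero give the all-zero solution", {
  m <- chain_model()
  prob <- tfa_problem(m, rate_constraints(c("up", "sink"), c(0, 0), 0))
  sol <- solve_tfa(prob)
  expect_equal(sol$status, "optimal")
  expect_equal(max(abs(sol$v)), 0, tolerance = 1e-9)
})

test_that("variability collapses to point ranges at fraction 1 on a chain", {
  m <- chain_model()
  prob <- tfa_problem(m, rate_constraints("up", 1, 0))
  va <- variability_at_optimum(prob, fraction = 1, what = "flux")
  expect_equal(va$flux$min, va$flux$max, tolerance = 1e-6)
})

test_that("objective slack frees a side branch", {
  # branched: up -> A, A -> B (obj), A -> C (waste)
  mets <- tibble::tibble(
    id = c("A", "X_e", "B_e", "C_e"), name = id,
    compartment = c("cytosol", rep("extracellular", 3)),
    conc_lb = 1e-6, conc_ub = 1e-2,
    is_balanced = c(TRUE, FALSE, FALSE, FALSE), measured = TRUE)
  eqs <- c(up = "X_e -> A", obj = "A -> B_e", waste = "A -> C_e")
  parsed <- lapply(eqs, parse_equation)
  rxns <- tibble::tibble(id = names(eqs), enzyme_label = names(eqs),
                         stoich = lapply(parsed, `[[`, "stoich"),
                         reversible = FALSE, lb = 0, ub = 10,
                         dg0_prime = NA_real_,
                         is_exchange = c(TRUE, TRUE, TRUE))
  m <- network_model(mets, rxns, objective_id = "obj")
  prob <- tfa_problem(m, rate_constraints("up", 1, 0))
  va <- variability_at_optimum(prob, fraction = 0.9, what = "flux")
  waste <- va$flux[va$flux$reaction_id == "waste", ]
  # oracle: with objective >= 0.9, waste can take up to 0.1 of the uptake
  expect_equal(waste$min, 0, tolerance = 1e-9)
  expect_equal(waste$max, 0.1, tolerance = 1e-6)
})

test_that("fraction 0 reproduces the unconstrained variability", {
  m <- chain_model()
  rts <- rate_constraints("up", 1, 0.2)
  fva <- loopless_fva(m, rts)
  prob <- tfa_problem(m, rts)
  va0 <- variability_at_optimum(prob, fraction = 0, what = "flux")
  expect_equal(va0$flux$min, fva$flux$min, tolerance = 1e-6)
  expect_equal(va0$flux$max, fva$flux$max, tolerance = 1e-6)
})

test_that("variability ranges are nested in the optimality fraction", {
  m <- packaged_model()
  rts <- reference_rates()
  fva <- packaged_fva()
  nulls <- fva$flux$reaction_id[fva$flux$null]
  met_ref <- packaged_dataset()$metabolome
  met_ref <- met_ref[met_ref$state_id == "ref", ]
  prob <- tfa_problem(m, rts, metabolome = met_ref, null_ids = nulls)
  va999 <- variability_at_optimum(prob, 0.999, what = "flux")
  va99 <- variability_at_optimum(prob, 0.99, what = "flux")
  expect_true(all(va999$flux$min >= va99$flux$min - 1e-6))
  expect_true(all(va999$flux$max <= va99$flux$max + 1e-6))
})

test_that("sampling is deterministic and honours the polytope", {
  m <- chain_model()
  rts <- rate_constraints("up", 1, 0.1)
  prob <- tfa_problem(m, rts)
  sol <- solve_tfa(prob)
  s1 <- sample_flux_space(prob, 50, seed = 4, solution = sol)
  s2 <- sample_flux_space(prob, 50, seed = 4, solution = sol)
  expect_identical(s1, s2)
  expect_lt(max(abs(m$S %*% t(s1))), 1e-6)
})

test_that("a single free dimension is sampled uniformly", {
  # up -> A with two parallel drains; total fixed, split free in [0, 1]
  mets <- tibble::tibble(
    id = c("A", "X_e", "B_e"), name = id,
    compartment = c("cytosol", "extracellular", "extracellular"),
    conc_lb = 1e-6, conc_ub = 1e-2,
    is_balanced = c(TRUE, FALSE, FALSE), measured = TRUE)
  eqs <- c(up = "X_e -> A", d1 = "A -> B_e", d2 = "A -> B_e")
  parsed <- lapply(eqs, parse_equation)
  rxns <- tibble::tibble(id = names(eqs), enzyme_label = names(eqs),
                         stoich = lapply(parsed, `[[`, "stoich"),
                         reversible = FALSE, lb = 0,
                         ub = c(1, 1, 1), dg0_prime = NA_real_,
                         is_exchange = TRUE)
  m <- network_model(mets, rxns, objective_id = "d1")
  prob <- tfa_problem(m, rate_constraints("up", 1, 0))
  sm <- sample_flux_space(prob, 2000, seed = 12)
  # d1 is uniform on [0, 1]: mean 0.5 within 3 standard errors
  se <- sqrt(1 / 12 / 2000)
  expect_lt(abs(mean(sm[, "d1"]) - 0.5), 3 * se)
})

test_that("a fully determined polytope returns the unique point", {
  m <- chain_model()
  prob <- tfa_problem(m, rate_constraints("up", 1, 0))
  expect_warning(sm <- sample_flux_space(prob, 10, seed = 2),
                 "fully determined")
  expect_equal(nrow(unique(sm)), 1L)
})
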