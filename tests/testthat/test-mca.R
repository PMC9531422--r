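# Elasticity regression, control coefficients, theorems, Monte Carlo.

# two-enzyme linear pathway in the lin-log formalism: boundary in/out with
# one internal metabolite; classical closed form C1 = e2 / (e2 - e1)
two_step_cc <- function(eps1, eps2) {
  S_R <- matrix(c(1, -1), 1, 2, dimnames = list("M", c("r1", "r2")))
  red <- structure(list(S_R = S_R,
                        L = matrix(1, 1, 1, dimnames = list("M", "M")),
                        independent_ids = "M", dependent_ids = character()),
                   class = "reduced_stoichiometry")
  eps <- matrix(c(eps1, eps2), 2, 1, dimnames = list(c("r1", "r2"), "M"))
  control_coefficients(eps, red, c(r1 = 1, r2 = 1))
}

test_that("two-step pathway control matches the classical closed form", {
  cc <- two_step_cc(-1, 1)
  expect_equal(unname(cc$C_J), matrix(0.5, 2, 2), tolerance = 1e-12)
  expect_equal(unname(cc$C_S), matrix(c(0.5, -0.5), 1), tolerance = 1e-12)
  cc2 <- two_step_cc(-2, 1)
  # C1 = eps2 / (eps2 - eps1) = 1/3
  expect_equal(unname(cc2$C_J[1, ]), c(1 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("summation theorems hold on random valid systems", {
  withr::with_seed(23, {
    for (i in 1:100) {
      n_met <- sample(2:5, 1); n_rxn <- n_met + sample(2:4, 1)
      S <- random_small_model(n_met, n_rxn, seed = 5000 + i)
      rownames(S) <- paste0("m", seq_len(n_met))
      colnames(S) <- paste0("r", seq_len(n_rxn))
      red <- reduce_stoichiometry(S)
      # reference flux in the null space of S (a true steady state)
      N <- svd(S, nv = n_rxn)$v[, (qr(S)$rank + 1):n_rxn, drop = FALSE]
      v <- as.numeric(N %*% rnorm(ncol(N)))
      if (max(abs(v)) < 1e-3) next
      eps <- matrix(rnorm(n_rxn * length(red$independent_ids)),
                    n_rxn, length(red$independent_ids),
                    dimnames = list(colnames(S), red$independent_ids))
      cc <- tryCatch(
        control_coefficients(eps, red, stats::setNames(v, colnames(S))),
        error = function(e) NULL)   # singular draws are skipped
      if (is.null(cc)) next
      expect_lt(max(abs(rowSums(cc$C_J) - 1)), 1e-8)
      expect_lt(max(abs(rowSums(cc$C_S))), 1e-8)
      # connectivity: C_J %*% eps_independent = 0
      expect_lt(max(abs(cc$C_J %*% eps[, colnames(cc$eps), drop = FALSE])),
                1e-7)
    }
  })
})

test_that("singular linearizations raise an informative error", {
  S_R <- matrix(c(1, -1), 1, 2, dimnames = list("M", c("r1", "r2")))
  red <- structure(list(S_R = S_R, independent_ids = "M",
                        dependent_ids = character()),
                   class = "reduced_stoichiometry")
  eps <- matrix(0, 2, 1, dimnames = list(c("r1", "r2"), "M"))
  expect_error(control_coefficients(eps, red, c(r1 = 1, r2 = 1)),
               "singular")
})

test_that("noise-free regression recovers the exact elasticities", {
  tm <- toy_branched_model()
  gt <- toy_gt()
  ds <- generate_perturbation_dataset(gt, noise_cv = c(rates = 0,
                                                       metabolome = 0),
                                      seed = 1)
  eps_hat <- estimate_elasticities(ds, tm)
  expect_lt(max(abs(eps_hat$eps - gt$eps_true)), 1e-8)
  expect_length(eps_hat$underdetermined, 0L)
})

test_that("a single perturbed state yields a flagged minimum-norm row", {
  tm <- toy_branched_model()
  gt <- toy_gt()
  ds <- generate_perturbation_dataset(gt, noise_cv = c(rates = 0,
                                                       metabolome = 0),
                                      seed = 1)
  keep <- c("glyc_1", "ref")
  ds1 <- perturbation_dataset(
    ds$states[ds$states$state_id %in% keep, ],
    ds$rates[ds$rates$state_id %in% keep, ],
    ds$metabolome[ds$metabolome$state_id %in% keep, ], "ref")
  eps1 <- estimate_elasticities(ds1, tm)
  expect_true(length(eps1$underdetermined) > 0L)
  expect_true(all(is.finite(eps1$eps)))
})

test_that("zero reference flux excludes a reaction with a warning", {
  tm <- toy_branched_model()
  gt <- toy_gt()
  ds <- generate_perturbation_dataset(gt, noise_cv = c(rates = 0,
                                                       metabolome = 0),
                                      seed = 1)
  ds$rates$mean[ds$rates$reaction_id == "r4" &
                  ds$rates$state_id == "ref"] <- 0
  expect_warning(eps_hat <- estimate_elasticities(ds, tm), "r4")
  expect_true("r4" %in% eps_hat$excluded)
})

test_that("Monte Carlo with zero uncertainty collapses to the point", {
  tm <- toy_branched_model()
  gt <- toy_gt()
  ds <- generate_perturbation_dataset(gt, noise_cv = c(rates = 0,
                                                       metabolome = 0),
                                      seed = 1)
  mc <- monte_carlo_mca(ds, tm, gt$reduced, n_cycles = 20, seed = 3)
  expect_equal(mc$mc_lo, mc$mc_hi, tolerance = 1e-12)
  expect_equal(mc$mc_mean, mc$C_J[rownames(mc$mc_mean), ], tolerance = 1e-9)
})

test_that("Monte Carlo summaries are deterministic in the seed", {
  tm <- toy_branched_model()
  gt <- toy_gt()
  ds <- generate_perturbation_dataset(gt, seed = 5)
  mc1 <- monte_carlo_mca(ds, tm, gt$reduced, n_cycles = 50, seed = 9)
  mc2 <- monte_carlo_mca(ds, tm, gt$reduced, n_cycles = 50, seed = 9)
  expect_identical(mc1$mc_mean, mc2$mc_mean)
  expect_identical(mc1$mc_lo, mc2$mc_lo)
  # every cycle satisfies the summation theorem, hence so does the mean
  expect_lt(max(abs(rowSums(mc1$mc_mean) - 1)), 1e-8)
})

test_that("tidy/glance/export round trip the coefficient tables", {
  tm <- toy_branched_model()
  gt <- toy_gt()
  cc <- ground_truth_fcc(gt)
  td <- tidy(cc)
  expect_true(all(c("flux_id", "enzyme", "fcc") %in% names(td)))
  gl <- glance(cc)
  expect_lt(gl$max_cj_row_dev, 1e-8)
  f <- withr::local_tempfile(fileext = ".csv")
  export_fcc_table(cc, f)
  back <- readr::read_csv(f, show_col_types = FALSE)
  m <- as.matrix(back[-1]); rownames(m) <- back$flux_id
  expect_equal(m, cc$C_J[rownames(m), colnames(m)])
  p <- ggplot2::autoplot(cc)
  expect_s3_class(p, "ggplot")
})
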