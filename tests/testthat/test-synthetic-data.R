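# Ground truths, lin-log steady states, the 12+1 dataset, fed-batch runs.

test_that("ground truths are deterministic and balanced", {
  tm <- toy_branched_model()
  g1 <- make_ground_truth(tm, seed = 3)
  g2 <- make_ground_truth(tm, seed = 3)
  expect_identical(g1$eps_true, g2$eps_true)
  expect_identical(g1$v_ref, g2$v_ref)
  expect_lt(max(abs(tm$S %*% g1$v_ref)), 1e-9)
  # elasticities respect the sparsity mask
  mask <- elasticity_mask(tm)
  expect_true(all(g1$eps_true[!mask[, colnames(g1$eps_true)]] == 0))
})

test_that("the reference state is an exact fixed point of the simulator", {
  tm <- toy_branched_model()
  gt <- make_ground_truth(tm, seed = 3)
  st <- simulate_steady_state(gt)
  expect_lt(max(abs(st$u)), 1e-12)
  expect_equal(st$fluxes, gt$v_ref, tolerance = 1e-12)
  expect_lt(max(abs(tm$S %*% st$fluxes)), 1e-9)
})

test_that("lin-log steady states agree with brute-force ODE integration", {
  tm <- toy_branched_model()
  gt <- make_ground_truth(tm, seed = 3)
  lv <- c(r1 = 2)   # double one internal enzyme
  st <- simulate_steady_state(gt, enzyme_levels = lv)
  ode <- ode_steady_state(gt, enzyme_levels = lv)
  expect_equal(st$u, ode$u[names(st$u)], tolerance = 1e-6)
  expect_equal(st$fluxes, ode$fluxes[names(st$fluxes)], tolerance = 1e-6)
})

test_that("zero boundary flux propagates to a zero chain", {
  tm <- toy_branched_model()
  gt <- make_ground_truth(tm, seed = 3)
  st <- simulate_steady_state(
    gt, boundary_fluxes = c(up1 = 0, up2 = 0, up3 = 0, up4 = 0))
  expect_lt(max(abs(st$fluxes[c("up1", "up2", "up3", "up4", "sink")])), 1e-9)
})

test_that("analytic and finite-difference control coefficients agree", {
  tm <- toy_branched_model()
  gt <- make_ground_truth(tm, seed = 3)
  cc <- ground_truth_fcc(gt)
  fd <- finite_difference_fcc(gt, delta = 1e-4)
  expect_lt(max(abs(fd - cc$C_J[rownames(fd), colnames(fd)])), 1e-3)
  expect_error(finite_difference_fcc(gt, delta = 0), "positive")
})

test_that("the packaged design yields 12 perturbed states and a 45-panel", {
  ds <- packaged_dataset()
  expect_equal(nrow(ds$states), 13L)
  expect_equal(sum(ds$states$substrate == "reference"), 1L)
  expect_equal(dplyr::n_distinct(ds$metabolome$metabolite_id), 45L)
  expect_setequal(unique(ds$states$substrate),
                  c("glucose", "glycerol", "pyruvate", "succinate",
                    "reference"))
})

test_that("noise-free observations equal the simulated states exactly", {
  tm <- toy_branched_model()
  gt <- make_ground_truth(tm, seed = 3)
  ds <- generate_perturbation_dataset(gt, noise_cv = c(rates = 0,
                                                       metabolome = 0),
                                      seed = 1)
  ref <- ds$rates[ds$rates$state_id == "ref", ]
  expect_equal(stats::setNames(ref$mean, ref$reaction_id)[names(gt$v_ref)],
               gt$v_ref)
  expect_true(all(ds$rates$sd == 0))
  # a perturbed state matches its exact lin-log solution
  des <- perturbation_design()
  q <- fluxcontrol:::stage_uptake(des, "glucose", 2)
  st <- simulate_steady_state(
    gt, boundary_fluxes = c(up2 = q, up1 = 0, up3 = 0, up4 = 0))
  obs <- ds$rates[ds$rates$state_id == "gluc_2", ]
  expect_equal(stats::setNames(obs$mean, obs$reaction_id)[names(st$fluxes)],
               st$fluxes, tolerance = 1e-9)
})

test_that("generated noise honours the requested coefficient of variation", {
  tm <- toy_branched_model()
  gt <- make_ground_truth(tm, seed = 3)
  clean <- generate_perturbation_dataset(gt, noise_cv = c(rates = 0,
                                                          metabolome = 0),
                                         seed = 1)
  # pool relative errors across many independent draws
  ratios <- unlist(lapply(1:20, function(s) {
    noisy <- generate_perturbation_dataset(
      gt, noise_cv = c(rates = 0.05, metabolome = 0.05), seed = 100 + s)
    noisy$metabolome$mean_mM / clean$metabolome$mean_mM
  }))
  cv <- stats::sd(ratios) / mean(ratios)
  expect_lt(abs(cv / 0.05 - 1), 0.1)
})

test_that("the perturbation design carries the published feed profiles", {
  des <- perturbation_design()
  f <- des$feeds
  expect_equal(nrow(f), 12L)
  expect_equal(f$rate_mL_h[f$substrate == "glucose"], c(31.7, 63.4, 95.1))
  expect_equal(unique(f$feed_conc_g_L[f$substrate == "glycerol"]), 87)
  expect_equal(f$rate_mL_h[f$substrate == "succinate"], c(32.2, 64.4, 69.6))
})

test_that("the fed-batch exponential phase realises the set growth rate", {
  fb <- simulate_fed_batch(t_end = 60)
  ph <- attr(fb, "phases")
  w <- fb$data[fb$data$time > ph$t_batch_end + 2 &
                 fb$data$time < ph$t_const_start - 2, ]
  mu_hat <- unname(coef(stats::lm(log(cdw * volume) ~ time, data = w))[2])
  expect_lt(abs(mu_hat / 0.07 - 1), 0.02)
})

test_that("the fed-batch mass ledger closes", {
  fb <- simulate_fed_batch(t_end = 60)
  lg <- attr(fb, "ledger")
  res <- lg$initial_g + lg$fed_g - lg$residual_g - lg$growth_g -
    lg$product_substrate_g - lg$acetate_substrate_g - lg$maintenance_g
  expect_lt(max(abs(res)) / max(lg$fed_g + lg$initial_g), 1e-6)
  # total_amount agrees with the simulator's internal product ledger
  t_probe <- 50
  ta <- total_amount(fb, "trp", t_probe)
  expect_equal(ta, lg$product_g[which.min(abs(lg$time - t_probe))],
               tolerance = 1e-6)
})

test_that("without feed the substrate is non-increasing and growth stops", {
  d <- fed_batch_design(feed_a_L = 0, feed_b_L = 0, feed_c_L = 0,
                        const_feed_g_per_gX_h = 0)
  fb <- simulate_fed_batch(d, t_end = 30)
  s <- fb$data$conc_glycerol * fb$data$volume
  expect_true(all(diff(s) <= 1e-6))
  late <- fb$data[fb$data$time > 20, ]
  expect_lt(max(late$cdw * late$volume) / min(late$cdw * late$volume), 1.001)
})

test_that("the MGO sub-model ends product formation after the threshold", {
  d <- fed_batch_design(mgo_on = TRUE, mgo_uptake_threshold = 1.0,
                        mgo_formation_rate = 0.2, mgo_shutoff_mg_L = 30)
  fb <- simulate_fed_batch(d, t_end = 75)
  dd <- fb$data
  expect_gt(max(dd$conc_mgo) * 1000, 30)   # threshold crossed
  cross <- min(dd$time[dd$conc_mgo * 1000 > 30])
  after <- dd[dd$time > cross + 1, ]
  # product amount (dilution-free) never increases after the shut-off
  amount <- after$conc_trp * after$volume
  expect_true(all(diff(amount) <= 1e-6))
})
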