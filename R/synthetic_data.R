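# Synthetic-data generation: lin-log kinetic ground truths with analytic
# control coefficients, the 4-substrate x 3-stage perturbation experiment,
# and a three-phase fed-batch process simulator.

#' Molar masses of the process species (g/mol)
#' @export
species_molar_mass <- c(glycerol = 92.09, glucose = 180.16, pyruvate = 88.06,
                        succinate = 118.09, trp = 204.23, acetate = 60.05,
                        mgo = 72.06, o2 = 32.00, co2 = 44.01)

#' The 4-substrate, 3-stage perturbation design
#'
#' Feed concentrations and staged supply rates of the parallel analysis
#' reactors, together with the analysis-reactor operating point.  The
#' stage rates step up 9 and 15 minutes after inoculation; the analysis
#' lasts 21 minutes, short enough that the proteome is taken as constant.
#'
#' @param volume_L analysis-reactor working volume.
#' @param cdw_g_L biomass concentration in the analysis reactors.
#' @return list of class `perturbation_design` with a `feeds` tibble
#'   (`substrate`, `feed_conc_g_L`, `stage`, `rate_mL_h`), the reactor
#'   operating point, and the sampling schedule (min).
#' @export
perturbation_design <- function(volume_L = 0.5, cdw_g_L = 25) {
  feeds <- tibble::tibble(
    substrate = rep(c("glucose", "glycerol", "pyruvate", "succinate"), each = 3),
    feed_conc_g_L = rep(c(62, 87, 87, 78), each = 3),
    stage = rep(1:3, times = 4),
    rate_mL_h = c(31.7, 63.4, 95.1,
                  29.2, 58.4, 87.6,
                  29.7, 59.3, 89.0,
                  32.2, 64.4, 69.6))
  structure(list(feeds = feeds, volume_L = volume_L, cdw_g_L = cdw_g_L,
                 duration_min = 21,
                 sampling_intracellular_min = c(8, 14, 20),
                 sampling_extracellular_min = c(1, 9, 15, 21)),
            class = "perturbation_design")
}

# biomass-specific uptake rate (mmol/gCDW/h) implied by a feed stage
stage_uptake <- function(design, substrate, stage) {
  f <- design$feeds
  row <- f[f$substrate == substrate & f$stage == stage, ]
  mm <- species_molar_mass[[substrate]]
  g_per_h <- row$rate_mL_h / 1000 * row$feed_conc_g_L
  g_per_h / mm * 1000 / (design$volume_L * design$cdw_g_L)
}

# map design substrate names onto the packaged model's uptake exchanges
substrate_uptake_reaction <- c(glycerol = "glyc_upt", glucose = "glc_pts",
                               pyruvate = "pyr_upt", succinate = "succ_upt")

#' A small branched test network with four substrate uptakes
#'
#' Four boundary uptakes feed a branched internal chain
#' (`A -> B -> C -> D` with a cross edge `A -> C`) drained by a product
#' sink.  With one uptake per internal metabolite the 12-state
#' perturbation design spans the full concentration-response space, so
#' every elasticity row is exactly identifiable -- the configuration used
#' to validate the estimation pipeline end to end.
#'
#' @param uptake_ub upper bound (and reference scale) of the uptakes.
#' @return a [network_model()].
#' @export
toy_branched_model <- function(uptake_ub = 1) {
  mets <- tibble::tibble(
    id = c("A", "B", "C", "D", "S1_e", "S2_e", "S3_e", "S4_e", "P_e"),
    name = id,
    compartment = c(rep("cytosol", 4), rep("extracellular", 5)),
    conc_lb = 1e-7, conc_ub = 1e-1,
    is_balanced = c(rep(TRUE, 4), rep(FALSE, 5)),
    measured = c(rep(TRUE, 4), rep(FALSE, 5)))
  eqs <- c(up1 = "S1_e -> A", up2 = "S2_e -> B", up3 = "S3_e -> C",
           up4 = "S4_e -> D", r1 = "A -> B", r2 = "B -> C", r3 = "C -> D",
           r4 = "A -> C", sink = "D -> P_e")
  parsed <- lapply(eqs, parse_equation)
  rxns <- tibble::tibble(
    id = names(eqs), enzyme_label = names(eqs),
    stoich = lapply(parsed, `[[`, "stoich"),
    reversible = FALSE,
    lb = c(rep(0, 7), 0.2, 0),
    ub = c(rep(uptake_ub, 4), rep(10, 5)),
    dg0_prime = NA_real_,
    is_exchange = c(rep(TRUE, 4), rep(FALSE, 4), TRUE))
  network_model(mets, rxns, objective_id = "sink")
}

# uptake map for a toy model built by toy_branched_model()
toy_uptake_map <- c(glycerol = "up1", glucose = "up2",
                    pyruvate = "up3", succinate = "up4")

#' Reference-process rate constraints for the packaged model
#'
#' The operating point of the production process at the time of the
#' metabolic analysis: constant glycerol feeding at 0.2 g/gCDW/h
#' (2.17 mmol/gCDW/h), slow residual growth, L-tryptophan and acetate
#' secretion, and respiration.  Small nonzero co-utilisation rates for the
#' three alternative substrates keep every perturbed uptake direction
#' represented in the lin-log reference state.
#'
#' @return a [rate_constraints()] tibble.
#' @export
reference_rates <- function() {
  rate_constraints(
    reaction_id = c("glyc_upt", "glc_pts", "pyr_upt", "succ_upt",
                    "trp_sec", "ac_sec", "o2_upt", "co2_sec", "growth"),
    mean = c(2.17, 0.04, 0.04, 0.04, 0.13, 0.04, 4.8, 5.0, 0.02),
    sd   = c(0.10, 0.01, 0.01, 0.01, 0.01, 0.01, 0.25, 0.25, 0.005),
    kind = c("uptake", "uptake", "uptake", "uptake", "secretion",
             "secretion", "respiration", "respiration", "growth"))
}

#' Reference cofactor levels reported with the metabolome panel (mM)
#' @keywords internal
cofactor_reference_mM <- c(atp_c = 3.0, nad_c = 1.5, nadh_c = 0.15,
                           nadph_c = 0.2, glu__L_c = 50, pi_c = 10)

#' Reference-state flux direction profile of the packaged model
#'
#' During glycerol-fed production every pathway of the reduced network
#' carries flux: glycolysis runs downward from DHAP with gluconeogenic
#' upper glycolysis (FBA and PGI in reverse, fructose bisphosphatase
#' forward), and the MGO route, TCA cycle, PPP, serine and aromatic
#' branches are all active.  The profile pins those directions with a
#' small flux floor so the linearization reference has no dead branches;
#' the gluconeogenic PEP routes (pps, pck) and PFK rest at zero.
#'
#' @param floor minimum absolute flux (mmol/gCDW/h) on active reactions.
#' @return tibble with `reaction_id`, `lb`, `ub` overrides.
#' @export
reference_direction_profile <- function(floor = 0.02) {
  forward <- c("glyk", "g3pd", "tpi", "gapd", "pgk", "pgm", "eno", "pyk",
               "pdh", "pck", "cs", "icd", "akgd", "sdh", "mdh", "ppc", "zwf",
               "gnd", "rpe", "rpi", "tkt1", "tal", "prpps", "sera", "psp_L",
               "dahpts", "dhqs", "shkdh", "pscvt", "chors", "anths", "anprt",
               "igps", "trps2", "ppndh", "mgsa", "glyox", "ldh", "fbp")
  backward <- c("fba", "pgi")
  zero <- c("pfk", "pps")
  tibble::tibble(
    reaction_id = c(forward, "glya", backward, zero),
    # glycine drains only into biomass, so its floor must stay below the
    # biomass glycine demand at the reference growth rate
    lb = c(rep(floor, length(forward)), min(floor, 5e-4),
           rep(NA_real_, length(backward)), rep(0, length(zero))),
    ub = c(rep(NA_real_, length(forward) + 1L), rep(-floor, length(backward)),
           rep(0, length(zero))))
}

# apply direction overrides to a model copy
apply_direction_profile <- function(model, profile) {
  for (i in seq_len(nrow(profile))) {
    j <- match(profile$reaction_id[i], model$reactions$id)
    if (is.na(j)) next
    if (!is.na(profile$lb[i])) model$reactions$lb[j] <- profile$lb[i]
    if (!is.na(profile$ub[i])) model$reactions$ub[j] <- profile$ub[i]
  }
  model
}

#' Build a lin-log kinetic ground truth
#'
#' Draws scaled elasticities with thermodynamically sensible signs
#' (substrates positive, products and declared inhibitors negative) on the
#' model's elasticity mask, anchors the reference fluxes and
#' concentrations to a thermodynamics-constrained flux solution (or plain
#' flux balance when the model carries no Gibbs energies), and redraws
#' until the lin-log steady state is locally stable and well conditioned.
#' The ground truth yields analytic control coefficients against which the
#' whole estimation pipeline can be validated.
#'
#' @param model a [network_model()].
#' @param seed integer seed (deterministic output).
#' @param rates optional [rate_constraints()] anchoring the reference
#'   state; defaults to [reference_rates()] for the packaged model layout.
#' @param max_tries redraw attempts before giving up.
#' @return object of class `kinetic_ground_truth` with `model`, `reduced`,
#'   `eps_true`, `v_ref`, `c_ref` (mM), `enzyme_levels`.
#' @export
make_ground_truth <- function(model, seed = 1L, rates = NULL, max_tries = 200L) {
  reduced <- reduce_stoichiometry(model)
  mask <- elasticity_mask(model)
  ind <- intersect(reduced$independent_ids, colnames(mask))

  # reference flux and concentration point
  covered <- any(!is.na(model$reactions$dg0_prime))
  packaged_layout <- all(substrate_uptake_reaction %in% model$reactions$id)
  if (is.null(rates) && packaged_layout) rates <- reference_rates()
  anchor_model <- if (packaged_layout)
    apply_direction_profile(model, reference_direction_profile()) else model
  if (covered && !is.null(rates)) {
    fva <- loopless_fva(anchor_model, rates)
    nulls <- fva$flux$reaction_id[fva$flux$null]
    sol <- solve_tfa(tfa_problem(anchor_model, rates, null_ids = nulls))
    if (sol$status != "optimal") stop("reference TFA infeasible: ", sol$hint)
    v_ref <- sol$v
    c_ref_full <- exp(sol$ln_conc) * 1000          # mM
  } else {
    bounds <- apply_rate_bounds(model, rates)
    obj <- as.numeric(model$reactions$id == model$objective_id)
    r <- solve_lp(obj, model$S, rep(0, nrow(model$S)), bounds$lb, bounds$ub,
                  maximize = TRUE)
    if (r$status != "optimal") stop("reference flux balance infeasible")
    v_ref <- stats::setNames(r$x, model$reactions$id)
    c_ref_full <- stats::setNames(rep(1, nrow(model$S)), rownames(model$S))
  }
  c_ref <- c_ref_full[ind]
  if (max(abs(model$S %*% v_ref)) > 1e-9) stop("reference state is not balanced")

  n <- nrow(model$reactions)
  ids <- model$reactions$id
  reg <- model$regulation

  withr::with_seed(seed, {
    eps <- NULL
    for (try in seq_len(max_tries)) {
      cand <- matrix(0, n, length(ind), dimnames = list(ids, ind))
      for (j in seq_len(n)) {
        cols <- ind[mask[j, ind]]
        if (length(cols) == 0L || v_ref[j] == 0) next
        s <- model$reactions$stoich[[j]]
        for (m_ in cols) {
          inhib <- any(reg$reaction_id == ids[j] & reg$metabolite_id == m_ &
                         reg$sign < 0)
          # substrate/product roles follow the direction the reference flux
          # actually runs, not the written direction of the equation
          sc <- (if (m_ %in% names(s)) s[[m_]] else 0) * sign(v_ref[j])
          cand[j, m_] <-
            if (inhib) -stats::runif(1, 0.2, 1.0)
            else if (sc < 0) stats::runif(1, 0.5, 1.5)    # consumed: positive
            else if (sc > 0) -stats::runif(1, 0.2, 0.8)   # produced: negative
            else stats::runif(1, 0.2, 1.0)                # activator
        }
      }
      S_R <- reduced$S_R[ind, , drop = FALSE]
      M <- S_R %*% (v_ref * cand)
      # a reasonably conditioned linearization keeps perturbed-state
      # excursions finite across the whole feeding design
      if (!is.finite(rcond(M)) || rcond(M) < 1e-6) next
      A <- diag(1 / c_ref) %*% M
      if (max(Re(eigen(A, only.values = TRUE)$values)) < -1e-10) {
        cand_gt <- structure(
          list(model = model, reduced = reduced, eps_true = cand,
               v_ref = v_ref, c_ref = c_ref, independent_ids = ind,
               enzyme_levels = stats::setNames(rep(1, n), ids)),
          class = "kinetic_ground_truth")
        up_rxn <- if (all(toy_uptake_map %in% ids)) toy_uptake_map
                  else if (packaged_layout) substrate_uptake_reaction
                  else NULL
        if (is.null(up_rxn) ||
            design_states_ok(cand_gt, up_rxn, perturbation_design())) {
          eps <- cand
          break
        }
      }
    }
    if (is.null(eps)) stop("no stable reference steady state found after ",
                           max_tries, " draws")
    structure(
      list(model = model, reduced = reduced, eps_true = eps, v_ref = v_ref,
           c_ref = c_ref, independent_ids = ind,
           enzyme_levels = stats::setNames(rep(1, n), ids)),
      class = "kinetic_ground_truth")
  })
}

# does a ground truth produce finite, bounded states across the staged
# feeding design?  (large uptake scalings can drive ill-conditioned draws
# into astronomic log-deviations)
design_states_ok <- function(gt, up_rxn, design, u_max = 200) {
  for (s in unique(design$feeds$substrate)) {
    for (g in 1:3) {
      bf <- stats::setNames(rep(0, length(up_rxn)), up_rxn)
      bf[up_rxn[[s]]] <- stage_uptake(design, s, g)
      st <- tryCatch(simulate_steady_state(gt, boundary_fluxes = bf),
                     error = function(e) NULL)
      if (is.null(st) || !all(is.finite(st$fluxes)) ||
          max(abs(st$u)) > u_max) return(FALSE)
    }
  }
  TRUE
}

#' @export
print.kinetic_ground_truth <- function(x, ...) {
  cat("<kinetic_ground_truth> ", length(x$v_ref), " reactions, ",
      length(x$c_ref), " independent metabolites\n", sep = "")
  invisible(x)
}

#' Analytic control coefficients of a ground truth
#'
#' @param gt a [make_ground_truth()] object.
#' @return a [control_coefficients()] object.
#' @export
ground_truth_fcc <- function(gt) {
  control_coefficients(gt$eps_true, gt$reduced, gt$v_ref)
}

#' Solve the lin-log steady state at given enzyme levels
#'
#' Under lin-log kinetics, `v = e * v_ref * (1 + eps %*% u)` with
#' `u = ln(c/c_ref)`; imposing the independent mass balances
#' `S_R v = 0` gives a linear system in `u`, solved exactly.  Boundary
#' (exchange) fluxes can be set directly; internally this scales the
#' corresponding enzyme level, since those reactions are feed-driven.
#'
#' @param gt a [make_ground_truth()] object.
#' @param enzyme_levels named vector of relative enzyme levels (default 1).
#' @param boundary_fluxes named vector of exchange fluxes to impose
#'   (mmol/gCDW/h); the named reactions must have nonzero reference flux.
#' @return list with `fluxes` (named), `conc` (mM, independent
#'   metabolites), `u` (log-deviations).
#' @export
simulate_steady_state <- function(gt, enzyme_levels = NULL,
                                  boundary_fluxes = NULL) {
  ids <- names(gt$v_ref)
  e <- gt$enzyme_levels
  if (!is.null(enzyme_levels)) e[names(enzyme_levels)] <- enzyme_levels
  if (!is.null(boundary_fluxes)) {
    for (id in names(boundary_fluxes)) {
      if (gt$v_ref[id] == 0)
        stop("cannot impose a flux on '", id, "': zero reference flux")
      e[id] <- boundary_fluxes[[id]] / gt$v_ref[id]
    }
  }
  ind <- gt$independent_ids
  S_R <- gt$reduced$S_R[ind, , drop = FALSE]
  ev <- e * gt$v_ref
  M_e <- S_R %*% (ev * gt$eps_true)
  rhs <- -as.numeric(S_R %*% ev)
  if (!is.finite(rcond(M_e)) || rcond(M_e) < 1e-12) {
    sv <- svd(M_e)
    free <- ind[order(-abs(sv$v[, ncol(sv$v)]))][1:min(3, length(ind))]
    stop("steady-state system singular; free directions near: ",
         paste(free, collapse = ", "))
  }
  u <- as.numeric(solve(M_e, rhs))
  names(u) <- ind
  v <- as.numeric(ev * (1 + gt$eps_true %*% u))
  names(v) <- ids
  list(fluxes = v, conc = gt$c_ref * exp(u), u = u)
}

#' Simulate the 12+1 state perturbation experiment
#'
#' Each perturbed state feeds one substrate at one of its three staged
#' supply rates; the implied biomass-specific uptake (feed rate x feed
#' concentration / biomass) is imposed on that substrate's uptake
#' reaction while the other three uptakes fall to zero (the analysis
#' medium carries no other carbon source).  The lin-log steady state is
#' solved exactly, multiplicative lognormal noise at the requested CVs is
#' applied to rates and metabolome, and truthful standard deviations are
#' recorded.  The 13th state is the unperturbed reference.
#'
#' @param gt a [make_ground_truth()] object.
#' @param design a [perturbation_design()].
#' @param noise_cv named numeric `c(rates = , metabolome = )` relative
#'   standard deviations (0 for noise-free data).
#' @param seed integer seed.
#' @param uptake_map named character mapping the four design substrates to
#'   uptake reaction ids; defaults to the packaged model's exchanges, or
#'   to the [toy_branched_model()] uptakes when those are present.
#' @return a [perturbation_dataset()].
#' @export
generate_perturbation_dataset <- function(gt, design = perturbation_design(),
                                          noise_cv = c(rates = 0.05,
                                                       metabolome = 0.05),
                                          seed = 1L, uptake_map = NULL) {
  model <- gt$model
  up_rxn <- uptake_map %||%
    (if (all(toy_uptake_map %in% model$reactions$id)) toy_uptake_map
     else substrate_uptake_reaction)
  if (!all(up_rxn %in% model$reactions$id))
    stop("model lacks the four substrate uptake reactions")
  subs <- unique(design$feeds$substrate)

  states <- list(); rates <- list(); metab <- list()
  add_obs <- function(sid, substrate, stage, fluxes, conc_mM) {
    states[[length(states) + 1L]] <<-
      tibble::tibble(state_id = sid, substrate = substrate, stage = stage)
    rates[[length(rates) + 1L]] <<-
      tibble::tibble(state_id = sid, reaction_id = names(fluxes),
                     true = as.numeric(fluxes))
    metab[[length(metab) + 1L]] <<-
      tibble::tibble(state_id = sid, metabolite_id = names(conc_mM),
                     true = as.numeric(conc_mM))
  }

  panel_cof <- cofactor_reference_mM[
    names(cofactor_reference_mM) %in% model$metabolites$id[model$metabolites$measured]]

  for (s in subs) {
    for (g in 1:3) {
      q <- stage_uptake(design, s, g)
      bf <- stats::setNames(rep(0, 4), up_rxn)
      bf[up_rxn[[s]]] <- q
      st <- tryCatch(simulate_steady_state(gt, boundary_fluxes = bf),
                     error = function(e)
                       stop("state (", s, ", stage ", g, ") failed: ",
                            conditionMessage(e)))
      if (!all(is.finite(st$fluxes)) || !all(is.finite(st$conc)))
        stop("state (", s, ", stage ", g, ") failed to converge")
      # quantification floor/ceiling: extreme lin-log excursions cannot
      # produce non-positive or unbounded measurements
      conc <- pmin(pmax(st$conc, 1e-9), 1e6)
      add_obs(paste0(substr(s, 1, 4), "_", g), s, as.character(g),
              st$fluxes, c(conc, panel_cof))
    }
  }
  add_obs("ref", "reference", "reference", gt$v_ref, c(gt$c_ref, panel_cof))

  states <- dplyr::bind_rows(states)
  rates <- dplyr::bind_rows(rates)
  metab <- dplyr::bind_rows(metab)

  cvr <- noise_cv[["rates"]]; cvm <- noise_cv[["metabolome"]]
  withr::with_seed(seed, {
    rates$mean <- rates$true *
      if (cvr > 0) stats::rlnorm(nrow(rates), -log1p(cvr^2) / 2,
                                 sqrt(log1p(cvr^2))) else 1
    rates$sd <- abs(rates$true) * cvr
    metab$mean_mM <- metab$true *
      if (cvm > 0) stats::rlnorm(nrow(metab), -log1p(cvm^2) / 2,
                                 sqrt(log1p(cvm^2))) else 1
    metab$sd_mM <- metab$true * cvm
  })
  perturbation_dataset(states,
                       rates[c("state_id", "reaction_id", "mean", "sd")],
                       metab[c("state_id", "metabolite_id", "mean_mM", "sd_mM")],
                       reference_id = "ref")
}

## ---- fed-batch process simulator ------------------------------------------

#' Fed-batch process design
#'
#' The three-phase 15 L production process: glycerol batch, exponential
#' feeding (feeds A then B) at a set specific growth rate, and a constant
#' feeding phase (feed C) dosed at 0.2 g glycerol per g CDW and hour, with
#' IPTG induction at the constant-feed switch.  The optional methylglyoxal
#' sub-model accumulates MGO once the specific glycerol uptake exceeds a
#' threshold and shuts production off once the MGO concentration passes
#' its threshold.
#'
#' @param initial_volume_L,batch_glycerol_g_L batch-phase start conditions.
#' @param feed_a_L,feed_a_conc,feed_b_L,feed_b_conc exponential feeds.
#' @param feed_c_L,feed_c_conc constant feed reservoir.
#' @param mu_set set-point specific growth rate of the exponential phase (1/h).
#' @param const_feed_g_per_gX_h constant-phase dosing (g glycerol/gCDW/h).
#' @param mgo_on enable the MGO sub-model.
#' @param mgo_uptake_threshold specific uptake (mmol/gCDW/h) above which
#'   MGO is formed.
#' @param mgo_formation_rate MGO formation rate (mmol/gCDW/h) when active.
#' @param mgo_shutoff_mg_L MGO concentration ending product formation.
#' @return list of class `fed_batch_design`.
#' @export
fed_batch_design <- function(initial_volume_L = 15, batch_glycerol_g_L = 4,
                             feed_a_L = 1.0, feed_a_conc = 120,
                             feed_b_L = 4.5, feed_b_conc = 400,
                             feed_c_L = 5.0, feed_c_conc = 800,
                             mu_set = 0.07, const_feed_g_per_gX_h = 0.2,
                             mgo_on = FALSE, mgo_uptake_threshold = 2.4,
                             mgo_formation_rate = 0.05,
                             mgo_shutoff_mg_L = 30) {
  structure(as.list(environment()), class = "fed_batch_design")
}

#' Physiological parameters of the fed-batch simulator
#'
#' @param mu_max,ks_g_L Monod growth kinetics on glycerol.
#' @param yxs_g_g biomass yield on glycerol.
#' @param x0_g_L inoculum concentration.
#' @param qp_g_gX_h specific L-tryptophan production rate after induction.
#' @param yps_g_g product yield on glycerol (carbon cost of production).
#' @param qac_g_gX_h specific acetate formation rate after induction.
#' @param ms_g_gX_h maintenance glycerol consumption.
#' @param base_rate_L_h constant base addition during production.
#' @param y_o2_mmol_g,our_m mmol O2 per g glycerol consumed and
#'   maintenance OUR (mmol/gCDW/h).
#' @param gas_flow_L_h,o2_in,co2_in off-gas settings (L/h, volume %).
#' @return list of class `fed_batch_params`.
#' @export
fed_batch_params <- function(mu_max = 0.40, ks_g_L = 0.10, yxs_g_g = 0.32,
                             x0_g_L = 0.05, qp_g_gX_h = 0.030,
                             yps_g_g = 0.30, qac_g_gX_h = 0.006,
                             ms_g_gX_h = 0.03, base_rate_L_h = 0.01,
                             y_o2_mmol_g = 12, our_m = 0.3,
                             gas_flow_L_h = 900, o2_in = 20.94,
                             co2_in = 0.04) {
  structure(as.list(environment()), class = "fed_batch_params")
}

#' Simulate a three-phase fed-batch production process
#'
#' Integrates mass balances for volume, biomass, glycerol, L-tryptophan,
#' acetate and (optionally) methylglyoxal through the batch, exponential
#' feeding and constant feeding phases with a fixed-step RK4 scheme, and
#' emits a [process_timeseries()] (concentrations in g/L, off-gas table,
#' time-resolved feed concentration) plus a cumulative mass ledger for
#' conservation checks.
#'
#' @param design a [fed_batch_design()].
#' @param params a [fed_batch_params()].
#' @param t_end total process time (h).
#' @param dt integration step (h).
#' @param sample_every output sampling interval (h).
#' @param production_stop_h optionally force product (and acetate)
#'   formation to zero from this process time on, with feeding continuing
#'   (used to isolate dilution effects).
#' @return a [process_timeseries()]; attributes `phases` (tibble of phase
#'   boundaries) and `ledger` (tibble of cumulative masses, g).
#' @export
simulate_fed_batch <- function(design = fed_batch_design(),
                               params = fed_batch_params(),
                               t_end = 80, dt = 0.005, sample_every = 0.25,
                               production_stop_h = NULL) {
  p <- params; d <- design
  stopifnot(p$mu_max > 0, p$yxs_g_g > 0, d$initial_volume_L > 0)
  mmg <- species_molar_mass[["glycerol"]]
  y_ace <- 0.6    # g acetate per g glycerol routed to overflow

  # state: V (L), X (g), S (g glycerol), P (g trp), A (g acetate), M (g MGO)
  # ledger channels c_*: cumulative glycerol (g) consumed per sink
  st <- c(V = d$initial_volume_L, X = p$x0_g_L * d$initial_volume_L,
          S = d$batch_glycerol_g_L * d$initial_volume_L, P = 0, A = 0, M = 0,
          fed = 0, c_gro = 0, c_prd = 0, c_ace = 0, c_mnt = 0)
  phase <- "batch"
  fed_ab <- 0       # L of exponential feed delivered
  const_F <- NA_real_   # L/h of feed C, fixed at phase switch
  t_batch_end <- NA_real_; t_const_start <- NA_real_
  mgo_stopped <- FALSE

  deriv <- function(st, phase, Ffeed, cfeed, prod_frac) {
    V <- st[["V"]]; X <- st[["X"]]; S <- st[["S"]]
    s_conc <- max(S / V, 0)
    mu <- p$mu_max * s_conc / (p$ks_g_L + s_conc)
    # all consumption terms vanish smoothly at substrate depletion so the
    # mass ledger closes exactly (no clamping needed)
    lim <- s_conc / (s_conc + 5e-5)
    qp <- p$qp_g_gX_h * lim * prod_frac
    qac <- if (prod_frac >= 1) p$qac_g_gX_h * lim else 0
    growth_g <- mu * X / p$yxs_g_g                     # g glycerol/h per sink
    prod_g <- qp * X / p$yps_g_g
    ace_g <- qac * X / y_ace
    maint_g <- p$ms_g_gX_h * lim * X
    mgo_form <- 0
    if (d$mgo_on && X > 0) {
      cons_mmol <- (growth_g + prod_g + ace_g + maint_g) / X / mmg * 1000
      if (cons_mmol > d$mgo_uptake_threshold)
        mgo_form <- d$mgo_formation_rate * X * species_molar_mass[["mgo"]] / 1000
    }
    c(V = Ffeed + p$base_rate_L_h * (phase != "batch"),
      X = mu * X,
      S = Ffeed * cfeed - (growth_g + prod_g + ace_g + maint_g),
      P = qp * X, A = qac * X, M = mgo_form,
      fed = Ffeed * cfeed, c_gro = growth_g, c_prd = prod_g,
      c_ace = ace_g, c_mnt = maint_g)
  }

  rows <- list(); og <- list(); ledger <- list()
  t <- 0; next_sample <- 0
  n_steps <- ceiling(t_end / dt)
  for (k in seq_len(n_steps + 1L)) {
    V <- st[["V"]]; X <- st[["X"]]; S <- st[["S"]]
    s_conc <- max(S / V, 0)

    # phase logic
    if (phase == "batch" && s_conc < 0.01) {
      phase <- "exp"; t_batch_end <- t
    } else if (phase == "exp" && fed_ab >= d$feed_a_L + d$feed_b_L) {
      phase <- "const"; t_const_start <- t
      const_F <- d$const_feed_g_per_gX_h * X / d$feed_c_conc
    }
    if (d$mgo_on && !mgo_stopped && st[["M"]] / V * 1000 > d$mgo_shutoff_mg_L)
      mgo_stopped <- TRUE    # product formation ends abruptly
    stopped <- mgo_stopped ||
      (!is.null(production_stop_h) && t >= production_stop_h)
    # leaky pre-induction expression: production starts in the exponential
    # phase at half strength, full strength after induction
    prod_frac <- if (stopped || phase == "batch") 0
                 else if (phase == "exp") 0.5 else 1

    Ffeed <- 0; cfeed <- 0
    if (phase == "exp") {
      cfeed <- if (fed_ab < d$feed_a_L) d$feed_a_conc else d$feed_b_conc
      Ffeed <- (d$mu_set / p$yxs_g_g + p$ms_g_gX_h +
                  0.5 * p$qp_g_gX_h / p$yps_g_g) * X / cfeed
    } else if (phase == "const") {
      Ffeed <- const_F; cfeed <- d$feed_c_conc
    }

    # output row
    if (t >= next_sample - 1e-9 || k == n_steps + 1L) {
      mu_now <- p$mu_max * s_conc / (p$ks_g_L + s_conc)
      lim_now <- s_conc / (s_conc + 5e-5)    # same limitation as the ODEs
      cons_g_h <- mu_now * X / p$yxs_g_g + p$ms_g_gX_h * lim_now * X +
        prod_frac * p$qp_g_gX_h * lim_now * X / p$yps_g_g +
        (if (prod_frac >= 1) p$qac_g_gX_h * lim_now * X / y_ace else 0)
      our <- p$y_o2_mmol_g * cons_g_h / X + p$our_m     # mmol/gX/h
      cpr <- our * 0.95
      o2_drop <- our * X / 1000 * 24.05 / p$gas_flow_L_h * 100
      co2_rise <- cpr * X / 1000 * 24.05 / p$gas_flow_L_h * 100
      rows[[length(rows) + 1L]] <- tibble::tibble(
        time = t, volume = V, cdw = X / V, feed_rate = Ffeed,
        base_rate = p$base_rate_L_h * (phase != "batch"),
        conc_glycerol = max(S, 0) / V, conc_trp = st[["P"]] / V,
        conc_acetate = st[["A"]] / V, conc_mgo = st[["M"]] / V,
        feed_conc_glycerol = cfeed, phase = phase)
      og[[length(og) + 1L]] <- tibble::tibble(
        time = t, o2_in = p$o2_in, o2_out = p$o2_in - o2_drop,
        co2_in = p$co2_in, co2_out = p$co2_in + co2_rise,
        gas_flow = p$gas_flow_L_h)
      ledger[[length(ledger) + 1L]] <- tibble::tibble(
        time = t, fed_g = st[["fed"]],
        initial_g = d$initial_volume_L * d$batch_glycerol_g_L,
        residual_g = max(S, 0), growth_g = st[["c_gro"]],
        product_substrate_g = st[["c_prd"]], acetate_substrate_g = st[["c_ace"]],
        maintenance_g = st[["c_mnt"]], product_g = st[["P"]])
      next_sample <- next_sample + sample_every
    }
    if (k > n_steps) break

    # RK4 step with frozen phase/feed decisions
    f1 <- deriv(st, phase, Ffeed, cfeed, prod_frac)
    f2 <- deriv(st + dt / 2 * f1, phase, Ffeed, cfeed, prod_frac)
    f3 <- deriv(st + dt / 2 * f2, phase, Ffeed, cfeed, prod_frac)
    f4 <- deriv(st + dt * f3, phase, Ffeed, cfeed, prod_frac)
    st <- st + dt / 6 * (f1 + 2 * f2 + 2 * f3 + f4)
    if (st[["S"]] < 0) st[["S"]] <- 0
    if (phase == "exp") fed_ab <- fed_ab + Ffeed * dt
    t <- t + dt
  }

  data <- dplyr::bind_rows(rows)
  series <- process_timeseries(
    data[setdiff(names(data), "phase")],
    species_units = c(glycerol = "g_per_L", trp = "g_per_L",
                      acetate = "g_per_L", mgo = "g_per_L"),
    feed_conc = c(glycerol = NA),    # time-resolved column used instead
    molar_mass = species_molar_mass[c("glycerol", "trp", "acetate", "mgo")],
    offgas = dplyr::bind_rows(og))
  attr(series, "phases") <- tibble::tibble(
    t_batch_end = t_batch_end, t_const_start = t_const_start)
  attr(series, "ledger") <- dplyr::bind_rows(ledger)
  attr(series, "phase_per_sample") <- data$phase
  series
}
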