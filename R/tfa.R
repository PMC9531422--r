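# Thermodynamics-based flux analysis: problem construction, loopless FVA,
# optimisation, variability at the optimum, and polytope sampling.

## ---- small LP builder ------------------------------------------------------
# Accumulates named variables, equality rows and <=-rows; inequalities are
# converted to equalities with slack variables just before solving.
new_lpb <- function() {
  env <- new.env(parent = emptyenv())
  env$vars <- character(); env$lb <- numeric(); env$ub <- numeric()
  env$rows <- list()   # list of list(coef = named numeric, rhs, type)
  env
}
lpb_var <- function(env, name, lb, ub) {
  env$vars <- c(env$vars, name); env$lb <- c(env$lb, lb); env$ub <- c(env$ub, ub)
  invisible(name)
}
lpb_con <- function(env, coef, type = c("=", "<="), rhs = 0) {
  type <- match.arg(type)
  env$rows[[length(env$rows) + 1L]] <- list(coef = coef, rhs = rhs, type = type)
  invisible(NULL)
}
lpb_build <- function(env) {
  nv <- length(env$vars)
  nslack <- sum(vapply(env$rows, function(r) r$type == "<=", TRUE))
  m <- length(env$rows)
  A <- matrix(0, m, nv + nslack)
  b <- numeric(m)
  idx <- stats::setNames(seq_len(nv), env$vars)
  sl <- 0L
  for (i in seq_len(m)) {
    r <- env$rows[[i]]
    A[i, idx[names(r$coef)]] <- r$coef
    b[i] <- r$rhs
    if (r$type == "<=") { sl <- sl + 1L; A[i, nv + sl] <- 1 }
  }
  list(A = A, b = b,
       lb = c(env$lb, rep(0, nslack)),
       ub = c(env$ub, rep(1e6, nslack)),
       index = idx, n_var = nv)
}

## ---- rate constraints ------------------------------------------------------

#' Build a rate-constraint table
#'
#' Measured biomass-specific extracellular rates used to constrain the flux
#' space.  All rates are positive numbers; the direction is carried by the
#' reaction each constraint is attached to (uptake and secretion exchanges
#' both run forward in the packaged model).
#'
#' @param reaction_id exchange (or growth) reaction ids.
#' @param mean,sd rate mean and standard deviation (mmol/gCDW/h; growth 1/h).
#' @param kind one of `"uptake"`, `"secretion"`, `"respiration"`, `"growth"`.
#' @return tibble of class `rate_constraints`.
#' @export
rate_constraints <- function(reaction_id, mean, sd = 0,
                             kind = "uptake") {
  out <- tibble::tibble(reaction_id = reaction_id, mean = mean,
                        sd = rep_len(sd, length(reaction_id)),
                        kind = rep_len(kind, length(reaction_id)))
  stopifnot(all(out$sd >= 0),
            all(out$kind %in% c("uptake", "secretion", "respiration", "growth")))
  class(out) <- c("rate_constraints", class(out))
  out
}

# intersect model flux bounds with rate boxes mean +/- k*sd
apply_rate_bounds <- function(model, rates, sd_mult = 2) {
  lb <- stats::setNames(model$reactions$lb, model$reactions$id)
  ub <- stats::setNames(model$reactions$ub, model$reactions$id)
  if (!is.null(rates) && nrow(rates) > 0L) {
    unknown <- setdiff(rates$reaction_id, names(lb))
    if (length(unknown) > 0L)
      stop("rate constraints name unknown reactions: ",
           paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(rates))) {
      id <- rates$reaction_id[i]
      lo <- rates$mean[i] - sd_mult * rates$sd[i]
      hi <- rates$mean[i] + sd_mult * rates$sd[i]
      lb[id] <- max(lb[id], lo); ub[id] <- min(ub[id], hi)
    }
    if (any(lb > ub + 1e-12))
      stop("rate constraints conflict with model bounds for: ",
           paste(names(lb)[lb > ub + 1e-12], collapse = ", "))
  }
  list(lb = lb, ub = ub)
}

## ---- loopless FVA ----------------------------------------------------------

# Reactions that can participate in an internal (exchange-free) cycle:
# support of the null space of the stoichiometry restricted to non-exchange
# columns.  All cytosolic species count here (including currency metabolites
# that are excluded from steady-state balances): a cofactor-driven futile
# cycle has net cofactor turnover and is thermodynamically admissible, so it
# must not be flagged as a loop.
internal_cycle_support <- function(model, tol = 1e-9) {
  internal <- !model$reactions$is_exchange
  cyto <- model$metabolites$id[model$metabolites$compartment != "extracellular"]
  Sf <- matrix(0, length(cyto), nrow(model$reactions),
               dimnames = list(cyto, model$reactions$id))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[j]]
    keep <- names(s) %in% cyto
    if (any(keep)) Sf[names(s)[keep], j] <- s[keep]
  }
  Si <- Sf[, internal, drop = FALSE]
  if (ncol(Si) == 0L) return(character())
  sv <- svd(Si, nu = 0, nv = ncol(Si))
  r <- sum(sv$d >= tol * max(sv$d, 1))
  if (r >= ncol(Si)) return(character())
  N <- sv$v[, (r + 1L):ncol(Si), drop = FALSE]
  supp <- rowSums(abs(N)) > 1e-8
  model$reactions$id[internal][supp]
}

#' Loopless flux variability analysis
#'
#' Per-reaction flux minimum/maximum under mass balance, flux bounds,
#' measured-rate boxes, and the loop law: no internal (exchange-free) cycle
#' may carry a circulation with thermodynamically consistent signs.  The
#' loop law is enforced with direction binaries coupled to pseudo reaction
#' energies derived from metabolite potentials, and only for the reactions
#' that can actually participate in an internal cycle (the support of the
#' internal null space); all other reactions cannot form loops and need no
#' binaries.  Reactions whose range collapses to `[0, 0]` are flagged
#' `null`, which the analysis workflow uses to pre-constrain TFA.
#'
#' @param model a [network_model()].
#' @param rates optional [rate_constraints()].
#' @param sd_mult rate box half-width in standard deviations.
#' @param big_M big-M constant for the loop-law coupling.
#' @return object of class `flux_ranges`: tibble `flux` with
#'   `reaction_id`, `min`, `max`, `null`.
#' @export
loopless_fva <- function(model, rates = NULL, sd_mult = 2, big_M = 1000) {
  bounds <- apply_rate_bounds(model, rates, sd_mult)
  n <- nrow(model$reactions)
  ids <- model$reactions$id
  loop_ids <- internal_cycle_support(model)

  env <- new_lpb()
  for (j in seq_len(n)) lpb_var(env, ids[j], bounds$lb[j], bounds$ub[j])
  bal <- rownames(model$S)
  cyto <- model$metabolites$id[model$metabolites$compartment != "extracellular"]
  if (length(loop_ids) > 0L) {
    for (m_ in cyto) lpb_var(env, paste0(".mu_", m_), -big_M, big_M)
    for (id in loop_ids) lpb_var(env, paste0(".b_", id), 0, 1)
  }
  # mass balance
  for (i in seq_along(bal)) {
    co <- model$S[i, ]; nz <- co != 0
    lpb_con(env, stats::setNames(co[nz], ids[nz]), "=", 0)
  }
  # loop law on cycle-support reactions, potentials over all cytosolic
  # species: g_j = sum_i S_ij mu_i;
  # b=1 -> v_j >= 0 and g_j <= -1; b=0 -> v_j <= 0 and g_j >= +1
  for (id in loop_ids) {
    j <- match(id, ids)
    co <- model$reactions$stoich[[j]]
    co <- co[names(co) %in% cyto]
    g <- stats::setNames(as.numeric(co), paste0(".mu_", names(co)))
    bj <- paste0(".b_", id)
    lpb_con(env, c(stats::setNames(1, id), stats::setNames(-bounds$ub[j], bj)), "<=", 0)
    lpb_con(env, c(stats::setNames(-1, id), stats::setNames(-bounds$lb[j], bj)), "<=",
            -bounds$lb[j])
    lpb_con(env, c(g, stats::setNames(big_M + 1, bj)), "<=", big_M)
    lpb_con(env, c(-g, stats::setNames(-(big_M + 1), bj)), "<=", -1)
  }
  p <- lpb_build(env)
  bin_idx <- which(startsWith(env$vars, ".b_"))

  check_feasible(p, bin_idx, model, rates)
  out <- fva_sweep(p, bin_idx, ids)
  structure(list(flux = out, conc = NULL, dg = NULL), class = "flux_ranges")
}

# derive a 0/1 direction pattern for the binaries from an LP-relaxation
# solution: forward-running flux suggests b=1, backward b=0; idle reactions
# take the sign of the (pseudo) energy if present, else the rounded binary
warm_pattern <- function(p, bin_idx, x) {
  nm <- names(p$index)
  vapply(bin_idx, function(k) {
    bname <- nm[match(k, p$index)]
    rid <- sub("^\\.b_", "", bname)
    v <- if (rid %in% nm) x[p$index[rid]] else 0
    if (v > 1e-9) return(1)
    if (v < -1e-9) return(0)
    dgk <- paste0(".dg_", rid)
    if (dgk %in% nm) return(if (x[p$index[dgk]] <= 0) 1 else 0)
    if (x[k] >= 0.5) 1 else 0
  }, numeric(1))
}

# solve a mixed-binary subproblem with an LP-relaxation-guided warm start;
# an already-integral relaxation is optimal as it stands
milp_guided <- function(obj, p, bin_idx, maximize) {
  if (length(bin_idx) == 0L)
    return(solve_lp(obj, p$A, p$b, p$lb, p$ub, maximize))
  rel <- solve_lp(obj, p$A, p$b, p$lb, p$ub, maximize)
  if (rel$status == "optimal" &&
      all(abs(rel$x[bin_idx] - round(rel$x[bin_idx])) <= 1e-6))
    return(rel)
  warm <- if (rel$status == "optimal") warm_pattern(p, bin_idx, rel$x) else NULL
  solve_milp(obj, p$A, p$b, p$lb, p$ub, bin_idx, maximize, warm = warm)
}

# minimise/maximise each listed variable of a built problem
fva_sweep <- function(p, bin_idx, var_names) {
  nv <- ncol(p$A)
  purrr::map_dfr(var_names, function(id) {
    obj <- numeric(nv); obj[p$index[id]] <- 1
    lo <- milp_guided(obj, p, bin_idx, maximize = FALSE)
    hi <- milp_guided(obj, p, bin_idx, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("variability subproblem failed for ", id, " (", lo$status, ")")
    tibble::tibble(reaction_id = id, min = lo$objval, max = hi$objval,
                   null = abs(lo$objval) <= 1e-9 & abs(hi$objval) <= 1e-9)
  })
}

check_feasible <- function(p, bin_idx, model, rates) {
  r <- milp_guided(numeric(ncol(p$A)), p, bin_idx, maximize = FALSE)
  if (r$status == "optimal") return(invisible(TRUE))
  hint <- infeasibility_hint(model, rates)
  stop("constraint set infeasible; ", hint)
}

# relax each constraint family in turn and report which restores feasibility
infeasibility_hint <- function(model, rates) {
  try_lp <- function(lb, ub) {
    r <- solve_lp(numeric(nrow(model$reactions)), model$S,
                  rep(0, nrow(model$S)), lb, ub)
    r$status == "optimal"
  }
  base <- apply_rate_bounds(model, NULL)
  if (!try_lp(base$lb, base$ub))
    return("model infeasible even without rate constraints (check bounds)")
  if (is.null(rates) || nrow(rates) == 0L)
    return("no relaxation found")
  for (k in unique(rates$kind)) {
    sub <- rates[rates$kind != k, ]
    bo <- apply_rate_bounds(model, sub)
    if (try_lp(bo$lb, bo$ub))
      return(paste0("relaxing the '", k, "' rate constraints restores feasibility"))
  }
  "no single rate-constraint family explains the conflict"
}

## ---- TFA problem -----------------------------------------------------------

#' Construct a thermodynamics-based flux analysis problem
#'
#' Combines mass balance, measured-rate boxes (mean +/- `sd_mult` sd),
#' metabolite-concentration bounds (measured species to mean +/- 2 sd, the
#' rest to the model defaults), and for every non-exchange reaction with a
#' known `dG0'` the coupling `sign(v) = -sign(dG')` with
#' `dG' = dG0' + R*T*sum(s*ln c)`.  A direction binary is introduced only
#' where the feasible `dG'` range straddles zero; elsewhere the direction
#' is fixed a priori, which keeps the mixed-binary program small.
#' Reactions flagged null by [loopless_fva()] can be pre-fixed to zero via
#' `null_ids`.
#'
#' @param model a [network_model()].
#' @param rates a [rate_constraints()] table.
#' @param metabolome optional tibble (`metabolite_id`, `mean_mM`, `sd_mM`)
#'   of measured concentrations.
#' @param null_ids reactions to fix at zero (from loopless FVA).
#' @param settings a [thermo_settings()].
#' @param big_M big-M constant (flux units and kJ/mol).
#' @param sd_mult rate box half-width in standard deviations.
#' @param objective_id objective reaction; default the model's.
#' @return object of class `tfa_problem`.
#' @export
tfa_problem <- function(model, rates, metabolome = NULL, null_ids = character(),
                        settings = thermo_settings(), big_M = 1000,
                        sd_mult = 2, objective_id = NULL) {
  objective_id <- objective_id %||% model$objective_id
  if (is.null(objective_id)) stop("no objective reaction defined")
  bounds <- apply_rate_bounds(model, rates, sd_mult)
  for (id in null_ids) { bounds$lb[id] <- 0; bounds$ub[id] <- 0 }

  cb <- if (!is.null(metabolome)) metabolome_conc_bounds(model, metabolome) else NULL
  conc <- conc_bounds_vector(model, cb)
  gr <- gibbs_ranges(model, cb, settings)

  ids <- model$reactions$id
  bal <- rownames(model$S)
  rt <- settings$gas_constant * settings$temperature
  eps <- settings$epsilon_dg

  env <- new_lpb()
  for (j in seq_along(ids)) lpb_var(env, ids[j], bounds$lb[j], bounds$ub[j])
  for (m_ in bal) lpb_var(env, paste0(".ln_", m_), log(conc$lb[m_]), log(conc$ub[m_]))

  covered <- gr$covered_ids
  binaries <- character()
  for (k in seq_len(nrow(gr$ranges))) {
    id <- gr$ranges$reaction_id[k]
    j <- match(id, ids)
    dgname <- paste0(".dg_", id)
    dg_lo <- gr$ranges$dg_min[k]; dg_hi <- gr$ranges$dg_max[k]
    lpb_var(env, dgname, dg_lo, dg_hi)
    # dg - RT * sum(s * ln c) = dg0
    s <- model$reactions$stoich[[j]]; s <- s[names(s) %in% bal]
    lpb_con(env, c(stats::setNames(1, dgname),
                   stats::setNames(-rt * as.numeric(s), paste0(".ln_", names(s)))),
            "=", model$reactions$dg0_prime[j])
    if (gr$ranges$dg_max[k] <= -eps) {
      # always downhill forward: backward flux impossible
      env$lb[match(id, env$vars)] <- max(bounds$lb[j], 0)
    } else if (gr$ranges$dg_min[k] >= eps) {
      env$ub[match(id, env$vars)] <- min(bounds$ub[j], 0)
    } else {
      bj <- paste0(".b_", id)
      lpb_var(env, bj, 0, 1)
      binaries <- c(binaries, bj)
      lpb_con(env, c(stats::setNames(1, id), stats::setNames(-max(bounds$ub[j], 0), bj)),
              "<=", 0)
      lbm <- min(bounds$lb[j], 0)
      lpb_con(env, c(stats::setNames(-1, id), stats::setNames(-lbm, bj)),
              "<=", -lbm)
      # tight per-reaction coupling: b=1 -> dg <= -eps, b=0 -> dg >= +eps
      lpb_con(env, c(stats::setNames(1, dgname), stats::setNames(dg_hi + eps, bj)),
              "<=", dg_hi)
      lpb_con(env, c(stats::setNames(-1, dgname), stats::setNames(dg_lo - eps, bj)),
              "<=", -eps)
    }
  }
  for (i in seq_along(bal)) {
    co <- model$S[i, ]; nz <- co != 0
    lpb_con(env, stats::setNames(co[nz], ids[nz]), "=", 0)
  }
  structure(list(model = model, rates = rates, env = env,
                 covered_ids = covered, skipped_ids = gr$skipped,
                 binaries = binaries, settings = settings,
                 objective_id = objective_id, big_M = big_M),
            class = "tfa_problem")
}

#' @export
print.tfa_problem <- function(x, ...) {
  cat("<tfa_problem> ", nrow(x$model$reactions), " reactions, ",
      length(x$covered_ids), " thermodynamically covered, ",
      length(x$binaries), " direction binaries\n", sep = "")
  invisible(x)
}

# extract named solution pieces from a raw LP vector
tfa_unpack <- function(problem, x) {
  env <- problem$env
  val <- stats::setNames(x[seq_along(env$vars)], env$vars)
  ids <- problem$model$reactions$id
  bal <- rownames(problem$model$S)
  list(v = val[ids],
       ln_conc = stats::setNames(val[paste0(".ln_", bal)], bal),
       dg_prime = stats::setNames(val[paste0(".dg_", problem$covered_ids)],
                                  problem$covered_ids),
       binaries = stats::setNames(round(val[problem$binaries]),
                                  sub("^\\.b_", "", problem$binaries)))
}

#' Solve a TFA problem by maximising the objective
#'
#' @param problem a [tfa_problem()].
#' @return object of class `flux_solution` with `v` (named flux vector),
#'   `ln_conc` (named, ln of molar concentration), `dg_prime` (named,
#'   kJ/mol), `objective_value` and `status`.
#' @export
solve_tfa <- function(problem) {
  p <- lpb_build(problem$env)
  obj <- numeric(ncol(p$A)); obj[p$index[problem$objective_id]] <- 1
  bin_idx <- unname(p$index[problem$binaries])
  r <- milp_guided(obj, p, bin_idx, maximize = TRUE)
  if (r$status != "optimal") {
    hint <- infeasibility_hint(problem$model, problem$rates)
    return(structure(list(v = NULL, ln_conc = NULL, dg_prime = NULL,
                          objective_value = NA_real_, status = "infeasible",
                          hint = hint), class = "flux_solution"))
  }
  sol <- tfa_unpack(problem, r$x)
  structure(c(sol, list(objective_value = r$objval, status = "optimal")),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> status: ", x$status, sep = "")
  if (x$status == "optimal")
    cat(", objective ", format(x$objective_value, digits = 6), sep = "")
  if (!is.null(x$hint)) cat("\n  hint: ", x$hint, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
#' @method tidy flux_solution
tidy.flux_solution <- function(x, ...) {
  if (x$status != "optimal") return(tibble::tibble())
  tibble::tibble(reaction_id = names(x$v), flux = as.numeric(x$v),
                 dg_prime = as.numeric(x$dg_prime[names(x$v)]))
}

#' Variability analysis at (a fraction of) the optimum
#'
#' Constrains the objective to at least `fraction` of the optimal value
#' (the variance criterion; 0.999 reproduces the analysis conditions) and
#' then minimises/maximises every flux, every log-concentration and every
#' covered reaction's Gibbs energy.
#'
#' @param problem a [tfa_problem()].
#' @param fraction optimality fraction in \[0, 1\].
#' @param what subset of `c("flux", "conc", "dg")` to sweep.
#' @return object of class `flux_ranges` with tibbles `flux`, `conc`, `dg`.
#' @export
variability_at_optimum <- function(problem, fraction = 0.999,
                                   what = c("flux", "conc", "dg")) {
  stopifnot(fraction >= 0, fraction <= 1)
  sol <- solve_tfa(problem)
  if (sol$status != "optimal") stop("TFA problem infeasible: ", sol$hint)
  env <- problem$env
  # objective >= fraction * z*  (as <= row)
  lpb_con(env, stats::setNames(-1, problem$objective_id), "<=",
          -fraction * sol$objective_value)
  on.exit(env$rows[[length(env$rows)]] <- NULL)
  p <- lpb_build(env)
  bin_idx <- unname(p$index[problem$binaries])
  ids <- problem$model$reactions$id
  flux <- if ("flux" %in% what) fva_sweep(p, bin_idx, ids) else NULL
  conc <- if ("conc" %in% what) {
    out <- fva_sweep(p, bin_idx, paste0(".ln_", rownames(problem$model$S)))
    tibble::tibble(metabolite_id = rownames(problem$model$S),
                   ln_min = out$min, ln_max = out$max)
  } else NULL
  dg <- if ("dg" %in% what && length(problem$covered_ids) > 0L) {
    out <- fva_sweep(p, bin_idx, paste0(".dg_", problem$covered_ids))
    tibble::tibble(reaction_id = problem$covered_ids,
                   dg_min = out$min, dg_max = out$max)
  } else NULL
  structure(list(flux = flux, conc = conc, dg = dg,
                 fraction = fraction, objective_value = sol$objective_value),
            class = "flux_ranges")
}

#' @export
print.flux_ranges <- function(x, ...) {
  cat("<flux_ranges>")
  if (!is.null(x$flux)) cat(" ", nrow(x$flux), " flux ranges", sep = "")
  if (!is.null(x$fraction)) cat(" at optimality fraction ", x$fraction, sep = "")
  cat("\n")
  invisible(x)
}

# feasible step interval along direction d from x within [lb, ub]
chord_interval <- function(x, d, lb, ub) {
  tmin <- -Inf; tmax <- Inf
  pos <- d > 1e-12; neg <- d < -1e-12
  if (any(pos)) {
    tmax <- min(tmax, (ub[pos] - x[pos]) / d[pos])
    tmin <- max(tmin, (lb[pos] - x[pos]) / d[pos])
  }
  if (any(neg)) {
    tmax <- min(tmax, (lb[neg] - x[neg]) / d[neg])
    tmin <- max(tmin, (ub[neg] - x[neg]) / d[neg])
  }
  c(tmin, tmax)
}

#' Sample the feasible flux polytope by hit-and-run
#'
#' Fixes the reaction directions of a TFA optimum (its binaries and the a
#' priori fixed signs), yielding a convex polytope
#' `{v : S v = 0, bounds}`, and draws approximately uniform samples with a
#' hit-and-run random walk in null-space coordinates (warm-up then
#' thinning).  For a zero-dimensional (fully determined) polytope the
#' unique point is returned `n_samples` times with a warning.
#'
#' @param problem a [tfa_problem()].
#' @param n_samples number of samples.
#' @param seed integer seed; fixed seed gives identical samples.
#' @param solution optional [solve_tfa()] result to take directions from.
#' @param warmup,thin hit-and-run warm-up steps and thinning interval.
#' @return matrix (`n_samples` x reactions) with reaction-id columns.
#' @export
sample_flux_space <- function(problem, n_samples, seed, solution = NULL,
                              warmup = 100, thin = 10) {
  sol <- solution %||% solve_tfa(problem)
  if (sol$status != "optimal") stop("cannot sample: TFA problem infeasible")
  model <- problem$model
  ids <- model$reactions$id
  env <- problem$env
  lb <- stats::setNames(env$lb[seq_along(ids)], ids)
  ub <- stats::setNames(env$ub[seq_along(ids)], ids)
  # direction-fix on covered reactions: the optimum's binaries where they
  # exist, the flux sign otherwise (idle reactions keep the sign their
  # Gibbs energy admits at the optimum)
  for (id in problem$covered_ids) {
    if (!is.null(sol$binaries) && id %in% names(sol$binaries)) {
      if (sol$binaries[[id]] >= 0.5) lb[id] <- max(lb[id], 0)
      else ub[id] <- min(ub[id], 0)
    } else if (sol$v[id] > 1e-9) lb[id] <- max(lb[id], 0)
    else if (sol$v[id] < -1e-9) ub[id] <- min(ub[id], 0)
    else if (sol$dg_prime[[id]] <= 0) lb[id] <- max(lb[id], 0)
    else ub[id] <- min(ub[id], 0)
  }
  S <- model$S
  # null-space basis of S, restricted to coordinates the bounds leave free
  # (directions along bound-fixed fluxes have zero chord length)
  fixed <- which(ub - lb < 1e-12)
  A <- S
  if (length(fixed) > 0L) {
    pin <- matrix(0, length(fixed), ncol(S))
    pin[cbind(seq_along(fixed), fixed)] <- 1
    A <- rbind(S, pin)
  }
  sv <- svd(A, nu = 0, nv = ncol(A))
  r <- sum(sv$d >= 1e-9 * max(sv$d))
  N <- if (r < ncol(A)) sv$v[, (r + 1L):ncol(A), drop = FALSE] else NULL
  k <- if (is.null(N)) 0L else ncol(N)

  out <- matrix(NA_real_, n_samples, length(ids), dimnames = list(NULL, ids))
  # interior starting point: a TFA optimum is a vertex, where hit-and-run
  # chords have zero length; the Chebyshev-style center LP (maximal uniform
  # slack to the non-fixed bounds) yields an interior point, and a zero
  # optimal slack identifies a fully determined polytope
  v0 <- pmin(pmax(as.numeric(sol$v), lb), ub)
  degenerate <- k == 0L
  if (!degenerate) {
    free <- setdiff(seq_along(ids), fixed)
    n <- length(ids)
    nr <- length(free)
    Aeq <- cbind(S, 0)
    Ain <- matrix(0, 2L * nr, n + 1L)
    bin <- numeric(2L * nr)
    for (i in seq_len(nr)) {
      j <- free[i]
      Ain[2L * i - 1L, j] <- -1; Ain[2L * i - 1L, n + 1L] <- 1
      bin[2L * i - 1L] <- -lb[j]
      Ain[2L * i, j] <- 1; Ain[2L * i, n + 1L] <- 1
      bin[2L * i] <- ub[j]
    }
    Afull <- rbind(cbind(Aeq, matrix(0, nrow(Aeq), 2L * nr)),
                   cbind(Ain, diag(2L * nr)))
    bfull <- c(rep(0, nrow(S)), bin)
    lbf <- c(lb, 0, rep(0, 2L * nr))
    ubf <- c(ub, 1e6, rep(1e6, 2L * nr))
    objf <- c(rep(0, n), 1, rep(0, 2L * nr))
    ch <- solve_lp(objf, Afull, bfull, lbf, ubf, maximize = TRUE)
    if (ch$status == "optimal" && ch$objval > 1e-9) {
      v0 <- pmin(pmax(ch$x[seq_len(n)], lb), ub)
    } else {
      degenerate <- TRUE
    }
  }
  if (degenerate) {
    warning("flux polytope is fully determined; returning the unique point")
    out[] <- rep(v0, each = n_samples)
    return(out)
  }
  withr::with_seed(seed, {
    x <- v0
    total <- warmup + n_samples * thin
    got <- 0L
    for (step in seq_len(total)) {
      d <- as.numeric(N %*% stats::rnorm(k))
      nd <- sqrt(sum(d^2))
      if (nd < 1e-12) next
      d <- d / nd
      span <- chord_interval(x, d, lb, ub)
      if (!is.finite(span[1]) || !is.finite(span[2]) || span[2] < span[1]) next
      x <- x + stats::runif(1, span[1], span[2]) * d
      x <- pmin(pmax(x, lb), ub)
      if (step > warmup && (step - warmup) %% thin == 0L) {
        got <- got + 1L
        out[got, ] <- x
      }
    }
  })
  out
}
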