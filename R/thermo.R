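#' Thermodynamic settings
#'
#' Physical constants and in vivo conditions used when transforming
#' standard Gibbs reaction energies.  Defaults reflect the measurement
#' conditions of the perturbation experiments: 37 degC, extracellular pH
#' 7.0, ionic strength 0.15 M.  Standard Gibbs energies supplied to the
#' package are taken to be already transformed to these conditions, so pH
#' and ionic strength are recorded for provenance, not re-applied.
#'
#' @param temperature K.
#' @param gas_constant kJ/mol/K.
#' @param ph unitless.
#' @param ionic_strength M.
#' @param standard_conc reference concentration (M) for activity ratios.
#' @param epsilon_dg minimum driving force (kJ/mol) treated as "strictly
#'   negative" when coupling flux direction to Gibbs energy sign.
#' @return list of class `thermo_settings`.
#' @export
thermo_settings <- function(temperature = 310.15, gas_constant = 8.314e-3,
                            ph = 7.0, ionic_strength = 0.15,
                            standard_conc = 1.0, epsilon_dg = 1e-6) {
  stopifnot(temperature > 0, ionic_strength >= 0, standard_conc > 0,
            epsilon_dg >= 0)
  structure(list(temperature = temperature, gas_constant = gas_constant,
                 ph = ph, ionic_strength = ionic_strength,
                 standard_conc = standard_conc, epsilon_dg = epsilon_dg),
            class = "thermo_settings")
}

#' Transformed Gibbs energy of a reaction at given concentrations
#'
#' Applies the concentration transform
#' `dG' = dG0' + R*T*sum_i(s_i*ln(c_i/c0))` over the balanced metabolites
#' of the reaction; currency and extracellular species are assumed to be
#' folded into the effective `dG0'`.
#'
#' @param dg0_prime standard transformed Gibbs energy (kJ/mol).
#' @param stoich named numeric, metabolite id -> signed coefficient.
#' @param ln_conc named numeric, metabolite id -> `ln(c/standard_conc)`.
#'   Must cover every metabolite named in `stoich` (ids absent from
#'   `ln_conc` but listed in `skip` are ignored).
#' @param settings a [thermo_settings()].
#' @param skip metabolite ids exempt from the concentration term.
#' @return dG' in kJ/mol.
#' @export
reaction_gibbs <- function(dg0_prime, stoich, ln_conc,
                           settings = thermo_settings(), skip = character()) {
  ids <- setdiff(names(stoich), skip)
  missing <- setdiff(ids, names(ln_conc))
  if (length(missing) > 0L)
    stop("missing concentration for metabolite(s): ",
         paste(missing, collapse = ", "))
  rt <- settings$gas_constant * settings$temperature
  dg0_prime + rt * sum(stoich[ids] * ln_conc[ids])
}

#' Is a flux direction thermodynamically feasible?
#'
#' A nonzero flux must run downhill: positive flux needs
#' `dG <= -epsilon_dg`, negative flux needs `dG >= +epsilon_dg`; a zero
#' flux is always feasible.
#'
#' @param v flux (any consistent unit).
#' @param dg transformed Gibbs energy (kJ/mol).
#' @param epsilon_dg minimum driving force (kJ/mol).
#' @return logical (vectorised over `v`/`dg`).
#' @export
direction_feasible <- function(v, dg, epsilon_dg = 1e-6) {
  v == 0 | (v > 0 & dg <= -epsilon_dg) | (v < 0 & dg >= epsilon_dg)
}

#' Feasible Gibbs-energy ranges over a concentration box
#'
#' For every non-exchange reaction with a known `dG0'`, computes the exact
#' minimum and maximum of `dG'` when each balanced metabolite concentration
#' ranges over its box.  `dG'` is linear in each `ln c`, so the extrema sit
#' at box corners selected by the sign of the stoichiometric coefficient.
#'
#' @param model a [network_model()].
#' @param conc_bounds optional named list/tibble overriding per-metabolite
#'   bounds; default uses the model's `conc_lb`/`conc_ub` columns (M).
#'   Accepts a tibble with `metabolite_id`, `lb`, `ub` or a named list of
#'   `c(lb, ub)` pairs.
#' @param settings a [thermo_settings()].
#' @return list of class `gibbs_energies`: tibble `ranges` with
#'   `reaction_id`, `dg_min`, `dg_max`, `covered_ids`, and `skipped`
#'   (reactions lacking `dG0'`).
#' @export
gibbs_ranges <- function(model, conc_bounds = NULL,
                         settings = thermo_settings()) {
  bounds <- conc_bounds_vector(model, conc_bounds)
  rt <- settings$gas_constant * settings$temperature
  bal <- model$metabolites$id[model$metabolites$is_balanced]
  has_dg <- !is.na(model$reactions$dg0_prime) & !model$reactions$is_exchange
  rows <- purrr::map_dfr(which(has_dg), function(j) {
    s <- model$reactions$stoich[[j]]
    s <- s[names(s) %in% bal]
    lo <- model$reactions$dg0_prime[j]
    hi <- lo
    for (k in seq_along(s)) {
      id <- names(s)[k]
      lnl <- log(bounds$lb[id] / settings$standard_conc)
      lnu <- log(bounds$ub[id] / settings$standard_conc)
      if (s[k] > 0) { lo <- lo + rt * s[k] * lnl; hi <- hi + rt * s[k] * lnu }
      else          { lo <- lo + rt * s[k] * lnu; hi <- hi + rt * s[k] * lnl }
    }
    tibble::tibble(reaction_id = model$reactions$id[j],
                   dg_min = unname(lo), dg_max = unname(hi))
  })
  if (nrow(rows) == 0L)
    rows <- tibble::tibble(reaction_id = character(), dg_min = numeric(),
                           dg_max = numeric())
  structure(list(ranges = rows,
                 covered_ids = rows$reaction_id,
                 skipped = model$reactions$id[!has_dg & !model$reactions$is_exchange]),
            class = "gibbs_energies")
}

#' @export
print.gibbs_energies <- function(x, ...) {
  cat("<gibbs_energies> ", nrow(x$ranges), " reactions covered, ",
      length(x$skipped), " without dG0'\n", sep = "")
  invisible(x)
}

# resolve concentration bounds into named lb/ub vectors (M)
conc_bounds_vector <- function(model, conc_bounds = NULL) {
  lb <- stats::setNames(model$metabolites$conc_lb, model$metabolites$id)
  ub <- stats::setNames(model$metabolites$conc_ub, model$metabolites$id)
  if (!is.null(conc_bounds)) {
    if (is.data.frame(conc_bounds)) {
      for (i in seq_len(nrow(conc_bounds))) {
        id <- conc_bounds$metabolite_id[i]
        lb[id] <- conc_bounds$lb[i]; ub[id] <- conc_bounds$ub[i]
      }
    } else {
      for (id in names(conc_bounds)) {
        lb[id] <- conc_bounds[[id]][1]; ub[id] <- conc_bounds[[id]][2]
      }
    }
  }
  if (any(lb <= 0)) stop("concentration bounds must be positive")
  if (any(lb > ub)) stop("concentration lower bound exceeds upper bound")
  list(lb = lb, ub = ub)
}

#' Concentration bounds from measured metabolome data
#'
#' Measured metabolites are constrained to mean +/- `k` standard
#' deviations (floored at `floor_m` M); unmeasured metabolites keep the
#' model defaults.
#'
#' @param model a [network_model()].
#' @param metabolome tibble with `metabolite_id`, `mean_mM`, `sd_mM`.
#' @param k half-width in standard deviations.
#' @param floor_m minimum concentration (M).
#' @return tibble with `metabolite_id`, `lb`, `ub` (M).
#' @export
metabolome_conc_bounds <- function(model, metabolome, k = 2, floor_m = 1e-8) {
  stopifnot(all(c("metabolite_id", "mean_mM", "sd_mM") %in% names(metabolome)))
  metabolome |>
    dplyr::filter(.data$metabolite_id %in% model$metabolites$id) |>
    dplyr::transmute(
      metabolite_id = .data$metabolite_id,
      lb = pmax((.data$mean_mM - k * .data$sd_mM) / 1000, floor_m),
      ub = pmax((.data$mean_mM + k * .data$sd_mM) / 1000, floor_m * 2))
}
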