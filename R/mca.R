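# Lin-log metabolic control analysis: elasticity regression over multiple
# steady states, control-coefficient computation via the reduced
# stoichiometry, finite-difference verification, and Monte Carlo
# uncertainty propagation.

#' Multi-steady-state perturbation dataset
#'
#' Holds the 12+1 steady-state observations of the perturbation design (or
#' any comparable multi-state experiment): per-state reaction rates/fluxes
#' with uncertainties and the measured metabolome.
#'
#' @param states tibble with `state_id`, `substrate`, `stage`
#'   (`"reference"` allowed for both).
#' @param rates tibble with `state_id`, `reaction_id`, `mean`, `sd`
#'   (mmol/gCDW/h); used both as measured extracellular rates and as the
#'   flux estimates entering the elasticity regression.
#' @param metabolome tibble with `state_id`, `metabolite_id`, `mean_mM`,
#'   `sd_mM`.
#' @param reference_id the reference state's id.
#' @return object of class `perturbation_dataset`.
#' @export
perturbation_dataset <- function(states, rates, metabolome, reference_id) {
  states <- tibble::as_tibble(states)
  rates <- tibble::as_tibble(rates)
  metabolome <- tibble::as_tibble(metabolome)
  if (!reference_id %in% states$state_id)
    stop("reference state '", reference_id, "' not among the states")
  if (any(rates$sd < 0) || any(metabolome$sd_mM < 0))
    stop("standard deviations must be nonnegative")
  if (any(metabolome$mean_mM <= 0))
    stop("metabolome concentrations must be strictly positive")
  structure(list(states = states, rates = rates, metabolome = metabolome,
                 reference_id = reference_id),
            class = "perturbation_dataset")
}

#' @export
print.perturbation_dataset <- function(x, ...) {
  cat("<perturbation_dataset> ", nrow(x$states), " states (reference: ",
      x$reference_id, "), ", dplyr::n_distinct(x$metabolome$metabolite_id),
      " metabolites\n", sep = "")
  invisible(x)
}

#' Allowed-nonzero elasticity pattern of a model
#'
#' Substrates, products and declared allosteric effectors of each
#' reaction, restricted to balanced, measured metabolites.  Feed-driven
#' boundary reactions -- exchanges that consume an extracellular species
#' (substrate and oxygen uptake) -- get empty rows: their rates are set by
#' the feed profile, not by intracellular concentrations.  Secretion
#' exchanges keep their intracellular substrate.  Reactions operating far
#' from equilibrium (standard transformed Gibbs energy below
#' `product_dg_cutoff`) lose their product entries: at strong thermodynamic
#' displacement the product elasticity vanishes.  Rows are capped at the
#' `cap` largest |stoichiometric coefficient| entries (effectors always
#' kept) so that every row stays identifiable from the 12-state design.
#'
#' @param model a [network_model()].
#' @param cap maximum number of stoichiometric mask entries per reaction.
#' @param product_dg_cutoff kJ/mol below which products are masked out.
#' @return logical matrix, reactions x (balanced & measured metabolites).
#' @export
elasticity_mask <- function(model, cap = 4L, product_dg_cutoff = -15) {
  mets <- model$metabolites
  cols <- mets$id[mets$is_balanced & mets$measured]
  extra <- mets$id[mets$compartment == "extracellular"]
  mask <- matrix(FALSE, nrow(model$reactions), length(cols),
                 dimnames = list(model$reactions$id, cols))
  for (j in seq_len(nrow(model$reactions))) {
    s <- model$reactions$stoich[[j]]
    if (model$reactions$is_exchange[j] &&
        any(s[names(s) %in% extra] < 0)) next   # feed/gas-driven uptake
    s <- s[names(s) %in% cols]
    dg0 <- model$reactions$dg0_prime[j]
    if (!is.na(dg0) && dg0 < product_dg_cutoff) s <- s[s < 0]
    if (length(s) > cap) s <- s[order(-abs(s))][seq_len(cap)]
    mask[j, names(s)] <- TRUE
  }
  for (i in seq_len(nrow(model$regulation))) {
    rid <- model$regulation$reaction_id[i]
    mid <- model$regulation$metabolite_id[i]
    if (rid %in% rownames(mask) && mid %in% cols) mask[rid, mid] <- TRUE
  }
  mask
}

#' Estimate scaled elasticities by lin-log regression
#'
#' Under lin-log kinetics with constant enzyme levels
#' (`v/v_ref = 1 + sum_i eps_i * ln(c_i/c_ref)`), each reaction's scaled
#' elasticities solve a weighted least-squares problem across the perturbed
#' steady states: response `y_m = v_m/v_ref - 1`, regressors
#' `x_im = ln(c_im/c_i_ref)` over the reaction's mask entries, weights the
#' inverse first-order variance of `y`.  Rank-deficient rows fall back to a
#' minimum-norm ridge solution and are flagged.
#'
#' @param dataset a [perturbation_dataset()].
#' @param model a [network_model()].
#' @param mask optional logical mask; default [elasticity_mask()].
#' @param ridge ridge penalty for under-determined rows.
#' @return object of class `elasticity_matrix` with `eps` (reactions x
#'   metabolites), `mask`, `underdetermined`, `excluded` (zero reference
#'   flux), `dropped_metabolites` (not measured in every state).
#' @export
estimate_elasticities <- function(dataset, model, mask = NULL, ridge = 1e-6) {
  mask <- mask %||% elasticity_mask(model)
  mat <- dataset_matrices(dataset)
  met_ids <- intersect(colnames(mask), colnames(mat$met_mean)[mat$met_complete])
  fit <- eps_core(mat$met_mean, mat$rate_mean, mat$rate_sd, mat$ref_row,
                  met_ids, mask, model$reactions$id, ridge)
  for (k in fit$excluded_zero)
    warning("reaction '", k, "' has zero/missing reference flux; excluded")
  structure(list(eps = fit$eps, mask = mask, underdetermined = fit$underdet,
                 excluded = c(fit$excluded_zero, fit$excluded_missing),
                 dropped_metabolites =
                   colnames(mat$met_mean)[!mat$met_complete]),
            class = "elasticity_matrix")
}

# wide-matrix view of a perturbation dataset (states x variables)
dataset_matrices <- function(dataset) {
  met <- tidyr::pivot_wider(dataset$metabolome[c("state_id", "metabolite_id", "mean_mM")],
                            names_from = "metabolite_id", values_from = "mean_mM")
  met_sd <- tidyr::pivot_wider(dataset$metabolome[c("state_id", "metabolite_id", "sd_mM")],
                               names_from = "metabolite_id", values_from = "sd_mM")
  rt <- tidyr::pivot_wider(dataset$rates[c("state_id", "reaction_id", "mean")],
                           names_from = "reaction_id", values_from = "mean")
  rt_sd <- tidyr::pivot_wider(dataset$rates[c("state_id", "reaction_id", "sd")],
                              names_from = "reaction_id", values_from = "sd")
  mm <- as.matrix(met[-1]); rownames(mm) <- met$state_id
  ms <- as.matrix(met_sd[-1]); rownames(ms) <- met_sd$state_id
  rm_ <- as.matrix(rt[-1]); rownames(rm_) <- rt$state_id
  rs <- as.matrix(rt_sd[-1]); rownames(rs) <- rt_sd$state_id
  list(met_mean = mm, met_sd = ms[rownames(mm), colnames(mm), drop = FALSE],
       rate_mean = rm_, rate_sd = rs[rownames(rm_), colnames(rm_), drop = FALSE],
       ref_row = dataset$reference_id,
       met_complete = apply(!is.na(mm), 2, all))
}

# matrix-form elasticity regression shared by the tibble interface and the
# Monte Carlo resampling loop
eps_core <- function(met_mean, rate_mean, rate_sd, ref, met_ids, mask,
                     rxn_ids, ridge = 1e-6) {
  pert <- setdiff(rownames(met_mean), ref)
  cref <- met_mean[ref, met_ids]
  X_all <- log(sweep(met_mean[pert, met_ids, drop = FALSE], 2, cref, "/"))
  eps <- matrix(0, length(rxn_ids), length(met_ids),
                dimnames = list(rxn_ids, met_ids))
  underdet <- character(); excl_zero <- character(); excl_miss <- character()
  for (k in rxn_ids) {
    cols <- met_ids[mask[k, met_ids]]
    if (length(cols) == 0L) next
    if (!k %in% colnames(rate_mean)) { excl_miss <- c(excl_miss, k); next }
    vref <- rate_mean[ref, k]
    if (is.na(vref) || vref == 0) { excl_zero <- c(excl_zero, k); next }
    v <- rate_mean[pert, k]
    y <- v / vref - 1
    vary <- (rate_sd[pert, k] / vref)^2 + (v * rate_sd[ref, k] / vref^2)^2
    wts <- if (all(vary <= 0 | is.na(vary))) rep(1, length(y))
           else 1 / pmax(vary, 1e-12)
    X <- X_all[, cols, drop = FALSE]
    XtW <- t(X * wts)
    G <- XtW %*% X
    rk <- qr(G, tol = 1e-10)$rank
    if (rk < length(cols)) {
      underdet <- c(underdet, k)
      G <- G + diag(ridge, length(cols))
    }
    eps[k, cols] <- as.numeric(solve(G, XtW %*% y))
  }
  list(eps = eps, underdet = underdet, excluded_zero = excl_zero,
       excluded_missing = excl_miss)
}

#' @export
print.elasticity_matrix <- function(x, ...) {
  cat("<elasticity_matrix> ", nrow(x$eps), " reactions x ", ncol(x$eps),
      " metabolites, ", sum(x$eps != 0), " nonzero entries\n", sep = "")
  if (length(x$underdetermined) > 0L)
    cat("  under-determined rows: ", paste(x$underdetermined, collapse = ", "), "\n")
  invisible(x)
}

#' Flux and concentration control coefficients from elasticities
#'
#' Implements the lin-log linearization of the mass balances: with
#' `M = S_R diag(v_ref) eps` over the independent measured metabolites,
#' the scaled concentration control matrix is
#' `C_S = -M^{-1} S_R diag(v_ref)` and the flux control matrix
#' `C_J = I + eps C_S`.  Both summation theorems (`C_J` rows sum to 1,
#' `C_S` rows to 0) hold exactly whenever `S_R v_ref = 0`, and the
#' connectivity identity `C_J eps = 0` holds by construction.
#'
#' @param eps an [estimate_elasticities()] result, or a plain matrix whose
#'   columns are independent metabolite ids.
#' @param reduced a [reduce_stoichiometry()] result for the same model.
#' @param v_ref named reference flux vector (reaction order of the model).
#' @param rcond_min condition threshold below which `M` is declared singular.
#' @return object of class `control_coefficients` with `C_J` (fluxes x
#'   enzymes), `C_S` (metabolites x enzymes), `v_ref`, `condition_number`.
#' @export
control_coefficients <- function(eps, reduced, v_ref, rcond_min = 1e-12) {
  E <- if (inherits(eps, "elasticity_matrix")) eps$eps else as.matrix(eps)
  excluded <- if (inherits(eps, "elasticity_matrix")) eps$excluded else character()
  rxn_ids <- rownames(E)
  stopifnot(!is.null(rxn_ids), !is.null(colnames(E)))
  v <- v_ref[rxn_ids]
  if (anyNA(v)) stop("v_ref missing entries for: ",
                     paste(rxn_ids[is.na(v)], collapse = ", "))

  ind <- intersect(reduced$independent_ids, colnames(E))
  if (length(ind) == 0L) stop("no independent metabolites overlap the elasticities")
  S_R <- reduced$S_R[ind, rxn_ids, drop = FALSE]
  E_i <- E[, ind, drop = FALSE]
  SV <- S_R %*% diag(as.numeric(v), length(v))
  colnames(SV) <- rxn_ids
  M <- SV %*% E_i
  rc <- rcond(M)
  if (!is.finite(rc) || rc < rcond_min) {
    sv <- svd(M)
    nullv <- sv$v[, ncol(sv$v)]
    worst <- ind[order(-abs(nullv))][seq_len(min(3L, length(ind)))]
    stop("linearized system is singular (rcond = ", format(rc, digits = 3),
         "); structurally undetermined around: ", paste(worst, collapse = ", "))
  }
  C_S <- -solve(M, SV)
  rownames(C_S) <- ind
  C_J <- diag(nrow(E)) + E_i %*% C_S
  dimnames(C_J) <- list(rxn_ids, rxn_ids)
  # flux control is undefined where the reference flux vanishes
  keep <- !(rxn_ids %in% excluded) & v != 0
  structure(list(C_J = C_J[keep, , drop = FALSE], C_S = C_S,
                 v_ref = v, condition_number = 1 / rc,
                 eps = E_i),
            class = "control_coefficients")
}

#' @export
print.control_coefficients <- function(x, ...) {
  cat("<control_coefficients> C_J: ", nrow(x$C_J), " fluxes x ", ncol(x$C_J),
      " enzymes; C_S: ", nrow(x$C_S), " metabolites", sep = "")
  if (!is.null(x$mc_mean)) cat("; Monte Carlo summaries attached")
  cat("\n")
  invisible(x)
}

#' @rdname control_coefficients
#' @param x a `control_coefficients` object.
#' @param ... unused.
#' @export
#' @method tidy control_coefficients
tidy.control_coefficients <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame.table(x$C_J, stringsAsFactors = FALSE))
  names(out) <- c("flux_id", "enzyme", "fcc")
  if (!is.null(x$mc_mean)) {
    out$mc_mean <- as.numeric(x$mc_mean[cbind(out$flux_id, out$enzyme)])
    out$mc_lo <- as.numeric(x$mc_lo[cbind(out$flux_id, out$enzyme)])
    out$mc_hi <- as.numeric(x$mc_hi[cbind(out$flux_id, out$enzyme)])
  }
  out
}

#' @rdname control_coefficients
#' @export
#' @method glance control_coefficients
glance.control_coefficients <- function(x, ...) {
  tibble::tibble(
    n_fluxes = nrow(x$C_J), n_enzymes = ncol(x$C_J),
    max_cj_row_dev = max(abs(rowSums(x$C_J) - 1)),
    max_cs_row_dev = max(abs(rowSums(x$C_S))),
    condition_number = x$condition_number,
    mc_cycles = x$mc_cycles %||% NA_integer_,
    mc_dropped = x$mc_dropped %||% NA_integer_)
}

#' Heatmap of flux control coefficients
#'
#' @param object a [control_coefficients()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
#' @method autoplot control_coefficients
autoplot.control_coefficients <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$enzyme, y = .data$flux_id,
                                   fill = .data$fcc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", midpoint = 0) +
    ggplot2::labs(x = "enzyme activity", y = "metabolic flux",
                  fill = "FCC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Brute-force control coefficients by finite differences
#'
#' Perturbs each enzyme level of a kinetic ground truth by a relative
#' `delta`, re-solves the lin-log steady state, and differences the fluxes:
#' `FCC_kj = (J_k(e_j (1+delta)) - J_k(e_j)) / (J_k delta)`.  Serves as the
#' independent oracle for [control_coefficients()].
#'
#' @param gt a [make_ground_truth()] object.
#' @param delta relative enzyme perturbation (> 0).
#' @return matrix fluxes x enzymes (reactions with nonzero reference flux).
#' @export
finite_difference_fcc <- function(gt, delta = 1e-4) {
  if (delta <= 0) stop("delta must be positive")
  ids <- names(gt$v_ref)
  base <- simulate_steady_state(gt)
  nz <- ids[abs(gt$v_ref) > 1e-12]
  out <- matrix(NA_real_, length(nz), length(ids), dimnames = list(nz, ids))
  for (j in ids) {
    lv <- stats::setNames(rep(1, length(ids)), ids)
    lv[j] <- 1 + delta
    pert <- simulate_steady_state(gt, enzyme_levels = lv)
    out[, j] <- (pert$fluxes[nz] - base$fluxes[nz]) / (base$fluxes[nz] * delta)
  }
  out
}

#' Monte Carlo uncertainty propagation for control coefficients
#'
#' Each cycle resamples the dataset within its measurement uncertainties
#' (concentrations lognormal matching mean/sd, fluxes normal, truncated to
#' the TFA flux ranges when provided), re-runs the elasticity regression
#' and the control-coefficient computation, and accumulates elementwise
#' summaries (mean and 2.5/97.5 percentiles).  Cycles with a singular
#' linearized system are dropped and counted; more than half dropped
#' aborts.
#'
#' @inheritParams estimate_elasticities
#' @param reduced a [reduce_stoichiometry()] of the model.
#' @param n_cycles number of Monte Carlo cycles (the study default is
#'   10000; scale down for quick runs).
#' @param seed integer seed (fixed seed gives identical summaries).
#' @param flux_ranges optional [loopless_fva()]/[variability_at_optimum()]
#'   result used to truncate flux draws.
#' @return a [control_coefficients()] object for the point estimate with
#'   `mc_mean`, `mc_lo`, `mc_hi`, `mc_cycles`, `mc_dropped` attached.
#' @export
monte_carlo_mca <- function(dataset, model, reduced, n_cycles = 10000L,
                            seed = 1L, mask = NULL, flux_ranges = NULL) {
  mask <- mask %||% elasticity_mask(model)
  point <- mca_point(dataset, model, reduced, mask)
  mat <- dataset_matrices(dataset)
  met_ids <- intersect(colnames(mask), colnames(mat$met_mean)[mat$met_complete])
  ind <- intersect(reduced$independent_ids, met_ids)
  S_R <- reduced$S_R[ind, colnames(mat$rate_mean)[
    colnames(mat$rate_mean) %in% rownames(mask)], drop = FALSE]
  rxn_ids <- colnames(S_R)

  # flux draws are projected back onto the steady-state balance space:
  # flux estimates entering the analysis are balanced by construction
  # (they come from constraint-based estimation), and the summation
  # theorems require S_R v_ref = 0 exactly
  P <- balance_projector(reduced$S_R[, rxn_ids, drop = FALSE])

  # lognormal parameters matching the metabolome means/sds elementwise
  cv2 <- (mat$met_sd / mat$met_mean)^2
  sig <- sqrt(log1p(cv2))
  mu <- log(mat$met_mean) - sig^2 / 2
  rng_lo <- rng_hi <- NULL
  if (!is.null(flux_ranges) && !is.null(flux_ranges$flux)) {
    rng_lo <- flux_ranges$flux$min[match(colnames(mat$rate_mean),
                                         flux_ranges$flux$reaction_id)]
    rng_hi <- flux_ranges$flux$max[match(colnames(mat$rate_mean),
                                         flux_ranges$flux$reaction_id)]
  }

  draws <- vector("list", n_cycles)
  dropped <- 0L
  withr::with_seed(seed, {
    for (cy in seq_len(n_cycles)) {
      met_d <- matrix(stats::rlnorm(length(mu), mu, sig), nrow(mu),
                      dimnames = dimnames(mu))
      rate_d <- matrix(stats::rnorm(length(mat$rate_mean), mat$rate_mean,
                                    mat$rate_sd),
                       nrow(mat$rate_mean), dimnames = dimnames(mat$rate_mean))
      if (!is.null(rng_lo)) {
        ok <- !is.na(rng_lo)
        rate_d[, ok] <- pmin(pmax(rate_d[, ok],
                                  rep(rng_lo[ok], each = nrow(rate_d))),
                             rep(rng_hi[ok], each = nrow(rate_d)))
      }
      rate_d[, rxn_ids] <- rate_d[, rxn_ids, drop = FALSE] %*% P
      cj <- tryCatch({
        fit <- eps_core(met_d, rate_d, mat$rate_sd, mat$ref_row, met_ids,
                        mask, rxn_ids)
        v_ref <- rate_d[mat$ref_row, rxn_ids]
        cj_core(fit$eps[, ind, drop = FALSE], S_R, v_ref,
                exclude = c(fit$excluded_zero, fit$excluded_missing))
      }, error = function(e) NULL)
      if (is.null(cj)) { dropped <- dropped + 1L; next }
      draws[[cy]] <- cj
    }
  })
  draws <- draws[!vapply(draws, is.null, TRUE)]
  if (dropped > n_cycles / 2)
    stop("more than half of the Monte Carlo cycles were singular (",
         dropped, "/", n_cycles, ")")
  if (length(draws) == 0L) stop("no successful Monte Carlo cycles")
  # align on the intersection of flux rows present in every cycle
  common <- Reduce(intersect, lapply(draws, rownames))
  arr <- simplify2array(lapply(draws, function(m) m[common, , drop = FALSE]))
  point$mc_mean <- apply(arr, c(1, 2), mean)
  point$mc_lo <- apply(arr, c(1, 2), stats::quantile, probs = 0.025, names = FALSE)
  point$mc_hi <- apply(arr, c(1, 2), stats::quantile, probs = 0.975, names = FALSE)
  point$mc_cycles <- length(draws)
  point$mc_dropped <- dropped
  point
}

# compact C_J computation used inside the Monte Carlo loop
cj_core <- function(E_i, S_R, v_ref, exclude = character(), rcond_min = 1e-12) {
  SV <- S_R %*% diag(as.numeric(v_ref), length(v_ref))
  M <- SV %*% E_i
  rc <- rcond(M)
  if (!is.finite(rc) || rc < rcond_min) stop("singular cycle")
  C_S <- -solve(M, SV)
  C_J <- diag(nrow(E_i)) + E_i %*% C_S
  dimnames(C_J) <- list(rownames(E_i), rownames(E_i))
  keep <- !(rownames(E_i) %in% exclude) & v_ref != 0
  C_J[keep, , drop = FALSE]
}

# orthogonal projector onto the null space of S_R (columns = reactions)
balance_projector <- function(S_R) {
  n <- ncol(S_R)
  sv <- svd(S_R, nu = 0, nv = n)
  r <- sum(sv$d >= 1e-9 * max(sv$d, 1))
  if (r >= n) return(diag(0, n))
  N <- sv$v[, (r + 1L):n, drop = FALSE]
  N %*% t(N)
}

# one elasticity-regression + control-coefficient pass; the reference flux
# vector is projected onto the balance space before inversion
mca_point <- function(dataset, model, reduced, mask) {
  eps <- suppressWarnings(estimate_elasticities(dataset, model, mask))
  ref_rates <- dataset$rates[dataset$rates$state_id == dataset$reference_id, ]
  v_ref <- stats::setNames(ref_rates$mean, ref_rates$reaction_id)
  ids <- intersect(colnames(reduced$S_R), names(v_ref))
  P <- balance_projector(reduced$S_R[, ids, drop = FALSE])
  v_ref[ids] <- as.numeric(v_ref[ids] %*% P)
  control_coefficients(eps, reduced, v_ref)
}

#' Export a flux-control-coefficient table
#'
#' Writes the mean FCC matrix as CSV (flux rows, enzyme columns, leading
#' `flux_id` column); when Monte Carlo summaries are present, companion
#' files `<stem>_lo.csv` / `<stem>_hi.csv` hold the 2.5 % and 97.5 %
#' percentile sheets.  Positive values mean an enzyme-activity increase
#' enhances the flux; negative values mean it reduces it.
#'
#' @param cc a [control_coefficients()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_fcc_table <- function(cc, path) {
  write_mat <- function(m, p) {
    df <- tibble::as_tibble(m, rownames = "flux_id")
    readr::write_csv(df, p)
  }
  write_mat(if (!is.null(cc$mc_mean)) cc$mc_mean else cc$C_J, path)
  if (!is.null(cc$mc_lo)) {
    stem <- sub("\\.csv$", "", path)
    write_mat(cc$mc_lo, paste0(stem, "_lo.csv"))
    write_mat(cc$mc_hi, paste0(stem, "_hi.csv"))
  }
  invisible(path)
}
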