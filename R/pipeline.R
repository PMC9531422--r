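# End-to-end orchestration: simulate (or ingest) -> rates -> TFA -> MCA ->
# exported tables, with seed and settings recorded for reproducibility.

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end run.  All study-level settings
#' (variance criterion 0.999, 10000 Monte Carlo cycles, pH 7.0, ionic
#' strength 0.15 M) are defaults here, never hard-coded downstream.
#'
#' @param model_path directory of a tabular model, or `NULL` for the
#'   packaged reduced model.
#' @param data_dir directory with `states.csv`, `rates.csv`,
#'   `metabolome.csv` of a measured dataset, or `NULL` to simulate.
#' @param seed integer seed controlling generator and Monte Carlo.
#' @param noise_cv generator noise (rates, metabolome) CVs.
#' @param fraction optimality fraction of the variability analysis.
#' @param big_M big-M constant of the direction coupling.
#' @param sd_mult rate-box half-width in standard deviations.
#' @param n_cycles Monte Carlo cycles.
#' @param ridge ridge penalty for under-determined elasticity rows.
#' @param settings a [thermo_settings()].
#' @param outdir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(model_path = NULL, data_dir = NULL, seed = 1L,
                       noise_cv = c(rates = 0.05, metabolome = 0.05),
                       fraction = 0.999, big_M = 1000, sd_mult = 2,
                       n_cycles = 10000L, ridge = 1e-6,
                       settings = thermo_settings(),
                       outdir = tempfile("fluxcontrol_run_")) {
  structure(as.list(environment()), class = "run_config")
}

validate_config <- function(config) {
  if (!is.null(config$model_path) && !dir.exists(config$model_path))
    stop("model_path does not exist: ", config$model_path)
  if (!is.null(config$data_dir) && !dir.exists(config$data_dir))
    stop("data_dir does not exist: ", config$data_dir)
  stopifnot(config$fraction >= 0, config$fraction <= 1,
            config$n_cycles >= 1, config$seed == as.integer(config$seed))
  invisible(config)
}

# reference-state rate constraints derived from a dataset's reference state
dataset_reference_rates <- function(dataset, model) {
  ref <- dataset$rates[dataset$rates$state_id == dataset$reference_id, ]
  keep <- model$reactions$id[model$reactions$is_exchange |
                               model$reactions$id %in% (model$objective_id %||% "")]
  ref <- ref[ref$reaction_id %in% keep, ]
  rate_constraints(ref$reaction_id, ref$mean, pmax(ref$sd, 1e-3),
                   kind = "uptake")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the 12+1 state perturbation dataset, constrains
#' the reference flux space by loopless FVA and thermodynamics-based flux
#' analysis, computes variability ranges at the optimality fraction,
#' estimates elasticities and control coefficients, propagates
#' uncertainty by Monte Carlo, and writes all result tables, a
#' heatmap-ready FCC matrix and a log into the configured directory.
#' Identical config and seed give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return the output directory, invisibly; the run artifacts as a list.
#' @export
run_pipeline <- function(config = run_config()) {
  validate_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$outdir, "log.txt")
  logline <- function(...) cat(..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("fluxcontrol ", as.character(utils::packageVersion("fluxcontrol")))
  logline("seed: ", config$seed)
  logline("fraction: ", config$fraction, "; big_M: ", config$big_M,
          "; sd_mult: ", config$sd_mult, "; n_cycles: ", config$n_cycles,
          "; ridge: ", config$ridge)
  logline("thermo: T=", config$settings$temperature, " K, pH=",
          config$settings$ph, ", I=", config$settings$ionic_strength, " M")

  model <- if (is.null(config$model_path)) ecoli_trp_model()
           else load_model(config$model_path, "tabular")
  logline("model: ", nrow(model$reactions), " reactions, ",
          nrow(model$metabolites), " metabolites")

  gt <- NULL
  if (is.null(config$data_dir)) {
    gt <- make_ground_truth(model, seed = config$seed)
    dataset <- generate_perturbation_dataset(gt, noise_cv = config$noise_cv,
                                             seed = config$seed)
    logline("dataset: simulated, noise CV rates=", config$noise_cv[["rates"]],
            " metabolome=", config$noise_cv[["metabolome"]])
  } else {
    dataset <- perturbation_dataset(
      readr::read_csv(file.path(config$data_dir, "states.csv"),
                      show_col_types = FALSE),
      readr::read_csv(file.path(config$data_dir, "rates.csv"),
                      show_col_types = FALSE),
      readr::read_csv(file.path(config$data_dir, "metabolome.csv"),
                      show_col_types = FALSE),
      reference_id = "ref")
    logline("dataset: loaded from ", config$data_dir)
  }

  rates <- dataset_reference_rates(dataset, model)
  met_ref <- dataset$metabolome[
    dataset$metabolome$state_id == dataset$reference_id, ]

  fva <- loopless_fva(model, rates, sd_mult = config$sd_mult,
                      big_M = config$big_M)
  nulls <- fva$flux$reaction_id[fva$flux$null]
  logline("loopless FVA nulls: ", paste(nulls, collapse = ", "))

  prob <- tfa_problem(model, rates, metabolome = met_ref, null_ids = nulls,
                      settings = config$settings, big_M = config$big_M,
                      sd_mult = config$sd_mult)
  sol <- solve_tfa(prob)
  if (sol$status != "optimal")
    stop("TFA stage failed: ", sol$hint %||% "infeasible")
  ranges <- variability_at_optimum(prob, config$fraction)

  readr::write_csv(tidy(sol), file.path(config$outdir, "fluxes.csv"))
  readr::write_csv(ranges$flux, file.path(config$outdir, "flux_ranges.csv"))
  readr::write_csv(ranges$conc, file.path(config$outdir, "conc_ranges.csv"))
  readr::write_csv(ranges$dg, file.path(config$outdir, "dg_ranges.csv"))

  reduced <- reduce_stoichiometry(model)
  mc <- monte_carlo_mca(dataset, model, reduced, n_cycles = config$n_cycles,
                        seed = config$seed, flux_ranges = ranges)
  logline("Monte Carlo: ", mc$mc_cycles, " cycles kept, ", mc$mc_dropped,
          " dropped")
  export_fcc_table(mc, file.path(config$outdir, "fcc_mean.csv"))
  readr::write_csv(tidy(mc), file.path(config$outdir, "fcc_tidy.csv"))
  readr::write_csv(glance(mc), file.path(config$outdir, "fcc_summary.csv"))
  logline("done")
  invisible(list(outdir = config$outdir, model = model, dataset = dataset,
                 ground_truth = gt, solution = sol, ranges = ranges,
                 control = mc))
}

#' Summarise a completed pipeline run
#'
#' Lists, for every metabolic flux, the enzymes with the largest absolute
#' mean flux control coefficients together with their Monte Carlo
#' intervals; ties are broken alphabetically by enzyme id.  Writes
#' `report.csv` next to the other artifacts and returns the table.
#'
#' @param outdir a [run_pipeline()] output directory.
#' @param top_n enzymes reported per flux.
#' @return tibble with `flux_id`, `rank`, `enzyme`, `fcc`, `lo`, `hi`.
#' @export
report_run <- function(outdir, top_n = 3L) {
  need <- file.path(outdir, c("fcc_mean.csv", "fcc_mean_lo.csv",
                              "fcc_mean_hi.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L)
    stop("incomplete run; missing artifact(s): ",
         paste(basename(missing), collapse = ", "))
  mread <- function(p) {
    df <- readr::read_csv(p, show_col_types = FALSE)
    m <- as.matrix(df[-1]); rownames(m) <- df$flux_id; m
  }
  mean_ <- mread(need[1]); lo <- mread(need[2]); hi <- mread(need[3])
  out <- purrr::map_dfr(rownames(mean_), function(fx) {
    v <- mean_[fx, ]
    ord <- order(-abs(v), names(v))[seq_len(min(top_n, length(v)))]
    tibble::tibble(flux_id = fx, rank = seq_along(ord),
                   enzyme = names(v)[ord], fcc = unname(v[ord]),
                   lo = unname(lo[fx, ord]), hi = unname(hi[fx, ord]))
  })
  readr::write_csv(out, file.path(outdir, "report.csv"))
  out
}
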