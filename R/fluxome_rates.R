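# Biomass-specific rate calculation from bioreactor time series: substrate
# uptake, product/by-product formation, off-gas respiration rates, total
# amounts, fold changes and the dilution share of a concentration decline.

#' Bioreactor process time series
#'
#' Wraps a wide table of process measurements together with the metadata
#' needed to turn them into biomass-specific rates.
#'
#' @param data tibble with columns `time` (h), `volume` (L), `cdw` (g/L),
#'   optional `feed_rate` and `base_rate` (L/h), and one `conc_<species>`
#'   column per tracked species.
#' @param species_units named character, species -> `"g_per_L"` or
#'   `"mmol_per_L"`.
#' @param feed_conc named numeric, species -> feed concentration (g/L);
#'   species absent from the feed may be omitted.
#' @param molar_mass named numeric, species -> g/mol (needed to convert
#'   mass concentrations to mmol).
#' @param offgas optional tibble with `time` (h), `o2_in`, `o2_out`,
#'   `co2_in`, `co2_out` (volume %), `gas_flow` (L/h).
#' @param molar_gas_volume molar volume of the off-gas (L/mol).
#' @return object of class `process_timeseries`.
#' @export
process_timeseries <- function(data, species_units, feed_conc = numeric(),
                               molar_mass = numeric(), offgas = NULL,
                               molar_gas_volume = 24.05) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("time", "volume", "cdw") %in% names(data)))
  if (is.unsorted(data$time, strictly = TRUE))
    stop("time must be strictly increasing")
  if (any(data$volume <= 0)) stop("volume must be positive")
  if (!"feed_rate" %in% names(data)) data$feed_rate <- 0
  if (!"base_rate" %in% names(data)) data$base_rate <- 0
  if (!is.null(offgas)) {
    offgas <- tibble::as_tibble(offgas)
    stopifnot(all(c("time", "o2_in", "o2_out", "co2_in", "co2_out",
                    "gas_flow") %in% names(offgas)))
    fr <- unlist(offgas[c("o2_in", "o2_out", "co2_in", "co2_out")])
    if (any(fr < 0 | fr > 100)) stop("off-gas fractions must be within [0, 100] %")
  }
  structure(list(data = data, species_units = species_units,
                 feed_conc = feed_conc, molar_mass = molar_mass,
                 offgas = offgas, molar_gas_volume = molar_gas_volume),
            class = "process_timeseries")
}

#' @export
print.process_timeseries <- function(x, ...) {
  sp <- sub("^conc_", "", grep("^conc_", names(x$data), value = TRUE))
  cat("<process_timeseries> ", nrow(x$data), " samples, ",
      format(min(x$data$time), digits = 4), "-",
      format(max(x$data$time), digits = 4), " h, species: ",
      paste(sp, collapse = ", "), "\n", sep = "")
  invisible(x)
}

ts_window <- function(series, interval) {
  d <- series$data
  w <- d[d$time >= interval[1] - 1e-9 & d$time <= interval[2] + 1e-9, ]
  if (nrow(w) < 2L)
    stop("need at least two samples inside the interval [",
         interval[1], ", ", interval[2], "]")
  w
}

conc_col <- function(series, species) {
  col <- paste0("conc_", species)
  if (!col %in% names(series$data)) stop("no concentration data for ", species)
  col
}

# concentration in mmol/L regardless of recorded unit
conc_mmol <- function(series, species, conc) {
  unit <- series$species_units[[species]] %||% "g_per_L"
  if (unit == "mmol_per_L") return(conc)
  mm <- series$molar_mass[[species]]
  if (is.null(mm) || is.na(mm))
    stop("molar mass required to convert ", species, " from g/L")
  conc / mm * 1000
}

#' Biomass-specific conversion rate of one species
#'
#' Finite-difference rate over a feeding-stage window:
#' `q = (d(V*c)/dt - F_feed*c_feed) / (V_mean * X_mean)`, reported positive
#' with the direction carried by `kind` (uptake rates are the negative of
#' the accumulation balance).
#'
#' @param series a [process_timeseries()].
#' @param species species name (must have a `conc_` column).
#' @param interval `c(t_start, t_end)` in h.
#' @param kind `"secretion"` (default) or `"uptake"`.
#' @return rate in mmol/gCDW/h.
#' @export
specific_rate <- function(series, species, interval,
                          kind = c("secretion", "uptake")) {
  kind <- match.arg(kind)
  w <- ts_window(series, interval)
  if (all(w$cdw <= 0)) stop("zero biomass over the interval")
  col <- conc_col(series, species)
  cm <- conc_mmol(series, species, w[[col]])       # mmol/L
  amount <- w$volume * cm                          # mmol
  dt <- w$time[nrow(w)] - w$time[1]
  if (dt <= 0) stop("degenerate interval")
  dAdt <- (amount[nrow(w)] - amount[1]) / dt       # mmol/h
  fcol <- paste0("feed_conc_", species)
  if (fcol %in% names(w)) {                        # time-resolved feed conc
    feed_term <- mean(w$feed_rate * conc_mmol(series, species, w[[fcol]]))
  } else {
    fc <- if (species %in% names(series$feed_conc))
      series$feed_conc[[species]] else 0
    if (is.na(fc)) fc <- 0
    feed_term <- mean(w$feed_rate) * conc_mmol(series, species, fc)
  }
  vbar <- mean(w$volume); xbar <- mean(w$cdw)
  q <- (dAdt - feed_term) / (vbar * xbar)
  if (kind == "uptake") -q else q
}

#' Respiration rates from off-gas analysis
#'
#' Gas balance over the interval:
#' `OUR = F_gas * (y_O2_in - y_O2_out)/100 / V_m / (V*X)` (mol -> mmol),
#' and CPR analogously with outlet minus inlet CO2.
#'
#' @inheritParams specific_rate
#' @return named numeric `c(OUR = , CPR = )` in mmol/gCDW/h.
#' @export
respiration_rates <- function(series, interval) {
  if (is.null(series$offgas)) stop("no off-gas data recorded")
  og <- series$offgas
  og <- og[og$time >= interval[1] - 1e-9 & og$time <= interval[2] + 1e-9, ]
  if (nrow(og) == 0L) stop("no off-gas samples inside the interval")
  w <- ts_window(series, interval)
  vbar <- mean(w$volume); xbar <- mean(w$cdw)
  if (xbar <= 0) stop("zero biomass over the interval")
  vm <- series$molar_gas_volume
  our <- mean(og$gas_flow * (og$o2_in - og$o2_out) / 100) / vm / (vbar * xbar) * 1000
  cpr <- mean(og$gas_flow * (og$co2_out - og$co2_in) / 100) / vm / (vbar * xbar) * 1000
  c(OUR = our, CPR = cpr)
}

#' Total amount of a species in the reactor
#'
#' `V(t) * c(t)` in grams, plus the cumulative mass withdrawn in samples if
#' a sampling log is supplied.
#'
#' @inheritParams specific_rate
#' @param t time (h) within the series span.
#' @param sampling_log optional tibble with `time` (h) and `mass_g` removed.
#' @return grams.
#' @export
total_amount <- function(series, species, t, sampling_log = NULL) {
  d <- series$data
  if (t < min(d$time) - 1e-9 || t > max(d$time) + 1e-9)
    stop("t outside the series span")
  col <- conc_col(series, species)
  conc <- stats::approx(d$time, d[[col]], xout = t)$y
  vol <- stats::approx(d$time, d$volume, xout = t)$y
  unit <- series$species_units[[species]] %||% "g_per_L"
  conc_g <- if (unit == "mmol_per_L") {
    mm <- series$molar_mass[[species]]
    if (is.null(mm) || is.na(mm)) stop("molar mass required for ", species)
    conc * mm / 1000
  } else conc
  out <- vol * conc_g
  if (!is.null(sampling_log))
    out <- out + sum(sampling_log$mass_g[sampling_log$time <= t + 1e-9])
  out
}

#' Fold change between two rates
#'
#' @param rate_a reference rate (nonzero).
#' @param rate_b comparison rate.
#' @return `rate_b / rate_a`.
#' @export
fold_change <- function(rate_a, rate_b) {
  if (any(rate_a == 0)) stop("fold change undefined for a zero reference rate")
  rate_b / rate_a
}

#' Share of a concentration decline explained by dilution
#'
#' For a species whose concentration declines over the interval, computes
#' the decline that volume increase alone would cause at zero net
#' production (mass conservation: `c_pred(t1) = c(t0) * V(t0) / V(t1)`) and
#' divides it by the observed decline.  A value of 1 means the decline is
#' pure dilution; values below 1 leave room for degradation or consumption.
#'
#' @inheritParams specific_rate
#' @return unitless fraction in `[0, Inf)`.
#' @export
dilution_explained_fraction <- function(series, species, interval) {
  w <- ts_window(series, interval)
  col <- conc_col(series, species)
  c0 <- w[[col]][1]; c1 <- w[[col]][nrow(w)]
  if (c1 >= c0) stop("concentration is not decreasing over the interval")
  v0 <- w$volume[1]; v1 <- w$volume[nrow(w)]
  predicted <- c0 * (1 - v0 / v1)
  observed <- c0 - c1
  predicted / observed
}
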