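#' Kinetic parameters for an aerobic batch fermentation
#'
#' Constructs the parameter set of the respiratory-bottleneck overflow
#' model used by [simulate_batch()]. Glucose uptake follows Monod
#' kinetics; uptake above the respiratory capacity `resp_cap` overflows
#' into ethanol fermentation. Crabtree-positive parameterisations grow on
#' the accumulated ethanol after glucose is exhausted (the
#' make-accumulate-consume strategy).
#'
#' @param qs_max Maximum specific glucose uptake rate, g glucose/gDW/h.
#' @param Ks Glucose half-saturation constant, g/L.
#' @param resp_cap Maximum respiratory glucose flux, g glucose/gDW/h;
#'   uptake above this overflows into fermentation.
#' @param Yxs_ox Biomass yield on respired glucose, gDW/g.
#' @param Yxs_ferm Biomass yield on fermented (overflowed) glucose, gDW/g.
#' @param Yes_ferm Ethanol yield on overflowed glucose, g/g; at most
#'   0.511, the theoretical maximum.
#' @param qe_max Maximum specific ethanol uptake rate after the diauxic
#'   shift, g ethanol/gDW/h.
#' @param Ke Ethanol half-saturation constant, g/L.
#' @param Yxe Biomass yield on ethanol, gDW/g.
#' @param ethanol_growth Logical; whether accumulated ethanol is consumed
#'   after glucose depletion.
#' @param lag_diauxic_h Lag between glucose depletion and the onset of
#'   ethanol consumption, h (derepression of respiratory metabolism);
#'   the culture idles during the lag.
#' @param Ygs_ferm,Yas_ferm Optional small by-product yields (glycerol,
#'   acetate) on overflowed glucose, g/g; default 0.
#' @param S0 Initial glucose, g/L (2% glucose = 20 g/L).
#' @param X0 Initial biomass, gDW/L; default `S0 * Yxs_ox / 500`,
#'   i.e. the roughly 500-fold diluted inoculum of the batch protocol.
#' @param duration_h Simulated duration, h.
#' @param sample_interval_h Sampling interval of the output series, h.
#' @param od_per_dw OD600 units per gDW/L (biomass-to-OD conversion).
#' @return An object of class `batch_sim_params` (named list).
#' @seealso [crabtree_preset()], [simulate_batch()]
#' @export
batch_sim_params <- function(qs_max, Ks = 0.1, resp_cap = qs_max,
                             Yxs_ox = 0.5, Yxs_ferm = 0.08,
                             Yes_ferm = 0, qe_max = 0, Ke = 0.1,
                             Yxe = 0.6, ethanol_growth = FALSE,
                             lag_diauxic_h = 1.5,
                             Ygs_ferm = 0, Yas_ferm = 0,
                             S0 = 20, X0 = S0 * Yxs_ox / 500,
                             duration_h = 48, sample_interval_h = 0.5,
                             od_per_dw = 2) {
  p <- list(qs_max = qs_max, Ks = Ks, resp_cap = resp_cap,
            Yxs_ox = Yxs_ox, Yxs_ferm = Yxs_ferm, Yes_ferm = Yes_ferm,
            qe_max = qe_max, Ke = Ke, Yxe = Yxe,
            ethanol_growth = isTRUE(ethanol_growth),
            lag_diauxic_h = lag_diauxic_h,
            Ygs_ferm = Ygs_ferm, Yas_ferm = Yas_ferm,
            S0 = S0, X0 = X0, duration_h = duration_h,
            sample_interval_h = sample_interval_h, od_per_dw = od_per_dw)
  num <- p[setdiff(names(p), "ethanol_growth")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(vapply(num, function(x) any(!is.finite(x)) || any(x < 0),
                 logical(1)))) {
    stop("all kinetic parameters must be finite and non-negative")
  }
  if (Yes_ferm > ETHANOL_YIELD_MAX + 1e-12) {
    stop("Yes_ferm exceeds the theoretical maximum ethanol yield 0.511 g/g")
  }
  # each fermented and respired gram of glucose must carry non-negative
  # residual carbon (the CO2 term)
  resid_ferm <- 1 / cmol_mass[["glucose"]] -
    Yxs_ferm / cmol_mass[["biomass"]] -
    Yes_ferm / cmol_mass[["ethanol"]] -
    Ygs_ferm / cmol_mass[["glycerol"]] -
    Yas_ferm / cmol_mass[["acetate"]]
  resid_ox <- 1 / cmol_mass[["glucose"]] - Yxs_ox / cmol_mass[["biomass"]]
  resid_e <- 1 / cmol_mass[["ethanol"]] - Yxe / cmol_mass[["biomass"]]
  if (resid_ferm < -1e-12 || resid_ox < -1e-12 ||
      (ethanol_growth && resid_e < -1e-12)) {
    stop("yields imply more product carbon than substrate carbon")
  }
  structure(p, class = "batch_sim_params")
}

#' @export
print.batch_sim_params <- function(x, ...) {
  cat("<batch_sim_params>\n")
  flat <- unlist(x)
  cat(paste0("  ", format(names(flat), width = 18), " ",
             format(flat)), sep = "\n")
  invisible(x)
}

#' Preset fermentation parameters for the three Crabtree phenotypes
#'
#' Parameter sets whose simulated batch cultures, run through the metric
#' extractor, fall into the three phenotype categories seen across
#' *Saccharomycetaceae*: `strong_positive` (S. cerevisiae-like: ethanol
#' yield above 0.33 g/g, biomass yield below 0.18 g/g,
#' make-accumulate-consume), `intermediate` (Lachancea-like: biomass
#' yield 0.20-0.33 g/g with moderate ethanol), and `negative`
#' (K. lactis-like: purely respiratory, no ethanol, biomass yield above
#' 0.33 g/g). All presets start from 2% glucose (20 g/L) and a ~500-fold
#' diluted inoculum.
#'
#' @param phenotype One of `"strong_positive"`, `"intermediate"`,
#'   `"negative"`.
#' @param ... Overrides passed on to [batch_sim_params()].
#' @return A `batch_sim_params` object.
#' @export
#' @examples
#' p <- crabtree_preset("strong_positive")
#' ts <- simulate_batch(p, seed = 1)
crabtree_preset <- function(phenotype = c("strong_positive", "intermediate",
                                          "negative"), ...) {
  phenotype <- match.arg(phenotype)
  args <- switch(phenotype,
    strong_positive = list(qs_max = 2.0, resp_cap = 0.35, Yxs_ox = 0.49,
                           Yxs_ferm = 0.08, Yes_ferm = 0.47,
                           qe_max = 0.15, Yxe = 0.6, ethanol_growth = TRUE),
    intermediate = list(qs_max = 1.1, resp_cap = 0.55, Yxs_ox = 0.50,
                        Yxs_ferm = 0.08, Yes_ferm = 0.48,
                        qe_max = 0.12, Yxe = 0.6, ethanol_growth = TRUE),
    negative = list(qs_max = 0.55, resp_cap = 0.55, Yxs_ox = 0.55,
                    Yxs_ferm = 0, Yes_ferm = 0, qe_max = 0,
                    ethanol_growth = FALSE)
  )
  over <- list(...)
  args[names(over)] <- over
  p <- do.call(batch_sim_params, args)
  attr(p, "phenotype") <- phenotype
  p
}

#' Analytic glucose-phase specific growth rate of a parameter set
#'
#' The specific growth rate of the model at glucose saturation
#' (`S >> Ks`): `Yxs_ox * min(qs_max, resp_cap) + Yxs_ferm *
#' max(qs_max - resp_cap, 0)`, in 1/h. Used as the ground truth for
#' growth-rate recovery checks.
#'
#' @param params A `batch_sim_params` object.
#' @return Specific growth rate, 1/h.
#' @export
analytic_mu <- function(params) {
  qox <- min(params$qs_max, params$resp_cap)
  qferm <- max(params$qs_max - params$resp_cap, 0)
  params$Yxs_ox * qox + params$Yxs_ferm * qferm
}

#' Analytic ethanol-phase specific growth rate
#'
#' `Yxe * qe_max` at ethanol saturation, 1/h; 0 for parameter sets
#' without growth on ethanol.
#'
#' @param params A `batch_sim_params` object.
#' @return Specific growth rate on ethanol, 1/h.
#' @export
analytic_mu_ethanol <- function(params) {
  if (!params$ethanol_growth) return(0)
  params$Yxe * params$qe_max
}

#' Closed-form glucose-phase yields of a parameter set
#'
#' Exact ethanol and biomass yields over the glucose phase, from the
#' analytic integrals of `dE/dS` and `dX/dS` along the Monod curve
#' (the overflow fraction shrinks as glucose runs out, so the yields are
#' not simply the saturation stoichiometry). Independent of the
#' numerical integrator; serves as ground truth for extractor-recovery
#' checks.
#'
#' @param params A `batch_sim_params` object.
#' @param s_switch Glucose level (g/L) at which the simulation switches
#'   phase / stops consuming; must match [simulate_batch()].
#' @return Named vector: `ethanol` and `biomass` yields, g per g glucose
#'   consumed.
#' @export
analytic_yields <- function(params, s_switch = 0.05) {
  qm <- params$qs_max; rc <- params$resp_cap; Ks <- params$Ks
  S0 <- params$S0
  s_end <- if (params$ethanol_growth) s_switch else 0
  dS <- S0 - s_end
  if (rc >= qm) {
    return(c(ethanol = 0, biomass = params$Yxs_ox))
  }
  # glucose level below which uptake fits within respiratory capacity
  s_star <- rc * Ks / (qm - rc)
  sa <- max(s_star, s_end)
  over <- S0 - sa # glucose consumed while overflowing
  lg <- log(S0 / sa)
  dE <- params$Yes_ferm * ((1 - rc / qm) * over - (rc * Ks / qm) * lg)
  dX <- params$Yxs_ferm * over +
    (params$Yxs_ox - params$Yxs_ferm) * (rc / qm) * (over + Ks * lg) +
    params$Yxs_ox * (sa - s_end)
  c(ethanol = dE / dS, biomass = dX / dS)
}

# right-hand sides ----------------------------------------------------------

# state vector: X (gDW/L), S (g/L), E (g/L), G glycerol, A acetate,
# CO2 cumulative (mol/L), O2 cumulative consumed (mol/L)
rhs_glucose <- function(state, p) {
  X <- state[1]; S <- max(state[2], 0)
  qS <- p$qs_max * S / (p$Ks + S)
  qSox <- min(qS, p$resp_cap)
  qSf <- qS - qSox
  mu <- p$Yxs_ox * qSox + p$Yxs_ferm * qSf
  qE <- p$Yes_ferm * qSf
  qG <- p$Ygs_ferm * qSf
  qA <- p$Yas_ferm * qSf
  # CO2 closes the carbon balance exactly: all substrate carbon not fixed
  # in biomass or excreted products leaves as CO2
  qCO2 <- qS / cmol_mass[["glucose"]] - mu / cmol_mass[["biomass"]] -
    qE / cmol_mass[["ethanol"]] - qG / cmol_mass[["glycerol"]] -
    qA / cmol_mass[["acetate"]]
  # respiration runs at RQ 1 on glucose; fermentative CO2 costs no O2
  qO2 <- qSox / cmol_mass[["glucose"]] -
    p$Yxs_ox * qSox / cmol_mass[["biomass"]]
  c(mu * X, -qS * X, qE * X, qG * X, qA * X, qCO2 * X, qO2 * X)
}

rhs_ethanol <- function(state, p) {
  X <- state[1]; E <- max(state[3], 0)
  qE <- p$qe_max * E / (p$Ke + E)
  mu <- p$Yxe * qE
  qCO2 <- qE / cmol_mass[["ethanol"]] - mu / cmol_mass[["biomass"]]
  # O2 demand from the electron balance on ethanol oxidation
  qO2 <- (GAMMA_ETHANOL * qE / cmol_mass[["ethanol"]] -
            GAMMA_BIOMASS * mu / cmol_mass[["biomass"]]) / 4
  c(mu * X, 0, -qE * X, 0, 0, qCO2 * X, qO2 * X)
}

#' Simulate an aerobic batch cultivation
#'
#' Integrates the overflow-metabolism model with a fixed-step 4th-order
#' Runge-Kutta scheme (step 0.01 h). During the glucose phase, Monod
#' uptake is split into a respiratory flux (capped at `resp_cap`, burned
#' at RQ 1) and an overflow flux fermented to ethanol plus CO2; CO2 is
#' the carbon not fixed in biomass or excreted products, so the model is
#' carbon-closed by construction. When glucose falls below 0.05 g/L the
#' culture switches (if `ethanol_growth`) to respiratory growth on the
#' accumulated ethanol, with O2 demand from the electron balance. The
#' trajectory is sampled every `sample_interval_h`.
#'
#' The simulation itself is deterministic; `seed` is recorded in the
#' metadata and seeds downstream [add_measurement_noise()] calls made via
#' the convenience `cv` argument.
#'
#' @param params A `batch_sim_params` object.
#' @param seed Integer seed recorded with the series.
#' @param cv Optional measurement-noise coefficient of variation; if
#'   positive the result is passed through [add_measurement_noise()].
#' @return A `culture_ts` tibble: columns `time_h`, `dw_gL`, `od600`,
#'   `glucose_gL`, `ethanol_gL`, `glycerol_gL`, `acetate_gL`,
#'   `pyruvate_gL`, `succinate_gL`, `lactate_gL`, `co2_cum_mol_per_L`,
#'   `o2_cum_mol_per_L`, with `params`, `seed` and `strain` attributes.
#' @export
simulate_batch <- function(params, seed = 1L, cv = 0) {
  stopifnot(inherits(params, "batch_sim_params"))
  dt <- 0.01
  n_per_sample <- max(1L, as.integer(round(params$sample_interval_h / dt)))
  n_samples <- floor(params$duration_h / params$sample_interval_h)
  state <- c(params$X0, params$S0, 0, 0, 0, 0, 0)
  out <- matrix(NA_real_, nrow = n_samples + 1, ncol = 8)
  out[1, ] <- c(0, state)
  s_switch <- 0.05
  t <- 0
  t_switch <- NA_real_ # time glucose first fell below the switch level
  for (i in seq_len(n_samples)) {
    for (k in seq_len(n_per_sample)) {
      depleted <- state[2] <= s_switch
      if (depleted && is.na(t_switch)) t_switch <- t
      if (depleted && params$ethanol_growth &&
          t < t_switch + params$lag_diauxic_h) {
        # diauxic lag: respiratory machinery derepressing, culture idles
        t <- t + dt
        next
      }
      glucose_phase <- !depleted || !params$ethanol_growth
      f <- if (glucose_phase) rhs_glucose else rhs_ethanol
      k1 <- f(state, params)
      k2 <- f(state + dt / 2 * k1, params)
      k3 <- f(state + dt / 2 * k2, params)
      k4 <- f(state + dt * k3, params)
      state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      # clamp depleted pools at zero (depletion event handling)
      state[2] <- max(state[2], 0)
      state[3] <- max(state[3], 0)
      t <- t + dt
      if (any(!is.finite(state))) {
        stop(sprintf("non-finite state at t = %.2f h (integration step %d)",
                     t, k))
      }
    }
    out[i + 1, ] <- c(i * params$sample_interval_h, state)
  }
  ts <- tibble::tibble(
    time_h = out[, 1],
    dw_gL = out[, 2],
    od600 = out[, 2] * params$od_per_dw,
    glucose_gL = out[, 3],
    ethanol_gL = out[, 4],
    glycerol_gL = out[, 5],
    acetate_gL = out[, 6],
    pyruvate_gL = 0,
    succinate_gL = 0,
    lactate_gL = 0,
    co2_cum_mol_per_L = out[, 7],
    o2_cum_mol_per_L = out[, 8]
  )
  ts <- new_culture_ts(ts,
                       strain = attr(params, "phenotype") %||% "custom",
                       seed = seed, params = params)
  if (cv > 0) ts <- add_measurement_noise(ts, cv = cv, seed = seed)
  ts
}

new_culture_ts <- function(ts, strain = "unknown", seed = NA_integer_,
                           params = NULL) {
  structure(ts, class = c("culture_ts", class(tibble::tibble())),
            strain = strain, seed = seed, params = params)
}

#' Add multiplicative measurement noise to a culture time series
#'
#' Each concentration and dry-weight sample is multiplied by an
#' independent lognormal factor with unit mean and coefficient of
#' variation `cv` (so the noise is unbiased), then clipped at zero.
#' Cumulative off-gas signals stay smooth and non-decreasing: noise is
#' applied to their increments, which are then re-accumulated.
#' Deterministic for a given `seed`.
#'
#' @param ts A `culture_ts` tibble.
#' @param cv Coefficient of variation of the multiplicative noise
#'   (fraction, e.g. 0.02).
#' @param seed Integer RNG seed.
#' @return A `culture_ts` tibble of the same shape.
#' @export
add_measurement_noise <- function(ts, cv, seed = 1L) {
  stopifnot(cv >= 0)
  if (cv == 0) return(ts)
  out <- tibble::as_tibble(ts)
  sdlog <- sqrt(log(1 + cv^2))
  noisy_cols <- c("dw_gL", "od600", "glucose_gL", PRODUCT_COLUMNS)
  gas_cols <- c("co2_cum_mol_per_L", "o2_cum_mol_per_L")
  # a private RNG stream: do not disturb the caller's RNG state
  old_seed <- if (exists(".Random.seed", envir = globalenv(),
                         inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  n <- nrow(out)
  rng <- lapply(seq_along(c(noisy_cols, gas_cols)), function(i) {
    exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  })
  if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
  for (i in seq_along(noisy_cols)) {
    out[[noisy_cols[i]]] <- pmax(out[[noisy_cols[i]]] * rng[[i]], 0)
  }
  for (j in seq_along(gas_cols)) {
    cl <- gas_cols[j]
    inc <- diff(c(0, out[[cl]]))
    inc <- pmax(inc * rng[[length(noisy_cols) + j]], 0)
    out[[cl]] <- cumsum(inc)
  }
  new_culture_ts(out, strain = attr(ts, "strain"),
                 seed = seed, params = attr(ts, "params"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read the culture time-series CSV dialect
#'
#' The on-disk format is a plain CSV with the canonical column header and
#' optional `#`-prefixed metadata comment lines before it. [write_culture_csv()]
#' records the strain label and seed as comments; [read_culture_csv()]
#' validates the schema and names any missing columns.
#'
#' @param ts A `culture_ts` tibble.
#' @param path File path.
#' @return `write_culture_csv()` returns `path` invisibly;
#'   `read_culture_csv()` returns a `culture_ts` tibble.
#' @export
write_culture_csv <- function(ts, path) {
  header <- c(
    sprintf("# strain: %s", attr(ts, "strain") %||% "unknown"),
    sprintf("# seed: %s", attr(ts, "seed") %||% NA),
    sprintf("# generator: crabtree %s",
            as.character(utils::packageVersion("crabtree")))
  )
  writeLines(header, path)
  suppressWarnings(utils::write.table(
    tibble::as_tibble(ts)[, CULTURE_COLUMNS],
    path, sep = ",", row.names = FALSE, quote = FALSE, append = TRUE
  ))
  invisible(path)
}

#' @rdname write_culture_csv
#' @export
read_culture_csv <- function(path) {
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  missing_cols <- setdiff(CULTURE_COLUMNS, names(d))
  if (length(missing_cols) > 0) {
    stop("culture CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_culture_ts(d)
  meta <- readLines(path, n = 10)
  strain <- sub("^# strain: ", "", grep("^# strain: ", meta, value = TRUE))
  seed <- suppressWarnings(as.integer(
    sub("^# seed: ", "", grep("^# seed: ", meta, value = TRUE))
  ))
  new_culture_ts(d[, CULTURE_COLUMNS],
                 strain = if (length(strain)) strain else "unknown",
                 seed = if (length(seed)) seed else NA_integer_)
}

#' Coerce a data frame to a culture time series
#'
#' Validates the required columns (`time_h`, `dw_gL`, `glucose_gL`),
#' fills absent product columns with zeros, and derives `od600` from dry
#' weight when missing. Off-gas columns are left absent unless supplied;
#' metrics that need them ([respiration_ratio()], [carbon_balance()])
#' will say so.
#'
#' @param df A data frame with at least `time_h`, `dw_gL`, `glucose_gL`.
#' @param strain Strain label stored with the series.
#' @param od_per_dw OD600 per gDW/L used when deriving `od600`.
#' @return A `culture_ts` tibble.
#' @export
as_culture_ts <- function(df, strain = "unknown", od_per_dw = 2) {
  required <- c("time_h", "dw_gL", "glucose_gL")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("culture series is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- tibble::as_tibble(df)
  if (!"od600" %in% names(out)) out$od600 <- out$dw_gL * od_per_dw
  for (cl in PRODUCT_COLUMNS) {
    if (!cl %in% names(out)) out[[cl]] <- 0
  }
  validate_culture_ts(out)
  new_culture_ts(out[, intersect(CULTURE_COLUMNS, names(out))],
                 strain = strain)
}

validate_culture_ts <- function(ts) {
  if (nrow(ts) < 2) stop("culture time series needs at least 2 samples")
  if (any(diff(ts$time_h) <= 0)) {
    stop("time_h must be strictly increasing")
  }
  invisible(ts)
}
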