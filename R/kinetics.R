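#' Detect the exponential growth window on glucose
#'
#' Finds the stretch of a batch culture over which the maximum specific
#' growth rate is fitted: the longest contiguous run of at least
#' `min_points` samples taken while glucose is still ample
#' (> `glc_min` g/L) and before any ethanol decline, whose log-linear
#' biomass fit reaches `r2_min`. Ties on length are broken toward the
#' window with the higher fitted slope.
#'
#' @param ts A `culture_ts` tibble (or data frame with the canonical
#'   columns).
#' @param basis `"dw"` (dry weight, the default basis) or `"od600"`.
#' @param min_points Minimum number of samples in the window.
#' @param r2_min Minimum r-squared of the log-linear fit.
#' @param glc_min Glucose concentration (g/L) below which samples no
#'   longer count as "glucose ample".
#' @return An `exp_window` object: list with `t_start_h`, `t_end_h`,
#'   `mu_per_h`, `fit_r2`, `n_points`, `basis`.
#' @export
detect_exponential_window <- function(ts, basis = c("dw", "od600"),
                                      min_points = 4, r2_min = 0.995,
                                      glc_min = 1) {
  basis <- match.arg(basis)
  sig <- if (basis == "dw") ts$dw_gL else ts$od600
  t <- ts$time_h
  # restrict to glucose-ample samples before any ethanol decline
  eth <- if ("ethanol_gL" %in% names(ts)) ts$ethanol_gL else rep(0, nrow(ts))
  t_eth_max <- if (any(eth > 0) && max(eth) > eth[length(eth)]) {
    t[which.max(eth)]
  } else {
    Inf
  }
  eligible <- which(ts$glucose_gL > glc_min & sig > 0 & t <= t_eth_max)
  if (length(eligible) < min_points) {
    stop("too few glucose-ample samples with positive biomass for an ",
         "exponential window; supply a manual window")
  }
  # eligible indices are contiguous runs; scan all contiguous subwindows
  runs <- split(eligible, cumsum(c(1, diff(eligible) != 1)))
  best <- NULL
  for (run in runs) {
    n <- length(run)
    if (n < min_points) next
    for (len in seq(n, min_points)) {
      for (s in seq_len(n - len + 1)) {
        idx <- run[s:(s + len - 1)]
        fit <- loglinear_fit(t[idx], sig[idx])
        if (is.na(fit$r2) || fit$r2 < r2_min) next
        if (is.null(best) || len > best$n_points ||
            (len == best$n_points && fit$slope > best$mu_per_h)) {
          best <- list(t_start_h = t[idx[1]], t_end_h = t[idx[len]],
                       mu_per_h = fit$slope, fit_r2 = fit$r2,
                       n_points = len, basis = basis)
        }
      }
      if (!is.null(best) && best$n_points == len) break
    }
    # longer windows in later runs could still win; keep scanning runs
  }
  if (is.null(best)) {
    stop("no contiguous window of >= ", min_points, " samples reaches r2 >= ",
         r2_min, "; supply a manual window")
  }
  structure(best, class = "exp_window")
}

loglinear_fit <- function(t, y) {
  ly <- log(y)
  n <- length(t)
  mt <- mean(t); my <- mean(ly)
  sxx <- sum((t - mt)^2)
  sxy <- sum((t - mt) * (ly - my))
  syy <- sum((ly - my)^2)
  slope <- sxy / sxx
  r2 <- if (syy <= 0) NA_real_ else (sxy^2) / (sxx * syy)
  list(slope = slope, r2 = r2)
}

#' @export
print.exp_window <- function(x, ...) {
  cat(sprintf(
    "<exp_window> %.2f-%.2f h, mu = %.4f /h (r2 = %.4f, %d points, %s)\n",
    x$t_start_h, x$t_end_h, x$mu_per_h, x$fit_r2, x$n_points, x$basis))
  invisible(x)
}

#' Fit the maximum specific growth rate over an explicit window
#'
#' Ordinary least-squares slope of `ln(biomass)` versus time over the
#' samples falling in `[t_start, t_end]` (inclusive). Dry weight is the
#' default basis; OD600 gives the identical slope up to the constant
#' biomass-to-OD factor.
#'
#' @param ts A `culture_ts` tibble.
#' @param window Numeric length-2 vector `c(t_start_h, t_end_h)` or an
#'   `exp_window` object.
#' @param basis `"dw"` or `"od600"`.
#' @return Specific growth rate, 1/h.
#' @export
fit_growth_rate <- function(ts, window, basis = c("dw", "od600")) {
  basis <- match.arg(basis)
  if (inherits(window, "exp_window")) {
    window <- c(window$t_start_h, window$t_end_h)
  }
  stopifnot(length(window) == 2, window[1] < window[2])
  sig <- if (basis == "dw") ts$dw_gL else ts$od600
  idx <- which(ts$time_h >= window[1] & ts$time_h <= window[2])
  if (length(idx) < 3) stop("fewer than 3 samples inside the window")
  if (any(sig[idx] <= 0)) {
    stop("non-positive biomass values inside the window")
  }
  loglinear_fit(ts$time_h[idx], sig[idx])$slope
}

#' Determine the yield-calculation endpoint of a batch culture
#'
#' Crabtree-positive cultures (maximum ethanol at or above
#' `ethanol_detect_gL`) end at the ethanol maximum (earliest sample on
#' ties); Crabtree-negative cultures end when glucose is depleted
#' (first crossing of `glc_depleted` g/L, linearly interpolated between
#' the bracketing samples). If the ethanol maximum is reached while
#' glucose is still above `glc_min_mixed` g/L, a mixed-metabolism
#' warning is raised (fermentative and respiratory metabolism
#' overlapped).
#'
#' @param ts A `culture_ts` tibble.
#' @param ethanol_detect_gL Ethanol detection threshold, g/L.
#' @param glc_depleted Glucose depletion threshold, g/L.
#' @param glc_min_mixed Residual glucose (g/L) above which an
#'   ethanol-maximum endpoint triggers the mixed-metabolism warning.
#' @return An `endpoint` object: list with `t_end_h`, `rule`
#'   (`"ETHANOL_MAX"` or `"GLUCOSE_DEPLETED"`), `crabtree_positive`,
#'   `mixed_metabolism`.
#' @export
determine_endpoint <- function(ts, ethanol_detect_gL = 0.5,
                               glc_depleted = 0.1, glc_min_mixed = 0.5) {
  if (!"glucose_gL" %in% names(ts)) stop("series lacks a glucose column")
  eth <- if ("ethanol_gL" %in% names(ts)) ts$ethanol_gL else rep(0, nrow(ts))
  if (max(eth) >= ethanol_detect_gL) {
    i <- which.max(eth) # which.max returns the earliest maximum
    mixed <- ts$glucose_gL[i] > glc_min_mixed
    if (mixed) {
      warning("ethanol maximum reached while glucose was still present ",
              sprintf("(%.2f g/L): mixed respiro-fermentative metabolism",
                      ts$glucose_gL[i]))
    }
    return(structure(list(t_end_h = ts$time_h[i], rule = "ETHANOL_MAX",
                          crabtree_positive = TRUE,
                          mixed_metabolism = mixed),
                     class = "endpoint"))
  }
  below <- which(ts$glucose_gL <= glc_depleted)
  if (length(below) == 0) {
    stop("culture not finished: glucose never depleted and no ethanol ",
         "detected")
  }
  i <- below[1]
  if (i == 1) {
    t_end <- ts$time_h[1]
  } else {
    # linear interpolation of the crossing between bracketing samples
    g0 <- ts$glucose_gL[i - 1]; g1 <- ts$glucose_gL[i]
    t0 <- ts$time_h[i - 1]; t1 <- ts$time_h[i]
    t_end <- t0 + (g0 - glc_depleted) / (g0 - g1) * (t1 - t0)
  }
  structure(list(t_end_h = t_end, rule = "GLUCOSE_DEPLETED",
                 crabtree_positive = FALSE, mixed_metabolism = FALSE),
            class = "endpoint")
}

#' @export
print.endpoint <- function(x, ...) {
  cat(sprintf("<endpoint> t = %.2f h, %s%s\n", x$t_end_h, x$rule,
              if (x$mixed_metabolism) " (mixed metabolism)" else ""))
  invisible(x)
}

# linear interpolation of the culture columns present, at time t
interpolate_at <- function(ts, t) {
  cols <- intersect(CULTURE_COLUMNS[-1], names(ts))
  vapply(cols, function(cl) {
    stats::approx(ts$time_h, ts[[cl]], xout = t, rule = 2)$y
  }, numeric(1))
}

at_val <- function(at, cl, default = 0) {
  if (cl %in% names(at)) at[[cl]] else default
}

#' Compute product and biomass yields over the culture interval
#'
#' For each product `p`, `Y_p/S = (c_p(t_end) - c_p(t_0)) / (S(t_0) -
#' S(t_end))` in g/g; the biomass yield uses dry weight. Concentrations
#' at the endpoint are linearly interpolated between samples. Negative
#' numerators (possible under measurement noise) are clipped to 0.
#'
#' @param ts A `culture_ts` tibble.
#' @param endpoint An `endpoint` object or a numeric endpoint time (h).
#' @return Named numeric vector of yields (g/g): `ethanol`, `glycerol`,
#'   `acetate`, `pyruvate`, `succinate`, `lactate`, `biomass`.
#' @export
compute_yields <- function(ts, endpoint) {
  t_end <- if (inherits(endpoint, "endpoint")) endpoint$t_end_h else endpoint
  stopifnot(t_end >= ts$time_h[1], t_end <= ts$time_h[nrow(ts)])
  at0 <- interpolate_at(ts, ts$time_h[1])
  at1 <- interpolate_at(ts, t_end)
  dS <- at0[["glucose_gL"]] - at1[["glucose_gL"]]
  if (dS <= 0) stop("zero glucose consumed over the interval")
  y <- vapply(PRODUCT_COLUMNS, function(cl) {
    max(at_val(at1, cl) - at_val(at0, cl), 0) / dS
  }, numeric(1))
  names(y) <- names(PRODUCT_COLUMNS)
  c(y, biomass = max(at1[["dw_gL"]] - at0[["dw_gL"]], 0) / dS)
}

#' Compute specific consumption and production rates
#'
#' Exponential-phase specific rates in g/gDW/h: `q_S = (dS / dX) * mu`
#' for glucose and `q_p = (dc_p / dX) * mu` for each product, where the
#' deltas are taken between the first and last samples of the
#' exponential window. Equivalently, the exponential-phase yield ratio
#' multiplied by the specific growth rate.
#'
#' @param ts A `culture_ts` tibble.
#' @param window An `exp_window` or numeric `c(t_start, t_end)`.
#' @param mu Specific growth rate over the window, 1/h.
#' @return Named numeric vector: `glucose` (consumption) and one
#'   production rate per product.
#' @export
compute_specific_rates <- function(ts, window, mu) {
  if (inherits(window, "exp_window")) {
    window <- c(window$t_start_h, window$t_end_h)
  }
  idx <- which(ts$time_h >= window[1] & ts$time_h <= window[2])
  if (length(idx) < 2) stop("window contains fewer than 2 samples")
  i0 <- idx[1]; i1 <- idx[length(idx)]
  dX <- ts$dw_gL[i1] - ts$dw_gL[i0]
  if (dX <= 0) stop("no biomass produced over the window")
  qs <- (ts$glucose_gL[i0] - ts$glucose_gL[i1]) / dX * mu
  qp <- vapply(PRODUCT_COLUMNS, function(cl) {
    if (!cl %in% names(ts)) return(0)
    max(ts[[cl]][i1] - ts[[cl]][i0], 0) / dX * mu
  }, numeric(1))
  names(qp) <- names(PRODUCT_COLUMNS)
  c(glucose = qs, qp)
}

#' Respiration ratio (mol CO2 evolved per mol O2 consumed)
#'
#' Ratio of the cumulative CO2 increment to the cumulative O2 increment
#' from the first sample to the end of growth on glucose (the endpoint
#' for glucose-depleted cultures, otherwise the first time glucose falls
#' to the depletion threshold). Near 1 for purely respiratory growth;
#' well above 1 when fermentation co-occurs. If essentially no O2 was
#' consumed the ratio is `Inf` (fermentation-only).
#'
#' @param ts A `culture_ts` tibble.
#' @param endpoint An `endpoint` object (optional; recomputed if absent).
#' @param glc_depleted Glucose depletion threshold, g/L.
#' @return Ratio (mol/mol), possibly `Inf`.
#' @export
respiration_ratio <- function(ts, endpoint = NULL, glc_depleted = 0.1) {
  if (!all(c("co2_cum_mol_per_L", "o2_cum_mol_per_L") %in% names(ts))) {
    stop("series lacks cumulative off-gas columns ",
         "(co2_cum_mol_per_L, o2_cum_mol_per_L)")
  }
  if (is.null(endpoint)) endpoint <- determine_endpoint(ts)
  t_glc_end <- if (endpoint$rule == "GLUCOSE_DEPLETED") {
    endpoint$t_end_h
  } else {
    below <- which(ts$glucose_gL <= glc_depleted)
    if (length(below) == 0) {
      ts$time_h[nrow(ts)]
    } else if (below[1] == 1) {
      ts$time_h[1]
    } else {
      i <- below[1]
      g0 <- ts$glucose_gL[i - 1]; g1 <- ts$glucose_gL[i]
      ts$time_h[i - 1] +
        (g0 - glc_depleted) / (g0 - g1) * (ts$time_h[i] - ts$time_h[i - 1])
    }
  }
  at0 <- interpolate_at(ts, ts$time_h[1])
  at1 <- interpolate_at(ts, t_glc_end)
  dco2 <- at1[["co2_cum_mol_per_L"]] - at0[["co2_cum_mol_per_L"]]
  do2 <- at1[["o2_cum_mol_per_L"]] - at0[["o2_cum_mol_per_L"]]
  if (do2 < 1e-6) return(Inf)
  dco2 / do2
}

#' C-mole carbon balance of a batch culture
#'
#' Ratio of carbon recovered in products (excreted metabolites, biomass
#' and CO2) to carbon in the consumed glucose, both in C-moles, over the
#' interval from inoculation to the endpoint. A value near 1 indicates a
#' carbon-closed experiment.
#'
#' @param ts A `culture_ts` tibble.
#' @param endpoint An `endpoint` object or numeric endpoint time (h).
#' @return Carbon balance (C-mol out / C-mol in).
#' @export
carbon_balance <- function(ts, endpoint) {
  if (!"co2_cum_mol_per_L" %in% names(ts)) {
    stop("series lacks the cumulative CO2 column")
  }
  t_end <- if (inherits(endpoint, "endpoint")) endpoint$t_end_h else endpoint
  at0 <- interpolate_at(ts, ts$time_h[1])
  at1 <- interpolate_at(ts, t_end)
  dS <- at0[["glucose_gL"]] - at1[["glucose_gL"]]
  if (dS <= 0) stop("zero glucose consumed over the interval")
  prod_c <- sum(vapply(names(PRODUCT_COLUMNS), function(p) {
    (at_val(at1, PRODUCT_COLUMNS[[p]]) - at_val(at0, PRODUCT_COLUMNS[[p]])) /
      cmol_mass[[p]]
  }, numeric(1)))
  bio_c <- (at1[["dw_gL"]] - at0[["dw_gL"]]) / cmol_mass[["biomass"]]
  co2 <- at1[["co2_cum_mol_per_L"]] - at0[["co2_cum_mol_per_L"]]
  (prod_c + bio_c + co2) / (dS / cmol_mass[["glucose"]])
}

#' Extract all physiological metrics from a culture time series
#'
#' Runs the full extraction pipeline: exponential-window detection (or a
#' manual window), log-linear growth-rate fit, endpoint determination,
#' endpoint yields, exponential-phase specific rates, respiration ratio
#' and C-mole carbon balance, with QC flags for carbon balances outside
#' `[0.9, 1.1]` and mixed respiro-fermentative metabolism.
#'
#' @param ts A `culture_ts` tibble.
#' @param basis Growth-rate basis, `"dw"` (default) or `"od600"`.
#' @param window Optional manual window `c(t_start_h, t_end_h)`;
#'   auto-detected when `NULL`.
#' @param min_points,r2_min,glc_min Window auto-detection settings, see
#'   [detect_exponential_window()].
#' @param ethanol_detect_gL,glc_depleted Endpoint thresholds, see
#'   [determine_endpoint()].
#' @return A `phenotype_metrics` object; use [generics::tidy()] for a
#'   one-row tibble or [generics::glance()] for the QC summary.
#' @export
#' @examples
#' ts <- simulate_batch(crabtree_preset("negative"))
#' m <- extract_metrics(ts)
#' generics::tidy(m)
extract_metrics <- function(ts, basis = c("dw", "od600"), window = NULL,
                            min_points = 4, r2_min = 0.995, glc_min = 1,
                            ethanol_detect_gL = 0.5, glc_depleted = 0.1) {
  basis <- match.arg(basis)
  validate_culture_ts(ts)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  win <- if (is.null(window)) {
    stage("window", detect_exponential_window(
      ts, basis = basis, min_points = min_points, r2_min = r2_min,
      glc_min = glc_min))
  } else {
    mu0 <- stage("growth_rate", fit_growth_rate(ts, window, basis = basis))
    idx <- which(ts$time_h >= window[1] & ts$time_h <= window[2])
    structure(list(t_start_h = window[1], t_end_h = window[2],
                   mu_per_h = mu0, fit_r2 = NA_real_,
                   n_points = length(idx), basis = basis),
              class = "exp_window")
  }
  mu <- win$mu_per_h
  ep <- stage("endpoint", determine_endpoint(
    ts, ethanol_detect_gL = ethanol_detect_gL, glc_depleted = glc_depleted))
  yields <- stage("yields", compute_yields(ts, ep))
  rates <- stage("rates", compute_specific_rates(ts, win, mu))
  rq <- stage("respiration_ratio",
              respiration_ratio(ts, ep, glc_depleted = glc_depleted))
  cb <- stage("carbon_balance", carbon_balance(ts, ep))
  qc <- character(0)
  if (is.finite(cb) && (cb < 0.9 || cb > 1.1)) {
    qc <- c(qc, sprintf("carbon balance %.3f outside [0.9, 1.1]", cb))
  }
  if (ep$mixed_metabolism) qc <- c(qc, "mixed respiro-fermentative metabolism")
  structure(list(
    strain = attr(ts, "strain") %||% "unknown",
    yields = yields, rates = rates, mu_per_h = mu,
    respiration_ratio = rq, carbon_balance = cb,
    endpoint = ep, window = win, qc_flags = qc
  ), class = "phenotype_metrics")
}

#' @export
print.phenotype_metrics <- function(x, ...) {
  cat(sprintf("<phenotype_metrics> %s\n", x$strain))
  cat(sprintf("  mu = %.3f /h; Y_E/S = %.3f, Y_X/S = %.3f g/g\n",
              x$mu_per_h, x$yields[["ethanol"]], x$yields[["biomass"]]))
  cat(sprintf("  q_S = %.3f, q_E = %.3f g/gDW/h; RQ = %.2f; C-balance = %.3f\n",
              x$rates[["glucose"]], x$rates[["ethanol"]],
              x$respiration_ratio, x$carbon_balance))
  cat(sprintf("  endpoint %.2f h (%s)%s\n", x$endpoint$t_end_h,
              x$endpoint$rule,
              if (length(x$qc_flags)) paste0("; QC: ",
                paste(x$qc_flags, collapse = "; ")) else ""))
  invisible(x)
}

#' Tidy a phenotype_metrics object into a one-row tibble
#'
#' @param x A `phenotype_metrics` object.
#' @param ... Unused.
#' @return One-row tibble mirroring the reference-table columns
#'   (yields, specific rates, growth rate) plus respiration ratio,
#'   carbon balance, endpoint and QC flags.
#' @export
tidy.phenotype_metrics <- function(x, ...) {
  tibble::tibble(
    strain = x$strain,
    ethanol_yield = x$yields[["ethanol"]],
    biomass_yield = x$yields[["biomass"]],
    glc_cons_rate = x$rates[["glucose"]],
    etoh_prod_rate = x$rates[["ethanol"]],
    growth_rate = x$mu_per_h,
    glycerol_yield = x$yields[["glycerol"]],
    acetate_yield = x$yields[["acetate"]],
    respiration_ratio = x$respiration_ratio,
    carbon_balance = x$carbon_balance,
    endpoint_h = x$endpoint$t_end_h,
    endpoint_rule = x$endpoint$rule,
    crabtree_positive = x$endpoint$crabtree_positive,
    qc_flags = paste(x$qc_flags, collapse = "; ")
  )
}

#' Glance at the fit quality of a phenotype_metrics object
#'
#' @param x A `phenotype_metrics` object.
#' @param ... Unused.
#' @return One-row tibble with window span, fit r-squared, carbon
#'   balance and QC flag count.
#' @export
glance.phenotype_metrics <- function(x, ...) {
  tibble::tibble(
    window_start_h = x$window$t_start_h,
    window_end_h = x$window$t_end_h,
    window_points = x$window$n_points,
    fit_r2 = x$window$fit_r2,
    basis = x$window$basis,
    carbon_balance = x$carbon_balance,
    n_qc_flags = length(x$qc_flags)
  )
}
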