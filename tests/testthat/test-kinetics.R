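test_that("doubling biomass gives mu = ln 2 with a perfect fit", {
  ts <- toy_series(0:3, c(0.1, 0.2, 0.4, 0.8), rep(18, 4))
  w <- detect_exponential_window(ts)
  expect_equal(w$mu_per_h, log(2), tolerance = 1e-12)
  expect_equal(w$fit_r2, 1, tolerance = 1e-12)
  expect_equal(w$n_points, 4L)
})

test_that("growth-rate fit recovers an exact exponential on either basis", {
  t <- 0:10
  ts <- toy_series(t, 0.05 * exp(0.3 * t), rep(18, 11))
  expect_equal(fit_growth_rate(ts, c(0, 10)), 0.3, tolerance = 1e-12)
  # OD600 is a constant multiple of dry weight: identical slope
  expect_equal(fit_growth_rate(ts, c(0, 10), basis = "od600"), 0.3,
               tolerance = 1e-12)
  expect_error(fit_growth_rate(ts, c(0, 1)), "fewer than 3")
  ts$dw_gL[5] <- 0
  expect_error(fit_growth_rate(ts, c(0, 10)), "non-positive biomass")
})

test_that("flat biomass yields no exponential window", {
  ts <- toy_series(0:9, rep(0.5, 10), rep(18, 10))
  expect_error(detect_exponential_window(ts), "window")
})

test_that("endpoint rule separates fermentative and respiratory cultures", {
  # ethanol peaks then declines: endpoint at the maximum
  eth <- c(0, 1, 3, 5.5, 7.8, 6.2, 4.0)
  ts <- toy_series(seq(0, 18, by = 3), 0.1 * exp(0.2 * seq(0, 18, by = 3)),
                   c(20, 15, 8, 2, 0.3, 0.05, 0.02), ethanol_gL = eth)
  ep <- determine_endpoint(ts)
  expect_equal(ep$t_end_h, 12)
  expect_equal(ep$rule, "ETHANOL_MAX")
  expect_true(ep$crabtree_positive)

  # no ethanol: glucose depletion, linearly interpolated crossing
  ts2 <- toy_series(0:21, 0.1 * exp(0.15 * (0:21)),
                    c(seq(20, 0.4, length.out = 21), 0))
  ep2 <- determine_endpoint(ts2)
  expect_equal(ep2$rule, "GLUCOSE_DEPLETED")
  expect_equal(ep2$t_end_h, 20 + 0.3 / 0.4)
  expect_false(ep2$crabtree_positive)

  # ethanol maximum while glucose remains: mixed-metabolism warning
  ts3 <- toy_series(0:6, 0.1 * exp(0.2 * (0:6)),
                    c(20, 16, 12, 8, 5, 3, 2),
                    ethanol_gL = c(0, 1, 3, 5.5, 7.8, 7.0, 6.0))
  expect_warning(ep3 <- determine_endpoint(ts3), "mixed")
  expect_equal(ep3$rule, "ETHANOL_MAX")
  expect_true(ep3$mixed_metabolism)

  # neither condition: culture not finished
  ts4 <- toy_series(0:4, 0.1 * exp(0.2 * (0:4)), c(20, 18, 16, 14, 12))
  expect_error(determine_endpoint(ts4), "not finished")
})

test_that("yields are delta-product over delta-substrate at the endpoint", {
  t <- 0:4
  ts <- toy_series(t, c(0.05, 0.2, 0.8, 2.0, 3.25),
                   c(20, 17, 11, 4, 0),
                   ethanol_gL = c(0, 1.2, 3.6, 6.5, 7.8))
  y <- compute_yields(ts, endpoint = 4)
  expect_equal(unname(y[["ethanol"]]), 7.8 / 20)
  expect_equal(unname(y[["biomass"]]), 3.2 / 20)
  expect_equal(unname(y[["glycerol"]]), 0)

  # respiratory culture: all glucose to biomass
  ts2 <- toy_series(0:2, c(0, 5, 11.4), c(20, 11, 0))
  y2 <- compute_yields(ts2, endpoint = 2)
  expect_equal(unname(y2[["biomass"]]), 0.57)
  expect_equal(unname(y2[["ethanol"]]), 0)

  expect_error(compute_yields(ts, endpoint = 0), "zero glucose")
})

test_that("specific rates are yield ratios scaled by growth rate", {
  ts <- toy_series(0:2, c(0.4, 1.0, 2.0), c(20, 16, 10),
                   ethanol_gL = c(0, 1.6, 4.0))
  q <- compute_specific_rates(ts, c(0, 2), mu = 0.28)
  expect_equal(unname(q[["glucose"]]), 10 / 1.6 * 0.28) # 1.75
  expect_equal(unname(q[["ethanol"]]), 4.0 / 1.6 * 0.28)
  expect_equal(unname(q[["acetate"]]), 0)
  ts$dw_gL <- rev(ts$dw_gL)
  expect_error(compute_specific_rates(ts, c(0, 2), mu = 0.28),
               "no biomass")
})

test_that("respiration ratio handles respiratory, fermentative and gas-free cases", {
  # simulated purely respiratory culture: RQ fixed at 1
  ts <- simulate_batch(crabtree_preset("negative"))
  expect_equal(respiration_ratio(ts), 1, tolerance = 0.02)
  # strongly fermentative culture: CO2 well in excess of O2
  ts2 <- simulate_batch(crabtree_preset("strong_positive"))
  expect_gt(respiration_ratio(ts2), 1.5)
  # no oxygen consumed at all: infinite-ratio flag
  ts3 <- toy_series(0:2, c(0.1, 0.1, 0.1), c(20, 10, 0.05),
                    ethanol_gL = c(0, 5, 10),
                    co2 = c(0, 0.1, 0.2), o2 = c(0, 0, 0))
  expect_equal(suppressWarnings(respiration_ratio(ts3)), Inf)
  ts4 <- toy_series(0:2, c(0.1, 0.2, 0.4), c(20, 10, 0.05))
  expect_error(respiration_ratio(ts4), "off-gas")
})

test_that("carbon balance closes on exact fermentation stoichiometry", {
  # C6H12O6 -> 2 EtOH + 2 CO2: 20 g/L glucose = 0.111 mol -> 0.222 mol CO2
  ts <- toy_series(0:2, c(0.1, 0.1, 0.1), c(20, 10, 0),
                   ethanol_gL = c(0, 5.11, 10.22),
                   co2 = c(0, 0.111, 0.222), o2 = c(0, 0, 0))
  expect_equal(carbon_balance(ts, endpoint = 2), 1, tolerance = 1e-3)
  # dropping the biomass term loses carbon
  ts2 <- toy_series(0:2, c(0.1, 2, 5), c(20, 10, 0),
                    ethanol_gL = c(0, 2, 4),
                    co2 = c(0, 0.05, 0.1), o2 = c(0, 0.05, 0.1))
  full <- carbon_balance(ts2, endpoint = 2)
  ts3 <- ts2
  ts3$dw_gL <- c(0.1, 0.1, 0.1)
  expect_lt(carbon_balance(ts3, endpoint = 2), full)
})

test_that("metrics are invariant to concentration scaling and time shifts", {
  base <- simulate_batch(crabtree_preset("intermediate"))
  m0 <- extract_metrics(base)
  scaled <- base
  for (cl in c("dw_gL", "od600", "glucose_gL", "ethanol_gL",
               "co2_cum_mol_per_L", "o2_cum_mol_per_L")) {
    scaled[[cl]] <- scaled[[cl]] * 3
  }
  # thresholds are absolute concentrations, so they scale with the data
  m1 <- extract_metrics(scaled, glc_min = 3, ethanol_detect_gL = 1.5,
                        glc_depleted = 0.3)
  expect_equal(m1$yields, m0$yields, tolerance = 1e-9)
  expect_equal(m1$mu_per_h, m0$mu_per_h, tolerance = 1e-9)
  expect_equal(m1$respiration_ratio, m0$respiration_ratio,
               tolerance = 1e-9)
  expect_equal(m1$carbon_balance, m0$carbon_balance, tolerance = 1e-9)
  expect_equal(m1$rates, m0$rates, tolerance = 1e-9)

  shifted <- base
  shifted$time_h <- shifted$time_h + 5
  m2 <- extract_metrics(shifted)
  expect_equal(m2$yields, m0$yields, tolerance = 1e-9)
  expect_equal(m2$mu_per_h, m0$mu_per_h, tolerance = 1e-9)
  expect_equal(m2$endpoint$t_end_h, m0$endpoint$t_end_h + 5)
})

test_that("rate and yield routes agree during the exponential phase", {
  ts <- simulate_batch(crabtree_preset("strong_positive"))
  m <- extract_metrics(ts)
  # q_E / q_S equals the exponential-phase ethanol-per-glucose yield
  w <- m$window
  idx <- which(ts$time_h >= w$t_start_h & ts$time_h <= w$t_end_h)
  i0 <- idx[1]; i1 <- idx[length(idx)]
  yield_ratio <- (ts$ethanol_gL[i1] - ts$ethanol_gL[i0]) /
    (ts$glucose_gL[i0] - ts$glucose_gL[i1])
  expect_rel(m$rates[["ethanol"]] / m$rates[["glucose"]], yield_ratio,
             1e-9)
})

test_that("every metric on a short series matches brute-force arithmetic", {
  # 5-point series checked entirely by hand-style recomputation
  t <- c(0, 2, 4, 6, 8)
  dw <- c(0.10, 0.18, 0.33, 0.60, 1.05)
  glc <- c(20, 17.5, 13.0, 5.2, 0.05)
  eth <- c(0, 0.9, 2.6, 5.6, 7.6)
  co2 <- c(0, 0.02, 0.06, 0.14, 0.21)
  o2 <- c(0, 0.01, 0.025, 0.05, 0.08)
  ts <- toy_series(t, dw, glc, ethanol_gL = eth, co2 = co2, o2 = o2)

  ep <- determine_endpoint(ts)
  expect_equal(ep$t_end_h, 8) # ethanol max at the last sample
  y <- compute_yields(ts, ep)
  expect_equal(unname(y[["ethanol"]]), (7.6 - 0) / (20 - 0.05))
  expect_equal(unname(y[["biomass"]]), (1.05 - 0.10) / (20 - 0.05))

  mu <- fit_growth_rate(ts, c(0, 8))
  # independent OLS of ln(dw) on t
  x <- t; ly <- log(dw)
  slope <- sum((x - mean(x)) * (ly - mean(ly))) / sum((x - mean(x))^2)
  expect_equal(mu, slope, tolerance = 1e-12)

  q <- compute_specific_rates(ts, c(0, 8), mu)
  expect_equal(unname(q[["glucose"]]), (20 - 0.05) / (1.05 - 0.10) * mu,
               tolerance = 1e-12)
  expect_equal(unname(q[["ethanol"]]), 7.6 / 0.95 * mu, tolerance = 1e-12)

  cb <- carbon_balance(ts, ep)
  by_hand <- (7.6 / 23.03 + (1.05 - 0.10) / 24.6 + 0.21) /
    ((20 - 0.05) / 30.03)
  expect_equal(cb, by_hand, tolerance = 1e-12)

  # glucose-phase end interpolates the 0.1 g/L crossing for the RQ window
  rq <- respiration_ratio(ts, ep)
  t_cross <- 6 + (5.2 - 0.1) / (5.2 - 0.05) * 2
  co2_at <- stats::approx(t, co2, t_cross)$y
  o2_at <- stats::approx(t, o2, t_cross)$y
  expect_equal(rq, co2_at / o2_at, tolerance = 1e-12)
})

test_that("extractor recovers the simulator's analytic growth rate and yields", {
  for (ph in c("strong_positive", "intermediate", "negative")) {
    p <- crabtree_preset(ph)
    m <- extract_metrics(simulate_batch(p))
    expect_rel(m$mu_per_h, analytic_mu(p), 0.02)
    ay <- analytic_yields(p)
    expect_equal(m$yields[["ethanol"]], ay[["ethanol"]], tolerance = 0.01)
    expect_rel(m$yields[["biomass"]], ay[["biomass"]], 0.01)
    if (ph == "negative") {
      # q_S = mu / Y_X/S for purely respiratory growth
      expect_rel(m$rates[["glucose"]], m$mu_per_h / p$Yxs_ox, 0.02)
    }
  }
})

test_that("growth on ethanol after the diauxic shift matches its closed form", {
  p <- crabtree_preset("strong_positive")
  ts <- simulate_batch(p)
  # pick a window in the ethanol-consumption phase, away from the shift
  i_max <- which.max(ts$ethanol_gL)
  t_lo <- ts$time_h[i_max] + p$lag_diauxic_h + 2
  idx <- which(ts$time_h >= t_lo & ts$ethanol_gL > 2)
  expect_gte(length(idx), 4)
  win <- c(ts$time_h[idx[1]], ts$time_h[idx[length(idx)]])
  mu_e <- fit_growth_rate(ts, win)
  expect_rel(mu_e, analytic_mu_ethanol(p), 0.05)
})

test_that("tidy and glance summarise extracted metrics", {
  m <- extract_metrics(simulate_batch(crabtree_preset("negative")))
  td <- generics::tidy(m)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$ethanol_yield, 0)
  expect_false(td$crabtree_positive)
  gl <- generics::glance(m)
  expect_equal(gl$n_qc_flags, 0)
  expect_gt(gl$fit_r2, 0.995)
})
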