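# Build small culture series for oracle tests. Columns not supplied
# default to zero (via as_culture_ts); gas columns are attached only
# when given.
toy_series <- function(time_h, dw_gL, glucose_gL, ethanol_gL = NULL,
                       co2 = NULL, o2 = NULL, ...) {
  df <- tibble::tibble(time_h = time_h, dw_gL = dw_gL,
                       glucose_gL = glucose_gL)
  if (!is.null(ethanol_gL)) df$ethanol_gL <- ethanol_gL
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  ts <- as_culture_ts(df, strain = "toy")
  if (!is.null(co2)) ts$co2_cum_mol_per_L <- co2
  if (!is.null(o2)) ts$o2_cum_mol_per_L <- o2
  ts
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual / expected - 1), tol)
}
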