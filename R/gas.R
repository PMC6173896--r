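## Headspace partial pressures (bar) from gas-phase state.
gas_partial_pressures <- function(y, phys) {
  RT <- phys$R * phys$T
  c(h2 = y[["G_h2"]] * RT / 16,
    ch4 = y[["G_ch4"]] * RT / 64,
    co2 = y[["G_co2"]] * RT)
}

#' Liquid-to-gas transfer rates
#'
#' Two-film transfer `kLa * (S_liq - K_H * p)` for H2, CH4 (gCOD/L/day) and
#' CO2 (mol/L/day; the dissolved-CO2 fraction of inorganic carbon is the
#' driving species). Negative rates mean re-dissolution.
#'
#' @param y named state vector
#' @param params an `adm1_parameters` object
#' @param S_co2 dissolved CO2 (M); computed from [solve_ph()] if missing
#' @return named vector of transfer rates for `h2`, `ch4`, `co2`
#' @export
gas_transfer_rates <- function(y, params, S_co2 = NULL) {
  phys <- params$phys
  p <- gas_partial_pressures(y, phys)
  if (is.null(S_co2)) S_co2 <- solve_ph(y, params)$S_co2
  c(h2 = phys$kLa * (y[["S_h2"]] - 16 * phys$K_H_h2 * p[["h2"]]),
    ch4 = phys$kLa * (y[["S_ch4"]] - 64 * phys$K_H_ch4 * p[["ch4"]]),
    co2 = phys$kLa * (S_co2 - phys$K_H_co2 * p[["co2"]]))
}

#' Overpressure-driven biogas outflow
#'
#' The headspace releases gas in proportion to its overpressure:
#' `q = k_p * (P - P_atm) * P / P_atm` for `P > P_atm`, zero otherwise
#' (volumetric flow at headspace conditions).
#'
#' @param P_head total headspace pressure, bar
#' @param params an `adm1_parameters` object (reads `k_p`, `P_atm`)
#' @return biogas volumetric flow, L/day
#' @export
gas_outflow <- function(P_head, params) {
  phys <- params$phys
  if (P_head <= phys$P_atm) return(0)
  phys$k_p * (P_head - phys$P_atm) * P_head / phys$P_atm
}

## Convert a wet volumetric flow at reactor conditions to a dry flow at
## 273.15 K and 1.01325 bar.
normalize_gas_flow <- function(q, P_head, phys) {
  q * (P_head - phys$p_h2o) / 1.01325 * 273.15 / phys$T
}
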