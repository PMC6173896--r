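#' Monod substrate uptake rate
#'
#' Standard ADM1 uptake kinetics: `k_m * S/(K+S) * X * I`, in gCOD substrate
#' per litre per day.
#'
#' @param S substrate concentration, gCOD/L
#' @param X biomass concentration, gCOD/L
#' @param kin a [population_kinetics()] object
#' @param I combined inhibition factor in `[0, 1]`
#' @return process rate, gCOD/L/day
#' @export
monod_uptake <- function(S, X, kin, I = 1) {
  if (any(S < 0) || any(X < 0)) stop("S and X must be non-negative")
  if (any(I < 0 | I > 1)) stop("I must lie in [0, 1]")
  kin$k_m * S / (kin$K + S) * X * I
}

#' pH inhibition factor (lower-limit exponential form)
#'
#' Inhibition sets in below the upper limit `pH_ul` and follows
#' `exp(-3 * ((pH - pH_ul)/(pH_ul - pH_ll))^2)`; above `pH_ul` the factor is
#' one. Guilds without configured limits are uninhibited. A switchable Hill
#' form (`form = "hill"`) is provided for sensitivity checks.
#'
#' @param pH pH value(s)
#' @param kin a [population_kinetics()] object carrying `pH_ul`, `pH_ll`
#' @param form `"exponential"` (default) or `"hill"`
#' @return inhibition factor in `[0, 1]`
#' @export
ph_inhibition <- function(pH, kin, form = c("exponential", "hill")) {
  form <- match.arg(form)
  if (is.na(kin$pH_ul) || is.na(kin$pH_ll)) return(rep(1, length(pH)))
  if (kin$pH_ul <= kin$pH_ll) stop("pH_ul must exceed pH_ll")
  if (form == "exponential") {
    ifelse(pH >= kin$pH_ul, 1,
           exp(-3 * ((pH - kin$pH_ul) / (kin$pH_ul - kin$pH_ll))^2))
  } else {
    n <- 3 / (kin$pH_ul - kin$pH_ll)
    K_pH <- 10^(-(kin$pH_ul + kin$pH_ll) / 2)
    H <- 10^(-pH)
    K_pH^n / (K_pH^n + H^n)
  }
}

#' Critical hydraulic retention time of a guild in a chemostat
#'
#' The persistence boundary of a single population growing on substrate fed
#' at `S_in`: below the returned HRT the population washes out. Computed as
#' `1 / (Y*k_m*S_in/(K+S_in) - k_dec)`; `Inf` if the population cannot grow
#' at all at that substrate level.
#'
#' @param kin a [population_kinetics()] object
#' @param S_in available substrate concentration, gCOD/L
#' @return critical HRT in days (`Inf` for a non-growing population)
#' @export
washout_hrt <- function(kin, S_in) {
  mu <- kin$Y * kin$k_m * S_in / (kin$K + S_in) - kin$k_dec
  if (mu <= 0) return(Inf)
  1 / mu
}
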