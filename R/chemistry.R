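## gCOD per mole of each volatile fatty acid (stoichiometric oxygen demand)
COD_PER_MOL <- c(ac = 64, pro = 112, bu = 160, va = 208)

## Charge balance in equivalents/L as a function of proton concentration H.
## Strictly increasing in H, hence a unique root.
charge_balance <- function(H, y, phys) {
  y[["S_cat"]] + y[["S_IN"]] * H / (H + phys$K_a_IN) + H -
    y[["S_IC"]] * phys$K_a_co2 / (H + phys$K_a_co2) -
    (y[["S_ac"]] / 64) * phys$K_a_ac / (H + phys$K_a_ac) -
    (y[["S_pro"]] / 112) * phys$K_a_pro / (H + phys$K_a_pro) -
    (y[["S_bu"]] / 160) * phys$K_a_bu / (H + phys$K_a_bu) -
    (y[["S_va"]] / 208) * phys$K_a_va / (H + phys$K_a_va) -
    phys$K_w / H - y[["S_an"]]
}

charge_balance_deriv <- function(H, y, phys) {
  y[["S_IN"]] * phys$K_a_IN / (H + phys$K_a_IN)^2 + 1 +
    y[["S_IC"]] * phys$K_a_co2 / (H + phys$K_a_co2)^2 +
    (y[["S_ac"]] / 64) * phys$K_a_ac / (H + phys$K_a_ac)^2 +
    (y[["S_pro"]] / 112) * phys$K_a_pro / (H + phys$K_a_pro)^2 +
    (y[["S_bu"]] / 160) * phys$K_a_bu / (H + phys$K_a_bu)^2 +
    (y[["S_va"]] / 208) * phys$K_a_va / (H + phys$K_a_va)^2 +
    phys$K_w / H^2
}

#' Solve the acid-base charge balance for pH
#'
#' Finds the unique proton concentration at which cations (including
#' ammonium), bicarbonate, dissociated VFAs, hydroxide and the strong-ion
#' states balance, then reports pH and the full speciation at equilibrium.
#' A damped Newton iteration (warm-startable) with bisection safeguarding is
#' used; the residual is driven below `tol` equivalents/L.
#'
#' @param y named state vector (only the ion/weak-acid totals are read)
#' @param params an `adm1_parameters` object, or its `phys` component
#' @param H0 optional warm-start proton concentration, mol/L
#' @param tol residual tolerance, equivalents/L
#' @return list with `pH`, `H`, `S_co2` (dissolved CO2, M), `S_hco3` (M),
#'   `S_nh3` (M), `S_nh4` (M), and the charge `residual`
#' @export
solve_ph <- function(y, params, H0 = NULL, tol = 1e-12) {
  phys <- if (inherits(params, "adm1_parameters")) params$phys else params
  lo <- 1e-14; hi <- 1
  f_lo <- charge_balance(lo, y, phys); f_hi <- charge_balance(hi, y, phys)
  if (is.na(f_lo) || is.na(f_hi) || f_lo > 0 || f_hi < 0)
    stop("charge balance has no root in pH [0, 14]: impossible composition")
  H <- if (!is.null(H0) && is.finite(H0) && H0 > lo && H0 < hi) H0 else 1e-7
  for (it in seq_len(60)) {
    fH <- charge_balance(H, y, phys)
    if (abs(fH) < tol) break
    if (fH > 0) hi <- H else lo <- H
    step <- fH / charge_balance_deriv(H, y, phys)
    Hn <- H - step
    if (!is.finite(Hn) || Hn <= lo || Hn >= hi) Hn <- sqrt(lo * hi)
    H <- Hn
  }
  co2 <- y[["S_IC"]] * H / (H + phys$K_a_co2)
  nh4 <- y[["S_IN"]] * H / (H + phys$K_a_IN)
  list(pH = -log10(H), H = H,
       S_co2 = co2, S_hco3 = y[["S_IC"]] - co2,
       S_nh4 = nh4, S_nh3 = y[["S_IN"]] - nh4,
       residual = charge_balance(H, y, phys))
}
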