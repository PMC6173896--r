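## Integer indices into the state vector, bound at install time.
for (.k in seq_along(STATE_NAMES))
  assign(paste0("i_", STATE_NAMES[.k]), .k)
rm(.k)

## Fast scalar Newton/bisection pH solve used inside the right-hand side.
## Same charge balance as solve_ph(), minus the bookkeeping.
ph_newton <- function(yc, pr, H0) {
  ac <- yc[i_S_ac] / 64; pro <- yc[i_S_pro] / 112
  bu <- yc[i_S_bu] / 160; va <- yc[i_S_va] / 208
  SIC <- yc[i_S_IC]; SIN <- yc[i_S_IN]
  base <- yc[i_S_cat] - yc[i_S_an]
  lo <- 1e-14; hi <- 1
  H <- if (is.finite(H0) && H0 > lo && H0 < hi) H0 else 1e-7
  for (it in 1:60) {
    f <- base + SIN * H / (H + pr$K_a_IN) + H -
      SIC * pr$K_a_co2 / (H + pr$K_a_co2) -
      ac * pr$K_a_ac / (H + pr$K_a_ac) -
      pro * pr$K_a_pro / (H + pr$K_a_pro) -
      bu * pr$K_a_bu / (H + pr$K_a_bu) -
      va * pr$K_a_va / (H + pr$K_a_va) -
      pr$K_w / H
    if (abs(f) < 1e-12) break
    if (f > 0) hi <- H else lo <- H
    df <- SIN * pr$K_a_IN / (H + pr$K_a_IN)^2 + 1 +
      SIC * pr$K_a_co2 / (H + pr$K_a_co2)^2 +
      ac * pr$K_a_ac / (H + pr$K_a_ac)^2 +
      pro * pr$K_a_pro / (H + pr$K_a_pro)^2 +
      bu * pr$K_a_bu / (H + pr$K_a_bu)^2 +
      va * pr$K_a_va / (H + pr$K_a_va)^2 +
      pr$K_w / H^2
    Hn <- H - f / df
    if (!is.finite(Hn) || Hn <= lo || Hn >= hi) Hn <- sqrt(lo * hi)
    H <- Hn
  }
  H
}

## Flatten parameters + segment-constant feed data into the list consumed by
## the right-hand side.
build_rhs_parms <- function(config, params) {
  pops <- params$populations
  phys <- params$phys
  dil <- numeric(N_STATE); dil[1:27] <- 1  # gas states are not diluted
  pr <- c(phys, list(
    M = params$M,
    k_dis = params$stoich$k_dis,
    k_hyd_ch = params$stoich$k_hyd_ch,
    k_hyd_pr = params$stoich$k_hyd_pr,
    k_hyd_li = params$stoich$k_hyd_li,
    km = vapply(pops, `[[`, numeric(1), "k_m"),
    Ks = vapply(pops, `[[`, numeric(1), "K"),
    kdec = vapply(pops, `[[`, numeric(1), "k_dec"),
    pH_ul = vapply(pops, `[[`, numeric(1), "pH_ul"),
    pH_ll = vapply(pops, `[[`, numeric(1), "pH_ll"),
    V_liq = config$V_liq, V_gas = config$V_gas,
    q = 0, influx = numeric(N_STATE), dil = dil,
    cache = new.env(parent = emptyenv())
  ))
  pr$cache$H <- 1e-7
  pr
}

## ADM1 right-hand side. `pr` carries unpacked constants plus the
## segment-constant feed terms `q` (L/d) and `influx` (mass/d by state).
adm1_rhs <- function(t, y, pr) {
  if (any(!is.finite(y)))
    stop(sprintf("non-finite state at t = %.4f d (component %s)",
                 t, STATE_NAMES[which(!is.finite(y))[1]]))
  yc <- pmax(y, 0)

  H <- ph_newton(yc, pr, pr$cache$H)
  pr$cache$H <- H
  pH <- -log10(H)

  ## inhibition factors
  ipH <- numeric(8)
  for (g in 1:8) {
    ul <- pr$pH_ul[g]; ll <- pr$pH_ll[g]
    ipH[g] <- if (is.na(ul) || pH >= ul) 1 else
      exp(-3 * ((pH - ul) / (ul - ll))^2)
  }
  SIN <- yc[i_S_IN]
  I_IN <- SIN / (SIN + pr$K_S_IN)
  nh3 <- SIN * pr$K_a_IN / (pr$K_a_IN + H)
  I_nh3 <- 1 / (1 + nh3 / pr$K_I_nh3)
  Sh2 <- yc[i_S_h2]
  I_h2_fa <- 1 / (1 + Sh2 / pr$K_I_h2_fa)
  I_h2_c4 <- 1 / (1 + Sh2 / pr$K_I_h2_c4)
  I_h2_pro <- 1 / (1 + Sh2 / pr$K_I_h2_pro)

  km <- pr$km; Ks <- pr$Ks
  Sva <- yc[i_S_va]; Sbu <- yc[i_S_bu]
  rho <- c(
    pr$k_dis * yc[i_X_c],
    pr$k_hyd_ch * yc[i_X_ch],
    pr$k_hyd_pr * yc[i_X_pr],
    pr$k_hyd_li * yc[i_X_li],
    km[1] * yc[i_S_su] / (Ks[1] + yc[i_S_su]) * yc[i_X_su] * ipH[1] * I_IN,
    km[2] * yc[i_S_aa] / (Ks[2] + yc[i_S_aa]) * yc[i_X_aa] * ipH[2] * I_IN,
    km[3] * yc[i_S_fa] / (Ks[3] + yc[i_S_fa]) * yc[i_X_fa] *
      ipH[3] * I_IN * I_h2_fa,
    km[4] * Sva / (Ks[4] + Sva) * yc[i_X_c4] * Sva / (Sva + Sbu + 1e-10) *
      ipH[4] * I_IN * I_h2_c4,
    km[4] * Sbu / (Ks[4] + Sbu) * yc[i_X_c4] * Sbu / (Sva + Sbu + 1e-10) *
      ipH[4] * I_IN * I_h2_c4,
    km[5] * yc[i_S_pro] / (Ks[5] + yc[i_S_pro]) * yc[i_X_pro] *
      ipH[5] * I_IN * I_h2_pro,
    km[6] * yc[i_S_ac] / (Ks[6] + yc[i_S_ac]) * yc[i_X_ac1] *
      ipH[6] * I_IN * I_nh3,
    km[7] * yc[i_S_ac] / (Ks[7] + yc[i_S_ac]) * yc[i_X_ac2] *
      ipH[7] * I_IN * I_nh3,
    km[8] * Sh2 / (Ks[8] + Sh2) * yc[i_X_h2] * ipH[8] * I_IN,
    pr$kdec * yc[GUILD_IDX]
  )

  dy <- drop(rho %*% pr$M) + (pr$influx - pr$q * y) / pr$V_liq * pr$dil

  ## liquid-gas transfer and headspace outflow
  RT <- pr$R * pr$T
  p_h2 <- yc[i_G_h2] * RT / 16
  p_ch4 <- yc[i_G_ch4] * RT / 64
  p_co2 <- yc[i_G_co2] * RT
  P <- p_h2 + p_ch4 + p_co2 + pr$p_h2o
  q_gas <- if (P > pr$P_atm) pr$k_p * (P - pr$P_atm) * P / pr$P_atm else 0
  Sco2 <- yc[i_S_IC] * H / (H + pr$K_a_co2)
  rt_h2 <- pr$kLa * (Sh2 - 16 * pr$K_H_h2 * p_h2)
  rt_ch4 <- pr$kLa * (yc[i_S_ch4] - 64 * pr$K_H_ch4 * p_ch4)
  rt_co2 <- pr$kLa * (Sco2 - pr$K_H_co2 * p_co2)

  dy[i_S_h2] <- dy[i_S_h2] - rt_h2
  dy[i_S_ch4] <- dy[i_S_ch4] - rt_ch4
  dy[i_S_IC] <- dy[i_S_IC] - rt_co2
  rV <- pr$V_liq / pr$V_gas
  dy[i_G_h2] <- rt_h2 * rV - yc[i_G_h2] * q_gas / pr$V_gas
  dy[i_G_ch4] <- rt_ch4 * rV - yc[i_G_ch4] * q_gas / pr$V_gas
  dy[i_G_co2] <- rt_co2 * rV - yc[i_G_co2] * q_gas / pr$V_gas

  list(dy)
}

#' Time derivative of the full model state
#'
#' Evaluates the modified ADM1 right-hand side at one instant: biochemical
#' conversions via the balanced process matrix, dilution at the
#' instantaneous feed flow, liquid-gas transfer and headspace outflow.
#'
#' @param t time, days
#' @param y named state vector
#' @param config a [reactor_config()]
#' @param params an `adm1_parameters` object
#' @param schedule a `feed_schedule`
#' @return named derivative vector, d(state)/dt
#' @export
adm1_derivatives <- function(t, y, config, params, schedule) {
  pr <- build_rhs_parms(config, params)
  seg <- schedule_segment(schedule, t)
  pr$q <- seg$q; pr$influx <- seg$influx
  stats::setNames(adm1_rhs(t, unname(y[STATE_NAMES]), pr)[[1]], STATE_NAMES)
}
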