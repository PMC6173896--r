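#' Kinetic parameters of one microbial guild
#'
#' @param name guild label
#' @param Y yield, gCOD biomass per gCOD substrate
#' @param k_m maximum specific substrate utilization rate,
#'   gCOD substrate / gCOD biomass / day
#' @param K half-saturation constant, gCOD/L
#' @param k_dec first-order decay rate, 1/day
#' @param pH_ul,pH_ll upper/lower pH-inhibition limits; inhibition starts
#'   below `pH_ul` and is essentially complete at `pH_ll`. `NA` disables
#'   pH inhibition for the guild.
#' @return an object of class `population_kinetics`
#' @export
population_kinetics <- function(name, Y, k_m, K, k_dec,
                                pH_ul = NA_real_, pH_ll = NA_real_) {
  if (!(Y > 0 && Y < 1)) stop("Y must lie in (0,1)")
  if (k_m <= 0) stop("k_m must be positive")
  if (K <= 0) stop("K must be positive")
  if (k_dec < 0) stop("k_dec must be non-negative")
  if (!is.na(pH_ul) && !is.na(pH_ll) && pH_ll >= pH_ul)
    stop("pH_ll must be below pH_ul")
  structure(list(name = name, Y = Y, k_m = k_m, K = K, k_dec = k_dec,
                 pH_ul = pH_ul, pH_ll = pH_ll),
            class = "population_kinetics")
}

## Guild kinetics presets.
## "this_study": the fitted acetogen/methanogen set of the VFA reactor
## experiments; the split acetoclastic guilds are X_ac1 (Methanosarcina:
## fast, acid-tolerant) and X_ac2 (Methanosaeta: high-affinity, inhibited
## already below pH 7). "literature": earlier published acetoclastic values
## (high Methanosarcina decay, slow Methanosaeta) used for the washout
## comparison. Remaining guilds follow the mesophilic ADM1 benchmark set.
kinetics_presets <- function() {
  std <- list(
    X_su  = population_kinetics("X_su",  0.10, 30,  0.5,  0.02, 5.5, 4),
    X_aa  = population_kinetics("X_aa",  0.08, 50,  0.3,  0.02, 5.5, 4),
    X_fa  = population_kinetics("X_fa",  0.06, 6,   0.4,  0.02, 5.5, 4),
    X_c4  = population_kinetics("X_c4",  0.06, 20,  0.2,  0.02, 5.5, 4),
    X_pro = population_kinetics("X_pro", 0.04, 13,  0.1,  0.02, 5.5, 4),
    X_ac1 = population_kinetics("X_ac1", 0.05, 8,   0.15, 0.02, 7,   6),
    X_ac2 = population_kinetics("X_ac2", 0.05, 8,   0.15, 0.02, 7,   6),
    X_h2  = population_kinetics("X_h2",  0.06, 35,  7e-6, 0.02, 6,   5)
  )
  this_study <- std
  this_study$X_c4  <- population_kinetics("X_c4",  0.012, 25,   0.2,  0.02)
  this_study$X_pro <- population_kinetics("X_pro", 0.012, 30,   0.1,  0.02)
  this_study$X_ac1 <- population_kinetics("X_ac1", 0.033, 20,   0.32, 0.02, 5.5, 4)
  this_study$X_ac2 <- population_kinetics("X_ac2", 0.033, 14.5, 0.09, 0.02, 7, 6.3)
  this_study$X_h2  <- population_kinetics("X_h2",  0.032, 35,   7e-6, 0.02, 6, 5)
  literature <- this_study
  literature$X_ac1 <- population_kinetics("X_ac1", 0.060, 8.95, 0.32, 0.1)
  literature$X_ac2 <- population_kinetics("X_ac2", 0.042, 2.77, 0.09, 0.0064)
  list(this_study = this_study, literature = literature, adm1_default = std)
}

#' Full model parameter set
#'
#' Assembles guild kinetics, stoichiometry (with per-process inorganic C and
#' N balancing so every process row closes elemental balances exactly),
#' acid-base and Henry constants at temperature `T`, and the liquid-gas
#' transfer / headspace outflow coefficients.
#'
#' @param preset `"this_study"`, `"literature"`, or `"adm1_default"`
#' @param overrides named list of `population_kinetics` objects replacing
#'   individual guilds, e.g. `list(X_ac2 = population_kinetics(...))`
#' @param T operating temperature, K
#' @param kLa liquid-gas transfer coefficient, 1/day
#' @param k_p headspace outflow resistance coefficient, L/day/bar
#' @return an object of class `adm1_parameters`
#' @export
adm1_parameters <- function(preset = c("this_study", "literature",
                                       "adm1_default"),
                            overrides = list(), T = 310.15,
                            kLa = 200, k_p = 5e4) {
  preset <- match.arg(preset)
  pops <- kinetics_presets()[[preset]]
  for (nm in names(overrides)) {
    stopifnot(inherits(overrides[[nm]], "population_kinetics"))
    pops[[nm]] <- overrides[[nm]]
  }

  ## composite disintegration fractions and acidogenesis product fractions
  stoich <- list(
    f_sI_xc = 0.1, f_ch_xc = 0.2, f_pr_xc = 0.2, f_li_xc = 0.3, f_xI_xc = 0.2,
    f_fa_li = 0.95,
    f_h2_su = 0.19, f_bu_su = 0.13, f_pro_su = 0.27, f_ac_su = 0.41,
    f_h2_aa = 0.06, f_va_aa = 0.23, f_bu_aa = 0.26, f_pro_aa = 0.05,
    f_ac_aa = 0.40,
    k_dis = 0.5, k_hyd_ch = 10, k_hyd_pr = 10, k_hyd_li = 10
  )

  ## elemental contents, mol per gCOD, indexed over the full state vector
  C <- stats::setNames(numeric(N_STATE), STATE_NAMES)
  C[c("S_su", "X_ch")] <- 0.0313
  C[c("S_aa", "X_pr")] <- 0.03
  C["S_fa"] <- 0.0217; C["S_va"] <- 0.024; C["S_bu"] <- 0.025
  C["S_pro"] <- 0.0268; C["S_ac"] <- 0.0313; C["S_ch4"] <- 0.0156
  C[c("S_I", "X_I")] <- 0.03
  C["X_c"] <- 0.02786; C["X_li"] <- 0.022
  C[names(GUILD_IDX)] <- 0.0313

  N <- stats::setNames(numeric(N_STATE), STATE_NAMES)
  N[c("S_aa", "X_pr")] <- 0.007
  N[c("S_I", "X_I")] <- 0.06 / 14
  N["X_c"] <- 0.0376 / 14
  N[names(GUILD_IDX)] <- 0.08 / 14

  ## temperature-corrected physicochemical constants (van't Hoff from 298 K)
  vh <- function(k298, dH) k298 * exp(dH / 8.3145 * (1 / 298.15 - 1 / T))
  phys <- list(
    T = T, R = 0.083145, P_atm = 1.013,
    p_h2o = 0.0313 * exp(5290 * (1 / 298.15 - 1 / T)),
    K_w = vh(1e-14, 55900),
    K_a_co2 = vh(10^-6.35, 7646),
    K_a_IN = vh(10^-9.25, 51965),
    K_a_ac = 10^-4.76, K_a_pro = 10^-4.88,
    K_a_bu = 10^-4.82, K_a_va = 10^-4.86,
    K_H_co2 = vh(0.035, -19410),
    K_H_ch4 = vh(0.0014, -14240),
    K_H_h2 = vh(7.8e-4, -4180),
    kLa = kLa, k_p = k_p,
    K_S_IN = 1e-4,
    K_I_h2_fa = 5e-6, K_I_h2_c4 = 1e-5, K_I_h2_pro = 3.5e-6,
    K_I_nh3 = 0.0018
  )

  p <- structure(list(preset = preset, populations = pops, stoich = stoich,
                      C = C, N = N, phys = phys),
                 class = "adm1_parameters")
  p$M <- build_stoichiometry(p)
  p
}

## Process rows of the Petersen matrix. Columns follow STATE_NAMES; the
## inorganic-carbon and inorganic-nitrogen columns are filled with the
## negative elemental-content-weighted sum of each row so that C and N close
## exactly in every process.
PROCESS_NAMES <- c("disintegration", "hydrolysis_ch", "hydrolysis_pr",
                   "hydrolysis_li", "uptake_su", "uptake_aa", "uptake_fa",
                   "uptake_va", "uptake_bu", "uptake_pro", "uptake_ac1",
                   "uptake_ac2", "uptake_h2",
                   paste0("decay_", names(GUILD_IDX)))

build_stoichiometry <- function(p) {
  s <- p$stoich
  pops <- p$populations
  M <- matrix(0, length(PROCESS_NAMES), N_STATE,
              dimnames = list(PROCESS_NAMES, STATE_NAMES))
  M["disintegration", c("X_c", "S_I", "X_ch", "X_pr", "X_li", "X_I")] <-
    c(-1, s$f_sI_xc, s$f_ch_xc, s$f_pr_xc, s$f_li_xc, s$f_xI_xc)
  M["hydrolysis_ch", c("X_ch", "S_su")] <- c(-1, 1)
  M["hydrolysis_pr", c("X_pr", "S_aa")] <- c(-1, 1)
  M["hydrolysis_li", c("X_li", "S_su", "S_fa")] <- c(-1, 1 - s$f_fa_li, s$f_fa_li)

  Y <- vapply(pops, `[[`, numeric(1), "Y")
  M["uptake_su", c("S_su", "S_bu", "S_pro", "S_ac", "S_h2", "X_su")] <-
    c(-1, (1 - Y[["X_su"]]) * c(s$f_bu_su, s$f_pro_su, s$f_ac_su, s$f_h2_su),
      Y[["X_su"]])
  M["uptake_aa", c("S_aa", "S_va", "S_bu", "S_pro", "S_ac", "S_h2", "X_aa")] <-
    c(-1, (1 - Y[["X_aa"]]) * c(s$f_va_aa, s$f_bu_aa, s$f_pro_aa, s$f_ac_aa,
                                s$f_h2_aa), Y[["X_aa"]])
  M["uptake_fa", c("S_fa", "S_ac", "S_h2", "X_fa")] <-
    c(-1, (1 - Y[["X_fa"]]) * c(0.7, 0.3), Y[["X_fa"]])
  M["uptake_va", c("S_va", "S_pro", "S_ac", "S_h2", "X_c4")] <-
    c(-1, (1 - Y[["X_c4"]]) * c(0.54, 0.31, 0.15), Y[["X_c4"]])
  M["uptake_bu", c("S_bu", "S_ac", "S_h2", "X_c4")] <-
    c(-1, (1 - Y[["X_c4"]]) * c(0.8, 0.2), Y[["X_c4"]])
  M["uptake_pro", c("S_pro", "S_ac", "S_h2", "X_pro")] <-
    c(-1, (1 - Y[["X_pro"]]) * c(0.57, 0.43), Y[["X_pro"]])
  M["uptake_ac1", c("S_ac", "S_ch4", "X_ac1")] <-
    c(-1, 1 - Y[["X_ac1"]], Y[["X_ac1"]])
  M["uptake_ac2", c("S_ac", "S_ch4", "X_ac2")] <-
    c(-1, 1 - Y[["X_ac2"]], Y[["X_ac2"]])
  M["uptake_h2", c("S_h2", "S_ch4", "X_h2")] <-
    c(-1, 1 - Y[["X_h2"]], Y[["X_h2"]])
  for (g in names(GUILD_IDX))
    M[paste0("decay_", g), c(g, "X_c")] <- c(-1, 1)

  ## amended balancing terms: close elemental C and N per process
  M[, "S_IC"] <- -drop(M %*% p$C)
  M[, "S_IN"] <- -drop(M %*% p$N)
  M
}

#' Verify conservation of COD, carbon and nitrogen in the process matrix
#'
#' Every process row must sum to zero over the COD-carrying species, and to
#' zero elemental carbon and nitrogen once the inorganic pools are included.
#'
#' @param params an `adm1_parameters` object
#' @param tol tolerance on the row sums
#' @return invisibly `TRUE`; errors otherwise
#' @export
check_balances <- function(params, tol = 1e-12) {
  M <- params$M
  cod <- rowSums(M[, COD_IDX])
  Cres <- drop(M %*% params$C) + M[, "S_IC"]
  Nres <- drop(M %*% params$N) + M[, "S_IN"]
  if (any(abs(cod) > tol)) stop("COD not conserved in process matrix")
  if (any(abs(Cres) > tol)) stop("carbon not conserved in process matrix")
  if (any(abs(Nres) > tol)) stop("nitrogen not conserved in process matrix")
  invisible(TRUE)
}
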