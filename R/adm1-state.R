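#' @keywords internal
"_PACKAGE"

## State vector layout shared by the whole model.
## Soluble and particulate species in gCOD/L, except S_IC, S_IN, S_cat, S_an
## (mol/L). Gas-phase species G_h2, G_ch4 in gCOD per L headspace, G_co2 in
## mol per L headspace.
STATE_NAMES <- c(
  "S_su", "S_aa", "S_fa", "S_va", "S_bu", "S_pro", "S_ac", "S_h2", "S_ch4",
  "S_IC", "S_IN", "S_I",
  "X_c", "X_ch", "X_pr", "X_li",
  "X_su", "X_aa", "X_fa", "X_c4", "X_pro", "X_ac1", "X_ac2", "X_h2", "X_I",
  "S_cat", "S_an",
  "G_h2", "G_ch4", "G_co2"
)
N_STATE <- length(STATE_NAMES)

## indices of species that carry COD (used for balance closure)
COD_IDX <- c(1:9, 12:25)
## guild biomass indices (degraders subject to decay)
GUILD_IDX <- c(X_su = 17L, X_aa = 18L, X_fa = 19L, X_c4 = 20L,
               X_pro = 21L, X_ac1 = 22L, X_ac2 = 23L, X_h2 = 24L)
## particulate indices (all count towards volatile solids)
PARTICULATE_IDX <- 13:25

#' Blank model state
#'
#' Returns a zeroed, named state vector in the model's canonical layout.
#' @return named numeric vector of length 30
#' @export
empty_state <- function() {
  stats::setNames(numeric(N_STATE), STATE_NAMES)
}

#' Influent for the synthetic VFA medium
#'
#' Builds an influent state vector for the mineral medium carrying acetic,
#' propionic and butyric acid as the only carbon sources. Fractions are on a
#' COD basis and must sum to one.
#'
#' @param total_cod total substrate concentration, gCOD/L
#' @param cod_fractions named fractions for `ac`, `pro`, `bu` (COD basis)
#' @param S_IC_in influent inorganic carbon, mol/L
#' @param S_IN_in influent inorganic nitrogen (ammonium), mol/L
#' @param S_cat_in,S_an_in influent metallic cation / strong anion
#'   concentrations, mol/L (charge equivalents not otherwise accounted for)
#' @return named influent state vector (gas entries zero)
#' @export
vfa_influent <- function(total_cod,
                         cod_fractions = c(ac = 0.45, pro = 0.10, bu = 0.45),
                         S_IC_in = 0.005, S_IN_in = 0.05,
                         S_cat_in = 0.0783, S_an_in = 0.0198) {
  stopifnot(total_cod >= 0, all(cod_fractions >= 0))
  if (abs(sum(cod_fractions) - 1) > 1e-12)
    stop("cod_fractions must sum to 1")
  inf <- empty_state()
  inf["S_ac"]  <- total_cod * cod_fractions[["ac"]]
  inf["S_pro"] <- total_cod * cod_fractions[["pro"]]
  inf["S_bu"]  <- total_cod * cod_fractions[["bu"]]
  inf["S_IC"]  <- S_IC_in
  inf["S_IN"]  <- S_IN_in
  inf["S_cat"] <- S_cat_in
  inf["S_an"]  <- S_an_in
  inf
}

#' Influent for a composite (maize silage) substrate
#'
#' The substrate enters as hydrolysable polymers (carbohydrate, protein,
#' lipid) plus inert COD, so disintegration/hydrolysis and acidogenesis run
#' with their standard parameters. Fractions are on a COD basis.
#'
#' @param total_cod total substrate concentration, gCOD/L
#' @param cod_fractions named fractions for `ch` (carbohydrate), `pr`
#'   (protein), `li` (lipid), `xi` (particulate inert), `si` (soluble inert)
#' @inheritParams vfa_influent
#' @return named influent state vector
#' @export
composite_influent <- function(total_cod,
                               cod_fractions = c(ch = 0.60, pr = 0.12,
                                                 li = 0.07, xi = 0.16,
                                                 si = 0.05),
                               S_IC_in = 0.005, S_IN_in = 0.01,
                               S_cat_in = 0.05, S_an_in = 0.01) {
  stopifnot(total_cod >= 0, all(cod_fractions >= 0))
  if (abs(sum(cod_fractions) - 1) > 1e-12)
    stop("cod_fractions must sum to 1")
  inf <- empty_state()
  inf["X_ch"] <- total_cod * cod_fractions[["ch"]]
  inf["X_pr"] <- total_cod * cod_fractions[["pr"]]
  inf["X_li"] <- total_cod * cod_fractions[["li"]]
  inf["X_I"]  <- total_cod * cod_fractions[["xi"]]
  inf["S_I"]  <- total_cod * cod_fractions[["si"]]
  inf["S_IC"] <- S_IC_in
  inf["S_IN"] <- S_IN_in
  inf["S_cat"] <- S_cat_in
  inf["S_an"]  <- S_an_in
  inf
}

#' Initial reactor state from an inoculum description
#'
#' Distributes the measured inoculum volatile-solids concentration over the
#' eight degrader guilds and seeds the soluble pools. Biomass VS is converted
#' to COD with `cod_per_vs` (gCOD/gVS).
#'
#' @param inoculum_vs inoculum volatile solids, g/L
#' @param partition named fractions over the guilds
#'   (`X_su`,`X_aa`,`X_fa`,`X_c4`,`X_pro`,`X_ac1`,`X_ac2`,`X_h2`); must sum
#'   to 1
#' @param cod_per_vs COD-to-VS conversion factor for biomass, gCOD/gVS
#' @param solubles named numeric vector of initial soluble/ion values to
#'   overwrite (e.g. `c(S_ac = 0.1, S_IC = 0.09, ...)`)
#' @param gas named numeric vector of initial gas-phase values
#' @return named state vector
#' @export
initial_state <- function(inoculum_vs = 0.87,
                          partition = c(X_su = 0.02, X_aa = 0.02, X_fa = 0.01,
                                        X_c4 = 0.16, X_pro = 0.06,
                                        X_ac1 = 0.03, X_ac2 = 0.46,
                                        X_h2 = 0.24),
                          cod_per_vs = 1.42,
                          solubles = c(S_ac = 0.10, S_pro = 0.05, S_bu = 0.10,
                                       S_IC = 0.10, S_IN = 0.045,
                                       S_cat = 0.0783, S_an = 0.0198),
                          gas = c(G_h2 = 1e-5, G_ch4 = 1.0, G_co2 = 0.014)) {
  if (abs(sum(partition) - 1) > 1e-9)
    stop("guild partition must sum to 1")
  y <- empty_state()
  y[names(GUILD_IDX)] <- inoculum_vs * cod_per_vs * partition[names(GUILD_IDX)]
  y[names(solubles)] <- solubles
  y[names(gas)] <- gas
  y
}

## total COD of a state row/vector (liquid phase only)
state_total_cod <- function(y) {
  if (is.matrix(y)) rowSums(y[, COD_IDX, drop = FALSE]) else sum(y[COD_IDX])
}
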