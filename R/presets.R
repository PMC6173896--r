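## Scenario constants for the laboratory experiments and the maize-silage
## transfer simulation. Influent inorganic carbon/nitrogen, the transfer
## coefficient kLa, the inoculum partition and the disturbance load are not
## printed quantities; they are the package's calibration, chosen to
## reproduce the reported fitted behaviour (steady pH and dissolved
## inorganic carbon of the continuous reactor, the acetoclastic community
## split, and the post-disturbance pH drop). See the methods vignette.
EXPERIMENTS <- list(
  exp1 = list(V_liq = 6, HRT = 5.5, total_cod = 37.2, inoculum_vs = 0.87,
              pulse_fraction = 0.885, period = 1),
  exp2 = list(V_liq = 6, HRT = 8, total_cod = 37.2, inoculum_vs = 0.41,
              pulse_fraction = 0.75, period = 1),
  exp3 = list(V_liq = 8, HRT = 5.5, total_cod = 12.4, inoculum_vs = 0.46,
              pulse_fraction = 0.75, period = 1),
  maize = list(V_liq = 6, HRT = 20, total_cod = 80, inoculum_vs = 2.0,
               pulse_fraction = 1, period = 2)
)

CAL <- list(
  S_IC_in = 0.010, S_IN_in = 0.056, kLa = 50,
  partition = c(X_su = 0.02, X_aa = 0.02, X_fa = 0.01, X_c4 = 0.16,
                X_pro = 0.06, X_ac1 = 0.03, X_ac2 = 0.46, X_h2 = 0.24),
  disturbance_cod = 37,
  maize = list(S_IC_in = 0.010, S_IN_in = 0.005, S_cat_in = 0.040,
               S_an_in = 0.010,
               cod_fractions = c(ch = 0.60, pr = 0.12, li = 0.07,
                                 xi = 0.16, si = 0.05))
)

#' Named simulation scenarios
#'
#' Builds the fully specified scenarios of the study: Experiments 1-3 under
#' continuous (`_conti`) or pulsed (`_disco`) feeding of the VFA medium, and
#' the maize-silage transfer case (`maize_conti`, `maize_disco`; pulses
#' every second day). Each scenario bundles reactor configuration, parameter
#' set, feed schedule, initial state and the phase landmarks.
#'
#' @param name one of `exp1_conti`, `exp1_disco`, `exp2_conti`,
#'   `exp2_disco`, `exp3_conti`, `exp3_disco`, `maize_conti`, `maize_disco`
#' @param t_end simulation horizon, days (default: training end for the
#'   VFA experiments, 365 for maize)
#' @param disturbance_cod COD mass (g) of an overloading pulse added at the
#'   end of the training phase; `0` for none, `NULL` for the calibrated
#'   default when `disturbed = TRUE`
#' @param disturbed append the calibrated disturbance and extend the
#'   horizon two weeks past it
#' @param preset kinetic preset passed to [adm1_parameters()]
#' @return list of class `adm1_scenario` with elements `name`, `config`,
#'   `params`, `schedule`, `y0`, `t_end`, `training_end`, `disturbance_day`
#' @export
preset_scenario <- function(name = c("exp1_conti", "exp1_disco",
                                     "exp2_conti", "exp2_disco",
                                     "exp3_conti", "exp3_disco",
                                     "maize_conti", "maize_disco"),
                            t_end = NULL, disturbance_cod = NULL,
                            disturbed = FALSE,
                            preset = "this_study") {
  name <- match.arg(name)
  parts <- strsplit(name, "_")[[1]]
  exp_id <- parts[1]; regime <- parts[2]
  ex <- EXPERIMENTS[[exp_id]]
  params <- adm1_parameters(preset = preset, kLa = CAL$kLa)

  if (exp_id == "maize") {
    mc <- CAL$maize
    influent <- composite_influent(ex$total_cod, mc$cod_fractions,
                                   S_IC_in = mc$S_IC_in,
                                   S_IN_in = mc$S_IN_in,
                                   S_cat_in = mc$S_cat_in,
                                   S_an_in = mc$S_an_in)
    config <- reactor_config(ex$V_liq, ex$HRT, influent)
    ## start from a methanogenic community with a deliberately seeded
    ## Methanosarcina population of 0.2 gCOD/L
    y0 <- initial_state(inoculum_vs = ex$inoculum_vs,
                        partition = c(X_su = 0.15, X_aa = 0.06, X_fa = 0.04,
                                      X_c4 = 0.12, X_pro = 0.08,
                                      X_ac1 = 0.0705, X_ac2 = 0.30,
                                      X_h2 = 0.1795),
                        solubles = c(S_ac = 0.1, S_IC = 0.08, S_IN = 0.03,
                                     S_cat = mc$S_cat_in, S_an = mc$S_an_in))
    y0["X_ac1"] <- 0.2
    training_end <- NA_real_
    if (is.null(t_end)) t_end <- 365
  } else {
    influent <- vfa_influent(ex$total_cod,
                             S_IC_in = CAL$S_IC_in, S_IN_in = CAL$S_IN_in)
    config <- reactor_config(ex$V_liq, ex$HRT, influent)
    y0 <- initial_state(inoculum_vs = ex$inoculum_vs,
                        partition = CAL$partition,
                        solubles = c(S_ac = 0.10, S_pro = 0.05, S_bu = 0.10,
                                     S_IC = 0.10, S_IN = 0.045,
                                     S_cat = 0.0783, S_an = 0.0198))
    training_end <- 64
    if (is.null(t_end)) t_end <- if (disturbed) 78 else 64
  }

  schedule <- if (regime == "conti") continuous_schedule(config)
              else discontinuous_schedule(config, t_end = t_end,
                                          pulse_fraction = ex$pulse_fraction,
                                          period = ex$period)
  disturbance_day <- NA_real_
  if (disturbed || (!is.null(disturbance_cod) && disturbance_cod > 0)) {
    if (is.null(disturbance_cod)) disturbance_cod <- CAL$disturbance_cod
    disturbance_day <- training_end
    schedule <- add_disturbance(schedule, disturbance_day, disturbance_cod)
  }
  structure(list(name = name, config = config, params = params,
                 schedule = schedule, y0 = y0, t_end = t_end,
                 training_end = training_end,
                 disturbance_day = disturbance_day),
            class = "adm1_scenario")
}

#' Simulate a named or assembled scenario
#'
#' @param scenario an `adm1_scenario` from [preset_scenario()] (or a name
#'   accepted by it)
#' @param ... passed to [simulate_adm1()]
#' @return an `adm1_trajectory`
#' @export
run_scenario <- function(scenario, ...) {
  if (is.character(scenario)) scenario <- preset_scenario(scenario)
  simulate_adm1(scenario$config, scenario$params, scenario$schedule,
                scenario$t_end, scenario$y0, ...)
}

#' Maize-silage feeding-regime switch experiment
#'
#' Reproduces the transfer scenario: a maize-silage digester (HRT 20 days)
#' is fed continuously until quasi steady state - during which
#' Methanosaeta takes over and the initially seeded Methanosarcina
#' population (0.2 gCOD/L) declines - and is then switched to
#' discontinuous feeding every second day. Returns both phases and the
#' Methanosarcina increase factor over the discontinuous phase.
#'
#' @param conti_max maximum length of the continuous phase, days
#' @param disco_days length of the discontinuous phase, days
#' @param ... passed to the integrator (e.g. `rtol`)
#' @return list with `conti` and `disco` trajectories, `x_ac1_at_switch`,
#'   `x_ac1_final`, and `increase_factor`
#' @export
maize_switch_experiment <- function(conti_max = 300, disco_days = 365, ...) {
  sc <- preset_scenario("maize_conti")
  conti <- run_to_steady_state(sc$config, sc$params, sc$schedule, sc$y0,
                               chunk = 100, max_t = conti_max, tol = 1e-4,
                               ...)
  y <- final_state(conti)
  x0 <- y[["X_ac1"]]
  sd <- preset_scenario("maize_disco", t_end = disco_days)
  disco <- simulate_adm1(sd$config, sd$params, sd$schedule, disco_days, y,
                         ...)
  x1 <- final_state(disco)[["X_ac1"]]
  list(conti = conti, disco = disco, x_ac1_at_switch = x0,
       x_ac1_final = x1, increase_factor = x1 / x0)
}
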