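test_that("the empty reactor with no feed is a fixed point", {
  params <- adm1_parameters()
  inf <- vfa_influent(0)
  config <- reactor_config(6, 5.5, inf)
  schedule <- new_schedule(0, inf, list(), 6, 5.5)
  dy <- adm1_derivatives(0, empty_state(), config, params, schedule)
  expect_equal(max(abs(dy)), 0)
})

test_that("dilution terms reproduce q/V * (in - out) exactly", {
  params <- adm1_parameters()
  inf <- vfa_influent(37.2, S_IC_in = 0.01, S_IN_in = 0.05)
  config <- reactor_config(6, 5.5, inf)
  schedule <- continuous_schedule(config)
  # no biomass, no gas: only transport moves the soluble state
  y <- empty_state()
  y["S_ac"] <- 1; y["S_bu"] <- 2; y["S_cat"] <- 0.05; y["S_an"] <- 0.01
  dy <- adm1_derivatives(0, y, config, params, schedule)
  q <- 6 / 5.5
  expect_equal(dy[["S_ac"]], q / 6 * (inf[["S_ac"]] - 1), tolerance = 1e-12)
  expect_equal(dy[["S_bu"]], q / 6 * (inf[["S_bu"]] - 2), tolerance = 1e-12)
  expect_equal(dy[["S_cat"]], q / 6 * (inf[["S_cat"]] - 0.05),
               tolerance = 1e-12)
  expect_equal(dy[["X_su"]], 0)
})

test_that("a single acetoclastic population matches a hand-coded chemostat", {
  ## reduced oracle: dS/dt = D (Sin - S) - km S/(K+S) X
  ##                 dX/dt = (Y km S/(K+S) - kdec - D) X
  Y <- 0.033; km <- 14.5; K <- 0.09; kdec <- 0.015
  Sin <- 5; D <- 1 / 4
  oracle <- function(t, y, p) {
    mon <- y[1] / (K + y[1])
    list(c(D * (Sin - y[1]) - km * mon * y[2],
           (Y * km * mon - kdec - D) * y[2]))
  }
  times <- seq(0, 30, by = 0.5)
  ref <- deSolve::lsoda(c(S = 1, X = 0.1), times, oracle, NULL,
                        rtol = 1e-10, atol = 1e-12)

  ## full model stripped to the same physics: only X_ac2 present, pH
  ## inhibition disabled, no decay recycling (decay routed to X_c but X_c
  ## disintegration disabled via k_dis override is not exposed; instead use
  ## kdec as a pure loss by zeroing the composite pathway through f-fractions
  ## -- simpler: keep kdec but compare against an oracle including recycle?
  ## cleanest: disable decay entirely and add it to the oracle as D only.
  ov <- list(X_ac2 = population_kinetics("X_ac2", Y, km, K, kdec))
  params <- adm1_parameters(overrides = ov)
  ## make the recycle loop inert: decayed biomass accumulates as X_c only
  params$stoich$k_dis <- 0
  params$M <- build_stoichiometry(params)
  ## neutralize the nitrogen limitation/inhibition factors so the reduced
  ## two-state chemostat is the exact limit of the full model
  params$phys$K_S_IN <- 0
  params$phys$K_I_nh3 <- Inf
  inf <- vfa_influent(Sin, cod_fractions = c(ac = 1, pro = 0, bu = 0),
                      S_IC_in = 0, S_IN_in = 0.02,
                      S_cat_in = 0.0, S_an_in = 0.01)
  config <- reactor_config(4, 4, inf)  # V/HRT gives D = 1/4
  schedule <- continuous_schedule(config)
  y0 <- empty_state()
  y0["S_ac"] <- 1; y0["X_ac2"] <- 0.1
  y0["S_IN"] <- 0.02; y0["S_an"] <- 0.01
  traj <- simulate_adm1(config, params, schedule, 30, y0,
                        dt_out = 0.5, rtol = 1e-10, atol = 1e-12)
  sel <- match(times, traj$time)
  expect_equal(traj$S_ac[sel], unname(ref[, "S"]), tolerance = 1e-5)
  expect_equal(traj$X_ac2[sel], unname(ref[, "X"]), tolerance = 1e-5)
})

test_that("non-finite states are reported with the failing component", {
  params <- adm1_parameters()
  config <- reactor_config(6, 5.5, vfa_influent(37.2))
  schedule <- continuous_schedule(config)
  y <- empty_state(); y["S_ac"] <- NaN
  expect_error(adm1_derivatives(0, y, config, params, schedule), "S_ac")
})
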