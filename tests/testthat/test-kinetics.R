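kin_ac1 <- population_kinetics("X_ac1", 0.033, 20, 0.32, 0.02, 5.5, 4)
kin_ac2 <- population_kinetics("X_ac2", 0.033, 14.5, 0.09, 0.02, 7, 6.3)

test_that("Monod uptake honours its limits and examples", {
  expect_equal(monod_uptake(0, 3, kin_ac1), 0)
  # at half saturation the rate is k_m/2 per unit biomass
  expect_equal(monod_uptake(0.32, 1, kin_ac1), 10)
  expect_equal(monod_uptake(0.09, 2, kin_ac2), 14.5)
  # monotone non-decreasing in S, bounded by k_m * X * I
  S <- seq(0, 10, by = 0.1)
  r <- monod_uptake(S, 1.7, kin_ac2, I = 0.6)
  expect_true(all(diff(r) >= 0))
  expect_true(all(r <= kin_ac2$k_m * 1.7 * 0.6))
  expect_error(monod_uptake(-1, 1, kin_ac1), "non-negative")
  expect_error(monod_uptake(1, 1, kin_ac1, I = 2), "I must")
})

test_that("pH inhibition follows the lower-limit exponential form", {
  expect_equal(ph_inhibition(7.3, kin_ac1), 1)
  expect_equal(ph_inhibition(5.5, kin_ac1), 1)
  # at the lower limit the factor is exp(-3) for any guild
  expect_equal(ph_inhibition(4, kin_ac1), exp(-3))
  expect_equal(ph_inhibition(6.3, kin_ac2), exp(-3))
  # the asymmetric windows drive the niche: at pH 6.5 Methanosaeta is
  # strongly inhibited while Methanosarcina is not
  expect_equal(ph_inhibition(6.5, kin_ac2), exp(-3 * (0.5 / 0.7)^2),
               tolerance = 1e-12)
  expect_equal(ph_inhibition(6.5, kin_ac1), 1)
  # strictly decreasing below the upper limit
  pH <- seq(6.99, 5, by = -0.01)
  expect_true(all(diff(ph_inhibition(pH, kin_ac2)) < 0))
  # guilds without limits are uninhibited
  kin_free <- population_kinetics("X_pro", 0.012, 30, 0.1, 0.02)
  expect_equal(ph_inhibition(4.2, kin_free), 1)
})

test_that("washout HRT separates the fitted from the literature kinetics", {
  S_in <- 0.45 * 37.2  # acetate supplied by the VFA medium
  # oracle: explicit chemostat persistence boundary
  boundary <- function(Y, km, K, kdec)
    1 / (Y * km * S_in / (K + S_in) - kdec)
  expect_equal(washout_hrt(kin_ac2, S_in),
               boundary(0.033, 14.5, 0.09, 0.02))
  expect_lt(washout_hrt(kin_ac2, S_in), 5.5)  # persists at HRT 5.5 d
  lit_ac2 <- population_kinetics("X_ac2", 0.042, 2.77, 0.09, 0.0064)
  expect_equal(washout_hrt(lit_ac2, S_in),
               boundary(0.042, 2.77, 0.09, 0.0064))
  expect_gt(washout_hrt(lit_ac2, S_in), 5.5)  # washes out at HRT 5.5 d
  # non-growing population: decay exceeds the yield-weighted uptake
  dying <- population_kinetics("x", 0.01, 1, 0.1, 0.05)
  expect_identical(washout_hrt(dying, 100), Inf)
})
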