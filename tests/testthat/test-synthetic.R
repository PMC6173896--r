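test_that("zero-noise observations equal the trajectory samples", {
  traj <- exp1_run("conti")
  obs <- generate_observations(traj, times = c(10, 20, 40), cv = 0,
                               ph_sd = 0, seed = 1)
  for (qt in c("VFA_total", "pH", "VS_biomass")) {
    o <- obs[obs$quantity == qt, ]
    truth <- stats::approx(traj$time,
                           traj[[c(VFA_total = "vfa_total", pH = "pH",
                                   VS_biomass = "biomass_vs")[[qt]]]],
                           xout = o$time)$y
    expect_equal(o$value, truth, tolerance = 1e-12)
  }
})

test_that("observation tables are reproducible by seed", {
  traj <- exp1_run("conti")
  a <- generate_observations(traj, seed = 99)
  b <- generate_observations(traj, seed = 99)
  d <- generate_observations(traj, seed = 100)
  expect_identical(a, b)
  expect_false(identical(a$value, d$value))
  expect_error(generate_observations(traj, times = c(1, 999)),
               "outside the simulated horizon")
})

test_that("the lognormal noise model delivers the configured CV", {
  traj <- exp1_run("conti")
  # 1000 replicate draws of the same sample
  obs <- generate_observations(traj, times = rep(40, 1000),
                               quantities = "VFA_total", cv = 0.10, seed = 5)
  cv_hat <- stats::sd(obs$value) / mean(obs$value)
  expect_gt(cv_hat, 0.08)
  expect_lt(cv_hat, 0.12)
  # and the multiplicative noise is mean-preserving
  truth <- stats::approx(traj$time, traj$vfa_total, xout = 40)$y
  expect_equal(mean(obs$value), truth, tolerance = 0.02)
})

test_that("synthetic community profiles have the promised structure", {
  u <- generate_community_profiles(8, "uniform")
  expect_equal(evenness(u$abundance, 2), 1, tolerance = 1e-12)
  one <- generate_community_profiles(1, "uniform")
  for (q in c(0, 1, 2)) expect_equal(hill_diversity(one$abundance, q), 1)
  # geometric series: inverse Simpson has a closed form
  g <- generate_community_profiles(8, "geometric", ratio = 0.5)
  r <- 0.5; n <- 8
  norm <- (1 - r^n) / (1 - r)
  d2_expected <- 1 / sum(((r^(0:(n - 1))) / norm)^2)
  expect_equal(hill_diversity(g$abundance, 2), d2_expected,
               tolerance = 1e-12)
  # reproducibility and validity
  expect_identical(generate_community_profiles(12, seed = 3),
                   generate_community_profiles(12, seed = 3))
  expect_equal(sum(g$abundance), 1, tolerance = 1e-12)
  expect_true(all(g$copy_number >= 1))
})
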