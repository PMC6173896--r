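test_that("Hill numbers match brute-force formulas and known identities", {
  profiles <- random_profiles()
  for (p in profiles) {
    # q = 0: richness
    expect_equal(hill_diversity(p, 0), sum(p > 0), tolerance = 1e-12)
    # q = 1: exponentiated Shannon entropy
    expect_equal(hill_diversity(p, 1), exp(-sum(p * log(p))),
                 tolerance = 1e-12)
    # q = 2: inverse Simpson concentration
    expect_equal(hill_diversity(p, 2), 1 / sum(p^2), tolerance = 1e-12)
    # generic order against the raw power-sum formula
    expect_equal(hill_diversity(p, 0.73), sum(p^0.73)^(1 / (1 - 0.73)),
                 tolerance = 1e-12)
    # continuity at q = 1
    expect_equal(hill_diversity(p, 1 + 1e-9), hill_diversity(p, 1),
                 tolerance = 1e-6)
  }
})

test_that("Hill numbers agree with vegan on Shannon and Simpson", {
  skip_if_not_installed("vegan")
  for (p in random_profiles()[1:10]) {
    expect_equal(hill_diversity(p, 1), exp(vegan::diversity(p, "shannon")),
                 tolerance = 1e-10)
    expect_equal(hill_diversity(p, 2), vegan::diversity(p, "invsimpson"),
                 tolerance = 1e-10)
  }
})

test_that("diversity is non-increasing in q and evenness lies in (0,1]", {
  qs <- c(0, 0.5, 1, 1.5, 2, 3, 5)
  for (p in random_profiles()[1:10]) {
    d <- vapply(qs, function(q) hill_diversity(p, q), numeric(1))
    expect_true(all(diff(d) <= 1e-10))
    e <- vapply(qs, function(q) evenness(p, q), numeric(1))
    expect_true(all(e > 0 & e <= 1 + 1e-12))
    expect_equal(e[1], 1)
  }
  expect_equal(evenness(rep(0.2, 5), 2), 1)
  expect_equal(evenness(c(0.75, 0.25), 2), 1.6 / 2)
  expect_equal(hill_diversity(c(0.75, 0.25), 2), 1.6)
  expect_error(hill_diversity(c(0.5, 0.5), -1), "non-negative")
})

test_that("copy-number correction rescales and preserves normalization", {
  pr <- community_profile(c("a", "b"), c(0.5, 0.5), copy_number = c(4, 1))
  out <- copy_number_correct(pr)
  expect_equal(out$abundance, c(0.2, 0.8))
  # equal copy numbers leave the profile unchanged
  pr2 <- community_profile(letters[1:4], c(0.4, 0.3, 0.2, 0.1),
                           copy_number = rep(3, 4))
  expect_equal(copy_number_correct(pr2)$abundance, pr2$abundance)
  # idempotent once copy numbers are 1
  out$copy_number <- 1
  expect_equal(copy_number_correct(out)$abundance, out$abundance)
  expect_equal(sum(out$abundance), 1)
  # missing values fall back or error
  pr3 <- community_profile(c("a", "b"), c(0.5, 0.5),
                           copy_number = c(2, NA))
  expect_error(copy_number_correct(pr3), "fallback")
  expect_equal(copy_number_correct(pr3, fallback = 2)$abundance, c(0.5, 0.5))
})

test_that("mrtA correction halves only the two carrier orders", {
  pr <- community_profile(c("tRF1", "tRF2"), c(0.4, 0.6),
                          order = c("Methanobacteriales",
                                    "Methanosarcinales"))
  out <- mrta_correct(pr)
  expect_equal(out$abundance, c(0.25, 0.75))
  # no carriers: unchanged
  pr2 <- community_profile(c("a", "b"), c(0.3, 0.7),
                           order = rep("Methanosarcinales", 2))
  expect_equal(mrta_correct(pr2)$abundance, pr2$abundance)
  # all carriers: still normalized
  pr3 <- community_profile(c("a", "b"), c(0.3, 0.7),
                           order = rep("Methanobacteriales", 2))
  expect_equal(sum(mrta_correct(pr3)$abundance), 1)
})

test_that("the 13C pathway ratio flags the dominant acetate route", {
  r <- c13_pathway_ratio(0.03, 1.0)
  expect_equal(r$ratio, 0.03)
  expect_identical(r$pathway, "acetoclastic")
  expect_identical(c13_pathway_ratio(2, 1)$pathway, "oxidative")
  expect_identical(c13_pathway_ratio(1, 1)$pathway, "ambiguous")
  # scale invariance
  expect_equal(c13_pathway_ratio(0.3, 10)$ratio,
               c13_pathway_ratio(0.03, 1)$ratio)
  inf <- c13_pathway_ratio(1, 0)
  expect_identical(inf$ratio, Inf)
  expect_identical(inf$pathway, "oxidative")
})

test_that("VFA unit conversion reproduces the medium characterization", {
  res <- vfa_unit_convert(c(ac = 0.45, pro = 0.10, bu = 0.45), total_cod = 1)
  expect_equal(res$total_mass, 0.74, tolerance = 0.01)
  res37 <- vfa_unit_convert(total_cod = 37.2)
  expect_equal(res37$total_mass, 27.4, tolerance = 0.01)
  expect_equal(round(100 * unname(res$mol_fractions)), c(65, 8, 26))
  expect_equal(round(100 * unname(res$mass_fractions)), c(57, 9, 34))
  # round trip mass -> COD -> mass
  back <- res$mass * VFA_COD_PER_G[names(res$mass)]
  expect_equal(unname(back), unname(res$cod), tolerance = 1e-12)
  expect_error(vfa_unit_convert(c(ac = 0.5, foo = 0.5)), "unknown acid")
  expect_error(vfa_unit_convert(c(ac = 0.5, pro = 0.3)), "sum to 1")
})
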