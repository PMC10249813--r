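# Cross-section tables, interpolation, and fluorescence constants.

test_that("attenuation tables satisfy their structural invariants", {
  for (nm in c("GaAs", "Ga", "As", "Al")) {
    att <- attenuation_table(nm)
    expect_false(is.unsorted(att$energy_keV, strictly = TRUE))
    expect_true(all(att$mu_pe_cm2_g > 0))
    expect_true(all(att$mu_tot_cm2_g > 0))
    expect_true(all(att$mu_pe_cm2_g <= att$mu_tot_cm2_g))
  }
  # upward K-edge jumps in the photoelectric coefficient
  att <- attenuation_table("GaAs")
  for (ke in att$kedges_keV) {
    below <- att$mu_pe_cm2_g[max(which(att$energy_keV < ke))]
    just_above <- att$mu_pe_cm2_g[which(att$energy_keV > ke)[1]]
    expect_gt(just_above, below)
  }
})

test_that("interpolation is exact at grid points and respects K edges", {
  att <- attenuation_table("GaAs")
  i <- which(abs(att$energy_keV - 22) < 1e-9)
  expect_equal(linear_attenuation(mat, 22, "total"),
               att$mu_tot_cm2_g[i] * att$density_g_cm3 * 1e-4)
  # jump across the Ga K edge preserved
  expect_gt(linear_attenuation(mat, 10.3672, "photoelectric"),
            2 * linear_attenuation(mat, 10.3670, "photoelectric"))
  expect_error(linear_attenuation(mat, 0.5), "range")
  expect_error(linear_attenuation(mat, 75), "range")
})

test_that("GaAs attenuation matches the generating compilation at 22 keV", {
  # independent evaluation of the Cromer-Liberman + Klein-Nishina source
  mu_tot <- linear_attenuation(mat, 22, "total") / (5.3176e-4)
  expect_equal(mu_tot, 32.1914, tolerance = 0.02)
})

test_that("fluorescence mean travel distances emerge from the physics", {
  expect_equal(mean_free_path(mat, 9.25), 42, tolerance = 0.15)
  expect_equal(mean_free_path(mat, 10.54), 16, tolerance = 0.15)
  # shorter path just above the Ga K edge than just below it
  expect_lt(mean_free_path(mat, 10.3672), mean_free_path(mat, 10.3670))
  # identity with the attenuation coefficient at arbitrary energies
  E <- seq(2, 59, by = 0.37)
  expect_equal(mean_free_path(mat, E) * linear_attenuation(mat, E, "total"),
               rep(1, length(E)))
  # the material can carry table-derived travel distances instead
  m2 <- gaas_material(lambda_from_table = TRUE)
  expect_equal(m2$elements$Ga$lambda_f_um, mean_free_path(mat, 9.25))
  expect_equal(m2$elements$As$lambda_f_um, mean_free_path(mat, 10.54))
})

test_that("absorption probability behaves as a truncated Beer-Lambert law", {
  expect_identical(absorption_probability(mat, 0, 22), 0)
  expect_equal(absorption_probability(mat, 1e6, 22), 1)
  # closed form from the independently evaluated coefficient at 22 keV
  expect_equal(absorption_probability(mat, 500, 22), 0.9997997,
               tolerance = 1e-5)
  expect_error(absorption_probability(mat, -1, 22), "thickness")
})

test_that("photoelectric element shares are normalized and edge-aware", {
  E <- seq(5, 50, by = 1)
  sh <- element_shares(mat, E)
  expect_equal(rowSums(sh), rep(1, length(E)))
  expect_true(all(sh >= 0 & sh <= 1))
  # only the Ga K shell is open between the two edges
  expect_gt(element_shares(mat, 11)[, "Ga"],
            element_shares(mat, 10.3)[, "Ga"])
  expect_equal(element_shares(mat, 22)[, "Ga"], c(Ga = 0.44306),
               tolerance = 1e-4)
})

test_that("empirical element selection matches the analytic share", {
  set.seed(42)
  n <- 1e5
  el <- select_interaction_element(mat, rep(22, n), runif(n))
  p <- element_shares(mat, 22)[, "Ga"]
  expect_lt(abs(mean(el == "Ga") - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("K fluorescence emission probabilities are the constant products", {
  expect_equal(fluorescence_emission_probability(mat, "Ga"), 0.88 * 0.528)
  expect_equal(fluorescence_emission_probability(mat, "As"), 0.88 * 0.589)
  expect_error(fluorescence_emission_probability(mat, "Cd"), "unknown")
  ln <- fluorescence_lines(mat)
  expect_equal(as.numeric(tapply(ln$yield, ln$element, sum)), c(1, 1))
  # line energies lie below the element's K edge
  for (i in seq_len(nrow(ln)))
    expect_lt(ln$energy_keV[i], mat$elements[[ln$element[i]]]$kedge_keV)
})
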