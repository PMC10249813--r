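# Deterministic cascade engine.

test_that("interaction depth distribution is a normalized truncated exponential", {
  dd <- interaction_depth_distribution(mat, 22, 500)
  expect_equal(stats::integrate(dd$density, 0, 500)$value, 1,
               tolerance = 1e-6)
  # closed-form mean from the independently evaluated coefficient
  expect_equal(dd$mean, 58.616, tolerance = 1e-3)
  expect_equal(dd$quantile(0), 0)
  u <- c(0.1, 0.5, 0.9)
  z <- dd$quantile(u)
  # quantile inverts the CDF
  cdf <- vapply(z, function(zz) stats::integrate(dd$density, 0, zz)$value,
                numeric(1))
  expect_equal(cdf, u, tolerance = 1e-6)
  expect_identical(dd$density(-1), 0)
  expect_identical(dd$density(501), 0)
})

test_that("attenuation concentrates interactions at the entrance face", {
  dd5 <- interaction_depth_distribution(mat, 5, 500)   # very opaque
  expect_lt(dd5$mean, 10)
  dd40 <- interaction_depth_distribution(mat, 40, 500)
  expect_gt(dd40$mean, dd5$mean)
})

test_that("fluorescence transport kernel has the right limits and escape", {
  k0 <- fluorescence_transport_kernel(c(0, 0, 250), 0, geo)
  expect_equal(k0$p_escape, 0)
  expect_equal(k0$points$x, 0)
  expect_error(fluorescence_transport_kernel(c(0, 0, 600), 42, geo),
               "outside")
  kk <- fluorescence_transport_kernel(c(0, 0, 250), 42, geo,
                                      fast_res)
  expect_equal(kk$p_escape + sum(kk$points$weight), 1, tolerance = 1e-9)
  # seeded MC oracle for the escape probability from mid-thickness
  set.seed(123)
  n <- 2e5
  cth <- runif(n, -1, 1)
  s <- rexp(n, 1 / 42)
  zend <- 250 + s * cth
  p_mc <- mean(zend < 0 | zend > 500)
  se <- sqrt(p_mc * (1 - p_mc) / n)
  kfine <- fluorescence_transport_kernel(c(0, 0, 250), 42, geo,
    response_resolution(polar = 128, azimuth = 16, path = 64))
  expect_lt(abs(kfine$p_escape - p_mc), 3 * se + 2e-3)
})

test_that("electronic noise blur preserves mass and composes in quadrature", {
  edges <- gaaspcd:::.internal_grid()
  nb <- length(edges) - 1
  delta <- matrix(0, 1, nb)
  delta[1, findInterval(22, edges)] <- 1
  expect_identical(gaaspcd:::.noise_blur(delta, 0, edges), delta)
  b <- gaaspcd:::.noise_blur(delta, 2.1, edges)
  expect_equal(sum(b), 1, tolerance = 1e-9)
  # Gaussian centered at the source bin midpoint with sd 2.1
  mids <- gaaspcd:::grid_mid(edges)
  m0 <- mids[findInterval(22, edges)]
  expected <- stats::pnorm(edges[-1], m0, 2.1) -
    stats::pnorm(edges[-length(edges)], m0, 2.1)
  expect_equal(b[1, ], expected, tolerance = 1e-12)
  # two blurs equal one blur with sigma in quadrature (up to grid width)
  b12 <- gaaspcd:::.noise_blur(gaaspcd:::.noise_blur(delta, 1.2, edges),
                               0.9, edges)
  b1 <- gaaspcd:::.noise_blur(delta, sqrt(1.2^2 + 0.9^2), edges)
  expect_lt(max(abs(b12 - b1)), 2e-3)
})

test_that("probabilities and energy are conserved by the cascade", {
  r <- compute_response(22, geo, model_params(11, 2.1), mat, fast_res)
  expect_equal(probability_ledger(r)$total, 1, tolerance = 1e-12)
  expect_equal(sum(r$outcomes$prob) + r$ledger$transmission, 1,
               tolerance = 1e-9)
  # per outcome, deposits plus escaped/truncated energy give back E
  expect_equal(outcome_total(r), rep(22, nrow(r$outcomes)),
               tolerance = 1e-9)
  # below both K edges there is no fluorescence branch, but it still runs
  r9 <- compute_response(9, geo, model_params(11, 2.1), mat, fast_res)
  expect_length(r9$ledger$branches, 0)
  expect_equal(sum(r9$outcomes$prob) + r9$ledger$transmission, 1,
               tolerance = 1e-9)
  expect_equal(outcome_total(r9), rep(9, nrow(r9$outcomes)),
               tolerance = 1e-9)
})

test_that("with no sharing and no noise every deposit is a full-energy delta", {
  r <- compute_response(9, geo, model_params(0, 0), mat, fast_res)
  oc <- as.matrix(r$outcomes[, paste0("d", 1:9), with = FALSE])
  expect_true(all(rowSums(oc > 0) == 1))
  expect_equal(oc[oc > 0], rep(9, sum(oc > 0)))
  spec <- recorded_spectrum(r)
  nz <- which(spec$values > 0)
  expect_length(nz, 1)
  expect_true(spec$edges[nz] <= 9 && spec$edges[nz + 1] > 9)
})

test_that("escape structure appears at 22 keV and not below the Ga K edge", {
  r <- compute_response(22, geo, model_params(11, 0.5), mat, mid_res,
                        level = "marginal")
  spec <- recorded_spectrum(r)
  mids <- gaaspcd:::grid_mid(spec$edges)
  v <- spec$values
  is_peak <- function(target, halfwidth = 0.8) {
    win <- which(abs(mids - target) <= halfwidth)
    i <- win[which.max(v[win])]
    v[i] > v[i - 2] && v[i] > v[i + 2]
  }
  expect_true(is_peak(22))
  expect_true(is_peak(22 - 9.25))   # Ga K-alpha escape
  expect_true(is_peak(22 - 10.54))  # As K-alpha escape
  # below the Ga K edge: single photopeak, no escape replica
  r9 <- compute_response(9, geo, model_params(11, 0.5), mat, mid_res,
                         level = "marginal")
  v9 <- recorded_spectrum(r9)$values
  m9 <- gaaspcd:::grid_mid(gaaspcd:::.internal_grid())
  # all mass lies in the sharing continuum plus photopeak: no local
  # maximum away from 9 keV above 1% of the peak
  pk <- max(v9)
  interior <- which(m9 > 1.5 & m9 < 7.5)
  loc <- interior[v9[interior] > 0.01 * pk &
                  v9[interior] > v9[interior - 2] &
                  v9[interior] > v9[interior + 2]]
  expect_length(loc, 0)
})

test_that("the response respects the 8-fold symmetry of the neighborhood", {
  r <- compute_response(22, geo, model_params(11, 2.1), mat, fast_res,
                        level = "marginal")
  mass <- rowSums(r$deposit)
  edgesn <- mass[c(2, 4, 6, 8)]
  corners <- mass[c(1, 3, 7, 9)]
  expect_lt(diff(range(edgesn)) / mean(edgesn), 1e-9)
  expect_lt(diff(range(corners)) / mean(corners), 1e-9)
})

test_that("larger charge clouds share more with the neighbors", {
  m5 <- compute_response(22, geo, model_params(5, 0), mat, fast_res,
                         level = "marginal")
  m13 <- compute_response(22, geo, model_params(13, 0), mat, fast_res,
                          level = "marginal")
  nb5 <- sum(m5$deposit[-5, ])
  nb13 <- sum(m13$deposit[-5, ])
  expect_gt(nb13, nb5)
})

test_that("count covariance has the required matrix structure", {
  r <- compute_response(22, geo, model_params(11, 2.1), mat, fast_res)
  cv <- compute_count_covariance(r, energy_grid(5, 29, 6))
  expect_equal(cv$cov, t(cv$cov))
  v <- diag(cv$cov)
  expect_true(all(abs(diag(cv$cor)[v > 1e-15] - 1) < 1e-9))
  expect_gt(min(eigen(cv$cov, symmetric = TRUE,
                      only.values = TRUE)$values), -1e-9)
  # no sharing, no fluorescence: counts are mutually exclusive across
  # pixels, so pixel-pixel covariances cannot be positive
  r0 <- compute_response(9, geo, model_params(0, 0), mat, fast_res)
  cv0 <- compute_count_covariance(r0, energy_grid(5, 29, 6))
  nw <- 4
  for (t1 in 1:8) for (t2 in (t1 + 1):9) {
    blk <- cv0$cov[(t1 - 1) * nw + 1:nw, (t2 - 1) * nw + 1:nw]
    expect_true(all(blk <= 1e-12))
  }
})

test_that("count covariance matches a Monte Carlo estimate", {
  # r0 = 0 keeps the charge geometry trivial so the comparison probes the
  # fluorescence cascade and the noise model
  par0 <- model_params(0, 2.1)
  r <- compute_response(22, geo, par0, mat, mid_res)
  win <- energy_grid(5, 29, 4)
  cv <- compute_count_covariance(r, win)
  n <- 2e5
  ev <- simulate_events(n, 22, geo, par0, mat, seed = 31)
  set.seed(77)
  dep <- ev$deposits
  rec <- dep
  act <- dep > 0
  rec[act] <- dep[act] + rnorm(sum(act), 0, 2.1)
  nw <- length(win) - 1
  X <- matrix(0, n, 9 * nw)
  for (t in 1:9) {
    b <- findInterval(rec[, t], win, left.open = TRUE)
    b[!act[, t]] <- 0
    ok <- b >= 1 & b <= nw
    X[cbind(which(ok), (t - 1) * nw + b[ok])] <- 1
  }
  mu_mc <- colMeans(X)
  se_mu <- sqrt(pmax(mu_mc * (1 - mu_mc), 1e-12) / n)
  z_mu <- abs(cv$mean - mu_mc) / pmax(se_mu, 1e-6)
  expect_gt(mean(z_mu < 3.5), 0.95)
  expect_lt(max(z_mu), 8)
  C_mc <- stats::cov(X) * (n - 1) / n
  # conservative per-entry scale for covariance sampling noise
  se_c <- sqrt((pmax(outer(mu_mc, mu_mc), 1e-10)) / n) + 2e-4
  z_c <- abs(cv$cov - C_mc) / se_c
  expect_gt(mean(z_c < 3.5), 0.95)
})

test_that("expected event counts match the no-sharing limit", {
  r <- compute_response(9, geo, model_params(0, 0), mat, fast_res)
  ec <- expected_event_counts(r, c(5, 7, 11))
  expect_equal(ec$n_multiple, rep(0, 3))
  expect_equal(ec$n_single[1:2], rep(r$ledger$p_abs, 2), tolerance = 1e-9)
  expect_equal(ec$n_single[3], 0)
})
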