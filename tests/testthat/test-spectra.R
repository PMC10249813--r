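# Spectrum containers, fixtures, sweeps, and comparison metrics.

test_that("Cd-109 fixture is a unit-weight 22 keV line that round-trips", {
  s <- make_cd109_spectrum()
  nz <- which(s$values > 0)
  expect_length(nz, 1)
  expect_true(s$edges[nz] <= 22 && s$edges[nz + 1] > 22)
  expect_equal(sum(s$values), 1)
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$edges, s$edges)
  expect_equal(s2$values, s$values)
})

test_that("tungsten fixture has endpoint, hardening, and kVp ordering", {
  w30 <- make_tungsten_spectrum(30)
  mids <- gaaspcd:::grid_mid(w30$edges)
  expect_true(all(w30$values[mids >= 30] == 0))
  expect_equal(max(w30$values), 1)
  # more filtration suppresses the soft half relative to the hard half
  soft <- function(s) {
    m <- gaaspcd:::grid_mid(s$edges)
    sum(s$values[m < 15]) / sum(s$values[m >= 15])
  }
  expect_gt(soft(make_tungsten_spectrum(30, 1)),
            soft(make_tungsten_spectrum(30, 4)))
  expect_gt(mean_energy(make_tungsten_spectrum(40)),
            mean_energy(make_tungsten_spectrum(30)))
})

test_that("folding a spectrum through the response is linear and consistent", {
  sr <- spectral_response(c(8, 9), geo, model_params(11, 1.5), mat,
                          fast_res)
  edges <- gaaspcd:::.incident_grid()
  mk <- function(w8, w9) {
    v <- numeric(length(edges) - 1)
    v[findInterval(8, edges)] <- w8
    v[findInterval(9, edges)] <- w9
    spectrum(edges, v)
  }
  s1 <- apply_response_to_spectrum(mk(1, 0), sr)
  s2 <- apply_response_to_spectrum(mk(0, 1), sr)
  s12 <- apply_response_to_spectrum(mk(2, 3), sr)
  expect_equal(s12$values, 2 * s1$values + 3 * s2$values, tolerance = 1e-12)
  # monochromatic folding reproduces the single-energy recorded spectrum
  r9 <- compute_response(9, geo, model_params(11, 1.5), mat, fast_res,
                         level = "marginal")
  expect_equal(s2$values, recorded_spectrum(r9)$values, tolerance = 1e-12)
  # energies outside the response nodes are a grid mismatch
  bad <- numeric(length(edges) - 1)
  bad[findInterval(14, edges)] <- 1
  expect_error(apply_response_to_spectrum(spectrum(edges, bad), sr),
               "mismatch")
})

test_that("near-unity quantum efficiency reproduces the incident line", {
  # no sharing, no noise, sub-K-edge: the detector records the input
  sr <- spectral_response(9, geo, model_params(0, 0), mat, fast_res)
  edges <- gaaspcd:::.incident_grid()
  v <- numeric(length(edges) - 1)
  v[findInterval(9, edges)] <- 1
  out <- apply_response_to_spectrum(spectrum(edges, v), sr)
  expect_equal(sum(out$values), 1, tolerance = 1e-4)
  expect_equal(sum(out$values[gaaspcd:::grid_mid(out$edges) > 8.5 &
                              gaaspcd:::grid_mid(out$edges) < 9.5]), 1,
               tolerance = 1e-4)
})

test_that("threshold sweep integrates strictly above threshold", {
  g <- energy_grid(0, 30, 0.5)
  v <- numeric(60); v[45] <- 3  # bin [22, 22.5)
  s <- spectrum(g, v)
  sw <- threshold_sweep(s, c(1, 15, 22, 22.5, 29))
  expect_equal(sw$counts, c(3, 3, 3, 0, 0))
  expect_true(all(diff(sw$counts) <= 0))
  expect_error(threshold_sweep(s, c(5, 3)), "increasing")
})

test_that("sweep differentiation recovers the rebinned spectrum exactly", {
  set.seed(8)
  thr <- seq(5, 29, 2)
  g <- energy_grid(0, 40, 0.5)
  v <- rpois(80, 4)
  s <- spectrum(g, v)
  d <- differentiate_sweep(threshold_sweep(s, thr))
  mids <- gaaspcd:::grid_mid(g)
  manual <- vapply(seq_len(length(thr) - 1), function(i)
    sum(v[mids > thr[i] & mids < thr[i + 1]]), numeric(1))
  expect_equal(d$values, manual)
  # telescoping identity
  sw <- threshold_sweep(s, thr)
  expect_equal(sum(d$values), sw$counts[1] - sw$counts[length(thr)])
  # noise-free line: a single nonzero differentiated bin
  vl <- numeric(80); vl[45] <- 1
  dl <- differentiate_sweep(threshold_sweep(spectrum(g, vl), thr))
  expect_equal(which(dl$values > 0), 9)  # the [21, 23) bin
})

test_that("NRMSE matches its closed forms and excludes zero bins", {
  g <- energy_grid(5, 29, 2)
  a <- spectrum(g, rep(2, 12))
  expect_equal(nrmse(a, a), 0)
  b <- spectrum(g, rep(2, 12) * 1.1)
  expect_equal(nrmse(b, a), 0.1, tolerance = 1e-12)
  # random cases against a direct evaluation of the formula
  set.seed(11)
  for (i in 1:100) {
    im <- runif(12, 0.5, 2); is_ <- runif(12, 0.5, 2)
    expect_equal(nrmse(spectrum(g, im), spectrum(g, is_)),
                 sqrt(mean(((im - is_) / is_)^2)), tolerance = 1e-12)
  }
  z <- spectrum(g, c(0, rep(1, 11)))
  expect_warning(val <- nrmse(a, z), "zero simulated")
  expect_equal(val, sqrt(mean(((rep(2, 11) - 1) / 1)^2)))
})

test_that("NCC is a bounded, affine-invariant correlation", {
  g <- energy_grid(5, 29, 2)
  set.seed(12)
  a <- spectrum(g, runif(12))
  expect_equal(normalized_cross_correlation(a, a), 1)
  flip <- spectrum(g, max(a$values) - a$values)
  expect_equal(normalized_cross_correlation(a, flip), -1)
  b <- spectrum(g, 0.3 * a$values + 2)
  expect_equal(normalized_cross_correlation(a, b), 1)
  for (i in 1:50) {
    x <- spectrum(g, runif(12)); y <- spectrum(g, runif(12))
    val <- normalized_cross_correlation(x, y)
    expect_gte(val, -1); expect_lte(val, 1)
  }
  expect_error(normalized_cross_correlation(a, spectrum(g, rep(1, 12))),
               "constant")
  expect_error(normalized_cross_correlation(a,
               spectrum(energy_grid(5, 17, 1), runif(12))), "grid")
})

test_that("sweep CSV round-trips", {
  sw <- structure(data.frame(threshold = seq(5, 29, 2),
                             counts = rev(cumsum(runif(13)))),
                  class = c("pcd_sweep", "data.frame"))
  path <- tempfile(fileext = ".csv")
  write_sweep_csv(sw, path)
  sw2 <- read_sweep_csv(path)
  expect_equal(sw2$threshold, sw$threshold)
  expect_equal(sw2$counts, sw$counts, tolerance = 1e-9)
})
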