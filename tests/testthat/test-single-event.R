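# Cluster classification and the single-event spectral estimators.

mkframe <- function(rows, cols) data.frame(row_ = rows, col_ = cols)

test_that("frame classification finds 8-connected clusters", {
  expect_identical(nrow(classify_frame(mkframe(integer(0), integer(0)))), 0L)
  one <- classify_frame(mkframe(10, 10))
  expect_equal(one$size, 1L)
  block <- classify_frame(mkframe(c(5, 5, 6, 6), c(7, 8, 7, 8)))
  expect_equal(block$size, 4L)
  # diagonal pixels are adjacent (corner contact)
  diag2 <- classify_frame(mkframe(c(5, 6), c(7, 8)))
  expect_equal(diag2$size, 2L)
  # separated pixels are distinct clusters
  two <- classify_frame(mkframe(c(5, 9), c(7, 7)))
  expect_equal(sort(two$size), c(1L, 1L))
})

test_that("event counting sums cluster classes over frames", {
  fr <- simulate_frames(50, 0, 22, geo, model_params(11, 2.1), mat,
                        seed = 4)
  cts <- count_events(fr, 5)
  expect_identical(cts$n_single, 0L)
  expect_identical(cts$n_multiple, 0L)
  sw <- count_events_sweep(fr, c(5, 15))
  expect_equal(sw$n_single, c(0, 0))
})

test_that("counting is invariant under frame relabeling", {
  fr <- simulate_frames(100, 4, 22, geo, model_params(11, 2.1), mat,
                        seed = 6)
  cts <- count_events(fr, 10)
  perm <- data.table::copy(data.table::as.data.table(fr))
  relab <- sample(max(perm$frame))
  perm[, frame := relab[frame]]
  cts2 <- count_events(perm, 10)
  expect_identical(cts$n_single, cts2$n_single)
  expect_identical(cts$n_multiple, cts2$n_multiple)
})

test_that("the central/neighbor estimators are exact identities", {
  thr <- seq(5, 29, 2)
  set.seed(10)
  ns <- rev(cumsum(rpois(13, 30)))
  nm <- rev(cumsum(rpois(13, 8)))
  counts <- data.frame(threshold = thr, n_single = ns, n_multiple = nm)
  est <- estimate_central_neighbor(counts, normalize = FALSE)
  expect_equal(est$central$counts, ns + nm)
  expect_equal(est$neighbor$counts, nm)
  expect_equal(est$central_spectrum$values, -diff(ns + nm))
  expect_equal(est$neighbor_spectrum$values, -diff(nm))
  # I_central >= I_neighbor at every threshold
  expect_true(all(est$central$counts >= est$neighbor$counts))
  # shared normalization factor
  estn <- estimate_central_neighbor(counts)
  k <- max(-diff(ns + nm))
  expect_equal(estn$central_spectrum$values, -diff(ns + nm) / k)
  expect_equal(estn$neighbor_spectrum$values, -diff(nm) / k)
  expect_equal(max(estn$central_spectrum$values), 1)
  # no multiples: neighbor spectrum identically zero
  est0 <- estimate_central_neighbor(
    data.frame(threshold = thr, n_single = ns, n_multiple = 0))
  expect_true(all(est0$neighbor_spectrum$values == 0))
  expect_error(estimate_central_neighbor(
    data.frame(threshold = thr, n_single = 0, n_multiple = 0)), "zero")
})

test_that("frames round-trip through the sparse CSV format", {
  fr <- simulate_frames(30, 4, 22, geo, model_params(11, 2.1), mat,
                        seed = 8)
  path <- tempfile(fileext = ".csv")
  write_frames_csv(fr, path)
  fr2 <- read_frames_csv(path, n_frames = 30)
  cts <- count_events_sweep(fr, c(5, 15))
  cts2 <- count_events_sweep(fr2, c(5, 15))
  expect_equal(cts, cts2)
})
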