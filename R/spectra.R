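# Spectrum containers, incident-spectrum fixture generators, threshold
# sweeps, and spectrum comparison metrics.

#' Binned spectrum
#'
#' A spectrum on a uniform energy grid: strictly increasing bin edges and
#' one non-negative value (counts or relative fluence) per bin.
#'
#' @param edges bin edges in keV (length nbins + 1), or a `pcd_grid`.
#' @param values non-negative bin values (length nbins).
#' @param normalization `"raw"` or `"max"` (maximum scaled to 1).
#' @return an object of class `pcd_spectrum`.
#' @export
spectrum <- function(edges, values, normalization = c("raw", "max")) {
  normalization <- match.arg(normalization)
  edges <- as.numeric(edges)
  if (is.unsorted(edges, strictly = TRUE)) stop("edges must be increasing")
  if (length(values) != length(edges) - 1)
    stop("values must have one entry per bin")
  if (any(values < 0)) stop("spectrum values must be >= 0")
  structure(list(edges = edges, values = as.numeric(values),
                 normalization = normalization), class = "pcd_spectrum")
}

#' @export
print.pcd_spectrum <- function(x, ...) {
  cat(sprintf("<pcd_spectrum> %d bins, %g-%g keV, total %.4g (%s)\n",
              length(x$values), min(x$edges), max(x$edges), sum(x$values),
              x$normalization))
  invisible(x)
}

#' Normalize a spectrum to its maximum value
#'
#' @param spec a `pcd_spectrum`.
#' @return the spectrum scaled so its maximum bin equals 1.
#' @export
max_normalize <- function(spec) {
  stopifnot(inherits(spec, "pcd_spectrum"))
  m <- max(spec$values)
  if (m <= 0) stop("cannot max-normalize an all-zero spectrum")
  spectrum(spec$edges, spec$values / m, "max")
}

#' Mean energy of a spectrum
#' @param spec a `pcd_spectrum`.
#' @return value-weighted mean of the bin midpoints, keV.
#' @export
mean_energy <- function(spec) {
  stats::weighted.mean(grid_mid(spec$edges), spec$values)
}

# standard incident grid: 0.5-keV bins centered on multiples of 0.5 keV,
# so nominal line energies and response node energies are bin midpoints
.incident_grid <- function(to = 60) seq(-0.25, to + 0.25, by = 0.5)

#' Cd-109 line spectrum fixture
#'
#' Monochromatic 22 keV line (the principal Ag K-alpha emission following
#' Cd-109 decay) with unit weight, on the standard incident grid.
#'
#' @return a `pcd_spectrum` with a single nonzero bin centered at 22 keV.
#' @export
make_cd109_spectrum <- function() {
  edges <- .incident_grid()
  v <- numeric(length(edges) - 1)
  v[findInterval(22, edges)] <- 1
  spectrum(edges, v)
}

#' Filtered tungsten-anode spectrum fixture
#'
#' Analytic bremsstrahlung fixture: a Kramers-type shape
#' `(kVp - E) / E` multiplied by the transmission of an aluminum filter,
#' zero at and above the tube potential, max-normalized. This is a test
#' and demonstration fixture with a realistic mammography-range shape,
#' not a calibrated source model.
#'
#' @param kvp tube potential in kV (30-45 covers the use cases here).
#' @param filtration_mm_al aluminum filtration thickness in mm.
#' @return a max-normalized `pcd_spectrum` on the standard incident grid.
#' @export
make_tungsten_spectrum <- function(kvp, filtration_mm_al = 2.7) {
  stopifnot(kvp > 10)
  edges <- .incident_grid(min(60, max(50, kvp + 5)))
  mids <- grid_mid(edges)
  al <- attenuation_table("Al")
  v <- numeric(length(mids))
  emin <- min(al$energy_keV)
  ok <- mids > emin & mids < kvp
  mu <- linear_attenuation(al, mids[ok], "total")        # per um
  v[ok] <- (kvp - mids[ok]) / mids[ok] *
    exp(-mu * filtration_mm_al * 1000)
  max_normalize(spectrum(edges, v))
}

#' Fold an incident spectrum through the detector response
#'
#' Linear superposition of the per-energy recorded spectra of a
#' `pcd_spectral_response`, weighted by the incident bin values, for one
#' pixel offset of the 3x3 neighborhood. The incident bin midpoints must
#' coincide with the response's incident energy nodes.
#'
#' @param incident a `pcd_spectrum` (relative fluence per bin).
#' @param sresp a `pcd_spectral_response` from [spectral_response()].
#' @param offset integer `(di, dj)` pixel offset, default the central
#'   pixel.
#' @return a `pcd_spectrum` of recorded counts per unit incident weight,
#'   on the internal recorded-energy grid.
#' @export
apply_response_to_spectrum <- function(incident, sresp, offset = c(0, 0)) {
  stopifnot(inherits(incident, "pcd_spectrum"),
            inherits(sresp, "pcd_spectral_response"))
  mids <- grid_mid(incident$edges)
  keep <- incident$values > 0
  pos <- match(round(mids[keep], 6), round(sresp$energies, 6))
  if (anyNA(pos))
    stop("incident spectrum has weight at energies not covered by the ",
         "response (grid mismatch)")
  t <- .offset_index(offset)
  vals <- colSums(matrix(sresp$recorded[pos, t, ], nrow = length(pos)) *
                    incident$values[keep])
  spectrum(sresp$grid, vals)
}

.offset_index <- function(offset) {
  off <- .offsets3()
  t <- which(off$di == offset[1] & off$dj == offset[2])
  if (!length(t)) stop("offset must lie in the 3x3 neighborhood")
  t
}

#' Multi-energy spectral response
#'
#' Runs the deterministic cascade at each incident energy node and stacks
#' the per-pixel deposit and recorded (post-noise) spectra.
#'
#' @param energies incident energy nodes in keV.
#' @param geometry,params,material,res as in [compute_response()].
#' @return an object of class `pcd_spectral_response` with `energies`,
#'   `grid` (recorded-energy bin edges), and `deposit` / `recorded`
#'   arrays of dimension (energy, pixel, bin).
#' @export
spectral_response <- function(energies, geometry = detector_geometry(),
                              params = model_params(),
                              material = gaas_material(),
                              res = response_resolution()) {
  grid <- .internal_grid()
  nb <- length(grid) - 1
  dep <- rec <- array(0, c(length(energies), 9, nb))
  for (i in seq_along(energies)) {
    r <- compute_response(energies[i], geometry, params, material, res,
                          level = "marginal")
    dep[i, , ] <- r$deposit
    rec[i, , ] <- r$recorded
  }
  structure(list(energies = energies, grid = grid, deposit = dep,
                 recorded = rec, geometry = geometry, params = params,
                 res = res),
            class = "pcd_spectral_response")
}

#' Recorded spectrum of a single-energy response
#'
#' @param response a `pcd_response`.
#' @param offset integer `(di, dj)` pixel offset.
#' @return a `pcd_spectrum` on the internal recorded-energy grid.
#' @export
recorded_spectrum <- function(response, offset = c(0, 0)) {
  spectrum(response$grid, response$recorded[.offset_index(offset), ])
}

#' Threshold sweep of a recorded spectrum
#'
#' Counts above each comparator threshold (strictly greater), integrating
#' the recorded spectrum over all bins whose lower edge is at or above
#' the threshold.
#'
#' @param spec a `pcd_spectrum` of recorded counts.
#' @param thresholds strictly increasing thresholds in keV.
#' @return an object of class `pcd_sweep`: data.frame with `threshold`
#'   and `counts`.
#' @export
threshold_sweep <- function(spec, thresholds) {
  stopifnot(inherits(spec, "pcd_spectrum"))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  lo <- spec$edges[-length(spec$edges)]
  counts <- vapply(thresholds, function(Tk) sum(spec$values[lo >= Tk]),
                   numeric(1))
  structure(data.frame(threshold = thresholds, counts = counts),
            class = c("pcd_sweep", "data.frame"))
}

#' Differentiate a threshold sweep into a binned spectrum
#'
#' Differences of counts at successive thresholds: the bin between
#' thresholds i and i+1 receives `counts(T_i) - counts(T_i+1)`, the
#' standard reconstruction of a spectrum from threshold-scan images.
#'
#' @param sweep a `pcd_sweep` (or data.frame with `threshold`, `counts`).
#' @return a `pcd_spectrum` with the thresholds as bin edges. Negative
#'   differences (possible in noisy measured sweeps) are kept, so the
#'   telescoping identity `sum = counts(T_min) - counts(T_max)` is exact.
#' @export
differentiate_sweep <- function(sweep) {
  if (nrow(sweep) < 2) stop("need at least two thresholds")
  structure(list(edges = as.numeric(sweep$threshold),
                 values = -diff(sweep$counts), normalization = "raw"),
            class = "pcd_spectrum")
}

#' Normalized root mean square error between two spectra
#'
#' `sqrt(mean(((Im - Is) / Is)^2))` over the common bins, where `Im` is
#' the measured and `Is` the simulated spectrum. Bins where the simulated
#' spectrum is zero are excluded (with a warning) because the relative
#' error is undefined there.
#'
#' @param measured,simulated `pcd_spectrum`s on the same grid.
#' @return the NRMSE (dimensionless fraction).
#' @export
nrmse <- function(measured, simulated) {
  .check_same_grid(measured, simulated)
  im <- measured$values; is_ <- simulated$values
  bad <- is_ == 0
  if (any(bad & im != 0))
    warning(sum(bad & im != 0),
            " bin(s) with zero simulated value excluded from NRMSE")
  use <- !bad
  if (!any(use)) stop("no usable bins for NRMSE")
  sqrt(mean(((im[use] - is_[use]) / is_[use])^2))
}

#' Normalized cross correlation between two spectra
#'
#' Pearson correlation of the bin values at zero lag: zero-mean,
#' unit-norm dot product. Invariant under affine rescaling of either
#' spectrum.
#'
#' @param a,b `pcd_spectrum`s on the same grid.
#' @return correlation in `[-1, 1]`.
#' @export
normalized_cross_correlation <- function(a, b) {
  .check_same_grid(a, b)
  if (stats::sd(a$values) == 0 || stats::sd(b$values) == 0)
    stop("normalized cross correlation undefined for a constant spectrum")
  stats::cor(a$values, b$values)
}

.check_same_grid <- function(a, b) {
  if (length(a$edges) != length(b$edges) ||
      max(abs(a$edges - b$edges)) > 1e-9)
    stop("spectra are not on the same energy grid")
}

#' Read/write spectra and sweeps as CSV
#'
#' Spectrum CSV columns: `energy_keV` (bin midpoint), `value`; bins must
#' be uniform. Sweep CSV columns: `threshold_keV`, `counts`.
#'
#' @param spec a `pcd_spectrum`.
#' @param path file path.
#' @return `read_spectrum_csv` returns a `pcd_spectrum`; writers return
#'   the path invisibly.
#' @export
write_spectrum_csv <- function(spec, path) {
  utils::write.csv(data.frame(energy_keV = grid_mid(spec$edges),
                              value = spec$values),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("energy_keV", "value") %in% names(d)))
    stop("spectrum CSV needs columns energy_keV, value: ", path)
  mids <- d$energy_keV
  if (length(mids) < 2) stop("spectrum CSV needs at least two bins")
  by <- diff(mids)
  if (max(abs(by - by[1])) > 1e-9) stop("spectrum CSV grid is not uniform")
  edges <- c(mids - by[1] / 2, mids[length(mids)] + by[1] / 2)
  spectrum(edges, d$value)
}

#' @rdname write_spectrum_csv
#' @param sweep a `pcd_sweep`.
#' @export
write_sweep_csv <- function(sweep, path) {
  utils::write.csv(data.frame(threshold_keV = sweep$threshold,
                              counts = sweep$counts),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_sweep_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("threshold_keV", "counts") %in% names(d)))
    stop("sweep CSV needs columns threshold_keV, counts: ", path)
  structure(data.frame(threshold = d$threshold_keV, counts = d$counts),
            class = c("pcd_sweep", "data.frame"))
}
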