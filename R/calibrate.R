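# Grid-search calibration of (r0, sigma_e) against a reference
# threshold-differentiated spectrum, scored by normalized cross
# correlation.

#' Simulated threshold-differentiated spectra over a parameter grid
#'
#' Precomputes, for every `r0` in the grid, the pre-noise central-pixel
#' deposit spectrum at the given incident energy, then applies each
#' `sigma_e` by Gaussian convolution, forms the threshold sweep, and
#' differentiates it. Because the electronic noise enters only through
#' the final convolution, the expensive cascade runs once per `r0`
#' rather than once per grid point.
#'
#' @param E incident energy in keV (22 for a Cd-109 source).
#' @param geometry a `pcd_geometry`.
#' @param material a `pcd_material`.
#' @param r0_grid charge-cloud radii in micrometers.
#' @param sigma_grid electronic noise values in keV.
#' @param thresholds threshold ladder in keV.
#' @param res a `pcd_resolution`.
#' @return an object of class `pcd_sim_grid`: list with `points`
#'   (data.table `r0`, `sigma_e`) and `spectra` (matrix, one row per grid
#'   point, columns = differentiated bins), plus the grid metadata.
#' @export
simulate_sweep_grid <- function(E = 22, geometry = detector_geometry(),
                                material = gaas_material(),
                                r0_grid = seq(5, 15, by = 1),
                                sigma_grid = seq(0.5, 2.5, by = 0.1),
                                thresholds = seq(5, 30, by = 2),
                                res = response_resolution()) {
  grid <- .internal_grid()
  pts <- data.table::CJ(sigma_e = sigma_grid, r0 = r0_grid)
  data.table::setcolorder(pts, c("r0", "sigma_e"))
  data.table::setorder(pts, r0, sigma_e)
  spectra <- matrix(0, nrow(pts), length(thresholds) - 1)
  for (r0 in r0_grid) {
    rsp <- compute_response(E, geometry, model_params(r0, 0), material,
                            res, level = "marginal")
    dep_c <- rsp$deposit[.offset_index(c(0, 0)), , drop = FALSE]
    for (s in sigma_grid) {
      rec <- .noise_blur(dep_c, s, grid)[1, ]
      sw <- threshold_sweep(spectrum(grid, rec), thresholds)
      i <- which(pts$r0 == r0 & abs(pts$sigma_e - s) < 1e-9)
      spectra[i, ] <- differentiate_sweep(sw)$values
    }
  }
  structure(list(points = pts, spectra = spectra, E = E,
                 thresholds = thresholds, geometry = geometry, res = res),
            class = "pcd_sim_grid")
}

#' Grid-search calibration of the charge-cloud radius and electronic noise
#'
#' Scores every (r0, sigma_e) grid point by the normalized cross
#' correlation between the reference threshold-differentiated spectrum
#' and the simulated one, and returns the full NCC surface and its
#' argmax. Ties are broken toward the smallest `r0`, then the smallest
#' `sigma_e`. NCC is invariant to rescaling, so raw and max-normalized
#' references give identical surfaces.
#'
#' @param reference a `pcd_spectrum` on the threshold-differentiated grid
#'   (bin edges equal to the thresholds of the simulation grid).
#' @param sims a `pcd_sim_grid` from [simulate_sweep_grid()], or `NULL`
#'   to compute one with the remaining arguments.
#' @param ... passed to [simulate_sweep_grid()] when `sims` is `NULL`.
#' @return an object of class `pcd_gridsearch`: list with `surface`
#'   (data.table `r0`, `sigma_e`, `ncc`), `best` (list `r0`, `sigma_e`,
#'   `ncc`), and the grid metadata.
#' @export
grid_search <- function(reference, sims = NULL, ...) {
  stopifnot(inherits(reference, "pcd_spectrum"))
  if (is.null(sims)) sims <- simulate_sweep_grid(...)
  if (length(reference$values) != ncol(sims$spectra))
    stop("reference spectrum is not on the threshold-differentiated grid")
  if (stats::sd(reference$values) == 0)
    stop("normalized cross correlation undefined for a constant reference")
  ref <- reference$values
  nccs <- apply(sims$spectra, 1, function(v) {
    if (stats::sd(v) == 0) return(NA_real_)
    stats::cor(ref, v)
  })
  surface <- data.table::data.table(sims$points, ncc = nccs)
  ord <- order(-surface$ncc, surface$r0, surface$sigma_e)
  best <- surface[ord[1]]
  structure(list(surface = surface,
                 best = list(r0 = best$r0, sigma_e = best$sigma_e,
                             ncc = best$ncc),
                 E = sims$E, thresholds = sims$thresholds),
            class = "pcd_gridsearch")
}

#' @export
print.pcd_gridsearch <- function(x, ...) {
  cat(sprintf("<pcd_gridsearch> %d grid points, E = %g keV\n",
              nrow(x$surface), x$E))
  cat(sprintf("  best: r0 = %g um, sigma_e = %g keV (NCC = %.5f)\n",
              x$best$r0, x$best$sigma_e, x$best$ncc))
  invisible(x)
}

#' Agreement report between a measured and a simulated spectrum
#'
#' Max-normalizes both spectra, then reports the normalized cross
#' correlation, the NRMSE, and the per-bin residuals
#' (measured - simulated).
#'
#' @param measured,simulated `pcd_spectrum`s on a common grid.
#' @return an object of class `pcd_report`: list with `ncc`, `nrmse`,
#'   `residuals` (data.frame `energy_keV`, `measured`, `simulated`,
#'   `residual`), and `normalized = TRUE`.
#' @export
compare_report <- function(measured, simulated) {
  .check_same_grid(measured, simulated)
  m <- max_normalize(measured)
  s <- max_normalize(simulated)
  structure(list(
    ncc = normalized_cross_correlation(m, s),
    nrmse = nrmse(m, s),
    residuals = data.frame(energy_keV = grid_mid(m$edges),
                           measured = m$values, simulated = s$values,
                           residual = m$values - s$values),
    normalized = TRUE), class = "pcd_report")
}

#' @export
print.pcd_report <- function(x, ...) {
  cat(sprintf("<pcd_report> NCC = %.5f, NRMSE = %.5f (max-normalized)\n",
              x$ncc, x$nrmse))
  invisible(x)
}

#' Write a calibration surface or report as CSV
#'
#' @param x a `pcd_gridsearch` or `pcd_report`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_surface_csv <- function(x, path) {
  stopifnot(inherits(x, "pcd_gridsearch"))
  utils::write.csv(data.frame(r0_um = x$surface$r0,
                              sigma_e_keV = x$surface$sigma_e,
                              ncc = x$surface$ncc),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
write_report_csv <- function(x, path) {
  stopifnot(inherits(x, "pcd_report"))
  utils::write.csv(cbind(x$residuals, ncc = x$ncc, nrmse = x$nrmse),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @export
read_report_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(ncc = d$ncc[1], nrmse = d$nrmse[1],
                 residuals = d[, c("energy_keV", "measured", "simulated",
                                   "residual")],
                 normalized = TRUE), class = "pcd_report")
}
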