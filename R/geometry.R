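# Detector geometry, model parameters, and energy grids.

#' Detector geometry
#'
#' @param pixel_pitch pixel pitch d0 in micrometers.
#' @param thickness sensor thickness in micrometers.
#' @param array_dim integer vector of length 2, pixel array extent used by
#'   the frame simulator.
#' @return an object of class `pcd_geometry`.
#' @export
detector_geometry <- function(pixel_pitch = 55, thickness = 500,
                              array_dim = c(256L, 256L)) {
  stopifnot(pixel_pitch > 0, thickness > 0, length(array_dim) == 2,
            all(array_dim >= 3))
  structure(list(pixel_pitch = pixel_pitch, thickness = thickness,
                 array_dim = as.integer(array_dim)),
            class = "pcd_geometry")
}

#' Charge-transport model parameters
#'
#' The two free parameters of the spatio-energetic model: the charge-cloud
#' radius `r0` (uniform-density sphere, micrometers) and the electronic
#' noise `sigma_e` (standard deviation of the Gaussian energy blur, keV).
#' Defaults are the values calibrated for a 55-um-pitch, 500-um-thick GaAs
#' sensor.
#'
#' @param r0 charge-cloud radius in micrometers (>= 0).
#' @param sigma_e electronic noise standard deviation in keV (>= 0).
#' @return an object of class `pcd_params`.
#' @export
model_params <- function(r0 = 11, sigma_e = 2.1) {
  stopifnot(r0 >= 0, sigma_e >= 0)
  structure(list(r0 = r0, sigma_e = sigma_e), class = "pcd_params")
}

#' Uniform energy grid
#'
#' A strictly increasing uniform grid of energy-bin edges in keV.
#'
#' @param from,to grid range in keV.
#' @param by bin width in keV.
#' @return an object of class `pcd_grid`: numeric vector of bin edges.
#' @export
energy_grid <- function(from = 0, to = 60, by = 1) {
  stopifnot(by > 0, to > from)
  edges <- seq(from, to, by = by)
  structure(edges, class = "pcd_grid")
}

grid_mid <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

# internal recorded-energy grid: 0.5 keV bins, padded so Gaussian noise up
# to sigma_e = 2.5 keV never loses mass off either end
.internal_grid <- function() seq(-20, 80, by = 0.5)

# flat index over the 3x3 neighborhood, column-major in (di, dj):
# t = (dj + 1) * 3 + (di + 1) + 1, di = horizontal (x) offset
.offsets3 <- function() {
  data.frame(di = rep(-1:1, times = 3), dj = rep(-1:1, each = 3))
}
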