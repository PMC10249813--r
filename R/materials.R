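# Material constants and photon cross-section lookups for Ga, As, GaAs, Al.

# bulk densities, g/cm^3
.densities <- c(Ga = 5.904, As = 5.727, GaAs = 5.3176, Al = 2.699)

# element constants used by the fluorescence cascade
.element_data <- list(
  Ga = list(
    atomic_mass = 69.723, kedge_keV = 10.3671,
    p_kvoid = 0.88,  # P(K-shell void | photoelectric absorption)
    wk = 0.528,      # K fluorescence yield
    lambda_f_um = 42 # mean travel distance of K fluorescence in GaAs
  ),
  As = list(
    atomic_mass = 74.9216, kedge_keV = 11.8667,
    p_kvoid = 0.88, wk = 0.589, lambda_f_um = 16
  )
)

.fluorescence_lines <- data.frame(
  element = c("Ga", "Ga", "As", "As"),
  line    = c("Ka", "Kb", "Ka", "Kb"),
  energy_keV = c(9.25, 10.26, 10.54, 11.73),
  yield   = c(0.9, 0.1, 0.9, 0.1),
  stringsAsFactors = FALSE
)

.attenuation_cache <- new.env(parent = emptyenv())

#' Load an embedded photon attenuation table
#'
#' Returns the packaged mass attenuation table for one material:
#' photoelectric and total (photoelectric + incoherent; coherent scattering
#' excluded) mass attenuation coefficients on a 1-60 keV grid with extra
#' points straddling each K edge, plus the bulk density and the K-edge
#' energies lying inside the tabulated range.
#'
#' @param name one of `"Ga"`, `"As"`, `"GaAs"`, `"Al"`.
#' @return a list of class `pcd_attenuation` with elements `name`,
#'   `energy_keV`, `mu_pe_cm2_g`, `mu_tot_cm2_g`, `density_g_cm3`,
#'   `kedges_keV` and `segment` (edge-delimited segment index per row).
#' @export
attenuation_table <- function(name = "GaAs") {
  name <- match.arg(name, c("GaAs", "Ga", "As", "Al"))
  if (!is.null(.attenuation_cache[[name]])) return(.attenuation_cache[[name]])
  path <- system.file("extdata", "attenuation.csv", package = "gaaspcd",
                      mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path)) {
    # during in-source development
    path <- file.path("inst", "extdata", "attenuation.csv")
    if (!file.exists(path)) stop("attenuation table 'attenuation.csv' not found")
  }
  tab <- utils::read.csv(path)
  tab <- tab[tab$element_or_compound == name, ]
  if (!nrow(tab)) stop("no attenuation data for material: ", name)
  kedges <- switch(name,
    GaAs = c(.element_data$Ga$kedge_keV, .element_data$As$kedge_keV),
    Ga = .element_data$Ga$kedge_keV,
    As = .element_data$As$kedge_keV,
    Al = numeric(0))
  kedges <- kedges[kedges > min(tab$energy_keV) & kedges < max(tab$energy_keV)]
  out <- structure(list(
    name = name,
    energy_keV = tab$energy_keV,
    mu_pe_cm2_g = tab$mu_pe_cm2_g,
    mu_tot_cm2_g = tab$mu_tot_cm2_g,
    density_g_cm3 = unname(.densities[name]),
    kedges_keV = kedges,
    # rows at kedge - eps fall below the edge, rows at kedge + eps above
    segment = findInterval(tab$energy_keV, kedges)
  ), class = "pcd_attenuation")
  assign(name, out, envir = .attenuation_cache)
  out
}

#' GaAs sensor material description
#'
#' Bundles everything the cascade and Monte Carlo engines need to know about
#' the sensor material: the attenuation table of the compound, per-element
#' photoelectric attenuation (for choosing the interaction site element),
#' K-edge energies, K-void and fluorescence-yield probabilities, K-line
#' energies and relative yields, and mean fluorescence travel distances.
#'
#' By default the mean travel distances are the fixed reference values
#' (42 um for Ga K x-rays, 16 um for As); with
#' `lambda_from_table = TRUE` they are instead computed as the inverse
#' total linear attenuation of the compound at the K-alpha line energy,
#' which is useful as a physics cross-check.
#'
#' @param lambda_from_table logical; derive fluorescence mean travel
#'   distances from the embedded cross sections instead of the fixed
#'   42/16 um defaults.
#' @return an object of class `pcd_material`.
#' @export
gaas_material <- function(lambda_from_table = FALSE) {
  mat <- structure(list(
    composition = "GaAs",
    elements = .element_data,
    lines = .fluorescence_lines,
    attenuation = attenuation_table("GaAs"),
    element_attenuation = list(Ga = attenuation_table("Ga"),
                               As = attenuation_table("As")),
    density_g_cm3 = unname(.densities["GaAs"])
  ), class = "pcd_material")
  if (lambda_from_table) {
    for (el in names(mat$elements)) {
      ka <- .fluorescence_lines$energy_keV[.fluorescence_lines$element == el &
                                           .fluorescence_lines$line == "Ka"]
      mat$elements[[el]]$lambda_f_um <- mean_free_path(mat, ka)
    }
  }
  mat
}

#' @export
print.pcd_material <- function(x, ...) {
  cat("<pcd_material>", x$composition,
      sprintf("(density %.4g g/cm^3)\n", x$density_g_cm3))
  for (el in names(x$elements)) {
    e <- x$elements[[el]]
    cat(sprintf("  %s: K edge %.4f keV, P(K void|PE) %.2f, W_K %.3f, lambda_F %.3g um\n",
                el, e$kedge_keV, e$p_kvoid, e$wk, e$lambda_f_um))
  }
  invisible(x)
}

.resolve_attenuation <- function(material) {
  if (inherits(material, "pcd_attenuation")) return(material)
  if (inherits(material, "pcd_material")) return(material$attenuation)
  if (is.character(material)) return(attenuation_table(material))
  stop("expected a pcd_material, pcd_attenuation, or material name")
}

# log-log interpolation of a mass attenuation column within edge-delimited
# segments; never interpolates across a K edge
.interp_mu <- function(att, E, column) {
  rng <- range(att$energy_keV)
  if (any(E < rng[1] - 1e-9 | E > rng[2] + 1e-9))
    stop(sprintf("energy outside tabulated range [%.4g, %.4g] keV", rng[1], rng[2]))
  E <- pmin(pmax(E, rng[1]), rng[2])
  seg <- findInterval(E, att$kedges_keV)  # energies exactly at an edge: above
  mu <- numeric(length(E))
  for (s in unique(seg)) {
    in_s <- att$segment == s
    idx <- seg == s
    mu[idx] <- exp(stats::approx(log(att$energy_keV[in_s]),
                                 log(att[[column]][in_s]),
                                 xout = log(E[idx]), rule = 2)$y)
  }
  mu
}

#' Linear attenuation coefficient
#'
#' Log-log interpolated linear attenuation coefficient of a material, in
#' inverse micrometers. Interpolation respects K-edge discontinuities:
#' values are never interpolated across an edge.
#'
#' @param material a `pcd_material`, `pcd_attenuation`, or material name.
#' @param E photon energy in keV (vectorized); must lie within the
#'   tabulated range.
#' @param kind `"total"` (photoelectric + incoherent) or `"photoelectric"`.
#' @return linear attenuation coefficient(s), per micrometer.
#' @export
linear_attenuation <- function(material, E, kind = c("total", "photoelectric")) {
  kind <- match.arg(kind)
  att <- .resolve_attenuation(material)
  col <- if (kind == "total") "mu_tot_cm2_g" else "mu_pe_cm2_g"
  .interp_mu(att, E, col) * att$density_g_cm3 * 1e-4  # cm^-1 -> um^-1
}

#' Mean free path
#'
#' Inverse of the total linear attenuation coefficient, in micrometers.
#' Evaluated at the Ga and As K-alpha line energies in GaAs this gives the
#' mean travel distance of fluorescence photons in the sensor.
#'
#' @inheritParams linear_attenuation
#' @return mean free path(s) in micrometers.
#' @export
mean_free_path <- function(material, E) {
  1 / linear_attenuation(material, E, "total")
}

#' Photoelectric absorption probability in a sensor slab
#'
#' Probability that a photon of energy `E` at normal incidence undergoes
#' photoelectric absorption within a slab of the given thickness:
#' `1 - exp(-mu_pe(E) * thickness)`. With Compton and Rayleigh scattering
#' excluded from the model, this is the interaction probability.
#'
#' @inheritParams linear_attenuation
#' @param thickness slab thickness in micrometers (>= 0).
#' @return absorption probability in `[0, 1]`.
#' @export
absorption_probability <- function(material, thickness, E) {
  if (any(thickness < 0)) stop("thickness must be >= 0")
  -expm1(-linear_attenuation(material, E, "photoelectric") * thickness)
}

#' Photoelectric share of each element at the interaction site
#'
#' For the GaAs compound, the probability that a photoelectric interaction
#' at energy `E` occurs on a Ga vs an As atom, proportional to each
#' element's mass-weighted photoelectric attenuation.
#'
#' @param material a `pcd_material`.
#' @param E photon energy in keV (scalar or vector).
#' @return a matrix with one row per energy and columns `Ga`, `As`,
#'   rows summing to 1.
#' @export
element_shares <- function(material, E) {
  stopifnot(inherits(material, "pcd_material"))
  w <- vapply(material$elements, `[[`, numeric(1), "atomic_mass")
  parts <- vapply(names(material$elements), function(el) {
    w[[el]] * .interp_mu(material$element_attenuation[[el]], E, "mu_pe_cm2_g")
  }, numeric(length(E)))
  parts <- matrix(parts, nrow = length(E),
                  dimnames = list(NULL, names(material$elements)))
  parts / rowSums(parts)
}

#' Choose the interaction-site element
#'
#' Maps a uniform random number to the element of the photoelectric
#' interaction site, with probabilities given by [element_shares()].
#'
#' @inheritParams element_shares
#' @param u uniform random number(s) in `[0, 1)`, recycled against `E`.
#' @return character vector of element labels.
#' @export
select_interaction_element <- function(material, E, u) {
  sh <- element_shares(material, E)
  ifelse(u < sh[, 1L], colnames(sh)[1L], colnames(sh)[2L])
}

#' K-fluorescence emission probability per photoelectric absorption
#'
#' Product of the K-void probability given photoelectric absorption and
#' the K fluorescence yield `W_K` of the element. This is conditional on
#' the photon energy exceeding the element's K edge; below the edge the
#' emission probability is zero (applied by the cascade engines).
#'
#' @param material a `pcd_material`.
#' @param element element label (`"Ga"` or `"As"`).
#' @return emission probability in `[0, 1]`.
#' @export
fluorescence_emission_probability <- function(material, element) {
  stopifnot(inherits(material, "pcd_material"))
  el <- material$elements[[element]]
  if (is.null(el)) stop("unknown element: ", element)
  el$p_kvoid * el$wk
}

#' Fluorescence line table
#'
#' K-alpha and K-beta line energies and relative yields for the elements
#' of the sensor material.
#'
#' @param material a `pcd_material`.
#' @return a data.frame with columns `element`, `line`, `energy_keV`,
#'   `yield`.
#' @export
fluorescence_lines <- function(material) {
  stopifnot(inherits(material, "pcd_material"))
  material$lines
}
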