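# Seeded event-level Monte Carlo: same physics as the deterministic
# cascade, sampled photon by photon. Serves as a brute-force cross-check
# of the cascade engine and generates low-fluence frames for single-event
# analysis.

.sample_incident_energy <- function(n, spec_or_E) {
  if (inherits(spec_or_E, "pcd_spectrum")) {
    mids <- grid_mid(spec_or_E$edges)
    keep <- spec_or_E$values > 0
    sample(mids[keep], n, replace = TRUE, prob = spec_or_E$values[keep])
  } else {
    rep_len(as.numeric(spec_or_E), n)
  }
}

#' Simulate photon events
#'
#' Samples the full interaction cascade for `n` photons incident uniformly
#' on the central pixel: transmission vs photoelectric absorption,
#' interaction element, K-fluorescence emission (line chosen by relative
#' yield), isotropic exponential fluorescence transport with escape
#' through the slab faces, and volume apportioning of the one or two
#' charge clouds over the 3x3 pixel neighborhood. Deposits falling in
#' pixels outside the neighborhood are dropped and tracked as lost energy.
#'
#' @param n number of photons.
#' @param E incident energy in keV (scalar) or a `pcd_spectrum` to sample
#'   energies from (bin midpoints weighted by bin values).
#' @param geometry a `pcd_geometry`.
#' @param params a `pcd_params` (only `r0` is used here; noise is applied
#'   at readout).
#' @param material a `pcd_material`.
#' @param seed integer RNG seed; runs are reproducible given the seed.
#' @return an object of class `pcd_events`: a list with `deposits`
#'   (n x 9 matrix of pre-noise deposited energies, `.offsets3()` column
#'   order), `meta` (data.table: `energy`, `absorbed`, `element`, `fluor`,
#'   `line`, `escaped`, `lost`), and the call parameters.
#' @export
simulate_events <- function(n, E, geometry = detector_geometry(),
                            params = model_params(),
                            material = gaas_material(), seed = 1L) {
  stopifnot(n > 0)
  set.seed(seed)
  d0 <- geometry$pixel_pitch; Tt <- geometry$thickness
  en <- .sample_incident_energy(n, E)
  u_abs <- stats::runif(n)
  x <- stats::runif(n, -d0 / 2, d0 / 2)
  y <- stats::runif(n, -d0 / 2, d0 / 2)
  u_el <- stats::runif(n)
  u_kv <- stats::runif(n)
  u_ln <- stats::runif(n)
  u_z <- stats::runif(n)
  cth <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  u_s <- stats::runif(n)

  mu_pe <- linear_attenuation(material, en, "photoelectric")
  absorbed <- u_abs < -expm1(-mu_pe * Tt)
  element <- select_interaction_element(material, en, u_el)
  eld <- material$elements
  kedge <- vapply(eld, `[[`, numeric(1), "kedge_keV")[element]
  emis <- vapply(eld, function(e) e$p_kvoid * e$wk, numeric(1))[element]
  fluor <- absorbed & en >= kedge & u_kv < emis
  lines <- material$lines
  line <- ifelse(u_ln < 0.9, "Ka", "Kb")
  lkey <- paste(element, line)
  ltab <- stats::setNames(lines$energy_keV, paste(lines$element, lines$line))
  e_line <- ltab[lkey]
  lambda_f <- vapply(eld, `[[`, numeric(1), "lambda_f_um")[element]

  z <- -log1p(-u_z * -expm1(-mu_pe * Tt)) / mu_pe
  s <- -lambda_f * log1p(-u_s)
  z_end <- z + s * cth
  escaped <- fluor & (z_end < 0 | z_end > Tt)
  reabs <- fluor & !escaped
  rho <- s * sqrt(pmax(1 - cth^2, 0))
  xf <- x + rho * cos(phi)
  yf <- y + rho * sin(phi)

  dep <- matrix(0, n, 9)
  lost <- numeric(n)
  idx9 <- function(di, dj) (dj + 1L) * 3L + (di + 1L) + 1L
  add_cloud <- function(rows, cx, cy, energy) {
    bl <- .cloud_block_fractions(cx, cy, params$r0, d0)
    pu <- list(c(0, 0, bl$f_c), c(bl$sx, 0, bl$f_x),
               c(0, bl$sy, bl$f_y), c(bl$sx, bl$sy, bl$f_xy))
    for (k in 1:4) {
      du <- bl$u + switch(k, 0, bl$sx, 0, bl$sx)
      dv <- bl$v + switch(k, 0, 0, bl$sy, bl$sy)
      f <- switch(k, bl$f_c, bl$f_x, bl$f_y, bl$f_xy)
      inside <- abs(du) <= 1 & abs(dv) <= 1 & f > 0
      if (any(inside)) {
        ii <- cbind(rows[inside], idx9(du[inside], dv[inside]))
        dep[ii] <<- dep[ii] + energy[inside] * f[inside]
      }
      out <- !inside & f > 0
      if (any(out)) lost[rows[out]] <<- lost[rows[out]] + energy[out] * f[out]
    }
  }
  pr <- which(absorbed)
  if (length(pr)) {
    e_dep <- ifelse(fluor, en - e_line, en)
    add_cloud(pr, x[pr], y[pr], e_dep[pr])
  }
  fr <- which(reabs)
  if (length(fr)) add_cloud(fr, xf[fr], yf[fr], e_line[fr])
  lost[which(escaped)] <- lost[which(escaped)] + e_line[which(escaped)]

  meta <- data.table::data.table(
    energy = en, absorbed = absorbed,
    element = ifelse(absorbed, element, NA_character_),
    fluor = fluor, line = ifelse(fluor, line, NA_character_),
    escaped = escaped, lost = lost)
  structure(list(deposits = dep, meta = meta, E = E, geometry = geometry,
                 params = params, seed = seed),
            class = "pcd_events")
}

#' Empirical joint count-pattern distribution from simulated events
#'
#' Applies Gaussian electronic noise to every pixel that received charge,
#' classifies each pixel's recorded energy into the windows delimited by
#' `thresholds` (a count requires recorded energy above the lowest
#' threshold), and tabulates the joint pattern over the 3x3 neighborhood
#' per event. Patterns are keyed as `"pixel:window"` pairs; the empty key
#' is the no-count pattern.
#'
#' @param events a `pcd_events`.
#' @param thresholds strictly increasing threshold ladder in keV.
#' @param sigma_e electronic noise (keV).
#' @param seed RNG seed for the noise draws.
#' @return a data.table with `key_`, `n`, and `phat` (share of all
#'   events).
#' @export
event_pattern_counts <- function(events, thresholds, sigma_e, seed = 1L) {
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  set.seed(seed)
  dep <- events$deposits
  act <- which(dep > 0)
  rec <- dep
  rec[act] <- dep[act] + stats::rnorm(length(act), 0, sigma_e)
  cat_ <- matrix(0L, nrow(dep), 9)
  cat_[act] <- findInterval(rec[act], thresholds, left.open = TRUE)
  dt <- data.table::data.table(
    oid = rep(seq_len(nrow(dep)), times = 9),
    pix = rep(1:9, each = nrow(dep)),
    cat_ = as.vector(cat_))
  dt <- dt[cat_ > 0]
  data.table::setorder(dt, oid, pix)
  keys <- dt[, .(key_ = paste(paste0(pix, ":", cat_), collapse = ";")),
             by = oid]
  n_ev <- nrow(dep)
  tab <- keys[, .(n = .N), by = key_]
  tab <- data.table::rbindlist(list(
    tab, data.table::data.table(key_ = "", n = n_ev - sum(tab$n))))
  tab[, phat := n / n_ev]
  tab[n > 0]
}

#' Simulate low-fluence detector frames
#'
#' Poisson photon counts per frame, impact pixels uniform over the array
#' (with a one-pixel border margin so the 3x3 neighborhood always fits),
#' per-photon deposits from the event simulator, and Gaussian readout
#' noise applied once per pixel that received charge. Frames store
#' recorded energies sparsely; thresholding is applied by the analysis
#' functions, mirroring acquisitions at a sequence of comparator
#' thresholds.
#'
#' @param n_frames number of frames.
#' @param mean_photons Poisson mean of photons per frame.
#' @param E incident energy (keV) or `pcd_spectrum`.
#' @param geometry,params,material detector description.
#' @param seed RNG seed.
#' @param margin border margin (pixels) excluded from photon impacts.
#' @return an object of class `pcd_frames`: a data.table with columns
#'   `frame`, `row_`, `col_`, `energy` (recorded, keV) plus attributes
#'   `n_frames`, `array_dim`, `n_photons`, `seed`.
#' @export
simulate_frames <- function(n_frames, mean_photons, E,
                            geometry = detector_geometry(),
                            params = model_params(),
                            material = gaas_material(), seed = 1L,
                            margin = 1L) {
  stopifnot(n_frames >= 1, mean_photons >= 0)
  set.seed(seed)
  nph <- stats::rpois(n_frames, mean_photons)
  n <- sum(nph)
  dims <- geometry$array_dim
  empty <- data.table::data.table(frame = integer(), row_ = integer(),
                                  col_ = integer(), energy = numeric())
  if (n == 0) {
    return(structure(empty, class = c("pcd_frames", class(empty)),
                     n_frames = n_frames, array_dim = dims, n_photons = 0L,
                     seed = seed))
  }
  frame_id <- rep(seq_len(n_frames), nph)
  irow <- sample(seq.int(1L + margin, dims[1] - margin), n, replace = TRUE)
  icol <- sample(seq.int(1L + margin, dims[2] - margin), n, replace = TRUE)
  ev <- simulate_events(n, E, geometry, params, material,
                        seed = seed + 1000003L)
  off <- .offsets3()
  dt <- data.table::data.table(
    frame = rep(frame_id, times = 9),
    row_ = rep(irow, times = 9) + rep(off$dj, each = n),
    col_ = rep(icol, times = 9) + rep(off$di, each = n),
    dep = as.vector(ev$deposits))
  dt <- dt[dep > 0]
  dt <- dt[, .(dep = sum(dep)), by = .(frame, row_, col_)]
  set.seed(seed + 2000003L)
  dt[, energy := dep + stats::rnorm(.N, 0, params$sigma_e)]
  dt[, dep := NULL]
  data.table::setorder(dt, frame, row_, col_)
  structure(dt, class = c("pcd_frames", class(empty)),
            n_frames = n_frames, array_dim = dims, n_photons = n,
            seed = seed)
}

#' Monte Carlo fraction of fluorescence transported beyond the 3x3 footprint
#'
#' Emits `n` fluorescence photons from interaction points distributed as
#' in the cascade (uniform lateral position in the central pixel, depth
#' from the truncated-exponential interaction distribution at
#' `E_primary`), transports them isotropically with exponential path
#' length, and reports the fraction whose transport endpoint - the
#' reabsorption point, or the lateral position where an escaping photon
#' crosses a slab face - lies laterally outside the 3x3 pixel footprint.
#'
#' @param n number of emitted photons.
#' @param element emitting element (`"Ga"` or `"As"`; sets the mean travel
#'   distance).
#' @param E_primary energy of the primary photon (keV), used for the
#'   interaction depth distribution.
#' @param geometry,material detector description.
#' @param seed RNG seed.
#' @return fraction in `[0, 1]`.
#' @export
fluorescence_escape_fraction <- function(n = 1e6, element = "Ga",
                                         E_primary = 22,
                                         geometry = detector_geometry(),
                                         material = gaas_material(),
                                         seed = 1L) {
  set.seed(seed)
  d0 <- geometry$pixel_pitch; Tt <- geometry$thickness
  lambda_f <- material$elements[[element]]$lambda_f_um
  x <- stats::runif(n, -d0 / 2, d0 / 2)
  y <- stats::runif(n, -d0 / 2, d0 / 2)
  dd <- interaction_depth_distribution(material, E_primary, Tt)
  z <- dd$quantile(stats::runif(n))
  cth <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  s <- stats::rexp(n, 1 / lambda_f)
  # distance to the face along the flight direction (Inf if parallel)
  t_face <- ifelse(cth > 0, (Tt - z) / cth, ifelse(cth < 0, -z / cth, Inf))
  travel <- pmin(s, t_face)
  rho <- travel * sqrt(pmax(1 - cth^2, 0))
  xf <- x + rho * cos(phi)
  yf <- y + rho * sin(phi)
  half <- 1.5 * d0
  mean(abs(xf) > half | abs(yf) > half)
}
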