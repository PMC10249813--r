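# Deterministic cascade engine: joint deposited-energy / count distribution
# over the 3x3 neighborhood for a photon incident on the central pixel.
#
# The cascade integrates, by fixed quadrature, over the uniform lateral
# interaction position in the central pixel, the truncated-exponential
# interaction depth, the interaction-site element, and the fluorescence
# branch (none / emitted with isotropic exponential transport per K line).
# Charge clouds are uniform-density spheres apportioned by volume over
# pixel columns; deposits belonging to pixels outside the 3x3 neighborhood
# are dropped from the outcome (their energy is tracked as "lost", their
# probability retained).

#' Quadrature resolutions of the cascade engine
#'
#' @param lateral lateral grid points per axis over the central pixel for
#'   the fluorescence branches (start and reabsorption lattice pitch).
#' @param lateral_primary lateral grid points per axis for the
#'   single-cloud (no-fluorescence-emission) branch, which is cheap to
#'   refine.
#' @param depth number of equal-probability depth nodes.
#' @param polar number of polar-angle nodes for fluorescence transport.
#' @param azimuth number of azimuthal nodes.
#' @param path number of equal-probability path-length nodes.
#' @param delta_cells displacement-histogram cells per pixel pitch
#'   (independent of the start lattice; endpoints are evaluated at
#'   continuous start + cell-center coordinates).
#' @param delta_keep fraction of the reabsorbed-fluorescence displacement
#'   mass resolved spatially; the remaining tail is treated as lost beyond
#'   the neighborhood.
#' @param round_keV outcome deposits are pooled on this energy pitch when
#'   aggregating the joint outcome table.
#' @return a list of class `pcd_resolution`.
#' @export
response_resolution <- function(lateral = 15L, lateral_primary = 61L,
                                depth = 64L, polar = 64L,
                                azimuth = 512L, path = 32L,
                                delta_cells = 15L,
                                delta_keep = 0.9999, round_keV = 0.25) {
  stopifnot(lateral >= 3, lateral_primary >= 3, depth >= 4, polar >= 8,
            azimuth >= 8, path >= 4, delta_cells >= 3,
            delta_keep > 0, delta_keep <= 1, round_keV > 0)
  structure(list(lateral = as.integer(lateral),
                 lateral_primary = as.integer(lateral_primary),
                 depth = as.integer(depth),
                 polar = as.integer(polar), azimuth = as.integer(azimuth),
                 path = as.integer(path),
                 delta_cells = as.integer(delta_cells),
                 delta_keep = delta_keep, round_keV = round_keV),
            class = "pcd_resolution")
}

#' Interaction depth distribution
#'
#' Depth distribution of photoelectric interactions in the sensor slab: a
#' truncated exponential with rate equal to the photoelectric linear
#' attenuation coefficient, normalized over `[0, thickness]`.
#'
#' @param material a `pcd_material`.
#' @param E photon energy in keV.
#' @param thickness slab thickness in micrometers.
#' @return a list with `mu` (per um), `density(z)`, `quantile(p)` and
#'   `mean` (mean interaction depth, um).
#' @export
interaction_depth_distribution <- function(material, E, thickness) {
  mu <- linear_attenuation(material, E, "photoelectric")
  norm <- -expm1(-mu * thickness)
  list(
    mu = mu,
    density = function(z) ifelse(z >= 0 & z <= thickness,
                                 mu * exp(-mu * z) / norm, 0),
    quantile = function(p) -log1p(-p * norm) / mu,
    mean = 1 / mu - thickness * exp(-mu * thickness) / norm
  )
}

#' Fluorescence transport kernel
#'
#' Deterministic quadrature of the fate of a fluorescence photon emitted
#' isotropically from `origin` with an exponential path length of mean
#' `lambda_f`: the photon either escapes the sensor slab through a face or
#' is reabsorbed at its path endpoint, producing a second charge cloud.
#' The slab is treated as laterally unbounded.
#'
#' @param origin numeric length-3 `(x, y, z)` in micrometers; `z` must lie
#'   in `[0, thickness]`.
#' @param lambda_f mean travel distance in micrometers.
#' @param geometry a `pcd_geometry`.
#' @param res a `pcd_resolution` (polar/azimuth/path nodes are used).
#' @return a list with `p_escape` and `points`, a data.frame of
#'   reabsorption positions `(x, y, z)` with weights summing to
#'   `1 - p_escape`.
#' @export
fluorescence_transport_kernel <- function(origin, lambda_f, geometry,
                                          res = response_resolution()) {
  stopifnot(length(origin) == 3)
  z0 <- origin[3]
  if (z0 < 0 || z0 > geometry$thickness) stop("origin outside sensor volume")
  if (lambda_f <= 0) {
    return(list(p_escape = 0,
                points = data.frame(x = origin[1], y = origin[2], z = z0,
                                    weight = 1)))
  }
  K <- res$polar; L <- res$path; A <- res$azimuth
  cth <- -1 + (seq_len(K) - 0.5) * 2 / K
  s <- -lambda_f * log1p(-(seq_len(L) - 0.5) / L)
  phi <- (seq_len(A) - 0.5) * 2 * pi / A
  g <- expand.grid(k = seq_len(K), l = seq_len(L), a = seq_len(A))
  c_ <- cth[g$k]; s_ <- s[g$l]; p_ <- phi[g$a]
  z <- z0 + s_ * c_
  esc <- z < 0 | z > geometry$thickness
  rho <- s_ * sqrt(pmax(1 - c_^2, 0))
  w <- 1 / (K * L * A)
  pts <- data.frame(x = origin[1] + rho[!esc] * cos(p_[!esc]),
                    y = origin[2] + rho[!esc] * sin(p_[!esc]),
                    z = z[!esc], weight = w)
  list(p_escape = sum(esc) * w, points = pts)
}

# Lateral displacement histogram of reabsorbed fluorescence photons,
# marginalized over the interaction depth distribution at energy E.
# Cells are squares of side pitch/n indexed by (p, q) = round(delta / step);
# photons landing beyond 3 pixels in either axis (or pruned tail mass) are
# "far": lost to the neighborhood. Returns masses summing to 1.
.fluor_displacement <- function(material, E, lambda_f, geometry, res) {
  n <- res$delta_cells
  step <- geometry$pixel_pitch / n
  M <- res$depth; K <- res$polar; L <- res$path; A <- res$azimuth
  dd <- interaction_depth_distribution(material, E, geometry$thickness)
  zq <- dd$quantile((seq_len(M) - 0.5) / M)
  cth <- -1 + (seq_len(K) - 0.5) * 2 / K
  s <- -lambda_f * log1p(-(seq_len(L) - 0.5) / L)
  # absorbed weight per (polar, path) node, summed over depth nodes
  dz <- outer(s, cth)                         # L x K displacement in z
  w_abs_kl <- matrix(0, L, K)
  for (m in seq_len(M)) {
    zt <- zq[m] + dz
    w_abs_kl <- w_abs_kl + (zt >= 0 & zt <= geometry$thickness)
  }
  w_abs_kl <- w_abs_kl / (M * K * L)
  p_escape <- 1 - sum(w_abs_kl)
  # radial histogram of lateral displacement of absorbed photons
  rho <- outer(s, sqrt(pmax(1 - cth^2, 0)))   # L x K
  rho_max <- 3 * sqrt(2) * geometry$pixel_pitch
  far <- rho > rho_max
  w_far <- sum(w_abs_kl[far])
  drho <- 0.25
  rbin <- pmin(floor(rho[!far] / drho), ceiling(rho_max / drho)) + 1L
  w_r <- rowsum(w_abs_kl[!far], rbin)
  r_centers <- (as.numeric(rownames(w_r)) - 0.5) * drho
  # spread each radial shell over azimuth nodes and bin onto the cell grid
  phi <- (seq_len(A) - 0.5) * 2 * pi / A
  px <- round(outer(r_centers, cos(phi)) / step)
  qy <- round(outer(r_centers, sin(phi)) / step)
  ww <- matrix(rep(w_r[, 1] / A, A), ncol = A)
  lim <- 3L * n - 1L
  out <- (abs(px) > lim) | (abs(qy) > lim)
  w_far <- w_far + sum(ww[out])
  cells <- data.table::data.table(p = as.integer(px[!out]),
                                  q = as.integer(qy[!out]), w = ww[!out])
  cells <- cells[, .(w = sum(w)), by = .(p, q)]
  # fold over the 8-fold symmetry of the neighborhood: the physical
  # displacement distribution is isotropic, so this removes the residual
  # floating-point asymmetry of the azimuth histogram exactly
  cells <- data.table::rbindlist(list(
    cells[, .(p, q, w)], cells[, .(p = -p, q, w)],
    cells[, .(p, q = -q, w)], cells[, .(p = -p, q = -q, w)],
    cells[, .(p = q, q = p, w)], cells[, .(p = -q, q = p, w)],
    cells[, .(p = q, q = -p, w)], cells[, .(p = -q, q = -p, w)]))
  cells <- cells[, .(w = sum(w) / 8), by = .(p, q)]
  data.table::setorder(cells, -w)
  if (res$delta_keep < 1 && nrow(cells) > 1) {
    keep <- cumsum(cells$w) <= res$delta_keep * sum(cells$w)
    keep[1] <- TRUE
    # never split a symmetry orbit: keep every cell at least as heavy as
    # the lightest kept one
    keep <- cells$w >= min(cells$w[keep]) * (1 - 1e-9)
    w_far <- w_far + sum(cells$w[!keep])
    cells <- cells[keep]
  }
  list(p_escape = p_escape, w_far = w_far, cells = cells)
}

# branch bookkeeping for one incident energy
.branch_table <- function(E, material) {
  sh <- element_shares(material, E)[1, ]
  lines <- material$lines
  out <- list()
  p_nofluor_given_abs <- 1
  for (el in names(material$elements)) {
    eld <- material$elements[[el]]
    if (E < eld$kedge_keV) next
    emis <- eld$p_kvoid * eld$wk
    p_nofluor_given_abs <- p_nofluor_given_abs - sh[[el]] * emis
    for (i in which(lines$element == el)) {
      out[[length(out) + 1]] <- list(
        element = el, line = lines$line[i], e_line = lines$energy_keV[i],
        lambda_f = eld$lambda_f_um,
        p_given_abs = sh[[el]] * emis * lines$yield[i])
    }
  }
  list(fluor = out, p_nofluor_given_abs = p_nofluor_given_abs)
}

#' Compute the spatio-energetic response at one incident energy
#'
#' Runs the deterministic cascade for photons of energy `E` incident
#' uniformly on the central pixel and returns the joint deposited-energy
#' outcome distribution over the 3x3 neighborhood together with per-pixel
#' recorded-energy spectra (after Gaussian electronic noise).
#'
#' @param E incident photon energy in keV (within the cross-section table
#'   range).
#' @param geometry a `pcd_geometry`.
#' @param params a `pcd_params` (`r0`, `sigma_e`).
#' @param material a `pcd_material`.
#' @param res a `pcd_resolution`.
#' @param level `"joint"` (full outcome table, marginals and ledger),
#'   `"marginal"` (per-pixel spectra and ledger only), or `"ledger"`
#'   (probability bookkeeping only).
#' @return an object of class `pcd_response` with elements `E`, `ledger`
#'   (probability bookkeeping: transmission and branch masses), `deposit`
#'   (9 x bins matrix of pre-noise deposited-energy mass per pixel, on the
#'   internal 0.5-keV grid given by `$grid`), `recorded` (same after
#'   noise), and (level `"joint"`) `outcomes`: a data.table with deposit
#'   columns `d1..d9` (keV, offsets in column-major `(di, dj)` order from
#'   `(-1,-1)` to `(1,1)`), `prob`, and `lost` (energy escaped or beyond
#'   the neighborhood). Outcome probabilities plus the transmission
#'   probability sum to 1.
#' @export
compute_response <- function(E, geometry = detector_geometry(),
                             params = model_params(),
                             material = gaas_material(),
                             res = response_resolution(),
                             level = c("joint", "marginal", "ledger")) {
  level <- match.arg(level)
  n <- res$lateral
  d0 <- geometry$pixel_pitch
  p_abs <- absorption_probability(material, geometry$thickness, E)
  br <- .branch_table(E, material)
  ledger <- list(E = E, transmission = 1 - p_abs, p_abs = p_abs,
                 p_nofluor = p_abs * br$p_nofluor_given_abs,
                 branches = list())
  disp_cache <- list()
  for (b in br$fluor) {
    key <- b$element
    if (is.null(disp_cache[[key]]))
      disp_cache[[key]] <- .fluor_displacement(material, E, b$lambda_f,
                                               geometry, res)
    d <- disp_cache[[key]]
    ledger$branches[[paste(b$element, b$line)]] <- list(
      prob = p_abs * b$p_given_abs, p_escape = d$p_escape, w_far = d$w_far,
      w_cells = sum(d$cells$w), e_line = b$e_line)
  }
  total <- ledger$transmission + ledger$p_nofluor +
    sum(vapply(ledger$branches, `[[`, numeric(1), "prob"))
  ledger$total <- total

  out <- structure(list(E = E, geometry = geometry, params = params,
                        res = res, ledger = ledger,
                        grid = .internal_grid()),
                   class = "pcd_response")
  if (level == "ledger") return(out)

  S <- .split_table(n, params$r0, d0)
  n2 <- n * n
  w_start <- 1 / n2
  edges <- out$grid
  nb <- length(edges) - 1L
  dm <- matrix(0, 9, nb)
  joint <- level == "joint"
  dcols <- paste0("d", 1:9)
  rk <- res$round_keV
  aggs <- list()
  # fold one block of (probability, 9 deposits, lost) rows into the
  # marginal histograms and, for the joint level, an aggregated outcome
  # table keyed by deposits rounded to round_keV (weighted-mean deposits)
  consume <- function(prob, dep, lost) {
    for (t in 1:9) {
      v <- dep[, t]
      pos <- v > 0
      if (any(pos)) {
        bin <- findInterval(v[pos], edges)
        acc <- rowsum(prob[pos], bin)
        bi <- as.integer(rownames(acc))
        dm[t, bi] <<- dm[t, bi] + acc[, 1]
      }
    }
    if (joint) {
      # outcomes keyed by deposits rounded to round_keV; deposit and lost
      # columns carried as probability-weighted sums (GForce-fast),
      # divided back into weighted means at the end
      # ceiling keeps exact-zero deposits in their own pool: a pixel with
      # zero charge can never count, a grazing deposit can (via noise)
      g <- do.call(paste, c(lapply(seq_len(9), function(t)
        ceiling(dep[, t] / rk)), sep = ","))
      ch <- data.table::data.table(g = g, prob = prob,
                                   dep = dep * prob,
                                   lost = rep_len(lost, length(prob)) * prob)
      data.table::setnames(ch, c("g", "prob", dcols, "lost"))
      aggs[[length(aggs) + 1L]] <<-
        ch[, lapply(.SD, sum), by = g, .SDcols = c("prob", dcols, "lost")]
    }
  }
  # branch without fluorescence emission: full E in the primary cloud,
  # on its own (finer) lateral lattice
  np <- res$lateral_primary
  Sp <- if (np == n) S else .split_table(np, params$r0, d0)
  consume(rep(ledger$p_nofluor / (np * np), np * np), E * Sp, 0)
  pos <- (seq_len(n) - 0.5) * (d0 / n) - d0 / 2
  for (b in br$fluor) {
    d <- disp_cache[[b$element]]
    p_branch <- p_abs * b$p_given_abs
    Ep <- E - b$e_line; Ef <- b$e_line
    # escape + unresolved-tail fate: primary cloud only, line energy lost
    w0 <- d$p_escape + d$w_far
    if (w0 > 0) consume(rep(p_branch * w0 * w_start, n2), Ep * S, Ef)
    nc <- nrow(d$cells)
    if (!nc) next
    stepd <- d0 / res$delta_cells
    reach <- 1.5 * d0 + params$r0
    block <- max(1L, ceiling(3e5 / n2))
    for (c0 in seq(1L, nc, by = block)) {
      cs <- c0:min(c0 + block - 1L, nc)
      nb_ <- length(cs)
      sidx <- rep(seq_len(n2), times = nb_)
      ci <- rep(cs, each = n2)
      xs <- pos[(sidx - 1L) %% n + 1L]
      ys <- pos[(sidx - 1L) %/% n + 1L]
      xe <- xs + d$cells$p[ci] * stepd
      ye <- ys + d$cells$q[ci] * stepd
      dep <- Ep * S[sidx, , drop = FALSE]
      fl_used <- numeric(length(sidx))
      # reabsorption cloud split evaluated at the continuous endpoint
      near <- which(abs(xe) < reach & abs(ye) < reach)
      if (length(near)) {
        bl <- .cloud_block_fractions(xe[near], ye[near], params$r0, d0)
        parts <- list(list(du = bl$u, dv = bl$v, f = bl$f_c),
                      list(du = bl$u + bl$sx, dv = bl$v, f = bl$f_x),
                      list(du = bl$u, dv = bl$v + bl$sy, f = bl$f_y),
                      list(du = bl$u + bl$sx, dv = bl$v + bl$sy,
                           f = bl$f_xy))
        for (pt in parts) {
          ok <- abs(pt$du) <= 1 & abs(pt$dv) <= 1 & pt$f > 0
          if (any(ok)) {
            ii <- cbind(near[ok],
                        (pt$dv[ok] + 1L) * 3L + (pt$du[ok] + 1L) + 1L)
            dep[ii] <- dep[ii] + Ef * pt$f[ok]
            fl_used[near[ok]] <- fl_used[near[ok]] + pt$f[ok]
          }
        }
      }
      consume(p_branch * w_start * d$cells$w[ci], dep,
              Ef * (1 - fl_used))
    }
    # keep the chunk-aggregate buffer compact
    if (joint && length(aggs) > 24) {
      all_ <- data.table::rbindlist(aggs)
      aggs <- list(all_[, lapply(.SD, sum), by = g,
                        .SDcols = c("prob", dcols, "lost")])
    }
  }
  out$deposit <- dm
  out$recorded <- .noise_blur(dm, params$sigma_e, edges)
  if (joint) {
    all_ <- data.table::rbindlist(aggs)
    outcomes <- all_[, lapply(.SD, sum), by = g,
                     .SDcols = c("prob", dcols, "lost")]
    outcomes[, g := NULL]
    for (cl in c(dcols, "lost"))
      data.table::set(outcomes, j = cl,
                      value = outcomes[[cl]] / outcomes$prob)
    out$outcomes <- outcomes
  }
  out
}

#' @export
print.pcd_response <- function(x, ...) {
  cat(sprintf("<pcd_response> E = %g keV, r0 = %g um, sigma_e = %g keV\n",
              x$E, x$params$r0, x$params$sigma_e))
  cat(sprintf("  transmission %.4f, absorbed %.4f\n",
              x$ledger$transmission, x$ledger$p_abs))
  if (!is.null(x$outcomes))
    cat(sprintf("  %d aggregated outcomes\n", nrow(x$outcomes)))
  invisible(x)
}

# Gaussian blur of per-bin masses located at bin midpoints; total mass is
# preserved because the internal grid pads well beyond the noise range.
.noise_blur <- function(dm, sigma_e, edges) {
  if (sigma_e == 0) return(dm)
  mids <- grid_mid(edges)
  K <- stats::pnorm(outer(-mids, edges[-1], `+`) / sigma_e) -
       stats::pnorm(outer(-mids, edges[-length(edges)], `+`) / sigma_e)
  dm %*% K
}

#' Probability bookkeeping of a response
#'
#' Returns the components of the total probability per incident photon
#' (transmission, no-fluorescence branch, and each fluorescence branch)
#' and their sum, which must equal 1.
#'
#' @param response a `pcd_response`.
#' @return a list with `components` (named numeric) and `total`.
#' @export
probability_ledger <- function(response) {
  lg <- response$ledger
  comp <- c(transmission = lg$transmission, no_fluorescence = lg$p_nofluor)
  for (nm in names(lg$branches)) comp[[nm]] <- lg$branches[[nm]]$prob
  list(components = comp, total = sum(comp))
}
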