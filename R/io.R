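# CSV serialization of the response matrix and count covariance.

#' Write a spectral response as long-format CSV
#'
#' One row per (incident energy, pixel offset, recorded bin) with nonzero
#' probability mass; columns `incident_keV`, `di`, `dj`,
#' `recorded_bin_low_keV`, `probability`.
#'
#' @param sresp a `pcd_spectral_response`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_response_csv <- function(sresp, path) {
  stopifnot(inherits(sresp, "pcd_spectral_response"))
  off <- .offsets3()
  lo <- sresp$grid[-length(sresp$grid)]
  rows <- list()
  for (i in seq_along(sresp$energies)) for (t in 1:9) {
    v <- sresp$recorded[i, t, ]
    nz <- v > 0
    if (!any(nz)) next
    rows[[length(rows) + 1]] <- data.frame(
      incident_keV = sresp$energies[i], di = off$di[t], dj = off$dj[t],
      recorded_bin_low_keV = lo[nz], probability = v[nz])
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("incident_keV", "di", "dj", "recorded_bin_low_keV",
            "probability")
  if (!all(need %in% names(d)))
    stop("response CSV needs columns ", paste(need, collapse = ", "))
  grid <- .internal_grid()
  lo <- grid[-length(grid)]
  energies <- sort(unique(d$incident_keV))
  rec <- array(0, c(length(energies), 9, length(lo)))
  off <- .offsets3()
  ei <- match(d$incident_keV, energies)
  ti <- match(paste(d$di, d$dj), paste(off$di, off$dj))
  bi <- match(round(d$recorded_bin_low_keV, 6), round(lo, 6))
  if (anyNA(bi)) stop("recorded bins do not match the internal grid")
  rec[cbind(ei, ti, bi)] <- d$probability
  structure(list(energies = energies, grid = grid, deposit = NULL,
                 recorded = rec, geometry = NULL, params = NULL,
                 res = NULL),
            class = "pcd_spectral_response")
}

#' Write a count covariance as CSV
#'
#' The normalized (correlation) or raw covariance matrix with
#' (pixel, window) labels as the first column and header row, preceded by
#' a `mean` row.
#'
#' @param cov a `pcd_cov`.
#' @param path file path.
#' @param which `"cor"` (normalized) or `"cov"` (raw).
#' @return the path, invisibly.
#' @export
write_covariance_csv <- function(cov, path, which = c("cor", "cov")) {
  which <- match.arg(which)
  stopifnot(inherits(cov, "pcd_cov"))
  M <- rbind(mean = cov$mean, cov[[which]])
  d <- data.frame(label = rownames(M), M, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
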