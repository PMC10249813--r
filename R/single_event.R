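# Single-event analysis: cluster classification of low-fluence frames,
# N_single / N_multiple counting over a threshold ladder, and estimation
# of the central- and neighbor-pixel spectra from those counts.

#' Classify one frame into pixel clusters
#'
#' Connected components of the above-threshold pixels under
#' 8-connectivity (edge- and corner-adjacent pixels belong to the same
#' cluster, since charge sharing reaches diagonal neighbors through pixel
#' corners).
#'
#' @param frame a data.frame with integer columns `row_`, `col_` of
#'   flagged pixels (one frame).
#' @return a data.frame with one row per cluster: `cluster`, `size`.
#' @export
classify_frame <- function(frame) {
  n <- nrow(frame)
  if (!n) return(data.frame(cluster = integer(0), size = integer(0)))
  sizes <- .cluster_sizes(frame$col_, frame$row_)
  data.frame(cluster = seq_along(sizes), size = sizes)
}

#' Count single and multiple events at one threshold
#'
#' Thresholds the recorded frame energies (strict greater-than), splits
#' each frame into 8-connected clusters, and counts clusters of size 1
#' (`N_single`) and of size >= 2 (`N_multiple`) over all frames. Each
#' cluster counts as one event; frames with several well-separated
#' clusters contribute each cluster independently.
#'
#' @param frames a `pcd_frames` object from [simulate_frames()] (sparse
#'   recorded energies per frame).
#' @param threshold comparator threshold in keV.
#' @return a list with `threshold`, `n_single`, `n_multiple`.
#' @export
count_events <- function(frames, threshold) {
  dt <- data.table::as.data.table(frames)[energy > threshold]
  if (!nrow(dt))
    return(list(threshold = threshold, n_single = 0L, n_multiple = 0L))
  per <- dt[, {
    sz <- .cluster_sizes(col_, row_)
    .(ns = sum(sz == 1L), nm = sum(sz >= 2L))
  }, by = frame]
  list(threshold = threshold, n_single = sum(per$ns),
       n_multiple = sum(per$nm))
}

#' Count events over a threshold ladder
#'
#' @param frames a `pcd_frames`.
#' @param thresholds strictly increasing thresholds in keV.
#' @return a data.frame with `threshold`, `n_single`, `n_multiple`.
#' @export
count_events_sweep <- function(frames, thresholds) {
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  rows <- lapply(thresholds, function(Tk) count_events(frames, Tk))
  data.frame(threshold = thresholds,
             n_single = vapply(rows, `[[`, numeric(1), "n_single"),
             n_multiple = vapply(rows, `[[`, numeric(1), "n_multiple"))
}

#' Estimate central- and neighbor-pixel spectra from event counts
#'
#' Applies the single-event estimators
#' `I_central(T) = N_single(T) + N_multiple(T)` and
#' `I_neighbor(T) = N_multiple(T)`, then differentiates each threshold
#' curve between successive thresholds. The differentiated central
#' spectrum is normalized to its maximum and the same factor is applied
#' to the neighbor spectrum, preserving their relative scale.
#'
#' @param counts a data.frame with `threshold`, `n_single`, `n_multiple`
#'   (strictly increasing thresholds).
#' @param normalize logical; apply the shared max-normalization.
#' @return a list with `central` and `neighbor` (threshold curves,
#'   data.frames with `threshold`, `counts`) and `central_spectrum`,
#'   `neighbor_spectrum` (`pcd_spectrum`s on the threshold bins).
#' @export
estimate_central_neighbor <- function(counts, normalize = TRUE) {
  stopifnot(all(c("threshold", "n_single", "n_multiple") %in% names(counts)))
  if (is.unsorted(counts$threshold, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  central <- data.frame(threshold = counts$threshold,
                        counts = counts$n_single + counts$n_multiple)
  neighbor <- data.frame(threshold = counts$threshold,
                         counts = counts$n_multiple)
  cs <- differentiate_sweep(central)
  ns <- differentiate_sweep(neighbor)
  if (normalize) {
    m <- max(cs$values)
    if (m <= 0) stop("central spectrum is all zero; cannot normalize")
    cs$values <- cs$values / m
    ns$values <- ns$values / m
    cs$normalization <- "max"
  }
  list(central = central, neighbor = neighbor,
       central_spectrum = cs, neighbor_spectrum = ns)
}

#' Write frames or event counts as CSV
#'
#' Frames are written sparsely (`frame,row,col,energy`); counts with one
#' row per threshold.
#'
#' @param frames a `pcd_frames`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_frames_csv <- function(frames, path) {
  utils::write.csv(data.frame(frame = frames$frame, row = frames$row_,
                              col = frames$col_, energy = frames$energy),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frames_csv
#' @param array_dim array extent of the frames being read.
#' @param n_frames number of frames recorded (frames with no
#'   above-threshold pixel are absent from the sparse file).
#' @export
read_frames_csv <- function(path, array_dim = c(256L, 256L),
                            n_frames = NULL) {
  d <- utils::read.csv(path)
  dt <- data.table::data.table(frame = as.integer(d$frame),
                               row_ = as.integer(d$row),
                               col_ = as.integer(d$col),
                               energy = as.numeric(d$energy))
  structure(dt, class = c("pcd_frames", class(dt)),
            n_frames = if (is.null(n_frames)) max(dt$frame) else n_frames,
            array_dim = array_dim, n_photons = NA_integer_, seed = NA)
}
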