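# Count statistics derived from the deterministic joint outcome
# distribution: joint count-pattern probabilities over the 3x3
# neighborhood, expected single/multiple cluster counts, and the count
# covariance over (pixel, energy window) pairs.
#
# Counting model: a pixel can only register a count if it received charge
# (no dark counting); its recorded energy is the deposit plus independent
# Gaussian noise of sd sigma_e.

# per-outcome long table of active pixels
.active_long <- function(response) {
  oc <- response$outcomes
  if (is.null(oc))
    stop("response was computed without the joint outcome table; ",
         "use level = \"joint\"")
  dcols <- paste0("d", 1:9)
  dt <- data.table::melt(
    data.table::data.table(oid = seq_len(nrow(oc)), prob = oc$prob,
                           oc[, dcols, with = FALSE]),
    id.vars = c("oid", "prob"), variable.name = "pix", value.name = "dep")
  dt[, pix := as.integer(sub("d", "", pix))]
  dt[dep > 0]
}

#' Joint count-pattern distribution of the deterministic response
#'
#' For the threshold ladder `thresholds`, computes the probability of
#' every joint pattern of (pixel, energy-window) counts over the 3x3
#' neighborhood per incident photon, marginalizing the Gaussian noise
#' per active pixel. Pattern keys match [event_pattern_counts()].
#'
#' @param response a `pcd_response` computed with `level = "joint"`.
#' @param thresholds strictly increasing thresholds (keV); window `k` is
#'   `(T_k, T_k+1]`, the last window is open-ended.
#' @param prune patterns and partial expansions below this probability are
#'   dropped (their mass is reported in the `pruned` attribute).
#' @return a data.table with `key_` and `prob`, carrying attribute
#'   `pruned`.
#' @export
outcome_pattern_distribution <- function(response, thresholds,
                                         prune = 1e-10) {
  stopifnot(!is.unsorted(thresholds, strictly = TRUE))
  sigma <- response$params$sigma_e
  act <- .active_long(response)
  # per active pixel, probability of each window category (0 = no count)
  nt <- length(thresholds)
  up <- stats::pnorm(outer(act$dep, thresholds, `-`) / max(sigma, 1e-12))
  if (sigma == 0) up <- (outer(act$dep, thresholds, `-`) > 0) * 1
  cats <- cbind(1 - up[, 1], up[, -nt, drop = FALSE] -
                  up[, -1, drop = FALSE], up[, nt])
  long <- data.table::data.table(
    oid = rep(act$oid, nt + 1), pix = rep(act$pix, nt + 1),
    cat_ = rep(0:nt, each = nrow(act)), pc = as.vector(cats))
  long <- long[pc > 1e-14]
  data.table::setkey(long, oid)
  n_out <- nrow(response$outcomes)
  chunks <- split(seq_len(n_out), ceiling(seq_len(n_out) / 5e4))
  parts <- vector("list", length(chunks))
  for (ic in seq_along(chunks)) {
    ids <- chunks[[ic]]
    state <- data.table::data.table(oid = ids, key_ = "",
                                    p = response$outcomes$prob[ids])
    sub_all <- long[.(ids)]
    for (t in 1:9) {
      sub <- sub_all[pix == t]
      if (!nrow(sub)) next
      merged <- merge(state, sub, by = "oid", all.x = TRUE,
                      allow.cartesian = TRUE)
      merged[, p := data.table::fifelse(is.na(pc), p, p * pc)]
      merged[, key_ := data.table::fifelse(
        is.na(pc) | cat_ == 0, key_,
        data.table::fifelse(key_ == "", paste0(t, ":", cat_),
                            paste0(key_, ";", t, ":", cat_)))]
      state <- merged[p > prune, .(oid, key_, p)]
    }
    parts[[ic]] <- state[, .(prob = sum(p)), by = key_]
  }
  out <- data.table::rbindlist(parts)[, .(prob = sum(prob)), by = key_]
  # transmitted photons produce the empty pattern
  tr <- response$ledger$transmission
  if ("" %in% out$key_) out[key_ == "", prob := prob + tr]
  else out <- data.table::rbindlist(list(out,
    data.table::data.table(key_ = "", prob = tr)))
  data.table::setorder(out, -prob)
  data.table::setattr(out, "pruned", 1 - sum(out$prob))
  out
}

#' Total variation distance between two pattern distributions
#'
#' @param a,b pattern tables with columns `key_` and `prob` (or `phat`).
#' @return total variation distance in `[0, 1]`.
#' @export
pattern_tv <- function(a, b) {
  pa <- if ("prob" %in% names(a)) a$prob else a$phat
  pb <- if ("prob" %in% names(b)) b$prob else b$phat
  m <- merge(data.table::data.table(key_ = a$key_, pa = pa),
             data.table::data.table(key_ = b$key_, pb = pb),
             by = "key_", all = TRUE)
  m[is.na(m)] <- 0
  sum(abs(m$pa - m$pb)) / 2
}

# cluster classification of every 3x3 occupancy mask (8-connectivity);
# cached: mask index = sum(2^(t-1)) + 1 -> c(n_single, n_multiple)
.mask_cluster_cache <- new.env(parent = emptyenv())
.mask_clusters <- function() {
  if (!is.null(.mask_cluster_cache$tab)) return(.mask_cluster_cache$tab)
  off <- .offsets3()
  tab <- matrix(0L, 512, 2)
  for (m in 1:511) {
    pix <- which(bitwAnd(m, bitwShiftL(1L, 0:8)) != 0)
    sizes <- .cluster_sizes(off$di[pix], off$dj[pix])
    tab[m + 1, ] <- c(sum(sizes == 1L), sum(sizes >= 2L))
  }
  .mask_cluster_cache$tab <- tab
  tab
}

# sizes of 8-connected components of a sparse pixel set (union-find)
.cluster_sizes <- function(x, y) {
  n <- length(x)
  if (!n) return(integer(0))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(x[i] - x[j]) <= 1 && abs(y[i] - y[j]) <= 1) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(table(roots))
}

#' Expected single/multiple event counts per incident photon
#'
#' For each threshold, enumerates the above-threshold occupancy patterns
#' of the 3x3 neighborhood implied by the deterministic outcome
#' distribution (noise marginalized per active pixel), classifies each
#' pattern into 8-connected clusters, and accumulates the expected number
#' of single-pixel and multiple-pixel clusters per incident photon --
#' the model-side analogue of the single-event analysis.
#'
#' @param response a `pcd_response` with `level = "joint"`.
#' @param thresholds threshold vector in keV.
#' @param prune probability floor for the pattern expansion.
#' @return a data.table with `threshold`, `n_single`, `n_multiple`
#'   (expected clusters per incident photon).
#' @export
expected_event_counts <- function(response, thresholds, prune = 1e-10) {
  sigma <- response$params$sigma_e
  act <- .active_long(response)
  ctab <- .mask_clusters()
  res <- data.table::data.table(threshold = thresholds,
                                n_single = 0, n_multiple = 0)
  for (i in seq_along(thresholds)) {
    Tk <- thresholds[i]
    if (sigma > 0) qv <- stats::pnorm((act$dep - Tk) / sigma)
    else qv <- as.numeric(act$dep > Tk)
    state <- data.table::data.table(oid = seq_len(nrow(response$outcomes)),
                                    mask = 0L,
                                    p = response$outcomes$prob)
    for (t in 1:9) {
      rows <- act$pix == t
      if (!any(rows)) next
      sub <- data.table::data.table(oid = act$oid[rows], q = qv[rows])
      merged <- merge(state, sub, by = "oid", all.x = TRUE)
      on <- merged[!is.na(q) & q > prune]
      on[, `:=`(mask = bitwOr(mask, bitwShiftL(1L, t - 1L)), p = p * q)]
      merged[, p := data.table::fifelse(is.na(q), p, p * (1 - q))]
      state <- data.table::rbindlist(list(merged[, .(oid, mask, p)],
                                          on[, .(oid, mask, p)]))
      state <- state[p > prune, .(p = sum(p)), by = .(oid, mask)]
    }
    agg <- state[, .(p = sum(p)), by = mask]
    res$n_single[i] <- sum(agg$p * ctab[agg$mask + 1L, 1])
    res$n_multiple[i] <- sum(agg$p * ctab[agg$mask + 1L, 2])
  }
  res
}

#' Count covariance over (pixel, energy window) pairs
#'
#' Per incident photon, the count in window `w` of pixel `j` is the
#' indicator that the pixel's recorded energy falls in that window.
#' Returns the mean count vector, the covariance matrix over the
#' outcome distribution and the noise, and its normalized (correlation)
#' form, over all 9 pixels and the windows of `windows` (a vector of bin
#' edges, default 1-keV windows).
#'
#' @param response a `pcd_response` with `level = "joint"`.
#' @param windows energy-window edges in keV (strictly increasing).
#' @return an object of class `pcd_cov`: list with `mean`, `cov`, `cor`,
#'   `windows`, `labels`.
#' @export
compute_count_covariance <- function(response,
                                     windows = energy_grid(0, 60, 1)) {
  windows <- as.numeric(windows)
  if (length(windows) < 2) stop("need at least one energy window")
  stopifnot(!is.unsorted(windows, strictly = TRUE))
  sigma <- response$params$sigma_e
  act <- .active_long(response)
  nw <- length(windows) - 1L
  nv <- 9L * nw
  # window probabilities per active (outcome, pixel)
  pw <- function(dep) {
    if (sigma > 0) {
      # column j of P is P(recorded > windows[j])
      P <- stats::pnorm(outer(dep, windows, `-`) / sigma)
      P[, -(nw + 1), drop = FALSE] - P[, -1, drop = FALSE]
    } else {
      b <- findInterval(dep, windows, left.open = TRUE)
      P <- matrix(0, length(dep), nw)
      ok <- b >= 1 & b <= nw
      P[cbind(which(ok), b[ok])] <- 1
      P
    }
  }
  Pact <- pw(act$dep)
  wrow <- response$outcomes$prob[act$oid]
  mu <- numeric(nv)
  for (t in 1:9) {
    rows <- act$pix == t
    if (any(rows))
      mu[(t - 1) * nw + seq_len(nw)] <-
        colSums(Pact[rows, , drop = FALSE] * wrow[rows])
  }
  # second moments: same pixel -> windows mutually exclusive
  S <- matrix(0, nv, nv)
  for (t in 1:9) {
    idx <- (t - 1) * nw + seq_len(nw)
    diag(S)[idx] <- mu[idx]
  }
  # pairs of distinct active pixels within the same outcome
  pair <- merge(act[, .(oid, pix, dep)], act[, .(oid, pix, dep)],
                by = "oid", allow.cartesian = TRUE,
                suffixes = c("_1", "_2"))
  pair <- pair[pix_1 < pix_2]
  if (nrow(pair)) {
    pair[, w := response$outcomes$prob[oid]]
    for (grp in split(seq_len(nrow(pair)),
                      paste(pair$pix_1, pair$pix_2))) {
      t1 <- pair$pix_1[grp[1]]; t2 <- pair$pix_2[grp[1]]
      P1 <- pw(pair$dep_1[grp]); P2 <- pw(pair$dep_2[grp])
      blk <- crossprod(P1 * pair$w[grp], P2)
      i1 <- (t1 - 1) * nw + seq_len(nw); i2 <- (t2 - 1) * nw + seq_len(nw)
      S[i1, i2] <- S[i1, i2] + blk
      S[i2, i1] <- S[i2, i1] + t(blk)
    }
  }
  C <- S - tcrossprod(mu)
  v <- diag(C)
  dn <- ifelse(v > 1e-15, 1 / sqrt(v), 0)
  R <- C * tcrossprod(dn)
  diag(R)[v > 1e-15] <- 1
  off <- .offsets3()
  labels <- paste0(rep(paste0("(", off$di, ",", off$dj, ")"), each = nw),
                   "|", rep(windows[-length(windows)], times = 9), "-",
                   rep(windows[-1], times = 9))
  dimnames(C) <- dimnames(R) <- list(labels, labels)
  names(mu) <- labels
  structure(list(mean = mu, cov = C, cor = R, windows = windows,
                 labels = labels), class = "pcd_cov")
}

#' @export
print.pcd_cov <- function(x, ...) {
  cat(sprintf("<pcd_cov> %d pixels x %d windows (%g-%g keV)\n",
              9, length(x$windows) - 1, min(x$windows), max(x$windows)))
  cat(sprintf("  total expected counts/photon: %.4f\n", sum(x$mean)))
  invisible(x)
}
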