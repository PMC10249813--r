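# shared fixtures: built once per test run

mat <- gaas_material()
geo <- detector_geometry()

# coarse quadrature for structural tests where speed matters more than
# the last digit of accuracy
fast_res <- response_resolution(lateral = 7, lateral_primary = 15,
                                depth = 16, polar = 24, azimuth = 64,
                                path = 12, delta_cells = 9)

# a mid-resolution setting for quantitative spot checks
mid_res <- response_resolution(lateral = 11, lateral_primary = 31,
                               depth = 32, polar = 32, azimuth = 192,
                               path = 16, delta_cells = 11)

offsets3 <- gaaspcd:::.offsets3()

# uniform points in a ball of radius r (rejection sampling, seeded)
sample_ball <- function(n, r, seed) {
  set.seed(seed)
  pts <- matrix(numeric(0), ncol = 3)
  while (nrow(pts) < n) {
    u <- matrix(stats::runif(3 * n, -1, 1), ncol = 3)
    u <- u[rowSums(u^2) <= 1, , drop = FALSE]
    pts <- rbind(pts, u)
  }
  pts[seq_len(n), ] * r
}

# total deposited energy + lost energy per outcome row
outcome_total <- function(response) {
  oc <- response$outcomes
  rowSums(as.matrix(oc[, paste0("d", 1:9), with = FALSE])) + oc$lost
}
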