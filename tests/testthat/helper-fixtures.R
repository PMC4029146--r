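# random valid cumulative DVH on a uniform grid (seeded by the caller)
random_cumulative_dvh <- function(max_dose = stats::runif(1, 10, 80),
                                  n_bins = sample(20:120, 1)) {
  grid <- seq(0, max_dose, length.out = n_bins + 1)
  # non-increasing complete curve from sorted uniforms, ending at 0
  v <- sort(stats::runif(n_bins - 1), decreasing = TRUE)
  v <- c(1, v * stats::runif(1, 0.2, 1), 0)
  v <- cummin(pmin(v, 1))
  dvh_cumulative(grid, v)
}

# two contiguous bins whose midpoints are exactly d1 and d2
two_bin_dvh <- function(d1, d2, f1 = 0.5, f2 = 0.5) {
  e <- (d1 + d2) / 2
  dvh_differential(dose_lo = c(max(2 * d1 - e, 0), e),
                   dose_hi = c(e, 2 * d2 - e),
                   volume_fraction = c(f1, f2))
}

# differential DVH from a voxel dose vector, 0.1 Gy bins
voxel_dvh <- function(doses, bin = 0.1) {
  breaks <- seq(0, max(doses) + bin, by = bin)
  h <- hist(doses, breaks = breaks, plot = FALSE)
  dvh_differential(breaks[-length(breaks)], breaks[-1],
                   h$counts / length(doses))
}
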