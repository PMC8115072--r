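# Shared builders for small synthetic study scenarios. Sizes are kept small
# (short durations, modest sampling rates) so the suite stays fast; the
# generator itself defaults to the full study conditions.

# Standard 4 x 8 grid at 2 mm pitch.
std_grid <- function(bad = integer(0)) make_grid(4, 8, 2, bad = bad)

# Bidirectional 6 Hz scenario: two opposite-direction components
# alternating in `seg_s`-second segments.
bidir_recording <- function(duration_s = 20, seg_s = 2, noise_sd = 2,
                            amplitude = 10, fs = 256, seed = 7,
                            dir1 = 30, dir2 = 210, k = 15,
                            topo1 = NULL, topo2 = NULL) {
  g <- std_grid()
  c1 <- wave_component(6, dir1, k, amplitude = amplitude,
                       amp_topography = topo1)
  c2 <- wave_component(6, dir2, k, amplitude = amplitude,
                       amp_topography = topo2)
  starts <- seq(0, duration_s - seg_s, by = seg_s)
  segs <- data.frame(start_s = starts, end_s = starts + seg_s)
  segs$component <- as.list(rep(1:2, length.out = length(starts)))
  synthesize(g, list(c1, c2), regime_schedule(segs),
             noise_sd = noise_sd, duration_s = duration_s, fs = fs,
             seed = seed)
}

# Brute-force Hodges-Ajne m: sweep half-plane boundaries on a fine grid.
brute_half_circle_min <- function(x) {
  n <- length(x)
  grid <- seq(0, 2 * pi, length.out = 7201)
  m <- n
  for (b in grid) {
    d <- (x - b) %% (2 * pi)
    cnt <- sum(d < pi)
    m <- min(m, cnt, n - cnt)
  }
  m
}

# Reference Benjamini-Hochberg step-up adjusted p-values.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}
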