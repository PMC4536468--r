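# Shared helpers for building small synthetic inputs in tests.

# A noise-free, oscillation-free simulation configuration.
noiseless_cfg <- function(...) {
  sim_config(noise_sigma_um = 0, osc_amplitude_um = 0, ...)
}

# Map a kinetochore row index of the generator's KT_INNER block (rows
# 1..n are the +axis sisters, n+1..2n the -axis sisters) to its
# generator pair index.
gen_pair_index <- function(i, n_pairs) ((i - 1L) %% n_pairs) + 1L

# Minimal well-formed detection data frame.
make_detections <- function(n = 3L, cell_id = "c1", channel = "KT_INNER",
                            frame = 0L, time_s = frame * 7.5) {
  data.frame(cell_id = cell_id, frame = frame, time_s = time_s,
             channel = channel,
             x_um = seq_len(n), y_um = 0, z_um = 0, intensity = 100,
             stringsAsFactors = FALSE)
}

# Random rigid rotation matrix (uniform axis, uniform angle).
random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0, 2 * pi)
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * k + (1 - cos(th)) * (k %*% k)
}
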