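# Shared fixtures: tiny schemes, single-voxel volumes and analytic decays.

hmb_shells <- c(100, 200, 300, 600, 900, 1200, 1500, 1800, 2100, 2400,
                2700, 3000)

# A compact multi-shell scheme: `n_dirs` directions on each of the HMb
# shells plus `n_b0` leading b0 measurements.
tiny_scheme <- function(shells = hmb_shells, n_dirs = 12, n_b0 = 6,
                        seed = 1) {
  dirs <- generate_directions(n_dirs, seed = seed)
  b <- c(rep(0, n_b0), rep(shells, each = n_dirs))
  g <- rbind(matrix(0, n_b0, 3),
             dirs[rep(seq_len(n_dirs), times = length(shells)), ])
  gradient_scheme(b, g, delta_small = 3.55, delta_big = 8.52, label = "tiny")
}

# Single-voxel volume from a measurement-wise signal vector.
one_voxel_volume <- function(signal, scheme) {
  dwi_volume(array(signal, c(1, 1, 1, length(signal))), scheme)
}

# Noise-free single-tensor signal over a scheme.
tensor_signal <- function(scheme, eigs, R = diag(3), s0 = 100) {
  D <- R %*% diag(eigs) %*% t(R)
  g <- cbind(scheme$gx, scheme$gy, scheme$gz)
  s0 * exp(-scheme$b * rowSums((g %*% D) * g))
}

# Analytic bi-exponential decay on a b-grid (fractions of S0).
biexp_decay <- function(b, v_f, D_f, D_s) {
  directional_decay(b, v_f * exp(-D_f * b) + (1 - v_f) * exp(-D_s * b))
}

native_rates <- list(v_f = 0.5, D_f = 1.3e-3, D_s = 0.17e-3)

k_biexp_true <- function(v_f, D_f, D_s) {
  d <- v_f * D_f + (1 - v_f) * D_s
  3 * v_f * (1 - v_f) * (D_f - D_s)^2 / d^2
}

# Rician-corrupted copy of a signal vector.
add_rician <- function(signal, sigma) {
  sqrt((signal + rnorm(length(signal), sd = sigma))^2 +
         rnorm(length(signal), sd = sigma)^2)
}
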