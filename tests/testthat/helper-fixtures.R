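# Shared fixtures: everything is generated in code at test time.

tiny_structure <- function(n = 10, chains = 1, seed = 42) {
  make_toy_structure(n, chains, seed)
}

# A mode set with planted per-system statistics, on a single subunit.
tiny_modes <- function(structure, n_modes = 2, seed = 11, sigma = 0,
                       systems = list(X = list(mu = c(2, 0), amp = c(1.5, 0.5)))) {
  m <- make_mode_set(structure, n_modes, seed, sigma_noise = sigma)
  for (tag in names(systems)) {
    m <- set_system_modes(m, tag, systems[[tag]]$mu, systems[[tag]]$amp)
  }
  m
}

# Random proper rotation (QR of a Gaussian matrix, det forced to +1).
random_rotation <- function() {
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# A chiral 4-point set (non-planar, no internal symmetry).
chiral_points <- function() {
  rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2.5, 0), c(0.3, 0.7, 3.1))
}

quick_truth <- function(kd = 0.6, n_bind = 5, n_null = 2, noise = 0,
                        L = c(0, 0.25, 0.5, 1, 2, 4, 8), seed = 5) {
  d0 <- c(seq(0.2, 0.4, length.out = n_bind), rep(0, n_null))
  names(d0) <- paste0("r", seq_along(d0))
  titration_ground_truth(kd, d0, P = 0.5, L = L, noise_sd = noise, seed = seed)
}
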