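# shared fixtures and independent oracles for the test suite

# small, fast phantom for smoke tests
tiny_phantom <- function(seed = 1, size = 32, frames = 6, amplitude = 2,
                         noise = 0.005) {
  generate_phantom(phantom_spec(image_size = size, num_frames = frames,
                                motion_amplitude_px = amplitude,
                                noise_std = noise, seed = seed))
}

# smooth random test image (superposition of random Gaussian blobs)
smooth_image <- function(h, w = h, n_blobs = 5) {
  img <- matrix(0, h, w)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(n_blobs))
    img <- img + runif(1, 0.3, 1) *
      exp(-((rows - runif(1, 1, h))^2 + (cols - runif(1, 1, w))^2) /
            (2 * runif(1, 2, 6)^2))
  img
}

# --- independent geodesic-medoid oracle (Floyd-Warshall) -------------------
# builds the symmetric kNN adjacency by direct sorting, runs the classic
# triple-loop all-pairs shortest path, and returns the index minimizing the
# geodesic distance sum; k is increased until the graph is connected
fw_medoid <- function(d, k0) {
  N <- nrow(d)
  for (k in k0:(N - 1)) {
    adj <- matrix(Inf, N, N)
    diag(adj) <- 0
    for (i in seq_len(N)) {
      others <- setdiff(seq_len(N), i)
      nb <- others[order(d[i, others], others)][seq_len(k)]
      adj[i, nb] <- d[i, nb]
      adj[nb, i] <- d[nb, i]
    }
    g <- adj
    for (m in seq_len(N)) for (i in seq_len(N)) for (j in seq_len(N))
      if (g[i, m] + g[m, j] < g[i, j]) g[i, j] <- g[i, m] + g[m, j]
    if (all(is.finite(g))) return(which.min(rowSums(g)))
  }
  which.min(rowSums(g))
}

# finite-difference gradient of the total loss with respect to the fields
numeric_loss_grad <- function(seq, template, u, cfg, eps = 1e-6) {
  num <- array(0, dim(u))
  for (i in seq_along(u)) {
    up <- u; up[i] <- up[i] + eps
    dn <- u; dn[i] <- dn[i] - eps
    num[i] <- (total_loss(seq, template, deformation_sequence(up),
                          cfg)$value -
               total_loss(seq, template, deformation_sequence(dn),
                          cfg)$value) / (2 * eps)
  }
  num
}
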