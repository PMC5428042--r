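# shared fixtures, built in code at test time

default_instrument <- build_instrument()

# polarimetric round trip: truth -> 24-frame stack -> inversion -> map
depol_roundtrip <- function(map, seed, noise_sd = 0.01) {
  truth <- render_mueller(map, seed = seed)
  stack <- simulate_stack(truth, default_instrument, noise = "gaussian",
                          noise_sd = noise_sd, seed = seed + 1L)
  depolarization_map(reconstruct_mueller(stack))
}

# random physically sensible Mueller factor triple: depolarizer (diagonal,
# positive), retarder (rotation about a random axis), diattenuator
random_factors <- function() {
  dv <- stats::runif(3, -0.3, 0.3)
  D <- sqrt(sum(dv^2))
  dh <- dv / D
  sq <- sqrt(1 - D^2)
  m_D <- sq * diag(3) + (1 - sq) * tcrossprod(dh)
  M_D <- rbind(c(1, dv), cbind(dv, m_D))
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, 0.9 * pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  R3 <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
  M_R <- rbind(c(1, 0, 0, 0), cbind(rep(0, 3), R3))
  a <- stats::runif(3, 0.3, 0.95)
  M_delta <- rbind(c(1, 0, 0, 0), cbind(rep(0, 3), diag(a)))
  list(M = M_delta %*% M_R %*% M_D,
       D = D, delta = 1 - mean(a), R = ang)
}

# PIRL organ spectra, n replicates per organ
organ_spectra <- function(organs = c("liver", "kidney", "brain", "lung"),
                          n_rep = 6L, duration_s = 10, seed0 = 100L) {
  specs <- list(); cls <- character(0); k <- 0L
  for (o in organs) for (r in seq_len(n_rep)) {
    k <- k + 1L
    specs[[k]] <- simulate_pirl(o, duration_s, seed = seed0 + k)
    cls[k] <- o
  }
  list(spectra = specs, classes = cls)
}
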