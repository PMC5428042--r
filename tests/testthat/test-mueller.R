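test_that("forward model reproduces hand-computed frame values", {
  inst <- default_instrument
  # identity optics, H generator / H analyzer -> unit intensity
  ident <- mueller_from_delta(matrix(0, 2, 2))
  st <- simulate_stack(ident, inst, noise = "none")
  k_hh <- which(inst$pairs[, 1] == 1 & inst$pairs[, 2] == 1)
  expect_equal(st$frames[k_hh, ], rep(1, 4))
  # ideal depolarizer diag(1,0,0,0): any generator, H analyzer -> 1/2
  dep <- mueller_from_delta(matrix(1, 2, 2))
  sd <- simulate_stack(dep, inst, noise = "none")
  for (k in which(inst$pairs[, 2] == 1))
    expect_equal(sd$frames[k, 1], 0.5)
  # frames agree with the direct matrix product at every pair
  M <- mueller_at(dep, 1, 1)
  for (k in seq_len(inst$n_frames)) {
    g <- inst$psg[, inst$pairs[k, 1]]
    a <- inst$psa[, inst$pairs[k, 2]]
    expect_equal(sd$frames[k, 1], as.numeric(t(a) %*% M %*% g) / 2)
  }
})

test_that("noiseless stacks invert exactly (round trip)", {
  truth <- mueller_from_delta(matrix(0.35, 8, 8))
  st <- simulate_stack(truth, default_instrument, noise = "none")
  rec <- reconstruct_mueller(st)
  expect_lt(max(abs(rec$vec - truth$vec)), 1e-10)
})

test_that("any physical Mueller image is recovered exactly without noise", {
  set.seed(21)
  n <- 12L
  vec <- vapply(seq_len(n), function(i) as.numeric(random_factors()$M),
                numeric(16))
  truth <- mueller_image(vec, c(3L, 4L))
  st <- simulate_stack(truth, default_instrument, noise = "none")
  rec <- reconstruct_mueller(st)
  expect_lt(max(abs(rec$vec - truth$vec)), 1e-8)
  # against a per-pixel dense least-squares oracle
  for (j in c(1L, 7L, 12L)) {
    oracle <- qr.solve(default_instrument$W, st$frames[, j])
    expect_equal(rec$vec[, j], oracle, tolerance = 1e-9)
  }
})

test_that("1% measurement noise keeps mean reconstructed depolarization within 0.01", {
  truth <- mueller_from_delta(matrix(0.35, 25, 40))  # 1000 pixels
  st <- simulate_stack(truth, default_instrument, noise = "gaussian",
                       noise_sd = 0.01, seed = 77)
  dm <- depolarization_map(reconstruct_mueller(st))
  expect_lt(abs(mean(dm$values) - 0.35), 0.01)
})

test_that("frame count mismatch is an input error", {
  truth <- mueller_from_delta(matrix(0.2, 2, 2))
  st <- simulate_stack(truth, default_instrument, noise = "none")
  st$frames <- st$frames[1:20, ]
  expect_error(reconstruct_mueller(st), "frames")
})

test_that("Lu-Chipman handles canonical matrices analytically", {
  d0 <- lu_chipman(diag(4))
  expect_equal(d0$diattenuation, 0)
  expect_equal(d0$depolarization, 0)
  expect_equal(d0$retardance, 0)
  d1 <- lu_chipman(diag(c(1, 0.65, 0.65, 0.65)))
  expect_equal(d1$depolarization, 0.35)
  expect_equal(d1$diattenuation, 0)
  expect_equal(d1$retardance, 0)
  d2 <- lu_chipman(diag(c(1, 0.80, 0.80, 0.80)))
  expect_equal(d2$depolarization, 0.20)
  # isotropic depolarizer family: delta = 1 - |a|, including negative a
  for (a in c(0, 0.25, 0.5, -0.4, 1)) {
    expect_equal(lu_chipman(diag(c(1, a, a, a)))$depolarization, 1 - abs(a))
  }
})

test_that("construct-then-decompose recovers known factors on 100 random triples", {
  set.seed(42)
  for (i in 1:100) {
    f <- random_factors()
    dec <- lu_chipman(f$M)
    expect_lt(abs(dec$diattenuation - f$D), 1e-8)
    expect_lt(abs(dec$depolarization - f$delta), 1e-8)
    expect_lt(abs(dec$retardance - f$R), 1e-8)
    # bounds and reassembly
    expect_true(dec$depolarization >= 0 && dec$depolarization <= 1)
    expect_true(dec$retardance >= 0 && dec$retardance <= pi)
    reassembled <- dec$M_delta %*% dec$M_R %*% dec$M_D
    expect_lt(max(abs(reassembled - f$M)), 1e-6)
  }
})

test_that("singular diattenuators fall back to a flagged pseudo-inverse", {
  M <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 0, 0), c(0, 0, 0, 0))
  dec <- lu_chipman(M)
  expect_true(dec$singular_diattenuator)
  expect_equal(dec$diattenuation, 1)
})

test_that("depolarization maps and the surviving-polarization convention agree", {
  img <- mueller_from_delta(matrix(0.35, 5, 5))
  dm <- depolarization_map(img)
  expect_equal(unname(dm$values), matrix(0.35, 5, 5))
  sp <- depolarization_map(img, metric = "surviving_polarization")
  expect_equal(unname(sp$values), matrix(0.65, 5, 5))
  expect_equal(convert_metric(sp)$values, dm$values)
  # invalid pixels propagate NaN/NA
  delta <- matrix(0.35, 5, 5); delta[3, 3] <- NA
  dm2 <- depolarization_map(mueller_from_delta(delta))
  expect_true(is.na(dm2$values[3, 3]))
  expect_equal(sum(is.na(dm2$values)), 1L)
})

test_that("negative noisy intensities are clamped and tallied", {
  truth <- mueller_from_delta(matrix(1, 10, 10))  # weak frames near zero
  expect_warning(
    st <- simulate_stack(truth, default_instrument, noise = "gaussian",
                         noise_sd = 3, seed = 5),
    "clamped")
  expect_true(st$n_clamped > 0)
  expect_true(all(st$frames >= 0))
})
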