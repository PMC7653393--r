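test_that("jump rates use the face diffusivity over h^2 with zero-flux outer faces", {
  g <- unit_geom()
  f <- compartment_field(g, 0, 1, h = 1/30, C0 = 10)
  expect_equal(unname(jump_rates(f, 15)), c(900, 900))
  expect_equal(unname(jump_rates(f, 1)), c(0, 900))
  expect_equal(unname(jump_rates(f, 30)), c(900, 0))
  # compartment-Brownian configuration: D1 vanishes at the I2 face, so the
  # rate of jumping right out of the final compartment is zero
  fcb <- compartment_field(g, 0, 2/3, h = 1/30, C0 = 10, diffusivity = "d1")
  expect_equal(unname(jump_rates(fcb, 20))[2], 0)
  # PDE-compartment configuration: D2 vanishes at the I1 face
  fpc <- compartment_field(g, 1/3, 1, h = 1/30, C0 = 10, diffusivity = "d2")
  expect_equal(unname(jump_rates(fpc, 1))[1], 0)
})

test_that("propensities follow the mass-action forms and floor at zero", {
  g <- blend_geometry(0, 1, 1/3, 2/3, D = 1)
  f <- compartment_field(g, 0, 1/3, h = 1/3, C0 = 0)
  r <- reaction_channels(k1 = 0.1, k2 = 89.7, mu = 10)
  p0 <- propensities(f, r)
  expect_equal(p0$production, 89.7 / 3)  # k2 * V with V = 1/3
  expect_equal(p0$decay, 0)
  expect_equal(p0$pair, 0)
  expect_equal(p0$diff_left + p0$diff_right, 0)
  f$C <- 5
  p <- propensities(f, r)
  expect_equal(p$decay, 50)
  expect_equal(p$pair, 0.1 * 5 * 4 / (2 / 3))
  # negative (transient blending) counts contribute nothing
  f$C <- -0.4
  pneg <- propensities(f, r)
  expect_equal(pneg$decay, 0)
  expect_equal(pneg$pair, 0)
})

test_that("diffusion-only SSA conserves the total count exactly", {
  g <- unit_geom()
  set.seed(101)
  f <- compartment_field(g, 0, 1, h = 1/20, C0 = 50)
  f <- ssa_advance(f, t0 = 0, t_end = 1)
  expect_identical(sum(f$C), 1000)
  # no particles and no production: state unchanged at t_end
  f0 <- compartment_field(g, 0, 1, h = 1/20, C0 = 0)
  f0 <- ssa_advance(f0, t0 = 0, t_end = 1)
  expect_identical(f0$C, rep(0, 20))
})

test_that("free-lattice mean-squared displacement grows as 2 D t", {
  # all mass in the centre compartment of a wide lattice, far from the walls;
  # non-interacting particles, so one big run estimates the single-particle MSD
  set.seed(102)
  gw <- blend_geometry(0, 8, 1, 7, D = 1)
  h <- 1/30
  n <- as.integer(8 / h)
  C0 <- rep(0, n); C0[n %/% 2] <- 10000
  f <- compartment_field(gw, 0, 8, h, C0 = C0)
  x0 <- f$centers[n %/% 2]
  f <- ssa_advance(f, t0 = 0, t_end = 0.2)
  msd <- sum(f$C * (f$centers - x0)^2) / sum(f$C)
  expect_equal(msd, 2 * 0.2, tolerance = 0.06)
})

test_that("spatially varying D2 jumps preserve the uniform equilibrium", {
  # face-evaluated rates give divergence-form diffusion, whose steady state
  # with zero-flux ends is uniform; Fickian hopping (rate from the compartment
  # centre) would pile mass where D2 is small
  g <- unit_geom()
  set.seed(103)
  reps <- 30
  acc <- numeric(20)
  for (r in seq_len(reps)) {
    f <- compartment_field(g, 1/3, 1, h = 1/30, C0 = 100, diffusivity = "d2")
    f <- ssa_advance(f, t0 = 0, t_end = 0.25)
    acc <- acc + f$C
  }
  dens <- acc / reps
  se <- sqrt(100 * (1 - 1/20)) / sqrt(reps)   # binomial occupancy scale
  expect_true(all(abs(dens - 100) < 6 * se))
})

test_that("production/pair-annihilation SSA matches the master-equation stationary mean", {
  # single well-mixed compartment, V = 1/3, birth rate k2*V = 29.9,
  # pair-annihilation rate k1 n (n-1) / (2V); stationary distribution of the
  # truncated master equation solved directly as the oracle
  V <- 1/3
  birth <- 89.7 * V
  k1 <- 0.1
  nmax <- 80
  Q <- matrix(0, nmax + 1, nmax + 1)
  for (n in 0:nmax) {
    i <- n + 1
    if (n < nmax) Q[i, i + 1] <- birth
    if (n >= 2) Q[i, i - 2] <- k1 * n * (n - 1) / (2 * V)
    Q[i, i] <- -sum(Q[i, ])
  }
  A <- t(Q)
  A[nmax + 1, ] <- 1                      # normalisation row
  pi_stat <- solve(A, c(rep(0, nmax), 1))
  mean_me <- sum(0:nmax * pi_stat)

  g <- blend_geometry(0, 1, 1/3, 2/3, D = 1)
  r <- reaction_channels(k1 = k1, k2 = 89.7)
  set.seed(104)
  M <- 400
  finals <- replicate(M, {
    f <- compartment_field(g, 0, 1/3, h = 1/3, C0 = 10)
    sum(ssa_advance(f, r, 0, 3)$C)
  })
  se <- sd(finals) / sqrt(M)
  expect_lt(abs(mean(finals) - mean_me), 4 * se)
})
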