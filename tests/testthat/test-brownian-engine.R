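test_that("the Euler-Maruyama update has the prescribed drift and noise scale", {
  g <- unit_geom()
  # zero deviates, constant D: positions unchanged
  p <- particle_set(c(0.1, 0.5, 0.9), 0, 1)
  p0 <- em_step(p, g, dt = 1e-4, "full", xi = matrix(0, 3, 1))
  expect_equal(p0$pos, p$pos)
  # unit deviate, constant D = 1: displacement sqrt(2 D dt)
  p1 <- em_step(p, g, dt = 1e-4, "full", xi = matrix(1, 3, 1))
  expect_equal(p1$pos[, 1] - p$pos[, 1], rep(sqrt(2e-4), 3))
  # linear D2 (slope 3 on a blending width 1/3): deterministic drift dt * 3
  pb <- particle_set(c(0.4, 0.5, 0.6), 1/3, 1)
  pb <- em_step(pb, g, dt = 1e-4, "d2", xi = matrix(0, 3, 1))
  expect_equal(pb$pos[, 1], c(0.4, 0.5, 0.6) + 3e-4)
  # outside the blending region D2 is flat: no drift
  pf <- particle_set(0.9, 1/3, 1)
  pf <- em_step(pf, g, dt = 1e-4, "d2", xi = matrix(0, 1, 1))
  expect_equal(pf$pos[1, 1], 0.9)
})

test_that("boundary handling mirrors positions back into the region", {
  p <- particle_set(c(1.01, 0.5, -0.02), 0, 1)
  p <- handle_boundaries(p)
  expect_equal(p$pos[, 1], c(0.99, 0.5, 0.02))
  # hybrid interface: a proposed position below I1 reflects to 2*I1 - y
  ph <- particle_set(1/3 - 0.005, 1/3, 1)
  ph <- handle_boundaries(ph)
  expect_equal(ph$pos[1, 1], 1/3 + 0.005)
  # count conserved
  expect_identical(nrow(p$pos), 3L)
})

test_that("free-space diffusion moments match N(y0, 2 D n dt)", {
  g <- blend_geometry(0, 100, 40, 60, D = 1)
  set.seed(201)
  n_part <- 20000
  p <- particle_set(rep(50, n_part), 0, 100)
  nsteps <- 40
  dt <- 1e-3
  for (s in seq_len(nsteps)) p <- em_step(p, g, dt, "full")
  x <- p$pos[, 1]
  v <- 2 * 1 * nsteps * dt
  expect_lt(abs(mean(x) - 50), 4 * sqrt(v / n_part))
  expect_equal(var(x), v, tolerance = 4 * sqrt(2 / n_part))
})

test_that("drift-corrected diffusion under linear D2 keeps the density uniform", {
  # the single most diagnostic test of the drift sign: with reflecting ends on
  # [I1, b] and D2 rising linearly through the blending region, the
  # equilibrium density is uniform only if the drift term dD2/dx is present
  # with the correct sign
  g <- unit_geom()
  set.seed(202)
  n_part <- 10000L
  p <- particle_set(runif(n_part, 1/3, 1), 1/3, 1)
  for (s in 1:1200) {
    p <- em_step(p, g, dt = 1e-3, "d2")
    p <- handle_boundaries(p)
  }
  expect_identical(nrow(p$pos), n_part)
  thirds <- cut(p$pos[, 1], c(1/3, 5/9, 7/9, 1), include.lowest = TRUE)
  cnt <- as.numeric(table(thirds))
  se <- sqrt(n_part * (1/3) * (2/3))
  expect_true(all(abs(cnt - n_part / 3) < 5 * se))
  # finer resolution: no pile-up near the low-diffusivity interface
  dec <- table(cut(p$pos[, 1], seq(1/3, 1, length.out = 11)))
  expect_lt(max(abs(as.numeric(dec) - n_part / 10)) / (n_part / 10), 0.12)
})

test_that("pair reactions respect the interaction radius and consume partners once", {
  r1 <- reaction_channels(rho = 0.1, P_lambda = 1)
  # two particles at distance 2*rho: never react
  p <- particle_set(c(0.2, 0.4), 0, 1)
  out <- react_pairs(p, r1)
  expect_identical(out$n_removed, 0L)
  # distance rho/2 with P_lambda = 1: always react, both removed
  p2 <- particle_set(c(0.2, 0.25), 0, 1)
  out2 <- react_pairs(p2, r1)
  expect_identical(out2$n_removed, 2L)
  expect_identical(nrow(out2$particles$pos), 0L)
  # single particle: no events
  out3 <- react_pairs(particle_set(0.5, 0, 1), r1)
  expect_identical(out3$n_removed, 0L)
  # three mutually close particles: only one pair can fire (a consumed
  # particle is ineligible)
  set.seed(203)
  p3 <- particle_set(c(0.5, 0.52, 0.54), 0, 1)
  out4 <- react_pairs(p3, r1)
  expect_identical(out4$n_removed, 2L)
  # per-step Bernoulli: survival over n steps is (1 - P)^n
  set.seed(204)
  P <- 0.2
  n <- 5
  rb <- reaction_channels(rho = 0.1, P_lambda = P)
  reacted <- replicate(2000, {
    q <- particle_set(c(0.5, 0.51), 0, 1)
    for (s in seq_len(n)) {
      if (nrow(q$pos) < 2) break
      q <- react_pairs(q, rb)$particles
    }
    nrow(q$pos) == 0
  })
  expected <- 1 - (1 - P)^n
  expect_lt(abs(mean(reacted) - expected),
            4 * sqrt(expected * (1 - expected) / 2000))
})

test_that("scalar reactions use the exact exponential and Poisson placement", {
  g <- unit_geom()
  # no rates: unchanged
  p <- particle_set(runif(100, 0, 1), 0, 1)
  expect_equal(react_scalar(p, reaction_channels(), dt = 1e-4)$pos, p$pos)
  # removal probability 1 - exp(-mu dt)
  set.seed(205)
  n_part <- 2e5
  p2 <- particle_set(runif(n_part), 0, 1)
  p2 <- react_scalar(p2, reaction_channels(mu = 10), dt = 1e-2)
  pk <- 1 - exp(-0.1)
  removed <- n_part - nrow(p2$pos)
  expect_lt(abs(removed - n_part * pk), 4 * sqrt(n_part * pk * (1 - pk)))
  # production: mean k2 * V * dt additions
  set.seed(206)
  adds <- replicate(400, {
    q <- particle_set(numeric(0), 0, 10/3)
    nrow(react_scalar(q, reaction_channels(k2 = 89.7), dt = 1e-2)$pos)
  })
  expect_lt(abs(mean(adds) - 89.7 * 10/3 * 1e-2),
            4 * sqrt(89.7 * 10/3 * 1e-2 / 400))
  expect_true(all(adds >= 0))
})
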