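test_that("problem configurations carry the documented study conditions", {
  cfg <- problem_config("uniform", "pde-compartment")
  expect_equal(cfg$N, 1000)
  expect_equal(cfg$h, 1/30)
  expect_equal(cfg$dx, 1/300)
  expect_equal(cfg$dt_p, 1e-4)
  expect_identical(cfg$repeats, 500L)
  m <- config_mesh(cfg)
  expect_identical(c(m$gamma, m$n_p, m$n_2, m$n_c), c(10L, 100L, 10L, 10L))
  cfg3 <- problem_config("morphogen", "compartment-brownian")
  expect_equal(c(cfg3$J, cfg3$mu), c(1e4, 10))
  expect_identical(cfg3$repeats, 1000L)
  cfg4 <- problem_config("bimolecular3d", "pure-compartment")
  expect_equal(c(cfg4$k1, cfg4$k2, cfg4$rho, cfg4$P_lambda),
               c(0.1, 89.7, 0.06, 2.5e-5))
  expect_equal(c(cfg4$b, cfg4$I1, cfg4$I2, cfg4$h), c(10, 10/3, 20/3, 1/3))
  expect_error(problem_config("uniform", "pure-pde", nonsense = 1), "unknown")
})

test_that("initial conditions realise the problem-specific profiles", {
  # bimolecular: expected total initial mass 465, one third in the blending
  # region, and blending/Brownian samples restricted to the profile support
  cfg <- problem_config("bimolecular3d", "compartment-brownian")
  expect_equal(blendsim:::profile_mass(cfg, 0, 10), 465)
  expect_equal(blendsim:::profile_mass(cfg, 10/3, 20/3), 155)
  set.seed(601)
  st <- make_initial_condition(cfg)
  expect_identical(total_count(st), 465)
  expect_identical(unname(region_masses(st)["C"]), 255)
  xs <- blendsim:::sample_profile(5000, 10/3, 20/3, cfg)
  expect_true(all(xs >= 10/3 & xs <= 20/3))
  # sampled positions follow the decreasing linear density
  expect_gt(mean(xs < 5), 0.5)
  # redistribution: no mass right of I1 at t = 0
  cfg2 <- problem_config("redistribution", "compartment-brownian")
  set.seed(602)
  st2 <- make_initial_condition(cfg2)
  expect_identical(nrow(st2$particles$pos), 0L)
  expect_identical(total_count(st2), 1000)
  cfg2p <- problem_config("redistribution", "pde-compartment")
  st2p <- make_initial_condition(cfg2p)
  expect_equal(sum(region_masses(st2p)[c("H", "C")]), 0)
  expect_equal(total_mass(st2p), 1000)
  # morphogen: uniform at D J / mu
  cfg3 <- problem_config("morphogen", "pde-compartment")
  st3 <- make_initial_condition(cfg3)
  expect_equal(st3$pde$q, rep(1000, length(st3$pde$q)))
})

test_that("apportionment distributes exactly N over the expected shares", {
  expect_identical(blendsim:::apportion(1000, c(1, 2)), c(333L, 667L))
  expect_identical(sum(blendsim:::apportion(465, c(255, 155, 55))), 465L)
  expect_identical(blendsim:::apportion(10, c(1, 0)), c(10L, 0L))
})

test_that("experiments are reproducible from (config, seed)", {
  cfg <- problem_config("uniform", "compartment-brownian", repeats = 2L,
                        seed = 603L, output_times = c(0.01))
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$mass_mean, r2$mass_mean)
  expect_identical(r1$rme, r2$rme)
  r3 <- run_experiment(problem_config("uniform", "compartment-brownian",
                                      repeats = 2L, seed = 604L,
                                      output_times = c(0.01)))
  expect_false(identical(r1$mass_mean, r3$mass_mean))
})

test_that("config JSON serialisation round-trips", {
  cfg <- problem_config("morphogen", "compartment-brownian", repeats = 7L,
                        seed = 11L, output_times = c(0.25, 0.5, 1))
  path <- tempfile(fileext = ".json")
  write_run_config(cfg, path)
  back <- read_run_config(path)
  expect_identical(back, cfg)
})

test_that("experiment CSV writers emit the documented columns", {
  cfg <- problem_config("uniform", "pde-compartment", repeats = 2L, seed = 9L,
                        output_times = c(0.01))
  r <- run_experiment(cfg)
  f1 <- tempfile(fileext = ".csv")
  write_rme_csv(r, f1)
  rme_df <- read.csv(f1)
  expect_identical(names(rme_df), c("time", "region", "rme", "mc_stderr"))
  f2 <- tempfile(fileext = ".csv")
  write_masses_csv(r, f2)
  expect_identical(names(read.csv(f2)), c("time", "P", "H", "C", "total"))
})
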