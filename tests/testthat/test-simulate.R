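test_that("frozen systems do not move and identical seeds reproduce bit-exactly", {
  sp <- tibble::tibble(species = c("A2A", "DPPC"), count = c(3, 20),
                       D = 0, Dr = 0, radius = c(1.8, 0.4))
  cfg <- sim_config(sp, box_spec(c(30, 30)), dt = 1e-3, n_steps = 50,
                    stride = 10, init_min_sep = 0)
  sim <- simulate_membrane(cfg, seed = 9)
  a <- memrate:::traj_arrays(sim$trajectory)
  expect_true(all(a$x == a$x[, 1]))
  expect_true(all(a$y == a$y[, 1]))

  cfg2 <- free_config(D = 0.3, n = 30)
  t1 <- simulate_membrane(cfg2, seed = 4)$trajectory
  t2 <- simulate_membrane(cfg2, seed = 4)$trajectory
  expect_identical(t1$x, t2$x)
  t3 <- simulate_membrane(cfg2, seed = 5)$trajectory
  expect_false(identical(t1$x, t3$x))
})

test_that("free motion is Brownian: normal per-axis steps with variance 2 D dt", {
  D <- 0.3
  cfg <- free_config(D = D, n = 500, dt = 1e-2, n_steps = 40)
  tr <- unwrap_trajectory(simulate_membrane(cfg, seed = 11)$trajectory)
  a <- memrate:::traj_arrays(tr)
  steps <- as.vector(diff(t(a$x)))
  v <- 2 * D * 1e-2
  n <- length(steps)
  expect_equal(mean(steps), 0, tolerance = 4 * sqrt(v / n))
  expect_equal(var(steps), v, tolerance = 4 * sqrt(2 / n))
  # excess kurtosis of a normal is 0
  kurt <- mean((steps - mean(steps))^4) / var(steps)^2 - 3
  expect_lt(abs(kurt), 5 * sqrt(24 / n))
})

test_that("ensemble MSD of free diffusion recovers the generating D within 5%", {
  D <- 0.3
  cfg <- free_config(D = D, n = 500, dt = 1e-2, n_steps = 200)
  tr <- unwrap_trajectory(simulate_membrane(cfg, seed = 21)$trajectory)
  est <- fit_diffusion(msd(tr))
  expect_equal(est$D, D, tolerance = 0.05)
})

test_that("soft-core repulsion keeps particles apart", {
  sp <- tibble::tibble(species = "DPPC", count = 120, D = 2.9, Dr = 0,
                       radius = 0.4)
  cfg <- sim_config(sp, box_spec(c(15, 15)), dt = 1e-4, n_steps = 2000,
                    stride = 200, init_min_sep = 0)
  tr <- simulate_membrane(cfg, seed = 2)$trajectory
  a <- memrate:::traj_arrays(tr)
  box <- trajectory_box(tr)
  # skip the random initial frame; inspect relaxed frames
  mins <- vapply(2:ncol(a$x), function(f) {
    d <- memrate:::min_image_dist(a$x[, f], a$y[, f], box)
    min(d[upper.tri(d)])
  }, numeric(1))
  expect_true(all(mins > 0.5 * 0.8))
})

test_that("timestep stability precondition is enforced with a suggestion", {
  sp <- tibble::tibble(species = "A2A", count = 2, D = 3, Dr = 0.3,
                       radius = 1.8)
  att <- tibble::tibble(a = "A2A", b = "A2A", epsilon = 2, sigma = 0.3)
  expect_error(
    sim_config(sp, box_spec(c(30, 30)), attractions = att, dt = 1e-2),
    "dt <=")
})

test_that("layout fixtures have the constructed contact structure", {
  dimers <- make_layout("dimers", n = 9, spacing = 4, n_frames = 2)
  expect_equal(contacts_per_protomer(dimers, window = c(0, 1))$summary$mean_contacts, 1)
  singles <- make_layout("singletons", n = 9)
  expect_equal(sum(contact_matrix(singles)), 0)
  ring <- make_layout("ring", n = 6, spacing = 4)
  expect_equal(unname(rowSums(contact_matrix(ring))), rep(2, 6))
  expect_error(make_layout("chain", n = 20, spacing = 4, box = box_spec(c(20, 20))),
               "fit")
})

test_that("demixing preset orders the contact fraction monotonically in strength", {
  f_tail <- function(strength, seed) {
    tr <- simulate_membrane(demix_preset(strength, n_steps = 6000L),
                            seed = seed)$trajectory
    mx <- mixing_contact_fraction(tr, "DPPC", "DOPC")
    mean(tail(mx$f_ab, 20), na.rm = TRUE)
  }
  seeds <- 1:5
  f0 <- vapply(seeds, function(s) f_tail(0, s), numeric(1))
  f1 <- vapply(seeds, function(s) f_tail(0.8, s), numeric(1))
  f2 <- vapply(seeds, function(s) f_tail(2, s), numeric(1))
  expect_equal(mean(f0), 0.5, tolerance = 0.1) # ideal mixing 2x(1-x)
  expect_lt(mean(f1), mean(f0))
  expect_lt(mean(f2), mean(f1))
})

test_that("different seeds give statistically indistinguishable free displacements", {
  cfg <- free_config(D = 0.5, n = 120, dt = 1e-2, n_steps = 50)
  step_of <- function(seed) {
    a <- memrate:::traj_arrays(
      unwrap_trajectory(simulate_membrane(cfg, seed = seed)$trajectory))
    as.vector(diff(t(a$x)))
  }
  ks <- stats::ks.test(step_of(31), step_of(32))
  expect_gt(ks$p.value, 0.01)
})
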