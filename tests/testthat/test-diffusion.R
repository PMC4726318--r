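static_traj <- function(n = 5, nf = 20) {
  set.seed(2)
  box <- box_spec(c(30, 30))
  x <- runif(n, 0, 30); y <- runif(n, 0, 30)
  df <- tibble::tibble(frame = rep(seq_len(nf) - 1L, each = n),
                       time = rep((seq_len(nf) - 1) * 0.1, each = n),
                       id = rep(seq_len(n), nf), species = "SDPC",
                       x = rep(x, nf), y = rep(y, nf), theta = NA_real_)
  as_trajectory(df, box)
}

test_that("MSD of static and drifting particles has the closed forms", {
  st <- static_traj()
  m0 <- msd(st)
  expect_true(all(m0$msd == 0))
  est0 <- fit_diffusion(m0)
  expect_equal(est0$D, 0)

  # constant velocity v: MSD = v^2 lag^2
  v <- 0.7
  nf <- 40
  df <- tibble::tibble(frame = seq_len(nf) - 1L, time = (seq_len(nf) - 1) * 0.1,
                       id = 1L, species = "A2A",
                       x = 5 + v * (seq_len(nf) - 1) * 0.1, y = 5, theta = 0)
  tr <- as_trajectory(df, box_spec(c(1000, 1000)), validate = TRUE)
  attr(tr, "unwrapped") <- TRUE
  m <- msd(tr)
  expect_equal(m$msd, v^2 * m$lag^2, tolerance = 1e-10)
})

test_that("MSD equals the brute-force double loop on a small trajectory", {
  cfg <- free_config(D = 0.4, n = 6, n_steps = 30)
  tr <- unwrap_trajectory(simulate_membrane(cfg, seed = 13)$trajectory)
  a <- memrate:::traj_arrays(tr)
  m <- msd(tr)
  for (L in c(1, 3, 7, 15)) {
    expect_equal(m$msd[which.min(abs(m$lag - L * 1e-2))],
                 brute_msd(a$x, a$y, L), tolerance = 1e-12)
  }
})

test_that("wrapped input is refused with advice to unwrap", {
  cfg <- free_config(D = 2, n = 20, box_len = 5, n_steps = 60)
  wrapped <- simulate_membrane(cfg, seed = 3)$trajectory
  expect_error(msd(wrapped), "unwrap")
})

test_that("an exact MSD line returns the generating D in both unit systems", {
  lag <- seq(0.01, 1, by = 0.01)
  curve <- tibble::tibble(lag = lag, msd = 4 * 0.48 * lag, n_samples = 100)
  class(curve) <- c("msd_curve", class(curve))
  est <- fit_diffusion(curve)
  expect_equal(est$D, 0.48, tolerance = 1e-10)
  expect_equal(convert_units(est$D, "nm2_us", "1e-9cm2_s"), 4.8,
               tolerance = 1e-10)
})

test_that("free walks at the low-DHA SDPC scale are recovered within 10%", {
  cfg <- free_config(D = 0.13, n = 500, dt = 1e-2, n_steps = 120)
  tr <- unwrap_trajectory(simulate_membrane(cfg, seed = 31)$trajectory)
  est <- fit_diffusion(msd(tr))
  expect_equal(est$D, 0.13, tolerance = 0.1)
})

test_that("D estimates are invariant under rotation and time-origin shift", {
  cfg <- free_config(D = 0.3, n = 80, n_steps = 80)
  tr <- unwrap_trajectory(simulate_membrane(cfg, seed = 17)$trajectory)
  est <- fit_diffusion(msd(tr))
  rot <- tr
  ang <- 0.7
  rot$x <- cos(ang) * tr$x - sin(ang) * tr$y
  rot$y <- sin(ang) * tr$x + cos(ang) * tr$y
  attr(rot, "unwrapped") <- TRUE
  expect_equal(fit_diffusion(msd(rot))$D, est$D, tolerance = 1e-10)
  shifted <- tr
  shifted$time <- tr$time + 5
  attr(shifted, "unwrapped") <- TRUE
  # shifting the origin perturbs lag spacings only at float precision
  expect_equal(fit_diffusion(msd(shifted))$D, est$D, tolerance = 1e-2)
})

test_that("orientation autocorrelation recovers rotational diffusion", {
  frozen <- make_layout("singletons", n = 4, n_frames = 10)
  rot0 <- rotational_acf(frozen)
  expect_true(all(rot0$curve$C == 1))
  expect_equal(rot0$estimate$D, 0)

  Dr <- 0.5
  cfg <- free_config(D = 0, n = 600, dt = 1e-2, n_steps = 300,
                     species = "A2A", Dr = Dr)
  tr <- simulate_membrane(cfg, seed = 23)$trajectory
  rot <- rotational_acf(tr)
  expect_equal(rot$estimate$D, Dr, tolerance = 0.1)
  expect_equal(rot$estimate$method, "rotational")
})

test_that("unit conversions are exact and invertible", {
  expect_equal(convert_units(0.48, "nm2_us", "cm2_s"), 4.8e-9)
  expect_equal(convert_units(2.1, "1e-8cm2_s", "nm2_us"), 2.1)
  x <- 1.37
  for (u in c("nm2_us", "cm2_s", "1e-8cm2_s", "1e-9cm2_s")) {
    expect_equal(convert_units(convert_units(x, "nm2_us", u), u, "nm2_us"), x)
  }
  expect_error(convert_units(1, "nm2_us", "furlongs"), "Unknown unit")
})

test_that("replica aggregation uses SEM over replicas or propagated errors", {
  mk <- function(D, se) memrate:::new_diffusion_estimate(D, se, window = c(0, 1),
                                                         method = "translational")
  same <- replica_aggregate(list(mk(2, 0.1), mk(2, 0.1), mk(2, 0.1)))
  expect_equal(same$D, 2)
  expect_equal(same$se, 0)
  three <- replica_aggregate(list(mk(2.0, 0.5), mk(2.2, 0.5), mk(2.4, 0.5)))
  expect_equal(three$D, 2.2)
  expect_equal(three$se, sd(c(2, 2.2, 2.4)) / sqrt(3), tolerance = 1e-12)
  expect_equal(round(three$se, 3), 0.115)
  one <- replica_aggregate(list(mk(1.5, 0.3)))
  expect_equal(one$se, 0.3)
  rot <- memrate:::new_diffusion_estimate(1, 0.1, window = c(0, 1),
                                          method = "rotational")
  expect_error(replica_aggregate(list(mk(1, 0.1), rot)), "mix")
})
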