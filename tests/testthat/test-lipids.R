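test_that("the RDF of a uniform gas is 1 and mass is conserved", {
  n_target <- 800; n_frames <- 30
  tr <- uniform_gas_traj(n_target = n_target, n_frames = n_frames)
  rdf <- rdf2d(tr, target = "DPPC", bin_width = 0.5)
  # per-bin deviations stay within 4 Poisson sigma of ideal mixing
  rho <- n_target / 30^2
  expected_counts <- 2 * pi * rdf$r * 0.5 * rho * n_frames
  dev <- abs(rdf$g - 1)
  keep <- rdf$r > 1
  expect_true(all(dev[keep] < 4 / sqrt(expected_counts[keep]) + 0.02))
  expect_equal(mean(rdf$g[keep]), 1, tolerance = 0.02)
  # integral of g rho 2 pi r dr recovers the mean in-range target count
  integral <- sum(rdf$g * rho * 2 * pi * rdf$r * 0.5)
  expect_equal(integral, sum(rdf$count) / (n_frames * 1), tolerance = 1e-9)
})

test_that("a fixed target lands all RDF mass in its distance bin", {
  box <- box_spec(c(30, 30))
  df <- tibble::tibble(frame = 0L, time = 0, id = 1:2,
                       species = c("A2A", "SDPC"),
                       x = c(10, 10 + 3.27), y = 10, theta = NA_real_)
  tr <- as_trajectory(df, box)
  rdf <- rdf2d(tr, target = "SDPC", bin_width = 0.1)
  expect_equal(sum(rdf$count), 1)
  expect_equal(rdf$r[rdf$count == 1], 3.25)
  expect_error(rdf2d(tr, target = "SDPC", r_max = 20), "half the box")
})

test_that("RDF bin counts equal a brute-force pair histogram", {
  tr <- uniform_gas_traj(n_target = 60, n_frames = 1, seed = 3)
  rdf <- rdf2d(tr, target = "DPPC", bin_width = 0.4)
  a <- memrate:::traj_arrays(tr)
  ref <- which(a$species == "A2A")
  d <- vapply(which(a$species == "DPPC"), function(j) {
    sqrt(sum(brute_min_image(c(a$x[ref, 1], a$y[ref, 1]),
                             c(a$x[j, 1], a$y[j, 1]), c(30, 30))^2))
  }, numeric(1))
  want <- as.integer(table(cut(d[d < 15], breaks = seq(0, 15, by = 0.4))))
  expect_equal(rdf$count[seq_along(want)], want)
})

test_that("shell detection finds the first minimum or declares none", {
  r <- seq(0.05, 10, by = 0.1)
  g <- 2.5 * exp(-(r - 2.5)^2 / 0.3) + 1 - exp(-(r - 3.3)^2 / 0.05) * 0.6
  g[r < 1.5] <- 0
  expect_equal(memrate:::first_shell_minimum(r, g), r[which.min(abs(r - 3.35))],
               tolerance = 0.2)
  expect_true(is.na(memrate:::first_shell_minimum(r, rep(1, length(r)))))

  # an ideally mixed (g == 1) curve has no shell to report
  flat <- tibble::tibble(r = seq(0.25, 10, by = 0.5), g = 1, count = 0)
  attr(flat, "bin_width") <- 0.5
  class(flat) <- c("rdf_curve", class(flat))
  rep_ <- shell_report(flat, make_layout("dimers", n = 2, spacing = 4))
  expect_false(rep_$detectable)
})

test_that("shell occupancy counts species membership by nearest receptor", {
  box <- box_spec(c(30, 30))
  # receptor at centre; 3 SDPC inside 3 nm, 1 DPPC inside, 4 DPPC far away
  df <- tibble::tibble(
    frame = 0L, time = 0, id = 1:9,
    species = c("A2A", "SDPC", "SDPC", "SDPC", "DPPC", rep("DPPC", 4)),
    x = c(15, 16.5, 13.8, 15.2, 16.0, 2, 4, 25, 27),
    y = c(15, 15, 15.8, 13.6, 14.0, 3, 22, 6, 28),
    theta = NA_real_
  )
  tr <- as_trajectory(df, box)
  rdf <- tibble::tibble(r = seq(0.25, 10, by = 0.5),
                        g = c(0, 0.2, 3, 2, 0.6, 0.9, rep(1, 14)),
                        count = 0)
  attr(rdf, "bin_width") <- 0.5
  class(rdf) <- c("rdf_curve", class(rdf))
  rep_ <- shell_report(rdf, tr)
  expect_true(rep_$detectable)
  # g falls 3 -> 2 -> 0.6 then rises to 0.9: first minimum at r = 2.25
  expect_equal(rep_$outer_radius, 2.25)
  occ <- rep_$occupancy
  expect_equal(occ$fraction[occ$species == "SDPC"], 0.75)
  expect_equal(sum(occ$fraction), 1)
})

test_that("receptor-lipid contact ratios follow the group counts", {
  box <- box_spec(c(30, 30))
  # receptor at centre, 4 unsaturated within cutoff, 2 saturated within, equal pools
  mk <- function() {
    tibble::tibble(
      frame = 0L, time = 0, id = 1:13,
      species = c("A2A", rep("DOPC", 6), rep("DPPC", 6)),
      x = c(15, 15 + c(1, -1, 1.5, -1.5, 9, 10), 15 + c(1.2, -1.2, 8, 9, 10, 11)),
      y = 15, theta = NA_real_)
  }
  tr <- as_trajectory(mk(), box)
  rr <- lipid_contact_ratio(tr, cutoff = 2.8)
  expect_equal(rr$ratio, (4 / 6) / (2 / 6)) # = 2.0 at equal particle counts
  # an all-saturated membrane has zero unsaturated contacts
  all_sat <- as_trajectory(
    dplyr::mutate(mk(), species = replace(species, species == "DOPC", "DSPC")),
    box)
  rs <- lipid_contact_ratio(all_sat, cutoff = 2.8)
  expect_equal(rs$ratio, 0)
})

test_that("mixing contact fraction matches enumeration and flags demixing", {
  st <- memrate:::striped_frame(seed = 2)
  ms <- mixing_contact_fraction(st, "DPPC", "DOPC")
  expect_lt(ms$f_ab, ms$random_expectation[1])

  # brute-force pair enumeration on a small random frame
  set.seed(14)
  box <- box_spec(c(12, 12))
  df <- tibble::tibble(frame = 0L, time = 0, id = 1:40,
                       species = sample(rep(c("DPPC", "DOPC"), 20)),
                       x = runif(40, 0, 12), y = runif(40, 0, 12),
                       theta = NA_real_)
  tr <- as_trajectory(df, box)
  got <- mixing_contact_fraction(tr, "DPPC", "DOPC", cutoff = 2)
  a <- memrate:::traj_arrays(tr)
  ab <- 0; tot <- 0
  for (i in 1:39) for (j in (i + 1):40) {
    d <- sqrt(sum(brute_min_image(c(a$x[i, 1], a$y[i, 1]),
                                  c(a$x[j, 1], a$y[j, 1]), c(12, 12))^2))
    if (d < 2) {
      tot <- tot + 1
      if (a$species[i] != a$species[j]) ab <- ab + 1
    }
  }
  expect_equal(got$f_ab, ab / tot)
  expect_equal(got$random_expectation[1], 0.5)
  expect_error(mixing_contact_fraction(tr, "DPPC", "DPPC"), "disjoint")
})

test_that("ideal equimolar mixtures sit at the random-mixing expectation", {
  tr <- simulate_membrane(demix_preset(0, n_steps = 4000L), seed = 8)$trajectory
  mx <- mixing_contact_fraction(tr, "DPPC", "DOPC")
  late <- tail(mx, 20)
  # binomial SE on the pooled late-window pairs
  se <- sqrt(0.25 / sum(late$n_pairs))
  expect_lt(abs(mean(late$f_ab) - 0.5), 3 * se + 0.02)
})

test_that("bound fraction counts shell membership and enforces contracts", {
  dimers <- make_layout("dimers", n = 2, spacing = 4, n_frames = 2)
  box <- trajectory_box(dimers)
  # add SDPC right next to each receptor
  rec <- dplyr::filter(dimers, frame == 0)
  extra <- purrr::map_dfr(0:1, function(f) {
    tibble::tibble(frame = f, time = f * 0.1, id = 100L + seq_len(nrow(rec)),
                   species = "SDPC", x = rec$x + 0.5, y = rec$y,
                   theta = NA_real_)
  })
  tr <- as_trajectory(dplyr::bind_rows(tibble::as_tibble(dimers), extra), box)
  bf <- bound_fraction(tr, "SDPC", shell_radius = 3)
  expect_equal(bf$summary$mean_fraction, 1)
  lip_only <- as_trajectory(dplyr::filter(tibble::as_tibble(tr), species == "SDPC"), box)
  expect_error(bound_fraction(lip_only, "SDPC", 3), "no receptors")
  expect_error(bound_fraction(dimers, "SDPC", 3), "absent")
})
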