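test_that("the contact criterion is strictly below the cutoff", {
  box <- box_spec(c(50, 50))
  # place the pair at x = 0 and x = d so the separation is represented
  # exactly and the tie at the cutoff is a true tie
  at <- function(d) receptor_frame(rbind(c(0, 10), c(d, 10)), box)
  expect_true(contact_matrix(at(4.19))[1, 2])
  expect_false(contact_matrix(at(4.20))[1, 2])
  one <- receptor_frame(rbind(c(5, 5)), box)
  m <- contact_matrix(one)
  expect_equal(dim(m), c(1, 1))
  expect_false(any(m))
  expect_error(contact_matrix(at(4), cutoff = 30), "half the box")
})

test_that("contact matrices equal the 9-image brute force on random frames", {
  set.seed(77)
  box <- box_spec(c(50, 50))
  for (k in 1:5) {
    pts <- cbind(runif(20, 0, 50), runif(20, 0, 50))
    tr <- receptor_frame(pts, box)
    got <- contact_matrix(tr)
    want <- brute_contact_matrix(pts[, 1], pts[, 2], c(50, 50), 4.2)
    expect_equal(unname(got), want)
  }
})

test_that("contact counts are invariant under rigid translation and wrapping", {
  set.seed(12)
  box <- box_spec(c(40, 40))
  pts <- cbind(runif(12, 0, 40), runif(12, 0, 40))
  base <- contact_matrix(receptor_frame(pts, box))
  for (shift in list(c(13.7, 5.1), c(-8, 31), c(100.2, -57.9))) {
    moved <- sweep(pts, 2, shift, `+`) %% 40
    expect_equal(unname(contact_matrix(receptor_frame(moved, box))),
                 unname(base))
  }
})

test_that("oligomer partitions equal the transitive-closure oracle", {
  chain <- contact_matrix(make_layout("chain", n = 4, spacing = 4))
  part <- oligomer_clusters(chain)
  expect_equal(part$oligomer_size, rep(4L, 4))
  expect_equal(sum(chain) / 2, 3) # 3 edges

  singles <- contact_matrix(make_layout("singletons", n = 9))
  ps <- oligomer_clusters(singles)
  expect_equal(ps$oligomer_size, rep(1L, 9))
  expect_equal(length(unique(ps$component)), 9)

  set.seed(41)
  for (k in 1:10) {
    n <- sample(5:14, 1)
    m <- matrix(runif(n * n) < 0.2, n, n)
    m <- m | t(m); diag(m) <- FALSE
    got <- oligomer_clusters(m)
    want <- brute_components(m)
    # same partition up to relabelling
    expect_equal(length(unique(got$component)), length(unique(want)))
    expect_true(all(tapply(want, got$component, function(v) length(unique(v))) == 1))
  }
})

test_that("a linear trimer gives per-protomer counts 1,2,1", {
  tri <- make_layout("chain", n = 3, spacing = 4, n_frames = 2)
  cs <- contacts_per_protomer(tri, window = c(0, 1))
  counts <- dplyr::filter(tidy(cs), frame == 0)$n_contacts
  expect_equal(sort(counts), c(1, 1, 2))
  expect_equal(cs$summary$mean_contacts, 4 / 3)
  expect_equal(dplyr::filter(tidy(cs), frame == 0)$oligomer_size, rep(3L, 3))
})

test_that("homo/hetero classification matches direct edge enumeration", {
  ring <- make_layout("ring", n = 6, spacing = 4) # alternating A2A/D2
  fr <- dplyr::filter(ring, frame == 0)
  cls <- classify_contacts(contact_matrix(ring), setNames(fr$species, fr$id))
  expect_equal(cls$fraction[cls$type == "A2A-D2"], 1)

  allA <- make_layout("ring", n = 6, spacing = 4, species = "A2A")
  frA <- dplyr::filter(allA, frame == 0)
  clsA <- classify_contacts(contact_matrix(allA), setNames(frA$species, frA$id))
  expect_equal(clsA$count[clsA$type == "A2A-A2A"], 6L)
  expect_equal(clsA$fraction[clsA$type == "A2A-D2"], 0)

  set.seed(9)
  for (k in 1:5) {
    n <- 10
    m <- matrix(runif(n * n) < 0.3, n, n); m <- m | t(m); diag(m) <- FALSE
    rownames(m) <- colnames(m) <- seq_len(n)
    sp <- sample(c("A2A", "D2"), n, replace = TRUE)
    cls <- classify_contacts(m, sp)
    idx <- which(m & upper.tri(m), arr.ind = TRUE)
    expect_equal(sum(cls$count), nrow(idx))
    expect_equal(cls$count[cls$type == "A2A-D2"],
                 sum(sp[idx[, 1]] != sp[idx[, 2]]))
  }
  expect_error(classify_contacts(matrix(FALSE, 2, 2), c("A2A", NA)), "label")
})

test_that("aggregation comparison arithmetic and degenerate cases", {
  dimers <- make_layout("dimers", n = 9, spacing = 4, n_frames = 3)
  cmp <- compare_aggregation(list(dimers, dimers), list(dimers, dimers),
                             window = c(0, 1))
  expect_equal(cmp$relative_difference_pct, 0)
  expect_equal(cmp$p_value, 1)

  # arithmetic on condition means alone: (1.48 - 1.20)/1.20 x 100
  expect_equal((1.48 - 1.20) / 1.20 * 100, 23.3, tolerance = 0.01)

  singles <- make_layout("singletons", n = 9, n_frames = 3)
  expect_warning(
    cmp0 <- compare_aggregation(dimers, singles, window = c(0, 1)),
    "zero")
  expect_equal(cmp0$absolute_difference, 1)
  expect_true(is.na(cmp0$relative_difference_pct))
})

test_that("effective-time conversion is exact and flagged", {
  expect_equal(as.numeric(effective_time(15)), 60)
  expect_equal(as.numeric(effective_time(0)), 0)
  expect_equal(as.numeric(effective_time(65)), 260)
  expect_equal(attr(effective_time(1), "time_axis"), "effective")
  expect_error(effective_time(-1), ">= 0")
})

test_that("the oligomerisation onset radius is cutoff plus two shell widths", {
  expect_equal(onset_radius(4.2, 0.9), 6.0)
  expect_equal(onset_radius(4.2, 0.0), 4.2)
  expect_equal(onset_radius(4.2, 0.8), 5.8)
  expect_gte(onset_radius(4.2, 0.8), 5.5) # printed onset range 5.5-6 nm
  expect_lte(onset_radius(4.2, 0.9), 6.0)
})

test_that("pair distance series finds the first sustained contact", {
  box <- box_spec(c(50, 50))
  # receptor 2 steps 6 -> 5 -> 4 nm from receptor 1 at frames 0,1,2, then stays
  d_seq <- c(6, 5, 4, 4, 4, 4)
  df <- purrr::map_dfr(seq_along(d_seq), function(f) {
    tibble::tibble(frame = f - 1L, time = (f - 1) * 0.1, id = 1:2,
                   species = c("A2A", "D2"),
                   x = c(10, 10 + d_seq[f]), y = 10, theta = 0)
  })
  tr <- as_trajectory(df, box)
  res <- pair_distance_series(tr, 1, 2, tau = 0.1)
  expect_equal(res$distances$distance, d_seq)
  expect_equal(res$onset_time, 0.2) # the 4 nm frame
  expect_true(is.na(pair_distance_series(tr, 1, 2, tau = 0.4)$onset_time))
  expect_error(pair_distance_series(tr, 1, 2, tau = 10), "span")
  expect_error(pair_distance_series(tr, 2, 2), "distinct")

  held <- make_layout("dimers", n = 1, spacing = 4, n_frames = 4)
  expect_equal(pair_distance_series(held, 1, 2, tau = 0.1)$onset_time, 0)
})
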