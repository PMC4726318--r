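#' Lateral radial distribution function around receptors
#'
#' 2D RDF of target particles around reference receptors, averaged over
#' frames and references with minimum-image distances. Normalisation is the
#' standard ideal-gas one — counts in the annulus `[r, r + dr)` divided by
#' `2 pi r dr rho n_ref n_frames` — so g tends to 1 at large r for
#' uniformly mixed targets, making curves comparable across species.
#'
#' @param traj A `mem_trajectory`.
#' @param target Species name(s) of the target particles.
#' @param reference Species/role selector for references: default all
#'   receptors.
#' @param bin_width Radial bin width in nm (default 0.05).
#' @param r_max Largest distance; must be at most half the box edge.
#' @return An `rdf_curve` tibble: `r` (bin midpoint), `g`, `count`.
#' @export
rdf2d <- function(traj, target, reference = NULL, bin_width = 0.05,
                  r_max = NULL) {
  box <- trajectory_box(traj)
  half <- min(box$lengths[1:2]) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) abort("`r_max` exceeds half the box edge.")
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  a <- traj_arrays(traj)
  ref_idx <- if (is.null(reference)) which(is_receptor_role(a$role))
             else which(a$species %in% reference)
  tgt_idx <- which(a$species %in% target)
  if (!length(ref_idx) || !length(tgt_idx)) {
    abort("Need at least one reference and one target particle.")
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  nf <- length(a$times)
  area <- box$lengths[1] * box$lengths[2]
  rho <- length(tgt_idx) / area
  for (f in seq_len(nf)) {
    d <- min_image_cross_dist(a$x[ref_idx, f], a$y[ref_idx, f],
                              a$x[tgt_idx, f], a$y[tgt_idx, f], box)
    self <- outer(ref_idx, tgt_idx, `==`)
    dv <- d[!self]
    dv <- dv[dv < edges[nb + 1]]
    if (length(dv)) {
      bi <- findInterval(dv, edges, rightmost.closed = FALSE)
      counts <- counts + tabulate(bi, nbins = nb)
    }
  }
  mid <- (edges[-1] + edges[-(nb + 1)]) / 2
  shell_area <- 2 * pi * mid * bin_width
  g <- counts / (shell_area * rho * length(ref_idx) * nf)
  out <- tibble(r = mid, g = g, count = counts)
  attr(out, "reference") <- if (is.null(reference)) "receptors" else reference
  attr(out, "target") <- target
  attr(out, "n_frames") <- nf
  attr(out, "bin_width") <- bin_width
  class(out) <- c("rdf_curve", class(out))
  out
}

# First local minimum of g after its global maximum; NA when no peak
# (max g below `peak_min`) or no subsequent rise.
first_shell_minimum <- function(r, g, peak_min = 1.1) {
  pk <- which.max(g)
  if (g[pk] < peak_min) return(NA_real_)
  i <- pk
  while (i < length(g) && g[i + 1] <= g[i]) i <- i + 1
  if (i == pk || i == length(g)) return(NA_real_)
  r[i]
}

#' Solvation-shell report
#'
#' Locates the first solvation shell from an all-lipid RDF (outer radius =
#' first local minimum of g after the global peak; excluded-core radius =
#' half-rise point where g first exceeds 0.5) and counts which lipid species
#' occupy the shell, frame by frame. When g has no detectable peak the
#' shell is reported undetectable.
#'
#' @param rdf An `rdf_curve` computed over all lipid species.
#' @param traj The trajectory the curve came from.
#' @return A `shell_report` list: `detectable`, `outer_radius`,
#'   `core_radius`, `width` (nm) and `occupancy` (tibble of per-species
#'   in-shell fractions summing to 1).
#' @export
shell_report <- function(rdf, traj) {
  outer_r <- first_shell_minimum(rdf$r, rdf$g)
  if (is.na(outer_r)) {
    return(structure(list(detectable = FALSE, outer_radius = NA_real_,
                          core_radius = NA_real_, width = NA_real_,
                          occupancy = NULL),
                     class = "shell_report"))
  }
  rise <- which(rdf$g > 0.5)
  core_r <- if (length(rise)) rdf$r[rise[1]] - attr(rdf, "bin_width") / 2 else 0
  a <- traj_arrays(traj)
  box <- a$box
  rec <- which(is_receptor_role(a$role))
  lip <- which(a$role %in% c("lipid", "sterol"))
  occ <- purrr::map_dfr(seq_along(a$times), function(f) {
    d <- min_image_cross_dist(a$x[lip, f], a$y[lip, f],
                              a$x[rec, f], a$y[rec, f], box)
    nearest <- apply(d, 1, min)
    tibble(species = a$species[lip][nearest < outer_r])
  })
  occupancy <- occ %>%
    group_by(.data$species) %>%
    summarise(n = n(), .groups = "drop") %>%
    mutate(fraction = .data$n / sum(.data$n)) %>%
    arrange(dplyr::desc(.data$fraction))
  structure(list(detectable = TRUE, outer_radius = outer_r,
                 core_radius = core_r, width = outer_r - core_r,
                 occupancy = occupancy),
            class = "shell_report")
}

#' @export
print.shell_report <- function(x, ...) {
  if (!x$detectable) {
    cat("<shell_report> no detectable first shell\n")
    return(invisible(x))
  }
  cat(sprintf("<shell_report> outer radius %.2f nm, width %.2f nm\n",
              x$outer_radius, x$width))
  print(x$occupancy)
  invisible(x)
}

#' Receptor-lipid contact ratios over time
#'
#' Counts receptor-lipid pairs within a lateral centre-centre cutoff per
#' frame, normalised per available lipid particle of each group, and forms
#' the ratio of two groups (by saturation class by default, or an explicit
#' species pair). The default cutoff, 2.8 nm, is the receptor radius plus
#' the lipid radius plus a bead-scale gap of 0.6 nm.
#'
#' @param traj A `mem_trajectory`.
#' @param cutoff Centre-centre contact cutoff in nm.
#' @param grouping `"saturation"` for unsaturated/saturated, or a character
#'   pair `c(numerator_species, denominator_species)`.
#' @return A tibble `time`, `contacts_num`, `contacts_den` (per-particle
#'   normalised counts), `ratio` (`NA` where the denominator has no
#'   contacts).
#' @export
lipid_contact_ratio <- function(traj, cutoff = 2.8, grouping = "saturation") {
  if (cutoff <= 0) abort("`cutoff` must be > 0.")
  a <- traj_arrays(traj)
  box <- a$box
  rec <- which(is_receptor_role(a$role))
  if (!length(rec)) abort("Trajectory contains no receptors.")
  reg <- trajectory_species_table(traj)
  if (identical(grouping, "saturation")) {
    cls <- lipid_saturation_class(a$species[a$role == "lipid"][1], reg) # force check
    cls_all <- rep(NA_character_, length(a$species))
    lipids <- which(a$role == "lipid")
    cls_all[lipids] <- lipid_saturation_class(a$species[lipids], reg)
    num_idx <- which(cls_all == "unsaturated")
    den_idx <- which(cls_all == "saturated")
    labels <- c("unsaturated", "saturated")
  } else {
    if (length(grouping) != 2) abort("`grouping` must be 'saturation' or a species pair.")
    num_idx <- which(a$species == grouping[1])
    den_idx <- which(a$species == grouping[2])
    labels <- grouping
  }
  if (!length(den_idx)) abort("The denominator group contains no particles.")
  per_particle <- function(idx, f) {
    if (!length(idx)) return(0) # absent class contributes no contacts
    d <- min_image_cross_dist(a$x[rec, f], a$y[rec, f],
                              a$x[idx, f], a$y[idx, f], box)
    sum(d < cutoff) / length(idx)
  }
  purrr::map_dfr(seq_along(a$times), function(f) {
    cn <- per_particle(num_idx, f)
    cd <- per_particle(den_idx, f)
    tibble(time = a$times[f], contacts_num = cn, contacts_den = cd,
           ratio = if (cd > 0) cn / cd else NA_real_)
  }) %>%
    mutate(numerator = labels[1], denominator = labels[2])
}

#' Saturated-unsaturated mixing contact fraction
#'
#' The demixing order parameter: per frame, the fraction of lipid-lipid
#' contact pairs (lateral centre distance below `cutoff`) that pair a
#' class-A with a class-B lipid. For an ideally mixed system the expected
#' value is `2 x_A x_B`; partial phase separation pushes it below that.
#'
#' @param traj A `mem_trajectory`.
#' @param class_a,class_b Disjoint character vectors of species names.
#' @param cutoff Contact cutoff in nm (default 1.1, bead-scale).
#' @return A tibble `time`, `f_ab`, `n_pairs`, plus the constant
#'   `random_expectation` column.
#' @export
mixing_contact_fraction <- function(traj, class_a, class_b, cutoff = 1.1) {
  if (length(intersect(class_a, class_b))) abort("Classes must be disjoint.")
  a <- traj_arrays(traj)
  box <- a$box
  ia <- which(a$species %in% class_a)
  ib <- which(a$species %in% class_b)
  if (!length(ia) || !length(ib)) abort("Both classes must be non-empty.")
  all_idx <- c(ia, ib)
  is_a <- c(rep(TRUE, length(ia)), rep(FALSE, length(ib)))
  xa <- length(ia) / length(all_idx)
  expectation <- 2 * xa * (1 - xa)
  out <- purrr::map_dfr(seq_along(a$times), function(f) {
    d <- min_image_dist(a$x[all_idx, f], a$y[all_idx, f], box)
    touch <- d < cutoff & upper.tri(d)
    total <- sum(touch)
    if (total == 0) {
      return(tibble(time = a$times[f], f_ab = NA_real_, n_pairs = 0L))
    }
    idx <- which(touch, arr.ind = TRUE)
    ab <- sum(is_a[idx[, 1]] != is_a[idx[, 2]])
    tibble(time = a$times[f], f_ab = ab / total, n_pairs = total)
  })
  if (any(out$n_pairs == 0)) {
    warn("Frames without lipid-lipid contacts: mixing fraction undefined there.")
  }
  mutate(out, random_expectation = expectation)
}

#' Fraction of a lipid species bound in receptor shells
#'
#' Per frame, the fraction of the chosen species whose lateral distance to
#' the nearest receptor is below `shell_radius`; summarised as a time
#' average with a 5-block SEM.
#'
#' @param traj A `mem_trajectory`.
#' @param species Lipid species name.
#' @param shell_radius Shell outer radius in nm.
#' @return A list with `series` (tibble `time`, `fraction`) and `summary`
#'   (tibble `mean_fraction`, `sem`).
#' @export
bound_fraction <- function(traj, species, shell_radius) {
  if (shell_radius <= 0) abort("`shell_radius` must be > 0.")
  a <- traj_arrays(traj)
  box <- a$box
  rec <- which(is_receptor_role(a$role))
  if (!length(rec)) abort("Trajectory contains no receptors.")
  idx <- which(a$species == species)
  if (!length(idx)) abort(paste0("Species absent from trajectory: ", species))
  series <- purrr::map_dfr(seq_along(a$times), function(f) {
    d <- min_image_cross_dist(a$x[idx, f], a$y[idx, f],
                              a$x[rec, f], a$y[rec, f], box)
    tibble(time = a$times[f], fraction = mean(apply(d, 1, min) < shell_radius))
  })
  blocks <- series %>%
    mutate(block = cut(rank(.data$time, ties.method = "first"),
                       min(5, nrow(series)), labels = FALSE)) %>%
    group_by(.data$block) %>%
    summarise(m = mean(.data$fraction), .groups = "drop")
  list(series = series,
       summary = tibble(mean_fraction = mean(series$fraction),
                        sem = sd(blocks$m) / sqrt(nrow(blocks))))
}
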