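#' Configure a Brownian membrane simulation
#'
#' Builds the configuration for the seeded 2D overdamped-Langevin generator.
#' Each species carries a particle count, a translational diffusion
#' coefficient D (nm^2/us), a rotational coefficient Dr (rad^2/us; receptors
#' only) and an excluded-volume radius (nm). Pairs interact through a
#' quadratic soft core inside `r0 = radius_a + radius_b` plus, where an
#' attraction is declared, a Gaussian well of depth `epsilon` (kT) and width
#' `sigma` (nm) centred at `r0` and truncated at `r0 + 3 sigma`. kT is 1
#' internally, so depths are in thermal units.
#'
#' @param species A tibble with columns `species`, `count`, `D`, `Dr`,
#'   `radius`.
#' @param box A [box_spec()].
#' @param attractions Optional tibble `a`, `b`, `epsilon`, `sigma` declaring
#'   attractive wells between species pairs (order-free).
#' @param dt Timestep in us. Refused if `sqrt(2 D dt)` exceeds a fifth of
#'   the narrowest attractive well.
#' @param n_steps Number of integration steps (must be a multiple of
#'   `stride`).
#' @param stride Save a frame every `stride` steps (frame 0 always saved).
#' @param k_rep Soft-core strength in kT (default 50).
#' @param init_min_sep Minimum initial receptor-receptor separation (nm).
#' @return A `sim_config` object.
#' @export
sim_config <- function(species, box, attractions = NULL, dt = 2e-4,
                       n_steps = 20000L, stride = 100L, k_rep = 50,
                       init_min_sep = 6) {
  species <- as_tibble(species)
  need <- c("species", "count", "D", "Dr", "radius")
  if (!all(need %in% names(species))) {
    abort(paste0("`species` needs columns: ", paste(need, collapse = ", ")))
  }
  if (any(species$D < 0) || any(species$Dr < 0) || any(species$radius <= 0)) {
    abort("D and Dr must be >= 0 and radius > 0.")
  }
  if (n_steps %% stride != 0) abort("`n_steps` must be a multiple of `stride`.")
  if (!is.null(attractions)) {
    attractions <- as_tibble(attractions)
    if (any(attractions$epsilon < 0) || any(attractions$sigma <= 0)) {
      abort("Attractions need epsilon >= 0 and sigma > 0.")
    }
    unknown <- setdiff(c(attractions$a, attractions$b), species$species)
    if (length(unknown)) {
      abort(paste0("Attraction references unknown species: ",
                   paste(unique(unknown), collapse = ", ")))
    }
    if (nrow(attractions)) {
      step_sd <- sqrt(2 * max(species$D) * dt)
      smin <- min(attractions$sigma)
      if (step_sd >= smin / 5) {
        abort(sprintf(
          "Timestep too coarse: sqrt(2 D dt) = %.3g nm but the narrowest well is %.3g nm; use dt <= %.3g us.",
          step_sd, smin, (smin / 5)^2 / (2 * max(species$D))))
      }
    }
  }
  structure(list(species = species, box = box, attractions = attractions,
                 dt = dt, n_steps = as.integer(n_steps),
                 stride = as.integer(stride), k_rep = k_rep,
                 init_min_sep = init_min_sep),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d species, %d particles, box %s nm, dt %g us, %d steps (stride %d)\n",
              nrow(x$species), sum(x$species$count),
              paste(format(x$box$lengths), collapse = " x "),
              x$dt, x$n_steps, x$stride))
  invisible(x)
}

config_matrices <- function(config) {
  sp <- config$species
  ns <- nrow(sp)
  eps <- matrix(0, ns, ns, dimnames = list(sp$species, sp$species))
  sig <- matrix(1, ns, ns)
  r0 <- outer(sp$radius, sp$radius, `+`)
  if (!is.null(config$attractions)) {
    for (k in seq_len(nrow(config$attractions))) {
      ai <- match(config$attractions$a[k], sp$species)
      bi <- match(config$attractions$b[k], sp$species)
      eps[ai, bi] <- eps[bi, ai] <- config$attractions$epsilon[k]
      sig[ai, bi] <- sig[bi, ai] <- config$attractions$sigma[k]
    }
  }
  list(eps = eps, sigma = sig, r0 = r0)
}

#' Run the Brownian membrane generator
#'
#' Integrates overdamped Langevin dynamics for the configured species and
#' returns the saved trajectory together with the generating ground truth
#' (the parameter-recovery oracle for every estimator in the package).
#' Identical `(config, seed)` pairs give bit-identical output.
#'
#' Receptors start mutually separated by at least `init_min_sep`
#' (dart-throwing placement); lipids start uniformly at random; receptor
#' orientations start uniform on the circle and evolve by rotational
#' diffusion.
#'
#' @param config A [sim_config()].
#' @param seed Integer RNG seed.
#' @return A list with elements `trajectory` (a `mem_trajectory`) and
#'   `ground_truth` (species parameters, interaction table, seed).
#' @export
simulate_membrane <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  sp <- config$species
  box <- config$box
  reg <- species_registry()
  roles <- species_role(sp$species, reg)
  roles[is.na(roles)] <- "unknown"
  counts <- sp$count
  np <- sum(counts)
  sp_idx <- rep(seq_len(nrow(sp)), counts)
  species <- sp$species[sp_idx]
  role <- roles[sp_idx]
  D <- sp$D[sp_idx]
  Dr <- sp$Dr[sp_idx]

  is_rec <- is_receptor_role(role)
  x <- runif(np, 0, box$lengths[1])
  y <- runif(np, 0, box$lengths[2])
  if (any(is_rec) && config$init_min_sep > 0) {
    ridx <- which(is_rec)
    placed_x <- numeric(0); placed_y <- numeric(0)
    for (i in ridx) {
      for (try in seq_len(2000L)) {
        cx <- runif(1, 0, box$lengths[1]); cy <- runif(1, 0, box$lengths[2])
        if (!length(placed_x)) break
        d <- min_image_cross_dist(cx, cy, placed_x, placed_y, box)
        if (min(d) >= config$init_min_sep) break
        if (try == 2000L) abort("Could not place receptors at the requested initial separation.")
      }
      placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
      x[i] <- cx; y[i] <- cy
    }
  }
  theta <- ifelse(is_rec, runif(np, 0, 2 * pi), NA_real_)

  mats <- config_matrices(config)
  res <- .bd_simulate(x, y, ifelse(is.na(theta), 0, theta),
                      sp_idx - 1L, D, Dr,
                      mats$eps, mats$sigma, mats$r0, config$k_rep,
                      box$lengths[1:2], config$dt, config$n_steps,
                      config$stride)
  nf <- ncol(res$x)
  times <- (seq_len(nf) - 1) * config$dt * config$stride
  TH <- res$theta
  TH[!is_rec, ] <- NA_real_
  a <- list(ids = seq_len(np), species = species, role = role,
            times = times, x = res$x, y = res$y, theta = TH, box = box)
  traj <- arrays_to_traj(a)
  gt <- structure(list(species = sp, attractions = config$attractions,
                       seed = seed, dt = config$dt, stride = config$stride,
                       box = box),
                  class = "ground_truth")
  list(trajectory = traj, ground_truth = gt)
}

receptor_param_table <- function(condition) {
  # Translational receptor D in nm^2/us for each condition; rotational rates
  # scaled like the translational ones (package convention).
  switch(condition,
    healthy = tibble(species = c("A2A", "D2"), D = c(0.48, 0.46)),
    diseased = tibble(species = c("A2A", "D2"), D = c(0.18, 0.22)),
    ternary_high_dha = tibble(species = c("A2A", "D2"), D = c(0.48, 0.46))
  )
}

lipid_param_table <- function(condition) {
  # Lipid D (nm^2/us == 1e-8 cm^2/s) per condition, crowded-system values.
  switch(condition,
    healthy = c(CHOL = 3.4, SM = 2.7, DPPC = 2.9, DSPC = 2.9, DOPC = 2.9,
                SDPC = 2.1),
    diseased = c(CHOL = 2.6, SM = 2.5, DPPC = 2.5, DSPC = 2.4, DOPC = 2.4,
                 SDPC = 1.3),
    ternary_high_dha = c(POPC = 8.1, SDPE = 8.1, CHOL = 12.4)
  )
}

#' Study-condition simulation presets
#'
#' Ready-made configurations for the DHA-rich (`"healthy"`), DHA-poor
#' (`"diseased"`) and very-high-DHA ternary membranes: 9 A2A + 9 D2
#' receptors plus lipids apportioned from the matching
#' [composition_preset()], species diffusion coefficients set to the
#' measured crowded-membrane values (receptors 0.48/0.46 vs 0.18/0.22
#' nm^2/us; lipids 1.3-3.4, ternary 8.1-12.4 nm^2/us), a receptor-receptor
#' attraction, and a DHA-lipid/receptor attraction that builds the
#' preferential DHA solvation shell. The DHA-lipid well is shared by SDPC
#' and SDPE.
#'
#' @param condition Preset name.
#' @param n_receptors Total receptor count (split evenly A2A/D2).
#' @param n_lipids Lipid particle count (sparse stand-in, not bilayer
#'   density).
#' @param box_length Square box edge in nm.
#' @param n_steps,stride,dt Integrator settings, see [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(condition = c("healthy", "diseased", "ternary_high_dha"),
                       n_receptors = 18L, n_lipids = 150L, box_length = 40,
                       n_steps = 20000L, stride = 100L, dt = 2e-4) {
  condition <- match.arg(condition)
  comp <- composition_preset(condition)
  lip_counts <- particle_counts(comp, n_lipids)
  lipD <- lipid_param_table(condition)
  recD <- receptor_param_table(condition)
  rec <- tibble(species = recD$species,
                count = c(ceiling(n_receptors / 2), floor(n_receptors / 2)),
                D = recD$D, Dr = recD$D, radius = 1.8)
  lip <- tibble(species = lip_counts$species, count = lip_counts$count,
                D = unname(lipD[lip_counts$species]), Dr = 0, radius = 0.4)
  dha_lipids <- intersect(c("SDPC", "SDPE"), lip$species)
  attr_tbl <- bind_rows(
    tidyr::expand_grid(a = rec$species, b = rec$species) %>%
      filter(.data$a <= .data$b) %>%
      mutate(epsilon = 3, sigma = 0.8),
    tidyr::expand_grid(a = rec$species, b = dha_lipids) %>%
      mutate(epsilon = 2, sigma = 0.5)
  )
  sim_config(bind_rows(rec, lip), box_spec(c(box_length, box_length)),
             attractions = attr_tbl, dt = dt, n_steps = n_steps,
             stride = stride)
}

#' Demixing preset: a binary mixture with like-like attraction
#'
#' An equimolar saturated/unsaturated lipid mixture (DPPC and DOPC) in which
#' `strength` scales the like-like attraction between saturation classes.
#' At `strength = 0` the mixture is ideal and the saturated-unsaturated
#' contact fraction relaxes to the random-mixing value 2 x (1 - x);
#' increasing strength drives partial demixing and pushes the contact
#' fraction below it.
#'
#' @param strength Like-like well depth in kT (>= 0).
#' @param n_lipids Total particles (split equally).
#' @param box_length Box edge (nm).
#' @param n_steps,stride,dt Integrator settings.
#' @return A `sim_config`.
#' @export
demix_preset <- function(strength, n_lipids = 200L, box_length = 25,
                         n_steps = 10000L, stride = 100L, dt = 2e-4) {
  if (strength < 0) abort("`strength` must be >= 0.")
  half <- n_lipids %/% 2
  sp <- tibble(species = c("DPPC", "DOPC"),
               count = c(half, n_lipids - half),
               D = c(2.9, 2.9), Dr = 0, radius = 0.4)
  attr_tbl <- if (strength > 0) {
    tibble(a = c("DPPC", "DOPC"), b = c("DPPC", "DOPC"),
           epsilon = strength, sigma = 0.4)
  } else NULL
  sim_config(sp, box_spec(c(box_length, box_length)),
             attractions = attr_tbl, dt = dt, n_steps = n_steps,
             stride = stride, init_min_sep = 0)
}

#' Deterministic receptor layout fixtures
#'
#' Places receptors in exactly known arrangements (isolated monomers, dimer
#' pairs, a linear chain, a ring, or custom coordinates) so that contact
#' analyses have constructed ground truth. Species alternate A2A/D2 by
#' default.
#'
#' @param arrangement One of `"singletons"`, `"dimers"`, `"chain"`,
#'   `"ring"`, `"custom"`.
#' @param n Number of receptors (for `dimers`: number of pairs).
#' @param spacing Nearest-neighbour centre spacing in nm (intra-pair
#'   spacing for `dimers`; chord length for `ring`).
#' @param box A [box_spec()].
#' @param coords For `"custom"`: a matrix/data frame of x, y.
#' @param species Recycled species labels (default alternating A2A/D2).
#' @param n_frames Number of identical frames to emit.
#' @param dt Frame spacing (us).
#' @param min_gap Minimum separation between distinct groups (nm).
#' @return A `mem_trajectory`.
#' @export
make_layout <- function(arrangement = c("singletons", "dimers", "chain",
                                        "ring", "custom"),
                        n = 9L, spacing = 4.0, box = box_spec(c(50, 50)),
                        coords = NULL, species = NULL, n_frames = 1L,
                        dt = 0.1, min_gap = 8) {
  arrangement <- match.arg(arrangement)
  pts <- switch(arrangement,
    singletons = grid_points(n, box, min_gap),
    dimers = {
      centers <- grid_points(n, box, max(min_gap, spacing + min_gap))
      do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
        rbind(centers[i, ] - c(spacing / 2, 0), centers[i, ] + c(spacing / 2, 0))
      }))
    },
    chain = {
      len <- (n - 1) * spacing
      if (len >= box$lengths[1]) abort("Chain does not fit in the box at this spacing.")
      x0 <- (box$lengths[1] - len) / 2
      cbind(x0 + (seq_len(n) - 1) * spacing, box$lengths[2] / 2)
    },
    ring = {
      r <- spacing / (2 * sin(pi / n))
      if (2 * r >= min(box$lengths[1:2]) - spacing) {
        abort("Ring does not fit in the box at this spacing.")
      }
      ang <- 2 * pi * (seq_len(n) - 1) / n
      cbind(box$lengths[1] / 2 + r * cos(ang),
            box$lengths[2] / 2 + r * sin(ang))
    },
    custom = {
      if (is.null(coords)) abort("`coords` required for custom arrangement.")
      as.matrix(coords)[, 1:2, drop = FALSE]
    })
  np <- nrow(pts)
  if (is.null(species)) species <- rep(c("A2A", "D2"), length.out = np)
  species <- rep(species, length.out = np)
  df <- tibble(
    frame = rep(seq_len(n_frames) - 1L, each = np),
    time = rep((seq_len(n_frames) - 1) * dt, each = np),
    id = rep(seq_len(np), n_frames),
    species = rep(species, n_frames),
    x = rep(wrap_coord(pts[, 1], box$lengths[1]), n_frames),
    y = rep(wrap_coord(pts[, 2], box$lengths[2]), n_frames),
    theta = 0
  )
  as_trajectory(df, box)
}

# Regular grid of n well-separated points; errors if the box is too small.
grid_points <- function(n, box, min_gap) {
  k <- ceiling(sqrt(n))
  sx <- box$lengths[1] / k
  sy <- box$lengths[2] / k
  if (sx < min_gap || sy < min_gap) {
    abort("Arrangement does not fit in the box at the requested spacing.")
  }
  g <- expand.grid(ix = seq_len(k) - 1, iy = seq_len(k) - 1)[seq_len(n), ]
  cbind((g$ix + 0.5) * sx, (g$iy + 0.5) * sy)
}
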