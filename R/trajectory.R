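#' Membrane trajectory container
#'
#' A trajectory is a tidy tibble with one row per particle per frame and
#' columns `frame` (0-based integer), `time` (us), `id` (integer particle
#' id), `species`, `role`, `x`, `y` (nm, wrapped into the box) and `theta`
#' (orientation in rad; `NA` for non-receptors). The periodic box and the
#' species table travel as attributes, so the object still pipes through
#' dplyr verbs; use [trajectory_box()] to recover the box and
#' [as_trajectory()] to re-assert the class after heavy manipulation.
#'
#' @param data A data frame with the columns above (`theta` optional).
#' @param box A [box_spec()].
#' @param species_table Species metadata, defaults to [species_registry()];
#'   rows for unknown species may be added by the caller.
#' @param validate Check structural invariants (identical particle set per
#'   frame, strictly increasing times). Default `TRUE`.
#' @return A `mem_trajectory` tibble.
#' @export
as_trajectory <- function(data, box, species_table = species_registry(),
                          validate = TRUE) {
  stopifnot(is_box_spec(box))
  data <- as_tibble(data)
  need <- c("frame", "time", "id", "species", "x", "y")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("Trajectory data is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  if (!"theta" %in% names(data)) data$theta <- NA_real_
  if (!"role" %in% names(data)) {
    data$role <- species_role(data$species, species_table)
    if (anyNA(data$role)) {
      warn(paste0("Species without a role mapping flagged as 'unknown': ",
                  paste(unique(data$species[is.na(data$role)]), collapse = ", ")))
      data$role[is.na(data$role)] <- "unknown"
    }
  }
  data <- arrange(data, .data$frame, .data$id)
  data <- data[, c("frame", "time", "id", "species", "role", "x", "y", "theta")]
  out <- new_tibble(data, box = box, species_table = species_table,
                    class = "mem_trajectory")
  if (validate) validate_trajectory(out)
  out
}

validate_trajectory <- function(traj) {
  box <- trajectory_box(traj)
  frames <- unique(traj$frame)
  times <- traj %>% distinct(.data$frame, .data$time) %>% arrange(.data$frame)
  if (anyDuplicated(times$frame)) {
    abort("Structural error: a frame index maps to more than one time.")
  }
  if (is.unsorted(times$time, strictly = TRUE)) {
    abort("Structural error: frame times must be strictly increasing.")
  }
  counts <- table(traj$frame)
  if (length(unique(as.integer(counts))) > 1L) {
    abort("Structural error: frames have differing particle counts.")
  }
  ids0 <- sort(traj$id[traj$frame == frames[1]])
  if (anyDuplicated(ids0)) {
    abort("Structural error: duplicated particle ids within a frame.")
  }
  invisible(traj)
}

#' @rdname as_trajectory
#' @param traj A `mem_trajectory`.
#' @export
trajectory_box <- function(traj) {
  box <- attr(traj, "box")
  if (is.null(box)) abort("Object carries no box attribute; use as_trajectory().")
  box
}

#' @rdname as_trajectory
#' @export
trajectory_species_table <- function(traj) {
  tab <- attr(traj, "species_table")
  if (is.null(tab)) species_registry() else tab
}

#' @export
print.mem_trajectory <- function(x, ...) {
  box <- attr(x, "box")
  nf <- length(unique(x$frame))
  np <- sum(x$frame == x$frame[1])
  cat(sprintf("<mem_trajectory> %d particles x %d frames, box %s nm\n",
              np, nf, paste(format(box$lengths), collapse = " x ")))
  NextMethod()
}

# Matrix view used by the analyses: particles in rows (sorted by id),
# frames in columns. Assumes a validated trajectory.
traj_arrays <- function(traj) {
  frames <- sort(unique(traj$frame))
  nf <- length(frames)
  ord <- order(traj$frame, traj$id)
  tr <- traj[ord, ]
  np <- nrow(tr) / nf
  first <- tr[seq_len(np), ]
  list(
    ids = first$id, species = first$species, role = first$role,
    times = tr$time[seq(1, nrow(tr), by = np)],
    x = matrix(tr$x, nrow = np, ncol = nf),
    y = matrix(tr$y, nrow = np, ncol = nf),
    theta = matrix(tr$theta, nrow = np, ncol = nf),
    box = trajectory_box(traj)
  )
}

# Rebuild a mem_trajectory from a traj_arrays()-shaped list.
arrays_to_traj <- function(a, species_table = species_registry(),
                           validate = FALSE) {
  nf <- ncol(a$x)
  np <- nrow(a$x)
  df <- tibble(
    frame = rep(seq_len(nf) - 1L, each = np),
    time = rep(a$times, each = np),
    id = rep(a$ids, nf),
    species = rep(a$species, nf),
    role = rep(a$role, nf),
    x = as.vector(a$x),
    y = as.vector(a$y),
    theta = as.vector(a$theta)
  )
  as_trajectory(df, a$box, species_table = species_table, validate = validate)
}

#' Unwrap periodic coordinates into continuous paths
#'
#' Rebuilds continuous particle paths from box-wrapped coordinates by
#' accumulating minimum-image frame-to-frame displacements, the prerequisite
#' for mean-squared-displacement analysis. Sampling must be dense enough
#' that no particle moves half a box length between saved frames; steps at
#' the ambiguity boundary trigger a warning naming the particles involved.
#'
#' @param traj A `mem_trajectory` with wrapped coordinates.
#' @return A `mem_trajectory` whose `x`, `y` are continuous (may leave the
#'   box); an attribute `unwrapped = TRUE` is set.
#' @export
unwrap_trajectory <- function(traj) {
  a <- traj_arrays(traj)
  box <- a$box
  nf <- ncol(a$x)
  if (nf > 1) {
    dx <- wrap_delta(a$x[, -1, drop = FALSE] - a$x[, -nf, drop = FALSE],
                     box$lengths[1])
    dy <- wrap_delta(a$y[, -1, drop = FALSE] - a$y[, -nf, drop = FALSE],
                     box$lengths[2])
    near_half <- abs(dx) >= box$lengths[1] / 2 * (1 - 1e-9) |
      abs(dy) >= box$lengths[2] / 2 * (1 - 1e-9)
    if (any(near_half)) {
      bad <- a$ids[unique(which(near_half, arr.ind = TRUE)[, 1])]
      warn(paste0("Unwrapping unreliable: step of half a box length for particle(s) ",
                  paste(bad, collapse = ", ")))
    }
    a$x <- cbind(a$x[, 1], a$x[, 1] + t(apply(dx, 1, cumsum)))
    a$y <- cbind(a$y[, 1], a$y[, 1] + t(apply(dy, 1, cumsum)))
  }
  out <- arrays_to_traj(a, trajectory_species_table(traj))
  attr(out, "unwrapped") <- TRUE
  out
}

#' Wrap trajectory coordinates back into the box
#'
#' @param traj A `mem_trajectory` (typically unwrapped).
#' @return A `mem_trajectory` with coordinates in `[0, L)` on periodic axes.
#' @export
wrap_trajectory <- function(traj) {
  box <- trajectory_box(traj)
  out <- traj
  out$x <- wrap_coord(out$x, box$lengths[1], box$periodic[1])
  out$y <- wrap_coord(out$y, box$lengths[2], box$periodic[2])
  attr(out, "unwrapped") <- NULL
  out
}

# Frame of reference particles (receptors by default) as a small tibble.
traj_frame <- function(traj, frame) {
  filter(traj, .data$frame == !!frame)
}

receptor_ids <- function(traj) {
  sort(unique(traj$id[is_receptor_role(traj$role)]))
}
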