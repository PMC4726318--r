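#' Receptor-receptor contact matrix for one frame
#'
#' Two receptors are in contact when their lateral (in-plane, minimum-image)
#' centre distance is strictly below `cutoff`; ties at exactly the cutoff
#' are non-contacts. The distance-only criterion deliberately includes
#' lipid-mediated closeness. The default 4.2 nm is the centre-of-mass
#' contact criterion for coarse receptor models.
#'
#' @param traj A `mem_trajectory`.
#' @param frame Frame index (0-based) to analyse.
#' @param cutoff Contact cutoff in nm (must be < half the box edge).
#' @return A symmetric logical matrix with receptor ids as dimnames.
#' @export
contact_matrix <- function(traj, frame = 0L, cutoff = 4.2) {
  box <- trajectory_box(traj)
  if (cutoff >= min(box$lengths[1:2]) / 2) {
    abort("`cutoff` must be below half the box edge (ambiguous under periodicity).")
  }
  fr <- traj_frame(traj, frame)
  fr <- fr[is_receptor_role(fr$role), ]
  if (nrow(fr) < 1L) abort("Frame contains no receptors.")
  d <- min_image_dist(fr$x, fr$y, box)
  m <- d < cutoff
  diag(m) <- FALSE
  dimnames(m) <- list(fr$id, fr$id)
  m
}

# Per-frame receptor contact counts and oligomer orders for a whole
# trajectory; internal workhorse shared by the contact analyses.
contact_count_frames <- function(traj, cutoff) {
  box <- trajectory_box(traj)
  if (cutoff >= min(box$lengths[1:2]) / 2) {
    abort("`cutoff` must be below half the box edge (ambiguous under periodicity).")
  }
  a <- traj_arrays(traj)
  rec <- which(is_receptor_role(a$role))
  if (!length(rec)) abort("Trajectory contains no receptors.")
  purrr::map_dfr(seq_along(a$times), function(f) {
    d <- min_image_dist(a$x[rec, f], a$y[rec, f], box)
    m <- d < cutoff
    diag(m) <- FALSE
    comp <- components_from_matrix(m)
    tibble(frame = f - 1L, time = a$times[f], id = a$ids[rec],
           species = a$species[rec],
           n_contacts = rowSums(m),
           oligomer_size = comp$size[comp$component])
  })
}

# Connected components of a logical adjacency matrix via igraph.
components_from_matrix <- function(m) {
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
  cl <- igraph::components(g)
  list(component = cl$membership, size = as.integer(cl$csize),
       n = cl$no)
}

resolve_window <- function(times, window) {
  span <- range(times)
  if (is.null(window)) {
    window <- c(span[1] + 2 / 3 * diff(span), span[2])
  }
  keep <- times >= window[1] & times <= window[2]
  if (!any(keep)) abort("Empty analysis window.")
  list(window = window, keep = keep)
}

#' Contacts per protomer over an analysis window
#'
#' Computes the per-frame number of receptor-receptor contacts for every
#' protomer and summarises the mean over receptors and frames in the
#' analysis window. The default window is the final third of the
#' trajectory, the equilibrated tail where stable contacts dominate. With a
#' list of replica trajectories the summary error is the SEM over replicas;
#' for a single run it is a 5-block block-averaged SEM.
#'
#' @param traj A `mem_trajectory` or a list of replica trajectories.
#' @param cutoff Contact cutoff in nm.
#' @param window Numeric `c(t_min, t_max)` in us, or `NULL` for the final
#'   third.
#' @return A `contact_series` object; `tidy()` gives per-frame per-receptor
#'   counts and oligomer orders, `glance()` the windowed summary.
#' @export
contacts_per_protomer <- function(traj, cutoff = 4.2, window = NULL) {
  runs <- if (inherits(traj, "mem_trajectory")) list(traj) else traj
  per_run <- purrr::imap(runs, function(tr, i) {
    counts <- contact_count_frames(tr, cutoff)
    w <- resolve_window(unique(counts$time), window)
    counts$replicate <- i
    counts$in_window <- counts$time >= w$window[1] & counts$time <= w$window[2]
    list(counts = counts, window = w$window)
  })
  counts <- bind_rows(purrr::map(per_run, "counts"))
  rep_means <- counts %>%
    filter(.data$in_window) %>%
    group_by(.data$replicate) %>%
    summarise(mean_contacts = mean(.data$n_contacts), .groups = "drop")
  n_rep <- nrow(rep_means)
  overall <- mean(rep_means$mean_contacts)
  err <- if (n_rep >= 3) {
    sd(rep_means$mean_contacts) / sqrt(n_rep)
  } else {
    # block SEM over 5 time blocks of the (pooled) windowed frames
    blk <- counts %>%
      filter(.data$in_window) %>%
      group_by(.data$replicate, .data$time) %>%
      summarise(m = mean(.data$n_contacts), .groups = "drop") %>%
      mutate(block = cut(rank(.data$time, ties.method = "first"), 5,
                         labels = FALSE)) %>%
      group_by(.data$block) %>%
      summarise(m = mean(.data$m), .groups = "drop")
    sd(blk$m) / sqrt(nrow(blk))
  }
  structure(list(counts = counts, cutoff = cutoff,
                 window = per_run[[1]]$window,
                 summary = tibble(mean_contacts = overall, sem = err,
                                  n_replicates = n_rep)),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("<contact_series> cutoff %.2f nm, window [%.3g, %.3g] us\n",
              x$cutoff, x$window[1], x$window[2]))
  cat(sprintf("  mean contacts/protomer %.4f +/- %.4f (%d replicate%s)\n",
              x$summary$mean_contacts, x$summary$sem,
              x$summary$n_replicates,
              if (x$summary$n_replicates == 1) "" else "s"))
  invisible(x)
}

#' @export
tidy.contact_series <- function(x, ...) x$counts

#' @export
glance.contact_series <- function(x, ...) {
  mutate(x$summary, cutoff = x$cutoff,
         window_start = x$window[1], window_end = x$window[2])
}

#' Oligomer partition of a contact matrix
#'
#' Connected components of the contact graph: every receptor belongs to
#' exactly one oligomer, monomers included as size-1 components.
#'
#' @param m A symmetric logical contact matrix (see [contact_matrix()]).
#' @return An `oligomer_partition`: tibble of `id`, `component`,
#'   `oligomer_size`, plus a `sizes` attribute (size histogram tibble).
#' @export
oligomer_clusters <- function(m) {
  comp <- components_from_matrix(m)
  ids <- if (!is.null(rownames(m))) rownames(m) else as.character(seq_len(nrow(m)))
  out <- tibble(id = ids, component = as.integer(comp$component),
                oligomer_size = comp$size[comp$component])
  hist <- tibble(size = comp$size) %>%
    group_by(.data$size) %>%
    summarise(n_oligomers = n(), .groups = "drop")
  attr(out, "sizes") <- hist
  class(out) <- c("oligomer_partition", class(out))
  out
}

#' Homomeric versus heteromeric contact classification
#'
#' @param m Contact matrix with receptor ids as dimnames.
#' @param species Named character vector (or vector in matrix order) giving
#'   each receptor's species (`"A2A"` or `"D2"`).
#' @return A tibble of contact type (`A2A-A2A`, `D2-D2`, `A2A-D2`), edge
#'   `count` and `fraction` (of all edges; `NaN`-free when edges exist).
#' @export
classify_contacts <- function(m, species) {
  ids <- rownames(m)
  sp <- if (!is.null(names(species))) unname(species[ids]) else species
  if (anyNA(sp) || length(sp) != nrow(m)) {
    abort("Every receptor must carry an A2A/D2 species label.")
  }
  idx <- which(m & upper.tri(m), arr.ind = TRUE)
  type <- character(nrow(idx))
  if (nrow(idx)) {
    pa <- sp[idx[, 1]]; pb <- sp[idx[, 2]]
    type <- ifelse(pa == pb, paste0(pa, "-", pb),
                   paste0(pmin(pa, pb), "-", pmax(pa, pb)))
  }
  lv <- c("A2A-A2A", "D2-D2", "A2A-D2")
  counts <- table(factor(type, levels = lv))
  tibble(type = lv, count = as.integer(counts),
         fraction = if (sum(counts) > 0) as.numeric(counts) / sum(counts)
                    else rep(NA_real_, 3))
}

#' Compare aggregation between two conditions
#'
#' Relative difference in windowed mean contacts per protomer between two
#' sets of replica runs, with a replicate-level Welch two-sample t test.
#'
#' @param runs_a,runs_b Lists of `mem_trajectory` replicas (condition A is
#'   the numerator condition, e.g. DHA-rich).
#' @param cutoff Contact cutoff in nm.
#' @param window Analysis window, `NULL` for final third.
#' @return A one-row tibble: per-condition means, `relative_difference_pct`
#'   = (mean_A - mean_B)/mean_B x 100, Welch `t`, `df`, `p_value`.
#' @export
compare_aggregation <- function(runs_a, runs_b, cutoff = 4.2, window = NULL) {
  if (inherits(runs_a, "mem_trajectory")) runs_a <- list(runs_a)
  if (inherits(runs_b, "mem_trajectory")) runs_b <- list(runs_b)
  mean_of <- function(runs) {
    vapply(runs, function(tr) {
      contacts_per_protomer(tr, cutoff = cutoff, window = window)$summary$mean_contacts
    }, numeric(1))
  }
  ma <- mean_of(runs_a); mb <- mean_of(runs_b)
  rel <- if (mean(mb) == 0) {
    warn("Condition B mean is zero; reporting absolute difference only.")
    NA_real_
  } else (mean(ma) - mean(mb)) / mean(mb) * 100
  tt <- if (length(ma) >= 2 && length(mb) >= 2 &&
            (sd(ma) > 0 || sd(mb) > 0)) {
    t.test(ma, mb, var.equal = FALSE)
  } else NULL
  tibble(mean_a = mean(ma), mean_b = mean(mb),
         absolute_difference = mean(ma) - mean(mb),
         relative_difference_pct = rel,
         n_a = length(ma), n_b = length(mb),
         t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
         df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
         p_value = if (is.null(tt)) {
           if (isTRUE(all.equal(ma, mb))) 1 else NA_real_
         } else tt$p.value)
}

#' Convert raw coarse-grained time to effective time
#'
#' Coarse models evolve faster than reality for lack of friction; reported
#' times carry the standard 4-fold speed-up conversion.
#'
#' @param raw_time Raw simulation time(s), us.
#' @param factor Speed-up factor (default 4).
#' @return Effective time(s) with attribute `time_axis = "effective"`.
#' @export
effective_time <- function(raw_time, factor = 4) {
  if (any(raw_time < 0)) abort("`raw_time` must be >= 0.")
  structure(raw_time * factor, time_axis = "effective")
}

#' Effective oligomerisation onset distance
#'
#' The distance at which aggregation effectively consolidates: the contact
#' cutoff plus the widths of the two DHA-lipid shells that coat the
#' approaching receptors.
#'
#' @param cutoff Contact cutoff (nm).
#' @param shell_width Single-shell width (nm), typically 0.8-0.9.
#' @return Onset distance in nm.
#' @examples
#' onset_radius(4.2, 0.9) # 6.0
#' @export
onset_radius <- function(cutoff = 4.2, shell_width = 0.9) {
  if (cutoff <= 0 || shell_width < 0) abort("cutoff > 0 and shell_width >= 0 required.")
  cutoff + 2 * shell_width
}

#' Pairwise receptor distance series and first sustained contact
#'
#' Lateral minimum-image distance between two receptors over time, plus the
#' onset time of the first contact sustained for at least `tau`
#' (a run of consecutive frames below `cutoff` spanning `tau` or more).
#'
#' @param traj A `mem_trajectory`.
#' @param i,j Receptor particle ids.
#' @param cutoff Contact cutoff (nm).
#' @param tau Persistence requirement in us.
#' @return A list with `distances` (tibble `time`, `distance`, `in_contact`)
#'   and `onset_time` (`NA` if no sustained contact).
#' @export
pair_distance_series <- function(traj, i, j, cutoff = 4.2, tau = 0.1) {
  if (i == j) abort("`i` and `j` must be distinct receptors.")
  a <- traj_arrays(traj)
  box <- a$box
  pi_ <- match(i, a$ids); pj <- match(j, a$ids)
  if (is.na(pi_) || is.na(pj)) abort("Unknown particle id.")
  span <- diff(range(a$times))
  if (tau > span) abort("`tau` exceeds the trajectory span.")
  dx <- wrap_delta(a$x[pj, ] - a$x[pi_, ], box$lengths[1])
  dy <- wrap_delta(a$y[pj, ] - a$y[pi_, ], box$lengths[2])
  d <- sqrt(dx^2 + dy^2)
  inc <- d < cutoff
  onset <- NA_real_
  r <- rle(inc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (r$values[k]) {
      dur <- a$times[ends[k]] - a$times[starts[k]]
      if (dur >= tau) { onset <- a$times[starts[k]]; break }
    }
  }
  list(distances = tibble(time = a$times, distance = d, in_contact = inc),
       onset_time = onset)
}
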