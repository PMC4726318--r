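#' Periodic simulation box
#'
#' A box is a rectangular region with per-axis lengths and periodicity flags.
#' All membrane-plane analyses in this package use lateral (x, y) distances;
#' both in-plane axes must be periodic for minimum-image geometry to be
#' meaningful.
#'
#' @param lengths Numeric vector of axis lengths in nm (length 2 or 3).
#' @param periodic Logical vector of per-axis periodicity, recycled to
#'   `length(lengths)`. Default all periodic.
#' @return An object of class `box_spec`.
#' @examples
#' box_spec(c(50, 50))
#' @export
box_spec <- function(lengths, periodic = TRUE) {
  lengths <- as.numeric(lengths)
  if (!length(lengths) %in% c(2L, 3L)) {
    abort("`lengths` must have 2 or 3 axes.")
  }
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("Box lengths must be finite and > 0.")
  }
  periodic <- rep_len(as.logical(periodic), length(lengths))
  if (!all(periodic[1:2])) {
    abort("The two in-plane axes must be periodic for membrane analyses.")
  }
  structure(list(lengths = lengths, periodic = periodic),
            class = "box_spec")
}

#' @export
print.box_spec <- function(x, ...) {
  cat("<box_spec> ", paste(format(x$lengths), collapse = " x "), " nm",
      " (periodic: ", paste(x$periodic, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

is_box_spec <- function(x) inherits(x, "box_spec")

# Wrap a single periodic coordinate difference into (-L/2, L/2].
wrap_delta <- function(d, L) {
  w <- d %% L
  ifelse(w > L / 2, w - L, w)
}

#' Minimum-image displacement between two points
#'
#' Returns the displacement vector from `p` to `q` under the minimum-image
#' convention, i.e. the shortest of all periodic images of `q - p`. Each
#' periodic component lies in `(-L/2, L/2]`.
#'
#' @param p,q Numeric vectors of coordinates (nm), matching the box
#'   dimensionality (extra trailing axes in `p`/`q` are an error).
#' @param box A [box_spec()].
#' @return Numeric displacement vector in nm.
#' @examples
#' minimum_image_displacement(c(0.5, 0.5), c(10.8, 0.5), box_spec(c(11, 11)))
#' @export
minimum_image_displacement <- function(p, q, box) {
  stopifnot(is_box_spec(box))
  nd <- length(box$lengths)
  if (length(p) != nd || length(q) != nd) {
    abort("`p` and `q` must match the box dimensionality.")
  }
  d <- as.numeric(q) - as.numeric(p)
  out <- numeric(nd)
  for (k in seq_len(nd)) {
    if (box$periodic[k]) {
      out[k] <- wrap_delta(d[k], box$lengths[k])
    } else {
      if (abs(d[k]) > box$lengths[k]) {
        abort("Non-periodic axis displacement exceeds the box length; geometry is ambiguous.")
      }
      out[k] <- d[k]
    }
  }
  out
}

# Vectorised lateral minimum-image difference matrices for one frame.
# x, y: numeric vectors. Returns list(dx, dy) of n x n matrices with
# dx[i, j] = wrapped (x[j] - x[i]).
min_image_diffs <- function(x, y, box) {
  dx <- outer(x, x, function(a, b) b - a)
  dy <- outer(y, y, function(a, b) b - a)
  list(dx = wrap_delta(dx, box$lengths[1]),
       dy = wrap_delta(dy, box$lengths[2]))
}

# Lateral minimum-image distance matrix for one frame.
min_image_dist <- function(x, y, box) {
  d <- min_image_diffs(x, y, box)
  sqrt(d$dx^2 + d$dy^2)
}

# Cross-set lateral distances: rows index (xa, ya), cols index (xb, yb).
min_image_cross_dist <- function(xa, ya, xb, yb, box) {
  dx <- wrap_delta(outer(xa, xb, function(a, b) b - a), box$lengths[1])
  dy <- wrap_delta(outer(ya, yb, function(a, b) b - a), box$lengths[2])
  sqrt(dx^2 + dy^2)
}

# Wrap coordinates into [0, L) on periodic axes.
wrap_coord <- function(v, L, periodic = TRUE) {
  if (periodic) v %% L else v
}

#' Periodic-safe centre of mass
#'
#' Computes a weighted centre of mass that respects periodic boundaries by
#' the circular-mean construction: each periodic coordinate is mapped to an
#' angle on a circle of circumference L, the weighted mean resultant angle is
#' taken, and mapped back. For clusters smaller than half the box this agrees
#' with the naive mean after recentring on any member.
#'
#' @param positions Numeric matrix (n x d) of coordinates in nm.
#' @param weights Numeric vector of non-negative weights (default equal).
#' @param box A [box_spec()].
#' @return Numeric vector of length d, wrapped into the box.
#' @export
center_of_mass <- function(positions, weights = NULL, box) {
  positions <- rbind(positions)
  if (nrow(positions) == 0L) abort("Empty selection: no positions.")
  if (is.null(weights)) weights <- rep(1, nrow(positions))
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("Weights must be non-negative and not all zero.")
  }
  d <- ncol(positions)
  out <- numeric(d)
  for (k in seq_len(d)) {
    L <- box$lengths[k]
    if (box$periodic[k]) {
      # circular mean as a reference point, then the exact weighted mean of
      # the coordinates unwrapped to the image nearest that reference: for
      # clusters narrower than half the box this equals the naive COM
      # recentred on any member
      theta <- 2 * pi * positions[, k] / L
      phi <- atan2(sum(weights * sin(theta)), sum(weights * cos(theta)))
      guess <- (phi / (2 * pi)) %% 1 * L
      local <- guess + wrap_delta(positions[, k] - guess, L)
      out[k] <- weighted.mean(local, weights) %% L
    } else {
      out[k] <- weighted.mean(positions[, k], weights)
    }
  }
  out
}
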