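#' Mean squared lateral displacement
#'
#' Time- and ensemble-averaged MSD over all origins (configurable stride)
#' and selected particles, lateral components only. Input must be unwrapped
#' ([unwrap_trajectory()]); wrapped input is detected by box-scale jumps
#' and refused.
#'
#' @param traj An unwrapped `mem_trajectory`.
#' @param selection Species name(s) or integer particle ids; default all
#'   particles.
#' @param lags Integer vector of frame lags; default `1:(n_frames %/% 2)`.
#' @param origin_stride Use every k-th frame as a time origin (default 1).
#' @return An `msd_curve` tibble: `lag` (us), `msd` (nm^2), `n_samples`.
#' @export
msd <- function(traj, selection = NULL, lags = NULL, origin_stride = 1L) {
  a <- traj_arrays(traj)
  box <- a$box
  nf <- length(a$times)
  if (nf < 2) abort("Need at least 2 frames for an MSD.")
  if (!isTRUE(attr(traj, "unwrapped"))) {
    jump <- max(abs(diff(t(a$x)))) > box$lengths[1] / 2 ||
      max(abs(diff(t(a$y)))) > box$lengths[2] / 2
    inside <- all(a$x >= 0 & a$x < box$lengths[1]) &&
      all(a$y >= 0 & a$y < box$lengths[2])
    if (jump && inside) {
      abort("Input looks box-wrapped (jumps of a box length); run unwrap_trajectory() first.")
    }
  }
  sel <- if (is.null(selection)) seq_len(nrow(a$x))
         else if (is.numeric(selection)) match(selection, a$ids)
         else which(a$species %in% selection)
  if (!length(sel) || anyNA(sel)) abort("Empty or unknown selection.")
  if (is.null(lags)) lags <- seq_len(nf %/% 2)
  lags <- sort(unique(as.integer(lags)))
  if (max(lags) > nf - 1) abort("Largest lag exceeds the trajectory length.")
  X <- a$x[sel, , drop = FALSE]
  Y <- a$y[sel, , drop = FALSE]
  spacing <- diff(a$times)
  if (diff(range(spacing)) > 1e-9 * mean(spacing)) {
    abort("MSD requires evenly spaced frames.")
  }
  dt_frame <- mean(spacing)
  origins_all <- seq(1L, nf, by = origin_stride)
  res <- purrr::map_dfr(lags, function(L) {
    org <- origins_all[origins_all + L <= nf]
    dx <- X[, org + L, drop = FALSE] - X[, org, drop = FALSE]
    dy <- Y[, org + L, drop = FALSE] - Y[, org, drop = FALSE]
    tibble(lag = L * dt_frame, msd = mean(dx^2 + dy^2),
           n_samples = length(org) * length(sel))
  })
  class(res) <- c("msd_curve", class(res))
  res
}

#' Fit a lateral diffusion coefficient from an MSD curve
#'
#' Weighted least squares of `MSD = 4 D lag + b` with a free intercept
#' (which absorbs short-time artefacts), weights proportional to the number
#' of origin-particle samples per lag. The default fit window keeps lags in
#' the 10-50% range of the largest lag, where the estimator is least biased
#' for free Brownian motion.
#'
#' @param curve An `msd_curve`.
#' @param window Numeric `c(min_lag, max_lag)` in us, or `NULL` for the
#'   default window.
#' @return A `diffusion_estimate` (method `"translational"`): D in nm^2/us
#'   with standard error, intercept, and the window used.
#' @export
fit_diffusion <- function(curve, window = NULL) {
  if (is.null(window)) {
    mx <- max(curve$lag)
    window <- c(0.1 * mx, 0.5 * mx)
  }
  pts <- filter(curve, .data$lag >= window[1], .data$lag <= window[2])
  if (nrow(pts) < 4) abort("Fit window must contain at least 4 lags.")
  w <- if ("n_samples" %in% names(pts)) pts$n_samples else rep(1, nrow(pts))
  fit <- lm(msd ~ lag, data = pts, weights = w)
  slope <- coef(fit)[["lag"]]
  se <- summary(fit)$coefficients["lag", "Std. Error"]
  D <- slope / 4
  if (slope < 0) {
    warn("Negative MSD slope; reporting D = 0.")
    D <- 0
  }
  new_diffusion_estimate(D = D, se = se / 4,
                         intercept = coef(fit)[[1]],
                         window = window, method = "translational")
}

new_diffusion_estimate <- function(D, se, intercept = NA_real_, window,
                                   method, n_replicates = 1L) {
  structure(list(D = D, se = se, intercept = intercept, window = window,
                 method = method, n_replicates = n_replicates),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("<diffusion_estimate> %s D = %.4g +/- %.2g nm^2/us (= %.4g +/- %.2g x 1e-8 cm^2/s)\n",
              x$method, x$D, x$se,
              convert_units(x$D, "nm2_us", "1e-8cm2_s"),
              convert_units(x$se, "nm2_us", "1e-8cm2_s")))
  invisible(x)
}

#' @export
tidy.diffusion_estimate <- function(x, ...) {
  tibble(term = "D", estimate = x$D, std.error = x$se, method = x$method)
}

#' @export
glance.diffusion_estimate <- function(x, ...) {
  tibble(D = x$D, se = x$se, D_cm2_s = convert_units(x$D, "nm2_us", "cm2_s"),
         method = x$method, window_min = x$window[1],
         window_max = x$window[2], n_replicates = x$n_replicates)
}

#' Rotational diffusion from the orientation autocorrelation
#'
#' Computes `C(lag) = <cos(theta(t + lag) - theta(t))>` over origins and
#' selected receptors. For a planar rotor this decays exactly as
#' `exp(-Dr lag)`, so Dr is the negative slope of a log-linear fit,
#' restricted to `C >= 0.3` to avoid log-noise.
#'
#' @param traj A `mem_trajectory` with orientation angles.
#' @param selection Species or ids; default all receptors.
#' @param lags Integer frame lags; default `1:(n_frames %/% 2)`.
#' @param c_min Smallest correlation used in the fit (default 0.3).
#' @return A list: `curve` (tibble `lag`, `C`) and `estimate`
#'   (`diffusion_estimate`, method `"rotational"`; `NA` D when C is
#'   non-positive across the fit range).
#' @export
rotational_acf <- function(traj, selection = NULL, lags = NULL, c_min = 0.3) {
  a <- traj_arrays(traj)
  sel <- if (is.null(selection)) which(is_receptor_role(a$role))
         else if (is.numeric(selection)) match(selection, a$ids)
         else which(a$species %in% selection)
  TH <- a$theta[sel, , drop = FALSE]
  if (!length(sel) || anyNA(TH)) {
    abort("Selection must consist of particles with orientation angles.")
  }
  nf <- ncol(TH)
  if (is.null(lags)) lags <- seq_len(nf %/% 2)
  dt_frame <- mean(diff(a$times))
  curve <- purrr::map_dfr(sort(unique(as.integer(lags))), function(L) {
    dtheta <- TH[, (1 + L):nf, drop = FALSE] - TH[, 1:(nf - L), drop = FALSE]
    tibble(lag = L * dt_frame, C = mean(cos(dtheta)))
  })
  fitpts <- filter(curve, .data$C >= c_min)
  est <- if (nrow(fitpts) < 2) {
    warn("Orientation correlation non-positive or too short in the fit range; Dr unidentifiable.")
    new_diffusion_estimate(NA_real_, NA_real_, window = c(NA, NA),
                           method = "rotational")
  } else {
    fit <- lm(log(C) ~ lag, data = fitpts)
    Dr <- -coef(fit)[["lag"]]
    se <- summary(fit)$coefficients["lag", "Std. Error"]
    new_diffusion_estimate(max(Dr, 0), se, window = range(fitpts$lag),
                           method = "rotational")
  }
  list(curve = curve, estimate = est)
}

.unit_factors <- c("nm2_us" = 1, "cm2_s" = 1e8,
                   "1e-8cm2_s" = 1, "1e-9cm2_s" = 0.1)

#' Convert diffusion-coefficient units
#'
#' Exact algebraic conversion between nm^2/us, cm^2/s and the scaled
#' 1e-8 / 1e-9 cm^2/s conventions (1e-9 cm^2/s = 0.1 nm^2/us).
#'
#' @param value Numeric value(s).
#' @param from,to One of `"nm2_us"`, `"cm2_s"`, `"1e-8cm2_s"`,
#'   `"1e-9cm2_s"`.
#' @return Converted value(s).
#' @examples
#' convert_units(0.48, "nm2_us", "1e-9cm2_s") # 4.8
#' @export
convert_units <- function(value, from, to) {
  if (!from %in% names(.unit_factors) || !to %in% names(.unit_factors)) {
    abort(paste0("Unknown unit; use one of: ",
                 paste(names(.unit_factors), collapse = ", ")))
  }
  value * .unit_factors[[from]] / .unit_factors[[to]]
}

#' Aggregate replica diffusion estimates
#'
#' Unweighted mean across replicas; the error is the SEM over replicas when
#' at least 3 are available, otherwise the propagated per-fit errors
#' (`sqrt(sum(se^2))/n`). All estimates must share the method tag.
#'
#' @param estimates A list of `diffusion_estimate` objects.
#' @return A `diffusion_estimate` with `n_replicates` set.
#' @export
replica_aggregate <- function(estimates) {
  if (inherits(estimates, "diffusion_estimate")) estimates <- list(estimates)
  if (!length(estimates)) abort("Need at least one estimate.")
  methods <- unique(vapply(estimates, `[[`, "", "method"))
  if (length(methods) > 1) abort("Estimates mix methods/units; refusing to aggregate.")
  Ds <- vapply(estimates, `[[`, numeric(1), "D")
  ses <- vapply(estimates, `[[`, numeric(1), "se")
  n <- length(Ds)
  err <- if (n >= 3) sd(Ds) / sqrt(n) else sqrt(sum(ses^2)) / n
  new_diffusion_estimate(mean(Ds), err, window = estimates[[1]]$window,
                         method = methods, n_replicates = n)
}
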