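#' BRET ratio in milli-BRET units
#'
#' The background-corrected fluorescence-over-luminescence ratio scaled by
#' 1000 (mBU): `1000 * (F - F_bg) / (L - L_bg)`.
#'
#' @param fluorescence,luminescence Acceptor fluorescence and donor
#'   luminescence readings (AU), vectorised.
#' @param f_background,l_background Background readings (default 0).
#' @return BRET ratio(s) in mBU.
#' @examples
#' bret_ratio(150, 1000) # 150 mBU
#' @export
bret_ratio <- function(fluorescence, luminescence,
                       f_background = 0, l_background = 0) {
  lum <- luminescence - l_background
  if (any(lum <= 0)) abort("Corrected luminescence must be > 0.")
  1000 * (fluorescence - f_background) / lum
}

#' Synthesize a BRET titration
#'
#' Generates seeded titration data for a donor-acceptor pair: in
#' `"specific"` mode the true curve is the saturation hyperbola
#' `BRETmax x / (BRET50 + x)`; in `"bystander"` mode it is the quasi-linear
#' ramp `slope x` typical of nonspecific transfer. Multiplicative Gaussian
#' noise of relative size `noise` is applied per well; each acceptor level
#' is measured in `replicates` wells (triplicates by default).
#'
#' @param bretmax Plateau in mBU (specific mode).
#' @param bret50 Acceptor level giving half the plateau (AU).
#' @param x_levels Acceptor expression levels (AU), at least 4 distinct.
#' @param noise Relative noise standard deviation (>= 0).
#' @param replicates Wells per level.
#' @param mode `"specific"` or `"bystander"`.
#' @param slope Bystander slope (mBU per AU), used in bystander mode.
#' @param condition,experiment Labels carried through to the output.
#' @param seed Integer seed; identical seeds give identical data.
#' @return A `bret_titration` tibble: `x`, `bret`, `replicate`, `mode`,
#'   `condition`, `experiment`.
#' @export
synthesize_titration <- function(bretmax = 100, bret50 = 0.5,
                                 x_levels = seq(0.25, 3.7, length.out = 8),
                                 noise = 0.05, replicates = 3,
                                 mode = c("specific", "bystander"),
                                 slope = 30, condition = "untreated",
                                 experiment = 1L, seed = 1L) {
  mode <- match.arg(mode)
  if (noise < 0) abort("`noise` must be >= 0.")
  set.seed(seed)
  x <- rep(x_levels, each = replicates)
  mu <- if (mode == "specific") bretmax * x / (bret50 + x) else slope * x
  y <- mu * (1 + noise * rnorm(length(x)))
  out <- tibble(x = x, bret = y,
                replicate = rep(seq_len(replicates), length(x_levels)),
                mode = mode, condition = condition,
                experiment = as.integer(experiment))
  class(out) <- c("bret_titration", class(out))
  out
}

#' Fit the BRET saturation hyperbola
#'
#' Nonlinear least squares of `BRET = BRETmax x / (BRET50 + x)` with
#' positivity enforced through multistart Levenberg-Marquardt fits from a
#' grid of starting values; parameter standard errors come from the fit
#' covariance. If no start converges the object falls back to the linear
#' (bystander) model with `converged = FALSE`.
#'
#' @param titration A data frame with columns `x` (acceptor level, AU) and
#'   `bret` (mBU); at least 4 distinct x levels.
#' @param weights Optional `"1/y"` weighting; default unweighted.
#' @return A `saturation_fit`: estimates, standard errors, residual
#'   variance, the chosen model and the data. Use [select_model()] to test
#'   hyperbolic against bystander transfer.
#' @export
fit_saturation <- function(titration, weights = c("none", "1/y")) {
  weights <- match.arg(weights)
  df <- as_tibble(titration)[, c("x", "bret")]
  df <- df[complete.cases(df), ]
  if (length(unique(df$x)) < 4) abort("Need at least 4 distinct acceptor levels.")
  w <- if (weights == "1/y") 1 / pmax(df$bret, 1e-8) else rep(1, nrow(df))
  ymax <- max(df$bret)
  starts <- tidyr::expand_grid(bretmax = ymax * c(1, 1.5, 3),
                               bret50 = unname(stats::quantile(df$x, c(0.15, 0.5, 0.9))))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(bret ~ bretmax * x / (bret50 + x), data = df,
                        start = as.list(starts[k, ]), weights = w,
                        lower = c(bretmax = 1e-9, bret50 = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(w * stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  lin <- lm(bret ~ x + 0, data = df, weights = w)
  if (is.null(best)) {
    warn("Hyperbolic fit did not converge; falling back to the linear model.")
    return(structure(list(model = "linear", converged = FALSE,
                          bretmax = NA_real_, bret50 = NA_real_,
                          se = c(bretmax = NA_real_, bret50 = NA_real_),
                          slope = coef(lin)[["x"]],
                          sigma2 = summary(lin)$sigma^2,
                          fit = lin, linear_fit = lin, data = df),
                     class = "saturation_fit"))
  }
  cf <- coef(best$fit)
  se <- tryCatch(summary(best$fit)$coefficients[, "Std. Error"],
                 error = function(e) c(bretmax = NA_real_, bret50 = NA_real_))
  structure(list(model = "hyperbolic", converged = TRUE,
                 bretmax = cf[["bretmax"]], bret50 = cf[["bret50"]],
                 se = c(bretmax = unname(se["bretmax"]),
                        bret50 = unname(se["bret50"])),
                 slope = coef(lin)[["x"]],
                 sigma2 = best$rss / stats::df.residual(best$fit),
                 fit = best$fit, linear_fit = lin, data = df),
            class = "saturation_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat("<saturation_fit> model:", x$model, "\n")
  if (x$model == "hyperbolic") {
    cat(sprintf("  BRETmax %.3f +/- %.3f mBU, BRET50 %.4f +/- %.4f AU\n",
                x$bretmax, x$se[["bretmax"]], x$bret50, x$se[["bret50"]]))
  } else {
    cat(sprintf("  slope %.3f mBU/AU\n", x$slope))
  }
  invisible(x)
}

#' @export
tidy.saturation_fit <- function(x, ...) {
  if (x$model == "hyperbolic") {
    tibble(term = c("bretmax", "bret50"),
           estimate = c(x$bretmax, x$bret50),
           std.error = c(x$se[["bretmax"]], x$se[["bret50"]]))
  } else {
    tibble(term = "slope", estimate = x$slope,
           std.error = summary(x$linear_fit)$coefficients["x", "Std. Error"])
  }
}

#' @export
glance.saturation_fit <- function(x, ...) {
  tibble(model = x$model, converged = x$converged, bretmax = x$bretmax,
         bret50 = x$bret50, sigma2 = x$sigma2,
         n = nrow(x$data), n_levels = length(unique(x$data$x)))
}

#' Choose between hyperbolic and bystander (linear) transfer
#'
#' Extra-sum-of-squares F test of the 2-parameter saturation hyperbola
#' against the 1-parameter proportional model through the origin, at
#' `alpha` (default 0.05). A significant F favours specific, saturable
#' transfer; otherwise the quasi-linear bystander model is retained.
#'
#' @param titration A data frame with `x` and `bret` columns.
#' @param alpha Test level.
#' @return A one-row tibble: `model` (`"hyperbolic"` or `"linear"`), `F`,
#'   `df1`, `df2`, `p_value`, plus both models' residual sums of squares.
#' @export
select_model <- function(titration, alpha = 0.05) {
  df <- as_tibble(titration)[, c("x", "bret")]
  if (length(unique(df$x)) <= 2) abort("Model selection needs more than 2 acceptor levels.")
  if (var(df$bret) == 0) {
    warn("Flat response: uninformative titration, linear model retained.")
    return(tibble(model = "linear", F = NA_real_, df1 = 1,
                  df2 = nrow(df) - 2, p_value = NA_real_,
                  rss_linear = 0, rss_hyperbolic = 0, flat = TRUE))
  }
  fit <- fit_saturation(df)
  rss_lin <- sum(stats::resid(fit$linear_fit)^2)
  rss_hyp <- if (fit$model == "hyperbolic") sum(stats::resid(fit$fit)^2) else rss_lin
  df2 <- nrow(df) - 2
  Fstat <- ((rss_lin - rss_hyp) / 1) / (rss_hyp / df2)
  # guard against numerically negative improvements
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  model <- if (fit$model == "hyperbolic" && p < alpha) "hyperbolic" else "linear"
  tibble(model = model, F = Fstat, df1 = 1, df2 = df2, p_value = p,
         rss_linear = rss_lin, rss_hyperbolic = rss_hyp, flat = FALSE)
}

#' Paired comparison of saturation parameters across conditions
#'
#' Paired two-sided t test on a fitted parameter (BRETmax or BRET50) across
#' matched independent experiments, e.g. DHA-treated versus untreated cells
#' titrated on the same days.
#'
#' @param fits_a,fits_b Equal-length lists of `saturation_fit` objects (or
#'   numeric vectors of the parameter), paired by experiment.
#' @param parameter `"bretmax"` or `"bret50"`.
#' @param conf_level Confidence level for the mean-difference CI.
#' @return A one-row tibble: mean paired difference with CI, `t`, `df`,
#'   `p_value`, `n`.
#' @export
compare_conditions <- function(fits_a, fits_b,
                               parameter = c("bretmax", "bret50"),
                               conf_level = 0.95) {
  parameter <- match.arg(parameter)
  getp <- function(l) {
    if (is.numeric(l)) return(l)
    vapply(l, function(f) f[[parameter]], numeric(1))
  }
  va <- getp(fits_a); vb <- getp(fits_b)
  if (length(va) != length(vb)) abort("Conditions must be paired: equal lengths required.")
  if (length(va) < 2) abort("Paired test needs at least 2 experiments.")
  d <- va - vb
  if (sd(d) == 0) {
    return(tibble(parameter = parameter, mean_difference = mean(d),
                  conf_low = mean(d), conf_high = mean(d),
                  t = if (all(d == 0)) 0 else NA_real_,
                  df = length(d) - 1,
                  p_value = if (all(d == 0)) 1 else NA_real_,
                  n = length(d)))
  }
  tt <- t.test(va, vb, paired = TRUE, conf.level = conf_level)
  tibble(parameter = parameter, mean_difference = unname(tt$estimate),
         conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, n = length(d))
}
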