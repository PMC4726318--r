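#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   labs theme_minimal stat_function geom_errorbar
NULL

#' Plot an MSD curve
#'
#' @param object An `msd_curve`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.msd_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$lag, y = .data$msd)) +
    geom_line() +
    geom_point(size = 0.8) +
    labs(x = "lag (μs)", y = expression(MSD ~ (nm^2))) +
    theme_minimal()
}

#' Plot a radial distribution function
#'
#' @param object An `rdf_curve`.
#' @param ... Ignored.
#' @return A ggplot with the ideal-mixing reference g = 1.
#' @export
autoplot.rdf_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$r, y = .data$g)) +
    geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    geom_line() +
    labs(x = "r (nm)", y = "g(r)",
         title = paste0("RDF of ", paste(attr(object, "target"), collapse = "+"),
                        " around ", paste(attr(object, "reference"), collapse = "+"))) +
    theme_minimal()
}

#' Plot per-receptor contact counts over time
#'
#' Mean contacts per protomer against time, one line per replicate, the
#' analysis window mean as a horizontal dashed line.
#'
#' @param object A `contact_series`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.contact_series <- function(object, ...) {
  per_frame <- object$counts %>%
    group_by(.data$replicate, .data$time) %>%
    summarise(mean_contacts = mean(.data$n_contacts), .groups = "drop")
  ggplot(per_frame, aes(x = .data$time, y = .data$mean_contacts,
                        group = .data$replicate)) +
    geom_line(alpha = 0.7) +
    geom_hline(yintercept = object$summary$mean_contacts,
               linetype = "dashed") +
    labs(x = "time (μs)", y = "contacts per protomer") +
    theme_minimal()
}

#' Plot a BRET saturation fit
#'
#' Titration points with the fitted hyperbola (or bystander line).
#'
#' @param object A `saturation_fit`.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.saturation_fit <- function(object, ...) {
  df <- object$data
  grid <- tibble(x = seq(0, max(df$x), length.out = 200))
  grid$y <- if (object$model == "hyperbolic") {
    object$bretmax * grid$x / (object$bret50 + grid$x)
  } else {
    object$slope * grid$x
  }
  ggplot(df, aes(x = .data$x, y = .data$bret)) +
    geom_point() +
    geom_line(data = grid, aes(x = .data$x, y = .data$y), colour = "steelblue") +
    labs(x = "acceptor level (AU)", y = "BRET (mBU)") +
    theme_minimal()
}

#' Plot the saturated-unsaturated mixing fraction over time
#'
#' @param mixing Output of [mixing_contact_fraction()], optionally with a
#'   `condition` column.
#' @return A ggplot with the random-mixing expectation dashed.
#' @export
plot_mixing_fraction <- function(mixing) {
  p <- ggplot(mixing, aes(x = .data$time, y = .data$f_ab))
  if ("condition" %in% names(mixing)) {
    p <- p + geom_line(aes(colour = .data$condition))
  } else {
    p <- p + geom_line()
  }
  p + geom_hline(aes(yintercept = .data$random_expectation),
                 linetype = "dashed", colour = "grey40") +
    labs(x = "time (μs)", y = "saturated-unsaturated contact fraction") +
    theme_minimal()
}
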