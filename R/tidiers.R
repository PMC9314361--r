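#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the coefficients of a rational approximant
#' @param x A `"rational_psd"`.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate`.
#' @export
tidy.rational_psd <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("kappa_", seq_along(x$kappa) - 1L),
             paste0("beta_", seq_along(x$den) - 1L)),
    estimate = c(x$kappa, x$den))
}

#' @export
tidy.psd_rational <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("num_u", seq_along(x$num_u) - 1L),
             paste0("den_u", seq_along(x$den_u) - 1L)),
    estimate = c(x$num_u, x$den_u))
}

#' One-row summary of a rational approximant
#' @param x A `"rational_psd"`.
#' @param ... Unused.
#' @export
glance.rational_psd <- function(x, ...) {
  tibble::tibble(p = x$p, q = x$q, stable = x$stable,
                 peak_frequency = peak_frequency(x),
                 psd_zero = psd_eval(x, 0))
}

#' One-row summary of a fitted spectral pipeline
#' @param x A `"pade_psd_fit"`.
#' @param ... Unused.
#' @export
glance.pade_psd_fit <- function(x, ...) {
  g <- glance.rational_psd(x$rational)
  g$variance <- x$derivatives$variance
  g$mean <- x$derivatives$mean
  g$validated <- if (is.null(x$validation)) NA else
    isTRUE(attr(x$validation, "pass"))
  g
}

#' @export
tidy.pade_psd_fit <- function(x, ...) tidy.rational_psd(x$rational)

psd_curve_tbl <- function(x, omega) {
  tibble::tibble(omega = omega, psd = as_psd_function(x)(omega))
}

#' Plot a PSD object
#'
#' @param object A `"rational_psd"`, `"psd_rational"`, `"pade_psd_fit"` or
#'   `"linear_network"`.
#' @param omega_max,n Frequency grid.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rational_psd <- function(object, omega_max = 5, n = 400, ...) {
  dat <- psd_curve_tbl(object, seq(0, omega_max, length.out = n))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$omega, y = .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(omega ~ "(rad/time)"),
                  y = expression(S(omega)))
}

#' @export
autoplot.psd_rational <- autoplot.rational_psd

#' @export
autoplot.linear_network <- function(object, omega_max = 5, n = 400, ...) {
  autoplot.rational_psd(psd_rational_exact(object), omega_max = omega_max,
                        n = n, ...)
}

#' @export
autoplot.pade_psd_fit <- function(object, omega_max = 5, n = 400, ...) {
  autoplot.rational_psd(object$rational, omega_max = omega_max, n = n, ...)
}

#' @export
autoplot.ctmc_trajectory <- function(object, species = NULL, ...) {
  d <- object$network$d
  if (is.null(species)) species <- object$network$species
  df <- as.data.frame(object)
  long <- do.call(rbind, lapply(species, function(s)
    data.frame(time = df$time, copy_number = df[[s]], species = s)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$copy_number,
                                     colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time", y = "copy number")
}

#' Plot an ensemble periodogram with its one-standard-deviation band
#'
#' @param psd_tbl Tibble from [ensemble_psd()].
#' @param overlay Optional PSD object drawn on top (e.g. the analytic or
#'   rational spectrum).
#' @export
plot_ensemble_psd <- function(psd_tbl, overlay = NULL) {
  p <- ggplot2::ggplot(psd_tbl, ggplot2::aes(x = .data$omega)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$mean_psd - .data$sd_psd, 0),
      ymax = .data$mean_psd + .data$sd_psd), fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_psd)) +
    ggplot2::labs(x = expression(omega ~ "(rad/time)"),
                  y = expression(S(omega)))
  if (!is.null(overlay)) {
    dat <- psd_curve_tbl(overlay, psd_tbl$omega[psd_tbl$omega > 0])
    p <- p + ggplot2::geom_line(data = dat,
                                ggplot2::aes(y = .data$psd),
                                colour = "red", linetype = 2)
  }
  p
}

#' @importFrom rlang .data
NULL
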