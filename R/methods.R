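# broom-style accessors and ggplot2 autoplot methods.

#' Tidy a fitted detection model
#'
#' One row per estimated parameter, on the natural scale: the key scale
#' `sigma` (m), the hazard-rate shape `b`, MCDS scale coefficients
#' (`beta*`, log scale) and adjustment coefficients (`a*`). Standard
#' errors come from the inverse observed information at the optimum,
#' delta-transformed for `sigma` and `b`.
#'
#' @param x A `detection_model` from [fit_detection()].
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error` (and `stratum`
#'   for CDS models).
#' @method tidy detection_model
#' @export
tidy.detection_model <- function(x, ...) {
  if (identical(x$stratification, "CDS")) {
    return(purrr::imap(x$submodels, function(m, lev) {
      dplyr::mutate(tidy(m), stratum = lev, .before = 1)
    }) |> purrr::list_rbind())
  }
  if (x$npar == 0) {
    return(tibble::tibble(term = character(), estimate = double(),
                          std.error = double()))
  }
  se_t <- sqrt(pmax(diag(x$vcov_t), 0))
  terms <- names(x$tpar)
  est <- x$tpar
  se <- se_t
  # natural scale for the log-parameterized key parameters
  for (i in seq_along(terms)) {
    if (terms[i] == "lsigma") {
      est[i] <- exp(x$tpar[i]); se[i] <- est[i] * se_t[i]
      terms[i] <- "sigma"
    } else if (terms[i] == "lbm1") {
      est[i] <- 1 + exp(x$tpar[i]); se[i] <- exp(x$tpar[i]) * se_t[i]
      terms[i] <- "b"
    }
  }
  tibble::tibble(term = terms, estimate = unname(est),
                 std.error = unname(se))
}

#' Model-level summary of a fitted detection model
#'
#' @param x A `detection_model`.
#' @param ... Unused.
#' @return A one-row tibble: key, adjustment, stratification, parameter
#'   count, log-likelihood, AIC, AICc, number of observations and
#'   truncation distance.
#' @method glance detection_model
#' @export
glance.detection_model <- function(x, ...) {
  tibble::tibble(
    key = x$key, adjustment = x$adjustment,
    stratification = x$stratification,
    npar = x$npar, logLik = x$logLik, AIC = x$AIC, AICc = x$AICc,
    n = x$n, w = x$w
  )
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf("Detection model: %s key, %s adjustment (%s)\n",
              x$key, x$adjustment, x$stratification))
  cat(sprintf("  n = %d, w = %.1f m, npar = %d, AIC = %.2f\n",
              x$n, x$w, x$npar, x$AIC))
  if (identical(x$stratification, "CDS")) {
    for (lev in names(x$submodels)) {
      m <- x$submodels[[lev]]
      cat(sprintf("  stratum %s: n = %d, ESW = %.2f m\n", lev, m$n, esw(m)))
    }
  } else if (!identical(x$stratification, "MCDS")) {
    cat(sprintf("  ESW = %.2f m\n", esw(x)))
  }
  invisible(x)
}

#' Plot a fitted detection function over the distance histogram
#'
#' @param object A `detection_model`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot detection_model
#' @export
autoplot.detection_model <- function(object, bins = 12, ...) {
  if (identical(object$stratification, "CDS")) {
    dat <- purrr::imap(object$submodels, function(m, lev) {
      tibble::tibble(stratum = lev, distance_m = m$distances)
    }) |> purrr::list_rbind()
    curve <- purrr::imap(object$submodels, function(m, lev) {
      grid <- seq(0, object$w, length.out = 200)
      mu <- esw(m)
      tibble::tibble(stratum = lev, distance_m = grid,
                     density = detection_g(m, grid) / mu)
    }) |> purrr::list_rbind()
    return(
      ggplot2::ggplot(dat, ggplot2::aes(.data$distance_m)) +
        ggplot2::geom_histogram(
          ggplot2::aes(y = ggplot2::after_stat(.data$density)),
          bins = bins, boundary = 0, fill = "grey80", colour = "grey40") +
        ggplot2::geom_line(data = curve,
                           ggplot2::aes(y = .data$density),
                           colour = "#2166ac", linewidth = 0.8) +
        ggplot2::facet_wrap(~stratum) +
        ggplot2::labs(x = "perpendicular distance (m)", y = "density")
    )
  }
  grid <- seq(0, object$w, length.out = 200)
  g <- if (identical(object$stratification, "MCDS")) {
    ref <- lapply(object$xlevels, `[`, 1)
    detection_g(object, grid, covariates = ref)
  } else {
    detection_g(object, grid)
  }
  mu <- sum(g) * (grid[2] - grid[1])
  ggplot2::ggplot(tibble::tibble(distance_m = object$distances),
                  ggplot2::aes(.data$distance_m)) +
    ggplot2::geom_histogram(
      ggplot2::aes(y = ggplot2::after_stat(.data$density)),
      bins = bins, boundary = 0, fill = "grey80", colour = "grey40") +
    ggplot2::geom_line(
      data = tibble::tibble(distance_m = grid, density = g / mu),
      ggplot2::aes(y = .data$density), colour = "#2166ac",
      linewidth = 0.8) +
    ggplot2::labs(x = "perpendicular distance (m)", y = "density",
                  title = sprintf("%s key, %s adjustment",
                                  object$key, object$adjustment))
}

#' Plot per-site composite densities
#'
#' Adult and total densities per site, ordered by increasing adult
#' density, with error bars of one cluster-density SD where available.
#'
#' @param object A `site_density` table from [estimate_density()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot site_density
#' @export
autoplot.site_density <- function(object, ...) {
  ord <- object$site[order(object$d_ad)]
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("site", "d_ad", "d_bad")],
    c("d_ad", "d_bad"), names_to = "metric", values_to = "density")
  long$site <- factor(long$site, levels = ord)
  long$metric <- dplyr::recode(long$metric,
                               d_ad = "adults", d_bad = "adults + cubs")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$site, .data$density,
                                          shape = .data$metric,
                                          colour = .data$metric))
  if (all(c("d_ad_sd", "d_bad_sd") %in% names(object))) {
    err <- tidyr::pivot_longer(
      tibble::as_tibble(object)[c("site", "d_ad_sd", "d_bad_sd")],
      -"site", names_to = "metric", values_to = "sd")
    err$metric <- dplyr::recode(err$metric,
                                d_ad_sd = "adults",
                                d_bad_sd = "adults + cubs")
    long <- dplyr::left_join(long, err, by = c("site", "metric"))
    p <- ggplot2::ggplot(long, ggplot2::aes(.data$site, .data$density,
                                            shape = .data$metric,
                                            colour = .data$metric)) +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = pmax(0, .data$density - .data$sd),
                     ymax = .data$density + .data$sd),
        width = 0.25, position = ggplot2::position_dodge(0.4))
  }
  p +
    ggplot2::geom_point(size = 2.4,
                        position = ggplot2::position_dodge(0.4)) +
    ggplot2::scale_colour_manual(values = c("black", "grey55")) +
    ggplot2::labs(x = "study site", y = "density (ind. / km²)",
                  colour = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
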