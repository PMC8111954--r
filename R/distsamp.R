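# Line-transect distance sampling: detection functions, model selection,
# effective strip width, stratified densities, bootstrap uncertainty.
#
# Detection function g(x), perpendicular distance x in metres on [0, w]:
#   uniform      g(x) = 1
#   half_normal  g(x) = exp(-x^2 / (2 sigma^2))
#   hazard_rate  g(x) = 1 - exp(-(x / sigma)^-b),  b > 1
# optionally times a normalized series adjustment (cosine, simple
# polynomial, Hermite) so that g(0) = 1 always.

#' Right-truncate perpendicular distance data
#'
#' Distance sampling discards the sparse right tail of the detection
#' distances before fitting. Either a fixed truncation distance `w` is kept
#' (`mode = "fixed"`), or the largest `value` fraction of the observations
#' is removed and `w` set to the largest retained distance
#' (`mode = "percent"`).
#'
#' @param data A data frame of observations with a `distance_m` column
#'   (covariate columns are carried along), or a bare numeric vector of
#'   distances.
#' @param mode `"fixed"` (keep `distance_m <= value`) or `"percent"`
#'   (drop the `floor(value * n)` largest distances).
#' @param value Truncation distance in metres, or the fraction in (0, 1)
#'   to remove.
#' @return A tibble of the retained observations with attributes `w`
#'   (truncation distance, metres) and `removed_fraction`.
#' @export
#' @examples
#' d <- truncate_distances(runif(200, 0, 100), mode = "percent", value = 0.1)
#' attr(d, "w"); attr(d, "removed_fraction")
truncate_distances <- function(data, mode = c("fixed", "percent"), value) {
  mode <- match.arg(mode)
  if (is.numeric(data)) data <- tibble::tibble(distance_m = data)
  stopifnot("distance_m" %in% names(data))
  x <- data$distance_m
  if (any(!is.finite(x)) || any(x < 0)) {
    abort("distances must be finite and nonnegative.")
  }
  if (!is.numeric(value) || length(value) != 1 || value <= 0) {
    abort("`value` must be a single positive number.")
  }
  n <- length(x)
  if (mode == "fixed") {
    keep <- x <= value
    w <- value
  } else {
    if (value >= 1) abort("percent truncation requires `value` < 1.")
    k <- floor(value * n + 1e-9)
    keep <- rank(x, ties.method = "first") <= n - k
    w <- max(x[keep])
  }
  out <- tibble::as_tibble(data[keep, , drop = FALSE])
  attr(out, "w") <- w
  attr(out, "removed_fraction") <- 1 - sum(keep) / n
  out
}

## ---- key and adjustment primitives -------------------------------------

key_value <- function(key, x, sigma = NULL, b = NULL) {
  switch(key,
    uniform = rep(1, length(x)),
    half_normal = exp(-x^2 / (2 * sigma^2)),
    hazard_rate = 1 - exp(-(x / sigma)^(-b)),
    abort(paste0("unknown key function: ", key))
  )
}

# probabilists' Hermite polynomials of even order used as adjustments
hermite_poly <- function(order, z) {
  switch(as.character(order),
    "4" = z^4 - 6 * z^2 + 3,
    "6" = z^6 - 15 * z^4 + 45 * z^2 - 15,
    "8" = z^8 - 28 * z^6 + 210 * z^4 - 420 * z^2 + 105,
    abort("Hermite adjustments implemented for orders 4, 6, 8.")
  )
}

adjustment_terms <- function(adjustment, orders, x, w, sigma) {
  if (adjustment == "none" || length(orders) == 0) {
    return(matrix(0, nrow = length(x), ncol = 0))
  }
  vapply(orders, function(j) {
    switch(adjustment,
      cosine = cos(j * pi * x / w),
      poly = (x / w)^(2 * j),
      hermite = hermite_poly(2 * j, x / sigma),
      abort(paste0("unknown adjustment series: ", adjustment))
    )
  }, numeric(length(x)))
}

# first adjustment order by convention: cosine order 1 for the uniform key
# (whose shape is flat) and 2 for peaked keys; polynomial/Hermite from 2.
first_adj_order <- function(key, adjustment) {
  if (adjustment == "cosine" && key == "uniform") 1L else 2L
}

# g(x) normalized to g(0) = 1; a = adjustment coefficients
detection_shape <- function(x, key, sigma, b, adjustment, orders, a, w) {
  k <- key_value(key, x, sigma, b)
  if (length(a) == 0) return(k)
  h <- adjustment_terms(adjustment, orders, x, w, sigma)
  h0 <- adjustment_terms(adjustment, orders, 0, w, sigma)
  num <- k * (1 + as.vector(h %*% a))
  num / as.vector(1 + h0 %*% a)
}

## ---- likelihood ---------------------------------------------------------

par_skeleton <- function(key, n_adj, n_beta = 0) {
  nm <- character(0)
  if (key %in% c("half_normal", "hazard_rate")) {
    nm <- if (n_beta > 0) paste0("beta", seq_len(n_beta) - 1) else "lsigma"
  }
  if (key == "hazard_rate") nm <- c(nm, "lbm1")
  if (n_adj > 0) nm <- c(nm, paste0("a", seq_len(n_adj)))
  nm
}

unpack_par <- function(tpar, key, n_adj, X = NULL) {
  i <- 0
  sigma <- NULL
  if (key %in% c("half_normal", "hazard_rate")) {
    if (is.null(X)) {
      sigma <- exp(tpar[i + 1]); i <- i + 1
    } else {
      nb <- ncol(X)
      sigma <- exp(as.vector(X %*% tpar[i + seq_len(nb)])); i <- i + nb
    }
  }
  b <- NULL
  if (key == "hazard_rate") { b <- 1 + exp(tpar[i + 1]); i <- i + 1 }
  a <- if (n_adj > 0) tpar[i + seq_len(n_adj)] else numeric(0)
  list(sigma = sigma, b = b, a = a)
}

# effective strip width integral for one sigma value
esw_integral <- function(key, sigma, b, adjustment, orders, a, w) {
  if (key == "uniform" && length(a) == 0) return(w)
  if (key == "half_normal" && length(a) == 0) {
    return(sigma * sqrt(2 * pi) * (pnorm(w / sigma) - 0.5))
  }
  val <- tryCatch(
    integrate(function(u) {
      detection_shape(u, key, sigma, b, adjustment, orders, a, w)
    }, 0, w, abs.tol = 1e-6, rel.tol = 1e-8, subdivisions = 400L)$value,
    error = function(e) NA_real_
  )
  val
}

neg_loglik <- function(tpar, x, w, key, adjustment, orders, X = NULL) {
  n_adj <- length(orders)
  p <- unpack_par(tpar, key, n_adj, X)
  big <- 1e10
  if (key == "hazard_rate" && (!is.finite(p$b) || p$b <= 1)) return(big)
  if (!is.null(p$sigma) && any(!is.finite(p$sigma) | p$sigma <= 0)) return(big)
  if (is.null(X) || length(unique(p$sigma)) <= 1) {
    sig <- if (is.null(p$sigma)) NULL else p$sigma[1]
    g <- detection_shape(x, key, sig, p$b, adjustment, orders, p$a, w)
    if (any(!is.finite(g) | g <= 0)) return(big)
    mu <- esw_integral(key, sig, p$b, adjustment, orders, p$a, w)
    if (!is.finite(mu) || mu <= 0) return(big)
    return(-(sum(log(g)) - length(x) * log(mu)))
  }
  # covariate-scaled sigma: per-observation mu via unique sigma values
  us <- unique(p$sigma)
  mus <- vapply(us, function(s) {
    esw_integral(key, s, p$b, adjustment, orders, p$a, w)
  }, 0)
  if (any(!is.finite(mus) | mus <= 0)) return(big)
  mu_i <- mus[match(p$sigma, us)]
  g <- vapply(seq_along(x), function(i) {
    detection_shape(x[i], key, p$sigma[i], p$b, adjustment, orders, p$a, w)
  }, 0)
  if (any(!is.finite(g) | g <= 0)) return(big)
  -(sum(log(g)) - sum(log(mu_i)))
}

fit_start_values <- function(x, w, key, X = NULL) {
  s0 <- max(sd(x), w / 20)
  starts <- list()
  mk <- function(lsig_mult, lb) {
    p <- numeric(0)
    if (key %in% c("half_normal", "hazard_rate")) {
      if (is.null(X)) {
        p <- log(s0 * lsig_mult)
      } else {
        p <- c(log(s0 * lsig_mult), rep(0, ncol(X) - 1))
      }
    }
    if (key == "hazard_rate") p <- c(p, lb)
    p
  }
  if (key == "uniform") return(list(numeric(0)))
  for (m in c(0.5, 1, 2)) {
    if (key == "half_normal") starts <- c(starts, list(mk(m, NULL)))
    else starts <- c(starts, list(mk(m, log(1)), mk(m, log(2.5))))
  }
  starts
}

fit_core <- function(x, w, key, adjustment, orders, X = NULL,
                     init = NULL, restarts = 5) {
  nll <- function(p) neg_loglik(p, x, w, key, adjustment, orders, X)
  n_free <- length(par_skeleton(key, length(orders),
                                if (is.null(X)) 0 else ncol(X)))
  if (n_free == 0) {
    return(list(par = numeric(0), value = nll(numeric(0)),
                convergence = 0L, hessian = matrix(0, 0, 0)))
  }
  starts <- fit_start_values(x, w, key, X)
  starts <- purrr::map(starts, function(s) c(s, rep(0, length(orders))))
  if (!is.null(init)) starts <- c(list(init), starts)
  starts <- head(starts, restarts + 1)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      if (length(s) == 1) {
        optim(s, nll, method = "Brent", lower = s - 8, upper = s + 8)
      } else {
        optim(s, nll, method = "Nelder-Mead",
              control = list(maxit = 2000, reltol = 1e-10))
      },
      error = function(e) NULL
    )
    if (!is.null(fit) && is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best) || best$value >= 1e9) {
    abort("detection function fit failed to converge after restarts.")
  }
  best$hessian <- tryCatch(
    optimHess(best$par, nll),
    error = function(e) matrix(NA_real_, length(best$par), length(best$par))
  )
  best
}

# TRUE if g is weakly decreasing on [0, w] (tolerance 1e-6 on a fine grid)
is_monotone_shape <- function(key, sigma, b, adjustment, orders, a, w) {
  grid <- seq(0, w, length.out = 1000)
  g <- detection_shape(grid, key, sigma, b, adjustment, orders, a, w)
  if (any(!is.finite(g)) || any(g < -1e-9)) return(FALSE)
  all(diff(g) <= 1e-6)
}

## ---- user-facing fit ----------------------------------------------------

#' Fit a line-transect detection function
#'
#' Maximizes the standard conditional line-transect likelihood
#' \eqn{\prod_i g(x_i) / \int_0^w g(u)\,du} over the key parameters
#' (half-normal scale \eqn{\sigma}; hazard-rate scale \eqn{\sigma} and
#' shape \eqn{b > 1}) and any series-adjustment coefficients. Adjustment
#' terms are added one order at a time and kept only while the AIC improves
#' and the fitted shape stays weakly monotone decreasing (checked on a
#' 1000-point grid, tolerance 1e-6).
#'
#' Stratification options mirror conventional and multiple-covariate
#' distance sampling:
#' \describe{
#'   \item{pooled}{one detection function for all observations (default).}
#'   \item{CDS post-stratification (`strata =` column name)}{an
#'     independent detection function per covariate level; the model's
#'     log-likelihood, parameter count and AIC are the sums over strata.}
#'   \item{MCDS (`scale_covariates =` column names)}{one key whose scale is
#'     log-linear in the covariates, \eqn{\sigma = \exp(X\beta)}, with
#'     treatment coding and the lexicographically first level as
#'     reference.}
#' }
#'
#' @param data Observations: a data frame with `distance_m` plus any
#'   covariate columns, typically from [truncate_distances()].
#' @param key `"uniform"`, `"half_normal"` or `"hazard_rate"`.
#' @param adjustment `"none"`, `"cosine"`, `"poly"` or `"hermite"`.
#' @param max_adj Maximum number of adjustment terms to try.
#' @param strata Optional column name for CDS post-stratification.
#' @param scale_covariates Optional character vector of covariate column
#'   names for an MCDS scale model (mutually exclusive with `strata`).
#' @param w Truncation distance in metres; defaults to the `w` attribute
#'   of `data`.
#' @param min_n Minimum observations required per fitted stratum.
#' @return An object of class `detection_model`; see [tidy.detection_model()],
#'   [glance.detection_model()], [esw()], [detection_g()].
#' @export
fit_detection <- function(data, key = c("hazard_rate", "half_normal", "uniform"),
                          adjustment = c("none", "cosine", "poly", "hermite"),
                          max_adj = 3, strata = NULL, scale_covariates = NULL,
                          w = attr(data, "w"), min_n = 10) {
  key <- match.arg(key)
  adjustment <- match.arg(adjustment)
  if (is.numeric(data)) data <- tibble::tibble(distance_m = data)
  stopifnot("distance_m" %in% names(data))
  if (is.null(w)) abort("truncation distance `w` is unknown; pass `w=`.")
  if (any(data$distance_m > w)) {
    abort("observations beyond the truncation distance w; truncate first.")
  }
  if (!is.null(strata) && !is.null(scale_covariates)) {
    abort("use either `strata` (CDS) or `scale_covariates` (MCDS), not both.")
  }
  if (key == "uniform" && !is.null(scale_covariates)) {
    abort("the uniform key has no scale parameter for covariates.")
  }

  if (!is.null(strata)) {
    stopifnot(strata %in% names(data))
    levels <- sort(unique(as.character(data[[strata]])))
    subs <- purrr::map(levels, function(lev) {
      sub <- data[data[[strata]] == lev, , drop = FALSE]
      fit_detection(sub, key, adjustment, max_adj, w = w, min_n = min_n)
    })
    names(subs) <- levels
    out <- structure(list(
      key = key, adjustment = adjustment,
      stratification = "CDS", strata_var = strata, submodels = subs,
      logLik = sum(purrr::map_dbl(subs, "logLik")),
      npar = sum(purrr::map_dbl(subs, "npar")),
      n = sum(purrr::map_dbl(subs, "n")), w = w
    ), class = "detection_model")
    out$AIC <- -2 * out$logLik + 2 * out$npar
    out$AICc <- out$AIC +
      2 * out$npar * (out$npar + 1) / max(out$n - out$npar - 1, 1)
    return(out)
  }

  x <- data$distance_m
  if (length(x) < min_n) {
    abort(sprintf("only %d observations (< min_n = %d).", length(x), min_n))
  }

  X <- NULL
  xlevels <- NULL
  if (!is.null(scale_covariates)) {
    stopifnot(all(scale_covariates %in% names(data)))
    mf <- data[scale_covariates]
    mf[] <- lapply(mf, function(v) factor(as.character(v)))
    xlevels <- lapply(mf, levels)
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(scale_covariates, collapse = "+"))),
      mf)
  }

  # base fit, then grow the adjustment series while AIC improves
  j0 <- first_adj_order(key, adjustment)
  orders <- integer(0)
  fit <- fit_core(x, w, key, adjustment, orders, X)
  n_try <- if (adjustment == "none") 0 else max_adj
  while (length(orders) < n_try) {
    cand_orders <- c(orders, j0 + length(orders))
    cand <- tryCatch(
      fit_core(x, w, key, adjustment, cand_orders, X,
               init = c(fit$par, 0)),
      error = function(e) NULL
    )
    if (is.null(cand)) break
    aic_old <- 2 * fit$value + 2 * length(fit$par)
    aic_new <- 2 * cand$value + 2 * length(cand$par)
    p <- unpack_par(cand$par, key, length(cand_orders), X)
    mono <- is_monotone_shape(key,
                              if (is.null(p$sigma)) NULL else p$sigma[1],
                              p$b, adjustment, cand_orders, p$a, w)
    if (aic_new < aic_old && mono) {
      orders <- cand_orders
      fit <- cand
    } else {
      break
    }
  }

  p <- unpack_par(fit$par, key, length(orders), X)
  npar <- length(fit$par)
  logLik <- -fit$value
  par_names <- par_skeleton(key, length(orders),
                            if (is.null(X)) 0 else ncol(X))
  tpar <- setNames(fit$par, par_names)
  vcov_t <- tryCatch(solve(fit$hessian),
                     error = function(e) {
                       matrix(NA_real_, npar, npar)
                     })
  out <- structure(list(
    key = key, adjustment = adjustment, adj_orders = orders,
    stratification = if (is.null(X)) "pooled" else "MCDS",
    scale_covariates = scale_covariates, xlevels = xlevels,
    tpar = tpar, vcov_t = vcov_t,
    sigma = p$sigma, b = p$b, adj_coef = p$a,
    X = X, distances = x,
    logLik = logLik, npar = npar, n = length(x), w = w
  ), class = "detection_model")
  out$AIC <- -2 * logLik + 2 * npar
  out$AICc <- out$AIC + 2 * npar * (npar + 1) / max(length(x) - npar - 1, 1)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a detection model from known parameters
#'
#' Builds an evaluable `detection_model` without fitting, for simulation
#' and for checking fitted models against known truth. [detection_g()]
#' and [esw()] work on the result; likelihood-based accessors do not.
#'
#' @param key `"uniform"`, `"half_normal"` or `"hazard_rate"`.
#' @param sigma Scale in metres (half-normal, hazard-rate).
#' @param b Hazard-rate shape, > 1.
#' @param w Truncation distance in metres.
#' @return A `detection_model`.
#' @export
#' @examples
#' esw(detection_model("half_normal", sigma = 20, w = 55))
detection_model <- function(key = c("hazard_rate", "half_normal", "uniform"),
                            sigma = NULL, b = NULL, w) {
  key <- match.arg(key)
  if (key != "uniform" && (is.null(sigma) || sigma <= 0)) {
    abort("`sigma` must be positive.")
  }
  if (key == "hazard_rate" && (is.null(b) || b <= 1)) {
    abort("hazard-rate shape `b` must exceed 1.")
  }
  structure(list(
    key = key, adjustment = "none", adj_orders = integer(0),
    adj_coef = numeric(0), stratification = "pooled",
    sigma = sigma, b = b, w = w,
    tpar = numeric(0), vcov_t = matrix(0, 0, 0),
    distances = numeric(0), logLik = NA_real_, npar = 0L, n = 0L,
    AIC = NA_real_, AICc = NA_real_
  ), class = "detection_model")
}

#' Evaluate a fitted detection function
#'
#' @param model A `detection_model` from [fit_detection()].
#' @param x Perpendicular distances in metres, all in `[0, w]`.
#' @param stratum For CDS-stratified models, the stratum level to evaluate.
#' @param covariates For MCDS models, a one-row data frame (or named list)
#'   of covariate values; omitted for pooled models.
#' @return Detection probabilities `g(x)` with `g(0) = 1`.
#' @export
detection_g <- function(model, x, stratum = NULL, covariates = NULL) {
  stopifnot(inherits(model, "detection_model"))
  if (any(x < 0 | x > model$w)) {
    abort("distances must lie within [0, w].")
  }
  if (identical(model$stratification, "CDS")) {
    if (is.null(stratum)) abort("stratified model: supply `stratum`.")
    return(detection_g(model$submodels[[as.character(stratum)]], x))
  }
  sigma <- model$sigma
  if (identical(model$stratification, "MCDS")) {
    if (is.null(covariates)) abort("MCDS model: supply `covariates`.")
    covariates <- as.data.frame(covariates)
    for (v in names(model$xlevels)) {
      covariates[[v]] <- factor(as.character(covariates[[v]]),
                                levels = model$xlevels[[v]])
    }
    Xn <- stats::model.matrix(
      stats::as.formula(paste("~", paste(model$scale_covariates,
                                         collapse = "+"))),
      covariates)
    sigma <- exp(as.vector(Xn %*% model$tpar[seq_len(ncol(Xn))]))[1]
  } else if (!is.null(sigma)) {
    sigma <- sigma[1]
  }
  detection_shape(x, model$key, sigma, model$b, model$adjustment,
                  model$adj_orders, model$adj_coef, model$w)
}

#' Effective strip width of a fitted detection function
#'
#' ESW = \eqn{\int_0^w g(x)\,dx}, the half-width of the strip that, under
#' perfect detection, would yield the same expected number of detections.
#' Computed by adaptive quadrature (absolute tolerance 1e-6 m); closed
#' forms are used for the unadjusted uniform and half-normal keys.
#'
#' @inheritParams detection_g
#' @return For pooled models a single value in metres; for stratified or
#'   MCDS models a tibble with one row per stratum / covariate level.
#' @export
esw <- function(model, stratum = NULL, covariates = NULL) {
  stopifnot(inherits(model, "detection_model"))
  if (identical(model$stratification, "CDS")) {
    if (!is.null(stratum)) {
      return(esw(model$submodels[[as.character(stratum)]]))
    }
    return(tibble::tibble(
      stratum = names(model$submodels),
      esw_m = unname(purrr::map_dbl(model$submodels, esw))
    ))
  }
  if (identical(model$stratification, "MCDS")) {
    if (is.null(covariates)) {
      grids <- expand.grid(model$xlevels, stringsAsFactors = FALSE)
      grids$esw_m <- purrr::map_dbl(seq_len(nrow(grids)), function(i) {
        esw(model, covariates = grids[i, , drop = FALSE])
      })
      return(tibble::as_tibble(grids))
    }
    g1 <- function(u) detection_g(model, u, covariates = covariates)
    return(integrate(g1, 0, model$w, abs.tol = 1e-6, rel.tol = 1e-8,
                     subdivisions = 400L)$value)
  }
  esw_integral(model$key, model$sigma, model$b, model$adjustment,
               model$adj_orders, model$adj_coef, model$w)
}

#' Select a detection model by AIC
#'
#' Returns the candidate with the smallest AIC. Candidates must have been
#' fitted on the same data and truncation. Ties go to the model with fewer
#' parameters, then to the simpler key (uniform, half-normal, hazard-rate).
#'
#' @param models A list of `detection_model` objects.
#' @return The selected `detection_model`.
#' @export
select_model <- function(models) {
  stopifnot(length(models) >= 1,
            all(purrr::map_lgl(models, inherits, "detection_model")))
  n <- purrr::map_dbl(models, "n")
  w <- purrr::map_dbl(models, "w")
  if (length(unique(n)) > 1 || length(unique(w)) > 1) {
    abort("candidate models were fitted on different data or truncation.")
  }
  key_rank <- match(purrr::map_chr(models, "key"),
                    c("uniform", "half_normal", "hazard_rate"))
  ord <- order(round(purrr::map_dbl(models, "AIC"), 10),
               purrr::map_dbl(models, "npar"), key_rank)
  models[[ord[1]]]
}

#' Chi-squared goodness of fit of a detection model
#'
#' Bins the observed distances into `n_bins` equal-width bins on `[0, w]`,
#' computes expected counts from the fitted detection function, and forms
#' the usual Pearson statistic with `df = n_bins - n_params - 1` (after
#' any merging). Adjacent bins are merged, with a warning, while any
#' expected count is below 1.
#'
#' @param model A pooled `detection_model` (for CDS models the statistic is
#'   the sum over strata, with summed df).
#' @param n_bins Number of equal-width bins; must exceed the parameter
#'   count by at least 2.
#' @return A tibble with `chi2`, `df` and `p_value`.
#' @export
gof_chi2 <- function(model, n_bins = 6) {
  stopifnot(inherits(model, "detection_model"))
  if (identical(model$stratification, "CDS")) {
    parts <- purrr::map(model$submodels, gof_chi2, n_bins = n_bins)
    chi2 <- sum(purrr::map_dbl(parts, "chi2"))
    df <- sum(purrr::map_dbl(parts, "df"))
    return(tibble::tibble(chi2 = chi2, df = df,
                          p_value = pchisq(chi2, df, lower.tail = FALSE)))
  }
  if (n_bins < model$npar + 2) {
    abort("n_bins must be at least n_params + 2.")
  }
  x <- model$distances
  breaks <- seq(0, model$w, length.out = n_bins + 1)
  obs <- as.vector(table(cut(x, breaks, include.lowest = TRUE)))
  mu <- esw(model)
  expd <- vapply(seq_len(n_bins), function(i) {
    integrate(function(u) detection_g(model, u), breaks[i], breaks[i + 1],
              abs.tol = 1e-8)$value / mu * length(x)
  }, 0)
  while (any(expd < 1) && length(expd) > 2) {
    warn("expected count < 1 in a bin: merging adjacent bins.")
    i <- which.min(expd)
    j <- if (i == length(expd)) i - 1 else i + 1
    lo <- min(i, j)
    expd[lo] <- expd[i] + expd[j]
    obs[lo] <- obs[i] + obs[j]
    expd <- expd[-max(i, j)]
    obs <- obs[-max(i, j)]
  }
  chi2 <- sum((obs - expd)^2 / expd)
  df <- length(obs) - model$npar - 1
  tibble::tibble(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Line-transect density estimate for one stratum
#'
#' \eqn{D = n / (2 \cdot \mathrm{ESW} \cdot L)} with ESW converted from
#' metres to kilometres: detections per unit of effectively surveyed area.
#'
#' @param n Number of detections (>= 0).
#' @param L_km Total transect length in kilometres (> 0).
#' @param esw_m Effective strip width in metres (> 0).
#' @return Density per square kilometre.
#' @export
#' @examples
#' stratum_density(20, 10, 20)  # 50 clusters / km2
stratum_density <- function(n, L_km, esw_m) {
  if (any(L_km <= 0)) abort("zero or negative transect effort.")
  if (any(esw_m <= 0)) abort("effective strip width must be positive.")
  if (any(n < 0)) abort("negative detection count.")
  n / (2 * (esw_m / 1000) * L_km)
}

#' Bootstrap the encounter-rate variance of a density estimate
#'
#' Nonparametric bootstrap resampling whole transects with replacement
#' within a site (resample size equal to the original number of
#' transects). The detection function -- hence the ESW -- is held fixed,
#' so the resampled variability is that of the encounter rate, the
#' dominant variance component of line-transect densities. Returns the
#' bootstrap coefficient of variation and the 2.5%/97.5% empirical
#' quantiles of the resampled densities.
#'
#' @param counts Integer vector of detections per transect.
#' @param lengths_km Transect lengths in kilometres, same order as
#'   `counts`.
#' @param esw_m Effective strip width in metres, treated as known.
#' @param B Number of bootstrap resamples (999 by convention).
#' @param seed Optional integer seed for reproducibility.
#' @param exhaustive If `TRUE`, enumerate all `n^n` equally likely
#'   resamples instead of sampling (only feasible for a handful of
#'   transects); the CV is then the exact SD of the bootstrap
#'   distribution.
#' @return A one-row tibble: `d_hat` (point estimate), `cv`, `ci_low`,
#'   `ci_high`, with the resampled densities in attribute `"boot"`. `cv`
#'   is `NA` (with a warning) when every replicate has zero detections.
#' @export
bootstrap_density <- function(counts, lengths_km, esw_m, B = 999,
                              seed = NULL, exhaustive = FALSE) {
  stopifnot(length(counts) == length(lengths_km))
  if (length(counts) < 2) abort("need >= 2 transects to bootstrap.")
  n_t <- length(counts)
  d_hat <- stratum_density(sum(counts), sum(lengths_km), esw_m)
  if (exhaustive) {
    if (n_t > 8) abort("exhaustive enumeration is limited to <= 8 transects.")
    idx_all <- as.matrix(expand.grid(rep(list(seq_len(n_t)), n_t)))
    boot <- apply(idx_all, 1, function(idx) {
      stratum_density(sum(counts[idx]), sum(lengths_km[idx]), esw_m)
    })
    if (all(boot == 0)) {
      warn("all resamples have zero detections; CV undefined.")
      cv <- NA_real_
    } else {
      cv <- sqrt(mean((boot - mean(boot))^2)) / d_hat
    }
    out <- tibble::tibble(
      d_hat = d_hat, cv = cv,
      ci_low = quantile(boot, 0.025, names = FALSE),
      ci_high = quantile(boot, 0.975, names = FALSE)
    )
    attr(out, "boot") <- boot
    return(out)
  }
  draw <- function() {
    idx <- sample.int(n_t, n_t, replace = TRUE)
    stratum_density(sum(counts[idx]), sum(lengths_km[idx]), esw_m)
  }
  boot <- withr::with_seed(
    seed %||% sample.int(.Machine$integer.max, 1),
    replicate(B, draw())
  )
  if (all(boot == 0) && d_hat == 0) {
    warn("all bootstrap replicates have zero detections; CV undefined.")
    cv <- NA_real_
  } else {
    cv <- sd(boot) / d_hat
  }
  out <- tibble::tibble(
    d_hat = d_hat, cv = cv,
    ci_low = quantile(boot, 0.025, names = FALSE),
    ci_high = quantile(boot, 0.975, names = FALSE)
  )
  attr(out, "boot") <- boot
  out
}

#' Correct a suitable-habitat density to the whole site
#'
#' Transects are placed only in suitable habitat (forest, forest edge,
#' hedgerow), so the distance-sampling density refers to suitable area.
#' Multiplying by the proportion of suitable habitat converts it to a
#' whole-site density; confidence-interval endpoints scale identically.
#'
#' @param d_c_distance Density (or vector of densities / CI endpoints) in
#'   suitable habitat, per km2.
#' @param suitable_fraction Proportion of the site that is suitable, in
#'   (0, 1].
#' @return Whole-site density, per km2.
#' @export
apply_suitable_fraction <- function(d_c_distance, suitable_fraction) {
  if (any(!is.finite(suitable_fraction)) ||
      any(suitable_fraction <= 0 | suitable_fraction > 1)) {
    abort("`suitable_fraction` must lie in (0, 1].")
  }
  d_c_distance * suitable_fraction
}
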