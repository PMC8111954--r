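# Spearman rank-correlation screen of density against its components,
# with Bonferroni control over the set of screened variables.

#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rho as the Pearson correlation of midranks (so ties
#' are handled by averaging ranks). For n <= 9 and untied data the
#' two-sided p-value is exact, obtained by enumerating all n! rank
#' permutations; otherwise the usual t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom is
#' used.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return A tibble with `rho`, `p_value`, `n` and `method` ("exact" or
#'   "t-approximation"). A constant vector yields `rho = NA` with a
#'   warning.
#' @export
#' @examples
#' spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    warn("constant vector: Spearman's rho is undefined.")
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          method = NA_character_))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  has_ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 9 && !has_ties) {
    # exact null distribution by enumeration of all n! permutations;
    # with untied ranks it does not depend on the observed vectors and
    # rho is a monotone function of sum(d^2)
    perms <- permutations_of(n)
    base <- matrix(seq_len(n), nrow(perms), n, byrow = TRUE)
    sum_d2 <- rowSums((perms - base)^2)
    rho_all <- 1 - 6 * sum_d2 / (n * (n^2 - 1))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(t_stat), df = n - 2, lower.tail = FALSE)
    p <- min(1, p)
    method <- "t-approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

# all permutations of 1..n as an n! x n matrix (n <= 9)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  smaller <- permutations_of(n - 1)
  out <- matrix(0L, nrow = n * nrow(smaller), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1) * nrow(smaller) + seq_len(nrow(smaller))
    out[rows, i] <- n
    out[rows, -i] <- smaller
  }
  out
}

#' Bonferroni adjustment for a fixed family of m tests
#'
#' Elementwise `min(1, p * m)`. With m screened variables the family-wise
#' alpha = 0.05 threshold corresponds to a per-test cutoff of `0.05 / m`.
#'
#' @param p_values Numeric vector of raw p-values.
#' @param m Number of tests in the family; must be at least
#'   `length(p_values)`.
#' @return Adjusted p-values.
#' @export
#' @examples
#' bonferroni_adjust(c(0.001, 0.5), m = 7)
bonferroni_adjust <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) {
    abort("`m` must be at least the number of p-values.")
  }
  pmin(1, p_values * m)
}

#' Correlation screen of a response against site-level covariates
#'
#' Runs [spearman_cor()] of `response` against each column in `vars` of a
#' wide per-site table and applies the Bonferroni adjustment over the
#' whole screen.
#'
#' @param data A data frame with one row per site.
#' @param response Name of the response column (e.g. `"d_ad"`).
#' @param vars Character vector of covariate column names.
#' @param alpha Family-wise error rate for the reported cutoff.
#' @return A tibble with one row per covariate: `variable`, `rho`,
#'   `p_value`, `p_adjusted`, `n`, `significant` and the per-test `cutoff`
#'   (`alpha / m`).
#' @export
correlation_screen <- function(data, response, vars, alpha = 0.05) {
  stopifnot(response %in% names(data), all(vars %in% names(data)))
  m <- length(vars)
  res <- purrr::map(vars, function(v) {
    dplyr::mutate(spearman_cor(data[[response]], data[[v]]), variable = v)
  }) |>
    purrr::list_rbind()
  dplyr::mutate(
    res,
    p_adjusted = bonferroni_adjust(.data$p_value, m),
    cutoff = alpha / m,
    significant = !is.na(.data$p_value) & .data$p_value < alpha / m
  ) |>
    dplyr::select("variable", "rho", "p_value", "p_adjusted", "n",
                  "method", "cutoff", "significant")
}
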