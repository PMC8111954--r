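#' Summary tables from a 13-site badger survey in France
#'
#' Site-level summaries of a national survey of European badger (*Meles
#' meles*) populations at 13 study sites (labelled A to M) surveyed by
#' walked line transects, camera traps and genetic hair traps. Sites fall
#' into two landscape classes: `forested` (at least 70% forest cover; sites
#' A, B, D and H) and `hedgerow` (all others). These tables are the inputs
#' of the package's worked example: sett-cluster counts per occupancy
#' category, distance-sampling cluster densities, and per-category social
#' group sizes.
#'
#' `badger_survey_sites()` returns one row per site:
#' \describe{
#'   \item{site}{site label, A--M.}
#'   \item{site_habitat}{landscape class of the whole site, `forested` or
#'     `hedgerow`.}
#'   \item{n_setts}{setts detected on the walked transects.}
#'   \item{n_clusters}{sett clusters formed at the 500 m grouping distance.}
#'   \item{n_SSC, n_MSC, n_MSCR}{occupied cluster counts by category:
#'     secondary-only (SSC), main without reproduction (MSC), main with
#'     reproduction (MSCR). Unoccupied clusters make up the remainder.}
#'   \item{d_c_distance}{cluster density in suitable habitat (clusters/km2)
#'     from distance sampling.}
#'   \item{d_c}{cluster density corrected by the proportion of suitable
#'     habitat in the site (clusters/km2).}
#'   \item{ci_low, ci_high}{95% bootstrap confidence interval of `d_c`
#'     (2.5% and 97.5% quantiles, 999 transect resamples).}
#'   \item{cv_percent}{bootstrap coefficient of variation of the density, %.}
#' }
#'
#' The published per-category proportions are the exact count fractions
#' `n_SSC / n_clusters` etc.; carry the counts, not rounded proportions,
#' into density composition (see [composite_density()]).
#'
#' @return A tibble with 13 rows.
#' @seealso [badger_group_sizes()], [estimate_density()]
#' @export
#' @examples
#' badger_survey_sites()
badger_survey_sites <- function() {
  tibble::tibble(
    site = LETTERS[1:13],
    site_habitat = ifelse(LETTERS[1:13] %in% c("A", "B", "D", "H"),
                          "forested", "hedgerow"),
    n_setts    = c(78L, 40L, 35L, 66L, 35L, 36L, 38L, 46L, 29L, 21L, 68L, 11L, 30L),
    n_clusters = c(24L, 23L, 21L, 29L, 18L, 22L, 18L, 26L, 15L, 16L, 34L, 11L, 16L),
    n_SSC      = c(3L, 3L, 2L, 15L, 1L, 7L, 4L, 10L, 1L, 1L, 7L, 1L, 2L),
    n_MSC      = c(3L, 6L, 3L, 5L, 7L, 5L, 3L, 7L, 7L, 4L, 14L, 9L, 9L),
    n_MSCR     = c(3L, 5L, 7L, 4L, 3L, 1L, 3L, 2L, 4L, 1L, 5L, 0L, 0L),
    d_c_distance = c(6.95, 6.62, 12.80, 6.21, 10.39, 11.30, 10.62, 7.80,
                     9.42, 8.80, 18.31, 6.70, 8.21),
    d_c        = c(5.39, 5.50, 3.55, 5.17, 3.17, 4.75, 2.29, 6.42,
                   2.62, 3.59, 3.79, 1.99, 4.11),
    ci_low     = c(3.08, 3.11, 2.19, 2.96, 1.84, 2.96, 1.28, 3.75,
                   1.30, 2.09, 1.95, 0.67, 2.26),
    ci_high    = c(8.64, 9.32, 5.24, 8.54, 4.85, 7.09, 3.52, 10.63,
                   4.36, 5.45, 6.04, 3.78, 6.49),
    cv_percent = c(27.01, 28.01, 21.71, 27.07, 24.44, 23.85, 25.08, 27.72,
                   29.44, 24.68, 28.80, 39.54, 25.98)
  )
}

#' @rdname badger_survey_sites
#'
#' @details
#' `badger_group_sizes()` returns the observed per-category group sizes in
#' long form, one row per site x occupied category: `ad` is the mean number
#' of adults per cluster (camera traps only) and `total` the mean social
#' group size, adults plus cubs (maximum of camera and genetic counts per
#' cluster). Cells that could not be estimated in the field are `NA`:
#' secondary clusters at sites E, I and L yielded no captures, and site M
#' had no cluster with reproduction. [impute_group_sizes()] fills them from
#' sites of the same landscape class.
#' @export
badger_group_sizes <- function() {
  wide <- tibble::tribble(
    ~site, ~ad_SSC, ~total_SSC, ~ad_MSC, ~total_MSC, ~ad_MSCR, ~total_MSCR,
    "A",   1.00,    1.00,       1.50,    2.25,       3.00,     5.43,
    "B",   1.00,    2.00,       1.75,    3.50,       2.29,     5.71,
    "C",   2.00,    3.50,       1.40,    1.60,       2.00,     4.30,
    "D",   1.60,    2.00,       2.25,    2.50,       2.20,     5.20,
    "E",   NA,      NA,         1.13,    1.13,       1.75,     4.50,
    "F",   1.33,    1.33,       1.25,    1.25,       2.00,     4.00,
    "G",   1.50,    2.00,       1.00,    1.00,       1.67,     2.67,
    "H",   1.00,    1.00,       1.00,    1.00,       1.50,     4.00,
    "I",   NA,      NA,         1.50,    1.50,       2.00,     5.17,
    "J",   1.00,    1.00,       1.25,    1.75,       1.40,     3.40,
    "K",   2.00,    2.00,       1.29,    1.29,       1.60,     3.40,
    "L",   NA,      NA,         1.00,    1.29,       2.00,     5.75,
    "M",   1.00,    1.00,       1.56,    2.11,       NA,       NA
  )
  long <- tidyr::pivot_longer(
    wide, -"site",
    names_to = c(".value", "category"),
    names_sep = "_"
  )
  dplyr::mutate(
    long,
    category = factor(.data$category, levels = OCCUPIED_CATEGORIES),
    ad_imputed = FALSE,
    total_imputed = FALSE
  ) |>
    dplyr::arrange(.data$site, .data$category)
}
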