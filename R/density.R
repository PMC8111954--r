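# Composite density estimation: cluster density x occupancy proportions
# x per-category group sizes.

#' Composite adult or total badger density
#'
#' The composite estimator for a group-living species:
#' \deqn{D = D_C \times (p_{SSC}\,s_{SSC} + p_{MSC}\,s_{MSC} +
#'       p_{MSCR}\,s_{MSCR})}
#' where \eqn{D_C} is the sett-cluster density (per km2), the \eqn{p}'s the
#' proportions of occupied clusters of each category among all clusters,
#' and the \eqn{s}'s the mean group sizes per category: adult counts for
#' the adult density, total counts (adults and cubs) for the total density.
#'
#' Proportions are best supplied as integer counts (`n_*` with
#' `n_clusters`), which are converted to exact fractions internally;
#' pre-rounded proportions introduce avoidable error in the product.
#'
#' @param d_c Sett-cluster density per km2 (suitable-habitat-corrected).
#' @param n_SSC,n_MSC,n_MSCR,n_clusters Integer cluster counts per
#'   category and in total. Alternatively pass proportions via `p_SSC`,
#'   `p_MSC`, `p_MSCR`.
#' @param size_SSC,size_MSC,size_MSCR Mean group size per category
#'   (adults, or adults plus cubs). A missing size is an error when the
#'   matching proportion is nonzero.
#' @param p_SSC,p_MSC,p_MSCR Proportions in `[0, 1]`; ignored when counts
#'   are given.
#' @return Density per km2 (vectorized over sites).
#' @export
#' @examples
#' # 16 clusters of which 1 SSC, 4 MSC, 1 MSCR; adult sizes 1, 1.25, 1.4
#' composite_density(3.59, n_SSC = 1, n_MSC = 4, n_MSCR = 1,
#'                   n_clusters = 16,
#'                   size_SSC = 1, size_MSC = 1.25, size_MSCR = 1.4)
composite_density <- function(d_c,
                              n_SSC = NULL, n_MSC = NULL, n_MSCR = NULL,
                              n_clusters = NULL,
                              size_SSC, size_MSC, size_MSCR,
                              p_SSC = NULL, p_MSC = NULL, p_MSCR = NULL) {
  if (!is.null(n_clusters)) {
    stopifnot(!is.null(n_SSC), !is.null(n_MSC), !is.null(n_MSCR))
    if (any(n_clusters <= 0)) abort("n_clusters must be positive.")
    p_SSC <- n_SSC / n_clusters
    p_MSC <- n_MSC / n_clusters
    p_MSCR <- n_MSCR / n_clusters
  }
  if (is.null(p_SSC) || is.null(p_MSC) || is.null(p_MSCR)) {
    abort("supply either cluster counts or proportions for every category.")
  }
  p <- cbind(p_SSC, p_MSC, p_MSCR)
  if (any(p < 0 | p > 1) || any(rowSums(p) > 1 + 1e-9)) {
    abort("proportions must lie in [0, 1] and sum to at most 1.")
  }
  s <- cbind(size_SSC, size_MSC, size_MSCR)
  if (any(!is.na(s) & s < 0)) abort("group sizes must be nonnegative.")
  needed <- p > 0 & is.na(s)
  if (any(needed)) {
    cat_names <- c("SSC", "MSC", "MSCR")[ceiling(which(needed) / nrow(p))]
    abort(paste0("missing group size for category with nonzero proportion: ",
                 paste(unique(cat_names), collapse = ", ")))
  }
  s[is.na(s)] <- 0
  d_c * rowSums(p * s)
}

#' Density of occupied main sett clusters
#'
#' \eqn{D_C \times (p_{MSC} + p_{MSCR})}: the density of clusters holding
#' an occupied main sett, a proxy for the density of resident social
#' (family) groups.
#'
#' @inheritParams composite_density
#' @return Density per km2.
#' @export
occupied_main_density <- function(d_c, n_MSC = NULL, n_MSCR = NULL,
                                  n_clusters = NULL,
                                  p_MSC = NULL, p_MSCR = NULL) {
  if (!is.null(n_clusters)) {
    if (any(n_clusters <= 0)) abort("n_clusters must be positive.")
    p_MSC <- n_MSC / n_clusters
    p_MSCR <- n_MSCR / n_clusters
  }
  if (is.null(p_MSC) || is.null(p_MSCR)) {
    abort("supply either counts or proportions for MSC and MSCR.")
  }
  p <- cbind(p_MSC, p_MSCR)
  if (any(p < 0 | p > 1) || any(rowSums(p) > 1 + 1e-9)) {
    abort("proportions must lie in [0, 1] and sum to at most 1.")
  }
  d_c * (p_MSC + p_MSCR)
}

#' Site-level composite densities from the three pipeline tables
#'
#' Joins per-site cluster densities, occupancy counts and per-category
#' group sizes, and computes the adult density `d_ad`, the total density
#' `d_bad` (adults and cubs) and the occupied-main-cluster density
#' `d_occupied_main` for every site. Uncertainty on `d_ad`/`d_bad` carries
#' over the relative uncertainty (CV) of the cluster density only;
#' proportions and group sizes are treated as fixed.
#'
#' @param sites A data frame with one row per site: `site`, `d_c`, counts
#'   `n_SSC`, `n_MSC`, `n_MSCR`, `n_clusters`, and optionally `cv_percent`
#'   (CV of `d_c`, in %), e.g. [badger_survey_sites()] or the output of the
#'   distance-sampling stage.
#' @param group_sizes A completed long group-size table from
#'   [impute_group_sizes()] (`site`, `category`, `ad`, `total`).
#' @return A tibble with one row per site: inputs plus `d_ad`, `d_bad`,
#'   `d_occupied_main`, and when `cv_percent` is present `d_ad_sd`,
#'   `d_bad_sd`. Classed `site_density` for [autoplot()].
#' @export
#' @examples
#' gs <- impute_group_sizes(badger_group_sizes(),
#'                          badger_survey_sites()[c("site", "site_habitat")])
#' estimate_density(badger_survey_sites(), gs)
estimate_density <- function(sites, group_sizes) {
  stopifnot(all(c("site", "d_c", "n_SSC", "n_MSC", "n_MSCR",
                  "n_clusters") %in% names(sites)))
  wide <- tidyr::pivot_wider(
    dplyr::select(group_sizes, "site", "category", "ad", "total"),
    names_from = "category", values_from = c("ad", "total")
  )
  out <- dplyr::left_join(tibble::as_tibble(sites), wide, by = "site")
  out <- dplyr::mutate(
    out,
    d_ad = composite_density(
      .data$d_c, .data$n_SSC, .data$n_MSC, .data$n_MSCR, .data$n_clusters,
      .data$ad_SSC, .data$ad_MSC, .data$ad_MSCR),
    d_bad = composite_density(
      .data$d_c, .data$n_SSC, .data$n_MSC, .data$n_MSCR, .data$n_clusters,
      .data$total_SSC, .data$total_MSC, .data$total_MSCR),
    d_occupied_main = occupied_main_density(
      .data$d_c, .data$n_MSC, .data$n_MSCR, .data$n_clusters)
  )
  if ("cv_percent" %in% names(out)) {
    out <- dplyr::mutate(
      out,
      d_ad_sd = .data$d_ad * .data$cv_percent / 100,
      d_bad_sd = .data$d_bad * .data$cv_percent / 100
    )
  }
  class(out) <- c("site_density", class(out))
  out
}

#' Cross-site summary of density metrics
#'
#' Mean, sample SD (n - 1 denominator), minimum and maximum with the sites
#' attaining them (ties broken by site label).
#'
#' @param densities A `site_density` table from [estimate_density()] (or
#'   any data frame with a `site` column and numeric metric columns).
#' @param metrics Character vector of columns to summarize.
#' @return A tibble with one row per metric: `mean`, `sd`, `min`,
#'   `min_site`, `max`, `max_site`, `n_sites`.
#' @export
summarize_sites <- function(densities,
                            metrics = c("d_ad", "d_bad", "d_occupied_main")) {
  stopifnot(all(metrics %in% names(densities)), "site" %in% names(densities))
  if (nrow(densities) < 2) abort("need >= 2 sites to summarize.")
  ord <- order(densities$site)
  densities <- densities[ord, ]
  purrr::map(metrics, function(m) {
    v <- densities[[m]]
    tibble::tibble(
      metric = m,
      mean = mean(v), sd = sd(v),
      min = min(v), min_site = densities$site[which.min(v)],
      max = max(v), max_site = densities$site[which.max(v)],
      n_sites = length(v)
    )
  }) |>
    purrr::list_rbind()
}
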