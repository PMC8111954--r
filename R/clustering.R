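#' Group sett records into sett clusters
#'
#' Badger social groups use several burrow systems (setts); setts whose
#' centroids lie within a fixed distance of each other are treated as one
#' "sett cluster", the residence of a single social group. Clustering is
#' single linkage: two setts join the same cluster whenever a chain of
#' pairwise centroid distances, each at or below `threshold_m`, connects
#' them (connected components of the distance graph). Clusters never span
#' study sites.
#'
#' @param setts A data frame of sett records with columns `sett_id`,
#'   `site` (or `site_id`), planar coordinates `x_m`, `y_m` in metres
#'   (a metric projection is assumed), `sett_type` (`"main"` or
#'   `"secondary"`), logicals `occupied` and `reproduction`, and optionally
#'   `perp_distance_m` (perpendicular distance to the walked transect) and
#'   a logical `first_detected` flag marking the member sett detected first.
#' @param threshold_m Positive grouping distance in metres between sett
#'   centroids. 500 m is the survey's operational definition of a shared
#'   territory.
#'
#' @return A tibble with one row per cluster: `cluster_id` (site label plus
#'   a per-site ordinal, ordered by smallest member `sett_id`), `site`,
#'   `n_setts`, `members` (list-column of member sett ids), `category`
#'   (see [classify_clusters()]) and `detection_distance_m`, the
#'   perpendicular distance of the first-detected member (falling back,
#'   with a warning, to the member with the smallest `perp_distance_m`
#'   when no flag is present).
#'
#' @details Cluster membership is invariant to the input row order; labels
#'   are made deterministic by ordering clusters within a site by their
#'   smallest member `sett_id`.
#' @seealso [classify_clusters()], [occupancy_proportions()]
#' @export
#' @examples
#' setts <- tibble::tibble(
#'   sett_id = c("s1", "s2", "s3"), site = "X",
#'   x_m = c(0, 400, 800), y_m = 0,
#'   sett_type = c("main", "secondary", "secondary"),
#'   occupied = c(TRUE, FALSE, TRUE), reproduction = c(TRUE, FALSE, FALSE)
#' )
#' cluster_setts(setts, threshold_m = 500)  # one chained cluster of 3
cluster_setts <- function(setts, threshold_m = 500) {
  if (!is.numeric(threshold_m) || length(threshold_m) != 1 ||
      !is.finite(threshold_m) || threshold_m <= 0) {
    abort("`threshold_m` must be a single positive finite number.")
  }
  setts <- normalise_setts(setts)
  if (nrow(setts) == 0) {
    return(empty_cluster_table())
  }
  if ("perp_distance_m" %in% names(setts) &&
      !"first_detected" %in% names(setts)) {
    warn(paste("no `first_detected` flag: using the member with the",
               "smallest perpendicular distance as the cluster detection."))
  }
  split(setts, setts$site) |>
    purrr::map(cluster_one_site, threshold_m = threshold_m) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$site, .data$cluster_ord) |>
    dplyr::select(-"cluster_ord")
}

normalise_setts <- function(setts) {
  stopifnot(is.data.frame(setts))
  if (!"site" %in% names(setts) && "site_id" %in% names(setts)) {
    setts <- dplyr::rename(setts, site = "site_id")
  }
  required <- c("sett_id", "site", "x_m", "y_m", "sett_type",
                "occupied", "reproduction")
  missing <- setdiff(required, names(setts))
  if (length(missing)) {
    abort(paste0("sett table lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(setts[c("site", "sett_id")])) {
    abort("duplicated sett_id within a site.")
  }
  if (!all(is.finite(setts$x_m)) || !all(is.finite(setts$y_m))) {
    abort("sett coordinates must be finite.")
  }
  bad <- setts$reproduction &
    !(setts$occupied & setts$sett_type == "main")
  if (any(bad)) {
    abort("reproduction = TRUE requires an occupied main sett.")
  }
  tibble::as_tibble(setts)
}

cluster_one_site <- function(site_setts, threshold_m) {
  n <- nrow(site_setts)
  if (n == 1) {
    comp <- 1L
  } else {
    d <- as.matrix(dist(site_setts[, c("x_m", "y_m")]))
    adj <- d <= threshold_m
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)$membership
  }
  groups <- split(site_setts, comp)
  # canonical order: by smallest member sett_id
  ord <- order(vapply(groups, function(g) min(as.character(g$sett_id)), ""))
  groups <- groups[ord]
  purrr::map(seq_along(groups), function(i) {
    g <- groups[[i]]
    tibble::tibble(
      cluster_id = sprintf("%s_%03d", g$site[1], i),
      site = g$site[1],
      cluster_ord = i,
      n_setts = nrow(g),
      members = list(sort(as.character(g$sett_id))),
      category = classify_members(g),
      detection_distance_m = cluster_detection_distance(g)
    )
  }) |>
    purrr::list_rbind()
}

cluster_detection_distance <- function(members) {
  if (!"perp_distance_m" %in% names(members)) {
    return(NA_real_)
  }
  if ("first_detected" %in% names(members) &&
      any(members$first_detected %in% TRUE)) {
    return(members$perp_distance_m[which(members$first_detected)[1]])
  }
  d <- members$perp_distance_m
  if (all(is.na(d))) {
    return(NA_real_)
  }
  min(d, na.rm = TRUE)
}

classify_members <- function(members) {
  occ_main <- members$occupied & members$sett_type == "main"
  if (any(occ_main & members$reproduction)) {
    "MSCR"
  } else if (any(occ_main)) {
    "MSC"
  } else if (all(members$sett_type == "secondary") && any(members$occupied)) {
    "SSC"
  } else {
    "UNOCCUPIED"
  }
}

empty_cluster_table <- function() {
  tibble::tibble(
    cluster_id = character(), site = character(), n_setts = integer(),
    members = list(), category = character(), detection_distance_m = double()
  )
}

#' Classify sett clusters by occupancy category
#'
#' A cluster is `MSCR` if any member is an occupied main sett with
#' reproduction; otherwise `MSC` if any member is an occupied main sett;
#' otherwise `SSC` if all members are secondary setts and at least one is
#' occupied; otherwise `UNOCCUPIED`. The precedence is strict and total,
#' so every cluster receives exactly one category.
#'
#' @param setts A sett data frame as in [cluster_setts()], with a
#'   `cluster_id` column assigning each sett to a cluster.
#' @return A tibble with `cluster_id`, `site` and `category`.
#' @export
classify_clusters <- function(setts) {
  stopifnot("cluster_id" %in% names(setts))
  setts <- normalise_setts(setts)
  dplyr::group_by(setts, .data$site, .data$cluster_id) |>
    dplyr::summarise(
      category = classify_members(dplyr::pick(dplyr::everything())),
      .groups = "drop"
    ) |>
    dplyr::select("cluster_id", "site", "category")
}

#' Per-site occupancy proportions of sett clusters
#'
#' The composite density estimator weights per-category group sizes by the
#' proportions of occupied clusters: p_SSC, p_MSC and p_MSCR, each an exact
#' count fraction of all clusters at the site (occupied and unoccupied).
#'
#' @param clusters A cluster table as returned by [cluster_setts()] (needs
#'   `site` and `category`).
#' @return A tibble with one row per site: counts `n_clusters`, `n_SSC`,
#'   `n_MSC`, `n_MSCR` and proportions `p_SSC`, `p_MSC`, `p_MSCR`.
#' @export
occupancy_proportions <- function(clusters) {
  stopifnot(all(c("site", "category") %in% names(clusters)))
  if (nrow(clusters) == 0) {
    abort("no clusters: occupancy proportions are undefined.")
  }
  bad <- setdiff(unique(clusters$category), CLUSTER_CATEGORIES)
  if (length(bad)) {
    abort(paste0("unknown cluster category: ", paste(bad, collapse = ", ")))
  }
  dplyr::group_by(clusters, .data$site) |>
    dplyr::summarise(
      n_clusters = dplyr::n(),
      n_SSC = sum(.data$category == "SSC"),
      n_MSC = sum(.data$category == "MSC"),
      n_MSCR = sum(.data$category == "MSCR"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      p_SSC = .data$n_SSC / .data$n_clusters,
      p_MSC = .data$n_MSC / .data$n_clusters,
      p_MSCR = .data$n_MSCR / .data$n_clusters
    )
}
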