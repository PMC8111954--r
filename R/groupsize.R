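# Social group sizes per sett cluster from camera-trap maximum
# simultaneous counts and genetic individual identification.

#' Maximum simultaneous camera-trap counts per cluster
#'
#' A social group's size is bounded below by the maximum number of animals
#' ever seen together on camera. For each cluster the componentwise maxima
#' over all camera nights (and all member setts) are taken: the maximum
#' number of adults seen simultaneously and the maximum total (adults and
#' cubs) seen simultaneously.
#'
#' @param camera A data frame of per-night records with columns
#'   `cluster_id`, `night`, `adults_simultaneous`, `total_simultaneous`.
#' @return A tibble with one row per cluster: `cam_adults`, `cam_total`,
#'   `n_nights`.
#' @export
#' @examples
#' camera_counts(tibble::tibble(
#'   cluster_id = "c1", night = 1:3,
#'   adults_simultaneous = c(1, 2, 1), total_simultaneous = c(1, 3, 2)
#' ))  # cam_adults 2, cam_total 3
camera_counts <- function(camera) {
  required <- c("cluster_id", "night", "adults_simultaneous",
                "total_simultaneous")
  stopifnot(all(required %in% names(camera)))
  if (any(camera$total_simultaneous < camera$adults_simultaneous)) {
    abort("total_simultaneous must be >= adults_simultaneous.")
  }
  if (any(camera$adults_simultaneous < 0)) {
    abort("camera counts must be nonnegative.")
  }
  dplyr::group_by(camera, .data$cluster_id) |>
    dplyr::summarise(
      cam_adults = max(.data$adults_simultaneous),
      cam_total = max(.data$total_simultaneous),
      n_nights = dplyr::n_distinct(.data$night),
      .groups = "drop"
    )
}

## ---- genetic individual identification ---------------------------------

# genotype columns: every column whose name starts with "loc"; values are
# "a/b" strings (unordered allele pairs) or NA for a missing locus.
genotype_matrix <- function(genetic) {
  loc_cols <- grep("^loc", names(genetic), value = TRUE)
  if (length(loc_cols) == 0) {
    abort("no genotype columns (expected names starting with 'loc').")
  }
  m <- as.matrix(genetic[loc_cols])
  # canonicalise allele order within a locus so "a/b" == "b/a"
  canon <- function(v) {
    parts <- strsplit(v, "/", fixed = TRUE)
    vapply(parts, function(p) {
      if (length(p) != 2 || anyNA(p)) return(NA_character_)
      paste(sort(p), collapse = "/")
    }, "")
  }
  apply(m, 2, function(col) ifelse(is.na(col), NA_character_, canon(col)))
}

#' Count distinct genotyped individuals in one cluster
#'
#' Hair samples are matched into individuals by multilocus genotype: two
#' samples belong to the same individual when they agree at every locus
#' where both were scored, disagree nowhere, and each has at most
#' `max_missing_loci` missing loci. Matching is the transitive closure of
#' pairwise compatibility; when closure chains together samples that are
#' not themselves pairwise compatible, a warning is issued (possible
#' over-merging through intermediate samples).
#'
#' @param genetic A data frame of samples with `sample_id` and genotype
#'   columns named `loc...` holding `"allele1/allele2"` strings (`NA` =
#'   locus not scored). All samples must share one locus panel.
#' @param max_missing_loci Samples missing more than this many loci are
#'   discarded before matching.
#' @return The number of distinct individuals (integer).
#' @export
count_genetic_individuals <- function(genetic, max_missing_loci = 4) {
  stopifnot("sample_id" %in% names(genetic))
  if (nrow(genetic) == 0) return(0L)
  gm <- genotype_matrix(genetic)
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = nrow(genetic))
  n_missing <- rowSums(is.na(gm))
  gm <- gm[n_missing <= max_missing_loci, , drop = FALSE]
  n <- nrow(gm)
  if (n == 0) return(0L)
  if (n == 1) return(1L)
  compatible <- function(i, j) {
    both <- !is.na(gm[i, ]) & !is.na(gm[j, ])
    all(gm[i, both] == gm[j, both])
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      adj[i, j] <- adj[j, i] <- compatible(i, j)
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(idx) > 2) {
      pairs <- combn(idx, 2)
      ok <- all(adj[cbind(pairs[1, ], pairs[2, ])])
      if (!ok) {
        warn("transitive matching chained samples that are not pairwise compatible.")
      }
    }
  }
  length(unique(comp))
}

#' Merge camera and genetic counts into a cluster group size
#'
#' Both methods undercount: cameras because not all animals are seen
#' simultaneously, genetics because not all individuals are sampled. The
#' total group size is therefore the maximum of the two. Adults come from
#' cameras only (genetic identification cannot separate adults from cubs).
#'
#' @param cam_adults,cam_total Camera maxima from [camera_counts()]
#'   (`NA` if the cluster had no camera survey).
#' @param genetic_count Distinct genotyped individuals from
#'   [count_genetic_individuals()] (`NA` if no hair-trap survey).
#' @return A one-row tibble with `adults` (camera only; `NA` without
#'   cameras) and `total` (max of the available methods; `NA` when both
#'   are absent).
#' @export
#' @examples
#' cluster_group_size(2, 3, 5)  # adults 2, total 5
cluster_group_size <- function(cam_adults, cam_total, genetic_count) {
  both_absent <- is.na(cam_total) & is.na(genetic_count)
  total <- pmax(dplyr::coalesce(cam_total, 0),
                dplyr::coalesce(genetic_count, 0))
  total[both_absent] <- NA_real_
  tibble::tibble(adults = as.numeric(cam_adults), total = as.numeric(total))
}

#' Per-site, per-category mean group sizes
#'
#' Averages the per-cluster group sizes within each site and occupied
#' cluster category (SSC, MSC, MSCR): `ad` is the mean number of adults
#' (camera traps only) and `total` the mean group size including cubs
#' (camera/genetic maximum). Site x category cells with no surveyed
#' cluster are absent from the output; [impute_group_sizes()] completes
#' them.
#'
#' @param cluster_sizes A data frame with one row per surveyed cluster:
#'   `site`, `category` (one of SSC/MSC/MSCR), `adults`, `total`.
#' @return A tibble: `site`, `category`, `ad`, `total`, `n_surveyed`,
#'   `ad_imputed`, `total_imputed` (all `FALSE` here).
#' @export
site_category_means <- function(cluster_sizes) {
  stopifnot(all(c("site", "category", "adults", "total") %in%
                  names(cluster_sizes)))
  bad <- setdiff(unique(as.character(cluster_sizes$category)),
                 OCCUPIED_CATEGORIES)
  if (length(bad)) {
    abort(paste0("group sizes only apply to occupied categories; got: ",
                 paste(bad, collapse = ", ")))
  }
  dplyr::group_by(cluster_sizes, .data$site, .data$category) |>
    dplyr::summarise(
      ad = mean(.data$adults, na.rm = TRUE),
      total = mean(.data$total, na.rm = TRUE),
      n_surveyed = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ad = ifelse(is.nan(.data$ad), NA_real_, .data$ad),
      total = ifelse(is.nan(.data$total), NA_real_, .data$total),
      category = factor(as.character(.data$category),
                        levels = OCCUPIED_CATEGORIES),
      ad_imputed = FALSE, total_imputed = FALSE
    ) |>
    dplyr::arrange(.data$site, .data$category)
}

#' Impute missing group sizes from sites of the same landscape class
#'
#' When no cluster of a category could be surveyed at a site, its mean
#' group size is taken as the average of the observed (non-imputed) values
#' for the same category across sites of the same landscape class
#' (forested or hedgerow). Imputed cells are flagged so that cross-site
#' summaries can exclude them. Imputation is idempotent and never alters
#' observed cells.
#'
#' @param group_sizes A long table as from [site_category_means()] or
#'   [badger_group_sizes()]: `site`, `category`, `ad`, `total`,
#'   `ad_imputed`, `total_imputed`. Missing site x category rows are
#'   created, then all `NA` cells filled.
#' @param site_habitat A data frame mapping `site` to `site_habitat`.
#' @return The completed table with imputation flags set.
#' @export
impute_group_sizes <- function(group_sizes, site_habitat) {
  stopifnot(all(c("site", "site_habitat") %in% names(site_habitat)))
  habitat_map <- dplyr::distinct(
    tibble::as_tibble(site_habitat)[c("site", "site_habitat")])
  all_sites <- unique(habitat_map$site)
  seen_categories <- intersect(OCCUPIED_CATEGORIES,
                               unique(as.character(group_sizes$category)))
  gs <- dplyr::mutate(group_sizes,
                      category = factor(as.character(.data$category),
                                        levels = seen_categories))
  gs$site_habitat <- NULL   # re-derived from the map below
  if (!"ad_imputed" %in% names(gs)) gs$ad_imputed <- FALSE
  if (!"total_imputed" %in% names(gs)) gs$total_imputed <- FALSE
  gs <- tidyr::complete(
    gs,
    site = .env$all_sites,
    category = factor(.env$seen_categories, levels = .env$seen_categories),
    fill = list(ad_imputed = FALSE, total_imputed = FALSE)
  )
  gs <- dplyr::left_join(gs, habitat_map, by = "site")
  pool_means <- function(values, imputed, habitat) {
    # per (category is implicit via grouping) mean of observed cells in
    # the same landscape class
    tapply(values[!imputed & !is.na(values)],
           habitat[!imputed & !is.na(values)], mean)
  }
  filled <- dplyr::group_by(gs, .data$category) |>
    dplyr::group_modify(function(d, key) {
      for (col in c("ad", "total")) {
        flag <- paste0(col, "_imputed")
        miss <- is.na(d[[col]])
        if (!any(miss)) next
        pm <- pool_means(d[[col]], d[[flag]], d$site_habitat)
        fill <- pm[d$site_habitat[miss]]
        if (anyNA(fill)) {
          hab <- unique(d$site_habitat[miss][is.na(fill)])
          abort(sprintf(
            "no observed %s value for category %s in %s sites: cannot impute.",
            col, as.character(key$category), paste(hab, collapse = "/")))
        }
        d[[col]][miss] <- unname(fill)
        d[[flag]][miss] <- TRUE
      }
      d
    }) |>
    dplyr::ungroup()
  dplyr::select(filled, "site", "category", "ad", "total",
                dplyr::any_of(c("n_surveyed", "site_habitat")),
                "ad_imputed", "total_imputed") |>
    dplyr::arrange(.data$site, .data$category)
}

#' Round for reporting
#'
#' Two-decimal report values round half away from zero (so 1.805 prints as
#' 1.81), matching conventional field-report formatting. All internal
#' composition uses full precision; rounding is applied only when values
#' are serialized or compared with printed tables.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
#' @examples
#' round_half_up(1.805)  # 1.81, where round() would give 1.80
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Cross-site summary of group sizes, excluding imputed cells
#'
#' @param group_sizes A completed table from [impute_group_sizes()].
#' @return A tibble per category with mean and sample SD of `ad` and
#'   `total` over sites where the cell was observed (not imputed).
#' @export
summarize_group_sizes <- function(group_sizes) {
  dplyr::group_by(group_sizes, .data$category) |>
    dplyr::summarise(
      ad_mean = mean(.data$ad[!.data$ad_imputed], na.rm = TRUE),
      ad_sd = sd(.data$ad[!.data$ad_imputed], na.rm = TRUE),
      total_mean = mean(.data$total[!.data$total_imputed], na.rm = TRUE),
      total_sd = sd(.data$total[!.data$total_imputed], na.rm = TRUE),
      n_observed = sum(!.data$ad_imputed & !is.na(.data$ad)),
      .groups = "drop"
    )
}
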