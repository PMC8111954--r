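# Synthetic study sites with known ground truth. Sett clusters are a
# parent-offspring (Thomas-like) point process restricted to a binary
# suitable-habitat mask; a gridded transect survey detects setts with a
# distance-dependent detection function; camera nights and hair traps
# sample a per-cluster individual roster.

#' Configuration of a synthetic study site
#'
#' Builds and validates the parameter set driving [generate_site()].
#' Defaults emulate the field conditions of the 13-site French badger
#' survey shipped with the package: sites of about 50 km2 with a binary
#' suitable-habitat mask, sett-cluster densities of order 9 clusters per
#' km2 of suitable habitat, about two setts per cluster, occupancy-category
#' frequencies matching the pooled survey (35.2% unoccupied, 20.9% SSC,
#' 30% MSC, 13.9% MSCR), a hazard-rate detection function, transects on a
#' 1-km grid of 1--2 km length, two-week camera sessions, and per-individual
#' genetic capture.
#'
#' @param site_id Site label.
#' @param area_km2 Site area (rectangular site), km2.
#' @param suitable_fraction Proportion of the site that is suitable
#'   habitat, in (0, 1].
#' @param site_habitat `"forested"` or `"hedgerow"`.
#' @param cluster_intensity Expected sett clusters per km2 of suitable
#'   habitat.
#' @param setts_per_cluster List with `mean` (>= 1): setts per cluster are
#'   `1 + Poisson(mean - 1)`.
#' @param cluster_spread_m Radius within which a cluster's setts scatter
#'   around the parent point; must stay below half the clustering
#'   threshold so true clusters are recoverable.
#' @param category_probs Named probabilities over `UNOCCUPIED`, `SSC`,
#'   `MSC`, `MSCR`, summing to 1 (tolerance 1e-9).
#' @param group_size_params Per-category list: mean adults for `SSC`,
#'   `MSC`, `MSCR`, plus mean cubs for `MSCR` (cubs exist only where
#'   reproduction does). Adults are `1 + Poisson(mean - 1)`; cubs
#'   `Poisson(mean_cubs)`.
#' @param detection List `key` (`"hazard_rate"`, `"half_normal"` or
#'   `"uniform"`), `sigma` (m), `b` (hazard-rate shape > 1) and, for the
#'   uniform key, `w` (the fixed detection range in m).
#' @param transect_spacing_m Spacing of the systematic transect grid, m.
#' @param transect_length_km Length-2 range for transect lengths, km.
#' @param camera_detect_prob Per-individual, per-night probability of
#'   appearing in the nightly simultaneous count, in [0, 1].
#' @param n_camera_nights Camera nights per surveyed cluster.
#' @param genetic_detect_prob Per-individual probability of leaving at
#'   least one usable hair sample, in [0, 1].
#' @param n_loci,alleles_per_locus,genetic_missing_rate Genotype panel:
#'   number of microsatellite loci, alleles per locus, and per-locus
#'   dropout rate in simulated samples.
#' @param clustering_threshold_m The grouping distance the downstream
#'   analysis will use; only used to validate `cluster_spread_m`.
#' @param seed Integer seed; the same configuration and seed give
#'   byte-identical outputs.
#' @return A validated list of class `site_config`.
#' @seealso [generate_site()]
#' @export
site_config <- function(site_id = "S1",
                        area_km2 = 50,
                        suitable_fraction = 0.4,
                        site_habitat = c("hedgerow", "forested"),
                        cluster_intensity = 9,
                        setts_per_cluster = list(mean = 2),
                        cluster_spread_m = 100,
                        category_probs = c(UNOCCUPIED = 0.352, SSC = 0.209,
                                           MSC = 0.300, MSCR = 0.139),
                        group_size_params = list(
                          SSC = list(adults = 1.3),
                          MSC = list(adults = 1.4),
                          MSCR = list(adults = 2.0, cubs = 2.5)
                        ),
                        detection = list(key = "hazard_rate", sigma = 15,
                                         b = 2.5),
                        transect_spacing_m = 1000,
                        transect_length_km = c(0.5, 1),
                        camera_detect_prob = 0.6,
                        n_camera_nights = 14,
                        genetic_detect_prob = 0.7,
                        n_loci = 24,
                        alleles_per_locus = 6,
                        genetic_missing_rate = 0.1,
                        clustering_threshold_m = 500,
                        seed = 1L) {
  site_habitat <- match.arg(site_habitat)
  cfg <- list(
    site_id = site_id, area_km2 = area_km2,
    suitable_fraction = suitable_fraction, site_habitat = site_habitat,
    cluster_intensity = cluster_intensity,
    setts_per_cluster = setts_per_cluster,
    cluster_spread_m = cluster_spread_m,
    category_probs = category_probs,
    group_size_params = group_size_params,
    detection = detection,
    transect_spacing_m = transect_spacing_m,
    transect_length_km = transect_length_km,
    camera_detect_prob = camera_detect_prob,
    n_camera_nights = n_camera_nights,
    genetic_detect_prob = genetic_detect_prob,
    n_loci = n_loci, alleles_per_locus = alleles_per_locus,
    genetic_missing_rate = genetic_missing_rate,
    clustering_threshold_m = clustering_threshold_m,
    seed = seed
  )
  validate_site_config(cfg)
}

validate_site_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) abort(sprintf("invalid configuration field `%s`: %s.",
                           field, what))
  }
  pos <- function(v) length(v) == 1 && is.numeric(v) && is.finite(v) && v > 0
  chk(pos(cfg$area_km2), "area_km2", "must be a positive number")
  chk(pos(cfg$suitable_fraction) && cfg$suitable_fraction <= 1,
      "suitable_fraction", "must lie in (0, 1]")
  chk(pos(cfg$cluster_intensity), "cluster_intensity",
      "must be a positive number")
  chk(pos(cfg$setts_per_cluster$mean) && cfg$setts_per_cluster$mean >= 1,
      "setts_per_cluster", "mean must be >= 1")
  chk(pos(cfg$cluster_spread_m), "cluster_spread_m",
      "must be a positive number")
  chk(cfg$cluster_spread_m < cfg$clustering_threshold_m / 2,
      "cluster_spread_m", "must be below half the clustering threshold")
  p <- cfg$category_probs
  chk(length(p) == 4 && all(CLUSTER_CATEGORIES %in% names(p)),
      "category_probs", "must name all of UNOCCUPIED, SSC, MSC, MSCR")
  chk(all(is.finite(p)) && all(p >= 0) && abs(sum(p) - 1) <= 1e-9,
      "category_probs", "must be nonnegative and sum to 1 (tol 1e-9)")
  for (cc in OCCUPIED_CATEGORIES) {
    chk(pos(cfg$group_size_params[[cc]]$adults),
        "group_size_params", paste0("mean adults required for ", cc))
  }
  chk(pos(cfg$group_size_params$MSCR$cubs), "group_size_params",
      "mean cubs required for MSCR")
  chk(cfg$detection$key %in% c("hazard_rate", "half_normal", "uniform"),
      "detection", "key must be hazard_rate, half_normal or uniform")
  if (cfg$detection$key != "uniform") {
    chk(pos(cfg$detection$sigma), "detection", "sigma must be positive")
  }
  if (cfg$detection$key == "hazard_rate") {
    chk(pos(cfg$detection$b) && cfg$detection$b > 1, "detection",
        "hazard-rate shape b must exceed 1")
  }
  if (cfg$detection$key == "uniform") {
    chk(pos(cfg$detection$w), "detection",
        "uniform key needs a detection range w")
  }
  chk(pos(cfg$transect_spacing_m), "transect_spacing_m",
      "must be a positive number")
  chk(length(cfg$transect_length_km) == 2 &&
        all(is.finite(cfg$transect_length_km)) &&
        all(cfg$transect_length_km > 0) &&
        cfg$transect_length_km[1] <= cfg$transect_length_km[2],
      "transect_length_km", "must be a positive increasing range")
  chk(cfg$transect_length_km[2] * 1000 <= cfg$transect_spacing_m,
      "transect_length_km",
      "straight transects longer than the grid spacing would overlap strips")
  prob_ok <- function(v) length(v) == 1 && is.numeric(v) && is.finite(v) &&
    v >= 0 && v <= 1
  chk(prob_ok(cfg$camera_detect_prob), "camera_detect_prob",
      "must lie in [0, 1]")
  chk(prob_ok(cfg$genetic_detect_prob), "genetic_detect_prob",
      "must lie in [0, 1]")
  chk(prob_ok(cfg$genetic_missing_rate), "genetic_missing_rate",
      "must lie in [0, 1]")
  chk(pos(cfg$n_camera_nights), "n_camera_nights", "must be positive")
  chk(pos(cfg$n_loci), "n_loci", "must be positive")
  chk(pos(cfg$alleles_per_locus), "alleles_per_locus", "must be positive")
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed",
      "must be a single integer")
  structure(cfg, class = "site_config")
}

# detection probability under the configured true detection function
true_detection_prob <- function(detection, d) {
  switch(detection$key,
    uniform = as.numeric(d <= detection$w),
    half_normal = exp(-d^2 / (2 * detection$sigma^2)),
    hazard_rate = 1 - exp(-(d / detection$sigma)^(-detection$b))
  )
}

#' Generate a synthetic study site
#'
#' Simulates one study site under the configured conditions and returns
#' the four survey tables a real site would yield, plus the ground truth:
#' \enumerate{
#'   \item a rectangular site with a binary suitable-habitat mask built
#'     from randomly selected axis-aligned 250-m-wide strips (emulating
#'     hedgerow and forest-edge corridors) covering `suitable_fraction`
#'     of the area;
#'   \item cluster parent points as a Poisson process on the mask
#'     (expected count `cluster_intensity` x suitable area), each parent
#'     spawning `1 + Poisson(mean - 1)` setts uniformly within
#'     `cluster_spread_m`, with an occupancy category drawn from
#'     `category_probs` and sett type/occupancy flags consistent with it;
#'   \item one transect per point of a `transect_spacing_m` grid, walked
#'     along the centreline of the suitable strip nearest the point, with
#'     lengths drawn from `transect_length_km` (capped at the grid
#'     spacing so that surveyed strips never overlap), clipped to the
#'     site;
#'   \item each sett detected with probability `g(d)` of the true
#'     detection function at its perpendicular distance `d` to the nearest
#'     transect; the detected member closest to a transect carries the
#'     cluster's `first_detected` flag;
#'   \item for each occupied cluster with a detected sett, a roster of
#'     adults (and cubs, in reproducing clusters only) sampled nightly by
#'     camera (binomial over the roster) and once by hair traps
#'     (independent per-individual capture, genotypes with random
#'     per-locus dropout).
#' }
#'
#' @param config A [site_config()].
#' @return A list of class `synthetic_site`: tibbles `setts`, `transects`,
#'   `camera`, `genetic`, and `truth`, a list holding
#'   `true_cluster_density_per_km2` (generated clusters / suitable km2),
#'   `true_category_props`, `true_group_sizes`, `member_map` (all setts,
#'   detected or not) and the per-individual `roster`.
#' @export
#' @examples
#' site <- generate_site(site_config(area_km2 = 10, seed = 42))
#' nrow(site$setts); site$truth$true_cluster_density_per_km2
generate_site <- function(config) {
  if (!inherits(config, "site_config")) config <- validate_site_config(config)
  withr::with_seed(as.integer(config$seed), generate_site_impl(config))
}

generate_site_impl <- function(cfg) {
  side_m <- sqrt(cfg$area_km2) * 1000
  # suitable-habitat mask: axis-aligned strips (250-m wide columns), the
  # width matching hedgerow / forest-edge corridors; randomly selected
  # columns cover suitable_fraction of the site
  strip_m <- 250
  n_cols <- max(1L, floor(side_m / strip_m))
  n_suit <- max(1L, min(n_cols, round(cfg$suitable_fraction * n_cols)))
  suit_cols <- sort(sample.int(n_cols, n_suit)) - 1L

  ## -- sett clusters -----------------------------------------------------
  suitable_km2 <- cfg$area_km2 * cfg$suitable_fraction
  n_clusters <- rpois(1, cfg$cluster_intensity * suitable_km2)
  parent_col <- if (n_clusters > 0) {
    suit_cols[sample.int(n_suit, n_clusters, replace = TRUE)]
  } else integer(0)
  parent_x <- (parent_col + runif(n_clusters)) * strip_m
  parent_y <- runif(n_clusters) * side_m
  categories <- if (n_clusters > 0) {
    sample(CLUSTER_CATEGORIES, n_clusters, replace = TRUE,
           prob = cfg$category_probs[CLUSTER_CATEGORIES])
  } else character(0)

  k <- if (n_clusters > 0) {
    1L + rpois(n_clusters, cfg$setts_per_cluster$mean - 1)
  } else integer(0)
  idx <- rep(seq_len(n_clusters), k)
  n_s <- length(idx)
  r <- cfg$cluster_spread_m * sqrt(runif(n_s))
  th <- runif(n_s, 0, 2 * pi)
  all_setts <- tibble::tibble(
    cluster = idx,
    x_m = parent_x[idx] + r * cos(th),
    y_m = parent_y[idx] + r * sin(th)
  )
  all_setts <- cbind(all_setts, sett_flags(categories[idx],
                                           !duplicated(idx)))
  all_setts$sett_id <- sprintf("%s_s%04d", cfg$site_id,
                               seq_len(nrow(all_setts)))

  ## -- transect grid -----------------------------------------------------
  # theoretical points on a regular grid; each transect is relocated to
  # the centreline of the nearest suitable strip (field crews walk the
  # suitable corridor closest to the theoretical point)
  sp <- cfg$transect_spacing_m
  gx <- seq(sp / 2, side_m - sp / 2 + 1e-9, by = sp)
  gy <- seq(sp / 2, side_m - sp / 2 + 1e-9, by = sp)
  grid <- expand.grid(x = gx, y = gy)
  centres <- (suit_cols + 0.5) * strip_m
  grid$x <- vapply(grid$x, function(x) centres[which.min(abs(centres - x))],
                   0)
  n_tr <- nrow(grid)
  len_m <- runif(n_tr, cfg$transect_length_km[1],
                 cfg$transect_length_km[2]) * 1000
  y0 <- pmax(0, grid$y - len_m / 2)
  y1 <- pmin(side_m, grid$y + len_m / 2)
  hab_levels <- if (cfg$site_habitat == "forested") {
    c("forest", "forest_edge", "hedgerow")
  } else {
    c("hedgerow", "forest_edge", "forest")
  }
  transects <- tibble::tibble(
    transect_id = sprintf("%s_t%03d", cfg$site_id, seq_len(n_tr)),
    site = cfg$site_id,
    x_m = grid$x, y0_m = y0, y1_m = y1,
    length_km = (y1 - y0) / 1000,
    habitat = sample(hab_levels, n_tr, replace = TRUE,
                     prob = c(0.6, 0.25, 0.15)),
    site_habitat = cfg$site_habitat
  )

  ## -- detection ---------------------------------------------------------
  if (nrow(all_setts) > 0 && n_tr > 0) {
    dx <- abs(outer(all_setts$x_m, transects$x_m, `-`))
    dy <- pmax(outer(all_setts$y_m, y0, function(s, a) a - s), 0) +
      pmax(outer(all_setts$y_m, y1, function(s, b) s - b), 0)
    dmat <- sqrt(dx^2 + dy^2)
    nearest <- max.col(-dmat, ties.method = "first")
    d_perp <- dmat[cbind(seq_len(nrow(dmat)), nearest)]
  } else {
    d_perp <- rep(Inf, nrow(all_setts))
    nearest <- rep(NA_integer_, nrow(all_setts))
  }
  all_setts$perp_distance_m <- d_perp
  all_setts$nearest_transect <- transects$transect_id[nearest]
  g <- true_detection_prob(cfg$detection, d_perp)
  detected <- runif(nrow(all_setts)) < g
  setts <- all_setts[detected, , drop = FALSE]
  if (nrow(setts) > 0) {
    setts <- dplyr::group_by(setts, .data$cluster) |>
      dplyr::mutate(first_detected =
                      dplyr::row_number(.data$perp_distance_m) == 1L) |>
      dplyr::ungroup()
  } else {
    setts$first_detected <- logical(0)
  }
  setts <- tibble::tibble(
    sett_id = setts$sett_id, site = cfg$site_id,
    x_m = setts$x_m, y_m = setts$y_m,
    sett_type = setts$sett_type, occupied = setts$occupied,
    reproduction = setts$reproduction,
    perp_distance_m = setts$perp_distance_m,
    transect_id = setts$nearest_transect,
    first_detected = setts$first_detected,
    true_cluster = setts$cluster
  )

  ## -- individual roster, camera and genetic sampling --------------------
  occ_cl <- which(categories != "UNOCCUPIED")
  mean_ad <- vapply(categories[occ_cl],
                    function(cc) cfg$group_size_params[[cc]]$adults, 0)
  n_ad <- 1L + rpois(length(occ_cl), mean_ad - 1)
  n_cub <- ifelse(categories[occ_cl] == "MSCR",
                  rpois(length(occ_cl), cfg$group_size_params$MSCR$cubs), 0L)
  cl_rep <- rep(occ_cl, n_ad + n_cub)
  age <- unlist(purrr::map2(n_ad, n_cub,
                            function(a, c) rep(c("adult", "cub"), c(a, c))),
                use.names = FALSE)
  roster <- tibble::tibble(
    cluster = cl_rep,
    category = categories[cl_rep],
    individual_id = sprintf("%s_c%03d_i%02d", cfg$site_id, cl_rep,
                            stats::ave(cl_rep, cl_rep, FUN = seq_along)),
    age_class = age %||% character(0),
    sex = sample(c("M", "F"), length(cl_rep), replace = TRUE)
  )
  # genotypes for every individual on the roster
  if (nrow(roster) > 0) {
    geno <- matrix("", nrow(roster), cfg$n_loci)
    for (l in seq_len(cfg$n_loci)) {
      a1 <- sample.int(cfg$alleles_per_locus, nrow(roster), replace = TRUE)
      a2 <- sample.int(cfg$alleles_per_locus, nrow(roster), replace = TRUE)
      geno[, l] <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
    }
    colnames(geno) <- sprintf("loc%02d", seq_len(cfg$n_loci))
    roster <- cbind(roster, tibble::as_tibble(geno))
  }

  surveyed <- sort(unique(setts$true_cluster[setts$occupied]))
  surveyed <- intersect(surveyed, roster$cluster)

  camera <- tibble::tibble(cluster_id = character(), night = integer(),
                           adults_simultaneous = integer(),
                           total_simultaneous = integer())
  if (cfg$camera_detect_prob > 0 && length(surveyed) > 0) {
    camera <- purrr::map(surveyed, function(i) {
      r <- roster[roster$cluster == i, ]
      n_ad <- sum(r$age_class == "adult")
      n_cub <- sum(r$age_class == "cub")
      ad_seen <- rbinom(cfg$n_camera_nights, n_ad, cfg$camera_detect_prob)
      cub_seen <- rbinom(cfg$n_camera_nights, n_cub, cfg$camera_detect_prob)
      tibble::tibble(
        cluster_id = cluster_label(cfg$site_id, i),
        night = seq_len(cfg$n_camera_nights),
        adults_simultaneous = ad_seen,
        total_simultaneous = ad_seen + cub_seen
      )
    }) |> purrr::list_rbind()
  }

  genetic <- tibble::tibble(cluster_id = character(), sample_id = character(),
                            sex = character())
  if (cfg$genetic_detect_prob > 0 && length(surveyed) > 0) {
    cap <- roster[roster$cluster %in% surveyed &
                    runif(nrow(roster)) < cfg$genetic_detect_prob, ,
                  drop = FALSE]
    if (nrow(cap) > 0) {
      loc_cols <- grep("^loc", names(cap), value = TRUE)
      gm <- as.matrix(cap[loc_cols])
      drop <- matrix(runif(length(gm)) < cfg$genetic_missing_rate,
                     nrow(gm))
      gm[drop] <- NA_character_
      genetic <- tibble::tibble(
        cluster_id = cluster_label(cfg$site_id, cap$cluster),
        sample_id = paste0(cap$individual_id, "_h1"),
        sex = cap$sex
      )
      genetic <- cbind(genetic, tibble::as_tibble(gm)) |> tibble::as_tibble()
    }
  }

  ## -- ground truth ------------------------------------------------------
  tgs <- if (nrow(roster) > 0) {
    dplyr::group_by(roster, .data$category, .data$cluster) |>
      dplyr::summarise(ad = sum(.data$age_class == "adult"),
                       tot = dplyr::n(), .groups = "drop_last") |>
      dplyr::summarise(mean_adults = mean(.data$ad),
                       mean_total = mean(.data$tot), .groups = "drop")
  } else {
    tibble::tibble(category = character(), mean_adults = double(),
                   mean_total = double())
  }
  truth <- list(
    true_cluster_density_per_km2 =
      n_clusters / (cfg$area_km2 * cfg$suitable_fraction),
    true_n_clusters = n_clusters,
    true_category_props = c(
      SSC = mean(categories == "SSC"),
      MSC = mean(categories == "MSC"),
      MSCR = mean(categories == "MSCR")
    ),
    true_group_sizes = tgs,
    member_map = tibble::tibble(
      sett_id = all_setts$sett_id,
      cluster_id = cluster_label(cfg$site_id, all_setts$cluster),
      detected = detected
    ),
    roster = dplyr::mutate(roster,
                           cluster_id = cluster_label(cfg$site_id,
                                                      .data$cluster))
  )

  structure(list(setts = setts, transects = transects, camera = camera,
                 genetic = genetic, truth = truth, config = cfg),
            class = "synthetic_site")
}

cluster_label <- function(site_id, i) sprintf("%s_c%03d", site_id, i)

# sett type / occupancy flags consistent with each sett's cluster
# category; `first` marks the anchor sett of every cluster (vectorized
# over all setts of a site)
sett_flags <- function(category, first) {
  n <- length(category)
  type <- rep("secondary", n)
  occupied <- rep(FALSE, n)
  reproduction <- rep(FALSE, n)
  u <- runif(n)
  anchor_main <- first & category %in% c("MSC", "MSCR")
  type[anchor_main] <- "main"
  occupied[anchor_main] <- TRUE
  reproduction[first & category == "MSCR"] <- TRUE
  other <- !first
  occupied[other & category %in% c("MSC", "MSCR")] <-
    u[other & category %in% c("MSC", "MSCR")] < 0.5
  occupied[first & category == "SSC"] <- TRUE
  occupied[other & category == "SSC"] <- u[other & category == "SSC"] < 0.3
  # unoccupied clusters may still contain a disused main sett
  type[first & category == "UNOCCUPIED" & u < 0.2] <- "main"
  tibble::tibble(sett_type = type, occupied = occupied,
                 reproduction = reproduction)
}

#' Write a synthetic site to disk
#'
#' Writes the four survey tables as CSV and the ground truth as a JSON
#' sidecar, so a generated site can be used as a file-based fixture.
#'
#' @param site A `synthetic_site` from [generate_site()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_site <- function(site, dir) {
  stopifnot(inherits(site, "synthetic_site"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in c("setts", "transects", "camera", "genetic")) {
    utils::write.csv(site[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  }
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    truth <- site$truth
    truth$true_group_sizes <- as.data.frame(truth$true_group_sizes)
    truth$member_map <- as.data.frame(truth$member_map)
    truth$roster <- as.data.frame(truth$roster)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(dir)
}
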