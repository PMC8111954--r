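# Independent oracles and simulation helpers shared across test files.

# rejection sampler: draws perpendicular distances with density
# proportional to g on [0, w]
sim_distances <- function(n, g, w) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- runif(2 * n, 0, w)
    out <- c(out, x[runif(2 * n) < g(x)])
  }
  out[seq_len(n)]
}

g_hr <- function(sigma, b) function(x) 1 - exp(-(x / sigma)^(-b))
g_hn <- function(sigma) function(x) exp(-x^2 / (2 * sigma^2))

# brute-force union-find over the pairwise distance graph; returns a
# canonical membership labelling (independent of cluster_setts' igraph
# route)
uf_components <- function(x, y, threshold) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j &&
          sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2) <= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  match(comp, unique(comp))
}

# canonical form of a clustering: sorted list of sorted member id sets
membership_sets <- function(ids, membership) {
  sets <- split(as.character(ids), membership)
  sets <- lapply(sets, sort)
  unname(sets[order(vapply(sets, `[`, "", 1))])
}

# one-dimensional midpoint Riemann sum, the quadrature oracle for ESW
riemann <- function(f, lower, upper, n = 1e6) {
  h <- (upper - lower) / n
  mid <- lower + (seq_len(n) - 0.5) * h
  sum(f(mid)) * h
}

# configuration used by the end-to-end density recovery checks: full
# suitability, single-sett clusters with negligible spread, hazard-rate
# detection, and a grouping distance scaled to the spread
recovery_config <- function(seed, area_km2 = 200) {
  site_config(
    site_id = "R", area_km2 = area_km2, suitable_fraction = 1,
    cluster_intensity = 5, setts_per_cluster = list(mean = 1),
    cluster_spread_m = 5, clustering_threshold_m = 50,
    detection = list(key = "hazard_rate", sigma = 15, b = 2.5),
    transect_length_km = c(1, 1),
    camera_detect_prob = 0, genetic_detect_prob = 0, seed = seed
  )
}
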