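test_that("camera counts are componentwise maxima over nights", {
  cam <- tibble::tibble(
    cluster_id = "c1", night = 1:3,
    adults_simultaneous = c(1, 2, 1), total_simultaneous = c(1, 3, 2))
  got <- camera_counts(cam)
  expect_equal(got$cam_adults, 2)
  expect_equal(got$cam_total, 3)

  z <- camera_counts(tibble::tibble(cluster_id = "c1", night = 1,
                                    adults_simultaneous = 0,
                                    total_simultaneous = 0))
  expect_equal(c(z$cam_adults, z$cam_total), c(0, 0))

  bad <- tibble::tibble(cluster_id = "c1", night = 1,
                        adults_simultaneous = 3, total_simultaneous = 2)
  expect_error(camera_counts(bad), ">=")
})

test_that("the chance of ever co-detecting the whole group matches enumeration", {
  # 4 adults, detection p = 0.6, 14 nights: P(max simultaneous = 4)
  # = 1 - (1 - p^4)^14 by independence across nights
  p <- 0.6; nights <- 14; n_ad <- 4
  p_all <- 1 - (1 - p^n_ad)^nights
  withr::with_seed(7, {
    hits <- replicate(4000, {
      max(rbinom(nights, n_ad, p)) == n_ad
    })
  })
  expect_equal(mean(hits), p_all, tolerance = 0.03)
  expect_lt(p_all, 1)  # the camera maximum underestimates with positive prob.
})

genotype_row <- function(id, alleles, miss = integer(0)) {
  g <- vapply(alleles, function(a) paste(sort(a), collapse = "/"), "")
  g[miss] <- NA_character_
  out <- tibble::as_tibble(as.list(setNames(g, sprintf("loc%02d",
                                                       seq_along(g)))))
  dplyr::mutate(out, sample_id = id, .before = 1)
}

test_that("genetic matching counts distinct multilocus genotypes", {
  a <- genotype_row("a", list(c(1, 2), c(3, 3), c(2, 4)))
  b <- genotype_row("b", list(c(2, 1), c(3, 3), c(4, 2)))  # same, reordered
  c2 <- genotype_row("c", list(c(1, 2), c(3, 4), c(2, 4)))  # one locus off
  expect_equal(count_genetic_individuals(rbind(a, b)), 1)
  expect_equal(count_genetic_individuals(rbind(a, c2)), 2)
  # missing loci do not block a match
  d <- genotype_row("d", list(c(1, 2), c(3, 3), c(2, 4)), miss = 2)
  expect_equal(count_genetic_individuals(rbind(a, d)), 1)
  # too many missing loci: sample discarded
  e <- genotype_row("e", list(c(1, 2), c(3, 3), c(2, 4)), miss = 1:3)
  expect_equal(count_genetic_individuals(rbind(a, e),
                                         max_missing_loci = 2), 1)
  expect_error(count_genetic_individuals(tibble::tibble(sample_id = "x")),
               "loc")
})

test_that("transitive chaining through a permissive sample warns", {
  a <- genotype_row("a", list(c(1, 1), c(2, 2)))
  b <- genotype_row("b", list(c(1, 1), c(3, 3)))
  bridge <- genotype_row("m", list(c(1, 1), c(2, 2)), miss = 2)
  expect_warning(
    n <- count_genetic_individuals(rbind(a, b, bridge),
                                   max_missing_loci = 1),
    "chained")
  expect_equal(n, 1)
})

test_that("samples from a synthetic roster collapse to the roster count", {
  s <- generate_site(site_config(area_km2 = 20, genetic_detect_prob = 1,
                                 genetic_missing_rate = 0.1,
                                 camera_detect_prob = 0.5, seed = 23))
  counts <- vapply(split(s$genetic, s$genetic$cluster_id),
                   count_genetic_individuals, 0L)
  roster_sizes <- table(s$truth$roster$cluster_id)
  for (cid in names(counts)) {
    expect_lte(counts[[cid]], roster_sizes[[cid]])
  }
  # with full capture and random dropout, most clusters resolve exactly
  # (two individuals can share a compatible genotype by chance)
  expect_gte(mean(counts == as.integer(roster_sizes[names(counts)])), 0.9)
})

test_that("camera/genetic merge takes the maximum and respects absences", {
  expect_equal(cluster_group_size(2, 3, 5), tibble::tibble(adults = 2,
                                                           total = 5))
  expect_equal(cluster_group_size(2, 4, 3)$total, 4)
  pilot <- cluster_group_size(NA, NA, 3)   # no cameras at a pilot site
  expect_true(is.na(pilot$adults))
  expect_equal(pilot$total, 3)
  none <- cluster_group_size(NA, NA, NA)
  expect_true(is.na(none$total))
})

test_that("site-category means average surveyed clusters", {
  cs <- tibble::tibble(
    site = c("A", "A", "A"), category = c("MSCR", "SSC", "SSC"),
    adults = c(3, 1, 2), total = c(5, 1, 2))
  got <- site_category_means(cs)
  expect_equal(got$ad[got$category == "MSCR"], 3)
  expect_equal(got$ad[got$category == "SSC"], 1.5)
  expect_equal(got$n_surveyed[got$category == "SSC"], 2)
  expect_error(site_category_means(dplyr::mutate(cs,
                                                 category = "UNOCCUPIED")),
               "occupied")
})

test_that("imputation reproduces the published hedgerow pools", {
  sites <- badger_survey_sites()
  gs <- impute_group_sizes(badger_group_sizes(),
                           sites[c("site", "site_habitat")])
  ssc <- gs[gs$category == "SSC", ]
  # hedgerow ad_SSC pool {2.00,1.33,1.50,1.00,2.00,1.00} -> 1.47
  for (s in c("E", "I", "L")) {
    expect_equal(round_half_up(ssc$ad[ssc$site == s]), 1.47)
    expect_equal(round_half_up(ssc$total[ssc$site == s]), 1.81)
    expect_true(ssc$ad_imputed[ssc$site == s])
  }
  mscr <- gs[gs$category == "MSCR", ]
  expect_equal(round(mscr$ad[mscr$site == "M"], 2), 1.80)
  expect_equal(round(mscr$total[mscr$site == "M"], 2), 4.15)
  # observed cells untouched, and idempotent
  expect_equal(ssc$ad[ssc$site == "C"], 2.00)
  again <- impute_group_sizes(gs, sites[c("site", "site_habitat")])
  expect_equal(again$ad, gs$ad)
  expect_equal(again$ad_imputed, gs$ad_imputed)
})

test_that("a single-value pool imputes that value; an empty pool errors", {
  gs <- tibble::tibble(
    site = c("X", "Y"), category = factor(c("SSC", "SSC"),
                                          levels = c("SSC", "MSC", "MSCR")),
    ad = c(2.5, NA), total = c(3, NA),
    ad_imputed = FALSE, total_imputed = FALSE)
  hab <- tibble::tibble(site = c("X", "Y"),
                        site_habitat = c("hedgerow", "hedgerow"))
  got <- impute_group_sizes(gs, hab)
  ssc <- got[got$category == "SSC", ]
  expect_equal(ssc$ad[ssc$site == "Y"], 2.5)
  hab2 <- tibble::tibble(site = c("X", "Y"),
                         site_habitat = c("forested", "hedgerow"))
  expect_error(impute_group_sizes(gs, hab2), "cannot impute")
})

test_that("cross-site means exclude imputed cells", {
  sites <- badger_survey_sites()
  gs <- impute_group_sizes(badger_group_sizes(),
                           sites[c("site", "site_habitat")])
  sm <- summarize_group_sizes(gs)
  expect_equal(round(sm$ad_mean[sm$category == "MSCR"], 2), 1.95)
  expect_equal(round(sm$total_mean[sm$category == "MSCR"], 2), 4.46)
  expect_equal(round(sm$ad_mean[sm$category == "SSC"], 2), 1.34)
  expect_equal(sm$n_observed[sm$category == "MSCR"], 12)
})
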