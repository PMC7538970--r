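toy_incidence <- function() {
  mem <- tibble::tibble(
    record_id = paste0("r", 1:12),
    site_id = c(rep("S1", 5), rep("S2", 4), rep("S3", 2), "S4"),
    haplotype_id = c("H1", "H1", "H1", "H2", "H2",
                     "H1", "H3", "H3", "H3",
                     "H2", "H2", "H4"))
  part <- new_partition(paste0("H", 1:4), c("A", "A", "B", "C"), method = "TEST")
  sites <- tibble::tibble(site_id = paste0("S", 1:4),
                          lat = c(45.7, 45.2, 48.1, 45.9),
                          lon = c(5, 6, 15, 5.5),
                          altitude_m = c(200, 400, 900, 300),
                          country = "XX")
  list(mem = mem, part = part, sites = sites)
}

test_that("incidence counts individuals per site and MOTU, conserving totals", {
  tc <- toy_incidence()
  inc <- incidence_table(tc$mem, tc$part, tc$sites)
  expect_equal(sum(inc$n), nrow(tc$mem))
  expect_equal(inc$n[inc$site_id == "S1" & inc$motu == "A"], 5L)
  # single site, single MOTU case
  one <- incidence_table(tc$mem[1:5, ], tc$part, tc$sites)
  expect_equal(nrow(one), 1L)
  expect_equal(one$n, 5L)
  # coverage errors name offenders
  expect_error(incidence_table(tc$mem, new_partition("H1", "A"), tc$sites),
               class = "cm_coverage_error")
  bad_sites <- tc$sites[1:2, ]
  expect_error(incidence_table(tc$mem, tc$part, bad_sites),
               class = "cm_coverage_error")
})

test_that("syntopy rates count multi-MOTU sites among eligible ones", {
  tc <- toy_incidence()
  inc <- incidence_table(tc$mem, tc$part, tc$sites)
  # S1 {A}, S2 {A,B}, S3 {A}, S4 {C}; eligible (>=2 ind): S1, S2, S3
  out <- syntopy_rates(inc)
  expect_equal(out$n_eligible, 3L)
  expect_equal(out$pct_syntopy, 100 / 3)
  expect_equal(out$n_sites_ge_k, 0L)
  # monomorphic everywhere -> 0%
  mono <- incidence_table(tc$mem[1:9, ],
                          new_partition(paste0("H", 1:4), rep("A", 4)),
                          tc$sites)
  expect_equal(syntopy_rates(mono)$pct_syntopy, 0)
  # no eligible site -> undefined percentage
  single <- incidence_table(tc$mem[12, ], tc$part, tc$sites)
  expect_error(syntopy_rates(single), class = "cm_undefined_percentage")
})

test_that("rare-MOTU profile uses least-frequent MOTU at multi-MOTU sites", {
  mem <- tibble::tibble(
    record_id = paste0("r", 1:24),
    site_id = c(rep("S1", 12), rep("S2", 12)),
    haplotype_id = c(rep("H1", 11), "H2", rep("H1", 6), rep("H2", 6)))
  part <- new_partition(c("H1", "H2"), c("A", "B"))
  sites <- tibble::tibble(site_id = c("S1", "S2"), lat = c(45, 46),
                          lon = c(5, 6), altitude_m = c(100, 200), country = "XX")
  inc <- incidence_table(mem, part, sites)
  prof <- rare_motu_profile(inc, min_individuals = 10)
  # S1 split 11/1: min freq 1/12 counts for both cutoffs; S2 split 6/6 for none
  expect_equal(prof$pct_sites[prof$cutoff == 0.2], 50)
  expect_equal(prof$pct_sites[prof$cutoff == 0.1], 50)
  expect_equal(unique(prof$n_eligible), 2L)
  # nested events: pct(0.2) >= pct(0.1) on arbitrary data
  tc <- toy_incidence()
  inc2 <- incidence_table(tc$mem, tc$part, tc$sites)
  p2 <- rare_motu_profile(inc2, min_individuals = 2)
  expect_gte(p2$pct_sites[p2$cutoff == 0.2], p2$pct_sites[p2$cutoff == 0.1])
})

test_that("nestedness counts fine MOTUs per coarse MOTU and spots straddlers", {
  fine <- new_partition(paste0("H", 1:6), c("f1", "f1", "f2", "f3", "f4", "f4"))
  coarse <- new_partition(paste0("H", 1:6), c("c1", "c1", "c1", "c2", "c2", "c2"))
  out <- nestedness(fine, coarse)
  expect_equal(sort(out$per_coarse$n_fine), c(2L, 2L))
  expect_equal(out$max_fine, 2L)
  expect_length(out$violations, 0L)
  # identical partitions: all counts 1
  out2 <- nestedness(coarse, coarse)
  expect_true(all(out2$per_coarse$n_fine == 1L))
  # a straddling fine MOTU is reported, not fatal
  fine3 <- new_partition(paste0("H", 1:6), c("f1", "f1", "f1", "f1", "f2", "f2"))
  out3 <- nestedness(fine3, coarse)
  expect_equal(out3$violations, "f1")
  # singletons as fine partition: counts equal coarse MOTU sizes
  singles <- new_partition(paste0("H", 1:6), paste0("s", 1:6))
  out4 <- nestedness(singles, coarse)
  expect_equal(sort(out4$per_coarse$n_fine), c(3L, 3L))
})

test_that("concordance counts id sets shared by all partitions", {
  p1 <- new_partition(c("A", "B", "C"), c("x", "x", "y"))
  p2 <- new_partition(c("A", "B", "C"), c("u", "u", "v"))
  p3 <- new_partition(c("A", "B", "C"), c("1", "2", "3"))
  expect_equal(as.integer(concordance_count(list(p1, p2))), 2L)
  # {A,B}{C} vs {A,B}{C} vs {A}{B}{C} -> only {C} concordant
  expect_equal(as.integer(concordance_count(list(p1, p2, p3))), 1L)
  # identical partitions: k MOTUs
  expect_equal(as.integer(concordance_count(list(p3, p3))), 3L)
  # completely crossed partitions: 0
  q1 <- new_partition(c("A", "B", "C", "D"), c("x", "x", "y", "y"))
  q2 <- new_partition(c("A", "B", "C", "D"), c("u", "v", "u", "v"))
  expect_equal(as.integer(concordance_count(list(q1, q2))), 0L)
  # order invariance and brute-force agreement on random partitions
  set.seed(61)
  for (i in 1:20) {
    ids <- paste0("H", 1:12)
    ps <- lapply(1:3, function(j) new_partition(ids, sample(letters[1:4], 12,
                                                            replace = TRUE)))
    mine <- as.integer(concordance_count(ps))
    expect_equal(mine, brute_concordance(ps))
    expect_equal(mine, as.integer(concordance_count(rev(ps))))
  }
})

test_that("haversine matches the independent geosphere oracle", {
  # frozen from geosphere::distHaversine(r = 6371 km)
  expect_equal(haversine_km(45, 5, 45, 6), 78.6261876769, tolerance = 1e-8)
  expect_equal(haversine_km(44, 5, 52, 17), 1257.2943874, tolerance = 1e-7)
  expect_equal(haversine_km(45, 5, 45, 5), 0)
  skip_if_not_installed("geosphere")
  set.seed(62)
  for (i in 1:20) {
    a <- c(stats::runif(1, -60, 60), stats::runif(1, -170, 170))
    b <- c(stats::runif(1, -60, 60), stats::runif(1, -170, 170))
    expect_equal(haversine_km(a[1], a[2], b[1], b[2]),
                 geosphere::distHaversine(c(a[2], a[1]), c(b[2], b[1]),
                                          r = 6371000) / 1000,
                 tolerance = 1e-9)
  }
})

test_that("range classes follow the 100/1000 km cutpoints", {
  tc <- toy_incidence()
  inc <- incidence_table(tc$mem, tc$part, tc$sites)
  rc <- range_classes(inc, tc$sites)
  # MOTU C at one site: narrow, 0 km
  expect_equal(rc$max_km[rc$motu == "C"], 0)
  expect_equal(rc$range_class[rc$motu == "C"], "narrow")
  # MOTU A spans S1(45.7,5) .. S3(48.1,15): several hundred km -> broad
  expect_equal(rc$range_class[rc$motu == "A"], "broad")
  # widespread beyond 1000 km
  mem <- tibble::tibble(record_id = c("r1", "r2"), site_id = c("Sa", "Sb"),
                        haplotype_id = c("H1", "H1"))
  part <- new_partition("H1", "W")
  sites <- tibble::tibble(site_id = c("Sa", "Sb"), lat = c(44, 52),
                          lon = c(5, 17), altitude_m = c(0, 0), country = "XX")
  rcw <- range_classes(incidence_table(mem, part, sites), sites)
  expect_equal(rcw$range_class, "widespread")
  expect_error(range_classes(inc, tc$sites[1:2, ]), class = "cm_coverage_error")
})

test_that("latitude bands and altitude summaries follow their conventions", {
  tc <- toy_incidence()
  inc <- incidence_table(tc$mem, tc$part, tc$sites)
  lb <- latitudinal_bins(inc, tc$sites)
  # half-open bands: 45.7 falls in [45.5, 46)
  expect_true(45.5 %in% lb$band_lo)
  expect_equal(lb$n_motus[lb$band_lo == 45.5], 2L)  # A (S1) and C (S4 at 45.9)
  # a MOTU counts once per band even with several sites in it
  expect_true(all(lb$n_motus >= 1))
  alt <- altitudinal_summary(inc, tc$sites, min_sites = 3)
  # only MOTU A occupies >= 3 sites: altitudes {200, 400, 900}
  expect_equal(alt$per_motu$motu, "A")
  expect_equal(alt$per_motu$min, 200)
  expect_equal(alt$per_motu$mean, 500)
  expect_equal(alt$per_motu$max, 900)
  expect_true(all(alt$histogram$n_motus >= 1))
})
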