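square_sites <- function() {
  tibble::tibble(site_id = paste0("S", 1:4),
                 lat = c(44, 44, 46, 46), lon = c(5, 7, 5, 7),
                 altitude_m = 100, country = "XX")
}

test_that("delaunay network has the expected edge counts", {
  s3 <- square_sites()[1:3, ]
  e3 <- delaunay_network(s3)
  expect_equal(nrow(e3), 3L)
  # 4 sites in convex position: 4 hull edges + 1 diagonal (Euler: 3n-3-h)
  e4 <- delaunay_network(square_sites())
  expect_equal(nrow(e4), 5L)
  # edges unique, undirected, no self loops
  expect_true(all(e4$site_a != e4$site_b))
  expect_equal(anyDuplicated(e4[, c("site_a", "site_b")]), 0L)
  # midpoints are arithmetic means
  first <- e4[1, ]
  sa <- square_sites()[square_sites()$site_id == first$site_a, ]
  sb <- square_sites()[square_sites()$site_id == first$site_b, ]
  expect_equal(first$mid_lon, (sa$lon + sb$lon) / 2)
  expect_equal(first$mid_lat, (sa$lat + sb$lat) / 2)
  expect_error(delaunay_network(s3[1:2, ]), class = "cm_geometry_error")
  coll <- tibble::tibble(site_id = paste0("S", 1:3), lat = c(44, 45, 46),
                         lon = c(5, 5, 5), altitude_m = 0, country = "XX")
  expect_error(delaunay_network(coll), class = "cm_geometry_error")
})

test_that("intersite divergence weights cross pairs correctly", {
  m <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("H1", "H2"), c("H1", "H2")))
  # A = {H1 x2}, B = {H1 x1, H2 x1}: individual-weighted (2*0 + 2*0.2)/4 = 0.1
  sh <- tibble::tibble(site_id = c("A", "B", "B"),
                       haplotype_id = c("H1", "H1", "H2"), n = c(2L, 1L, 1L))
  expect_equal(intersite_divergence(sh, "A", "B", m), 0.1)
  # haplotype weighting ignores counts: (0 + 0.2)/2
  expect_equal(intersite_divergence(sh, "A", "B", m, weighting = "haplotype"), 0.1)
  sh2 <- tibble::tibble(site_id = c("A", "A", "B", "B"),
                        haplotype_id = c("H1", "H2", "H1", "H2"),
                        n = c(3L, 1L, 1L, 1L))
  expect_equal(intersite_divergence(sh2, "A", "B", m, weighting = "haplotype"),
               mean(c(0, 0.2, 0.2, 0)))
  # monomorphic identical sites diverge by zero
  sh3 <- tibble::tibble(site_id = c("A", "B"), haplotype_id = c("H1", "H1"),
                        n = c(2L, 5L))
  expect_equal(intersite_divergence(sh3, "A", "B", m), 0)
  expect_error(intersite_divergence(sh3, "A", "C", m), class = "cm_coverage_error")
})

test_that("IDW surface is exact at midpoints, bounded, and constant-preserving", {
  sites <- square_sites()
  edges <- delaunay_network(sites)
  # constant input -> constant surface
  edges$divergence <- 0.15
  g <- interpolate_surface(edges, sites, n_x = 21, n_y = 21)
  expect_true(all(abs(g$value[!g$masked] - 0.15) < 1e-12))
  # varying input stays within input extremes
  edges$divergence <- seq(0.05, 0.30, length.out = nrow(edges))
  g2 <- interpolate_surface(edges, sites, n_x = 25, n_y = 25)
  vals <- g2$value[!g2$masked]
  expect_gte(min(vals), 0.05 - 1e-12)
  expect_lte(max(vals), 0.30 + 1e-12)
  # a cell placed exactly on a midpoint takes that value
  mid <- edges[2, ]
  hit <- which(abs(g2$lon - mid$mid_lon) < 1e-9 & abs(g2$lat - mid$mid_lat) < 1e-9)
  if (length(hit)) expect_equal(g2$value[hit], mid$divergence)
  # masked cells lie outside the hull
  expect_true(all(is.na(g2$value[g2$masked])))
})

test_that("surface is invariant to edge order and consistent across resolutions", {
  sites <- square_sites()
  edges <- delaunay_network(sites)
  set.seed(71)
  edges$divergence <- stats::runif(nrow(edges), 0.02, 0.3)
  g1 <- interpolate_surface(edges, sites, n_x = 11, n_y = 11)
  g2 <- interpolate_surface(edges[sample.int(nrow(edges)), ], sites,
                            n_x = 11, n_y = 11)
  expect_equal(g1$value, g2$value)
  # doubling resolution minus one keeps old cell centers on the lattice
  g3 <- interpolate_surface(edges, sites, n_x = 21, n_y = 21)
  old <- g1[!g1$masked, ]
  match_idx <- vapply(seq_len(nrow(old)), function(i) {
    hit <- which(abs(g3$lon - old$lon[i]) < 1e-9 & abs(g3$lat - old$lat[i]) < 1e-9)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  keep <- !is.na(match_idx)
  expect_equal(g3$value[match_idx[keep]], old$value[keep], tolerance = 1e-9)
})

test_that("ESRI ASCII export round-trips the grid dimensions", {
  sites <- square_sites()
  edges <- delaunay_network(sites)
  edges$divergence <- 0.1
  g <- interpolate_surface(edges, sites, n_x = 12, n_y = 9)
  path <- withr::local_tempfile(fileext = ".asc")
  write_landscape_asc(g, path)
  hdr <- readLines(path, n = 6)
  expect_match(hdr[1], "^ncols 12$")
  expect_match(hdr[2], "^nrows 9$")
  body <- readLines(path)[-(1:6)]
  expect_length(body, 9L)
  expect_length(strsplit(body[1], " ")[[1]], 12L)
})

test_that("lineage exclusion filters records and reports what remains", {
  mem <- tibble::tibble(record_id = paste0("r", 1:6),
                        site_id = c("S1", "S1", "S2", "S2", "S3", "S3"),
                        haplotype_id = c("H1", "H2", "H2", "H3", "H4", "H4"))
  part <- new_partition(paste0("H", 1:4), c("A", "A", "B", "C"))
  # empty exclusion is the identity
  same <- exclude_lineages(mem, part, character(0))
  expect_equal(same$membership, mem)
  # excluding A removes H1,H2 records and empties S1
  out <- exclude_lineages(mem, part, "A")
  expect_equal(out$n_sites, 2L)
  expect_equal(out$n_haplotypes, 2L)
  expect_equal(out$n_records, 3L)
  # excluding everything flags the empty result
  all_out <- exclude_lineages(mem, part, c("A", "B", "C"))
  expect_true(all_out$empty)
  expect_error(exclude_lineages(mem, part, "Z"), class = "cm_coverage_error")
})
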