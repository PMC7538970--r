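# matrix whose upper-triangle distances are exactly the given values
matrix_from_distances <- function(d) {
  k <- length(d)
  n <- ceiling((1 + sqrt(1 + 8 * k)) / 2)
  stopifnot(n * (n - 1) / 2 == k)
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- d
  m <- m + t(m)
  dimnames(m) <- list(paste0("H", 1:n), paste0("H", 1:n))
  m
}

test_that("find_barcode_gap follows the scan rule on constructed ladders", {
  # distances {0.01, 0.02, 0.21, 0.22}: the only qualifying interval ending
  # at/above the prior 0.05 is (0.02, 0.21) -> threshold 0.02; the other
  # pairs stay undefined so the defined set IS those four values
  m4 <- matrix(NA_real_, 4, 4, dimnames = list(paste0("H", 1:4), paste0("H", 1:4)))
  m4[1, 2] <- 0.01; m4[1, 3] <- 0.02; m4[2, 4] <- 0.21; m4[3, 4] <- 0.22
  m4[lower.tri(m4)] <- t(m4)[lower.tri(m4)]
  diag(m4) <- 0
  expect_equal(find_barcode_gap(m4, prior_p = 0.05), 0.02)
  # all distances equal -> no positive-width interval
  meq <- matrix_from_distances(rep(0.1, 3))
  expect_true(is.na(find_barcode_gap(meq, prior_p = 0.05)))
  # all distances below the prior -> empty candidate set
  mlow <- matrix_from_distances(c(0.01, 0.02, 0.03))
  expect_true(is.na(find_barcode_gap(mlow, prior_p = 0.5)))
})

test_that("partition_at_threshold matches brute-force union-find", {
  set.seed(21)
  for (i in 1:60) {
    m <- random_distance_matrix(12, na_frac = 0.15)
    t <- stats::runif(1, 0, 0.4)
    p <- partition_at_threshold(m, t)
    oracle <- uf_components(m, t)
    expect_true(same_partition(p, new_partition(names(oracle), oracle)))
  }
  # single-linkage transitivity on a chain
  chain <- matrix_from_distances(c(0.01, 0.02, 0.01))  # A-B .01, A-C .02, B-C .01
  p <- partition_at_threshold(chain, 0.015)
  expect_equal(n_motus(p), 1L)
  # extremes
  m <- random_distance_matrix(8)
  expect_equal(n_motus(partition_at_threshold(m, max(m))), 1L)
  expect_equal(n_motus(partition_at_threshold(m, 0)), 8L)
})

test_that("MOTU count is non-increasing in the threshold", {
  set.seed(22)
  for (i in 1:10) {
    m <- random_distance_matrix(15)
    ts <- sort(stats::runif(8, 0, 0.4))
    counts <- vapply(ts, function(t) n_motus(partition_at_threshold(m, t)),
                     integer(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("between-MOTU minimum distance exceeds the threshold", {
  set.seed(23)
  for (i in 1:10) {
    m <- random_distance_matrix(12)
    t <- stats::runif(1, 0.05, 0.3)
    p <- partition_at_threshold(m, t)
    lab <- partition_labels(p)[rownames(m)]
    if (dplyr::n_distinct(lab) > 1) {
      between <- m[outer(lab, lab, "!=") & upper.tri(m)]
      expect_gt(min(between), t)
    }
  }
})

test_that("abgd primary recovers well-separated lineages and is stable", {
  set.seed(24)
  # 3 lineages: within <= 0.01, between >= 0.20
  ids <- paste0("H", 1:9)
  lin <- rep(1:3, each = 3)
  m <- matrix(0, 9, 9, dimnames = list(ids, ids))
  for (i in 1:8) for (j in (i + 1):9) {
    m[i, j] <- m[j, i] <- if (lin[i] == lin[j]) stats::runif(1, 0.002, 0.01)
      else stats::runif(1, 0.20, 0.24)
  }
  res <- delimit_abgd(m)
  expect_equal(n_motus(res$primary), 3L)
  # never under-split, and every prior above the within-lineage spread
  # finds exactly the 3 groups (smaller priors may over-split: with no
  # distances below the prior the baseline increment cannot calibrate)
  counts <- vapply(res$by_prior, n_motus, integer(1))
  expect_true(all(counts >= 3L))
  expect_true(all(counts[res$priors > 0.012] == 3L))
  # oracle: single-linkage components at t = 0.1 (inside the gap)
  oracle <- uf_components(m, 0.1)
  expect_equal(mclust::adjustedRandIndex(partition_labels(res$primary)[ids], oracle), 1)
  # all identical haplotypes -> single MOTU at every prior
  m0 <- matrix(0, 4, 4, dimnames = list(paste0("H", 1:4), paste0("H", 1:4)))
  res0 <- delimit_abgd(m0)
  expect_true(all(vapply(res0$by_prior, n_motus, integer(1)) == 1L))
  # fully undefined matrix refuses to delimit
  mna <- matrix(NA_real_, 3, 3, dimnames = list(paste0("H", 1:3), paste0("H", 1:3)))
  diag(mna) <- 0
  expect_error(delimit_abgd(mna), class = "cm_delimitation_error")
})

test_that("abgd config validates its invariants", {
  expect_error(abgd_config(p_min = 0.2, p_max = 0.1), class = "cm_config_error")
  expect_error(abgd_config(n_steps = 0), class = "cm_config_error")
  cfg <- abgd_config()
  expect_equal(cfg$p_min, 0.001)
  expect_equal(cfg$p_max, 0.1)
})
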