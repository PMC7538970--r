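test_that("k2p reproduces the closed form on constructed (P,Q) cases", {
  # 20 sites, 2 transitions (A->G), 1 transversion (A->C): P=0.10, Q=0.05
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c("G", "G", "C", rep("A", 17)), collapse = "")
  # frozen oracle: -0.5*log((1-2*0.1-0.05)*sqrt(1-2*0.05)) evaluated directly
  expect_equal(k2p(a, b, min_overlap = 20), 0.17018116514, tolerance = 1e-9)
  expect_equal(k2p(a, a, min_overlap = 20), 0)
  expect_error(k2p(a, "ACG"), class = "cm_alignment_error")
})

test_that("k2p is undefined under saturation and low overlap", {
  # P = 0.5, Q = 0: log argument 1-2P-Q = 0
  a <- paste(rep(c("A", "C"), 10), collapse = "")
  b <- paste(rep(c("G", "C"), 10), collapse = "")
  expect_true(is.na(k2p(a, b, min_overlap = 10)))
  # overlap below the floor
  a2 <- "AANNNN"; b2 <- "AACCGG"
  expect_true(is.na(k2p(a2, b2, min_overlap = 3)))
  expect_equal(k2p(a2, b2, min_overlap = 2), 0)
})

test_that("k2p agrees with ape::dist.dna on random sequence pairs", {
  set.seed(11)
  for (i in 1:20) {
    L <- 200
    x <- sample(c("a", "c", "g", "t"), L, replace = TRUE)
    nmut <- sample(5:60, 1)
    y <- x
    idx <- sample(L, nmut)
    y[idx] <- sample(c("a", "c", "g", "t"), nmut, replace = TRUE)
    bin <- ape::as.DNAbin(rbind(x, y))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    mine <- k2p(paste(x, collapse = ""), paste(y, collapse = ""), min_overlap = 10)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("k2p matrix is symmetric, zero-diagonal, and matches scalar k2p", {
  set.seed(3)
  seqs <- replicate(8, paste(sample(c("A", "C", "G", "T", "N"), 400,
                                    replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                             collapse = ""))
  haps <- tibble::tibble(haplotype_id = paste0("H", 1:8), sequence = seqs)
  m <- k2p_matrix(haps, min_overlap = 100)
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(diag(m), stats::setNames(rep(0, 8), haps$haplotype_id))
  for (pair in list(c(1, 2), c(3, 7), c(5, 8))) {
    expect_equal(m[pair[1], pair[2]],
                 k2p(seqs[pair[1]], seqs[pair[2]], min_overlap = 100),
                 tolerance = 1e-12)
  }
})

test_that("k2p is at least the p-distance and survives complementation", {
  set.seed(4)
  for (i in 1:10) {
    x <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
    y <- x
    idx <- sample(300, 40)
    y[idx] <- sample(c("A", "C", "G", "T"), 40, replace = TRUE)
    p_dist <- mean(x != y)
    d <- k2p(paste(x, collapse = ""), paste(y, collapse = ""), min_overlap = 10)
    expect_gte(d, p_dist - 1e-12)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    d2 <- k2p(paste(comp[x], collapse = ""), paste(comp[y], collapse = ""),
              min_overlap = 10)
    expect_equal(d, d2, tolerance = 1e-12)
  }
})

test_that("adding a duplicate haplotype row leaves existing entries unchanged", {
  set.seed(5)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                             collapse = ""))
  haps <- tibble::tibble(haplotype_id = paste0("H", 1:5), sequence = seqs)
  m1 <- k2p_matrix(haps, min_overlap = 10)
  haps2 <- rbind(haps, tibble::tibble(haplotype_id = "H6", sequence = seqs[1]))
  m2 <- k2p_matrix(haps2, min_overlap = 10)
  expect_equal(unclass(m2)[1:5, 1:5], unclass(m1)[1:5, 1:5])
  expect_equal(m2["H6", "H1"], 0)
})

test_that("distance histogram uses half-open bins and conserves pair counts", {
  m <- random_distance_matrix(10, na_frac = 0.1)
  h <- distance_histogram(m, bin_width = 0.01)
  n_def <- sum(!is.na(m[upper.tri(m)]))
  expect_equal(sum(h$count), n_def)
  # exact placement of a single value
  m2 <- matrix(c(0, 0.22, 0.22, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  h2 <- distance_histogram(m2, 0.01)
  expect_equal(h2$bin_lo, 0.22)
  expect_equal(h2$count, 1L)
  expect_error(distance_histogram(m, bin_width = 0), class = "cm_bounds_error")
})

test_that("within_between classifies by label equality and demands coverage", {
  m <- random_distance_matrix(6)
  one <- new_partition(rownames(m), rep("M1", 6))
  wb <- within_between(m, one)
  expect_true(all(wb$comparison == "within"))
  singletons <- new_partition(rownames(m), rownames(m))
  wb2 <- within_between(m, singletons)
  expect_true(all(wb2$comparison == "between"))
  expect_error(within_between(m, new_partition("H1", "M1")),
               class = "cm_coverage_error")
})
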