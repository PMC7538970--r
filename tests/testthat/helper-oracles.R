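# Independent oracles used by the tests. These deliberately use different
# algorithms/code paths from the package implementation.

# brute-force union-find single-linkage components at threshold t
uf_components <- function(m, t) {
  ids <- rownames(m)
  parent <- seq_along(ids)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (!is.na(m[i, j]) && m[i, j] <= t) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), ids)
}

# random symmetric distance matrix with optional NA pairs
random_distance_matrix <- function(n, na_frac = 0) {
  m <- matrix(0, n, n)
  v <- stats::runif(n * (n - 1) / 2, 0, 0.4)
  if (na_frac > 0) v[stats::runif(length(v)) < na_frac] <- NA
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- 0
  dimnames(m) <- list(paste0("H", seq_len(n)), paste0("H", seq_len(n)))
  m
}

# exhaustive PTP: enumerate every tip-covering antichain recursively and
# score it with per-edge exponential log-densities (not the package's
# aggregate shortcut)
enumerate_antichains <- function(tree) {
  ntip <- ape::Ntip(tree)
  kids <- vector("list", ntip + tree$Nnode)
  for (k in seq_len(nrow(tree$edge))) {
    kids[[tree$edge[k, 1]]] <- c(kids[[tree$edge[k, 1]]], tree$edge[k, 2])
  }
  rec <- function(v) {
    if (v <= ntip) return(list(v))
    subs <- lapply(kids[[v]], rec)
    combos <- subs[[1]]
    for (s in subs[-1]) {
      combos <- unlist(lapply(combos, function(a) lapply(s, function(b) c(a, b))),
                       recursive = FALSE)
    }
    c(list(v), combos)
  }
  rec(ntip + 1L)
}

loglik_per_edge <- function(tree, crowns) {
  ntip <- ape::Ntip(tree)
  inside <- rep(FALSE, nrow(tree$edge))
  for (cn in crowns) {
    if (cn <= ntip) next
    desc <- c(cn, unlist(phangorn::Descendants(tree, cn, type = "all")))
    inside <- inside | (tree$edge[, 1] %in% desc)
  }
  ll_class <- function(lens) {
    if (!length(lens)) return(0)
    lam <- length(lens) / sum(lens)
    sum(stats::dexp(lens, rate = lam, log = TRUE))
  }
  ll_class(tree$edge.length[inside]) + ll_class(tree$edge.length[!inside])
}

exhaustive_ptp <- function(tree) {
  acs <- enumerate_antichains(tree)
  lls <- vapply(acs, function(cr) loglik_per_edge(tree, cr), numeric(1))
  list(crowns = sort(acs[[which.max(lls)]]), loglik = max(lls))
}

# brute-force concordance: id sets present as a block in every partition
brute_concordance <- function(partitions) {
  blocks <- lapply(partitions, function(p) {
    unname(lapply(split(p$haplotype_id, p$motu), sort))
  })
  common <- 0L
  for (b in blocks[[1]]) {
    in_all <- all(vapply(blocks[-1], function(bl) {
      any(vapply(bl, identical, logical(1), b))
    }, logical(1)))
    if (in_all) common <- common + 1L
  }
  common
}

# small test fixtures -------------------------------------------------------

# 8 tips in 4 tight cherries joined by deep branches; distances constructed
# directly (within cherry 0.02, between cherries >= 0.21)
lagrue_fixture <- function() {
  tips <- LETTERS[1:8]
  m <- matrix(0.22, 8, 8, dimnames = list(tips, tips))
  cherries <- list(c(1, 2), c(3, 4), c(5, 6), c(7, 8))
  for (ch in cherries) m[ch, ch] <- 0.02
  # nearer cherries slightly less divergent, still above the 0.20 cutoff
  m[1:4, 5:8] <- 0.25
  m[5:8, 1:4] <- 0.25
  diag(m) <- 0
  tree <- ape::read.tree(text = "(((A:0.01,B:0.01):0.1,(C:0.01,D:0.01):0.1):0.05,((E:0.01,F:0.01):0.1,(G:0.01,H:0.01):0.1):0.05);")
  list(tree = tree, m = m)
}

# toy alignment with known haplotype structure
toy_alignment <- function() {
  barcode_alignment(tibble::tibble(
    record_id = paste0("r", 1:6),
    site_id = c("S1", "S1", "S1", "S2", "S2", "S2"),
    sequence = c("AAAT", "AAAT", "AATT", "AAAT", "CCCT", "CCCT")
  ))
}
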