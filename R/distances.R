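#' Kimura two-parameter distance between two aligned sequences
#'
#' Only columns where both sequences carry an unambiguous base (A/C/G/T)
#' are compared (pairwise deletion of gaps, `N` and ambiguity codes). With
#' transition proportion `P` and transversion proportion `Q` over those
#' columns, the distance is `-1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`
#' substitutions/site. The value is undefined (`NA`) when fewer than
#' `min_overlap` columns are comparable or when a log argument is
#' non-positive (saturation).
#'
#' @param a,b Aligned sequences (equal-length strings).
#' @param min_overlap Minimum number of comparable sites (default 300,
#'   matching the shortest sequences admitted to MOTU assignment).
#' @return K2P distance, or `NA_real_` if undefined.
#' @export
k2p <- function(a, b, min_overlap = 300) {
  if (nchar(a) != nchar(b)) abort("sequences differ in length", class = "cm_alignment_error")
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(toupper(b), "")[[1]]
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n < min_overlap) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  diffs <- x != y
  purine_x <- x %in% c("A", "G")
  purine_y <- y %in% c("A", "G")
  ts <- sum(diffs & (purine_x == purine_y))
  tv <- sum(diffs & (purine_x != purine_y))
  k2p_from_pq(ts / n, tv / n)
}

# closed form; NA when outside the model's domain (saturation)
k2p_from_pq <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  ok <- !is.na(w1) & !is.na(w2) & w1 > 0 & w2 > 0
  d <- -0.5 * log(ifelse(ok, w1, 1) * sqrt(ifelse(ok, w2, 1)))
  d[!ok] <- NA_real_
  d
}

# inverse map used by the simulator's calibration: distance for given
# transition/transversion *probabilities* is k2p_from_pq; this solves the
# per-site hit intensity that yields a target expected K2P under the
# two-rate mutation kernel (see simulate_barcodes).
encode_dna <- function(seqs) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  code <- match(m, c("A", "C", "G", "T"))
  dim(code) <- dim(m)
  code
}

#' K2P distance matrix among haplotypes
#'
#' Computes all pairwise K2P distances with pairwise deletion. Undefined
#' pairs (overlap below `min_overlap`, or saturated) are `NA` and listed in
#' the `undefined_pairs` attribute.
#'
#' @param haps A `haplotype_table` from [collapse_haplotypes()], or any data
#'   frame with columns `haplotype_id` and `sequence`.
#' @param min_overlap Minimum comparable sites per pair (default 300).
#' @return A symmetric numeric matrix of class `k2p_dist` with dimnames set
#'   to the haplotype ids and zero diagonal.
#' @export
k2p_matrix <- function(haps, min_overlap = 300) {
  ids <- haps$haplotype_id
  if (length(ids) < 2L) abort("need at least two haplotypes", class = "cm_empty_input")
  code <- encode_dna(haps$sequence)
  n <- length(ids)
  # indicator algebra: per-base incidence matrices give, for every pair,
  # the comparable-site count, matches, and transition counts in a handful
  # of dense products instead of an O(n^2 L) loop
  ind <- lapply(1:4, function(b) {
    M <- code == b
    M[is.na(M)] <- FALSE
    storage.mode(M) <- "double"
    M
  })
  valid <- ind[[1]] + ind[[2]] + ind[[3]] + ind[[4]]
  overlap <- valid %*% t(valid)
  same <- Reduce(`+`, lapply(ind, function(M) M %*% t(M)))
  ts <- ind[[1]] %*% t(ind[[3]]) + ind[[3]] %*% t(ind[[1]]) +  # A<->G
    ind[[2]] %*% t(ind[[4]]) + ind[[4]] %*% t(ind[[2]])        # C<->T
  diff <- overlap - same
  tv <- diff - ts
  P <- ts / overlap
  Q <- tv / overlap
  d <- k2p_from_pq(P, Q)
  d[overlap < min_overlap] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  undef <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
  attr(d, "min_overlap") <- min_overlap
  attr(d, "undefined_pairs") <- tibble(id_a = ids[undef[, 1]], id_b = ids[undef[, 2]])
  class(d) <- c("k2p_dist", "matrix", "array")
  d
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- nrow(x)
  nu <- nrow(attr(x, "undefined_pairs"))
  cat(sprintf("<k2p_dist> %d haplotypes, %d pairs (%d undefined)\n",
              n, n * (n - 1) / 2, nu))
  invisible(x)
}

#' @export
tidy.k2p_dist <- function(x, ...) {
  ids <- rownames(x)
  ut <- which(upper.tri(x), arr.ind = TRUE)
  tibble(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]], distance = x[ut]) |>
    arrange(.data$id_a, .data$id_b)
}

# defined upper-triangle distances as a plain vector
pairwise_distances <- function(m) {
  v <- m[upper.tri(m)]
  v[!is.na(v)]
}

#' Histogram of pairwise K2P distances
#'
#' Bins the defined upper-triangle entries into half-open bins
#' `[lo, lo + bin_width)`.
#'
#' @param m A `k2p_dist` matrix.
#' @param bin_width Bin width in substitutions/site (default 0.01).
#' @return Tibble with columns `bin_lo`, `bin_hi`, `count`.
#' @export
distance_histogram <- function(m, bin_width = 0.01) {
  if (bin_width <= 0) abort("bin_width must be positive", class = "cm_bounds_error")
  v <- pairwise_distances(m)
  idx <- floor(v / bin_width)
  tab <- table(idx)
  tibble(bin_lo = as.numeric(names(tab)) * bin_width,
         bin_hi = (as.numeric(names(tab)) + 1) * bin_width,
         count = as.integer(tab))
}

#' Decompose pairwise distances within vs between MOTUs
#'
#' @param m A `k2p_dist` matrix.
#' @param partition A `motu_partition` covering all matrix ids.
#' @return Tibble with columns `id_a`, `id_b`, `distance`, `comparison`
#'   (`"within"` / `"between"`), restricted to defined pairs.
#' @export
within_between <- function(m, partition) {
  ids <- rownames(m)
  miss <- setdiff(ids, partition$haplotype_id)
  if (length(miss)) {
    abort(paste0("partition does not cover matrix id(s): ",
                 paste(utils::head(miss, 5), collapse = ", ")),
          class = "cm_coverage_error")
  }
  lab <- partition_labels(partition)
  tidy.k2p_dist(m) |>
    filter(!is.na(.data$distance)) |>
    mutate(comparison = ifelse(lab[.data$id_a] == lab[.data$id_b],
                               "within", "between"))
}

#' Plot a pairwise-distance histogram
#'
#' @param m A `k2p_dist` matrix.
#' @param bin_width Bin width (default 0.01).
#' @return A ggplot.
#' @export
plot_distance_histogram <- function(m, bin_width = 0.01) {
  h <- distance_histogram(m, bin_width)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_lo + bin_width / 2, y = .data$count)) +
    ggplot2::geom_col(width = bin_width, fill = "grey35") +
    ggplot2::labs(x = "K2P distance (substitutions/site)", y = "haplotype pairs") +
    ggplot2::theme_minimal()
}
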