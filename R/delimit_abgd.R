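#' ABGD-style configuration
#'
#' Parameters of barcode-gap discovery: a ladder of prior maximum
#' intraspecific distances (log-spaced from `p_min` to `p_max`) and the
#' relative gap-width factor.
#'
#' @param p_min Minimum prior intraspecific distance (default 0.001).
#' @param p_max Maximum prior explored (default 0.1).
#' @param n_steps Number of priors on the log-spaced ladder (default 10).
#' @param gap_factor Relative gap width `X` a candidate interval must exceed
#'   (default 1.5).
#' @return A list of class `abgd_config`.
#' @export
abgd_config <- function(p_min = 0.001, p_max = 0.1, n_steps = 10, gap_factor = 1.5) {
  if (!(p_min > 0 && p_min < p_max && p_max < 1)) {
    abort("need 0 < p_min < p_max < 1", class = "cm_config_error")
  }
  if (n_steps < 1 || gap_factor <= 0) abort("n_steps >= 1 and gap_factor > 0 required",
                                            class = "cm_config_error")
  structure(list(p_min = p_min, p_max = p_max, n_steps = as.integer(n_steps),
                 gap_factor = gap_factor),
            class = "abgd_config")
}

#' Find a barcode gap in a set of pairwise distances
#'
#' Sorts the defined pairwise distances and scans consecutive intervals
#' `(d_i, d_{i+1})`. The baseline increment `b` is the 95th percentile of
#' consecutive differences among distances at or below the prior (0 if fewer
#' than two such distances). A candidate gap must end at or above the prior
#' (`d_{i+1} >= prior_p`; distances below the prior are presumed
#' intraspecific) and be wider than `X * max(b, prior_p / 10)`. The widest
#' qualifying interval wins, ties going to the smaller threshold, and its
#' lower endpoint `d_i` is returned as the partitioning threshold.
#'
#' @param m A `k2p_dist` matrix (or any symmetric matrix with `NA` for
#'   undefined pairs).
#' @param prior_p Prior maximum intraspecific distance.
#' @param gap_factor Relative width factor `X` (default 1.5).
#' @return The threshold distance, or `NA_real_` if no interval qualifies.
#' @export
find_barcode_gap <- function(m, prior_p, gap_factor = 1.5) {
  d <- sort(pairwise_distances(m))
  if (length(d) < 2L) return(NA_real_)
  gaps <- diff(d)
  low <- d[d <= prior_p]
  b <- if (length(low) >= 2L) stats::quantile(diff(low), 0.95, names = FALSE) else 0
  min_width <- gap_factor * max(b, prior_p / 10)
  cand <- which(d[-1] >= prior_p & gaps > min_width)
  if (!length(cand)) return(NA_real_)
  best <- cand[which.max(gaps[cand])]  # which.max takes the first = smaller threshold
  d[best]
}

#' Single-linkage partition of a distance matrix at a threshold
#'
#' MOTUs are the connected components of the graph joining every pair at
#' distance `<= t`; undefined pairs contribute no edge.
#'
#' @param m A `k2p_dist` (or symmetric numeric) matrix.
#' @param t Distance threshold (>= 0).
#' @param method Method tag stored on the partition (default `"ABGD"`).
#' @return A `motu_partition`; labels are `M001`, ... in order of first
#'   member appearance.
#' @export
partition_at_threshold <- function(m, t, method = "ABGD") {
  if (t < 0) abort("threshold must be >= 0", class = "cm_bounds_error")
  ids <- rownames(m)
  adj <- !is.na(m) & m <= t
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  relabelled_partition(ids, comp, method = method, provenance = list(threshold = t))
}

# relabel integer components M001.. in order of first appearance
relabelled_partition <- function(ids, comp, method, provenance = list()) {
  first <- comp[!duplicated(comp)]
  lab <- sprintf("M%03d", match(comp, first))
  new_partition(ids, lab, method = method, provenance = provenance)
}

# recursive gap splitting inside one group of ids
abgd_recurse <- function(m, ids, prior_p, gap_factor) {
  if (length(ids) < 2L) return(list(ids))
  sub <- m[ids, ids, drop = FALSE]
  t <- find_barcode_gap(sub, prior_p, gap_factor)
  if (is.na(t)) return(list(ids))
  p <- partition_at_threshold(sub, t)
  groups <- split(p$haplotype_id, p$motu)
  if (length(groups) < 2L) return(list(ids))
  unlist(lapply(groups, function(g) abgd_recurse(m, g, prior_p, gap_factor)),
         recursive = FALSE)
}

#' ABGD-style delimitation with primary partition
#'
#' For each prior on the ladder, barcode-gap discovery and single-linkage
#' splitting are applied recursively inside every group until no group shows
#' a gap. The primary partition is the one observed over the longest
#' contiguous run of priors (ties broken toward larger priors) — the stable,
#' conservative output.
#'
#' @param m A `k2p_dist` matrix.
#' @param config An [abgd_config()].
#' @return A list of class `abgd_result`: `primary` (`motu_partition`),
#'   `by_prior` (named list of partitions), `priors` (numeric ladder).
#' @export
delimit_abgd <- function(m, config = abgd_config()) {
  if (all(is.na(m[upper.tri(m)]))) {
    abort("all pairwise distances are undefined", class = "cm_delimitation_error")
  }
  priors <- exp(seq(log(config$p_min), log(config$p_max),
                    length.out = config$n_steps))
  ids <- rownames(m)
  by_prior <- lapply(priors, function(p) {
    groups <- abgd_recurse(m, ids, p, config$gap_factor)
    comp <- integer(length(ids)); names(comp) <- ids
    for (i in seq_along(groups)) comp[groups[[i]]] <- i
    relabelled_partition(ids, comp[ids], method = "ABGD",
                         provenance = list(prior = p,
                                           gap_factor = config$gap_factor))
  })
  names(by_prior) <- sprintf("p=%.5f", priors)
  keys <- vapply(by_prior, partition_key, character(1))
  runs <- rle(keys)
  ends <- cumsum(runs$lengths)
  # longest run; ties -> later (larger-prior) run
  best <- max(which(runs$lengths == max(runs$lengths)))
  primary <- by_prior[[ends[best]]]
  attr(primary, "provenance") <- c(attr(primary, "provenance"),
                                   list(run_length = runs$lengths[best]))
  structure(list(primary = primary, by_prior = by_prior, priors = priors),
            class = "abgd_result")
}

#' @export
print.abgd_result <- function(x, ...) {
  counts <- vapply(x$by_prior, n_motus, integer(1))
  cat("<abgd_result>\n  priors:", signif(x$priors, 3), "\n  MOTUs: ",
      counts, "\n  primary:", n_motus(x$primary), "MOTUs\n")
  invisible(x)
}

#' @export
glance.abgd_result <- function(x, ...) {
  tibble(method = "ABGD", n_motus = n_motus(x$primary),
         n_priors = length(x$priors),
         stable_run = attr(x$primary, "provenance")$run_length)
}

#' @export
tidy.abgd_result <- function(x, ...) tidy(x$primary)
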