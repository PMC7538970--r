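# root-to-tip path lengths of a rooted phylo
root_tip_depths <- function(tree) {
  depths <- ape::node.depth.edgelength(tree)
  depths[seq_len(ape::Ntip(tree))]
}

#' Is a rooted tree ultrametric (within tolerance)?
#'
#' @param tree A rooted `phylo`.
#' @param tol Relative tolerance on root-to-tip path spread, as a fraction
#'   of tree height (default 1e-6).
#' @return Logical.
#' @export
is_ultrametric <- function(tree, tol = 1e-6) {
  d <- root_tip_depths(tree)
  h <- max(d)
  h == 0 || (max(d) - min(d)) <= tol * h
}

#' Rescale a substitutions/site tree to time with a strict clock
#'
#' Divides every branch length by the clock rate, turning an ultrametric
#' tree in substitutions/site into a chronogram in My. The default rate is
#' the conventional arthropod COI rate of 0.0115 substitutions/site/My.
#'
#' @param tree A rooted ultrametric `phylo` with branch lengths in
#'   substitutions/site.
#' @param rate Clock rate, substitutions/site/My (default 0.0115).
#' @param tol Ultrametricity tolerance passed to [is_ultrametric()].
#' @return A `chronogram`: a `phylo` with branch lengths in My and a
#'   `root_age` attribute.
#' @export
rescale_to_time <- function(tree, rate = 0.0115, tol = 1e-6) {
  if (rate <= 0) abort("clock rate must be > 0", class = "cm_config_error")
  if (!is_ultrametric(tree, tol)) {
    abort("tree is not ultrametric at the current tolerance; raise `tol` or supply a chronogram",
          class = "cm_clock_error")
  }
  tree$edge.length <- tree$edge.length / rate
  attr(tree, "root_age") <- max(root_tip_depths(tree))
  class(tree) <- c("chronogram", class(tree))
  tree
}

#' Lineage-through-time table of a chronogram
#'
#' One row per internal node, ordered from the root toward the present:
#' `time_my` is the node's age (time before present) and `n_lineages` the
#' number of reconstructed lineages immediately after that node's split.
#' Counts start at 2 after the root and end at the tip count.
#'
#' @param chron A rooted ultrametric `phylo`/`chronogram` in My.
#' @return Tibble with columns `time_my`, `n_lineages`.
#' @export
ltt_table <- function(chron) {
  ntip <- ape::Ntip(chron)
  depths <- ape::node.depth.edgelength(chron)
  h <- max(depths[seq_len(ntip)])
  internal <- (ntip + 1L):(ntip + chron$Nnode)
  ages <- h - depths[internal]
  ord <- order(ages, decreasing = TRUE)
  tibble(time_my = ages[ord], n_lineages = seq_along(internal) + 1L)
}

#' Plot a lineage-through-time curve
#'
#' @param chron A `chronogram` (or its [ltt_table()]).
#' @return A ggplot with time running toward the present.
#' @export
plot_ltt <- function(chron) {
  tab <- if (is.data.frame(chron)) chron else ltt_table(chron)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$time_my, y = .data$n_lineages)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "time before present (My)", y = "lineages") +
    ggplot2::theme_minimal()
}

# tips (labels) under each node, indexed by node id
node_tip_sets <- function(tree) {
  ntip <- ape::Ntip(tree)
  all_nodes <- seq_len(ntip + tree$Nnode)
  lapply(all_nodes, function(nd) {
    if (nd <= ntip) tree$tip.label[nd]
    else tree$tip.label[phangorn::Descendants(tree, nd, "tips")[[1]]]
  })
}

# between-group distance over defined pairs
between_group_distance <- function(m, a, b, linkage = "mean") {
  vals <- m[a, b, drop = FALSE]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_real_)
  if (linkage == "mean") mean(vals) else min(vals)
}

#' Sister-clade MOTUs from a divergence cutoff (Lagrue rule)
#'
#' Post-order agglomeration over a rooted tree: every tip starts as its own
#' group; at an internal node whose two child clades each currently form a
#' single group, the two groups merge if their between-group K2P distance
#' is at or below the cutoff. Once a child clade holds several groups, no
#' merge happens at or above it, so every MOTU is a clade. The default
#' 0.20 cutoff is the conservative reproductive-isolation calibration:
#' lineage pairs near 4% K2P mate randomly while pairs near 16% are
#' isolated.
#'
#' @param tree A rooted `phylo` whose tips appear in `m`.
#' @param m A `k2p_dist` matrix.
#' @param cutoff K2P divergence above which sister clades are distinct
#'   MOTUs (default 0.20).
#' @param linkage Between-clade distance summary over defined pairs:
#'   `"mean"` (default) or `"min"`.
#' @return A `motu_partition` with method `"LAGRUE"`.
#' @export
delimit_lagrue <- function(tree, m, cutoff = 0.20, linkage = c("mean", "min")) {
  linkage <- match.arg(linkage)
  if (cutoff <= 0) abort("cutoff must be > 0", class = "cm_config_error")
  miss <- setdiff(tree$tip.label, rownames(m))
  if (length(miss)) {
    abort(paste0("tree tip(s) missing from matrix: ", paste(miss, collapse = ", ")),
          class = "cm_coverage_error")
  }
  ntip <- ape::Ntip(tree)
  children <- node_children(tree)
  # group id per tip label; single-group flag per node, filled post-order
  group <- setNames(seq_len(ntip), tree$tip.label)
  post <- rev(unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1]))
  node_group <- c(seq_len(ntip), rep(NA_integer_, tree$Nnode))  # NA = multi-group
  for (nd in post) {
    ch <- children[[nd]]
    gs <- node_group[ch]
    if (length(ch) == 2L && !anyNA(gs)) {
      a <- names(group)[group == gs[1]]
      b <- names(group)[group == gs[2]]
      d <- between_group_distance(m, a, b, linkage)
      if (!is.na(d) && d <= cutoff) {
        group[group == gs[2]] <- gs[1]
        node_group[nd] <- gs[1]
      }
    }
  }
  relabelled_partition(tree$tip.label, unname(group[tree$tip.label]),
                       method = "LAGRUE",
                       provenance = list(cutoff = cutoff, linkage = linkage))
}

#' Sister-clade pairs of a rooted tree
#'
#' One row per internal node: the two child clades' tip sets and, when a
#' distance matrix is supplied, their between-clade divergence. Used to
#' count sister pairs exceeding a divergence cutoff.
#'
#' @param tree A rooted binary `phylo`.
#' @param m Optional `k2p_dist` matrix covering the tips.
#' @param linkage Between-clade summary (`"mean"` or `"min"`).
#' @return Tibble with columns `node`, `tips_a`, `tips_b` (list-columns)
#'   and, if `m` is given, `distance`.
#' @export
sister_pairs <- function(tree, m = NULL, linkage = c("mean", "min")) {
  linkage <- match.arg(linkage)
  ntip <- ape::Ntip(tree)
  children <- node_children(tree)
  tip_sets <- node_tip_sets(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  out <- tibble(
    node = internal,
    tips_a = lapply(internal, function(nd) tip_sets[[children[[nd]][1]]]),
    tips_b = lapply(internal, function(nd) tip_sets[[children[[nd]][2]]])
  )
  if (!is.null(m)) {
    out$distance <- purrr::map2_dbl(out$tips_a, out$tips_b,
                                    function(a, b) between_group_distance(m, a, b, linkage))
  }
  out
}
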