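#' RESL/BIN-style configuration
#'
#' @param t_intra Initial single-linkage threshold (default 0.022
#'   substitutions/site).
#' @param t_isolation Inter-cluster isolation floor: clusters closer than
#'   this are merge candidates (default 0.044, twice `t_intra`).
#' @param len_full Minimum sequence length (called bases) to found a cluster
#'   (default 500 nt).
#' @param len_assign Minimum length to be assigned to an existing cluster
#'   (default 300 nt).
#' @param silhouette_min Mean-silhouette threshold above which an internal
#'   bipartition counts as a discontinuity (default 0.5).
#' @return A list of class `resl_config`.
#' @export
resl_config <- function(t_intra = 0.022, t_isolation = 0.044,
                        len_full = 500, len_assign = 300,
                        silhouette_min = 0.5) {
  if (!(t_intra > 0 && t_intra < t_isolation)) {
    abort("need 0 < t_intra < t_isolation", class = "cm_config_error")
  }
  if (!(len_assign < len_full)) abort("need len_assign < len_full", class = "cm_config_error")
  structure(list(t_intra = t_intra, t_isolation = t_isolation,
                 len_full = len_full, len_assign = len_assign,
                 silhouette_min = silhouette_min),
            class = "resl_config")
}

# mean silhouette of a 2-group labelling of ids under distance matrix m;
# NA entries are replaced by the largest observed distance (they separate)
mean_silhouette <- function(m, labels) {
  if (dplyr::n_distinct(labels) < 2L) return(-Inf)
  mm <- unclass(m)
  big <- max(mm, na.rm = TRUE)
  mm[is.na(mm)] <- big * 2 + 1e-6
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = mm)
  mean(sil[, "sil_width"])
}

# top single-linkage bipartition of a group; NULL if group too small
top_cut <- function(m, ids) {
  if (length(ids) < 3L) return(NULL)
  sub <- unclass(m)[ids, ids]
  big <- max(sub, na.rm = TRUE)
  sub[is.na(sub)] <- big * 2 + 1e-6
  hc <- stats::hclust(stats::as.dist(sub), method = "single")
  split(ids, stats::cutree(hc, k = 2))
}

# does a set of ids show an internal discontinuity? (top dendrogram cut
# with mean silhouette >= threshold)
has_discontinuity <- function(m, ids, silhouette_min) {
  cut <- top_cut(m, ids)
  if (is.null(cut)) return(FALSE)
  labels <- stats::setNames(rep(seq_along(cut), lengths(cut)), unlist(cut))[ids]
  mean_silhouette(m[ids, ids, drop = FALSE], labels) >= silhouette_min
}

#' Initial RESL clustering of full-length haplotypes
#'
#' Single-linkage components at `t_intra`, followed by the isolation rule:
#' any two clusters whose minimum between-cluster distance is at or below
#' `t_isolation` are merged unless the merged set shows an internal
#' discontinuity (a single-linkage dendrogram cut with mean silhouette at or
#' above `silhouette_min`). Candidate merges are processed in order of
#' increasing between-cluster distance until none remains.
#'
#' @param m A `k2p_dist` matrix restricted to full-length haplotypes.
#' @param config A [resl_config()].
#' @return A `motu_partition` with method `"RESL"`.
#' @export
resl_initial_clusters <- function(m, config = resl_config()) {
  p <- partition_at_threshold(m, config$t_intra, method = "RESL")
  groups <- unname(split(p$haplotype_id, p$motu))
  repeat {
    if (length(groups) < 2L) break
    # minimum between-cluster distance for every cluster pair
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq((i + 1L), length(groups))) {
        dij <- suppressWarnings(min(m[groups[[i]], groups[[j]]], na.rm = TRUE))
        if (is.finite(dij) && dij <= config$t_isolation && dij < best_d) {
          merged <- c(groups[[i]], groups[[j]])
          if (!has_discontinuity(m, merged, config$silhouette_min)) {
            best <- c(i, j); best_d <- dij
          }
        }
      }
    }
    if (is.null(best)) break
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  groups_to_partition(rownames(m), groups, method = "RESL",
                      provenance = list(t_intra = config$t_intra,
                                        t_isolation = config$t_isolation))
}

groups_to_partition <- function(ids, groups, method, provenance = list()) {
  comp <- integer(length(ids)); names(comp) <- ids
  for (i in seq_along(groups)) comp[groups[[i]]] <- i
  relabelled_partition(ids, comp[ids], method = method, provenance = provenance)
}

#' Refine RESL clusters by internal discontinuities
#'
#' Within each cluster the top cut of its single-linkage dendrogram is
#' evaluated; if its mean silhouette reaches `silhouette_min` the cluster is
#' split there, and the rule is applied recursively to the parts. This
#' splits clusters with clear internal partitions even when their separation
#' is below `t_intra`, while high-variation clusters without discontinuity
#' stay whole.
#'
#' @param partition A `motu_partition` from [resl_initial_clusters()].
#' @param m The `k2p_dist` matrix used for clustering.
#' @param config A [resl_config()].
#' @return A refined `motu_partition`.
#' @export
resl_refine <- function(partition, m, config = resl_config()) {
  refine_group <- function(ids) {
    cut <- top_cut(m, ids)
    if (is.null(cut)) return(list(ids))
    labels <- stats::setNames(rep(seq_along(cut), lengths(cut)), unlist(cut))[ids]
    if (mean_silhouette(m[ids, ids, drop = FALSE], labels) >= config$silhouette_min) {
      unlist(lapply(cut, refine_group), recursive = FALSE)
    } else {
      list(ids)
    }
  }
  groups <- unlist(lapply(unname(split(partition$haplotype_id, partition$motu)),
                          refine_group),
                   recursive = FALSE)
  groups_to_partition(partition$haplotype_id, groups, method = "RESL",
                      provenance = c(attr(partition, "provenance"),
                                     list(silhouette_min = config$silhouette_min)))
}

#' Assign short sequences to RESL clusters
#'
#' Sequences long enough to be assigned but too short to found a cluster
#' (`len_assign <= length < len_full`) join the cluster of their nearest
#' full-length haplotype if that distance is at or below `t_intra`;
#' otherwise each becomes a flagged BIN-equivalent singleton MOTU.
#' Sequences shorter than `len_assign` are rejected.
#'
#' @param partition Final partition over full-length haplotypes.
#' @param m A `k2p_dist` matrix covering full-length and short ids.
#' @param lengths Named integer vector: called-base length per matrix id.
#' @param config A [resl_config()].
#' @return A `motu_partition` over full + admissible short ids, with
#'   attributes `bin_equivalent` (character vector of flagged singleton ids)
#'   and `rejected` (ids below `len_assign`).
#' @export
resl_assign_short <- function(partition, m, lengths, config = resl_config()) {
  full_ids <- partition$haplotype_id
  other <- setdiff(rownames(m), full_ids)
  short_ids <- other[lengths[other] >= config$len_assign]
  rejected <- other[lengths[other] < config$len_assign]
  if (length(rejected)) {
    inform(paste0("rejected (shorter than ", config$len_assign, " nt): ",
                  paste(rejected, collapse = ", ")))
  }
  lab <- partition_labels(partition)
  bin_equiv <- character(0)
  out_ids <- full_ids
  out_lab <- unname(lab[full_ids])
  for (s in short_ids) {
    d <- m[s, full_ids]
    if (all(is.na(d))) nearest <- NA_integer_ else nearest <- which.min(d)
    if (!is.na(nearest) && d[nearest] <= config$t_intra) {
      out_lab <- c(out_lab, unname(lab[full_ids[nearest]]))
    } else {
      new_lab <- paste0("BINEQ_", s)
      out_lab <- c(out_lab, new_lab)
      bin_equiv <- c(bin_equiv, s)
    }
    out_ids <- c(out_ids, s)
  }
  out <- new_partition(out_ids, out_lab, method = "RESL",
                       provenance = attr(partition, "provenance"))
  attr(out, "bin_equivalent") <- bin_equiv
  attr(out, "rejected") <- rejected
  out
}

#' RESL/BIN-style delimitation
#'
#' Runs [resl_initial_clusters()], [resl_refine()] and, when sequence
#' lengths are supplied, [resl_assign_short()]: full-length ids
#' (`length >= len_full`) found clusters, shorter admissible ids are
#' assigned or flagged BIN-equivalent.
#'
#' @param m A `k2p_dist` matrix over all haplotypes.
#' @param lengths Optional named vector of called-base lengths per id; when
#'   `NULL` every id is treated as full-length.
#' @param config A [resl_config()].
#' @return A `motu_partition` with method `"RESL"`.
#' @export
delimit_resl <- function(m, lengths = NULL, config = resl_config()) {
  ids <- rownames(m)
  if (is.null(lengths)) lengths <- stats::setNames(rep(config$len_full, length(ids)), ids)
  full <- ids[lengths[ids] >= config$len_full]
  if (!length(full)) abort("no full-length haplotype to found clusters",
                           class = "cm_delimitation_error")
  mf <- m[full, full, drop = FALSE]
  p <- resl_initial_clusters(mf, config)
  p <- resl_refine(p, mf, config)
  if (length(full) < length(ids)) p <- resl_assign_short(p, m, lengths, config)
  p
}
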