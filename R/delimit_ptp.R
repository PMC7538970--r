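#' @importFrom stats setNames runif
NULL

# for each edge, TRUE if it lies strictly inside some crown subtree
# (its parent node is a crown node or a descendant of one)
edge_within_class <- function(tree, crown_nodes) {
  ord <- ape::reorder.phylo(tree, "cladewise")
  nn <- ape::Ntip(tree) + tree$Nnode
  cover <- rep(FALSE, nn)
  cover[crown_nodes] <- TRUE
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    if (cover[p]) cover[ch] <- TRUE
  }
  within <- cover[tree$edge[, 1]]
  within
}

# validate a crown set: pairwise non-nested, tips all covered
validate_crowns <- function(tree, crown_nodes) {
  within <- edge_within_class(tree, crown_nodes)
  cover <- rep(FALSE, ape::Ntip(tree) + tree$Nnode)
  cover[crown_nodes] <- TRUE
  cover[tree$edge[within, 2]] <- TRUE
  if (!all(cover[seq_len(ape::Ntip(tree))])) {
    abort("crown nodes do not cover all tips", class = "cm_tree_error")
  }
  internal <- crown_nodes[crown_nodes > ape::Ntip(tree)]
  if (length(internal)) {
    desc <- unlist(phangorn::Descendants(tree, internal, type = "all"))
    if (any(desc %in% crown_nodes)) {
      abort("crown nodes are nested", class = "cm_tree_error")
    }
  }
  invisible(TRUE)
}

#' Poisson-tree-process log-likelihood of a delimitation
#'
#' Branches strictly inside a crown subtree belong to the within-species
#' (coalescent) class; all other branches, including the root edge if
#' present, belong to the speciation class. Each non-empty class with `n`
#' branches of total length `L` (substitutions/site) contributes
#' `n * log(n/L) - n` at the plug-in maximum-likelihood rate
#' `lambda = n / L` of an exponential branch-length model; an empty class
#' contributes 0.
#'
#' @param tree A rooted `phylo` with branch lengths in substitutions/site.
#' @param crown_nodes Integer node ids (tips or internal) forming an
#'   antichain that covers all tips.
#' @param check Validate the crown set (default TRUE).
#' @return A list with `loglik`, `lambda_spec`, `lambda_coal`, and the
#'   per-class branch counts `n_spec`, `n_coal`.
#' @export
ptp_loglik <- function(tree, crown_nodes, check = TRUE) {
  if (check) validate_crowns(tree, crown_nodes)
  within <- edge_within_class(tree, crown_nodes)
  len <- tree$edge.length
  class_ll <- function(l) {
    n <- length(l)
    if (n == 0L) return(list(ll = 0, lambda = NA_real_))
    L <- sum(l)
    if (L <= 0) abort("non-empty branch class with zero total length",
                      class = "cm_degenerate_branch")
    list(ll = n * log(n / L) - n, lambda = n / L)
  }
  spec <- class_ll(len[!within])
  coal <- class_ll(len[within])
  list(loglik = spec$ll + coal$ll,
       lambda_spec = spec$lambda, lambda_coal = coal$lambda,
       n_spec = sum(!within), n_coal = sum(within))
}

# children lookup: list indexed by node id
node_children <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", nn)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[k, 2])
  }
  ch
}

crown_to_partition <- function(tree, crown_nodes, method = "PTP",
                               provenance = list()) {
  ntip <- ape::Ntip(tree)
  lab <- character(ntip)
  for (i in seq_along(crown_nodes)) {
    c_node <- crown_nodes[i]
    tips <- if (c_node <= ntip) c_node else
      phangorn::Descendants(tree, c_node, type = "tips")[[1]]
    lab[tips] <- sprintf("M%03d", i)
  }
  new_partition(tree$tip.label, lab, method = method, provenance = provenance)
}

# per-node subtree edge counts and total lengths (edges strictly below
# each node)
subtree_edge_stats <- function(tree) {
  nn <- ape::Ntip(tree) + tree$Nnode
  n_sub <- integer(nn); l_sub <- numeric(nn)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    len <- ord$edge.length[k]
    n_sub[p] <- n_sub[p] + n_sub[ch] + 1L
    l_sub[p] <- l_sub[p] + l_sub[ch] + len
  }
  list(n = n_sub, l = l_sub)
}

# loglik from the coalescent-class aggregate (n_coal, L_coal), with fixed
# tree totals
ll_from_aggregate <- function(n_coal, l_coal, n_tot, l_tot) {
  cls <- function(n, L) if (n == 0L) 0 else n * log(n / L) - n
  n_spec <- n_tot - n_coal
  l_spec <- l_tot - l_coal
  if ((n_spec > 0L && l_spec <= 0) || (n_coal > 0L && l_coal <= 0)) return(-Inf)
  cls(n_spec, l_spec) + cls(n_coal, l_coal)
}

# count antichains covering all tips, capped at `cap`
count_antichains <- function(tree, cap) {
  children <- node_children(tree)
  ntip <- ape::Ntip(tree)
  cnt <- function(v) {
    if (v <= ntip) return(1)
    ch <- children[[v]]
    total <- 1 + prod(vapply(ch, cnt, numeric(1)))
    min(total, cap)
  }
  cnt(ntip + 1L)
}

# exact maximum-likelihood crown set by dynamic-programming enumeration of
# all tip-covering antichains (aggregate (n_coal, L_coal) per antichain)
exact_ptp_crowns <- function(tree) {
  children <- node_children(tree)
  ntip <- ape::Ntip(tree)
  stats <- subtree_edge_stats(tree)
  n_tot <- nrow(tree$edge); l_tot <- sum(tree$edge.length)
  enum <- function(v) {
    own <- list(list(crowns = v, n = stats$n[v], l = stats$l[v]))
    if (v <= ntip) return(own)
    ch <- children[[v]]
    left <- enum(ch[1]); right <- enum(ch[2])
    combos <- vector("list", length(left) * length(right))
    i <- 0L
    for (a in left) for (b in right) {
      i <- i + 1L
      combos[[i]] <- list(crowns = c(a$crowns, b$crowns),
                          n = a$n + b$n, l = a$l + b$l)
    }
    c(own, combos)
  }
  all_ac <- enum(ntip + 1L)
  lls <- vapply(all_ac, function(a) ll_from_aggregate(a$n, a$l, n_tot, l_tot),
                numeric(1))
  # ties (within numerical noise) go to the delimitation with fewest crowns
  near <- which(lls >= max(lls) - 1e-9)
  sizes <- vapply(all_ac[near], function(a) length(a$crowns), integer(1))
  all_ac[[near[which.min(sizes)]]]$crowns
}

# deterministic hill climbing over crown sets with split and merge moves;
# each move changes the coalescent-class aggregate by the two child edges
# of the affected node, so proposals are evaluated in O(1)
ptp_hill_climb <- function(tree, start_crowns, children, ntip) {
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  stats <- subtree_edge_stats(tree)
  n_tot <- nrow(tree$edge); l_tot <- sum(tree$edge.length)
  # child-edge aggregate removed when a node stops being a crown
  own_n <- function(v) stats$n[v] - sum(stats$n[children[[v]]])
  own_l <- function(v) {
    stats$l[v] - sum(stats$l[children[[v]]])
  }
  crowns <- sort(start_crowns)
  n_coal <- sum(stats$n[crowns]); l_coal <- sum(stats$l[crowns])
  cur <- ll_from_aggregate(n_coal, l_coal, n_tot, l_tot)
  path <- cur
  repeat {
    cand <- list()
    for (cn in crowns[crowns > ntip]) {
      cand[[length(cand) + 1L]] <-
        list(type = "split", node = cn,
             ll = ll_from_aggregate(n_coal - own_n(cn), l_coal - own_l(cn),
                                    n_tot, l_tot))
    }
    for (p in setdiff(unique(parent[as.character(crowns)]), NA)) {
      pi <- as.integer(p)
      if (all(children[[pi]] %in% crowns)) {
        cand[[length(cand) + 1L]] <-
          list(type = "merge", node = pi,
               ll = ll_from_aggregate(n_coal + own_n(pi), l_coal + own_l(pi),
                                      n_tot, l_tot))
      }
    }
    if (!length(cand)) break
    lls <- vapply(cand, `[[`, numeric(1), "ll")
    best <- which.max(lls)
    if (lls[best] <= cur + 1e-12) break
    mv <- cand[[best]]
    if (mv$type == "split") {
      crowns <- sort(c(setdiff(crowns, mv$node), children[[mv$node]]))
      n_coal <- n_coal - own_n(mv$node); l_coal <- l_coal - own_l(mv$node)
    } else {
      crowns <- sort(c(setdiff(crowns, children[[mv$node]]), mv$node))
      n_coal <- n_coal + own_n(mv$node); l_coal <- l_coal + own_l(mv$node)
    }
    cur <- mv$ll
    path <- c(path, cur)
  }
  list(crowns = crowns, loglik = cur, path = path)
}

# seed crown sets: for each threshold on a branch-length ladder, the
# maximal subtrees whose internal edges are all at or below the threshold
threshold_seeds <- function(tree, n_thresholds = 20) {
  ntip <- ape::Ntip(tree)
  children <- node_children(tree)
  lens <- sort(unique(tree$edge.length))
  th <- unique(stats::quantile(lens, seq(0, 1, length.out = n_thresholds),
                               names = FALSE, type = 1))
  post <- ape::reorder.phylo(tree, "postorder")
  edge_by_child <- setNames(tree$edge.length[match(tree$edge[, 2], tree$edge[, 2])],
                            tree$edge[, 2])
  lapply(th, function(t) {
    ok <- rep(TRUE, ntip + tree$Nnode)
    for (k in seq_len(nrow(post$edge))) {
      p <- post$edge[k, 1]; ch <- post$edge[k, 2]
      if (!ok[ch] || post$edge.length[k] > t) ok[p] <- FALSE
    }
    # maximal ok nodes: ok, but parent not ok (or root)
    parent <- setNames(tree$edge[, 1], tree$edge[, 2])
    nodes <- which(ok)
    is_max <- vapply(nodes, function(v) {
      pv <- parent[as.character(v)]
      is.na(pv) || !ok[as.integer(pv)]
    }, logical(1))
    sort(nodes[is_max])
  })
}

#' Maximum-likelihood PTP delimitation
#'
#' Finds the crown-node antichain maximising [ptp_loglik()]. For trees
#' where the number of tip-covering antichains is modest (at most
#' `exact_limit`) the optimum is found exactly by dynamic-programming
#' enumeration. Larger trees use deterministic hill climbing over crown
#' sets with single split and merge moves from multiple starts — a single
#' species (crown = root), all tips, and branch-length-threshold seeds
#' (maximal subtrees whose internal edges all sit at or below a ladder of
#' thresholds) — keeping the best local maximum. The globally shared rate
#' estimates make the surface multimodal, so a split-only walk from the
#' root is easily trapped; the threshold seeds start the climb near every
#' plausible rate-shift depth. Deterministic given the tree.
#'
#' @param tree A rooted binary `phylo` (>= 3 tips) with branch lengths in
#'   substitutions/site.
#' @param exact_limit Antichain-count cap for the exact search
#'   (default 20000).
#' @return A `ptp_delimitation`: list with `crown_nodes`, `partition`
#'   (`motu_partition`, method `"PTP"`), `loglik`, `lambda_spec`,
#'   `lambda_coal`, `search` (`"exact"` or `"hill-climb"`), `search_path`.
#' @export
delimit_ptp <- function(tree, exact_limit = 20000) {
  if (!ape::is.rooted(tree)) abort("tree must be rooted", class = "cm_tree_error")
  if (!ape::is.binary(tree)) abort("tree must be binary (resolve polytomies first)",
                                   class = "cm_tree_error")
  if (ape::Ntip(tree) < 3L) abort("need at least 3 tips", class = "cm_tree_error")
  ntip <- ape::Ntip(tree)
  children <- node_children(tree)
  if (count_antichains(tree, exact_limit + 1) <= exact_limit) {
    crowns <- sort(exact_ptp_crowns(tree))
    search <- "exact"
    path <- NULL
  } else {
    starts <- c(list(ntip + 1L, seq_len(ntip)), threshold_seeds(tree))
    climbs <- lapply(starts, function(s) ptp_hill_climb(tree, s, children, ntip))
    best <- climbs[[which.max(vapply(climbs, `[[`, numeric(1), "loglik"))]]
    crowns <- best$crowns
    search <- "hill-climb"
    path <- best$path
  }
  cur <- ptp_loglik(tree, crowns, check = FALSE)
  structure(list(crown_nodes = crowns,
                 partition = crown_to_partition(tree, crowns, "PTP",
                                                list(search = search)),
                 loglik = cur$loglik, lambda_spec = cur$lambda_spec,
                 lambda_coal = cur$lambda_coal, search = search,
                 search_path = path, tree = tree),
            class = "ptp_delimitation")
}

#' @export
print.ptp_delimitation <- function(x, ...) {
  cat(sprintf("<ptp_delimitation> %d MOTUs, loglik %.3f, lambda_spec %.3g, lambda_coal %.3g\n",
              n_motus(x$partition), x$loglik,
              x$lambda_spec %||% NA, x$lambda_coal %||% NA))
  invisible(x)
}

#' @export
glance.ptp_delimitation <- function(x, ...) {
  tibble(method = "PTP", n_motus = n_motus(x$partition), loglik = x$loglik,
         lambda_spec = x$lambda_spec, lambda_coal = x$lambda_coal)
}

#' @export
tidy.ptp_delimitation <- function(x, ...) {
  out <- tidy(x$partition)
  if (!is.null(x$support)) {
    out$support <- x$support[out$motu]
  }
  out
}

#' MCMC configuration for Bayesian PTP
#'
#' @param iterations MCMC iterations per run (default 500000).
#' @param burn_in Burn-in fraction discarded before summarising
#'   (default 0.10).
#' @param seed Integer seed.
#' @param n_runs Independent runs whose MOTU counts are compared for
#'   convergence (default 3).
#' @param thin Keep every `thin`-th sample (default 10).
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(iterations = 500000, burn_in = 0.10, seed = 1,
                        n_runs = 3, thin = 10) {
  if (iterations <= 0) abort("iterations must be > 0", class = "cm_config_error")
  if (burn_in < 0 || burn_in >= 1) abort("burn_in must be in [0, 1)", class = "cm_config_error")
  structure(list(iterations = as.integer(iterations), burn_in = burn_in,
                 seed = as.integer(seed), n_runs = as.integer(n_runs),
                 thin = as.integer(thin)),
            class = "mcmc_config")
}

# one MH run over delimitations; returns sampled crown sets (post thinning)
bptp_run <- function(tree, iterations, thin, start_crowns, children, ntip) {
  crowns <- start_crowns
  ll <- ptp_loglik(tree, crowns, check = FALSE)$loglik
  parent <- setNames(tree$edge[, 1], tree$edge[, 2])
  n_moves <- function(cr) {
    splits <- sum(cr > ntip)
    par <- setdiff(unique(parent[as.character(cr)]), NA)
    merges <- sum(vapply(par, function(p) all(children[[p]] %in% cr), logical(1)))
    c(splits = splits, merges = merges)
  }
  samples <- vector("list", floor(iterations / thin))
  si <- 0L
  for (it in seq_len(iterations)) {
    mv <- n_moves(crowns)
    total <- sum(mv)
    if (total == 0L) {
      if (it %% thin == 0L) { si <- si + 1L; samples[[si]] <- crowns }
      next
    }
    u <- sample.int(total, 1L)
    if (u <= mv["splits"]) {
      internal <- crowns[crowns > ntip]
      cn <- internal[sample.int(length(internal), 1L)]
      prop <- c(setdiff(crowns, cn), children[[cn]])
    } else {
      par <- setdiff(unique(parent[as.character(crowns)]), NA)
      mergeable <- par[vapply(par, function(p) all(children[[p]] %in% crowns),
                              logical(1))]
      p <- as.integer(mergeable[sample.int(length(mergeable), 1L)])
      prop <- c(setdiff(crowns, children[[p]]), p)
    }
    ll_prop <- ptp_loglik(tree, prop, check = FALSE)$loglik
    # symmetric up to move counts; Hastings ratio corrects the proposal mass
    log_alpha <- ll_prop - ll + log(total) - log(sum(n_moves(prop)))
    if (log(runif(1)) < log_alpha) {
      crowns <- sort(prop)
      ll <- ll_prop
    }
    if (it %% thin == 0L) { si <- si + 1L; samples[[si]] <- crowns }
  }
  samples[seq_len(si)]
}

#' Bayesian PTP delimitation by MCMC
#'
#' Metropolis-Hastings sampling over delimitations with split/merge
#' proposals (replace an internal crown node by its children, or two
#' sibling crowns by their parent), corrected for the number of available
#' moves in each state. The reported delimitation is the most frequently
#' sampled one after burn-in; `support` gives the post-burn-in frequency of
#' each of its crown subtrees. Convergence is assessed by agreement of the
#' modal MOTU count across independent runs; disagreement beyond 10% raises
#' a warning, not an error.
#'
#' @param tree A rooted binary `phylo` with branch lengths in
#'   substitutions/site.
#' @param config An [mcmc_config()].
#' @return A `ptp_delimitation` with elements `support` (named by MOTU
#'   label), `run_motu_counts`, and `converged`.
#' @export
delimit_bptp <- function(tree, config = mcmc_config()) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    abort("tree must be rooted and binary", class = "cm_tree_error")
  }
  ntip <- ape::Ntip(tree)
  children <- node_children(tree)
  run_samples <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    set.seed(config$seed + r - 1L)
    run_samples[[r]] <- bptp_run(tree, config$iterations, config$thin,
                                 start_crowns = ntip + 1L,
                                 children = children, ntip = ntip)
  }
  keep <- lapply(run_samples, function(s) {
    s[seq_len(length(s)) > floor(config$burn_in * length(s))]
  })
  modal_count <- function(s) {
    counts <- vapply(s, length, integer(1))
    as.integer(names(which.max(table(counts))))
  }
  run_counts <- vapply(keep, modal_count, integer(1))
  converged <- (max(run_counts) - min(run_counts)) <= 0.1 * max(max(run_counts), 1L)
  if (!converged) {
    warn(paste0("bPTP runs disagree in modal MOTU count: ",
                paste(run_counts, collapse = ", ")))
  }
  pooled <- do.call(c, keep)
  keys <- vapply(pooled, function(cr) paste(sort(cr), collapse = ","), character(1))
  tab <- table(keys)
  best_key <- names(which.max(tab))
  crowns <- as.integer(strsplit(best_key, ",")[[1]])
  # per-crown-subtree support: frequency a crown node appears in the sample
  crown_freq <- vapply(crowns, function(cn) {
    mean(vapply(pooled, function(cr) cn %in% cr, logical(1)))
  }, numeric(1))
  ll <- ptp_loglik(tree, crowns, check = FALSE)
  part <- crown_to_partition(tree, crowns, "PTP",
                             list(search = "bptp-mcmc",
                                  iterations = config$iterations,
                                  n_runs = config$n_runs, seed = config$seed))
  support <- setNames(crown_freq, sprintf("M%03d", seq_along(crowns)))
  structure(list(crown_nodes = crowns, partition = part, loglik = ll$loglik,
                 lambda_spec = ll$lambda_spec, lambda_coal = ll$lambda_coal,
                 support = support, run_motu_counts = run_counts,
                 converged = converged, tree = tree),
            class = "ptp_delimitation")
}

#' Neighbor-joining surrogate tree from a K2P matrix
#'
#' Builds a midpoint-rooted, binary NJ tree from the haplotype distance
#' matrix, for tree-based delimitation when no externally inferred
#' phylogeny is supplied. Negative NJ branch lengths are clamped to zero.
#'
#' @param m A `k2p_dist` matrix without undefined entries.
#' @return A rooted binary `phylo`.
#' @export
nj_tree <- function(m) {
  mm <- unclass(m)
  if (any(is.na(mm))) abort("distance matrix has undefined entries; NJ needs a complete matrix",
                            class = "cm_delimitation_error")
  tr <- ape::nj(stats::as.dist(mm))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  ape::multi2di(tr)
}
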