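# relative-state mutation kernel per hit: transition kappa : each
# transversion 1/2 (states: 0 same, 1 transition partner, 2/3 the two
# transversion partners of the starting base)
hit_kernel <- function(kappa) {
  pt <- kappa / (kappa + 1)
  pv <- (1 - pt) / 2
  matrix(c(0, pt, pv, pv,
           pt, 0, pv, pv,
           pv, pv, 0, pt,
           pv, pv, pt, 0), 4, 4, byrow = TRUE)
}

# expected (P, Q) between two sequences separated by per-site hit
# intensity theta (Poisson number of hits, kernel above)
expected_pq <- function(theta, kappa, kmax = 60) {
  M <- hit_kernel(kappa)
  state <- c(1, 0, 0, 0)
  wts <- stats::dpois(0:kmax, theta)
  P <- 0; Q <- 0
  for (k in 0:kmax) {
    P <- P + wts[k + 1] * state[2]
    Q <- Q + wts[k + 1] * (state[3] + state[4])
    state <- as.vector(state %*% M)
  }
  c(P = P, Q = Q)
}

# per-site hit intensity whose expected K2P equals a target distance
# (the K2P inverse map used for calibration)
calibrate_theta <- function(target_d, kappa) {
  if (target_d <= 0) return(0)
  f <- function(theta) {
    pq <- expected_pq(theta, kappa)
    k2p_from_pq(pq["P"], pq["Q"]) - target_d
  }
  stats::uniroot(f, c(1e-8, 5), tol = 1e-10)$root
}

# sprinkle m hits (positions with replacement) on an integer-coded sequence
mutate_seq <- function(code, m, kappa) {
  if (m == 0L) return(code)
  pos <- sample.int(length(code), m, replace = TRUE)
  pt <- kappa / (kappa + 1)
  # base order A C G T: transition partners (G T A C); transversions the rest
  ts_partner <- c(3L, 4L, 1L, 2L)
  for (p in pos) {
    b <- code[p]
    if (runif(1) < pt) {
      code[p] <- ts_partner[b]
    } else {
      tv <- setdiff(1:4, c(b, ts_partner[b]))
      code[p] <- tv[sample.int(2L, 1L)]
    }
  }
  code
}

decode_dna <- function(code) paste(c("A", "C", "G", "T")[code], collapse = "")

#' Simulation configuration
#'
#' Defines the statistical structure of a synthetic barcode dataset:
#' `n_lineages` deeply divergent lineages whose between-lineage K2P
#' concentrates near `target_between`, each with shallow internal diversity
#' near `target_within`, producing a bimodal pairwise-distance
#' distribution; block-contiguous geography with a controllable fraction of
#' two-lineage (syntopic) sites; overdispersed per-site sample sizes.
#'
#' @param n_lineages Number of divergent lineages `K` (default 12).
#' @param seq_length Barcode length in nt (default 530).
#' @param target_between Expected between-lineage (founder) K2P
#'   (default 0.22).
#' @param target_within Expected within-lineage pairwise K2P
#'   (default 0.02).
#' @param ts_tv_ratio Transition:transversion hit ratio kappa (default 4).
#' @param n_sites Number of sampling sites (default 60).
#' @param syntopy_prob Probability a site hosts two lineages (default 0.3).
#' @param mean_samples Mean individuals per site; draws are overdispersed
#'   negative-binomial with minimum 1 (default 10).
#' @param n_haplotypes_per_lineage Haplotype pool size per lineage,
#'   founder included (default 6).
#' @param lon_range,lat_range,altitude_range Geographic extent (degrees,
#'   degrees, metres).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_lineages = 12, seq_length = 530,
                              target_between = 0.22, target_within = 0.02,
                              ts_tv_ratio = 4, n_sites = 60,
                              syntopy_prob = 0.3, mean_samples = 10,
                              n_haplotypes_per_lineage = 6,
                              lon_range = c(5, 25), lat_range = c(44, 52),
                              altitude_range = c(100, 1500)) {
  if (n_lineages < 1) abort("need n_lineages >= 1", class = "cm_config_error")
  if (target_between > 0 && target_within >= target_between) {
    abort("target_within must be below target_between", class = "cm_config_error")
  }
  if (syntopy_prob < 0 || syntopy_prob > 1) {
    abort("syntopy_prob must be in [0, 1]", class = "cm_config_error")
  }
  structure(list(n_lineages = as.integer(n_lineages),
                 seq_length = as.integer(seq_length),
                 target_between = target_between, target_within = target_within,
                 ts_tv_ratio = ts_tv_ratio, n_sites = as.integer(n_sites),
                 syntopy_prob = syntopy_prob, mean_samples = mean_samples,
                 n_haplotypes_per_lineage = as.integer(n_haplotypes_per_lineage),
                 lon_range = lon_range, lat_range = lat_range,
                 altitude_range = altitude_range),
            class = "simulation_config")
}

#' Simulate a barcode dataset with known ground truth
#'
#' A uniform-random root sequence spawns `K` lineage founders by
#' fixed-count substitution sprinkling under a two-rate
#' (transition/transversion) kernel; the substitution count is calibrated
#' through the K2P inverse map so expected pairwise founder divergence hits
#' `target_between`. Each founder then spawns a haplotype pool at
#' `target_within` expected pairwise divergence. Sites occupy a lon/lat
#' lattice in contiguous longitude blocks per lineage; a site hosts a
#' second, block-adjacent lineage with probability `syntopy_prob`, so
#' syntopy concentrates at block borders. Individuals are drawn per site
#' from the hosted lineages' pools. All randomness comes from `seed`.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return A list of class `barcode_simulation`: `alignment`
#'   ([barcode_alignment]), `sites` (site table), `truth` (tibble
#'   `record_id`, `site_id`, `lineage`, `sim_haplotype`), `site_lineages`,
#'   `founders` (lineage founder sequences), `true_tree` (binary `phylo`
#'   over simulated haplotype names, branch lengths in expected
#'   substitutions/site), `config`, `seed`.
#' @export
simulate_barcodes <- function(config = simulation_config(), seed = 1) {
  set.seed(seed)
  K <- config$n_lineages
  L <- config$seq_length
  kappa <- config$ts_tv_ratio
  root <- sample.int(4L, L, replace = TRUE)
  # fixed per-branch substitution counts from the calibrated intensities
  theta_b <- calibrate_theta(config$target_between, kappa)
  theta_w <- calibrate_theta(config$target_within, kappa)
  m_b <- round(theta_b / 2 * L)
  m_w <- round(theta_w / 2 * L)
  founders <- lapply(seq_len(K), function(k) mutate_seq(root, m_b, kappa))
  # haplotype pools: founder first, then shallow variants
  pools <- lapply(seq_len(K), function(k) {
    pool <- c(list(founders[[k]]),
              lapply(seq_len(config$n_haplotypes_per_lineage - 1L),
                     function(i) mutate_seq(founders[[k]], m_w, kappa)))
    names(pool) <- sprintf("L%02d_h%02d", k, seq_along(pool))
    pool
  })
  # block-contiguous geography along longitude
  n_sites <- config$n_sites
  block <- pmin(K, 1L + floor((seq_len(n_sites) - 1L) * K / n_sites))
  lon_blocks <- seq(config$lon_range[1], config$lon_range[2], length.out = K + 1L)
  lon <- lon_blocks[block] + runif(n_sites) * diff(config$lon_range) / K
  lat <- runif(n_sites, config$lat_range[1], config$lat_range[2])
  alt <- runif(n_sites, config$altitude_range[1], config$altitude_range[2])
  second <- ifelse(runif(n_sites) < config$syntopy_prob,
                   ifelse(block == K, block - 1L, block + 1L), NA_integer_)
  if (K == 1L) second <- rep(NA_integer_, n_sites)
  sites <- tibble(site_id = sprintf("S%03d", seq_len(n_sites)),
                  lat = round(lat, 5), lon = round(lon, 5),
                  altitude_m = round(alt), country = "XX")
  site_lineages <- lapply(seq_len(n_sites), function(i) {
    stats::na.omit(c(block[i], second[i]))
  })
  n_ind <- 1L + stats::rnbinom(n_sites, size = 2, mu = max(config$mean_samples - 1, 0.01))
  recs <- purrr::map_dfr(seq_len(n_sites), function(i) {
    hosted <- site_lineages[[i]]
    lin <- hosted[sample.int(length(hosted), n_ind[i], replace = TRUE)]
    hap_idx <- sample.int(config$n_haplotypes_per_lineage, n_ind[i], replace = TRUE)
    tibble(site_id = sites$site_id[i], lineage = lin,
           sim_haplotype = sprintf("L%02d_h%02d", lin, hap_idx))
  })
  recs$record_id <- sprintf("ind%05d", seq_len(nrow(recs)))
  all_pools <- do.call(c, pools)
  recs$sequence <- vapply(recs$sim_haplotype,
                          function(h) decode_dna(all_pools[[h]]), character(1))
  aln <- barcode_alignment(recs[, c("record_id", "site_id", "sequence")])
  truth <- tibble(record_id = recs$record_id, site_id = recs$site_id,
                  lineage = sprintf("L%02d", recs$lineage),
                  sim_haplotype = recs$sim_haplotype)
  # genealogy: lineage star from the root, haplotype stars from founders,
  # resolved to binary with zero-length branches
  lin_nwk <- vapply(seq_len(K), function(k) {
    tips <- paste0(names(pools[[k]]), ":",
                   c(0, rep(m_w / L, length(pools[[k]]) - 1L)), collapse = ",")
    sprintf("(%s):%g", tips, m_b / L)
  }, character(1))
  true_tree <- ape::read.tree(text = sprintf("(%s);", paste(lin_nwk, collapse = ",")))
  true_tree <- ape::multi2di(true_tree, random = FALSE)
  true_tree$edge.length[is.na(true_tree$edge.length)] <- 0
  structure(list(alignment = aln, sites = sites, truth = truth,
                 site_lineages = tibble(site_id = sites$site_id,
                                        lineages = lapply(site_lineages,
                                                          function(l) sprintf("L%02d", l))),
                 founders = tibble(lineage = sprintf("L%02d", seq_len(K)),
                                   sequence = vapply(founders, decode_dna, character(1))),
                 true_tree = true_tree, config = config, seed = seed),
            class = "barcode_simulation")
}

#' @export
print.barcode_simulation <- function(x, ...) {
  cat(sprintf("<barcode_simulation> K=%d lineages, %d sites, %d individuals (seed %d)\n",
              x$config$n_lineages, nrow(x$sites), nrow(x$truth), x$seed))
  invisible(x)
}

#' Ground-truth lineage partition at the haplotype level
#'
#' Maps collapsed haplotypes to their true lineage. Errors if any collapsed
#' haplotype mixes records from different true lineages (impossible at the
#' default divergence targets).
#'
#' @param haps A `haplotype_table` from [collapse_haplotypes()] on the
#'   simulated alignment.
#' @param truth The `truth` tibble of a [simulate_barcodes()] result.
#' @return A `motu_partition` with method `"TRUTH"`.
#' @export
true_haplotype_partition <- function(haps, truth) {
  mem <- haplotype_membership(haps)
  joined <- dplyr::inner_join(mem, truth[, c("record_id", "lineage")], by = "record_id")
  per_hap <- joined |>
    group_by(.data$haplotype_id) |>
    summarise(n_lineages = dplyr::n_distinct(.data$lineage),
              lineage = .data$lineage[1], .groups = "drop")
  if (any(per_hap$n_lineages > 1L)) {
    abort("a collapsed haplotype spans several true lineages", class = "cm_truth_error")
  }
  new_partition(per_hap$haplotype_id, per_hap$lineage, method = "TRUTH")
}

#' Compare an inferred partition with the truth
#'
#' @param inferred,truth `motu_partition`s over the same id universe.
#' @return A list: `delta` (inferred minus true MOTU count), `agreement`
#'   (adjusted Rand index, chance-corrected pair-counting agreement in
#'   `[0, 1]` up to noise), `misassigned` (ids whose true label differs
#'   from the majority true label of their inferred MOTU).
#' @export
truth_metrics <- function(inferred, truth) {
  stopifnot(setequal(inferred$haplotype_id, truth$haplotype_id))
  tl <- partition_labels(truth)[inferred$haplotype_id]
  ari <- mclust::adjustedRandIndex(inferred$motu, tl)
  mis <- tibble(id = inferred$haplotype_id, inf = inferred$motu, tru = unname(tl)) |>
    group_by(.data$inf) |>
    mutate(majority = names(which.max(table(.data$tru)))) |>
    ungroup() |>
    filter(.data$tru != .data$majority)
  list(delta = n_motus(inferred) - n_motus(truth),
       agreement = ari,
       misassigned = mis$id)
}
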