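#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the full analysis. Any component
#' left `NULL` uses that stage's defaults.
#'
#' @param window Optional `c(start, length)` trimming window (0-based).
#' @param min_overlap Minimum comparable sites per K2P pair (default 300).
#' @param abgd An [abgd_config()].
#' @param resl A [resl_config()].
#' @param lagrue_cutoff Sister-clade divergence cutoff (default 0.20).
#' @param clock_rate Strict-clock rate, substitutions/site/My
#'   (default 0.0115).
#' @param use_bptp Run the Bayesian PTP sampler instead of the greedy ML
#'   search (default FALSE).
#' @param mcmc An [mcmc_config()] (used when `use_bptp = TRUE`).
#' @param landscape_grid `c(n_x, n_y)` landscape resolution
#'   (default `c(60, 60)`).
#' @param run_landscape Compute the genetic landscape surface
#'   (default TRUE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = NULL, min_overlap = 300,
                            abgd = abgd_config(), resl = resl_config(),
                            lagrue_cutoff = 0.20, clock_rate = 0.0115,
                            use_bptp = FALSE, mcmc = mcmc_config(),
                            landscape_grid = c(60, 60),
                            run_landscape = TRUE) {
  structure(list(window = window, min_overlap = min_overlap, abgd = abgd,
                 resl = resl, lagrue_cutoff = lagrue_cutoff,
                 clock_rate = clock_rate, use_bptp = use_bptp, mcmc = mcmc,
                 landscape_grid = landscape_grid,
                 run_landscape = run_landscape),
            class = "pipeline_config")
}

#' Run the full cryptic-diversity pipeline
#'
#' Collapse to haplotypes, K2P distances, four MOTU delimitations (ABGD
#' primary, RESL, PTP on an NJ surrogate tree, Lagrue sister-clade),
#' concordance/nestedness, per-method syntopy, rare-MOTU and range-size
#' summaries, and the genetic landscape surface. If ground truth is
#' supplied (a [simulate_barcodes()] result carries it), agreement metrics
#' are added.
#'
#' @param aln A [barcode_alignment], or a `barcode_simulation` (whose
#'   alignment, sites and truth are used).
#' @param sites A site table (ignored when `aln` is a simulation).
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the stochastic stages (bPTP MCMC).
#' @param out_dir Optional directory; when given, stage outputs (TSVs,
#'   FASTA, report JSON) are written there and listed in the manifest with
#'   checksums.
#' @return A list of class `pipeline_report`; see Details.
#' @details The report contains `n_records`, `n_haplotypes`, `motu_counts`
#'   (named per method), `partitions`, `concordance`, `syntopy` (per-method
#'   tibble), `rare_motus`, `nestedness_extremes`, `range_classes`,
#'   `truth` (agreement per method, when available), `landscape`, and a
#'   `manifest` of written files.
#' @export
run_pipeline <- function(aln, sites = NULL, config = pipeline_config(),
                         seed = 1, out_dir = NULL) {
  truth <- NULL
  if (inherits(aln, "barcode_simulation")) {
    sites <- aln$sites
    truth <- aln$truth
    aln <- aln$alignment
  }
  if (is.null(sites)) abort("a site table is required", class = "cm_config_error")
  sites <- validate_site_table(sites)
  if (!is.null(config$window)) {
    aln <- trim_to_window(aln, config$window[1], config$window[2])
  }
  haps <- collapse_haplotypes(aln)
  mem <- haplotype_membership(haps)
  m <- k2p_matrix(haps, min_overlap = config$min_overlap)
  tree <- nj_tree(m)
  abgd <- delimit_abgd(m, config$abgd)
  resl <- delimit_resl(m, config = config$resl)
  ptp <- if (config$use_bptp) {
    cfg <- config$mcmc; cfg$seed <- seed
    delimit_bptp(tree, cfg)
  } else {
    delimit_ptp(tree)
  }
  lagrue <- delimit_lagrue(tree, m, cutoff = config$lagrue_cutoff)
  partitions <- list(ABGD = abgd$primary, RESL = resl,
                     PTP = ptp$partition, LAGRUE = lagrue)
  motu_counts <- vapply(partitions, n_motus, integer(1))
  conc <- concordance_count(partitions[c("ABGD", "RESL", "PTP")])
  syntopy <- purrr::imap_dfr(partitions, function(p, nm) {
    inc <- incidence_table(mem, p, sites)
    dplyr::bind_cols(tibble(method = nm), syntopy_rates(inc))
  })
  inc_resl <- incidence_table(mem, resl, sites)
  rare <- rare_motu_profile(inc_resl)
  nest <- nestedness(fine = resl, coarse = abgd$primary)
  ranges <- range_classes(incidence_table(mem, abgd$primary, sites), sites)
  truth_res <- NULL
  if (!is.null(truth)) {
    tp <- true_haplotype_partition(haps, truth)
    truth_res <- purrr::imap_dfr(partitions, function(p, nm) {
      tm <- truth_metrics(p, tp)
      tibble(method = nm, delta = tm$delta, agreement = tm$agreement,
             n_misassigned = length(tm$misassigned))
    })
  }
  landscape <- NULL
  if (isTRUE(config$run_landscape) && nrow(sites) >= 3L) {
    site_haps <- mem |> count(.data$site_id, .data$haplotype_id, name = "n")
    edges <- edge_divergences(delaunay_network(sites), site_haps, m)
    landscape <- interpolate_surface(edges, sites,
                                     n_x = config$landscape_grid[1],
                                     n_y = config$landscape_grid[2])
  }
  report <- structure(
    list(schema_version = "1.0", seed = seed,
         n_records = nrow(aln), n_haplotypes = nrow(haps),
         motu_counts = motu_counts, partitions = partitions,
         concordance = as.integer(conc), syntopy = syntopy,
         rare_motus = rare,
         nestedness_extremes = c(min = nest$min_fine, max = nest$max_fine),
         range_classes = ranges, truth = truth_res,
         landscape = landscape, distance_matrix = m, tree = tree,
         haplotypes = haps, manifest = NULL),
    class = "pipeline_report")
  if (!is.null(out_dir)) report$manifest <- write_pipeline_outputs(report, mem, out_dir)
  report
}

write_pipeline_outputs <- function(report, mem, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(report$partitions)) {
    p <- file.path(out_dir, paste0(tolower(nm), "_partition.tsv"))
    write_partition(report$partitions[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "distance_matrix.tsv")
  utils::write.table(tidy(report$distance_matrix), p, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "tree.nwk")
  ape::write.tree(report$tree, p)
  paths <- c(paths, p)
  summary_json <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(schema_version = report$schema_version, seed = report$seed,
         n_records = report$n_records, n_haplotypes = report$n_haplotypes,
         motu_counts = as.list(report$motu_counts),
         concordance = report$concordance,
         syntopy = report$syntopy, rare_motus = report$rare_motus,
         nestedness_extremes = as.list(report$nestedness_extremes)),
    summary_json, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, summary_json)
  tibble(path = paths,
         sha = unname(vapply(paths, function(f) {
           as.character(tools::md5sum(f))
         }, character(1))))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d records -> %d haplotypes\n", x$n_records, x$n_haplotypes))
  cat("  MOTUs:", paste(names(x$motu_counts), x$motu_counts, sep = "=",
                        collapse = ", "), "\n")
  cat(sprintf("  concordant MOTUs (ABGD/RESL/PTP): %d\n", x$concordance))
  if (!is.null(x$truth)) {
    cat("  agreement vs truth:",
        paste(x$truth$method, signif(x$truth$agreement, 4), sep = "=",
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.pipeline_report <- function(x, ...) {
  tibble(n_records = x$n_records, n_haplotypes = x$n_haplotypes,
         abgd_motus = x$motu_counts[["ABGD"]],
         resl_motus = x$motu_counts[["RESL"]],
         ptp_motus = x$motu_counts[["PTP"]],
         lagrue_motus = x$motu_counts[["LAGRUE"]],
         concordance = x$concordance)
}
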