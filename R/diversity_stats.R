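#' Site-by-MOTU incidence table
#'
#' Counts individuals (not haplotypes) per site and MOTU, joining a
#' record-to-haplotype membership, a MOTU partition of the haplotypes, and
#' a site table.
#'
#' @param membership Tibble with columns `record_id`, `site_id`,
#'   `haplotype_id` (see [haplotype_membership()]).
#' @param partition A `motu_partition` labelling every haplotype.
#' @param sites A site table; every `site_id` in `membership` must appear.
#' @return An `incidence_table`: a long tibble (`site_id`, `motu`, `n`)
#'   with per-site totals in attribute `site_totals`.
#' @export
incidence_table <- function(membership, partition, sites) {
  unlab <- setdiff(membership$haplotype_id, partition$haplotype_id)
  if (length(unlab)) {
    abort(paste0("unlabelled haplotype(s): ",
                 paste(utils::head(unlab, 5), collapse = ", ")),
          class = "cm_coverage_error")
  }
  unknown <- setdiff(membership$site_id, sites$site_id)
  if (length(unknown)) {
    abort(paste0("unknown site(s): ", paste(utils::head(unknown, 5), collapse = ", ")),
          class = "cm_coverage_error")
  }
  lab <- partition_labels(partition)
  out <- membership |>
    mutate(motu = unname(lab[.data$haplotype_id])) |>
    count(.data$site_id, .data$motu, name = "n") |>
    arrange(.data$site_id, .data$motu)
  totals <- out |> group_by(.data$site_id) |> summarise(total = sum(.data$n), .groups = "drop")
  attr(out, "site_totals") <- totals
  attr(out, "method") <- attr(partition, "method")
  class(out) <- c("incidence_table", class(tibble()))
  out
}

#' @export
print.incidence_table <- function(x, ...) {
  cat(sprintf("<incidence_table> %d sites x %d MOTUs, %d individuals (method %s)\n",
              dplyr::n_distinct(x$site_id), dplyr::n_distinct(x$motu),
              sum(x$n), attr(x, "method") %||% "?"))
  NextMethod()
}

#' Within-site syntopy rates
#'
#' Among sites with at least `min_individuals` sampled individuals, the
#' percentage harbouring two or more MOTUs, and the count harbouring at
#' least `k_high`.
#'
#' @param inc An [incidence_table()].
#' @param min_individuals Eligibility floor on per-site sample size
#'   (default 2).
#' @param k_high Secondary co-occurrence level reported as a count
#'   (default 3).
#' @return One-row tibble: `n_sites`, `n_eligible`, `pct_syntopy`
#'   (percentage of eligible sites with >= 2 MOTUs), `n_sites_ge_k`.
#' @export
syntopy_rates <- function(inc, min_individuals = 2, k_high = 3) {
  per_site <- inc |>
    group_by(.data$site_id) |>
    summarise(total = sum(.data$n), n_motus = dplyr::n_distinct(.data$motu),
              .groups = "drop")
  eligible <- per_site |> filter(.data$total >= min_individuals)
  if (nrow(eligible) == 0L) {
    abort("no site meets the individual-count floor; syntopy undefined",
          class = "cm_undefined_percentage")
  }
  tibble(n_sites = nrow(per_site),
         n_eligible = nrow(eligible),
         pct_syntopy = 100 * mean(eligible$n_motus >= 2L),
         n_sites_ge_k = sum(eligible$n_motus >= k_high))
}

#' Rare-MOTU frequency profile
#'
#' Among multi-MOTU sites with more than `min_individuals` individuals, the
#' percentage whose least-frequent MOTU has relative frequency at or below
#' each cutoff. Monomorphic sites have no rare MOTU and are excluded from
#' the denominator.
#'
#' @param inc An [incidence_table()].
#' @param min_individuals Sites must exceed this sample size (default 10).
#' @param cutoffs Relative-frequency cutoffs (default `c(0.2, 0.1)`).
#' @return Tibble with columns `cutoff`, `n_eligible`, `pct_sites`.
#' @export
rare_motu_profile <- function(inc, min_individuals = 10, cutoffs = c(0.2, 0.1)) {
  per_site <- inc |>
    group_by(.data$site_id) |>
    summarise(total = sum(.data$n), n_motus = dplyr::n_distinct(.data$motu),
              min_freq = min(.data$n) / sum(.data$n), .groups = "drop") |>
    filter(.data$total > min_individuals, .data$n_motus >= 2L)
  tibble(cutoff = cutoffs,
         n_eligible = nrow(per_site),
         pct_sites = vapply(cutoffs, function(ct) {
           if (nrow(per_site) == 0L) NA_real_ else 100 * mean(per_site$min_freq <= ct)
         }, numeric(1)))
}

#' Nestedness of a fine partition within a coarse one
#'
#' Counts distinct fine MOTUs inside each coarse MOTU and lists violations
#' (fine MOTUs straddling two or more coarse MOTUs).
#'
#' @param fine,coarse `motu_partition`s over the same id universe.
#' @return A list: `per_coarse` (tibble `motu`, `n_fine`), `min_fine`,
#'   `max_fine`, and `violations` (character vector of straddling fine
#'   MOTUs).
#' @export
nestedness <- function(fine, coarse) {
  stopifnot(setequal(fine$haplotype_id, coarse$haplotype_id))
  joined <- dplyr::inner_join(
    tibble(haplotype_id = fine$haplotype_id, fine = fine$motu),
    tibble(haplotype_id = coarse$haplotype_id, coarse = coarse$motu),
    by = "haplotype_id")
  per_coarse <- joined |>
    group_by(motu = .data$coarse) |>
    summarise(n_fine = dplyr::n_distinct(.data$fine), .groups = "drop")
  straddle <- joined |>
    group_by(.data$fine) |>
    summarise(n_coarse = dplyr::n_distinct(.data$coarse), .groups = "drop") |>
    filter(.data$n_coarse > 1L)
  list(per_coarse = per_coarse,
       min_fine = min(per_coarse$n_fine), max_fine = max(per_coarse$n_fine),
       violations = straddle$fine)
}

#' Count MOTUs concordant across partitions
#'
#' A MOTU is concordant when exactly the same id set appears as a MOTU in
#' every supplied partition.
#'
#' @param partitions A list of two or more `motu_partition`s over the same
#'   id universe.
#' @return Integer count; the concordant id sets are attached as attribute
#'   `sets`.
#' @export
concordance_count <- function(partitions) {
  if (length(partitions) < 2L) abort("need at least two partitions", class = "cm_config_error")
  set_keys <- lapply(partitions, function(p) {
    vapply(partition_sets(p), paste, character(1), collapse = ",")
  })
  common <- Reduce(intersect, set_keys)
  structure(length(common), sets = strsplit(common, ","))
}

#' Great-circle distance (haversine)
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @param radius_km Earth radius (default 6371 km).
#' @return Distance in km (vectorised).
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(a)))
}

#' Geographic range-size class per MOTU
#'
#' The maximum great-circle distance among a MOTU's occupied sites puts it
#' in one of three classes: narrow (< 100 km, including single-site MOTUs
#' at 0 km), broad (100-1000 km), widespread (> 1000 km).
#'
#' @param inc An [incidence_table()].
#' @param sites Site table with coordinates for every occupied site.
#' @return Tibble with columns `motu`, `n_sites`, `max_km`, `range_class`.
#' @export
range_classes <- function(inc, sites) {
  missing_sites <- setdiff(inc$site_id, sites$site_id)
  if (length(missing_sites)) {
    abort(paste0("site(s) without coordinates: ",
                 paste(utils::head(missing_sites, 5), collapse = ", ")),
          class = "cm_coverage_error")
  }
  coords <- sites[match(inc$site_id, sites$site_id), c("lat", "lon")]
  df <- dplyr::bind_cols(inc, coords)
  per_motu <- df |>
    group_by(.data$motu) |>
    summarise(n_sites = dplyr::n_distinct(.data$site_id),
              max_km = {
                la <- .data$lat; lo <- .data$lon
                if (length(la) < 2L) 0 else {
                  pr <- utils::combn(length(la), 2)
                  max(haversine_km(la[pr[1, ]], lo[pr[1, ]], la[pr[2, ]], lo[pr[2, ]]))
                }
              },
              .groups = "drop")
  per_motu |>
    mutate(range_class = dplyr::case_when(
      .data$max_km < 100 ~ "narrow",
      .data$max_km <= 1000 ~ "broad",
      TRUE ~ "widespread"))
}

#' MOTU counts per latitudinal band
#'
#' A MOTU counts once in every half-open band `[lo, lo + band_width)` where
#' it occupies at least one site.
#'
#' @param inc An [incidence_table()].
#' @param sites Site table.
#' @param band_width Band width in degrees latitude (default 0.5).
#' @return Tibble with columns `band_lo`, `band_hi`, `n_motus`.
#' @export
latitudinal_bins <- function(inc, sites, band_width = 0.5) {
  lat <- sites$lat[match(inc$site_id, sites$site_id)]
  df <- tibble(motu = inc$motu, band = floor(lat / band_width)) |> distinct()
  df |>
    count(.data$band, name = "n_motus") |>
    mutate(band_lo = .data$band * band_width,
           band_hi = (.data$band + 1) * band_width) |>
    select("band_lo", "band_hi", "n_motus") |>
    arrange(.data$band_lo)
}

#' Altitudinal distribution of MOTUs
#'
#' Box-plot statistics (min, Q1, mean, Q3, max of site altitude) per MOTU
#' present at `min_sites` or more sites, plus a pooled histogram of MOTU
#' presence per altitude band.
#'
#' @param inc An [incidence_table()].
#' @param sites Site table with `altitude_m`.
#' @param min_sites Minimum occupied sites for the per-MOTU summary
#'   (default 3).
#' @param bin_m Histogram bin width in metres (default 100).
#' @return A list: `per_motu` tibble (`motu`, `n_sites`, `min`, `q1`,
#'   `mean`, `q3`, `max`) and `histogram` tibble (`band_lo`, `band_hi`,
#'   `n_motus`).
#' @export
altitudinal_summary <- function(inc, sites, min_sites = 3, bin_m = 100) {
  alt <- sites$altitude_m[match(inc$site_id, sites$site_id)]
  df <- tibble(motu = inc$motu, site_id = inc$site_id, altitude_m = alt)
  per_motu <- df |>
    distinct() |>
    group_by(.data$motu) |>
    summarise(n_sites = dplyr::n_distinct(.data$site_id),
              min = min(.data$altitude_m),
              q1 = stats::quantile(.data$altitude_m, 0.25, names = FALSE),
              mean = mean(.data$altitude_m),
              q3 = stats::quantile(.data$altitude_m, 0.75, names = FALSE),
              max = max(.data$altitude_m), .groups = "drop") |>
    filter(.data$n_sites >= min_sites)
  hist <- df |>
    mutate(band = floor(.data$altitude_m / bin_m)) |>
    distinct(.data$motu, .data$band) |>
    count(.data$band, name = "n_motus") |>
    mutate(band_lo = .data$band * bin_m, band_hi = (.data$band + 1) * bin_m) |>
    select("band_lo", "band_hi", "n_motus") |>
    arrange(.data$band_lo)
  list(per_motu = per_motu, histogram = hist)
}
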