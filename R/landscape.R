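#' Delaunay neighbour network over sampling sites
#'
#' Planar Delaunay triangulation on (lon, lat) treated as Euclidean
#' coordinates, as genetic-landscape software does; adequate at continental
#' extent for a visualisation surface.
#'
#' @param sites Site table with `site_id`, `lat`, `lon` (>= 3 non-collinear
#'   sites).
#' @return Tibble of unique undirected edges: `site_a`, `site_b`,
#'   `mid_lon`, `mid_lat` (arithmetic midpoints).
#' @export
delaunay_network <- function(sites) {
  if (nrow(sites) < 3L) abort("need at least 3 sites", class = "cm_geometry_error")
  xy <- cbind(sites$lon, sites$lat)
  if (qr(cbind(1, xy))$rank < 3) abort("sites are collinear", class = "cm_geometry_error")
  dd <- deldir::deldir(sites$lon, sites$lat, suppressMsge = TRUE)
  seg <- dd$delsgs
  a <- pmin(seg$ind1, seg$ind2)
  b <- pmax(seg$ind1, seg$ind2)
  keep <- !duplicated(cbind(a, b)) & a != b
  tibble(site_a = sites$site_id[a[keep]], site_b = sites$site_id[b[keep]],
         mid_lon = (sites$lon[a[keep]] + sites$lon[b[keep]]) / 2,
         mid_lat = (sites$lat[a[keep]] + sites$lat[b[keep]]) / 2) |>
    arrange(.data$site_a, .data$site_b)
}

#' Mean between-site genetic divergence
#'
#' Mean pairwise K2P distance over cross-site pairs of sequences. With
#' `weighting = "individual"` every individual counts (haplotype distances
#' weighted by member counts); with `"haplotype"` each haplotype counts
#' once.
#'
#' @param site_haps Tibble `site_id`, `haplotype_id`, `n` (individuals per
#'   haplotype per site), e.g. built from [haplotype_membership()].
#' @param a,b Site ids.
#' @param m A `k2p_dist` matrix over the haplotypes.
#' @param weighting `"individual"` (default) or `"haplotype"`.
#' @return Mean divergence (substitutions/site) over defined pairs.
#' @export
intersite_divergence <- function(site_haps, a, b, m, weighting = c("individual", "haplotype")) {
  weighting <- match.arg(weighting)
  ha <- site_haps[site_haps$site_id == a, ]
  hb <- site_haps[site_haps$site_id == b, ]
  if (nrow(ha) == 0L || nrow(hb) == 0L) {
    abort(paste0("no usable sequence at site ", if (nrow(ha) == 0L) a else b),
          class = "cm_coverage_error")
  }
  d <- m[ha$haplotype_id, hb$haplotype_id, drop = FALSE]
  w <- if (weighting == "individual") outer(ha$n, hb$n) else array(1, dim(d))
  ok <- !is.na(d)
  sum(d[ok] * w[ok]) / sum(w[ok])
}

#' Divergence values on a Delaunay network
#'
#' @param edges Edge tibble from [delaunay_network()].
#' @param site_haps Per-site haplotype counts (see
#'   [intersite_divergence()]).
#' @param m A `k2p_dist` matrix.
#' @param weighting Passed to [intersite_divergence()].
#' @return `edges` with a `divergence` column.
#' @export
edge_divergences <- function(edges, site_haps, m, weighting = "individual") {
  edges$divergence <- purrr::map2_dbl(edges$site_a, edges$site_b,
                                      function(a, b) intersite_divergence(site_haps, a, b, m, weighting))
  edges
}

#' Interpolate a genetic landscape surface
#'
#' Inverse-distance-weighted interpolation of edge-midpoint divergence
#' values onto a regular lon/lat lattice. A cell coinciding with a midpoint
#' takes that midpoint's value exactly; cells outside the convex hull of
#' the sites are masked. All unmasked values lie within the range of the
#' input edge values (convex combination).
#'
#' @param edges Edge tibble with `mid_lon`, `mid_lat`, `divergence`
#'   (see [edge_divergences()]).
#' @param sites Site table (defines the bounding box and the hull mask).
#' @param n_x,n_y Grid resolution (default 200 x 200).
#' @param power IDW exponent (default 2).
#' @param pad Fractional bounding-box padding (default 0.02).
#' @return A `landscape_grid`: tibble (`lon`, `lat`, `value`, `masked`)
#'   with grid metadata attributes.
#' @export
interpolate_surface <- function(edges, sites, n_x = 200, n_y = 200,
                                power = 2, pad = 0.02) {
  edges <- edges[!is.na(edges$divergence), ]
  if (nrow(edges) == 0L) abort("no edge values to interpolate", class = "cm_empty_input")
  rng_x <- range(sites$lon); rng_y <- range(sites$lat)
  px <- diff(rng_x) * pad; py <- diff(rng_y) * pad
  gx <- seq(rng_x[1] - px, rng_x[2] + px, length.out = n_x)
  gy <- seq(rng_y[1] - py, rng_y[2] + py, length.out = n_y)
  grid <- expand.grid(lon = gx, lat = gy, KEEP.OUT.ATTRS = FALSE)
  # IDW over all midpoints; exact value at coincident cells
  dx <- outer(grid$lon, edges$mid_lon, "-")
  dy <- outer(grid$lat, edges$mid_lat, "-")
  dist2 <- sqrt(dx^2 + dy^2)
  vals <- numeric(nrow(grid))
  hit <- dist2 < 1e-12
  any_hit <- rowSums(hit) > 0
  w <- 1 / dist2^power
  vals[!any_hit] <- (w[!any_hit, , drop = FALSE] %*% edges$divergence) /
    rowSums(w[!any_hit, , drop = FALSE])
  if (any(any_hit)) {
    vals[any_hit] <- apply(hit[any_hit, , drop = FALSE], 1,
                           function(h) edges$divergence[which(h)[1]])
  }
  hull <- grDevices::chull(sites$lon, sites$lat)
  bnd <- list(x = sites$lon[hull], y = sites$lat[hull])
  inside <- mgcv::in.out(cbind(c(bnd$x, bnd$x[1]), c(bnd$y, bnd$y[1])),
                         cbind(grid$lon, grid$lat))
  out <- tibble(lon = grid$lon, lat = grid$lat,
                value = ifelse(inside, vals, NA_real_), masked = !inside)
  attr(out, "n_x") <- n_x; attr(out, "n_y") <- n_y
  attr(out, "power") <- power
  attr(out, "bbox") <- c(xmin = min(gx), xmax = max(gx), ymin = min(gy), ymax = max(gy))
  class(out) <- c("landscape_grid", class(tibble()))
  out
}

#' @export
print.landscape_grid <- function(x, ...) {
  cat(sprintf("<landscape_grid> %d x %d cells, %d unmasked, value range [%.4f, %.4f]\n",
              attr(x, "n_x"), attr(x, "n_y"), sum(!x$masked),
              min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE)))
  invisible(x)
}

#' Plot a genetic landscape surface
#'
#' @param object A `landscape_grid`.
#' @param ... Unused.
#' @return A ggplot raster of divergence over the site hull.
#' @exportS3Method ggplot2::autoplot
autoplot.landscape_grid <- function(object, ...) {
  ggplot2::ggplot(object[!object$masked, ],
                  ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(colours = c("#2166ac", "#f7f7f7", "#b2182b"),
                                  name = "divergence") +
    ggplot2::coord_quickmap() +
    ggplot2::theme_minimal()
}

#' Write a landscape grid as an ESRI ASCII raster
#'
#' @param grid A `landscape_grid`.
#' @param path Output `.asc` path.
#' @param nodata NODATA value for masked cells (default -9999).
#' @return `path`, invisibly.
#' @export
write_landscape_asc <- function(grid, path, nodata = -9999) {
  n_x <- attr(grid, "n_x"); n_y <- attr(grid, "n_y")
  bb <- attr(grid, "bbox")
  vals <- matrix(ifelse(grid$masked, nodata, grid$value), nrow = n_y, byrow = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", n_x), sprintf("nrows %d", n_y),
               sprintf("xllcorner %.8f", bb["xmin"]),
               sprintf("yllcorner %.8f", bb["ymin"]),
               sprintf("cellsize %.10f", (bb["xmax"] - bb["xmin"]) / (n_x - 1)),
               sprintf("NODATA_value %d", nodata)), con)
  for (r in n_y:1) writeLines(paste(signif(vals[r, ], 7), collapse = " "), con)
  invisible(path)
}

#' Exclude lineages from a dataset
#'
#' Removes all records belonging to the excluded MOTUs (for example, to map
#' divergence without highly divergent endemic lineages), drops sites left
#' empty, and reports what remains.
#'
#' @param membership Record membership tibble (`record_id`, `site_id`,
#'   `haplotype_id`).
#' @param partition A `motu_partition` over the haplotypes.
#' @param excluded Character vector of MOTU labels to drop (must exist in
#'   the partition).
#' @return A list: `membership` (filtered tibble), `n_sites`,
#'   `n_haplotypes`, `n_records`, `empty` (TRUE when nothing remains).
#' @export
exclude_lineages <- function(membership, partition, excluded) {
  unknown <- setdiff(excluded, partition$motu)
  if (length(unknown)) {
    abort(paste0("unknown MOTU label(s): ", paste(unknown, collapse = ", ")),
          class = "cm_coverage_error")
  }
  lab <- partition_labels(partition)
  keep <- membership[!(lab[membership$haplotype_id] %in% excluded), ]
  list(membership = keep,
       n_sites = dplyr::n_distinct(keep$site_id),
       n_haplotypes = dplyr::n_distinct(keep$haplotype_id),
       n_records = nrow(keep),
       empty = nrow(keep) == 0L)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
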