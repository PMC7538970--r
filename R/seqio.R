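#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows distinct n count pull rename across
#' @importFrom tibble tibble as_tibble
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")

#' Construct a barcode alignment
#'
#' A `barcode_alignment` is a tibble of per-individual sequence records plus a
#' 0-based half-open column window marking the portion of the alignment used
#' for analysis. All sequences must share one aligned length; the analysis
#' window defaults to the full alignment.
#'
#' @param records A data frame with columns `record_id`, `site_id`,
#'   `sequence`, and optionally `source` (`"new"` or `"literature"`).
#' @param window Integer vector `c(start, end)`, 0-based half-open, within
#'   the aligned length.
#' @return A tibble of class `barcode_alignment` with columns `record_id`,
#'   `site_id`, `sequence`, `length_nt`, `source` and a `window` attribute.
#' @export
barcode_alignment <- function(records, window = NULL) {
  records <- as_tibble(records)
  if (nrow(records) == 0L) abort("alignment has no records", class = "cm_empty_input")
  if (!all(c("record_id", "sequence") %in% names(records))) {
    abort("records need at least `record_id` and `sequence` columns",
          class = "cm_format_error")
  }
  if (!"site_id" %in% names(records)) records$site_id <- NA_character_
  if (!"source" %in% names(records)) records$source <- "new"
  if (anyDuplicated(records$record_id)) {
    dup <- unique(records$record_id[duplicated(records$record_id)])
    abort(paste0("duplicate record_id: ", paste(dup, collapse = ", ")),
          class = "cm_format_error")
  }
  records$sequence <- toupper(records$sequence)
  lens <- nchar(records$sequence)
  if (length(unique(lens)) != 1L) {
    abort("sequences are not aligned to one common length", class = "cm_alignment_error")
  }
  bad <- !vapply(strsplit(records$sequence, ""),
                 function(ch) all(ch %in% IUPAC_CHARS), logical(1))
  if (any(bad)) {
    abort(paste0("non-IUPAC character in record(s): ",
                 paste(records$record_id[bad], collapse = ", ")),
          class = "cm_format_error")
  }
  records$length_nt <- nchar(gsub("[-?]", "", records$sequence))
  aln_len <- lens[[1]]
  if (is.null(window)) window <- c(0L, aln_len)
  window <- as.integer(window)
  if (window[1] < 0L || window[2] > aln_len || window[1] >= window[2]) {
    abort("window must be 0-based half-open within the aligned length",
          class = "cm_bounds_error")
  }
  out <- records[, c("record_id", "site_id", "sequence", "length_nt", "source")]
  attr(out, "window") <- window
  attr(out, "aligned_length") <- aln_len
  class(out) <- c("barcode_alignment", class(tibble()))
  out
}

#' @export
print.barcode_alignment <- function(x, ...) {
  w <- attr(x, "window")
  cat(sprintf("<barcode_alignment> %d records, aligned length %d, window [%d,%d)\n",
              nrow(x), attr(x, "aligned_length"), w[1], w[2]))
  NextMethod()
}

#' Read aligned barcode sequences from FASTA
#'
#' Headers are parsed as `record_id|site_id`; a site map (`record_id` to
#' `site_id` TSV) overrides or supplies site assignments for exports that do
#' not follow that convention.
#'
#' @param path FASTA file of pre-aligned (equal-length) DNA sequences.
#' @param site_map Optional path to a two-column TSV (`record_id`,
#'   `site_id`).
#' @param source Provenance tag recorded on every sequence, `"new"` or
#'   `"literature"`.
#' @return A [barcode_alignment] with the window spanning the full alignment.
#' @export
read_barcode_fasta <- function(path, site_map = NULL, source = "new") {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "cm_io_error")
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  parts <- strsplit(headers, "|", fixed = TRUE)
  rec <- tibble(
    record_id = vapply(parts, function(p) trimws(p[[1]]), character(1)),
    site_id = vapply(parts, function(p) if (length(p) >= 2) trimws(p[[2]]) else NA_character_,
                     character(1)),
    sequence = unname(as.character(ss)),
    source = source
  )
  if (!is.null(site_map)) {
    sm <- utils::read.delim(site_map, colClasses = "character")
    names(sm)[1:2] <- c("record_id", "site_id")
    rec <- rec |>
      select(-"site_id") |>
      left_join(sm[, c("record_id", "site_id")], by = "record_id")
  }
  barcode_alignment(rec)
}

#' Write a barcode alignment to FASTA
#'
#' Headers follow the `record_id|site_id` convention read back by
#' [read_barcode_fasta()].
#'
#' @param aln A [barcode_alignment].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(aln, path) {
  hdr <- ifelse(is.na(aln$site_id), aln$record_id,
                paste0(aln$record_id, "|", aln$site_id))
  ss <- Biostrings::BStringSet(aln$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = 80L)
  invisible(path)
}

#' Read a sampling-site table
#'
#' @param path TSV with header columns `site_id`, `lat`, `lon`, `altitude_m`,
#'   `country`.
#' @return A validated tibble (one row per site).
#' @export
read_site_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path), class = "cm_io_error")
  validate_site_table(as_tibble(utils::read.delim(path)))
}

#' Validate a site table
#'
#' Checks column presence, coordinate ranges and site-id uniqueness.
#'
#' @param sites Data frame with columns `site_id`, `lat`, `lon`,
#'   `altitude_m`, `country`.
#' @return The sites as a tibble.
#' @export
validate_site_table <- function(sites) {
  sites <- as_tibble(sites)
  need <- c("site_id", "lat", "lon", "altitude_m", "country")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    abort(paste0("site table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "cm_format_error")
  }
  if (anyDuplicated(sites$site_id)) abort("duplicate site_id", class = "cm_format_error")
  if (any(sites$lat < -90 | sites$lat > 90, na.rm = TRUE) ||
      any(sites$lon < -180 | sites$lon > 180, na.rm = TRUE)) {
    abort("coordinates outside WGS84 bounds", class = "cm_bounds_error")
  }
  sites
}

#' Trim an alignment to an analysis window
#'
#' Cuts every sequence to the 0-based half-open column interval
#' `[start, start + length)`. Records whose windowed sequence contains no
#' called base (all `N`/gap/`?`) are dropped with a message; the drop count is
#' available as attribute `n_dropped`.
#'
#' @param aln A [barcode_alignment].
#' @param start 0-based first column of the window.
#' @param length Number of columns to keep.
#' @return A [barcode_alignment] whose window spans the trimmed alignment.
#' @export
trim_to_window <- function(aln, start, length) {
  aln_len <- attr(aln, "aligned_length")
  if (start < 0 || start + length > aln_len) {
    abort(sprintf("window [%d,%d) outside alignment of length %d",
                  start, start + length, aln_len),
          class = "cm_bounds_error")
  }
  seqs <- substr(aln$sequence, start + 1L, start + length)
  keep <- grepl("[ACGTURYSWKMBDHV]", seqs)
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    inform(sprintf("dropping %d record(s) with no called base in the window", n_drop))
  }
  rec <- tibble(record_id = aln$record_id[keep], site_id = aln$site_id[keep],
                sequence = seqs[keep], source = aln$source[keep])
  out <- barcode_alignment(rec)
  attr(out, "n_dropped") <- n_drop
  out
}

#' Collapse aligned sequences into haplotypes
#'
#' Groups records by exact string identity of the windowed sequence. IUPAC
#' ambiguity codes, `N` and gaps are ordinary characters, so two sequences
#' share a haplotype only if their windowed strings are identical. Haplotype
#' ids are `H0001`, `H0002`, ... in order of first appearance.
#'
#' @param aln A [barcode_alignment] (typically after [trim_to_window()]).
#' @return A `haplotype_table`: a tibble with one row per haplotype
#'   (`haplotype_id`, `sequence`, `n_members`, `members` list-column) and a
#'   `membership` attribute mapping every `record_id` to its `haplotype_id`.
#' @export
collapse_haplotypes <- function(aln) {
  if (nrow(aln) == 0L) abort("empty alignment", class = "cm_empty_input")
  first_seen <- !duplicated(aln$sequence)
  uniq <- aln$sequence[first_seen]
  ids <- sprintf("H%04d", seq_along(uniq))
  hap_of <- ids[match(aln$sequence, uniq)]
  membership <- tibble(record_id = aln$record_id, site_id = aln$site_id,
                       haplotype_id = hap_of)
  tab <- membership |>
    group_by(.data$haplotype_id) |>
    summarise(n_members = n(), members = list(.data$record_id), .groups = "drop") |>
    arrange(.data$haplotype_id)
  tab$sequence <- uniq[match(tab$haplotype_id, ids)]
  out <- tab[, c("haplotype_id", "sequence", "n_members", "members")]
  attr(out, "membership") <- membership
  attr(out, "window") <- attr(aln, "window")
  class(out) <- c("haplotype_table", class(tibble()))
  out
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("<haplotype_table> %d haplotypes from %d records\n",
              nrow(x), nrow(attr(x, "membership"))))
  NextMethod()
}

#' Record-to-haplotype membership of a haplotype table
#'
#' @param haps A `haplotype_table` from [collapse_haplotypes()].
#' @return Tibble with columns `record_id`, `site_id`, `haplotype_id`.
#' @export
haplotype_membership <- function(haps) attr(haps, "membership")

#' Read a rooted tree from Newick
#'
#' @param path Newick file. Tips must be labelled and branch lengths present.
#' @param tip_universe Optional character vector of known ids (for example
#'   haplotype ids); any tip outside it raises an error naming the offenders.
#' @return An `ape` `phylo` tree.
#' @export
read_tree_newick <- function(path, tip_universe = NULL) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort("could not parse Newick file", class = "cm_format_error")
  if (is.null(tr$edge.length)) abort("tree lacks branch lengths", class = "cm_format_error")
  if (any(is.na(tr$tip.label)) || any(tr$tip.label == "")) {
    abort("tree has unlabeled tips", class = "cm_format_error")
  }
  if (!is.null(tip_universe)) {
    extra <- setdiff(tr$tip.label, tip_universe)
    if (length(extra)) {
      abort(paste0("tree tips absent from the haplotype table: ",
                   paste(extra, collapse = ", ")),
            class = "cm_coverage_error")
    }
  }
  tr
}

#' Write / read a MOTU partition as TSV
#'
#' The on-disk format is a 3-column TSV: `haplotype_id`, `method`,
#' `motu_label`.
#'
#' @param partition A `motu_partition` (see [partition_at_threshold()]).
#' @param path File path.
#' @return `write_partition()` returns `path` invisibly; `read_partition()`
#'   returns a `motu_partition`.
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(haplotype_id = partition$haplotype_id,
                   method = attr(partition, "method") %||% "NA",
                   motu_label = partition$motu)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition
#' @export
read_partition <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  new_partition(df$haplotype_id, df$motu_label, method = df$method[1])
}
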