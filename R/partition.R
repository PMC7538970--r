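#' MOTU partitions
#'
#' A `motu_partition` is a tibble with columns `haplotype_id` and `motu`
#' (character labels), carrying the delimitation `method` and its parameters
#' as attributes. Every id is labelled exactly once.
#'
#' @param ids Character vector of haplotype (or sequence) ids.
#' @param labels MOTU labels, one per id.
#' @param method Delimitation method name (`"ABGD"`, `"RESL"`, `"PTP"`,
#'   `"LAGRUE"`, or any user tag).
#' @param provenance Named list of the parameters that produced the
#'   partition.
#' @return A `motu_partition` tibble.
#' @export
new_partition <- function(ids, labels, method = "USER", provenance = list()) {
  if (length(ids) != length(labels)) abort("ids and labels differ in length",
                                           class = "cm_format_error")
  if (anyDuplicated(ids)) abort("duplicate id in partition", class = "cm_format_error")
  out <- tibble(haplotype_id = as.character(ids), motu = as.character(labels))
  attr(out, "method") <- method
  attr(out, "provenance") <- provenance
  class(out) <- c("motu_partition", class(tibble()))
  out
}

#' @export
print.motu_partition <- function(x, ...) {
  cat(sprintf("<motu_partition> method %s: %d ids in %d MOTUs\n",
              attr(x, "method"), nrow(x), dplyr::n_distinct(x$motu)))
  NextMethod()
}

#' Number of MOTUs in a partition
#'
#' @param partition A `motu_partition`.
#' @return Integer MOTU count.
#' @export
n_motus <- function(partition) dplyr::n_distinct(partition$motu)

#' MOTUs of a partition as a list of id sets
#'
#' @param partition A `motu_partition`.
#' @return Named list of character vectors (sorted ids per MOTU).
#' @export
partition_sets <- function(partition) {
  lapply(split(partition$haplotype_id, partition$motu), sort)
}

# canonical string form for comparing partitions as set-of-sets
partition_key <- function(partition) {
  sets <- vapply(partition_sets(partition),
                 function(s) paste(s, collapse = ","), character(1))
  paste(sort(unname(sets)), collapse = ";")
}

#' Do two partitions group the ids identically?
#'
#' Label names are ignored; only the induced set-of-sets matters.
#'
#' @param a,b `motu_partition`s over the same id universe.
#' @return Logical.
#' @export
same_partition <- function(a, b) {
  identical(sort(a$haplotype_id), sort(b$haplotype_id)) &&
    partition_key(a) == partition_key(b)
}

#' Labels of a partition as a named vector
#'
#' @param partition A `motu_partition`.
#' @return Character vector of MOTU labels named by id.
#' @export
partition_labels <- function(partition) {
  stats::setNames(partition$motu, partition$haplotype_id)
}

#' @export
tidy.motu_partition <- function(x, ...) {
  tibble(haplotype_id = x$haplotype_id, motu = x$motu,
         method = attr(x, "method"))
}

#' @export
glance.motu_partition <- function(x, ...) {
  sizes <- table(x$motu)
  tibble(method = attr(x, "method"), n_ids = nrow(x), n_motus = length(sizes),
         n_singletons = sum(sizes == 1L), largest_motu = max(sizes))
}

#' Tidy and summarise fitted objects
#'
#' `tidy()` returns one row per element (haplotype, MOTU, grid cell ...);
#' `glance()` returns a one-row summary. Methods exist for the package's
#' result classes.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @return A tibble.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")
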