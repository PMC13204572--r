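# Shared/exclusive partitioning of variant and gene sets across breeds:
# pairwise and three-way comparisons and the thirteen-list report.

#' Canonical variant keys
#'
#' Builds the positional identity key `chrom:pos:REF:ALT` (alleles
#' upper-cased) for each record. rsIDs are labels, not identity: two records
#' differing only in rsID share a key.
#'
#' @param records A variant table, or a `data.frame` with columns `chrom`,
#'   `pos`, `ref`, `alt`.
#' @return Character vector of keys.
#' @export
variant_key <- function(records) {
  if (any(!nzchar(records$ref)) || any(!nzchar(records$alt)))
    stop("empty allele in variant record")
  paste(records$chrom, records$pos, toupper(records$ref),
        toupper(records$alt), sep = ":")
}

#' Pairwise set partition
#'
#' Splits two key (or gene-symbol) sets into shared and exclusive cells.
#'
#' @param a,b Character vectors treated as sets.
#' @return List with `shared` (intersection), `only_a`, `only_b`.
#' @export
pairwise_partition <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  list(shared = intersect(a, b), only_a = setdiff(a, b),
       only_b = setdiff(b, a))
}

#' Three-way set partition
#'
#' Splits three sets into the seven disjoint Venn cells.
#'
#' @param a,b,c Character vectors treated as sets.
#' @param labels Population names for the three sets (cosmetic).
#' @return List with `labels` and `cells`, the latter a named list with
#'   elements `ABC`, `AB`, `AC`, `BC`, `A_only`, `B_only`, `C_only`. Cells are
#'   pairwise disjoint and cover the union of the inputs.
#' @export
threeway_partition <- function(a, b, c, labels = c("A", "B", "C")) {
  a <- unique(a)
  b <- unique(b)
  c <- unique(c)
  cells <- list(
    ABC = intersect(intersect(a, b), c),
    AB = setdiff(intersect(a, b), c),
    AC = setdiff(intersect(a, c), b),
    BC = setdiff(intersect(b, c), a),
    A_only = setdiff(a, union(b, c)),
    B_only = setdiff(b, union(a, c)),
    C_only = setdiff(c, union(a, b)))
  list(labels = labels, cells = cells)
}

#' Thirteen-list comparison report
#'
#' Produces the full set of shared/exclusive lists from the pairwise and
#' three-way comparisons of three populations: for each of the three pairs,
#' the shared set and the two pair-exclusive sets (nine lists), plus the
#' three-way core and the three breed-exclusive sets (four lists) — exactly
#' thirteen lists. Works on SNP keys or gene symbols alike.
#'
#' @param a,b,c Character vectors treated as sets.
#' @param labels Population names used in the list names.
#' @return Named list of thirteen character vectors.
#' @export
thirteen_list_report <- function(a, b, c, labels = c("A", "B", "C")) {
  stopifnot(length(labels) == 3L)
  out <- list()
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  sets <- list(unique(a), unique(b), unique(c))
  for (pr in pairs) {
    pp <- pairwise_partition(sets[[pr[1]]], sets[[pr[2]]])
    nm <- paste(labels[pr[1]], labels[pr[2]], sep = "_")
    out[[paste0(nm, "_shared")]] <- pp$shared
    out[[paste0(nm, "_only_", labels[pr[1]])]] <- pp$only_a
    out[[paste0(nm, "_only_", labels[pr[2]])]] <- pp$only_b
  }
  tw <- threeway_partition(sets[[1]], sets[[2]], sets[[3]], labels)$cells
  out[["core_shared"]] <- tw$ABC
  out[[paste0(labels[1], "_exclusive")]] <- tw$A_only
  out[[paste0(labels[2], "_exclusive")]] <- tw$B_only
  out[[paste0(labels[3], "_exclusive")]] <- tw$C_only
  out
}

#' Gene sets from variant tables
#'
#' Maps each breed's variant table to the set of (upper-cased) gene symbols it
#' touches, for gene-level comparisons.
#'
#' @param records A variant table.
#' @return Character vector of unique gene symbols.
#' @export
gene_set <- function(records) {
  unique(toupper(records$gene[nzchar(records$gene)]))
}

#' Venn cell counts
#'
#' Convenience summary of a three-way partition: the seven cell sizes plus
#' the pairwise margins.
#'
#' @param partition Output of [threeway_partition()].
#' @return Named integer vector.
#' @export
venn_counts <- function(partition) {
  cl <- partition$cells
  sizes <- vapply(cl, length, integer(1))
  margins <- c(
    AB_shared = length(cl$ABC) + length(cl$AB),
    AC_shared = length(cl$ABC) + length(cl$AC),
    BC_shared = length(cl$ABC) + length(cl$BC))
  c(sizes, margins)
}
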