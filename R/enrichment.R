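# Generic hypergeometric over-representation analysis against user-supplied
# gene sets. This is a documented stand-in for service-based enrichment
# (g:Profiler/g:SCS); q-values here use BH or Bonferroni and are not
# comparable to g:SCS-corrected results.

#' Read a GMT gene-set file
#'
#' GMT lines are tab-separated: set id, description, then member gene
#' symbols. Members are de-duplicated per set; empty sets are dropped with a
#' warning; duplicate set ids are an error.
#'
#' @param path GMT file path.
#' @param universe Optional character vector of background genes. Defaults to
#'   the union of all set members.
#' @return List with `sets` (named list of character vectors),
#'   `descriptions` (named character vector) and `universe`.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set id: ", ids[duplicated(ids)][1])
  desc <- vapply(parts, function(x) if (length(x) >= 2L) x[2] else "", "")
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- ids
  names(desc) <- ids
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping empty gene set(s): ",
            paste(ids[empty], collapse = ", "))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  if (is.null(universe)) universe <- unique(unlist(sets))
  if (!length(universe)) stop("empty gene universe")
  list(sets = sets, descriptions = desc, universe = unique(universe))
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for the overlap `k` between a query
#' list and a gene set under sampling without replacement from the universe,
#' `X ~ Hypergeometric(N, K, n)` with `N` the universe size, `K` the
#' in-universe set size, and `n` the query size. Query genes outside the
#' universe are dropped with a warning.
#'
#' @param query Character vector of query genes.
#' @param gene_set Character vector of set members.
#' @param universe Character vector of background genes.
#' @return p-value in (0, 1].
#' @export
ora_test <- function(query, gene_set, universe) {
  universe <- unique(universe)
  N <- length(universe)
  if (N == 0L) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  n <- length(query)
  if (n == 0L) stop("empty query after universe restriction")
  set_in <- intersect(unique(gene_set), universe)
  K <- length(set_in)
  k <- length(intersect(query, set_in))
  if (k == 0L) return(1)
  # upper tail P(X >= k); phyper is exclusive on the upper tail
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

#' Over-representation analysis of a query list against a collection
#'
#' Runs [ora_test()] per set and applies multiple-testing correction over all
#' tested sets.
#'
#' @param query Character vector of query genes.
#' @param collection Gene-set collection from [read_gmt()].
#' @param correction `"bh"` (Benjamini-Hochberg, default) or `"bonferroni"`.
#' @return `data.frame` with one row per set — `set_id`, `description`,
#'   `overlap_k`, `set_size_K`, `query_size_n`, `universe_N`, `p`, `q` —
#'   sorted by ascending p, ties by set id.
#' @export
enrich <- function(query, collection, correction = c("bh", "bonferroni")) {
  correction <- match.arg(correction)
  universe <- collection$universe
  query_in <- intersect(unique(query), universe)
  outside <- length(unique(query)) - length(query_in)
  if (outside > 0L)
    warning(outside, " query gene(s) outside the universe dropped")
  if (!length(query_in)) stop("empty query after universe restriction")
  rows <- lapply(names(collection$sets), function(id) {
    set_in <- intersect(collection$sets[[id]], universe)
    k <- length(intersect(query_in, set_in))
    p <- if (k == 0L) 1 else
      phyper(k - 1L, length(set_in), length(universe) - length(set_in),
             length(query_in), lower.tail = FALSE)
    data.frame(set_id = id,
               description = unname(collection$descriptions[id]),
               overlap_k = k, set_size_K = length(set_in),
               query_size_n = length(query_in),
               universe_N = length(universe), p = min(max(p, 0), 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- switch(correction,
                  bh = p.adjust(out$p, method = "BH"),
                  bonferroni = p.adjust(out$p, method = "bonferroni"))
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
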