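# Missense/indel prioritization and per-gene length-normalized variant
# densities (SNPs/kb, indels/kb).

#' Select prioritized missense SNPs
#'
#' Keeps exonic single-nucleotide variants whose predicted effect is
#' nonsynonymous (missense). Synonymous, stop-gain/loss, unknown-effect SNPs
#' and all indels are dropped.
#'
#' @param records A normalized variant table.
#' @return The missense rows.
#' @export
select_missense <- function(records) {
  keep <- records$vtype == "SNP" & records$region_class == "exonic" &
    records$func_class == "nonsynonymous"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select exonic indels
#'
#' Keeps all exonic insertions and deletions regardless of frameshift status.
#'
#' @param records A normalized variant table.
#' @return The exonic indel rows.
#' @export
select_exonic_indels <- function(records) {
  keep <- records$vtype %in% c("INS", "DEL") & records$region_class == "exonic"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene models
#'
#' Loads gene coordinates from either a 1-based TSV (columns `gene`,
#' `ensembl_id`, `chrom`, `start`, `end`) or a BED file (0-based half-open;
#' columns chrom, start, end, name — converted to 1-based inclusive on read).
#'
#' @param path Input path.
#' @param format `"tsv"` or `"bed"`.
#' @return A `data.frame` with columns `gene`, `ensembl_id`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @export
read_gene_models <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read gene model file: ", path)
  if (format == "tsv") {
    df <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(chrom = "character"))
    need <- c("gene", "chrom", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop("gene TSV missing column(s): ", paste(miss, collapse = ", "))
    if (is.null(df$ensembl_id)) df$ensembl_id <- ""
  } else {
    df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 4L) stop("BED gene file needs at least 4 columns")
    df <- data.frame(gene = as.character(df[[4]]), ensembl_id = "",
                     chrom = as.character(df[[1]]),
                     start = as.integer(df[[2]]) + 1L,
                     end = as.integer(df[[3]]), stringsAsFactors = FALSE)
  }
  if (any(df$end < df$start)) stop("gene model with end < start")
  df[, c("gene", "ensembl_id", "chrom", "start", "end")]
}

#' Compute gene lengths in kilobases
#'
#' Collapses gene models to one genomic span per gene — genes listed more than
#' once take the union span (min start, max end) — and returns the span length
#' in kb, `(end - start + 1) / 1000`.
#'
#' @param models Gene models as returned by [read_gene_models()].
#' @return Named numeric vector, gene symbol -> length in kb.
#' @export
compute_gene_lengths <- function(models) {
  if (any(models$end < models$start)) stop("gene model with end < start")
  split_idx <- split(seq_len(nrow(models)), models$gene)
  lengths_kb <- vapply(split_idx, function(i) {
    chroms <- unique(models$chrom[i])
    if (length(chroms) > 1L)
      stop("gene '", models$gene[i[1]], "' annotated on multiple chromosomes: ",
           paste(chroms, collapse = ", "))
    (max(models$end[i]) - min(models$start[i]) + 1) / 1000
  }, numeric(1))
  lengths_kb
}

#' Per-gene normalized variant densities
#'
#' Counts prioritized missense SNPs and exonic indels per gene and normalizes
#' by gene length: `snp_density = snp_count / length_kb` (SNPs/kb) and
#' likewise for indels. Genes carrying variants but absent from the length
#' table are excluded and listed in the `"unmapped_genes"` attribute.
#'
#' @param snps Missense SNP table ([select_missense()]).
#' @param indels Exonic indel table ([select_exonic_indels()]).
#' @param lengths Named vector of gene lengths in kb
#'   ([compute_gene_lengths()]).
#' @return `data.frame` with columns `gene`, `snp_count`, `indel_count`,
#'   `length_kb`, `snp_density`, `indel_density`, one row per gene present in
#'   both a variant set and the length table.
#' @export
compute_density <- function(snps, indels, lengths) {
  genes_seen <- unique(c(snps$gene, indels$gene))
  mapped <- genes_seen[genes_seen %in% names(lengths)]
  unmapped <- setdiff(genes_seen, mapped)
  mapped <- sort(mapped)
  snp_count <- as.integer(table(factor(snps$gene, levels = mapped)))
  indel_count <- as.integer(table(factor(indels$gene, levels = mapped)))
  len_kb <- unname(lengths[mapped])
  out <- data.frame(gene = mapped, snp_count = snp_count,
                    indel_count = indel_count, length_kb = len_kb,
                    snp_density = snp_count / len_kb,
                    indel_density = indel_count / len_kb,
                    stringsAsFactors = FALSE)
  attr(out, "unmapped_genes") <- unmapped
  out
}

#' Top genes by variant density
#'
#' Ranks density records in descending order of the chosen metric, breaking
#' ties by ascending gene symbol, and returns the first `n`.
#'
#' @param density_records Output of [compute_density()].
#' @param metric `"snp_density"` or `"indel_density"`.
#' @param n Number of genes to return (the whole ranking if shorter).
#' @return The top-`n` rows in rank order.
#' @export
top_n_genes <- function(density_records, metric = c("snp_density",
                                                    "indel_density"),
                        n = 20L) {
  metric <- match.arg(metric)
  if (n < 1L) stop("n must be >= 1")
  ord <- order(-density_records[[metric]], density_records$gene)
  out <- density_records[ord[seq_len(min(n, length(ord)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}
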