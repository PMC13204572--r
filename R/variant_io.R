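# Reading, quality filtering, normalization and functional tallying of
# annotated variant records for a single breed/sample.

# ANNOVAR-style functional class strings -> internal classes. Fixed mapping;
# anything else on an exonic_variant_function line is treated as malformed.
ANNOVAR_CLASS_MAP <- c(
  "nonsynonymous SNV"       = "nonsynonymous",
  "synonymous SNV"          = "synonymous",
  "stopgain"                = "stopgain",
  "stoploss"                = "stoploss",
  "unknown"                 = "unknown",
  "frameshift insertion"    = "indel_frameshift",
  "frameshift deletion"     = "indel_frameshift",
  "nonframeshift insertion" = "indel_nonframeshift",
  "nonframeshift deletion"  = "indel_nonframeshift"
)

#' Build a variant table
#'
#' Assembles a normalized variant table (one row per site/alternate-allele
#' pair) from parallel vectors, inferring the variant type from the allele
#' lengths. Alleles are upper-cased. ANNOVAR-style gap alleles (`"-"`) are
#' honoured: a reference of `"-"` denotes an insertion and an alternate of
#' `"-"` a deletion.
#'
#' @param chrom,pos,ref,alt Coordinates (1-based) and alleles.
#' @param rsid Optional identifier; `""` when absent.
#' @param dp,mq Read depth and mapping quality at the site (`NA` when the
#'   source format does not carry them).
#' @param region_class One of `"exonic"`, `"intronic"`, `"intergenic"`,
#'   `"other"`.
#' @param func_class Functional class (see [ANNOVAR_CLASS_MAP] values), or
#'   `"none"`.
#' @param gene Gene symbol, `""` when unannotated.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `rsid`,
#'   `dp`, `mq`, `region_class`, `func_class`, `gene`, `vtype`.
#' @export
variant_table <- function(chrom, pos, ref, alt, rsid = "", dp = NA_integer_,
                          mq = NA_real_, region_class = "other",
                          func_class = "none", gene = "") {
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(rsid), length(dp), length(mq), length(region_class),
           length(func_class), length(gene))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  ref <- rep_len(toupper(as.character(ref)), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("empty REF or ALT allele")
  pos <- as.integer(pos)
  if (any(is.na(pos)) || any(pos < 1L))
    stop("positions must be integers >= 1")
  bad_r <- setdiff(unique(region_class), REGION_CLASSES)
  if (length(bad_r)) stop("unknown region_class: ", paste(bad_r, collapse = ", "))
  bad_f <- setdiff(unique(func_class), FUNC_CLASSES)
  if (length(bad_f)) stop("unknown func_class: ", paste(bad_f, collapse = ", "))
  reflen <- ifelse(ref == "-", 0L, nchar(ref))
  altlen <- ifelse(alt == "-", 0L, nchar(alt))
  vtype <- ifelse(altlen > reflen, "INS",
                  ifelse(reflen > altlen, "DEL", "SNP"))
  if (any(reflen == altlen & reflen > 1L))
    stop("multi-nucleotide substitutions are not supported")
  data.frame(chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
             rsid = rep_len(as.character(rsid), n),
             dp = rep_len(as.integer(dp), n), mq = rep_len(as.double(mq), n),
             region_class = rep_len(region_class, n),
             func_class = rep_len(func_class, n),
             gene = rep_len(as.character(gene), n),
             vtype = vtype, stringsAsFactors = FALSE)
}

#' Read an annotated variant table
#'
#' Parses single-sample variant calls from either a VCF (plain or bgzipped;
#' per-site `DP` and `MQ` are taken from the INFO field) or an ANNOVAR
#' `exonic_variant_function`-style TSV. Multi-allelic VCF sites are split into
#' one record per alternate allele.
#'
#' The ANNOVAR dialect is tab-separated with columns: line id, functional
#' class, gene annotation string (`GENE:transcript:...`), chrom, start, end,
#' ref, alt, plus optional trailing numeric `DP` and `MQ` fields. The gene
#' symbol is the first `:`-delimited token of the annotation string.
#'
#' @param path Path to the input file.
#' @param dialect `"vcf"` or `"annovar_exonic"`.
#' @return A variant table as built by [variant_table()].
#' @export
read_variant_table <- function(path, dialect = c("vcf", "annovar_exonic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read variant file: ", path)
  if (dialect == "vcf") read_vcf_dialect(path) else read_annovar_dialect(path)
}

read_vcf_dialect <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  dp <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "DP")))
  mq <- suppressWarnings(as.double(vcfR::extract.info(vcf, "MQ")))
  rsid <- fix[, "ID"]
  rsid[is.na(rsid) | rsid == "."] <- ""
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  idx <- rep(seq_along(alts), lengths(alts))
  variant_table(chrom = fix[idx, "CHROM"], pos = fix[idx, "POS"],
                ref = fix[idx, "REF"], alt = unlist(alts),
                rsid = rsid[idx], dp = dp[idx], mq = mq[idx])
}

read_annovar_dialect <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (!length(raw)) {
    return(variant_table(character(), integer(), character(),
                         character())[0, ])
  }
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad))
    stop("malformed ANNOVAR line ", bad[1], ": expected >= 8 fields")
  get <- function(i) vapply(parts, `[`, "", i)
  cls_raw <- get(2L)
  unknown <- which(!cls_raw %in% names(ANNOVAR_CLASS_MAP))
  if (length(unknown))
    stop("malformed ANNOVAR line ", unknown[1],
         ": unrecognised functional class '", cls_raw[unknown[1]], "'")
  pos <- suppressWarnings(as.integer(get(5L)))
  if (anyNA(pos))
    stop("malformed ANNOVAR line ", which(is.na(pos))[1],
         ": non-integer start position")
  gene_str <- get(3L)
  gene <- vapply(strsplit(gene_str, ":", fixed = TRUE), function(x) {
    if (length(x)) x[1] else ""
  }, "")
  gene[gene_str == "." | is.na(gene_str)] <- ""
  dp <- rep(NA_integer_, length(raw))
  mq <- rep(NA_real_, length(raw))
  has9 <- lengths(parts) >= 9L
  dp[has9] <- suppressWarnings(as.integer(get(9L)[has9]))
  has10 <- lengths(parts) >= 10L
  mq[has10] <- suppressWarnings(as.double(get(10L)[has10]))
  variant_table(chrom = get(4L), pos = pos, ref = get(7L), alt = get(8L),
                dp = dp, mq = mq, region_class = "exonic",
                func_class = unname(ANNOVAR_CLASS_MAP[cls_raw]),
                gene = gene)
}

#' Quality-filter variant records
#'
#' Retains records with read depth and mapping quality strictly above the
#' thresholds (`DP > dp_min` and `MQ > mq_min`). Records missing either field
#' are rejected with a warning. A breakdown of removals is attached as the
#' `"filter_report"` attribute (categories `missing_quality`, `low_dp`,
#' `low_mq`; a record is counted in the first category that applies).
#'
#' @param records A variant table.
#' @param dp_min,mq_min Exclusive thresholds (defaults 4 and 20).
#' @return The retained rows, input order preserved.
#' @export
apply_quality_filters <- function(records, dp_min = 4L, mq_min = 20) {
  missing_q <- is.na(records$dp) | is.na(records$mq)
  low_dp <- !missing_q & records$dp <= dp_min
  low_mq <- !missing_q & !low_dp & records$mq <= mq_min
  keep <- !missing_q & !low_dp & !low_mq
  if (any(missing_q))
    warning(sum(missing_q), " record(s) rejected for missing DP/MQ")
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- list(
    n_input = nrow(records), n_retained = sum(keep), n_removed = sum(!keep),
    removed = c(missing_quality = sum(missing_q), low_dp = sum(low_dp),
                low_mq = sum(low_mq)))
  out
}

#' Drop unannotated records and collapse duplicates
#'
#' Removes records whose gene annotation is a missing-value sentinel, then
#' collapses duplicates — records sharing (chrom, pos, ref, alt) — keeping the
#' first occurrence. Counts are attached as the `"dedupe_report"` attribute.
#'
#' @param records A variant table (multi-allelic sites already split).
#' @param invalid_gene Character vector of gene-field sentinels treated as
#'   missing annotation.
#' @return The surviving rows, first occurrences, input order preserved.
#' @export
normalize_and_dedupe <- function(records,
                                 invalid_gene = c("", "NA", "NONE", "-")) {
  bad_gene <- is.na(records$gene) | records$gene %in% invalid_gene
  kept <- records[!bad_gene, , drop = FALSE]
  key <- variant_key(kept)
  dup <- duplicated(key)
  out <- kept[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dedupe_report") <- list(
    n_input = nrow(records), n_invalid_gene = sum(bad_gene),
    n_duplicates = sum(dup), n_output = nrow(out))
  out
}

#' Tally SNP functional classes
#'
#' Counts records per predicted functional class (synonymous, nonsynonymous,
#' stop-gain, stop-loss, unknown). All records must be SNPs.
#'
#' @param records A variant table of SNPs.
#' @return A list with `counts` (named integer vector over the five classes)
#'   and `total`.
#' @export
tally_functional_classes <- function(records) {
  if (any(records$vtype != "SNP"))
    stop("tally_functional_classes expects SNP records only")
  bad <- setdiff(unique(records$func_class), SNP_FUNC_CLASSES)
  if (length(bad))
    stop("non-SNP functional class present: ", paste(bad, collapse = ", "))
  counts <- table(factor(records$func_class, levels = SNP_FUNC_CLASSES))
  counts <- setNames(as.integer(counts), SNP_FUNC_CLASSES)
  list(counts = counts, total = sum(counts))
}

#' Write a filtered variant table
#'
#' @param records A variant table.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  cols <- c("chrom", "pos", "rsid", "ref", "alt", "vtype", "func_class",
            "gene")
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a filtered variant table written by [write_variant_table()]
#'
#' @param path TSV path.
#' @return A variant table (quality fields absent are `NA`).
#' @export
read_filtered_variants <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character", rsid = "character"))
  variant_table(df$chrom, df$pos, df$ref, df$alt, rsid = df$rsid,
                region_class = "exonic", func_class = df$func_class,
                gene = df$gene)
}
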