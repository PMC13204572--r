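# Validation-phase statistics: genotype call-rate QC, per-breed allele
# frequencies, exact/approximate contingency tests with BH FDR control, and
# the four-way pattern classification of validated SNPs against their
# discovery-phase breed labels.

#' Classifier configuration
#'
#' @param alpha Significance level on FDR-adjusted q-values (default 0.05).
#' @param delta Allele-frequency margin separating a "consistent but not
#'   significant" call from an inconsistent one, for breed-specific SNPs
#'   (default 0.08).
#' @param m Number of tests for the FDR family; `NULL` means the number of
#'   SNPs tested together.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(alpha = 0.05, delta = 0.08, m = NULL) {
  stopifnot(alpha > 0, alpha < 1, delta >= 0, delta < 1)
  structure(list(alpha = alpha, delta = delta, m = m),
            class = "classifier_config")
}

#' Load a wide genotype matrix
#'
#' Reads a TSV with header `sample_id`, `breed`, then one column per SNP.
#' Genotype tokens are `"A/G"`-style diploid calls or `"./."` for missing.
#' When `meta` (a `data.frame` with `snp_id`, `ref`, `alt`) is supplied,
#' alleles are validated against it.
#'
#' @param path Genotype TSV path.
#' @param meta Optional per-SNP ref/alt map.
#' @param breeds Allowed breed labels.
#' @return List with `samples` (`data.frame`: `sample_id`, `breed`), `snps`
#'   (character), and `calls` (character matrix samples x snps, `NA` for
#'   missing).
#' @export
load_genotypes <- function(path, meta = NULL, breeds = BREEDS) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (!all(c("sample_id", "breed") %in% names(df)))
    stop("genotype TSV must start with sample_id and breed columns")
  snps <- setdiff(names(df), c("sample_id", "breed"))
  bad_breed <- setdiff(unique(df$breed), breeds)
  if (length(bad_breed))
    stop("unknown breed label(s): ", paste(bad_breed, collapse = ", "))
  calls <- as.matrix(df[, snps, drop = FALSE])
  rownames(calls) <- df$sample_id
  calls[calls %in% c("./.", ".", "")] <- NA_character_
  present <- !is.na(calls)
  toks <- strsplit(calls[present], "/", fixed = TRUE)
  if (any(lengths(toks) != 2L))
    stop("genotype token without exactly two alleles")
  if (!is.null(meta)) {
    for (s in snps) {
      mrow <- meta[meta$snp_id == s, , drop = FALSE]
      if (!nrow(mrow)) stop("SNP missing from metadata: ", s)
      ok <- c(mrow$ref[1], mrow$alt[1])
      al <- unlist(strsplit(calls[!is.na(calls[, s]), s], "/", fixed = TRUE))
      bad <- setdiff(unique(al), ok)
      if (length(bad))
        stop("allele '", bad[1], "' at ", s, " not in {",
             paste(ok, collapse = ","), "}")
    }
  }
  list(samples = data.frame(sample_id = df$sample_id, breed = df$breed,
                            stringsAsFactors = FALSE),
       snps = snps, calls = calls)
}

#' Call-rate quality control
#'
#' Drops samples whose call rate (fraction of non-missing genotypes across
#' SNPs) falls below `threshold`, then SNPs whose call rate over the
#' remaining samples falls below `threshold`.
#'
#' @param gm Genotype matrix from [load_genotypes()].
#' @param threshold Completeness threshold (default 0.90).
#' @return List with the filtered `matrix` and a `report` holding per-sample
#'   and per-SNP call rates and the excluded ids.
#' @export
qc_call_rates <- function(gm, threshold = 0.90) {
  sample_rate <- rowMeans(!is.na(gm$calls))
  keep_s <- sample_rate >= threshold
  if (!any(keep_s)) stop("all samples fail the call-rate threshold")
  calls2 <- gm$calls[keep_s, , drop = FALSE]
  snp_rate <- colMeans(!is.na(calls2))
  keep_v <- snp_rate >= threshold
  out <- list(samples = gm$samples[keep_s, , drop = FALSE],
              snps = gm$snps[keep_v],
              calls = calls2[, keep_v, drop = FALSE])
  rownames(out$samples) <- NULL
  report <- list(sample_call_rate = sample_rate, snp_call_rate = snp_rate,
                 excluded_samples = gm$samples$sample_id[!keep_s],
                 excluded_snps = gm$snps[!keep_v], threshold = threshold)
  list(matrix = out, report = report)
}

#' Per-breed allele frequencies
#'
#' Counts ref/alt alleles per SNP and breed over non-missing calls, and
#' reports the alternate-allele frequency `alt / (2 * n_called)` (`NA` when a
#' breed has no calls).
#'
#' @param gm Genotype matrix (after QC).
#' @param meta Per-SNP metadata with columns `snp_id`, `ref`, `alt`.
#' @return `data.frame` with one row per SNP x breed: `snp_id`, `breed`,
#'   `n_called`, `ref_count`, `alt_count`, `af`.
#' @export
allele_frequencies <- function(gm, meta) {
  breeds <- unique(gm$samples$breed)
  rows <- list()
  for (s in gm$snps) {
    mrow <- meta[meta$snp_id == s, , drop = FALSE]
    if (!nrow(mrow)) stop("SNP missing from metadata: ", s)
    alt <- mrow$alt[1]
    for (b in breeds) {
      calls <- gm$calls[gm$samples$breed == b, s]
      calls <- calls[!is.na(calls)]
      n_called <- length(calls)
      alleles <- unlist(strsplit(calls, "/", fixed = TRUE))
      alt_count <- sum(alleles == alt)
      ref_count <- length(alleles) - alt_count
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s, breed = b, n_called = n_called, ref_count = ref_count,
        alt_count = alt_count,
        af = if (n_called > 0) alt_count / (2 * n_called) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exact test of allele-distribution homogeneity for a 2 x c table
#'
#' Two-sided exact test by complete enumeration of all 2 x c tables sharing
#' the observed margins. Each table's probability is the multivariate
#' hypergeometric mass; the p-value sums the mass of tables no more probable
#' than the observed one, with a small relative tie tolerance
#' (`P(T) <= P(obs) * (1 + 1e-7)`) guarding floating-point misses of exact
#' ties. Computation is in log space (compiled).
#'
#' @param table Integer matrix with 2 rows (ref/alt allele counts) and
#'   `c >= 2` columns (breeds).
#' @return p-value in (0, 1].
#' @export
fisher_exact_2xc <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) != 2L) stop("table must have exactly 2 rows")
  if (ncol(table) < 2L) stop("table must have at least 2 columns")
  if (any(table < 0)) stop("negative cell count")
  if (any(table != round(table))) stop("non-integer cell count")
  if (sum(table) < 1) stop("table total must be >= 1")
  .fisher2xc_cpp(as.integer(table[1, ]), as.integer(table[2, ]), 1e-7)
}

#' Batched exact tests
#'
#' Runs [fisher_exact_2xc()] on many tables with a shared column count.
#'
#' @param row1,row2 Integer matrices; row i of each gives the first/second
#'   row of the i-th 2 x c table.
#' @return Numeric vector of p-values.
#' @export
fisher_exact_2xc_many <- function(row1, row2) {
  row1 <- as.matrix(row1)
  row2 <- as.matrix(row2)
  stopifnot(identical(dim(row1), dim(row2)))
  if (any(row1 < 0) || any(row2 < 0)) stop("negative cell count")
  storage.mode(row1) <- "integer"
  storage.mode(row2) <- "integer"
  .fisher2xc_batch_cpp(row1, row2, 1e-7)
}

#' Pearson chi-squared test of homogeneity
#'
#' Pearson statistic with `df = (r - 1)(c - 1)` and upper-tail chi-squared
#' p-value. All expected counts must be positive; callers should fall back to
#' the exact test otherwise.
#'
#' @param table Non-negative count matrix.
#' @return List with `statistic`, `df`, `p`.
#' @export
chisq_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative cell count")
  n <- sum(table)
  expected <- outer(rowSums(table), colSums(table)) / n
  if (any(expected <= 0)) stop("zero expected count; use the exact test")
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df, p = pchisq(stat, df, lower.tail = FALSE))
}

#' Choose between exact and chi-squared tests
#'
#' Default rule: exact test if any expected count is below 5, chi-squared
#' otherwise. `mode = "fisher-always"` (the pipeline default for panel
#' reproduction) forces the exact test; `mode = "chisq-always"` forces
#' chi-squared.
#'
#' @param table 2 x c count matrix.
#' @param mode `"auto"`, `"fisher-always"`, or `"chisq-always"`.
#' @return List with `p` and `method` (`"fisher"` or `"chisq"`).
#' @export
choose_test <- function(table, mode = c("auto", "fisher-always",
                                        "chisq-always")) {
  mode <- match.arg(mode)
  table <- as.matrix(table)
  if (mode == "fisher-always")
    return(list(p = fisher_exact_2xc(table), method = "fisher"))
  if (mode == "chisq-always")
    return(list(p = chisq_test(table)$p, method = "chisq"))
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5))
    list(p = fisher_exact_2xc(table), method = "fisher")
  else
    list(p = chisq_test(table)$p, method = "chisq")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR q-values: sort p ascending, `r_i = p_(i) * m / i`, take the
#' running minimum from the largest rank down, cap at 1, and map back to the
#' input order. Delegates to [stats::p.adjust()] with family size `m`.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @param m Family size (defaults to `length(pvalues)`).
#' @return q-values in input order.
#' @export
bh_adjust <- function(pvalues, m = length(pvalues)) {
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop("p-values must lie in (0, 1]")
  if (m < length(pvalues)) stop("m must be >= length(pvalues)")
  p.adjust(pvalues, method = "BH", n = m)
}

#' Classify one validated SNP against its discovery-phase label
#'
#' Four-way pattern call relating observed breed allele frequencies to the
#' whole-genome discovery classification:
#' \itemize{
#'   \item `wgs_class = "Common"`: `"Shared"` if `q >= alpha`, else
#'     `"Inconsistent"`.
#'   \item breed-specific: if the target breed's AF is not the strict maximum
#'     across breeds, `"Inconsistent"`. Otherwise, with
#'     `margin = AF(target) - max(other AFs)`: `"Significant"` if
#'     `q < alpha`; else `"Consistent (NS)"` if `margin >= delta`; else
#'     `"Inconsistent"`.
#' }
#'
#' @param wgs_class `"LES-specific"`, `"SER-specific"`, `"THR-specific"`, or
#'   `"Common"`.
#' @param af Named numeric vector of per-breed alternate-allele frequencies
#'   (names `LES`, `SER`, `THR`).
#' @param q FDR-adjusted q-value for the SNP.
#' @param config A [classifier_config()].
#' @return List with `pattern` and `margin` (`NA` for Common-class SNPs).
#' @export
classify_pattern <- function(wgs_class, af, q, config = classifier_config()) {
  if (any(is.na(af))) stop("missing allele frequency")
  if (is.na(q)) stop("missing q-value")
  if (wgs_class == "Common") {
    pattern <- if (q >= config$alpha) "Shared" else "Inconsistent"
    return(list(pattern = pattern, margin = NA_real_))
  }
  target <- sub("-specific$", "", wgs_class)
  if (!target %in% names(af))
    stop("unknown WGS classification: ", wgs_class)
  others <- af[setdiff(names(af), target)]
  margin <- unname(af[target] - max(others))
  if (margin <= 0) return(list(pattern = "Inconsistent", margin = margin))
  pattern <- if (q < config$alpha) "Significant"
             else if (margin >= config$delta) "Consistent (NS)"
             else "Inconsistent"
  list(pattern = pattern, margin = margin)
}

#' Reconstruct allele counts from a rounded frequency
#'
#' Inverts a reported alternate-allele frequency to integer counts for
#' `n_called` diploid animals: `alt = round-half-up(af * 2 * n_called)`,
#' `ref = 2 * n_called - alt`. Enables recomputation of the panel statistics
#' from published frequencies.
#'
#' @param af Alternate-allele frequency in \[0, 1\].
#' @param n_called Number of genotyped animals.
#' @return Named integer vector `c(ref, alt)`.
#' @export
reconstruct_counts <- function(af, n_called) {
  stopifnot(af >= 0, af <= 1, n_called >= 1)
  alt <- as.integer(floor(af * 2 * n_called + 0.5))
  c(ref = as.integer(2 * n_called - alt), alt = alt)
}

#' Validate a panel from published per-breed frequencies
#'
#' Frequency-mode pipeline: reconstructs per-breed allele counts from rounded
#' frequencies ([reconstruct_counts()]), tests allele-distribution
#' homogeneity per SNP, adjusts p-values by BH over the panel, and classifies
#' every SNP against its discovery-phase label.
#'
#' @param tbl `data.frame` with columns `snp_id`, `wgs_class`, `af_les`,
#'   `af_ser`, `af_thr` (e.g. [table5_fixture()]).
#' @param n_per_breed Genotyped animals per breed (default 18).
#' @param config A [classifier_config()].
#' @param mode Test-selection mode, see [choose_test()].
#' @return `data.frame` with per-SNP counts, `p`, `q`, `method`, `margin`,
#'   and `pattern`.
#' @export
validate_from_frequencies <- function(tbl, n_per_breed = 18L,
                                      config = classifier_config(),
                                      mode = "fisher-always") {
  afm <- as.matrix(tbl[, c("af_les", "af_ser", "af_thr")])
  colnames(afm) <- BREEDS
  alt <- matrix(floor(afm * 2 * n_per_breed + 0.5), ncol = 3,
                dimnames = list(NULL, BREEDS))
  ref <- 2 * n_per_breed - alt
  res <- lapply(seq_len(nrow(tbl)), function(i) {
    choose_test(rbind(ref = ref[i, ], alt = alt[i, ]), mode = mode)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  method <- vapply(res, `[[`, character(1), "method")
  m <- if (is.null(config$m)) length(p) else config$m
  q <- bh_adjust(p, m = m)
  cls <- lapply(seq_len(nrow(tbl)), function(i) {
    classify_pattern(tbl$wgs_class[i], afm[i, ], q[i], config)
  })
  out <- data.frame(snp_id = tbl$snp_id, wgs_class = tbl$wgs_class,
                    af_les = afm[, "LES"], af_ser = afm[, "SER"],
                    af_thr = afm[, "THR"], p = p, q = q, method = method,
                    margin = vapply(cls, `[[`, numeric(1), "margin"),
                    pattern = vapply(cls, `[[`, character(1), "pattern"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full validation pipeline from genotypes
#'
#' Runs call-rate QC, per-breed allele-frequency estimation, per-SNP tests of
#' allele-distribution homogeneity, BH adjustment over the panel, and the
#' four-way pattern classification.
#'
#' @param gm Genotype matrix from [load_genotypes()].
#' @param meta Per-SNP metadata: `snp_id`, `gene`, `wgs_class`, `ref`, `alt`.
#' @param config A [classifier_config()].
#' @param mode Test-selection mode, see [choose_test()].
#' @param qc_threshold Call-rate threshold (default 0.90).
#' @return List with `results` (per-SNP `data.frame`), `frequencies` (long
#'   per-SNP x breed table), `qc` (QC report), and `summary` (pattern
#'   counts).
#' @export
validate_panel <- function(gm, meta, config = classifier_config(),
                           mode = "fisher-always", qc_threshold = 0.90) {
  qc <- qc_call_rates(gm, threshold = qc_threshold)
  freq <- allele_frequencies(qc$matrix, meta)
  snps <- qc$matrix$snps
  res <- lapply(snps, function(s) {
    f <- freq[freq$snp_id == s, , drop = FALSE]
    f <- f[match(BREEDS, f$breed), , drop = FALSE]
    tab <- rbind(ref = f$ref_count, alt = f$alt_count)
    colnames(tab) <- BREEDS
    choose_test(tab, mode = mode)
  })
  p <- vapply(res, `[[`, numeric(1), "p")
  method <- vapply(res, `[[`, character(1), "method")
  m <- if (is.null(config$m)) length(p) else config$m
  q <- bh_adjust(p, m = m)
  af_by_snp <- do.call(rbind, lapply(snps, function(s) {
    f <- freq[freq$snp_id == s, , drop = FALSE]
    setNames(f$af[match(BREEDS, f$breed)], BREEDS)
  }))
  meta_idx <- match(snps, meta$snp_id)
  if (anyNA(meta_idx)) stop("SNP missing from metadata")
  cls <- lapply(seq_along(snps), function(i) {
    classify_pattern(meta$wgs_class[meta_idx[i]], af_by_snp[i, ], q[i],
                     config)
  })
  results <- data.frame(
    snp_id = snps,
    gene = if ("gene" %in% names(meta)) meta$gene[meta_idx] else "",
    wgs_class = meta$wgs_class[meta_idx],
    af_les = af_by_snp[, "LES"], af_ser = af_by_snp[, "SER"],
    af_thr = af_by_snp[, "THR"], p = p, q = q, method = method,
    margin = vapply(cls, `[[`, numeric(1), "margin"),
    pattern = vapply(cls, `[[`, character(1), "pattern"),
    stringsAsFactors = FALSE)
  rownames(results) <- NULL
  summary <- table(factor(results$pattern,
                          levels = c("Significant", "Consistent (NS)",
                                     "Shared", "Inconsistent")))
  list(results = results, frequencies = freq, qc = qc$report,
       summary = setNames(as.integer(summary), names(summary)))
}
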