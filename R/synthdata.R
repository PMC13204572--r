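# Seeded synthetic-data generation emulating the statistical structure of
# the study inputs: gene models with known lengths, per-breed variant tables
# with configurable shared/exclusive fractions and functional-class mix, and
# diploid genotype matrices drawn under Hardy-Weinberg equilibrium. The
# published 46-SNP validation panel ships as a packaged fixture.

#' Simulation configuration
#'
#' Defaults mirror the study conditions: three breeds, a 46-SNP validation
#' panel genotyped in 18 animals per breed, and sample call rates in the
#' 90-100% range. Functional-class probabilities default to the observed
#' discovery-phase class mix (synonymous-dominated, with missense the second
#' largest class and rare stop-gain/stop-loss/unknown calls).
#'
#' @param seed Integer RNG seed; identical configurations give identical
#'   outputs.
#' @param n_genes Number of synthetic gene models.
#' @param gene_length_range_bp Min/max gene length in bp.
#' @param variants_per_breed Exonic SNVs generated per breed.
#' @param shared_fraction Fraction of each breed's variants drawn from a pool
#'   common to all breeds.
#' @param class_probs Probabilities over the five SNP functional classes
#'   (synonymous, nonsynonymous, stopgain, stoploss, unknown); must sum to 1.
#' @param indels_per_breed Exonic indels generated per breed.
#' @param n_snps_panel Panel size for genotype simulation.
#' @param n_animals_per_breed Validation-cohort animals per breed.
#' @param missing_rate Per-call missingness probability in \[0, 0.1\].
#' @param af_spec Optional matrix (SNPs x breeds) of true alternate-allele
#'   frequencies; built by [panel_af_spec()] when `NULL`.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 100L,
                              gene_length_range_bp = c(1000L, 5000L),
                              variants_per_breed = 300L,
                              shared_fraction = 0.4,
                              class_probs = c(synonymous = 0.595,
                                              nonsynonymous = 0.39,
                                              stopgain = 0.012,
                                              stoploss = 0.002,
                                              unknown = 0.001),
                              indels_per_breed = 20L,
                              n_snps_panel = 46L,
                              n_animals_per_breed = 18L,
                              missing_rate = 0.03,
                              af_spec = NULL) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8,
            shared_fraction >= 0, shared_fraction <= 1,
            missing_rate >= 0, missing_rate <= 0.1,
            n_genes >= 1, gene_length_range_bp[1] >= 1,
            gene_length_range_bp[2] >= gene_length_range_bp[1])
  if (!identical(names(class_probs), SNP_FUNC_CLASSES))
    stop("class_probs must be named over the five SNP functional classes")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 gene_length_range_bp = as.integer(gene_length_range_bp),
                 variants_per_breed = as.integer(variants_per_breed),
                 shared_fraction = shared_fraction,
                 class_probs = class_probs,
                 indels_per_breed = as.integer(indels_per_breed),
                 n_snps_panel = as.integer(n_snps_panel),
                 n_animals_per_breed = as.integer(n_animals_per_breed),
                 missing_rate = missing_rate, af_spec = af_spec),
            class = "simulation_config")
}

#' True allele-frequency specification for a validation panel
#'
#' Builds the SNPs x breeds matrix of true alternate-allele frequencies the
#' genotype generator samples from. The `"study"` layout mirrors the
#' validated panel: 10 SNPs specific to each breed (target-breed frequency
#' `af_background + gap`, other breeds at `af_background`) plus common SNPs
#' with equal frequencies across breeds. The `"null"` layout gives every SNP
#' equal frequencies in all breeds.
#'
#' @param n_snps Panel size (default 46).
#' @param layout `"study"` or `"null"`.
#' @param n_specific_per_breed Breed-specific SNPs per breed (study layout).
#' @param gap True target-breed allele-frequency gap (default 0.45).
#' @param af_background Non-target breed frequency for specific SNPs.
#' @param common_af_range Range the common/null frequencies are drawn from.
#' @param seed Seed for the common/null frequency draws.
#' @return List with `af` (matrix, rownames are SNP ids, colnames breeds) and
#'   `wgs_class` (character vector of discovery-phase labels).
#' @export
panel_af_spec <- function(n_snps = 46L, layout = c("study", "null"),
                          n_specific_per_breed = 10L, gap = 0.45,
                          af_background = 0.20,
                          common_af_range = c(0.1, 0.7), seed = 1L) {
  layout <- match.arg(layout)
  set.seed(seed)
  ids <- sprintf("snp%02d", seq_len(n_snps))
  af <- matrix(NA_real_, n_snps, 3, dimnames = list(ids, BREEDS))
  if (layout == "null") {
    base <- runif(n_snps, common_af_range[1], common_af_range[2])
    af[, ] <- base
    return(list(af = af, wgs_class = rep("Common", n_snps)))
  }
  n_spec <- 3L * n_specific_per_breed
  if (n_spec > n_snps)
    stop("more breed-specific SNPs than panel slots")
  wgs_class <- rep("Common", n_snps)
  for (b in seq_along(BREEDS)) {
    idx <- ((b - 1L) * n_specific_per_breed + 1L):(b * n_specific_per_breed)
    af[idx, ] <- af_background
    af[idx, BREEDS[b]] <- af_background + gap
    wgs_class[idx] <- paste0(BREEDS[b], "-specific")
  }
  common_idx <- (n_spec + 1L):n_snps
  af[common_idx, ] <- runif(length(common_idx), common_af_range[1],
                            common_af_range[2])
  list(af = af, wgs_class = wgs_class)
}

#' Generate non-overlapping gene models
#'
#' Places `n_genes` genes end to end on one synthetic chromosome with random
#' inter-gene gaps; lengths are uniform over the configured range.
#'
#' @param config A [simulation_config()].
#' @return Gene-model `data.frame` (`gene`, `ensembl_id`, `chrom`, `start`,
#'   `end`).
#' @export
gen_gene_models <- function(config) {
  set.seed(config$seed)
  rng <- config$gene_length_range_bp
  lens <- sample(rng[1]:rng[2], config$n_genes, replace = TRUE)
  gaps <- sample(100:1000, config$n_genes, replace = TRUE)
  starts <- cumsum(c(1L, head(lens + gaps, -1L)))
  data.frame(gene = sprintf("GENE%03d", seq_len(config$n_genes)),
             ensembl_id = sprintf("ENSOARG%011d", seq_len(config$n_genes)),
             chrom = "1", start = as.integer(starts),
             end = as.integer(starts + lens - 1L), stringsAsFactors = FALSE)
}

# Draw one exonic SNV inside a random gene; positions are unique across the
# pool so variant identity is positional.
draw_snvs <- function(n, models, class_probs) {
  gene_idx <- sample(nrow(models), n, replace = TRUE)
  pos <- integer(n)
  for (i in seq_len(n)) {
    pos[i] <- sample(models$start[gene_idx[i]]:models$end[gene_idx[i]], 1L)
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  data.frame(chrom = models$chrom[gene_idx], pos = pos, ref = ref,
             alt = unname(alt),
             func_class = sample(names(class_probs), n, replace = TRUE,
                                 prob = class_probs),
             gene = models$gene[gene_idx], stringsAsFactors = FALSE)
}

#' Generate per-breed variant tables with known truth
#'
#' Draws a pool of shared exonic SNVs present in every breed plus
#' breed-exclusive variants, all placed uniformly within the synthetic gene
#' models, with functional classes sampled from the configured mix. Exonic
#' indels (1-3 bp insertions/deletions) are breed-exclusive. The returned
#' truth log records the realized counts per Venn cell and per functional
#' class, for verification against the set-partitioning operations.
#'
#' @param config A [simulation_config()].
#' @param models Gene models from [gen_gene_models()] (regenerated from the
#'   config when omitted).
#' @return List with `tables` (named list of per-breed variant tables) and
#'   `truth` (shared/exclusive keys and per-class counts per breed).
#' @export
gen_variant_tables <- function(config, models = NULL) {
  if (is.null(models)) models <- gen_gene_models(config)
  set.seed(config$seed + 1L)
  n <- config$variants_per_breed
  n_shared <- round(config$shared_fraction * n)
  n_excl <- n - n_shared
  # one draw pool large enough for shared + 3 exclusive sets + indels,
  # de-duplicated on position so keys are distinct by construction
  pool <- draw_snvs(4L * n + 200L, models, config$class_probs)
  pool <- pool[!duplicated(pool$pos), , drop = FALSE]
  need <- n_shared + 3L * n_excl
  if (nrow(pool) < need)
    stop("synthetic variant pool too small; reduce variants_per_breed")
  shared <- pool[seq_len(n_shared), , drop = FALSE]
  tables <- list()
  truth_class <- list()
  excl_keys <- list()
  offset <- n_shared
  for (b in BREEDS) {
    excl <- pool[offset + seq_len(n_excl), , drop = FALSE]
    offset <- offset + n_excl
    df <- rbind(shared, excl)
    vt <- variant_table(df$chrom, df$pos, df$ref, df$alt,
                        region_class = "exonic", func_class = df$func_class,
                        gene = df$gene)
    tables[[b]] <- vt
    truth_class[[b]] <- table(factor(df$func_class,
                                     levels = SNP_FUNC_CLASSES))
    excl_keys[[b]] <- variant_key(excl)
  }
  # breed-exclusive exonic indels appended to each table
  n_ind <- config$indels_per_breed
  if (n_ind > 0L) {
    remaining <- pool[offset + seq_len(min(3L * n_ind, nrow(pool) - offset)),
                      , drop = FALSE]
    if (nrow(remaining) < 3L * n_ind)
      stop("synthetic variant pool too small for indels")
    for (b in seq_along(BREEDS)) {
      sl <- remaining[(b - 1L) * n_ind + seq_len(n_ind), , drop = FALSE]
      ins <- seq_len(n_ind) %% 2L == 0L
      ref <- ifelse(ins, sl$ref, paste0(sl$ref, "A"))
      alt <- ifelse(ins, paste0(sl$ref, "G"), sl$ref)
      fc <- rep(c("indel_frameshift", "indel_nonframeshift"),
                length.out = n_ind)
      vt <- variant_table(sl$chrom, sl$pos, ref, alt,
                          region_class = "exonic", func_class = fc,
                          gene = sl$gene)
      tables[[BREEDS[b]]] <- rbind(tables[[BREEDS[b]]], vt)
    }
  }
  truth <- list(shared_keys = variant_key(shared),
                exclusive_keys = excl_keys,
                n_shared = n_shared, n_exclusive = n_excl,
                class_counts = truth_class,
                n_indels_per_breed = n_ind)
  list(tables = tables, truth = truth)
}

#' Simulate a diploid genotype matrix under Hardy-Weinberg equilibrium
#'
#' For each animal and SNP, the alternate-allele dosage is
#' `Binomial(2, af_true)`; calls are masked missing independently with the
#' configured missingness rate. Allele letters are `ref = "A"`,
#' `alt = "G"` for every SNP.
#'
#' @param config A [simulation_config()]; its `af_spec` (see
#'   [panel_af_spec()]) defines the true frequencies and discovery-phase
#'   labels. A `"study"`-layout spec is built from the config seed when
#'   absent.
#' @return List with `gm` (genotype matrix as from [load_genotypes()]),
#'   `meta` (per-SNP `snp_id`, `gene`, `wgs_class`, `ref`, `alt`), and
#'   `truth_af` (the true frequency matrix).
#' @export
gen_genotypes <- function(config) {
  spec <- config$af_spec
  if (is.null(spec))
    spec <- panel_af_spec(n_snps = config$n_snps_panel, layout = "study",
                          seed = config$seed)
  af <- spec$af
  if (any(af < 0) || any(af > 1)) stop("true allele frequency outside [0, 1]")
  if (nrow(af) != config$n_snps_panel)
    stop("af_spec row count must equal n_snps_panel")
  set.seed(config$seed + 2L)
  n_per <- config$n_animals_per_breed
  samples <- data.frame(
    sample_id = sprintf("%s_%02d", rep(BREEDS, each = n_per),
                        rep(seq_len(n_per), times = 3L)),
    breed = rep(BREEDS, each = n_per), stringsAsFactors = FALSE)
  n_samp <- nrow(samples)
  n_snp <- nrow(af)
  calls <- matrix(NA_character_, n_samp, n_snp,
                  dimnames = list(samples$sample_id, rownames(af)))
  geno_str <- c("A/A", "A/G", "G/G")
  for (j in seq_len(n_snp)) {
    dose <- rbinom(n_samp, 2L, af[j, samples$breed])
    calls[, j] <- geno_str[dose + 1L]
  }
  miss <- matrix(runif(n_samp * n_snp) < config$missing_rate, n_samp, n_snp)
  calls[miss] <- NA_character_
  meta <- data.frame(snp_id = rownames(af), gene = rownames(af),
                     wgs_class = spec$wgs_class, ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  list(gm = list(samples = samples, snps = rownames(af), calls = calls),
       meta = meta, truth_af = af)
}

#' Write a genotype matrix as a wide TSV
#'
#' @param gm Genotype matrix (as from [gen_genotypes()] or
#'   [load_genotypes()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  calls <- gm$calls
  calls[is.na(calls)] <- "./."
  df <- data.frame(sample_id = gm$samples$sample_id,
                   breed = gm$samples$breed, calls, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged 46-SNP validation panel table
#'
#' Returns the published validation-panel summary shipped with the package:
#' per SNP, the gene, the discovery-phase classification, per-breed
#' alternate-allele frequencies, the reported FDR-adjusted q-value, and the
#' reported pattern call.
#'
#' @return `data.frame` with columns `snp_id`, `gene`, `wgs_class`,
#'   `af_les`, `af_ser`, `af_thr`, `q_value`, `pattern` (46 rows).
#' @export
table5_fixture <- function() {
  path <- system.file("extdata", "table5_panel.tsv", package = "breedvar",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(snp_id = "character"))
}
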