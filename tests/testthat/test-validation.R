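toy_genotype_file <- function(rows, .env = parent.frame()) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = .env)
  writeLines(rows, f)
  f
}

test_that("wide genotype TSVs load with validated tokens", {
  f <- toy_genotype_file(c("sample_id\tbreed\tsnp1",
                           "s1\tLES\tA/A",
                           "s2\tLES\tA/G",
                           "s3\tSER\t./."))
  gm <- load_genotypes(f)
  expect_equal(dim(gm$calls), c(3L, 1L))
  expect_true(is.na(gm$calls["s3", "snp1"]))
  # 2 called samples x 1 SNP: 4 alleles, 1 alt
  af <- allele_frequencies(gm, data.frame(snp_id = "snp1", ref = "A",
                                          alt = "G"))
  les <- af[af$breed == "LES", ]
  expect_equal(les$ref_count + les$alt_count, 2L * les$n_called)
  expect_equal(les$alt_count, 1L)
  bad <- toy_genotype_file(c("sample_id\tbreed\tsnp1", "s1\tLES\tA/G/T"))
  expect_error(load_genotypes(bad), "two alleles")
  badbreed <- toy_genotype_file(c("sample_id\tbreed\tsnp1",
                                  "s1\tMYSTERY\tA/A"))
  expect_error(load_genotypes(badbreed), "unknown breed")
  badallele <- toy_genotype_file(c("sample_id\tbreed\tsnp1", "s1\tLES\tA/T"))
  expect_error(load_genotypes(badallele,
                              meta = data.frame(snp_id = "snp1", ref = "A",
                                                alt = "G")), "allele 'T'")
})

test_that("call-rate QC drops below-threshold samples then SNPs", {
  cfg <- simulation_config(seed = 2, missing_rate = 0)
  sim <- gen_genotypes(cfg)
  gm <- sim$gm
  clean <- qc_call_rates(gm)
  expect_equal(dim(clean$matrix$calls), dim(gm$calls))
  # 41/46 calls (0.8913) drops; 42/46 (0.9130) stays
  gm2 <- gm
  gm2$calls[1, 1:5] <- NA   # sample 1: 41/46
  gm2$calls[2, 1:4] <- NA   # sample 2: 42/46
  res <- qc_call_rates(gm2)
  expect_equal(res$report$excluded_samples, gm$samples$sample_id[1])
  expect_true(gm$samples$sample_id[2] %in% res$matrix$samples$sample_id)
  expect_equal(unname(res$report$sample_call_rate[1]), 41 / 46)
  # SNP-level drop after sample removal
  gm3 <- gm
  gm3$calls[1:10, 3] <- NA   # snp 3: 44/54 = 0.8148
  res3 <- qc_call_rates(gm3)
  expect_equal(res3$report$excluded_snps, gm$snps[3])
  expect_error(qc_call_rates(gm, threshold = 1.5), "all samples")
})

test_that("allele frequencies count non-missing calls per breed", {
  # 18 animals with 26 alt alleles -> af = 26/36
  calls <- c(rep("G/G", 10), rep("A/G", 6), rep("A/A", 2))
  rows <- c("sample_id\tbreed\tsnpX",
            sprintf("s%02d\tLES\t%s", 1:18, calls),
            sprintf("t%02d\tSER\t%s", 1:18, rep("A/A", 18)))
  gm <- load_genotypes(toy_genotype_file(rows))
  af <- allele_frequencies(gm, data.frame(snp_id = "snpX", ref = "A",
                                          alt = "G"))
  expect_equal(af$af[af$breed == "LES"], 26 / 36)
  expect_equal(af$af[af$breed == "SER"], 0)
  # all-missing breed: af reported missing
  rows2 <- c("sample_id\tbreed\tsnpX", "a\tLES\tA/G", "b\tSER\t./.")
  gm2 <- load_genotypes(toy_genotype_file(rows2))
  af2 <- allele_frequencies(gm2, data.frame(snp_id = "snpX", ref = "A",
                                            alt = "G"))
  expect_true(is.na(af2$af[af2$breed == "SER"]))
})

test_that("the exact test matches hand enumeration and degenerate cases", {
  # [[2,0],[0,2]]: 3 margin-consistent tables, p = 1/3
  expect_equal(fisher_exact_2xc(matrix(c(2, 0, 0, 2), 2)), 1 / 3,
               tolerance = 1e-12)
  # identical columns: no table less probable in the two-sided sense
  expect_equal(fisher_exact_2xc(cbind(c(10, 26), c(10, 26), c(10, 26))), 1)
  expect_error(fisher_exact_2xc(matrix(c(1, 2), 2, 1)), "2 columns")
  expect_error(fisher_exact_2xc(matrix(c(-1, 2, 3, 4), 2)), "negative")
  expect_error(fisher_exact_2xc(matrix(0L, 2, 3)), "total")
})

test_that("the exact test is invariant to column permutation and row swap", {
  set.seed(71)
  for (i in 1:20) {
    tab <- matrix(sample(0:12, 6, TRUE), 2, 3)
    if (sum(tab) == 0) tab[1, 1] <- 1L
    p <- fisher_exact_2xc(tab)
    expect_equal(fisher_exact_2xc(tab[, c(3, 1, 2)]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2xc(tab[c(2, 1), ]), p, tolerance = 1e-12)
  }
})

test_that("the exact test agrees with independent references", {
  set.seed(73)
  for (i in 1:30) {
    tab <- matrix(sample(0:10, 6, TRUE), 2, 3)
    if (sum(tab) == 0) tab[2, 3] <- 2L
    expect_equal(fisher_exact_2xc(tab), oracle_fisher_2xc(tab),
                 tolerance = 1e-9)
  }
  # spot-check against the stock implementation in stats
  for (tab in list(matrix(c(8, 2, 1, 5), 2),
                   cbind(c(10, 26), c(26, 10), c(20, 16)),
                   cbind(c(3, 15), c(9, 9)))) {
    expect_equal(fisher_exact_2xc(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("chi-squared test computes the Pearson statistic and upper tail", {
  res <- chisq_test(matrix(c(10, 20, 20, 10), 2))
  expect_equal(res$statistic, 20 / 3, tolerance = 1e-10)
  expect_equal(res$df, 1L)
  expect_equal(res$p, pchisq(20 / 3, 1, lower.tail = FALSE))
  same <- chisq_test(cbind(c(5, 10), c(5, 10), c(5, 10)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(chisq_test(cbind(c(0, 0), c(3, 4))), "expected")
  # large balanced tables: asymptotic agreement with the exact test
  set.seed(79)
  for (i in 1:10) {
    tab <- matrix(sample(20:60, 6, TRUE), 2, 3)
    expect_lt(abs(chisq_test(tab)$p - fisher_exact_2xc(tab)), 0.02)
  }
})

test_that("test selection follows the expected-count rule and modes", {
  small <- cbind(c(2, 16), c(2, 16), c(2, 16))  # expected first-row cells = 2
  big <- cbind(c(15, 21), c(18, 18), c(12, 24))
  expect_equal(choose_test(small)$method, "fisher")
  expect_equal(choose_test(big)$method, "chisq")
  expect_equal(choose_test(big, mode = "fisher-always")$method, "fisher")
  expect_equal(choose_test(small, mode = "chisq-always")$method, "chisq")
})

test_that("BH adjustment reproduces hand step-up values", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 0.5, 0.9, 0.04)),
               c(0.004, 2 / 3, 0.9, 0.08), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # family larger than the vector scales q up
  expect_equal(bh_adjust(0.01, m = 10), 0.1)
})

test_that("BH output satisfies the step-up properties on random vectors", {
  set.seed(83)
  for (i in 1:200) {
    p <- runif(sample(1:30, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    o <- order(p)
    expect_true(!is.unsorted(q[o]))
  }
})

test_that("pattern classification follows the four-way rule", {
  cfg <- classifier_config()
  af <- function(l, s, t) c(LES = l, SER = s, THR = t)
  # published panel rows exercising each branch
  expect_equal(classify_pattern("LES-specific", af(0.72, 0.17, 0.24),
                                1.0e-4, cfg)$pattern, "Significant")
  expect_equal(classify_pattern("SER-specific", af(0.33, 0.39, 0.28),
                                0.62, cfg)$pattern, "Inconsistent")
  expect_equal(classify_pattern("LES-specific", af(0.58, 0.40, 0.37),
                                0.084, cfg)$pattern, "Consistent (NS)")
  expect_equal(classify_pattern("Common", af(0.52, 0.29, 0.48),
                                0.09, cfg)$pattern, "Shared")
  # target not the strict maximum is inconsistent regardless of q
  expect_equal(classify_pattern("LES-specific", af(0.4, 0.4, 0.2),
                                1e-6, cfg)$pattern, "Inconsistent")
  # common with q < alpha is inconsistent by the deterministic rule
  expect_equal(classify_pattern("Common", af(0.7, 0.2, 0.2),
                                0.01, cfg)$pattern, "Inconsistent")
  expect_error(classify_pattern("LES-specific", af(NA, 0.2, 0.2), 0.5, cfg),
               "missing")
  m <- classify_pattern("SER-specific", af(0.33, 0.39, 0.28), 0.62, cfg)
  expect_equal(m$margin, 0.06, tolerance = 1e-12)
})

test_that("counts reconstruct from rounded frequencies by half-up rounding", {
  expect_equal(reconstruct_counts(0.72, 18), c(ref = 10L, alt = 26L))
  expect_equal(reconstruct_counts(0, 18), c(ref = 36L, alt = 0L))
  expect_equal(reconstruct_counts(0.5, 18), c(ref = 18L, alt = 18L))
  # half-up at the boundary: 0.125 * 4 = 0.5 rounds up
  expect_equal(reconstruct_counts(0.125, 2), c(ref = 3L, alt = 1L))
})

test_that("the genotype pipeline ties its stages together", {
  cfg <- simulation_config(seed = 41)
  sim <- gen_genotypes(cfg)
  out <- validate_panel(sim$gm, sim$meta)
  # QC may drop SNPs whose simulated call rate dips below 90%
  expect_equal(nrow(out$results), 46L - length(out$qc$excluded_snps))
  expect_equal(sum(out$summary), nrow(out$results))
  expect_true(all(out$results$q >= out$results$p - 1e-15))
  expect_true(all(out$results$method == "fisher"))
  # empirical frequencies agree with the truth within binomial error
  expect_true(max(abs(out$results$af_les -
                        sim$truth_af[out$results$snp_id, "LES"])) < 0.35)
})
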