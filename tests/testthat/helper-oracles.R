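# Independent oracles used to verify the package's statistics. These are
# deliberately written against the definitions, not against the
# implementation paths they check.

# Brute-force exact 2xc homogeneity test: enumerate every first row
# consistent with the margins on a grid, with linear-space choose()
# arithmetic (the package enumerates recursively in log space).
oracle_fisher_2xc <- function(tab) {
  tab <- as.matrix(tab)
  colsum <- colSums(tab)
  r1 <- sum(tab[1, ])
  n <- sum(tab)
  grid <- expand.grid(lapply(colsum, function(cj) 0:cj))
  grid <- grid[rowSums(grid) == r1, , drop = FALSE]
  num <- rep(1, nrow(grid))
  for (j in seq_along(colsum)) num <- num * choose(colsum[j], grid[[j]])
  obs <- prod(choose(colsum, tab[1, ]))
  sum(num[num <= obs * (1 + 1e-7)]) / choose(n, r1)
}

# Hand step-up BH adjustment from the definition.
oracle_bh <- function(p, m = length(p)) {
  o <- order(p)
  r <- p[o] * m / seq_along(p)
  q_sorted <- rev(cummin(rev(r)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(length(p))
  q[o] <- q_sorted
  q
}

# Upper-tail hypergeometric P(X >= k) by direct combinatorial summation.
oracle_hyper_upper <- function(N, K, n, k) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# Write a minimal single-sample VCF with per-site DP/MQ INFO fields.
write_test_vcf <- function(path, body_lines) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    body_lines), path)
  path
}

# Per-element membership scan used as an oracle for the set partitions.
oracle_threeway_cell <- function(x, a, b, c) {
  ina <- x %in% a
  inb <- x %in% b
  inc <- x %in% c
  ifelse(ina & inb & inc, "ABC",
    ifelse(ina & inb, "AB",
      ifelse(ina & inc, "AC",
        ifelse(inb & inc, "BC",
          ifelse(ina, "A_only", ifelse(inb, "B_only", "C_only"))))))
}
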