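# Fixture builders shared across test files. Everything is generated in code;
# no stored data.

# A tiny deterministic count matrix with gene/sample names.
tiny_counts <- function(n_genes = 10, n_samples = 8, seed = 42, mu = 50) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = 10),
              n_genes, n_samples,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}

# Minimal metadata for a one-region cohort.
tiny_meta <- function(n = 8, seed = 42) {
  set.seed(seed)
  tibble::tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    donor_id = sprintf("D%02d", seq_len(n)),
    sex = rep(c("F", "M"), length.out = n),
    diagnosis = rep(c("CTL", "CTL", "SZ", "SZ"), length.out = n),
    region = "A",
    age = runif(n, 20, 70),
    RIN = rnorm(n), snpPC1 = rnorm(n), snpPC2 = rnorm(n), snpPC3 = rnorm(n)
  )
}

tiny_annotation <- function(gene_ids, chromosome = "1", gene_length = 1000,
                            par_flag = FALSE, xci_status = "not_applicable") {
  tibble::tibble(
    gene_id = gene_ids,
    chromosome = rep_len(chromosome, length(gene_ids)),
    gene_length = rep_len(gene_length, length(gene_ids)),
    par_flag = rep_len(par_flag, length(gene_ids)),
    xci_status = rep_len(xci_status, length(gene_ids))
  )
}

# A small single-region simulated dataset used by several modules.
small_dataset <- function(seed = 11, n_genes = 300, regions = "A",
                          n_per_cell = c(F_CTL = 12, F_SZ = 8, M_CTL = 14, M_SZ = 10),
                          ...) {
  simulate_dataset(sim_config(n_genes = n_genes, regions = regions,
                              n_per_cell = n_per_cell, seed = seed, ...))
}

# Brute-force single-sample TMM factor straight from the trimmed-mean
# definition (unweighted simple version is NOT equivalent; this mirrors the
# weighted definition). Used as the independent oracle for tmm_factors().
brute_tmm_two_sample <- function(obs, ref, logratio_trim = 0.30, sum_trim = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  keep2 <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
}

# Exact Mann-Whitney two-sided p by full enumeration of label assignments.
enumerate_mwu_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(vals), n1)
  u_of <- function(sel) {
    a <- vals[sel]; b <- vals[-sel]
    sum(outer(a, b, ">")) # U counts wins of group 1 (no ties assumed)
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(idx, 2, u_of)
  mu <- n1 * (length(vals) - n1) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Hypergeometric enumeration of the two-sided Fisher p for a 2x2 table
# (minimum-likelihood method).
enumerate_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) dhyper(x, m, n, k), double(1))
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Step-up BH from the definition.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# Spearman rho with average ranks, from the definition.
brute_spearman <- function(x, y) {
  cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}
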