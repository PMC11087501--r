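test_that("effective lengths follow length - fragment + 1 with the <= 1 mask", {
  ann <- tiny_annotation(c("a", "b", "c"), gene_length = c(300, 201, 150))
  el <- effective_lengths(ann, 200)
  expect_equal(el$eff_length, c(101, 2, -49))
  expect_equal(el$retained, c(TRUE, TRUE, FALSE))
})

test_that("TPM matches hand evaluation and conserves column sums", {
  counts <- matrix(c(10L, 20L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm <- compute_tpm(counts, c(a = 100, b = 200))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))

  counts2 <- matrix(c(30L, 10L), 2, 1, dimnames = list(c("a", "b"), "s1"))
  tpm2 <- compute_tpm(counts2, c(a = 100, b = 200))
  expect_equal(unname(tpm2[, 1]), c(1e6 * 0.3 / 0.35, 1e6 * 0.05 / 0.35),
               tolerance = 1e-9)

  single <- matrix(5L, 1, 1, dimnames = list("a", "s1"))
  expect_equal(unname(compute_tpm(single, c(a = 50))[1, 1]), 1e6)

  counts3 <- tiny_counts(20, 5)
  tpm3 <- compute_tpm(counts3, setNames(rep(500, 20), rownames(counts3)))
  expect_equal(unname(colSums(tpm3)), rep(1e6, 5), tolerance = 1e-9)

  zero <- matrix(c(1L, 0L), 2, 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  zero[, 2] <- 0L
  expect_error(compute_tpm(zero, c(a = 10, b = 10)), "all-zero")
})

test_that("expression filter counts qualifying samples against the smallest-group quota", {
  meta <- tiny_meta(4)   # 2 F, 2 M -> quota = ceiling(0.7 * 2) = 2
  lib <- 1e6
  counts <- rbind(
    keep = c(12L, 11L, 0L, 0L),   # CPM 12, 11 -> 2 qualifying
    drop = c(12L, 0L, 0L, 0L)     # 1 qualifying
  )
  # pad library so CPM == count
  pad <- matrix(0L, 1, 4, dimnames = list("pad", NULL))
  pad[1, ] <- as.integer(lib - colSums(counts))
  m <- rbind(counts, pad)
  colnames(m) <- meta$sample_id
  flt <- filter_by_expression(m, meta, cpm_threshold = 10)
  expect_equal(attr(flt, "quota"), 2L)
  expect_true(flt$retained[flt$gene_id == "keep"])
  expect_false(flt$retained[flt$gene_id == "drop"])

  # threshold 0: presence (nonzero count) is what qualifies
  flt0 <- filter_by_expression(m, meta, cpm_threshold = 0)
  expect_true(all(flt0$retained[flt0$gene_id %in% c("keep", "pad")]))
  expect_false(flt0$retained[flt0$gene_id == "drop"])
})

test_that("raising the CPM threshold never adds genes", {
  counts <- tiny_counts(60, 10, seed = 8, mu = 30)
  meta <- tiny_meta(10)
  kept <- lapply(c(0, 5, 10, 50, 200), function(th) {
    flt <- filter_by_expression(counts, meta, cpm_threshold = th)
    flt$gene_id[flt$retained]
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("TMM factors: symmetry, depth invariance, geometric mean 1", {
  counts <- tiny_counts(50, 4, seed = 1, mu = 100)
  same <- counts[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  f <- tmm_factors(same)
  expect_equal(f$factor, rep(1, 3), tolerance = 1e-12)

  two <- counts[, 1:2]
  two[, 2] <- two[, 1] * 2L
  f2 <- tmm_factors(two)
  expect_equal(f2$factor, c(1, 1), tolerance = 1e-9)

  f3 <- tmm_factors(counts)
  expect_equal(exp(mean(log(f3$factor))), 1, tolerance = 1e-9)
})

test_that("TMM agrees with a brute-force trimmed-mean oracle", {
  set.seed(31)
  for (rep in 1:5) {
    ref <- rnbinom(20, mu = 200, size = 5) + 1L
    obs <- ref
    half <- sample(20, 10)
    obs[half] <- obs[half] * 2L   # half the genes doubled
    counts <- cbind(ref = ref, obs = obs)
    rownames(counts) <- sprintf("g%02d", 1:20)
    storage.mode(counts) <- "integer"
    f <- tmm_factors(counts)
    chosen <- attr(f, "reference")
    other <- setdiff(colnames(counts), chosen)
    ratio_pkg <- f$factor[f$sample_id == other] / f$factor[f$sample_id == chosen]
    expect_equal(ratio_pkg, brute_tmm_two_sample(counts[, other], counts[, chosen]),
                 tolerance = 0.01)
  }
})

test_that("log-CPM matches its definition and is depth-scale invariant", {
  counts <- matrix(0L, 1, 1, dimnames = list("g", "s"))
  lib_filler <- matrix(as.integer(1e6), 1, 1, dimnames = list("f", "s"))
  m <- rbind(counts, lib_filler)
  lc <- log_cpm(m, NULL, prior_count = 0.5)
  expect_equal(lc["g", "s"], log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-5)

  counts2 <- tiny_counts(30, 4)
  lc1 <- log_cpm(counts2, NULL, prior_count = 0)
  lc2 <- log_cpm(counts2 * 2L, NULL, prior_count = 0)
  expect_equal(lc1, lc2, tolerance = 1e-12)
  # prior 0 and positive counts: exact log2 CPM
  expect_equal(lc1[1, 1],
               log2(counts2[1, 1] / sum(counts2[, 1]) * 1e6))
})

test_that("voom-style weights are flat for homoskedastic data and track a planted trend", {
  set.seed(77)
  n <- 40; G <- 300
  design <- cbind(1, rep(0:1, each = n / 2))
  colnames(design) <- c("(Intercept)", "grp")
  means <- seq(2, 12, length.out = G)
  flat <- matrix(rnorm(G * n, mean = rep(means, n), sd = 0.6), G, n,
                 dimnames = list(sprintf("g%03d", 1:G), sprintf("s%02d", 1:n)))
  w_flat <- voom_weights(flat, design)
  expect_lt(max(w_flat) / min(w_flat), 1.5)

  sds <- seq(1.2, 0.3, length.out = G)   # variance decreasing with mean
  trendy <- matrix(rnorm(G * n, mean = rep(means, n), sd = rep(sds, n)), G, n,
                   dimnames = dimnames(flat))
  w_tr <- voom_weights(trendy, design)
  gene_w <- rowMeans(w_tr)
  expect_gt(cor(means, gene_w, method = "spearman"), 0.9)

  # extreme gene: clamped to the trend endpoint, finite positive weight
  extreme <- rbind(trendy, extreme = rnorm(n, mean = 30, sd = 0.5))
  w_ex <- voom_weights(extreme, design)
  expect_true(all(is.finite(w_ex["extreme", ])) && all(w_ex["extreme", ] > 0))
  expect_error(voom_weights(flat[, 1:3], cbind(1, c(0, 1, 0), c(1, 0, 0))),
               "residual degrees")
})
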