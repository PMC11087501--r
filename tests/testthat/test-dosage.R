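make_tpm <- function(mat) {
  tpm <- sweep(mat, 2, colSums(mat), "/") * 1e6
  attr(tpm, "kind") <- "TPM"
  tpm
}

test_that("RXE follows log2(mean X) - log2(mean autosome)", {
  ann <- dplyr::bind_rows(
    tiny_annotation(c("x1", "x2"), chromosome = "X", xci_status = "inactive"),
    tiny_annotation(c("a1", "a2"), chromosome = "7")
  )
  # equal means -> 0
  m <- matrix(c(8, 8, 8, 8), 4, 1, dimnames = list(c("x1", "x2", "a1", "a2"), "s1"))
  tpm <- m; attr(tpm, "kind") <- "TPM"   # not rescaled: RXE only uses ratios
  expect_equal(compute_rxe(tpm, ann)$rxe, 0)
  # mean X = 4, mean autosome = 8 -> -1
  m2 <- matrix(c(4, 4, 8, 8), 4, 1, dimnames = dimnames(m))
  tpm2 <- m2; attr(tpm2, "kind") <- "TPM"
  expect_equal(compute_rxe(tpm2, ann)$rxe, -1)
  # zero X mean errors naming the sample
  m3 <- matrix(c(0, 0, 8, 8), 4, 1, dimnames = dimnames(m))
  tpm3 <- m3; attr(tpm3, "kind") <- "TPM"
  expect_error(compute_rxe(tpm3, ann, presence_fraction = 0), "zero mean X.*s1")
})

test_that("RXE is invariant to rescaling a sample's TPM", {
  set.seed(19)
  ann <- dplyr::bind_rows(
    tiny_annotation(sprintf("x%d", 1:10), chromosome = "X", xci_status = "inactive"),
    tiny_annotation(sprintf("a%d", 1:40), chromosome = "3")
  )
  m <- matrix(rexp(50 * 4, 1 / 50), 50, 4,
              dimnames = list(ann$gene_id, sprintf("s%d", 1:4)))
  tpm <- m; attr(tpm, "kind") <- "TPM"
  r1 <- compute_rxe(tpm, ann)$rxe
  m2 <- m; m2[, 2] <- m2[, 2] * 7.3
  tpm2 <- m2; attr(tpm2, "kind") <- "TPM"
  r2 <- compute_rxe(tpm2, ann)$rxe
  expect_lt(max(abs(r1 - r2)), 1e-12)
})

test_that("PAR and Y genes are excluded from the RXE gene sets", {
  ann <- dplyr::bind_rows(
    tiny_annotation("x1", chromosome = "X", xci_status = "inactive"),
    tiny_annotation("p1", chromosome = "X", par_flag = TRUE, xci_status = "escape"),
    tiny_annotation("y1", chromosome = "Y"),
    tiny_annotation(c("a1", "a2"), chromosome = "12")
  )
  m <- matrix(c(4, 1000, 1000, 8, 8), 5, 1,
              dimnames = list(ann$gene_id, "s1"))
  tpm <- m; attr(tpm, "kind") <- "TPM"
  expect_equal(compute_rxe(tpm, ann)$rxe, -1)   # p1/y1 ignored
  expect_equal(attr(compute_rxe(tpm, ann), "n_x_genes"), 1)
})

test_that("Mann-Whitney exact p matches full enumeration and handles ties", {
  mw <- mann_whitney(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(unname(mw$U), 0)
  expect_equal(mw$p, 0.1)   # 2/20 label assignments as extreme
  expect_equal(mw$method, "exact")

  same <- mann_whitney(c(1:8, 1.5 + 1:8), rep(c("a", "b"), each = 8))
  expect_equal(mw2 <- same$method, "exact")

  set.seed(8)
  for (r in 1:50) {
    x <- sample(seq(0.01, 1, 0.01), 6)
    y <- sample(seq(1.005, 2, 0.005), 7)
    p_pkg <- mann_whitney(c(x, y), rep(c("a", "b"), c(6, 7)))$p
    expect_equal(p_pkg, enumerate_mwu_p(x, y), tolerance = 1e-12)
  }
  tied <- mann_whitney(c(1, 1, 2, 2, 3, 3, 4, 4), rep(c("a", "b"), 4))
  expect_equal(tied$method, "normal_approx")
  expect_gt(tied$p, 0.5)
  expect_error(mann_whitney(1:3, rep("a", 3)), "two non-empty groups")
})

test_that("Fisher two-sided p equals hypergeometric enumeration", {
  f <- sexdimorph:::fisher_2x2(3, 1, 1, 3)
  expect_equal(f$p, 34 / 70, tolerance = 1e-12)
  set.seed(12)
  for (r in 1:40) {
    cells <- rpois(4, 5)
    f <- sexdimorph:::fisher_2x2(cells[1], cells[2], cells[3], cells[4])
    expect_equal(f$p, enumerate_fisher_p(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
})

test_that("XCI enrichment flags a pure escape DEG set and stays null-calibrated", {
  # universe mirrors the published catalogue sizes: 99/101/431
  ann <- dplyr::bind_rows(
    tiny_annotation(sprintf("e%03d", 1:99), chromosome = "X", xci_status = "escape"),
    tiny_annotation(sprintf("v%03d", 1:101), chromosome = "X", xci_status = "variable"),
    tiny_annotation(sprintf("i%03d", 1:431), chromosome = "X", xci_status = "inactive")
  )
  de <- tibble::tibble(
    feature_id = ann$gene_id,
    logFC = -1,
    adj.P.Val = ifelse(ann$xci_status == "escape", 0.001, 0.9)
  )
  enr <- xci_enrichment(de, ann)
  esc_all <- enr[enr$category == "escape" & enr$stratum == "all", ]
  expect_lt(esc_all$p_bonferroni, 1e-6)
  expect_true(is.infinite(esc_all$odds_ratio) || esc_all$odds_ratio > 100)

  # random DEG sets: significant pre-correction in <= ~5% of draws
  set.seed(33)
  hits <- vapply(1:60, function(r) {
    deg <- sample(ann$gene_id, 60)
    de_r <- tibble::tibble(feature_id = ann$gene_id, logFC = -1,
                           adj.P.Val = ifelse(ann$gene_id %in% deg, 0.01, 0.9))
    e <- xci_enrichment(de_r, ann)
    e$p[e$category == "escape" & e$stratum == "all"] < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.12)   # 5% nominal, binomial noise at 60 draws
})

test_that("rxe_comparisons runs the sex and diagnosis contrasts per region", {
  ds <- small_dataset(seed = 14, n_genes = 400)
  nm <- normalize_counts(ds$counts, ds$meta, ds$annotation)
  rxe <- compute_rxe(nm$tpm, ds$annotation, meta = ds$meta)
  cmp <- rxe_comparisons(rxe)
  expect_setequal(unique(cmp$comparison), c("M_vs_F", "SZ_vs_CTL"))
  expect_true(all(cmp$p >= 0 & cmp$p <= 1))
})
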