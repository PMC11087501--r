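make_resid <- function(genes, meta, signal_genes = character(), sep = 3) {
  r <- matrix(rnorm(length(genes) * nrow(meta)), length(genes), nrow(meta),
              dimnames = list(genes, meta$sample_id))
  for (g in signal_genes) {
    sz <- meta$diagnosis == "SZ"
    r[g, sz] <- r[g, sz] + sep
  }
  r
}

de_stub <- function(ids, sig) {
  tibble::tibble(feature_id = ids, logFC = 1,
                 adj.P.Val = ifelse(ids %in% sig, 0.01, 0.5))
}

test_that("stringent filter removes shared and opposite-sex-signal genes with reasons", {
  set.seed(71)
  meta <- tiny_meta(24)
  genes <- c("A", "B", "C", "D")
  # C carries a diagnosis signal in MALE samples only
  male_meta <- meta[meta$sex == "M", ]
  resid <- make_resid(genes, meta)
  sz_m <- meta$sex == "M" & meta$diagnosis == "SZ"
  resid["C", sz_m] <- resid["C", sz_m] + 6

  rep_ <- stringent_sex_filter(de_stub(genes, c("A", "B", "C")),
                               de_stub(genes, "B"), resid, meta)
  f <- rep_$female_specific
  expect_equal(f$gene_id[f$retained], "A")
  expect_equal(f$removal_reason[f$gene_id == "B"], "shared")
  expect_equal(f$removal_reason[f$gene_id == "C"], "opposite_sex_signal")
  expect_equal(attr(f, "n_stage_a"), 3)
  expect_equal(attr(f, "n_stage_b"), 2)
  expect_equal(attr(f, "n_stage_c"), 1)
  # nestedness: c subset of b subset of a
  expect_lte(attr(f, "n_stage_c"), attr(f, "n_stage_b"))
  expect_lte(attr(f, "n_stage_b"), attr(f, "n_stage_a"))

  # disjoint sets, no opposite-sex signal: identity
  rep2 <- stringent_sex_filter(de_stub(genes, "A"), de_stub(genes, "D"),
                               make_resid(genes, meta), meta)
  expect_true(all(rep2$female_specific$retained))
  expect_true(all(rep2$male_specific$retained))

  expect_error(
    stringent_sex_filter(de_stub(c("Z"), "Z"), de_stub(genes, character()),
                         resid, meta),
    "absent.*Z")
})

test_that("a sex-shared diagnosis effect is mostly filtered out", {
  # the filter's purpose: effects present in both sexes must not survive
  ds <- small_dataset(
    seed = 31, n_genes = 300,
    n_per_cell = c(F_CTL = 25, F_SZ = 25, M_CTL = 25, M_SZ = 25),
    dx_effect = list(frac = 0.1, lfc = 2, sex = c("F", "M"), regions = "A"),
    sex_effect = list(frac = 0, lfc = 0), batch_sd = 0
  )
  de_f <- de_analysis(ds$counts, ds$meta, "diagnosis_by_sex", sex = "F",
                      covariates = "RIN", n_sv = 0)
  de_m <- de_analysis(ds$counts, ds$meta, "diagnosis_by_sex", sex = "M",
                      covariates = "RIN", n_sv = 0)
  n_deg_f <- sum(de_f$table$adj.P.Val < 0.05)
  expect_gt(n_deg_f, 5)   # strong planted effect: the filter has work to do
  nm <- normalize_counts(ds$counts, ds$meta, ds$annotation)
  null_b <- build_design(ds$meta, design_spec("null_minimal", covariates = "RIN"))
  resid <- residualize(nm$logcpm, null_b$design)
  rep_ <- stringent_sex_filter(de_f, de_m, resid, ds$meta)
  frac_removed <- 1 - attr(rep_$female_specific, "n_stage_c") / n_deg_f
  expect_gte(frac_removed, 0.8)
})

test_that("empirical p follows the add-one two-sided formula", {
  # all 9 null counts above the observation
  p <- empirical_p(rep(10, 9), 2)
  expect_equal(p$p_lower, 0.1)
  expect_equal(p$p_two_sided, 0.2)
  # observation at the centre of a symmetric null
  p2 <- empirical_p(c(1:9), 5)
  expect_equal(p2$p_two_sided, 1)
  expect_error(empirical_p(numeric(0), 1), "empty")
})

test_that("subsampling null is deterministic and respects preconditions", {
  ds <- small_dataset(seed = 51, n_genes = 150,
                      n_per_cell = c(F_CTL = 6, F_SZ = 6, M_CTL = 12, M_SZ = 12))
  args <- list(covariates = character(), sex = "M", n_sv = 0, use_weights = FALSE)
  a <- subsampling_null(ds$counts, ds$meta, B = 5, seed = 99, de_args = args)
  b <- subsampling_null(ds$counts, ds$meta, B = 5, seed = 99, de_args = args)
  expect_identical(a$counts, b$counts)
  expect_identical(a$observed, b$observed)
  expect_equal(a$target_n, 12)
  expect_error(subsampling_null(ds$counts, ds$meta, target_n = 24, B = 2,
                                de_args = args),
               "smaller than the male sample count")
})

test_that("subsampled power does not exceed full-male power on planted effects", {
  ds <- small_dataset(
    seed = 61, n_genes = 200,
    n_per_cell = c(F_CTL = 8, F_SZ = 8, M_CTL = 25, M_SZ = 25),
    dx_effect = list(frac = 0.15, lfc = 1.5, sex = "M", regions = "A"),
    sex_effect = list(frac = 0, lfc = 0), batch_sd = 0
  )
  args <- list(covariates = character(), sex = "M", n_sv = 0)
  full_m <- de_analysis(ds$counts, ds$meta, "diagnosis_by_sex", sex = "M",
                        covariates = character(), n_sv = 0)
  full_count <- sum(full_m$table$adj.P.Val < 0.05)
  sub <- subsampling_null(ds$counts, ds$meta, target_n = 16, B = 15, seed = 5,
                          de_args = args)
  expect_lte(median(sub$counts), full_count)
})
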