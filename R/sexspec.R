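# The two bespoke procedures for sex-specific schizophrenia signal: the
# stringent sex-specific DEG filter and the male-subsampling permutation
# null.

#' Stringent sex-specific DEG filter
#'
#' Starting from the FDR-significant diagnosis DEGs of one sex, removes
#' (a -> b) genes that are also FDR-significant in the opposite sex, then
#' (b -> c) genes whose residualized expression differs between diagnoses in
#' the *opposite* sex (Mann-Whitney, p < `mwu_alpha`). The surviving set is
#' sex-specific in the strict sense: no detectable diagnosis signal in the
#' other sex by either route. Stages are strictly nested: c within b within a.
#'
#' @param de_female,de_male `moderated_fit`s or tidied DE tables for the
#'   diagnosis-within-sex analyses.
#' @param resid_expr residualized z-scored expression ([residualize()] under
#'   the minimal null that keeps diagnosis out), covering all samples.
#' @param meta sample metadata aligned with `resid_expr` columns (`sample_id`,
#'   `sex`, `diagnosis`).
#' @param fdr_cutoff DEG threshold (default 0.05).
#' @param mwu_alpha opposite-sex Mann-Whitney removal threshold (default 0.05).
#' @return list with `female_specific` and `male_specific`, each a
#'   `filter_report`: per-gene tibble (`gene_id`, `removal_reason`,
#'   `retained`) plus stage counts in attributes `n_stage_a`, `n_stage_b`,
#'   `n_stage_c`.
#' @export
stringent_sex_filter <- function(de_female, de_male, resid_expr, meta,
                                 fdr_cutoff = 0.05, mwu_alpha = 0.05) {
  tab_f <- if (inherits(de_female, "moderated_fit")) de_female$table else de_female
  tab_m <- if (inherits(de_male, "moderated_fit")) de_male$table else de_male
  check_columns(tab_f, c("feature_id", "adj.P.Val"), "female DE table")
  check_columns(tab_m, c("feature_id", "adj.P.Val"), "male DE table")
  check_columns(meta, c("sample_id", "sex", "diagnosis"), "metadata")
  set_f <- tab_f$feature_id[!is.na(tab_f$adj.P.Val) & tab_f$adj.P.Val < fdr_cutoff]
  set_m <- tab_m$feature_id[!is.na(tab_m$adj.P.Val) & tab_m$adj.P.Val < fdr_cutoff]
  list(
    female_specific = one_sided_filter(set_f, set_m, opposite_sex = "M",
                                       resid_expr, meta, mwu_alpha),
    male_specific = one_sided_filter(set_m, set_f, opposite_sex = "F",
                                     resid_expr, meta, mwu_alpha)
  )
}

one_sided_filter <- function(own_set, other_set, opposite_sex, resid_expr,
                             meta, mwu_alpha) {
  missing <- setdiff(own_set, rownames(resid_expr))
  if (length(missing) > 0) {
    sd_validation_error(sprintf("gene(s) absent from residualized expression: %s",
                                paste(missing, collapse = ", ")))
  }
  reason <- setNames(rep(NA_character_, length(own_set)), own_set)
  shared <- intersect(own_set, other_set)
  reason[shared] <- "shared"
  survivors <- setdiff(own_set, shared)
  opp <- meta$sample_id[meta$sex == opposite_sex]
  opp <- intersect(opp, colnames(resid_expr))
  dx <- meta$diagnosis[match(opp, meta$sample_id)]
  for (g in survivors) {
    p <- mann_whitney(resid_expr[g, opp], dx)$p
    if (p < mwu_alpha) reason[g] <- "opposite_sex_signal"
  }
  rep_tbl <- tibble(gene_id = own_set, removal_reason = unname(reason),
                    retained = is.na(reason))
  structure(rep_tbl, class = c("filter_report", class(rep_tbl)),
            n_stage_a = length(own_set),
            n_stage_b = length(survivors),
            n_stage_c = sum(is.na(reason)))
}

#' Male-subsampling permutation null for DEG counts
#'
#' Draws `B` simple random subsamples (without replacement) of the male
#' samples at the female sample size, reruns the full diagnosis-within-sex
#' differential-expression pipeline on each draw, and records the FDR-
#' significant DEG count. The observed female DEG count is then located in
#' this null with an add-one empirical p-value:
#' `p = 2 * min((1 + #{counts <= obs}) / (B + 1),
#'              (1 + #{counts >= obs}) / (B + 1))`, capped at 1.
#'
#' @param counts integer gene x sample matrix (one region).
#' @param meta sample metadata aligned with the count columns.
#' @param target_n subsample size; defaults to the number of female samples.
#' @param B number of subsamples (default 1000).
#' @param seed integer seed; fixes the draws exactly.
#' @param observed observed female DEG count; if NULL it is computed by
#'   running the same pipeline on the female samples.
#' @param stratify_by_diagnosis preserve the female CTL/SZ composition in
#'   each draw (default FALSE: simple random sampling).
#' @param fdr_cutoff DEG threshold (default 0.05).
#' @param de_args list of arguments forwarded to [de_analysis()] (covariates,
#'   `n_sv`, `use_weights`, ...); hidden factors are re-estimated within each
#'   subsample when `n_sv` is not 0.
#' @return object of class `subsample_null`: `counts` (length B),
#'   `observed`, `p_two_sided`, `p_lower`, `p_upper`, `B`, `target_n`,
#'   `seed`.
#' @export
subsampling_null <- function(counts, meta, target_n = NULL, B = 1000, seed = 13,
                             observed = NULL, stratify_by_diagnosis = FALSE,
                             fdr_cutoff = 0.05, de_args = list()) {
  check_columns(meta, c("sample_id", "sex", "diagnosis"), "metadata")
  males <- which(meta$sex == "M")
  females <- which(meta$sex == "F")
  target_n <- target_n %||% length(females)
  if (target_n >= length(males)) {
    sd_validation_error(sprintf("target_n (%d) must be smaller than the male sample count (%d)",
                                target_n, length(males)))
  }
  run_de <- function(cols) {
    args <- modifyList(list(counts = counts[, cols, drop = FALSE],
                            meta = meta[cols, , drop = FALSE],
                            model = "diagnosis_by_sex"), de_args)
    args$sex <- NULL   # columns are already the subset of interest
    fit <- do.call(de_analysis, args)
    sum(fit$table$adj.P.Val < fdr_cutoff, na.rm = TRUE)
  }
  if (is.null(observed)) {
    if (length(females) == 0) sd_validation_error("no female samples to compute the observed DEG count")
    observed <- run_de(females)
  }
  draws <- with_preserved_seed(seed, {
    lapply(seq_len(B), function(b) {
      if (stratify_by_diagnosis) {
        f_dx <- table(meta$diagnosis[females])
        n_sz <- round(target_n * f_dx[["SZ"]] / sum(f_dx))
        c(sample(males[meta$diagnosis[males] == "SZ"], n_sz),
          sample(males[meta$diagnosis[males] == "CTL"], target_n - n_sz))
      } else {
        sample(males, target_n)
      }
    })
  })
  null_counts <- vapply(draws, run_de, integer(1))
  p <- empirical_p(null_counts, observed)
  structure(
    c(list(counts = null_counts, observed = observed), p,
      list(B = B, target_n = target_n, seed = seed)),
    class = "subsample_null"
  )
}

#' Add-one empirical p-value against a permutation null
#'
#' `p_lower = (1 + #\{null <= obs\}) / (B + 1)`, `p_upper` symmetric, and the
#' two-sided p is twice the smaller tail, capped at 1. The add-one form never
#' returns 0.
#'
#' @param null_counts numeric vector of B null statistics.
#' @param observed observed statistic.
#' @return list: `p_two_sided`, `p_lower`, `p_upper`.
#' @export
empirical_p <- function(null_counts, observed) {
  B <- length(null_counts)
  if (B == 0) sd_validation_error("empty null distribution")
  p_lower <- (1 + sum(null_counts <= observed)) / (B + 1)
  p_upper <- (1 + sum(null_counts >= observed)) / (B + 1)
  list(p_two_sided = min(1, 2 * min(p_lower, p_upper)),
       p_lower = p_lower, p_upper = p_upper)
}

#' @export
print.subsample_null <- function(x, ...) {
  cat(sprintf("<subsample_null> B = %d male subsamples of size %d (seed %d)\n",
              x$B, x$target_n, x$seed))
  cat(sprintf("  null DEG counts: median %.0f [%.0f, %.0f]; observed %d; two-sided p = %.3g\n",
              median(x$counts), quantile(x$counts, 0.025), quantile(x$counts, 0.975),
              x$observed, x$p_two_sided))
  invisible(x)
}

#' @export
tidy.subsample_null <- function(x, ...) {
  tibble(draw = seq_len(x$B), deg_count = x$counts)
}

#' @export
glance.subsample_null <- function(x, ...) {
  tibble(B = x$B, target_n = x$target_n, observed = x$observed,
         null_median = median(x$counts), p_two_sided = x$p_two_sided,
         p_lower = x$p_lower, p_upper = x$p_upper, seed = x$seed)
}
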