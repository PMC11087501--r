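# X-chromosome dosage: relative X expression (RXE), Mann-Whitney group
# comparisons, and XCI-status enrichment of sex-biased genes.

#' Relative X expression (RXE)
#'
#' Per sample: `log2(mean TPM over X genes) - log2(mean TPM over autosomal
#' genes)`, after dropping genes expressed (TPM > 0) in fewer than
#' `presence_fraction` of samples. Autosomes are chromosomes 1-22; the X set
#' excludes pseudoautosomal genes and chromosome Y is excluded everywhere
#' (both configurable). Multiplying a sample's TPM by a constant leaves its
#' RXE unchanged (the constant cancels in the two means).
#'
#' @param tpm TPM matrix from [compute_tpm()].
#' @param annotation gene annotation covering the TPM genes.
#' @param meta optional sample metadata; `sex`, `diagnosis`, `region` are
#'   carried into the result for grouping.
#' @param presence_fraction minimum fraction of samples with TPM > 0
#'   (default 0.2).
#' @param method `"log_of_mean"` (the definition above, default) or
#'   `"mean_of_log"` (difference of mean `log2(TPM + 1)`, reported for
#'   comparison).
#' @param exclude_par drop PAR genes from the X set (default TRUE).
#' @param restrict_xci_class optional XCI classes (e.g. `"inactive"`) to
#'   restrict the X gene set to.
#' @return tibble of class `rxe_table`: `sample_id`, `rxe`, group columns;
#'   attributes `n_x_genes`, `n_auto_genes`, `method`.
#' @export
compute_rxe <- function(tpm, annotation, meta = NULL, presence_fraction = 0.2,
                        method = c("log_of_mean", "mean_of_log"),
                        exclude_par = TRUE, restrict_xci_class = NULL) {
  method <- match.arg(method)
  if (!identical(attr(tpm, "kind"), "TPM")) {
    sd_validation_error("compute_rxe expects a TPM matrix (attribute kind = 'TPM')")
  }
  check_columns(annotation, c("gene_id", "chromosome", "par_flag", "xci_status"),
                "annotation")
  ann <- annotation[match(rownames(tpm), annotation$gene_id), ]
  if (anyNA(ann$gene_id)) sd_validation_error("annotation does not cover all TPM genes")

  present <- rowMeans(tpm > 0) >= presence_fraction
  x_set <- present & ann$chromosome == "X" & (!exclude_par | !ann$par_flag)
  if (!is.null(restrict_xci_class)) {
    x_set <- x_set & ann$xci_status %in% restrict_xci_class
  }
  auto_set <- present & !(ann$chromosome %in% c("X", "Y"))
  if (sum(x_set) == 0 || sum(auto_set) == 0) {
    sd_validation_error("no X or no autosomal genes survive the presence filter")
  }

  if (method == "log_of_mean") {
    mx <- colMeans(tpm[x_set, , drop = FALSE])
    ma <- colMeans(tpm[auto_set, , drop = FALSE])
    if (any(mx == 0)) {
      sd_validation_error(sprintf("zero mean X-gene TPM in sample(s): %s",
                                  paste(colnames(tpm)[mx == 0], collapse = ", ")))
    }
    rxe <- log2(mx) - log2(ma)
  } else {
    rxe <- colMeans(log2(tpm[x_set, , drop = FALSE] + 1)) -
      colMeans(log2(tpm[auto_set, , drop = FALSE] + 1))
  }

  out <- tibble(sample_id = colnames(tpm), rxe = unname(rxe))
  if (!is.null(meta)) {
    keep <- intersect(c("sex", "diagnosis", "region"), names(meta))
    out <- dplyr::left_join(out, meta[, c("sample_id", keep)], by = "sample_id")
  }
  attr(out, "n_x_genes") <- sum(x_set)
  attr(out, "n_auto_genes") <- sum(auto_set)
  attr(out, "method") <- method
  class(out) <- c("rxe_table", class(out))
  out
}

#' Mann-Whitney U test
#'
#' Exact null enumeration when both groups have at most 8 observations and
#' there are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction.
#'
#' @param values numeric vector.
#' @param labels vector with exactly two distinct values; the U statistic
#'   counts wins of the first level.
#' @return one-row tibble: `U`, `p`, `method`, `n1`, `n2`.
#' @export
mann_whitney <- function(values, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) {
    sd_validation_error("mann_whitney needs exactly two non-empty groups")
  }
  labels <- droplevels(labels)
  x <- values[labels == levels(labels)[1]]
  y <- values[labels == levels(labels)[2]]
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 8 && length(y) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble(U = unname(wt$statistic), p = min(wt$p.value, 1),
         method = if (exact) "exact" else "normal_approx",
         n1 = length(x), n2 = length(y))
}

# Shared 2x2 Fisher helper: two-sided p (minimum-likelihood method, as in
# stats::fisher.test) and the sample cross-product odds ratio.
fisher_2x2 <- function(a, b, c_, d) {
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
  p <- fisher.test(tab, alternative = "two.sided")$p.value
  or <- (a * d) / (b * c_)
  list(p = p, odds_ratio = or)
}

#' XCI-status enrichment of sex-biased genes
#'
#' For each XCI category (escape / variable / inactive) and each direction
#' stratum (female-biased, male-biased, all), builds the 2x2 table of
#' membership in the DEG set versus the category over the universe of tested
#' X-annotated genes and applies a two-sided Fisher's exact test, Bonferroni-
#' corrected over all tables computed.
#'
#' @param de a tidied DE table (or `moderated_fit`) with `feature_id`,
#'   `logFC`, `adj.P.Val`; negative logFC = female-biased (male-vs-female
#'   coding).
#' @param annotation gene annotation with `gene_id`, `chromosome`,
#'   `xci_status`.
#' @param universe character vector of tested X-annotated genes; defaults to
#'   all tested genes with an XCI class.
#' @param fdr_cutoff DEG threshold (default 0.05).
#' @return tibble: `category`, `stratum`, 2x2 cells, `odds_ratio`
#'   (cross-product), `p`, `p_bonferroni`.
#' @export
xci_enrichment <- function(de, annotation, universe = NULL, fdr_cutoff = 0.05) {
  if (inherits(de, "moderated_fit")) de <- de$table
  check_columns(de, c("feature_id", "logFC", "adj.P.Val"), "DE table")
  check_columns(annotation, c("gene_id", "xci_status"), "annotation")
  xci <- setNames(annotation$xci_status, annotation$gene_id)
  if (is.null(universe)) {
    universe <- de$feature_id[de$feature_id %in%
                                annotation$gene_id[annotation$xci_status %in%
                                                     c("escape", "variable", "inactive")]]
  }
  if (length(universe) == 0) sd_validation_error("empty XCI universe")
  de <- de[de$feature_id %in% universe, , drop = FALSE]
  deg <- de$feature_id[!is.na(de$adj.P.Val) & de$adj.P.Val < fdr_cutoff]
  sets <- list(
    all = deg,
    `female-bias` = de$feature_id[de$feature_id %in% deg & de$logFC < 0],
    `male-bias` = de$feature_id[de$feature_id %in% deg & de$logFC > 0]
  )
  cats <- intersect(c("escape", "variable", "inactive"), unique(xci[universe]))
  rows <- purrr::map_dfr(names(sets), function(st) {
    s <- sets[[st]]
    purrr::map_dfr(cats, function(ct) {
      in_cat <- universe[xci[universe] == ct]
      a <- length(intersect(s, in_cat))
      b <- length(setdiff(s, in_cat))
      c_ <- length(setdiff(in_cat, s))
      d <- length(universe) - a - b - c_
      f <- fisher_2x2(a, b, c_, d)
      tibble(category = ct, stratum = st, set_in_cat = a, set_not_cat = b,
             nonset_in_cat = c_, nonset_not_cat = d,
             odds_ratio = f$odds_ratio, p = f$p)
    })
  })
  rows$p_bonferroni <- pmin(1, rows$p * nrow(rows))
  rows
}

#' Mann-Whitney RXE group comparisons
#'
#' Convenience wrapper reproducing the standard dosage contrasts: RXE between
#' sexes per region, and between diagnoses within sex per region.
#'
#' @param rxe an `rxe_table` with `sex`, `diagnosis`, `region` columns.
#' @return tibble: `region`, `comparison`, `stratum`, `U`, `p`, group sizes.
#' @export
rxe_comparisons <- function(rxe) {
  check_columns(rxe, c("rxe", "sex", "diagnosis", "region"), "RXE table")
  by_region <- split(as.data.frame(rxe), rxe$region)
  purrr::map_dfr(names(by_region), function(rg) {
    d <- by_region[[rg]]
    rows <- dplyr::bind_cols(
      tibble(region = rg, comparison = "M_vs_F", stratum = "all"),
      mann_whitney(d$rxe, factor(d$sex, levels = c("M", "F")))
    )
    for (sx in unique(d$sex)) {
      ds <- d[d$sex == sx, ]
      if (length(unique(ds$diagnosis)) == 2) {
        rows <- dplyr::bind_rows(rows, dplyr::bind_cols(
          tibble(region = rg, comparison = "SZ_vs_CTL", stratum = sx),
          mann_whitney(ds$rxe, factor(ds$diagnosis, levels = c("SZ", "CTL")))
        ))
      }
    }
    rows
  })
}
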