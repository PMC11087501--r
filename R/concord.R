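# Cross-dataset / cross-region replication statistics: the pi1 shared-signal
# estimate, effect-size concordance, and DEG overlap enrichment.

#' Estimate pi1 (fraction of shared true signals)
#'
#' Storey-style estimate: `pi0(lambda) = #{p > lambda} / (n * (1 - lambda))`
#' on a lambda grid, smoothed with a cubic smoothing spline (df = 3) and
#' evaluated at the largest lambda, clamped to `[0, 1]`; `pi1 = 1 - pi0`.
#' With fewer than 20 p-values the smoother is unreliable and a fixed-lambda
#' estimate at `lambda = 0.5` is used instead.
#'
#' @param p p-values in `[0, 1]` (typically: replication-dataset p-values of
#'   the discovery dataset's significant features).
#' @param method `"smoother"` (default) or `"fixed"`.
#' @param lambda_grid grid for the smoother (default 0.05..0.95 by 0.05).
#' @param lambda single lambda for `method = "fixed"` (default 0.5).
#' @return one-row tibble: `pi0`, `pi1`, `method`, `n`.
#' @export
pi1 <- function(p, method = c("smoother", "fixed"),
                lambda_grid = seq(0.05, 0.95, by = 0.05), lambda = 0.5) {
  method <- match.arg(method)
  p <- p[!is.na(p)]
  n <- length(p)
  if (n == 0) sd_validation_error("no p-values supplied")
  if (any(p < 0 | p > 1)) sd_validation_error("p-values must lie in [0, 1]")
  if (method == "smoother" && n < 20) {
    method <- "fixed"
  }
  if (method == "fixed") {
    pi0 <- sum(p > lambda) / (n * (1 - lambda))
  } else {
    pi0_l <- vapply(lambda_grid, function(l) sum(p > l) / (n * (1 - l)), double(1))
    fit <- smooth.spline(lambda_grid, pi0_l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda_grid))$y
  }
  pi0 <- min(max(pi0, 0), 1)
  tibble(pi0 = pi0, pi1 = 1 - pi0, method = method, n = n)
}

#' Effect-size concordance between two DE analyses
#'
#' Spearman correlation (average ranks under ties) and the fraction of shared
#' features whose log fold changes agree in sign.
#'
#' @param de_a,de_b `moderated_fit`s or tidied DE tables with `feature_id`,
#'   `logFC` (and `adj.P.Val` when restricting).
#' @param restrict `"all"` shared features (default) or `"significant"`
#'   (adjusted p < 0.05 in both).
#' @return one-row tibble: `rho`, `rho_p`, `sign_concordance`, `n`.
#' @export
effect_concordance <- function(de_a, de_b, restrict = c("all", "significant")) {
  restrict <- match.arg(restrict)
  a <- if (inherits(de_a, "moderated_fit")) de_a$table else de_a
  b <- if (inherits(de_b, "moderated_fit")) de_b$table else de_b
  check_columns(a, c("feature_id", "logFC"), "DE table A")
  check_columns(b, c("feature_id", "logFC"), "DE table B")
  m <- dplyr::inner_join(a, b, by = "feature_id", suffix = c("_a", "_b"))
  if (restrict == "significant") {
    m <- m[!is.na(m$adj.P.Val_a) & !is.na(m$adj.P.Val_b) &
             m$adj.P.Val_a < 0.05 & m$adj.P.Val_b < 0.05, , drop = FALSE]
  }
  if (nrow(m) < 3) sd_validation_error("fewer than 3 shared features")
  rho <- cor(m$logFC_a, m$logFC_b, method = "spearman")
  rho_p <- suppressWarnings(cor.test(m$logFC_a, m$logFC_b,
                                     method = "spearman")$p.value)
  sign_conc <- mean(sign(m$logFC_a) == sign(m$logFC_b))
  tibble(rho = rho, rho_p = rho_p, sign_concordance = sign_conc, n = nrow(m))
}

#' DEG overlap enrichment
#'
#' Two-sided Fisher's exact test of the overlap of two gene sets against a
#' universe: `[[|A & B|, |A \\ B|], [|B \\ A|, |universe \\ (A | B)|]]`. The
#' reported odds ratio is the sample cross-product ratio.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible features.
#' @return one-row tibble: overlap cells, `expected_overlap`, `odds_ratio`,
#'   `p`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe) {
  if (length(universe) == 0) sd_validation_error("empty universe")
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) > 0 || length(out_b) > 0) {
    sd_validation_error("sets must be subsets of the universe")
  }
  set_a <- unique(set_a); set_b <- unique(set_b)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c_ <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c_
  f <- fisher_2x2(a, b, c_, d)
  tibble(n_overlap = a, n_a_only = b, n_b_only = c_, n_neither = d,
         expected_overlap = length(set_a) * length(set_b) / length(universe),
         odds_ratio = f$odds_ratio, p = f$p)
}

#' Full replication statistics between two DE analyses
#'
#' Combines the three replication views: pi1 of dataset-B p-values over
#' dataset-A's nominally significant features, effect-size concordance, and
#' Fisher enrichment of the FDR-significant DEG overlap.
#'
#' @param de_a,de_b `moderated_fit`s or tidied DE tables (A = discovery,
#'   B = replication).
#' @param p_select nominal significance for selecting A's features for pi1
#'   (default 0.05).
#' @param fdr_cutoff DEG threshold for the overlap test (default 0.05).
#' @return one-row tibble: `pi0`, `pi1`, `rho`, `rho_p`, `sign_concordance`,
#'   `overlap`, `overlap_or`, `overlap_p`, `n_shared`, `n_selected`.
#' @export
replication_stats <- function(de_a, de_b, p_select = 0.05, fdr_cutoff = 0.05) {
  a <- if (inherits(de_a, "moderated_fit")) de_a$table else de_a
  b <- if (inherits(de_b, "moderated_fit")) de_b$table else de_b
  shared <- intersect(a$feature_id, b$feature_id)
  a <- a[a$feature_id %in% shared, ]
  b <- b[b$feature_id %in% shared, ]
  sel <- a$feature_id[!is.na(a$P.Value) & a$P.Value < p_select]
  pi <- if (length(sel) > 0) {
    pi1(b$P.Value[match(sel, b$feature_id)])
  } else {
    tibble(pi0 = NA_real_, pi1 = NA_real_, method = NA_character_, n = 0L)
  }
  conc <- effect_concordance(a, b)
  deg_a <- a$feature_id[!is.na(a$adj.P.Val) & a$adj.P.Val < fdr_cutoff]
  deg_b <- b$feature_id[!is.na(b$adj.P.Val) & b$adj.P.Val < fdr_cutoff]
  ov <- overlap_enrichment(deg_a, deg_b, shared)
  tibble(pi0 = pi$pi0, pi1 = pi$pi1, rho = conc$rho, rho_p = conc$rho_p,
         sign_concordance = conc$sign_concordance,
         overlap = ov$n_overlap, overlap_or = ov$odds_ratio, overlap_p = ov$p,
         n_shared = length(shared), n_selected = length(sel))
}
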