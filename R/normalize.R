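# Expression units and preprocessing: effective lengths, TPM, the CPM-based
# low-expression filter, TMM normalization factors, log-CPM and voom-style
# precision weights.

#' Effective gene lengths
#'
#' Effective length = gene length - mean fragment length + 1. Genes whose
#' effective length is <= 1 cannot be quantified at this fragment length and
#' are masked out.
#'
#' @param annotation gene annotation tibble with `gene_id`, `gene_length`.
#' @param mean_fragment_length mean sequencing fragment length (bp), > 0.
#' @return tibble: `gene_id`, `eff_length`, `retained`.
#' @export
effective_lengths <- function(annotation, mean_fragment_length) {
  check_columns(annotation, c("gene_id", "gene_length"), "annotation")
  if (mean_fragment_length <= 0) sd_validation_error("mean_fragment_length must be > 0")
  eff <- annotation$gene_length - mean_fragment_length + 1
  tibble(gene_id = annotation$gene_id, eff_length = eff, retained = eff > 1)
}

#' Transcripts per million
#'
#' Per sample: `rate = count / effective_length`, then rates are scaled so each
#' column sums to one million. Genes masked by [effective_lengths()] are
#' dropped before scaling.
#'
#' @param counts integer gene x sample matrix.
#' @param eff_len the tibble from [effective_lengths()], or a named numeric
#'   vector of effective lengths (all > 1) covering the count genes.
#' @return real matrix of TPM over retained genes, columns summing to 1e6,
#'   with attribute `kind = "TPM"`.
#' @export
compute_tpm <- function(counts, eff_len) {
  check_count_matrix(counts)
  if (is.data.frame(eff_len)) {
    eff_len <- eff_len[eff_len$retained, , drop = FALSE]
    len <- setNames(eff_len$eff_length, eff_len$gene_id)
  } else {
    len <- eff_len
  }
  keep <- intersect(rownames(counts), names(len))
  if (length(keep) == 0) sd_validation_error("no genes shared between counts and effective lengths")
  len <- len[keep]
  if (any(len <= 1)) sd_validation_error("effective lengths must be > 1 for retained genes")
  rate <- counts[keep, , drop = FALSE] / len
  tot <- colSums(rate)
  if (any(tot == 0)) {
    sd_validation_error(sprintf("TPM undefined for all-zero sample(s): %s",
                                paste(colnames(counts)[tot == 0], collapse = ", ")))
  }
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  attr(tpm, "kind") <- "TPM"
  tpm
}

#' Low-expression filter
#'
#' A gene is retained when its CPM reaches `cpm_threshold` (with a nonzero
#' count) in at least `ceiling(group_fraction x smallest-group size)` samples,
#' counting qualifying samples across the whole cohort. The default mirrors
#' the "10 CPM in 70% of the smallest group" rule with sex as the grouping
#' variable.
#'
#' @param counts integer gene x sample matrix.
#' @param meta sample metadata containing the grouping column.
#' @param cpm_threshold minimum CPM to qualify (default 10).
#' @param group_fraction fraction of the smallest group defining the quota
#'   (default 0.7, rounded up).
#' @param group metadata column defining groups (default `"sex"`).
#' @return tibble: `gene_id`, `n_qualifying`, `retained`; attribute `quota`.
#' @export
filter_by_expression <- function(counts, meta, cpm_threshold = 10,
                                 group_fraction = 0.7, group = "sex") {
  check_count_matrix(counts)
  check_columns(meta, group, "metadata")
  sizes <- table(meta[[group]])
  if (length(sizes) == 0 || any(sizes == 0)) sd_validation_error("empty grouping level")
  quota <- ceiling(group_fraction * min(sizes))
  lib <- colSums(counts)
  if (any(lib == 0)) {
    sd_validation_error(sprintf("zero library size for sample(s): %s",
                                paste(colnames(counts)[lib == 0], collapse = ", ")))
  }
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  qualifying <- (cpm >= cpm_threshold) & (counts > 0)
  n_q <- rowSums(qualifying)
  out <- tibble(gene_id = rownames(counts), n_qualifying = as.integer(n_q),
                retained = n_q >= quota)
  attr(out, "quota") <- as.integer(quota)
  out
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values library-size factors (weighted trimmed mean of
#' log ratios against a reference sample; 30% trim on M, 5% on A), rescaled
#' to geometric mean 1. Computation is delegated to edgeR's TMM
#' implementation; the reference sample is the one whose 75th-percentile
#' CPM is closest to the cohort mean.
#'
#' @param counts integer gene x sample matrix (>= 2 samples, positive
#'   library sizes).
#' @return tibble: `sample_id`, `factor`; attribute `reference` = reference
#'   sample id.
#' @export
tmm_factors <- function(counts) {
  check_count_matrix(counts)
  if (ncol(counts) < 2) sd_validation_error("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    sd_validation_error(sprintf("zero library size for sample(s): %s",
                                paste(colnames(counts)[lib == 0], collapse = ", ")))
  }
  f75 <- apply(counts, 2, function(x) quantile(x, p = 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  # a sample must co-express something with the reference to be comparable
  ref_pos <- counts[, ref] > 0
  shared <- colSums(counts[ref_pos, , drop = FALSE] > 0)
  if (any(shared == 0)) {
    sd_validation_error(sprintf("sample(s) share no co-expressed genes with the reference (%s): %s",
                                colnames(counts)[ref],
                                paste(colnames(counts)[shared == 0], collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref)
  f <- f / geo_mean(f)
  out <- tibble(sample_id = colnames(counts), factor = unname(f))
  attr(out, "reference") <- colnames(counts)[ref]
  out
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (lib x factor + 2 * prior) x 1e6)` with effective
#' library sizes (raw library x TMM factor) and a fixed prior count.
#'
#' @param counts integer gene x sample matrix.
#' @param factors the tibble from [tmm_factors()] (or NULL for unit factors).
#' @param prior_count pseudo-count (default 0.5).
#' @return real matrix of log2 CPM with attribute `kind = "logCPM"`.
#' @export
log_cpm <- function(counts, factors = NULL, prior_count = 0.5) {
  check_count_matrix(counts)
  lib <- colSums(counts)
  f <- rep(1, ncol(counts))
  if (!is.null(factors)) {
    f <- factors$factor[match(colnames(counts), factors$sample_id)]
    if (anyNA(f)) sd_validation_error("factors missing for some samples")
  }
  eff_lib <- lib * f
  out <- log2(sweep(counts + prior_count, 2, eff_lib + 2 * prior_count, "/") * 1e6)
  attr(out, "kind") <- "logCPM"
  out
}

#' Voom-style precision weights
#'
#' Fits per-gene least squares on the log-CPM matrix, smooths the
#' sqrt-standard-deviation versus mean log-CPM relationship with lowess, and
#' converts the predicted sqrt-sd at each observation's fitted value into an
#' inverse-variance weight (`predicted^-4`). Predictions outside the trend's
#' range are clamped to its endpoints, so extreme genes get finite positive
#' weights.
#'
#' @param logcpm log-CPM matrix from [log_cpm()].
#' @param design numeric design matrix (samples x coefficients), full rank,
#'   with >= 2 residual degrees of freedom.
#' @param span lowess span for the mean-variance trend (default 0.5).
#' @return gene x sample matrix of positive weights.
#' @export
voom_weights <- function(logcpm, design, span = 0.5) {
  design <- as.matrix(design)
  n <- ncol(logcpm)
  p <- qr(design)$rank
  if (p < ncol(design)) sd_validation_error("design matrix is not full rank")
  if (n - p < 2) sd_validation_error("need >= 2 residual degrees of freedom for the variance trend")
  fit <- lm.fit(design, t(logcpm))
  res <- as.matrix(fit$residuals)                     # samples x genes
  sigma <- sqrt(colSums(res^2) / (n - p))
  fitted <- design %*% as.matrix(fit$coefficients)    # samples x genes
  amean <- rowMeans(logcpm)
  trend <- lowess(amean, sqrt(sigma), f = span)
  pred <- approx(trend$x, trend$y, xout = as.vector(fitted), rule = 2,
                 ties = mean)$y
  pred <- pmax(pred, 1e-4)
  w <- matrix(pred^-4, nrow = n)                      # samples x genes
  w <- t(w)
  dimnames(w) <- dimnames(logcpm)
  if (any(!is.finite(w)) || any(w <= 0)) sd_abort("non-finite or non-positive voom weights")
  w
}

#' One-call normalization of a count matrix
#'
#' Applies the low-expression filter, TMM factors, log-CPM and TPM in the
#' standard order and returns all artifacts.
#'
#' @inheritParams filter_by_expression
#' @param annotation gene annotation (for effective lengths / TPM).
#' @param mean_fragment_length fragment length for [effective_lengths()].
#' @param prior_count pseudo-count for [log_cpm()].
#' @return list: `tpm`, `logcpm`, `factors`, `filter` (filter report),
#'   `eff_len`, `counts` (filtered counts).
#' @export
normalize_counts <- function(counts, meta, annotation,
                             mean_fragment_length = 200, cpm_threshold = 10,
                             group_fraction = 0.7, group = "sex",
                             prior_count = 0.5) {
  flt <- filter_by_expression(counts, meta, cpm_threshold, group_fraction, group)
  kept <- flt$gene_id[flt$retained]
  counts_f <- counts[kept, , drop = FALSE]
  factors <- tmm_factors(counts_f)
  logcpm <- log_cpm(counts_f, factors, prior_count)
  el <- effective_lengths(annotation, mean_fragment_length)
  el <- el[el$gene_id %in% kept, , drop = FALSE]
  tpm <- compute_tpm(counts_f, el)
  list(tpm = tpm, logcpm = logcpm, factors = factors, filter = flt,
       eff_len = el, counts = counts_f)
}
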