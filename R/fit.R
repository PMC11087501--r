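# Weighted per-gene linear fits with empirical-Bayes variance moderation,
# BH adjustment, residualization, and the one-call differential-expression
# wrapper.

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement. Missing p-values propagate with
#' a warning and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA/NaN allowed).
#' @return vector of FDR-adjusted p-values.
#' @export
adjust_bh <- function(p) {
  if (anyNA(p)) rlang::warn("NA/NaN p-values propagated through BH adjustment")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) sd_validation_error("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

#' Fit moderated per-gene linear models
#'
#' Per-gene (weighted) least squares followed by empirical-Bayes shrinkage of
#' the residual variances toward a common prior `s0^2` with prior degrees of
#' freedom `d0`, estimated by moment-matching a scaled-F distribution across
#' genes. The posterior variance is
#' `(d0 * s0^2 + d * s^2) / (d0 + d)`; the moderated t uses it in place of
#' `s^2` with `d + d0` degrees of freedom. For multi-column contrasts a joint
#' moderated F over the contrast columns is used. `d0` can be overridden:
#' `d0 = 0` reproduces the ordinary (W)LS t exactly and `d0 = Inf` pins every
#' posterior variance at `s0^2`.
#'
#' With `cluster` set (donor-repeated designs), per-gene CR1 cluster-robust
#' standard errors replace the model-based ones and no variance moderation is
#' applied; tests use `n_clusters - 1` degrees of freedom.
#'
#' @param expr genes x samples matrix (log scale expression).
#' @param design samples x coefficients matrix, full rank, residual df >= 1.
#' @param contrast character vector of design column names to test (one
#'   column: moderated t; several: joint moderated F).
#' @param weights optional genes x samples matrix of positive finite
#'   precision weights.
#' @param d0 optional prior-df override (default: estimated).
#' @param cluster optional factor of length n-samples for cluster-robust
#'   inference.
#' @return object of class `moderated_fit`; see [tidy.moderated_fit()].
#' @export
fit_moderated <- function(expr, design, contrast, weights = NULL, d0 = NULL,
                          cluster = NULL) {
  design <- as.matrix(design)
  n <- ncol(expr)
  p <- ncol(design)
  if (qr(design)$rank < p) sd_validation_error("design matrix is not full rank")
  df_resid <- n - p
  if (df_resid < 1) sd_validation_error("zero residual degrees of freedom")
  if (!all(contrast %in% colnames(design))) {
    sd_validation_error(sprintf("contrast column(s) not in design: %s",
                                paste(setdiff(contrast, colnames(design)), collapse = ", ")))
  }
  if (!is.null(weights) && (any(!is.finite(weights)) || any(weights <= 0))) {
    sd_validation_error("weights must be positive and finite")
  }
  G <- nrow(expr)
  cidx <- match(contrast, colnames(design))
  q <- length(cidx)

  if (!is.null(cluster)) {
    return(fit_cluster_robust(expr, design, cidx, weights, cluster))
  }

  coefs <- matrix(NA_real_, G, p)
  sigma2 <- numeric(G)
  se_unscaled <- matrix(NA_real_, G, q)       # sqrt diag of (X'WX)^-1, contrast cols
  vinv_quad <- numeric(G)                     # coef_c' Vc^-1 coef_c for F contrasts

  if (is.null(weights)) {
    fit <- lm.fit(design, t(expr))
    coefs <- t(as.matrix(fit$coefficients))
    res <- as.matrix(fit$residuals)
    sigma2 <- colSums(res^2) / df_resid
    XtXinv <- chol2inv(chol(crossprod(design)))
    se_unscaled <- matrix(sqrt(diag(XtXinv)[cidx]), G, q, byrow = TRUE)
    if (q > 1) {
      Vc_inv <- solve(XtXinv[cidx, cidx])
      cc <- coefs[, cidx, drop = FALSE]
      vinv_quad <- rowSums((cc %*% Vc_inv) * cc)
    }
  } else {
    for (g in seq_len(G)) {
      w <- weights[g, ]
      fg <- lm.wfit(design, expr[g, ], w)
      coefs[g, ] <- fg$coefficients
      sigma2[g] <- sum(w * fg$residuals^2) / df_resid
      XtXinv <- chol2inv(qr.R(fg$qr))
      se_unscaled[g, ] <- sqrt(diag(XtXinv)[cidx])
      if (q > 1) {
        cc <- coefs[g, cidx]
        vinv_quad[g] <- drop(crossprod(cc, solve(XtXinv[cidx, cidx], cc)))
      }
    }
  }

  sq <- limma::squeezeVar(sigma2, df = df_resid)
  s0_2 <- sq$var.prior
  d0_est <- sq$df.prior
  d0_use <- d0 %||% d0_est
  s2_post <- posterior_var(sigma2, df_resid, s0_2, d0_use)
  df_total <- df_resid + d0_use

  if (q == 1) {
    logFC <- coefs[, cidx]
    tstat <- logFC / (se_unscaled[, 1] * sqrt(s2_post))
    pval <- 2 * pt(abs(tstat), df = df_total, lower.tail = FALSE)
    stat <- tstat
  } else {
    cc <- coefs[, cidx, drop = FALSE]
    logFC <- cc[cbind(seq_len(G), max.col(abs(cc)))]   # largest interaction term
    stat <- vinv_quad / (q * s2_post)
    pval <- pf(stat, q, df_total, lower.tail = FALSE)
  }

  new_moderated_fit(
    feature_id = rownames(expr), logFC = logFC, AveExpr = rowMeans(expr),
    stat = stat, stat_type = if (q == 1) "t" else "F", pval = pval,
    contrast = contrast, df_resid = df_resid, df_total = df_total,
    params = list(s0_2 = s0_2, d0 = d0_use, d0_estimated = d0_est),
    method = "eBayes-moderated"
  )
}

posterior_var <- function(s2, d, s0_2, d0) {
  if (is.infinite(d0)) return(rep(s0_2, length(s2)))
  if (d0 == 0) return(s2)
  (d0 * s0_2 + d * s2) / (d0 + d)
}

fit_cluster_robust <- function(expr, design, cidx, weights, cluster) {
  cluster <- as.factor(cluster)
  n_cl <- nlevels(droplevels(cluster))
  if (n_cl < 2) sd_validation_error("cluster-robust inference needs >= 2 clusters")
  G <- nrow(expr)
  q <- length(cidx)
  logFC <- stat <- pval <- numeric(G)
  df2 <- n_cl - 1
  for (g in seq_len(G)) {
    dat <- data.frame(y = expr[g, ], design[, -1, drop = FALSE], check.names = FALSE)
    fit <- if (is.null(weights)) lm(y ~ ., data = dat) else
      lm(y ~ ., data = dat, weights = weights[g, ])
    V <- sandwich::vcovCL(fit, cluster = cluster, type = "HC1")
    b <- coef(fit)
    if (q == 1) {
      logFC[g] <- b[cidx]
      stat[g] <- b[cidx] / sqrt(V[cidx, cidx])
      pval[g] <- 2 * pt(abs(stat[g]), df = df2, lower.tail = FALSE)
    } else {
      bc <- b[cidx]
      logFC[g] <- bc[which.max(abs(bc))]
      stat[g] <- drop(crossprod(bc, solve(V[cidx, cidx], bc))) / q
      pval[g] <- pf(stat[g], q, df2, lower.tail = FALSE)
    }
  }
  new_moderated_fit(
    feature_id = rownames(expr), logFC = logFC, AveExpr = rowMeans(expr),
    stat = stat, stat_type = if (q == 1) "t" else "F", pval = pval,
    contrast = colnames(design)[cidx], df_resid = df2, df_total = df2,
    params = list(s0_2 = NA_real_, d0 = 0, d0_estimated = NA_real_),
    method = "cluster-robust"
  )
}

new_moderated_fit <- function(feature_id, logFC, AveExpr, stat, stat_type,
                              pval, contrast, df_resid, df_total, params,
                              method) {
  fdr <- adjust_bh(pval)
  direction <- direction_label(logFC, contrast[1])
  tab <- tibble(
    feature_id = feature_id, logFC = unname(logFC), AveExpr = unname(AveExpr),
    t = unname(stat), P.Value = unname(pval), adj.P.Val = unname(fdr),
    direction = direction
  )
  structure(
    list(table = tab, contrast = contrast, stat_type = stat_type,
         df_resid = df_resid, df_total = df_total, params = params,
         method = method),
    class = "moderated_fit"
  )
}

direction_label <- function(logFC, contrast_name) {
  if (grepl("^sexM$", contrast_name)) {
    ifelse(logFC > 0, "male-biased", "female-biased")
  } else if (grepl("diagnosisSZ", contrast_name)) {
    ifelse(logFC > 0, "up_in_SZ", "down_in_SZ")
  } else {
    ifelse(logFC > 0, "positive", "negative")
  }
}

#' @export
print.moderated_fit <- function(x, ...) {
  cat(sprintf("<moderated_fit> %d features, contrast %s (%s), %s\n",
              nrow(x$table), paste(x$contrast, collapse = "+"), x$stat_type,
              x$method))
  cat(sprintf("  s0^2 = %.4g, d0 = %.4g, residual df = %d; %d features at FDR < 0.05\n",
              x$params$s0_2, x$params$d0, x$df_resid,
              sum(x$table$adj.P.Val < 0.05, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a moderated fit
#'
#' @param x a `moderated_fit`.
#' @param ... unused.
#' @return per-feature tibble: `feature_id`, `logFC`, `AveExpr`, `t`
#'   (moderated t, or moderated F for joint contrasts), `P.Value`,
#'   `adj.P.Val` (BH), `direction`.
#' @export
tidy.moderated_fit <- function(x, ...) x$table

#' @rdname tidy.moderated_fit
#' @return for `glance`: one-row tibble with the moderation hyperparameters
#'   and the FDR < 0.05 feature count.
#' @export
glance.moderated_fit <- function(x, ...) {
  tibble(
    n_features = nrow(x$table), stat_type = x$stat_type,
    s0_2 = x$params$s0_2, d0 = x$params$d0, df_resid = x$df_resid,
    n_signif = sum(x$table$adj.P.Val < 0.05, na.rm = TRUE),
    method = x$method
  )
}

#' Residualized, z-scored expression
#'
#' Regresses a null design out of each gene and z-scores the residuals across
#' samples. Genes with zero residual variance are excluded (listed in the
#' `excluded` attribute) with a warning.
#'
#' @param expr genes x samples matrix.
#' @param null_design samples x coefficients matrix, full rank.
#' @return genes x samples matrix of per-gene standardized residuals
#'   (`kind = "residual_z"`).
#' @export
residualize <- function(expr, null_design) {
  null_design <- as.matrix(null_design)
  if (qr(null_design)$rank < ncol(null_design)) {
    sd_validation_error("null design is not full rank")
  }
  res <- t(as.matrix(lm.fit(null_design, t(expr))$residuals))
  sds <- apply(res, 1, sd)
  bad <- !is.finite(sds) | sds < 1e-10
  if (any(bad)) {
    rlang::warn(sprintf("excluding %d gene(s) with zero residual variance", sum(bad)))
  }
  out <- (res[!bad, , drop = FALSE] - rowMeans(res[!bad, , drop = FALSE])) / sds[!bad]
  attr(out, "kind") <- "residual_z"
  attr(out, "excluded") <- rownames(expr)[bad]
  out
}

#' End-to-end differential expression for one design
#'
#' Chains the standard pipeline on a raw count matrix: low-expression filter,
#' TMM factors, log-CPM, hidden-factor estimation, voom-style weights, and
#' the moderated fit.
#'
#' @param counts integer gene x sample matrix.
#' @param meta sample metadata aligned with the count columns.
#' @param model model name, see [design_spec()].
#' @param covariates numeric metadata columns to adjust for.
#' @param sex optional single sex (`"F"`/`"M"`) to subset to (required for
#'   `diagnosis_by_sex`).
#' @param n_sv hidden factors: `"auto"`, or a count (0 disables). Factors
#'   are estimated from residuals of the full design (without SVs), so they
#'   capture structure orthogonal to the modelled effects.
#' @param use_weights apply voom-style precision weights (default TRUE).
#' @param cluster_by_donor use donor-clustered robust errors (default TRUE
#'   for `sex_x_region`, which spans regions with repeated donors).
#' @param cpm_threshold,group_fraction low-expression filter parameters.
#' @param d0 optional moderation prior-df override (testing hook).
#' @return a `moderated_fit`; its `pipeline` element records the filter
#'   report, factors, design, number of SVs, and the log-CPM matrix.
#' @export
de_analysis <- function(counts, meta, model, covariates = character(),
                        sex = NULL, n_sv = 0, use_weights = TRUE,
                        cluster_by_donor = (model == "sex_x_region"),
                        cpm_threshold = 10, group_fraction = 0.7, d0 = NULL) {
  if (!is.null(sex)) {
    keep <- meta$sex == sex
    meta <- meta[keep, , drop = FALSE]
    counts <- counts[, keep, drop = FALSE]
  }
  filter_group <- if (length(unique(meta$sex)) > 1) "sex" else "diagnosis"
  flt <- filter_by_expression(counts, meta, cpm_threshold, group_fraction,
                              group = filter_group)
  counts <- counts[flt$gene_id[flt$retained], , drop = FALSE]
  factors <- tmm_factors(counts)
  logcpm <- log_cpm(counts, factors)

  spec <- design_spec(model, covariates = covariates, n_sv = n_sv)
  base <- build_design(meta, spec, factors = NULL)
  sv <- NULL
  if (!identical(n_sv, 0) && model %in% SD_MODELS_WITH_SV) {
    # factors come from residuals of the full (SV-free) design, so they pick
    # up structure orthogonal to the modelled effects rather than the
    # contrast itself
    sv <- estimate_hidden_factors(logcpm, base$design, k = n_sv)
  }
  built <- build_design(meta, spec, factors = sv)
  weights <- if (use_weights) voom_weights(logcpm, built$design) else NULL
  cluster <- if (cluster_by_donor) meta$donor_id else NULL
  fit <- fit_moderated(logcpm, built$design, built$contrast, weights = weights,
                       d0 = d0, cluster = cluster)
  fit$pipeline <- list(filter = flt, factors = factors, design = built$design,
                       n_sv = if (is.null(sv)) 0L else ncol(sv),
                       logcpm = logcpm, meta = meta, model = model)
  fit
}
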