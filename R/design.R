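# Linear-model designs for the four differential-expression analyses and the
# two residualization nulls, covariate screening, and hidden-factor
# (surrogate-variable style) estimation.

SD_MODELS <- c("sex", "sex_x_region", "sex_x_diagnosis", "diagnosis_by_sex",
               "null_for_sex", "null_minimal")

# Which models carry surrogate-variable terms. The sex-by-region model and
# the diagnosis-only null deliberately do not.
SD_MODELS_WITH_SV <- c("sex", "sex_x_diagnosis", "diagnosis_by_sex", "null_minimal")

#' Specify a differential-expression design
#'
#' The six supported models:
#' \describe{
#'   \item{sex}{sex + diagnosis + age + covariates (+ SVs); tests the sex
#'     coefficient (male vs female).}
#'   \item{sex_x_region}{sex * region + diagnosis + age + covariates (no
#'     SVs); tests the sex-by-region interaction terms jointly.}
#'   \item{sex_x_diagnosis}{sex * diagnosis + age + covariates (+ SVs);
#'     tests the interaction term(s).}
#'   \item{diagnosis_by_sex}{diagnosis + age + covariates (+ SVs) on a
#'     single-sex subset; tests the diagnosis coefficient (SZ vs CTL).}
#'   \item{null_for_sex}{diagnosis + age + covariates, no SVs; the
#'     residualization null that leaves sex signal in the residuals.}
#'   \item{null_minimal}{age + covariates (+ SVs); the residualization null
#'     that also leaves diagnosis signal in.}
#' }
#' Treatment coding uses female and CTL as references, so a positive sex
#' logFC means male-biased and a positive diagnosis logFC means up in SZ.
#'
#' @param model one of the model names above.
#' @param covariates character vector of numeric metadata columns to adjust
#'   for (quality covariates, snpPCs, ...).
#' @param n_sv number of hidden factors to include: a count, or `"auto"` for
#'   permutation-chosen (ignored for models without SV terms).
#' @return list of class `design_spec`.
#' @export
design_spec <- function(model, covariates = character(), n_sv = 0) {
  model <- match.arg(model, SD_MODELS)
  structure(list(model = model, covariates = covariates, n_sv = n_sv),
            class = "design_spec")
}

#' Build the design matrix for a specification
#'
#' @param meta sample metadata (rows in column order of the expression
#'   matrix). For `diagnosis_by_sex` it must contain a single sex.
#' @param spec a [design_spec()].
#' @param factors optional samples x k matrix of hidden factors (columns
#'   SV1..SVk) to append for SV-carrying models.
#' @return list: `design` (samples x coefficients matrix), `contrast`
#'   (character vector of tested column names; empty for null models),
#'   `spec`.
#' @export
build_design <- function(meta, spec, factors = NULL) {
  stopifnot(inherits(spec, "design_spec"))
  check_columns(meta, c("sex", "diagnosis", "age"), "metadata")
  check_columns(meta, spec$covariates, "metadata")
  df <- data.frame(
    sex = factor(meta$sex, levels = c("F", "M")),
    diagnosis = factor(meta$diagnosis, levels = c("CTL", "SZ")),
    age = meta$age
  )
  if (spec$model == "sex_x_region") {
    check_columns(meta, "region", "metadata")
    df$region <- factor(meta$region)
    if (nlevels(droplevels(df$region)) < 2) {
      sd_validation_error("sex_x_region needs >= 2 regions")
    }
  }
  if (spec$model == "diagnosis_by_sex" && length(unique(meta$sex)) != 1) {
    sd_validation_error("diagnosis_by_sex requires metadata pre-subset to a single sex")
  }
  for (cv in spec$covariates) df[[cv]] <- meta[[cv]]
  cv_terms <- c("age", spec$covariates)
  rhs <- switch(spec$model,
    sex              = c("sex", "diagnosis", cv_terms),
    sex_x_region     = c("sex * region", "diagnosis", cv_terms),
    sex_x_diagnosis  = c("sex * diagnosis", cv_terms),
    diagnosis_by_sex = c("diagnosis", cv_terms),
    null_for_sex     = c("diagnosis", cv_terms),
    null_minimal     = cv_terms
  )
  form <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X <- model.matrix(form, data = df)
  if (!is.null(factors) && spec$model %in% SD_MODELS_WITH_SV && NCOL(factors) > 0) {
    factors <- as.matrix(factors)
    colnames(factors) <- colnames(factors) %||% paste0("SV", seq_len(ncol(factors)))
    X <- cbind(X, factors)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    sd_validation_error(sprintf("design is rank-deficient; aliased column(s): %s",
                                paste(aliased, collapse = ", ")))
  }
  contrast <- switch(spec$model,
    sex              = "sexM",
    sex_x_region     = grep("^sexM:region", colnames(X), value = TRUE),
    sex_x_diagnosis  = "sexM:diagnosisSZ",
    diagnosis_by_sex = "diagnosisSZ",
    character(0)
  )
  if (length(contrast) > 0 && !all(contrast %in% colnames(X))) {
    sd_abort("internal: contrast column(s) missing from built design")
  }
  list(design = X, contrast = contrast, spec = spec)
}

#' Screen candidate covariates against expression principal components
#'
#' Candidates pairwise correlated above `cor_cutoff` are pruned first
#' (keeping the first of each pair). Each surviving candidate is then
#' correlated, within each sex, with the top principal components of the
#' expression matrix; candidates with a Bonferroni-significant correlation
#' (over all candidate x PC x sex tests) in either sex are selected.
#'
#' @param expr genes x samples expression matrix (log scale).
#' @param meta sample metadata with a `sex` column (>= 3 samples per sex).
#' @param candidates character vector of numeric metadata columns to screen.
#' @param n_pcs number of PCs per sex (default 10, capped by the data).
#' @param alpha family-wise significance level (default 0.05).
#' @param cor_cutoff pairwise Pearson threshold for the collinearity
#'   pre-prune (default 0.95).
#' @return tibble: `covariate`, `min_p` (Bonferroni-adjusted), `selected`,
#'   `pruned` (dropped in the collinearity pre-step).
#' @export
screen_covariates <- function(expr, meta, candidates, n_pcs = 10, alpha = 0.05,
                              cor_cutoff = 0.95) {
  check_columns(meta, c("sex", candidates), "metadata")
  if (any(table(meta$sex) < 3)) sd_validation_error("need >= 3 samples per sex")
  cand <- candidates
  const <- vapply(cand, function(cv) sd(meta[[cv]]) == 0 || !is.numeric(meta[[cv]]),
                  logical(1))
  if (any(const)) {
    rlang::warn(sprintf("excluding constant/non-numeric covariate(s): %s",
                        paste(cand[const], collapse = ", ")))
    cand <- cand[!const]
  }
  pruned <- character(0)
  if (length(cand) > 1) {
    cm <- abs(cor(as.matrix(as.data.frame(meta)[cand])))
    drop <- rep(FALSE, length(cand))
    for (j in seq_along(cand)[-1]) {
      if (any(cm[j, seq_len(j - 1)][!drop[seq_len(j - 1)]] > cor_cutoff)) drop[j] <- TRUE
    }
    pruned <- cand[drop]
    cand <- cand[!drop]
  }
  rows <- list()
  for (sx in c("F", "M")) {
    idx <- which(meta$sex == sx)
    k <- min(n_pcs, length(idx) - 1)
    pcs <- prcomp(t(expr[, idx, drop = FALSE]), center = TRUE, scale. = FALSE)$x[, seq_len(k), drop = FALSE]
    for (cv in cand) {
      p <- vapply(seq_len(k), function(j) cor.test(meta[[cv]][idx], pcs[, j])$p.value,
                  double(1))
      rows[[length(rows) + 1]] <- tibble(covariate = cv, sex = sx, min_raw_p = min(p),
                                         n_tests = k)
    }
  }
  res <- dplyr::bind_rows(rows)
  m <- sum(res$n_tests)   # Bonferroni over every test performed
  out <- res |>
    dplyr::group_by(.data$covariate) |>
    dplyr::summarise(min_p = min(pmin(.data$min_raw_p * m, 1)), .groups = "drop") |>
    dplyr::mutate(selected = .data$min_p < alpha, pruned = FALSE)
  if (length(pruned) > 0) {
    out <- dplyr::bind_rows(out, tibble(covariate = pruned, min_p = NA_real_,
                                        selected = FALSE, pruned = TRUE))
  }
  out[match(candidates[candidates %in% out$covariate], out$covariate), ]
}

#' Estimate hidden expression factors
#'
#' Principal components of the per-gene residual matrix after regressing out
#' a null design. The number of factors is chosen by a permutation test in
#' the Buja-Eyuboglu style: each gene's residuals are permuted independently
#' `n_perm` times, and leading PCs are kept while their add-one permutation
#' p-value `(1 + #\{perm >= obs\}) / (n_perm + 1)` stays at or below `alpha`
#' (stopping at the first failure).
#'
#' @param expr genes x samples matrix (log scale).
#' @param null_design samples x coefficients matrix, full rank.
#' @param k `"auto"` (permutation choice) or a fixed count (`0` gives an
#'   empty factor matrix).
#' @param n_perm permutations for the auto rule (default 19).
#' @param alpha per-PC permutation significance level (default 0.05).
#' @return samples x k matrix with columns SV1..SVk (0 columns allowed).
#' @export
estimate_hidden_factors <- function(expr, null_design, k = "auto", n_perm = 19,
                                    alpha = 0.05) {
  null_design <- as.matrix(null_design)
  n <- ncol(expr)
  r <- qr(null_design)$rank
  if (r < ncol(null_design)) sd_validation_error("null design is not full rank")
  resid_df <- n - r
  if (!identical(k, "auto") && k >= resid_df) {
    sd_validation_error(sprintf("k = %s >= residual df (%d)", k, resid_df))
  }
  empty <- matrix(numeric(0), nrow = n, ncol = 0)
  if (identical(k, 0) || identical(k, 0L)) return(empty)
  R <- t(as.matrix(lm.fit(null_design, t(expr))$residuals))  # genes x samples
  sv <- svd(R, nu = 0)
  if (identical(k, "auto")) {
    kmax <- min(resid_df - 1, 10L, n - 1L)
    if (kmax < 1) return(empty)
    perm_d <- matrix(NA_real_, n_perm, kmax)
    for (b in seq_len(n_perm)) {
      Rp <- t(apply(R, 1, sample))
      perm_d[b, ] <- svd(Rp, nu = 0, nv = 0)$d[seq_len(kmax)]
    }
    p_pc <- vapply(seq_len(kmax), function(j) {
      (1 + sum(perm_d[, j] >= sv$d[j])) / (n_perm + 1)
    }, double(1))
    pass <- p_pc <= alpha
    k <- if (any(!pass)) which.min(pass) - 1L else kmax
    if (k == 0) return(empty)
  }
  f <- sv$v[, seq_len(k), drop = FALSE] * rep(sv$d[seq_len(k)], each = n)
  f <- scale(f)   # unit-variance factor scores
  colnames(f) <- paste0("SV", seq_len(k))
  rownames(f) <- colnames(expr)
  f[, , drop = FALSE]
}
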