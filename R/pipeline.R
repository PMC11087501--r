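# Orchestration: one configured run chaining simulation (or user data),
# normalization, differential expression, dosage, the sex-specific filter,
# the subsampling null, and cross-region replication, with stage logging and
# resolved-config capture.

#' Configure a pipeline run
#'
#' @param sim a [sim_config()] to simulate input data, or NULL when reading
#'   from files.
#' @param counts,meta,annotation input paths (used when `sim` is NULL).
#' @param out_dir output directory for the TSV artifacts, run log and
#'   resolved config.
#' @param covariates metadata columns to adjust for; `"auto"` screens the
#'   simulated quality covariates and snpPCs with [screen_covariates()] and
#'   always keeps snpPC1..3.
#' @param n_sv hidden factors per DE analysis (`"auto"` or a count).
#' @param cpm_threshold,group_fraction low-expression filter parameters.
#' @param mean_fragment_length fragment length for TPM effective lengths.
#' @param presence_fraction RXE presence filter.
#' @param subsample_B subsampling-null draws (default 100 for a desk-scale
#'   run; the full procedure uses 1000).
#' @param subsample_region region for the subsampling null (default: first).
#' @param fdr_cutoff DEG threshold used throughout.
#' @param seed master seed: stage seeds are derived from it and recorded.
#' @param stages character vector of stages to run, in order, among
#'   `"normalize"`, `"de"`, `"dosage"`, `"sexspec"`, `"concord"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), counts = NULL, meta = NULL,
                            annotation = NULL, out_dir = tempfile("sexdim_run_"),
                            covariates = "auto", n_sv = 2,
                            cpm_threshold = 10, group_fraction = 0.7,
                            mean_fragment_length = NULL, presence_fraction = 0.2,
                            subsample_B = 100, subsample_region = NULL,
                            fdr_cutoff = 0.05, seed = 1L,
                            stages = c("normalize", "de", "dosage", "sexspec",
                                       "concord")) {
  if (is.null(sim)) {
    for (p in c(counts, meta, annotation)) {
      if (is.null(p) || !file.exists(p)) {
        sd_validation_error(sprintf("input path missing or nonexistent: %s",
                                    p %||% "<NULL>"))
      }
    }
  }
  structure(
    list(sim = sim, counts = counts, meta = meta, annotation = annotation,
         out_dir = out_dir, covariates = covariates, n_sv = n_sv,
         cpm_threshold = cpm_threshold, group_fraction = group_fraction,
         mean_fragment_length = mean_fragment_length,
         presence_fraction = presence_fraction, subsample_B = subsample_B,
         subsample_region = subsample_region, fdr_cutoff = fdr_cutoff,
         seed = as.integer(seed), stages = stages),
    class = "pipeline_config"
  )
}

#' Run the full pipeline
#'
#' Executes the configured stages in order, writing every artifact as TSV
#' under `config$out_dir` together with `run.log` (feature counts in/out at
#' every filter) and `resolved_config.yaml` (all parameters and derived
#' seeds). Reruns with the same resolved config reproduce identical tables.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list of in-memory results: `dataset`, per-region
#'   `norm`, `de_sex`, `de_dx` (per sex), `rxe`, `rxe_tests`, `xci`,
#'   `sex_specific`, `subsample`, `replication`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  res <- list()

  # --- input data -----------------------------------------------------------
  if (!is.null(config$sim)) {
    ds <- simulate_dataset(config$sim)
    logf("[data] simulated %d genes x %d samples (seed %d)",
         nrow(ds$counts), ncol(ds$counts), config$sim$seed)
  } else {
    ds <- list(counts = read_counts(config$counts),
               meta = read_meta(config$meta),
               annotation = read_annotation(config$annotation),
               truth = NULL)
    logf("[data] read %d genes x %d samples", nrow(ds$counts), ncol(ds$counts))
  }
  ds$meta <- ds$meta[match(colnames(ds$counts), ds$meta$sample_id), ]
  res$dataset <- ds
  frag <- config$mean_fragment_length %||%
    (if (!is.null(config$sim)) config$sim$mean_fragment_length else 200)
  regions <- unique(ds$meta$region)

  covs <- config$covariates
  snp_cols <- intersect(c("snpPC1", "snpPC2", "snpPC3"), names(ds$meta))

  per_region <- function(rg) {
    idx <- ds$meta$region == rg
    list(counts = ds$counts[, idx, drop = FALSE],
         meta = ds$meta[idx, , drop = FALSE])
  }

  # --- normalize ------------------------------------------------------------
  if ("normalize" %in% config$stages) {
    res$norm <- lapply(setNames(regions, regions), function(rg) {
      d <- per_region(rg)
      nm <- normalize_counts(d$counts, d$meta, ds$annotation,
                             mean_fragment_length = frag,
                             cpm_threshold = config$cpm_threshold,
                             group_fraction = config$group_fraction)
      logf("[normalize:%s] %d/%d genes pass the expression filter; TMM reference %s",
           rg, sum(nm$filter$retained), nrow(nm$filter),
           attr(nm$factors, "reference"))
      write_matrix_tsv(nm$tpm, file.path(config$out_dir, paste0("TPM_", rg, ".tsv")))
      write_matrix_tsv(nm$logcpm, file.path(config$out_dir, paste0("logCPM_", rg, ".tsv")))
      readr::write_tsv(nm$factors, file.path(config$out_dir, paste0("factors_", rg, ".tsv")))
      readr::write_tsv(nm$filter, file.path(config$out_dir, paste0("filter_report_", rg, ".tsv")))
      nm
    })
  }

  # resolve covariates once, on the first region's log-CPM
  if (identical(covs, "auto")) {
    cand <- setdiff(names(ds$meta)[vapply(ds$meta, is.numeric, logical(1))],
                    c("age"))
    d <- per_region(regions[1])
    nm <- res$norm[[regions[1]]] %||%
      normalize_counts(d$counts, d$meta, ds$annotation, mean_fragment_length = frag)
    scr <- with_preserved_seed(config$seed + 101L,
                               screen_covariates(nm$logcpm, d$meta, cand))
    covs <- union(scr$covariate[scr$selected], snp_cols)
    logf("[covariates] screened %d candidates; selected: %s",
         length(cand), paste(covs, collapse = ", "))
  }

  # --- differential expression ---------------------------------------------
  if ("de" %in% config$stages) {
    res$de_sex <- lapply(setNames(regions, regions), function(rg) {
      d <- per_region(rg)
      fit <- with_preserved_seed(config$seed + 11L,
        de_analysis(d$counts, d$meta, "sex", covariates = covs,
                    n_sv = config$n_sv, cpm_threshold = config$cpm_threshold,
                    group_fraction = config$group_fraction))
      logf("[de:sex:%s] %d features tested, %d DEGs at FDR < %g",
           rg, nrow(fit$table), sum(fit$table$adj.P.Val < config$fdr_cutoff),
           config$fdr_cutoff)
      readr::write_tsv(fit$table, file.path(config$out_dir,
                                            paste0("de_sex_", rg, ".tsv")))
      fit
    })
    res$de_dx <- lapply(setNames(regions, regions), function(rg) {
      d <- per_region(rg)
      lapply(setNames(c("F", "M"), c("F", "M")), function(sx) {
        fit <- with_preserved_seed(config$seed + 23L,
          de_analysis(d$counts, d$meta, "diagnosis_by_sex", covariates = covs,
                      sex = sx, n_sv = config$n_sv,
                      cpm_threshold = config$cpm_threshold,
                      group_fraction = config$group_fraction))
        logf("[de:dx:%s:%s] %d features tested, %d DEGs at FDR < %g",
             rg, sx, nrow(fit$table),
             sum(fit$table$adj.P.Val < config$fdr_cutoff), config$fdr_cutoff)
        readr::write_tsv(fit$table, file.path(config$out_dir,
                                              paste0("de_dx_", rg, "_", sx, ".tsv")))
        fit
      })
    })
  }

  # --- dosage ---------------------------------------------------------------
  if ("dosage" %in% config$stages && !is.null(res$norm)) {
    res$rxe <- purrr::map_dfr(regions, function(rg) {
      compute_rxe(res$norm[[rg]]$tpm, ds$annotation, meta = per_region(rg)$meta,
                  presence_fraction = config$presence_fraction)
    })
    res$rxe_tests <- rxe_comparisons(res$rxe)
    readr::write_tsv(res$rxe, file.path(config$out_dir, "rxe.tsv"))
    readr::write_tsv(res$rxe_tests, file.path(config$out_dir, "rxe_tests.tsv"))
    logf("[dosage] RXE computed for %d samples; %d group comparisons",
         nrow(res$rxe), nrow(res$rxe_tests))
    if (!is.null(res$de_sex)) {
      res$xci <- purrr::map_dfr(regions, function(rg) {
        dplyr::mutate(xci_enrichment(res$de_sex[[rg]], ds$annotation,
                                     fdr_cutoff = config$fdr_cutoff),
                      region = rg, .before = 1)
      })
      readr::write_tsv(res$xci, file.path(config$out_dir, "xci_enrichment.tsv"))
      logf("[dosage] XCI enrichment: %d tables", nrow(res$xci))
    }
  }

  # --- sex-specific schizophrenia signal ------------------------------------
  if ("sexspec" %in% config$stages && !is.null(res$de_dx)) {
    res$sex_specific <- lapply(setNames(regions, regions), function(rg) {
      d <- per_region(rg)
      nm <- res$norm[[rg]]
      null_built <- build_design(d$meta, design_spec("null_minimal",
                                                     covariates = covs))
      resid <- residualize(nm$logcpm, null_built$design)
      rep_ <- stringent_sex_filter(res$de_dx[[rg]]$F, res$de_dx[[rg]]$M,
                                   resid, d$meta,
                                   fdr_cutoff = config$fdr_cutoff)
      for (side in names(rep_)) {
        logf("[sexspec:%s:%s] stages a/b/c: %d/%d/%d", rg, side,
             attr(rep_[[side]], "n_stage_a"), attr(rep_[[side]], "n_stage_b"),
             attr(rep_[[side]], "n_stage_c"))
        readr::write_tsv(rep_[[side]],
                         file.path(config$out_dir,
                                   paste0("sexspec_", side, "_", rg, ".tsv")))
      }
      rep_
    })
    sub_rg <- config$subsample_region %||% regions[1]
    d <- per_region(sub_rg)
    res$subsample <- subsampling_null(
      d$counts, d$meta, B = config$subsample_B, seed = config$seed + 37L,
      fdr_cutoff = config$fdr_cutoff,
      de_args = list(covariates = covs, sex = "M", n_sv = 0,
                     cpm_threshold = config$cpm_threshold,
                     group_fraction = config$group_fraction)
    )
    readr::write_tsv(tidy(res$subsample),
                     file.path(config$out_dir, "subsample_null.tsv"))
    logf("[sexspec] subsampling null (%s): observed %d vs null median %.0f, two-sided p = %.3g",
         sub_rg, res$subsample$observed, median(res$subsample$counts),
         res$subsample$p_two_sided)
  }

  # --- cross-region replication --------------------------------------------
  if ("concord" %in% config$stages && !is.null(res$de_sex) &&
      length(regions) >= 2) {
    pairs <- utils::combn(regions, 2, simplify = FALSE)
    res$replication <- purrr::map_dfr(pairs, function(pr) {
      dplyr::mutate(replication_stats(res$de_sex[[pr[1]]], res$de_sex[[pr[2]]],
                                      fdr_cutoff = config$fdr_cutoff),
                    region_a = pr[1], region_b = pr[2], .before = 1)
    })
    readr::write_tsv(res$replication, file.path(config$out_dir, "replication.tsv"))
    logf("[concord] %d region pairs compared", length(pairs))
  }

  resolved <- unclass(config)
  resolved$sim <- if (!is.null(config$sim)) unclass(config$sim) else NULL
  resolved$covariates_resolved <- covs
  resolved$derived_seeds <- list(covariate_screen = config$seed + 101L,
                                 de_sex = config$seed + 11L,
                                 de_dx = config$seed + 23L,
                                 subsample = config$seed + 37L)
  yaml::write_yaml(resolved, file.path(config$out_dir, "resolved_config.yaml"))
  logf("[done] artifacts in %s", config$out_dir)
  invisible(res)
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  readr::write_tsv(df, path)
  invisible(path)
}
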