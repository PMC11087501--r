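#' Configuration for the synthetic brain-cohort generator
#'
#' Builds and validates a configuration for [simulate_dataset()]. Defaults
#' emulate a scaled-down multi-region case/control brain cohort: three brain
#' regions with repeated donors, unbalanced sexes, negative-binomial counts
#' with library-size variation, autosomal/X/Y/PAR gene geography, XCI
#' escape/variable/inactive classes with female-biased escape expression,
#' planted sex and sex-specific schizophrenia effects, a male-schizophrenia
#' X-dosage reduction in one region, and a hidden batch factor.
#'
#' @param n_genes number of genes.
#' @param chrom_props named fractions for `autosome`, `X`, `Y`, `PAR`
#'   (PAR genes sit on chromosome X with `par_flag = TRUE`); must sum to 1.
#' @param xci_probs named fractions of non-PAR X genes in the `escape`,
#'   `variable` and `inactive` XCI classes; must sum to 1. Defaults follow the
#'   published XCI catalogue proportions (99 escape / 101 variable /
#'   431 inactive of 631).
#' @param n_per_cell samples per (sex x diagnosis) cell within each region:
#'   a single count or a named vector with names `F_CTL`, `F_SZ`, `M_CTL`,
#'   `M_SZ`. The same donors recur across regions (one sample per donor per
#'   region).
#' @param regions character vector of region labels.
#' @param baseline_mean negative-binomial mean scale (counts) for a typical
#'   gene; per-gene baselines are spread around it on the log2 scale with
#'   standard deviation `baseline_log2_sd`.
#' @param baseline_log2_sd spread of per-gene log2 baselines.
#' @param dispersion NB dispersion phi (variance = mu + phi * mu^2); > 0.
#' @param sex_effect list with `frac` (fraction of autosomal genes that are
#'   sex-biased) and `lfc` (planted |log2 fold change|, random sign,
#'   male-vs-female orientation).
#' @param escape_shift female up-shift (log2) for XCI escape genes; variable
#'   escape genes receive a per-gene shift drawn uniformly on
#'   `[0, escape_shift]`. Male X expression equals the female inactive-gene
#'   baseline (dosage-compensated).
#' @param dx_effect list with `frac` (fraction of autosomal genes carrying a
#'   schizophrenia effect), `lfc` (|log2FC|, random sign), `sex` (character,
#'   which sexes carry it) and `regions` (which regions).
#' @param rxe_effect list with `factor` (multiplies the expression mean of
#'   non-PAR X genes), `sex`, `diagnosis`, `region` naming the group it
#'   applies to. `factor = 1` disables it.
#' @param batch_sd scale of per-gene loadings on a standard-normal hidden
#'   batch factor (0 disables it).
#' @param covariate_names names of the per-sample numeric quality covariates
#'   to draw (independent standard normal); `snpPC1..3` are drawn per donor.
#' @param covariate_loading_sd optional confounding: scale of per-gene
#'   loadings on the first quality covariate (0 = covariates independent of
#'   expression).
#' @param library_size_log_sd standard deviation of the per-sample natural-log
#'   library-size factor; >= 0.
#' @param mean_fragment_length mean sequencing fragment length in bp (used
#'   downstream for effective lengths).
#' @param seed integer seed; a fixed seed makes [simulate_dataset()]
#'   bit-identical across runs.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       chrom_props = c(autosome = 0.92, X = 0.05, Y = 0.01, PAR = 0.02),
                       xci_probs = c(escape = 99, variable = 101, inactive = 431) / 631,
                       n_per_cell = c(F_CTL = 25, F_SZ = 15, M_CTL = 25, M_SZ = 15),
                       regions = c("Caudate", "DLPFC", "Hippocampus"),
                       baseline_mean = 50,
                       baseline_log2_sd = 1.5,
                       dispersion = 0.1,
                       sex_effect = list(frac = 0.02, lfc = 1),
                       escape_shift = 0.4,
                       dx_effect = list(frac = 0.01, lfc = 1, sex = "M", regions = NULL),
                       rxe_effect = list(factor = 0.8, sex = "M", diagnosis = "SZ", region = NULL),
                       batch_sd = 0.2,
                       covariate_names = c("RIN", "MitoRate", "rRNArate",
                                           "TotalAssignedGenes", "OverallMappingRate",
                                           "Mean3Bias"),
                       covariate_loading_sd = 0,
                       library_size_log_sd = 0.2,
                       mean_fragment_length = 200,
                       seed = 1L) {
  if (length(n_per_cell) == 1L) {
    n_per_cell <- setNames(rep(n_per_cell, 4L), c("F_CTL", "F_SZ", "M_CTL", "M_SZ"))
  }
  dx_effect$regions <- dx_effect$regions %||% regions[1]
  rxe_effect$region <- rxe_effect$region %||% regions[length(regions)]
  cfg <- structure(
    list(n_genes = as.integer(n_genes), chrom_props = chrom_props,
         xci_probs = xci_probs, n_per_cell = n_per_cell, regions = regions,
         baseline_mean = baseline_mean, baseline_log2_sd = baseline_log2_sd,
         dispersion = dispersion, sex_effect = sex_effect,
         escape_shift = escape_shift, dx_effect = dx_effect,
         rxe_effect = rxe_effect, batch_sd = batch_sd,
         covariate_names = covariate_names,
         covariate_loading_sd = covariate_loading_sd,
         library_size_log_sd = library_size_log_sd,
         mean_fragment_length = mean_fragment_length, seed = as.integer(seed)),
    class = "sim_config"
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) sd_validation_error("n_genes must be >= 1")
  for (nm in c("chrom_props", "xci_probs")) {
    p <- cfg[[nm]]
    if (any(p < 0 | p > 1)) sd_validation_error(sprintf("%s must lie in [0, 1]", nm))
    if (abs(sum(p) - 1) > 1e-12) sd_validation_error(sprintf("%s must sum to 1", nm))
  }
  if (!all(c("F_CTL", "F_SZ", "M_CTL", "M_SZ") %in% names(cfg$n_per_cell))) {
    sd_validation_error("n_per_cell must name the F_CTL, F_SZ, M_CTL, M_SZ cells")
  }
  if (any(cfg$n_per_cell < 1)) {
    sd_validation_error("every (sex x diagnosis) cell needs at least one sample")
  }
  if (cfg$dispersion <= 0) sd_validation_error("dispersion must be > 0")
  if (cfg$library_size_log_sd < 0) sd_validation_error("library_size_log_sd must be >= 0")
  if (cfg$mean_fragment_length <= 0) sd_validation_error("mean_fragment_length must be > 0")
  if (!is.null(cfg$rxe_effect$factor) && cfg$rxe_effect$factor <= 0) {
    sd_validation_error("rxe_effect$factor must be > 0")
  }
  cfg
}

with_preserved_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Integer split of n into length(p) parts proportional to p (largest-remainder).
prop_split <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    idx <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[idx] <- base[idx] + 1
  }
  as.integer(base)
}

#' Simulate a synthetic multi-region brain RNA-seq dataset
#'
#' Draws gamma-Poisson (negative-binomial) gene counts under the structure
#' described in [sim_config()] and returns the count matrix, sample metadata,
#' gene annotation and the full ground truth of every planted effect.
#'
#' Expression model, on the log2 scale of the NB mean: per-gene baseline +
#' per-sample library factor + hidden-batch term + planted sex, diagnosis and
#' X-dosage effects. Females do not express chromosome-Y genes; males express
#' non-PAR X genes at the female inactive-gene baseline (dosage-compensated),
#' while female escape genes are shifted up by `escape_shift`.
#'
#' @param config a [sim_config()].
#' @return A list of class `sexdim_dataset` with elements
#'   \describe{
#'     \item{counts}{integer gene x sample matrix with dimnames.}
#'     \item{meta}{tibble: `sample_id`, `donor_id`, `sex` (F/M),
#'       `diagnosis` (CTL/SZ), `region`, `age`, quality covariates, snpPC1..3.}
#'     \item{annotation}{tibble: `gene_id`, `chromosome`, `gene_length`,
#'       `par_flag`, `xci_status`.}
#'     \item{truth}{list: `gene` (per-gene true male-vs-female log2FC and
#'       sex-biased flag), `dx` (planted diagnosis log2FCs by sex and region),
#'       `rxe` (true log2 X-dosage shift per group), `hidden` (per-sample
#'       hidden-factor value), and the resolved `config`.}
#'   }
#' @export
#' @examples
#' ds <- simulate_dataset(sim_config(n_genes = 200, n_per_cell = 4, seed = 7))
#' dim(ds$counts)
simulate_dataset <- function(config) {
  config <- validate_sim_config(config)
  with_preserved_seed(config$seed, {
    ann <- simulate_annotation(config)
    meta_h <- simulate_meta(config)
    meta <- meta_h$meta
    hidden <- meta_h$hidden

    n_g <- config$n_genes
    n_s <- nrow(meta)
    male <- meta$sex == "M"
    female <- !male

    baseline <- rnorm(n_g, mean = log2(config$baseline_mean), sd = config$baseline_log2_sd)
    lib_log2 <- rnorm(n_s, sd = config$library_size_log_sd) / log(2)

    log2mu <- matrix(baseline, n_g, n_s) +
      matrix(lib_log2, n_g, n_s, byrow = TRUE)

    if (config$batch_sd > 0) {
      loadings <- rnorm(n_g, sd = config$batch_sd)
      log2mu <- log2mu + tcrossprod(loadings, hidden)
    }
    if (config$covariate_loading_sd > 0 && length(config$covariate_names) > 0) {
      cov1 <- meta[[config$covariate_names[1]]]
      log2mu <- log2mu + tcrossprod(rnorm(n_g, sd = config$covariate_loading_sd), cov1)
    }

    # Planted autosomal sex effects (male-vs-female orientation).
    auto_idx <- which(ann$chromosome != "X" & ann$chromosome != "Y")
    sex_lfc <- rep(0, n_g)
    n_sex <- round(config$sex_effect$frac * length(auto_idx))
    if (n_sex > 0) {
      chosen <- sample(auto_idx, n_sex)
      sex_lfc[chosen] <- config$sex_effect$lfc * sample(c(-1, 1), n_sex, replace = TRUE)
    }

    # Allosome rules: escape genes up in females; variable escape genes get a
    # per-gene shift in [0, escape_shift]; Y genes silent in females.
    esc <- which(ann$xci_status == "escape")
    varesc <- which(ann$xci_status == "variable")
    shift <- rep(0, n_g)
    shift[esc] <- config$escape_shift
    if (length(varesc) > 0) shift[varesc] <- runif(length(varesc), 0, config$escape_shift)
    sex_lfc <- sex_lfc - shift   # female up-shift = negative male/female log2FC

    log2mu[, male] <- log2mu[, male] + sex_lfc

    y_idx <- which(ann$chromosome == "Y")
    sex_biased <- sex_lfc != 0 | seq_len(n_g) %in% y_idx

    # Sex-specific diagnosis effects on autosomal genes.
    dx <- config$dx_effect
    dx_truth <- tibble(gene_id = character(), sex = character(),
                       region = character(), lfc = double())
    n_dx <- round(dx$frac * length(auto_idx))
    if (n_dx > 0 && length(dx$sex) > 0) {
      dx_genes <- sample(auto_idx, n_dx)
      dx_lfc <- dx$lfc * sample(c(-1, 1), n_dx, replace = TRUE)
      for (sx in dx$sex) {
        for (rg in dx$regions) {
          cols <- which(meta$sex == sx & meta$diagnosis == "SZ" & meta$region == rg)
          if (length(cols) > 0) log2mu[dx_genes, cols] <- log2mu[dx_genes, cols] + dx_lfc
          dx_truth <- dplyr::bind_rows(
            dx_truth,
            tibble(gene_id = ann$gene_id[dx_genes], sex = sx, region = rg, lfc = dx_lfc)
          )
        }
      }
    }

    # X-dosage shift for the designated group (non-PAR X genes).
    rxe <- config$rxe_effect
    x_idx <- which(ann$chromosome == "X" & !ann$par_flag)
    rxe_truth <- tibble(sex = character(), diagnosis = character(),
                        region = character(), log2_factor = double())
    if (!is.null(rxe$factor) && rxe$factor != 1) {
      cols <- which(meta$sex == rxe$sex & meta$diagnosis == rxe$diagnosis &
                      meta$region == rxe$region)
      if (length(cols) > 0) {
        log2mu[x_idx, cols] <- log2mu[x_idx, cols] + log2(rxe$factor)
        rxe_truth <- tibble(sex = rxe$sex, diagnosis = rxe$diagnosis,
                            region = rxe$region, log2_factor = log2(rxe$factor))
      }
    }

    mu <- 2^log2mu
    if (length(y_idx) > 0) mu[y_idx, female] <- 0

    counts <- matrix(
      rnbinom(n_g * n_s, mu = as.vector(mu), size = 1 / config$dispersion),
      n_g, n_s, dimnames = list(ann$gene_id, meta$sample_id)
    )
    storage.mode(counts) <- "integer"

    gene_truth <- tibble(
      gene_id = ann$gene_id,
      sex_lfc = ifelse(seq_len(n_g) %in% y_idx, NA_real_, sex_lfc),
      sex_biased = sex_biased
    )

    structure(
      list(counts = counts, meta = meta, annotation = ann,
           truth = list(gene = gene_truth, dx = dx_truth, rxe = rxe_truth,
                        hidden = tibble(sample_id = meta$sample_id,
                                        hidden_factor = hidden),
                        config = config)),
      class = "sexdim_dataset"
    )
  })
}

simulate_annotation <- function(config) {
  n <- config$n_genes
  n_by_class <- prop_split(n, config$chrom_props[c("autosome", "X", "Y", "PAR")])
  class_vec <- rep(c("autosome", "X", "Y", "PAR"), n_by_class)
  chromosome <- character(n)
  chromosome[class_vec == "autosome"] <-
    as.character(sample(1:22, n_by_class[1], replace = TRUE))
  chromosome[class_vec %in% c("X", "PAR")] <- "X"
  chromosome[class_vec == "Y"] <- "Y"
  par_flag <- class_vec == "PAR"
  xci <- rep("not_applicable", n)
  nx <- n_by_class[2]
  if (nx > 0) {
    k <- prop_split(nx, config$xci_probs[c("escape", "variable", "inactive")])
    xci[class_vec == "X"] <- sample(rep(c("escape", "variable", "inactive"), k))
  }
  xci[par_flag] <- "escape"  # PAR genes escape XCI by construction
  tibble(
    gene_id = sprintf("G%05d", seq_len(n)),
    chromosome = chromosome,
    gene_length = pmax(200L, as.integer(round(rlnorm(n, log(1500), 0.7)))),
    par_flag = par_flag,
    xci_status = xci
  )
}

simulate_meta <- function(config) {
  cells <- tidyr::expand_grid(
    sex = c("F", "M"), diagnosis = c("CTL", "SZ")
  )
  donors <- purrr::pmap_dfr(cells, function(sex, diagnosis) {
    n <- config$n_per_cell[[paste(sex, diagnosis, sep = "_")]]
    tibble(
      donor_id = sprintf("D_%s_%s_%03d", sex, diagnosis, seq_len(n)),
      sex = sex, diagnosis = diagnosis,
      age = runif(n, 17, 80),
      snpPC1 = rnorm(n), snpPC2 = rnorm(n), snpPC3 = rnorm(n)
    )
  })
  meta <- tidyr::expand_grid(region = config$regions, donors) |>
    dplyr::mutate(sample_id = paste(.data$region, .data$donor_id, sep = "_"),
                  .before = 1)
  for (nm in config$covariate_names) meta[[nm]] <- rnorm(nrow(meta))
  hidden <- rnorm(nrow(meta))
  list(meta = dplyr::relocate(meta, "sample_id", "donor_id", "sex",
                              "diagnosis", "region", "age"),
       hidden = hidden)
}

#' @export
print.sexdim_dataset <- function(x, ...) {
  cat(sprintf("<sexdim_dataset> %d genes x %d samples, %d region(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$meta$region))))
  cat(sprintf("  planted: %d sex-biased genes, %d diagnosis effect rows, %d dosage shift group(s)\n",
              sum(x$truth$gene$sex_biased), nrow(x$truth$dx), nrow(x$truth$rxe)))
  invisible(x)
}
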