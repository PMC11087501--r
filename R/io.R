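# Reading and writing the pipeline's tabular artifacts. TSV is the canonical
# interchange; counts may also travel as MatrixMarket (.mtx) with row/column
# name sidecars.

#' Write / read a count matrix
#'
#' @param counts integer gene x sample matrix with dimnames.
#' @param path output path; `format = "mtx"` writes `path` plus
#'   `<path>.rownames` / `<path>.colnames` sidecars.
#' @param format `"tsv"` (gene rows, sample columns, `gene_id` first column)
#'   or `"mtx"` (MatrixMarket).
#' @return `write_counts` returns `path` invisibly; `read_counts` returns the
#'   integer matrix.
#' @export
write_counts <- function(counts, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  check_count_matrix(counts)
  if (format == "tsv") {
    df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
    readr::write_tsv(df, path)
  } else {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    writeLines(rownames(counts), paste0(path, ".rownames"))
    writeLines(colnames(counts), paste0(path, ".colnames"))
  }
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(path))
    rn <- paste0(path, ".rownames")
    cn <- paste0(path, ".colnames")
    if (!file.exists(rn) || !file.exists(cn)) {
      sd_validation_error(sprintf("missing name sidecars for %s (.rownames/.colnames)", path))
    }
    dimnames(m) <- list(readLines(rn), readLines(cn))
  } else {
    df <- utils::read.delim(path, check.names = FALSE)
    if (names(df)[1] != "gene_id") {
      sd_validation_error(sprintf("%s: first column must be 'gene_id', found '%s'",
                                  path, names(df)[1]))
    }
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$gene_id
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))
    if (length(bad) > 0) {
      sd_validation_error(sprintf("%s: non-numeric count column '%s'",
                                  path, names(df[-1])[bad[1]]))
    }
  }
  storage.mode(m) <- "integer"
  check_count_matrix(m)
  m
}

#' Read sample metadata / gene annotation tables
#'
#' TSV with mandatory headers. Metadata requires `sample_id`, `donor_id`,
#' `sex` (F/M), `diagnosis` (CTL/SZ), `region`, `age`; annotation requires
#' `gene_id`, `chromosome`, `gene_length`, `par_flag`, `xci_status`.
#'
#' @param path TSV path.
#' @return a tibble.
#' @export
read_meta <- function(path) {
  df <- as_tibble(utils::read.delim(path, check.names = FALSE))
  check_columns(df, c("sample_id", "donor_id", "sex", "diagnosis", "region", "age"),
                what = sprintf("metadata file %s", path))
  bad_sex <- setdiff(unique(df$sex), c("F", "M"))
  if (length(bad_sex) > 0) {
    sd_validation_error(sprintf("%s: sex must be F or M, found: %s", path,
                                paste(bad_sex, collapse = ", ")))
  }
  bad_dx <- setdiff(unique(df$diagnosis), c("CTL", "SZ"))
  if (length(bad_dx) > 0) {
    sd_validation_error(sprintf("%s: diagnosis must be CTL or SZ, found: %s", path,
                                paste(bad_dx, collapse = ", ")))
  }
  df
}

#' @rdname read_meta
#' @export
read_annotation <- function(path) {
  df <- as_tibble(utils::read.delim(path, check.names = FALSE))
  check_columns(df, c("gene_id", "chromosome", "gene_length", "par_flag", "xci_status"),
                what = sprintf("annotation file %s", path))
  df$par_flag <- as.logical(df$par_flag)
  if (any(df$gene_length < 1)) sd_validation_error(sprintf("%s: gene_length must be >= 1", path))
  df
}

#' Write / read a full synthetic dataset directory
#'
#' Serializes the four objects produced by [simulate_dataset()] (counts,
#' metadata, annotation, ground truth) plus the resolved generator
#' configuration into a directory of plain-text files, and reads them back
#' field-for-field.
#'
#' @param dataset a `sexdim_dataset`.
#' @param dir directory (created if needed).
#' @param counts_format `"tsv"` or `"mtx"` for the count matrix.
#' @return `write_dataset` returns `dir` invisibly; `read_dataset` returns a
#'   `sexdim_dataset`.
#' @export
write_dataset <- function(dataset, dir, counts_format = c("tsv", "mtx")) {
  counts_format <- match.arg(counts_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fn <- if (counts_format == "tsv") "counts.tsv" else "counts.mtx"
  write_counts(dataset$counts, file.path(dir, fn), format = counts_format)
  readr::write_tsv(dataset$meta, file.path(dir, "meta.tsv"))
  readr::write_tsv(dataset$annotation, file.path(dir, "annotation.tsv"))
  readr::write_tsv(dataset$truth$gene, file.path(dir, "truth_gene.tsv"))
  readr::write_tsv(dataset$truth$dx, file.path(dir, "truth_dx.tsv"))
  readr::write_tsv(dataset$truth$rxe, file.path(dir, "truth_rxe.tsv"))
  readr::write_tsv(dataset$truth$hidden, file.path(dir, "truth_hidden.tsv"))
  cfg <- unclass(dataset$truth$config)
  # yaml drops names on atomic vectors; store named vectors as maps
  for (nm in c("chrom_props", "xci_probs", "n_per_cell")) {
    cfg[[nm]] <- as.list(cfg[[nm]])
  }
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  counts_path <- if (file.exists(file.path(dir, "counts.tsv"))) {
    file.path(dir, "counts.tsv")
  } else if (file.exists(file.path(dir, "counts.mtx"))) {
    file.path(dir, "counts.mtx")
  } else {
    sd_validation_error(sprintf("no counts.tsv or counts.mtx under %s", dir))
  }
  counts <- read_counts(counts_path)
  meta <- read_meta(file.path(dir, "meta.tsv"))
  ann <- read_annotation(file.path(dir, "annotation.tsv"))
  read_tsv_tbl <- function(f, col_types) {
    as_tibble(utils::read.delim(file.path(dir, f), check.names = FALSE,
                                colClasses = col_types))
  }
  truth <- list(
    gene = read_tsv_tbl("truth_gene.tsv",
                        c(gene_id = "character", sex_lfc = "numeric",
                          sex_biased = "logical")),
    dx = read_tsv_tbl("truth_dx.tsv",
                      c(gene_id = "character", sex = "character",
                        region = "character", lfc = "numeric")),
    rxe = read_tsv_tbl("truth_rxe.tsv",
                       c(sex = "character", diagnosis = "character",
                         region = "character", log2_factor = "numeric")),
    hidden = read_tsv_tbl("truth_hidden.tsv",
                          c(sample_id = "character", hidden_factor = "numeric"))
  )
  cfg_path <- file.path(dir, "config.yaml")
  if (file.exists(cfg_path)) {
    raw <- yaml::read_yaml(cfg_path)
    truth$config <- sim_config(
      n_genes = raw$n_genes,
      chrom_props = unlist(raw$chrom_props),
      xci_probs = unlist(raw$xci_probs),
      n_per_cell = unlist(raw$n_per_cell),
      regions = unlist(raw$regions),
      baseline_mean = raw$baseline_mean,
      baseline_log2_sd = raw$baseline_log2_sd,
      dispersion = raw$dispersion,
      sex_effect = raw$sex_effect,
      escape_shift = raw$escape_shift,
      dx_effect = raw$dx_effect,
      rxe_effect = raw$rxe_effect,
      batch_sd = raw$batch_sd,
      covariate_names = unlist(raw$covariate_names),
      covariate_loading_sd = raw$covariate_loading_sd,
      library_size_log_sd = raw$library_size_log_sd,
      mean_fragment_length = raw$mean_fragment_length,
      seed = raw$seed
    )
  }
  structure(list(counts = counts, meta = meta, annotation = ann, truth = truth),
            class = "sexdim_dataset")
}
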