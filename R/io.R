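#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample identifiers, a first column of gene
#' identifiers (any header) and a numeric body. Duplicate gene identifiers,
#' missing values and non-numeric cells are rejected with errors naming the
#' offending gene and sample.
#'
#' @param path file path.
#' @return A numeric genes x samples matrix with dimnames.
#' @seealso [write_expression_tsv()]
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("expression TSV needs a gene column and >= 1 sample")
  genes <- df[[1]]
  if (anyDuplicated(genes)) {
    stop("duplicated gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad)) {
    first <- bad[1, ]
    stop(sprintf("non-numeric or missing value at gene '%s', sample '%s'",
                 genes[first[1]], samples[first[2]]))
  }
  dimnames(num) <- list(genes, samples)
  num
}

#' Read and validate a pipeline run configuration
#'
#' Configurations are YAML mappings. Recognized keys: `n_genes`, `n_tfs`,
#' `mean_out_degree`, `noise_sd`, `seed`, `designs`, `n_samples`, `n_wt`,
#' `n_mut`, `fnr`, `fpr`, `fdr_level`, `alpha_level`, `approaches`,
#' `n_perm`, `out_dir`. Unknown keys are rejected so typos fail loudly; all
#' randomness is controlled by the single `seed`.
#'
#' @param path YAML file path, or `NULL` for defaults.
#' @param overrides named list merged over the file values (used by the
#'   command-line interface).
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  defaults <- list(
    n_genes = 30L, n_tfs = 5L, mean_out_degree = 3, noise_sd = 0.3,
    seed = 1L,
    designs = c("replicates", "environment_time", "compendium", "perturbation"),
    n_samples = 60L, n_wt = 12L, n_mut = 12L,
    fnr = 0.1, fpr = 0.002,
    fdr_level = 0.05, alpha_level = 0.05,
    approaches = names(benchmark_approaches()),
    n_perm = 200L, out_dir = "grnbench_out")
  cfg <- defaults
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown)) {
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(overrides)] <- overrides
  bad <- setdiff(cfg$approaches, names(benchmark_approaches()))
  if (length(bad)) stop("unknown approach(es): ", paste(bad, collapse = ", "))
  bad <- setdiff(cfg$designs,
                 c("replicates", "environment_time", "compendium", "perturbation"))
  if (length(bad)) stop("unknown design(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}
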