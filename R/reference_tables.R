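#' Published benchmark accuracy tables for yeast network inference
#'
#' The package ships, as plain-text fixtures, the published per-cell
#' accuracy values of the eighteen benchmark approaches applied to thirteen
#' yeast microarray datasets, evaluated against the most conservative
#' gold-standard network: sensitivity/specificity pairs and PPV/NPV pairs,
#' with the reported significance flags. Together with
#' [combined_distance()] and [metrics_table()] these reproduce the study's
#' combined-metric summary tables (method, dataset and data-type averages)
#' without any external download.
#'
#' @param pair which table to load: `"sens_spec"` or `"ppv_npv"`.
#' @return A long-format data.frame with columns `approach`, `dataset`,
#'   `data_type`, the two metric columns (`sensitivity`/`specificity` or
#'   `ppv`/`npv`), and logical `significant`; 18 x 13 = 234 rows.
#' @examples
#' tab <- reference_accuracy("sens_spec")
#' head(tab)
#' @export
reference_accuracy <- function(pair = c("sens_spec", "ppv_npv")) {
  pair <- match.arg(pair)
  path <- system.file("extdata",
                      sprintf("yeast_accuracy_%s.tsv", pair),
                      package = "grnbench", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE)
  df$significant <- as.logical(df$significant)
  df
}
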