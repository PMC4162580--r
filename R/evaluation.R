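#' Confusion counts of an inferred network against a gold standard
#'
#' The candidate universe defaults to every ordered (TF, gene) pair with the
#' TF among the gold standard's regulators, the gene in its universe and
#' TF != gene; an alternative universe can be injected as a data.frame of
#' (`regulator`, `target`) pairs. An inferred unordered pair `{a, b}` counts
#' as predicting `a -> b` when `a` is a candidate regulator (and `b -> a`
#' too when both are), and inferred pairs outside the universe are ignored,
#' since the inference methods are undirected and genome-wide while the
#' gold standard covers only assayed TFs.
#'
#' @param inferred an `undirected_network`.
#' @param gold a `directed_edge_set` (the gold standard).
#' @param universe_spec `NULL` for the default universe, or a data.frame
#'   with columns `regulator`, `target` enumerating candidate pairs.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`, `universe_size`, `universe_spec`.
#' @examples
#' gold <- directed_edge_set(data.frame(regulator = "A", target = "B", sign = "+"),
#'                           regulators = "A", universe = c("A", "B", "C"))
#' inf <- undirected_network(data.frame(gene_a = c("A", "A"), gene_b = c("B", "C")))
#' confusion_counts(inf, gold)
#' @export
confusion_counts <- function(inferred, gold, universe_spec = NULL) {
  stopifnot(inherits(inferred, "undirected_network"),
            inherits(gold, "directed_edge_set"))
  if (is.null(universe_spec)) {
    regs <- gold$regulators
    cand_reg <- rep(regs, each = length(gold$universe))
    cand_tgt <- rep(gold$universe, times = length(regs))
    ok <- cand_reg != cand_tgt
    cand_reg <- cand_reg[ok]; cand_tgt <- cand_tgt[ok]
    spec_desc <- "gold regulators x gold universe"
  } else {
    universe_spec <- as.data.frame(universe_spec, stringsAsFactors = FALSE)
    stopifnot(all(c("regulator", "target") %in% names(universe_spec)))
    cand_reg <- as.character(universe_spec$regulator)
    cand_tgt <- as.character(universe_spec$target)
    spec_desc <- "user-supplied candidate pairs"
  }
  if (length(cand_reg) == 0L) stop("empty candidate universe")
  cand <- edge_key(cand_reg, cand_tgt)
  if (anyDuplicated(cand)) stop("duplicate candidate pairs in universe")
  gold_keys <- edge_key(gold$edges$regulator, gold$edges$target)
  gold_keys <- gold_keys[gold_keys %in% cand]
  pred <- unique(c(edge_key(inferred$pairs$gene_a, inferred$pairs$gene_b),
                   edge_key(inferred$pairs$gene_b, inferred$pairs$gene_a)))
  pred <- pred[pred %in% cand]
  tp <- sum(pred %in% gold_keys)
  fp <- length(pred) - tp
  fn <- length(gold_keys) - tp
  tn <- length(cand) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 universe_size = length(cand), universe_spec = spec_desc),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion: tp=%d fp=%d tn=%d fn=%d (universe %d: %s)\n",
              x$tp, x$fp, x$tn, x$fn, x$universe_size, x$universe_spec))
  invisible(x)
}

#' Core and combined accuracy metrics from confusion counts
#'
#' Computes sensitivity (recall) `tp/(tp+fn)`, specificity `tn/(tn+fp)`,
#' positive predictive value (precision) `tp/(tp+fp)` and negative
#' predictive value `tn/(tn+fn)`, plus the three combined Euclidean
#' distances from the ideal point: `d_ss` (sens/spec), `d_pn` (PPV/NPV) and
#' `d_rp` (recall/precision). A 0/0 ratio is reported as `NA` and listed in
#' the `undefined` field, never silently imputed; a combined distance is
#' `NA` whenever a constituent is.
#'
#' @param counts a `confusion_counts` object.
#' @return An object of class `metric_set` with fields `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `d_ss`, `d_pn`, `d_rp`, `undefined`
#'   (character vector of undefined core metrics).
#' @examples
#' core_metrics(structure(list(tp = 5, fp = 5, tn = 85, fn = 5,
#'   universe_size = 100, universe_spec = "demo"), class = "confusion_counts"))
#' @export
core_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- ratio(counts$tp, counts$tp + counts$fn)
  spec <- ratio(counts$tn, counts$tn + counts$fp)
  ppv <- ratio(counts$tp, counts$tp + counts$fp)
  npv <- ratio(counts$tn, counts$tn + counts$fn)
  vals <- c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv)
  structure(list(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
                 d_ss = combined_distance(sens, spec),
                 d_pn = combined_distance(ppv, npv),
                 d_rp = combined_distance(sens, ppv),
                 undefined = names(vals)[is.na(vals)]),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "NA", sprintf("%.3f", v))
  cat(sprintf("sens=%s spec=%s ppv=%s npv=%s | d_ss=%s d_pn=%s d_rp=%s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv), fmt(x$npv),
              fmt(x$d_ss), fmt(x$d_pn), fmt(x$d_rp)))
  if (length(x$undefined)) cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Combined Euclidean distance from the ideal metric pair
#'
#' `sqrt((1 - m1)^2 + (1 - m2)^2)` for an antagonistic pair of core metrics
#' (sensitivity/specificity, PPV/NPV or recall/precision): 0 is the ideal
#' algorithm, `sqrt(2)` the worst possible. Vectorized; `NA` inputs give
#' `NA`.
#'
#' @param m1,m2 metric values in \[0, 1\].
#' @return Numeric distance(s) in \[0, sqrt(2)\].
#' @examples
#' combined_distance(0.52, 0.58)  # 0.64 to two decimals
#' @export
combined_distance <- function(m1, m2) {
  bad <- !is.na(m1) & !is.na(m2) & (m1 < 0 | m1 > 1 | m2 < 0 | m2 > 1)
  if (any(bad)) stop("metric values must lie in [0, 1]")
  sqrt((1 - m1)^2 + (1 - m2)^2)
}

#' Hypergeometric significance of a reconstructed network
#'
#' Upper-tail hypergeometric probability of drawing at least `tp` gold
#' edges when `tp + fp` candidate pairs are selected at random from a
#' universe of `universe_size` pairs containing `tp + fn` gold edges.
#'
#' @param counts a `confusion_counts` object.
#' @param log.p return the natural-log tail probability.
#' @return The tail probability `P[X >= tp]`.
#' @export
network_significance <- function(counts, log.p = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  lp <- phyper(counts$tp - 1, counts$tp + counts$fn,
               counts$universe_size - (counts$tp + counts$fn),
               counts$tp + counts$fp, lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

#' Benjamini-Hochberg adjustment over a grid of network p-values
#'
#' Applies BH across all applications of network reverse-engineering in a
#' benchmark run (approaches x datasets x gold standards) and flags cells
#' surviving at `alpha`.
#'
#' @param p numeric vector of per-network hypergeometric p-values.
#' @param alpha significance level after adjustment (default 0.05).
#' @return A list with `p_adjusted` and logical `significant`.
#' @examples
#' batch_adjust(c(0.001, 0.02, 0.9))
#' @export
batch_adjust <- function(p, alpha = 0.05) {
  adj <- p.adjust(p, method = "BH")
  list(p_adjusted = adj, significant = adj <= alpha)
}

#' Pareto-frontier ROC over sensitivity/specificity pairs
#'
#' Maps each reconstruction result to ROC space (`fpr = 1 - specificity`,
#' `tpr = sensitivity`), retains the Pareto-optimal points (those not
#' dominated by another point with lower-or-equal fpr and
#' higher-or-equal tpr), anchors the staircase at (0, 0) and (1, 1), and
#' integrates the area under the frontier by the trapezoid rule. When
#' effective positive/negative counts are supplied, the p-value for
#' AUROC > 0.5 is computed with the Hanley-McNeil normal approximation.
#'
#' @param points data.frame with columns `sensitivity` and `specificity`
#'   (one row per reconstruction result; >= 1 row).
#' @param n_pos,n_neg effective numbers of positive and negative instances
#'   behind the curve (optional; without them no p-value is computed).
#' @return An object of class `pareto_roc`: `frontier` (data.frame `fpr`,
#'   `tpr` including anchors), `auroc`, `p_value`.
#' @examples
#' pareto_roc(data.frame(sensitivity = c(0.5, 0.4), specificity = c(0.6, 0.4)))
#' @export
pareto_roc <- function(points, n_pos = NULL, n_neg = NULL) {
  points <- as.data.frame(points)
  stopifnot(nrow(points) >= 1,
            all(c("sensitivity", "specificity") %in% names(points)))
  fpr <- 1 - points$specificity
  tpr <- points$sensitivity
  keep <- vapply(seq_along(fpr), function(i) {
    dominated <- fpr <= fpr[i] & tpr >= tpr[i] &
      (fpr < fpr[i] | tpr > tpr[i])
    !any(dominated)
  }, logical(1))
  fr <- unique(data.frame(fpr = c(0, fpr[keep], 1), tpr = c(0, tpr[keep], 1)))
  fr <- fr[order(fr$fpr, fr$tpr), , drop = FALSE]
  rownames(fr) <- NULL
  auroc <- sum(diff(fr$fpr) * (head(fr$tpr, -1) + fr$tpr[-1]) / 2)
  p_value <- NA_real_
  if (!is.null(n_pos) && !is.null(n_neg)) {
    p_value <- hanley_mcneil_p(auroc, n_pos, n_neg)
  }
  structure(list(frontier = fr, auroc = auroc, p_value = p_value),
            class = "pareto_roc")
}

# One-sided p for AUROC > 0.5 under the Hanley-McNeil (1982) standard
# error of the area under a ROC curve.
hanley_mcneil_p <- function(auroc, n_pos, n_neg) {
  a <- auroc
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  se2 <- (a * (1 - a) + (n_pos - 1) * (q1 - a^2) + (n_neg - 1) * (q2 - a^2)) /
    (n_pos * n_neg)
  if (se2 <= 0) return(if (a > 0.5) 0 else 1)
  pnorm((a - 0.5) / sqrt(se2), lower.tail = FALSE)
}

#' @export
print.pareto_roc <- function(x, ...) {
  cat(sprintf("Pareto-frontier ROC: %d frontier points, AUROC = %.3f",
              nrow(x$frontier), x$auroc))
  if (!is.na(x$p_value)) cat(sprintf(" (p = %.3g)", x$p_value))
  cat("\n")
  invisible(x)
}

#' Summarize an approach x dataset grid of metric pairs
#'
#' Takes a complete long-format grid (one row per approach and dataset,
#' with the two core metric values and optionally a data type and a
#' significance flag) and produces the standard benchmark tables: a wide
#' table of paired values (`"m1|m2"`, two decimals, `*`-marked when
#' significant), a wide table of combined Euclidean distances (two
#' decimals), per-approach means over datasets (method averages),
#' per-dataset means over approaches (dataset averages) and per-data-type
#' means over all member cells. Averages are computed on the unrounded
#' per-cell distances and rounded to two decimals for display.
#'
#' @param grid data.frame with columns `approach`, `dataset`, the two
#'   columns named in `pair`, and optionally `data_type`, `significant`.
#' @param pair length-2 character: names of the metric columns, e.g.
#'   `c("sensitivity", "specificity")`.
#' @return A list of class `metrics_table`: `values`, `distances` (wide
#'   data.frames), `method_avg`, `dataset_avg`, `datatype_avg` (named
#'   numeric vectors, two decimals).
#' @examples
#' grid <- data.frame(approach = "A", dataset = c("d1", "d2"),
#'                    sensitivity = c(0.5, 0.6), specificity = c(0.9, 0.8))
#' metrics_table(grid, c("sensitivity", "specificity"))$method_avg
#' @export
metrics_table <- function(grid, pair) {
  grid <- as.data.frame(grid, stringsAsFactors = FALSE)
  stopifnot(length(pair) == 2,
            all(c("approach", "dataset", pair) %in% names(grid)))
  approaches <- unique(grid$approach)
  datasets <- unique(grid$dataset)
  full <- paste(rep(approaches, each = length(datasets)),
                rep(datasets, times = length(approaches)))
  got <- paste(grid$approach, grid$dataset)
  if (anyDuplicated(got)) stop("duplicate (approach, dataset) cells")
  missing <- setdiff(full, got)
  if (length(missing)) {
    stop("incomplete grid; missing cells: ", paste(missing, collapse = "; "))
  }
  m1 <- grid[[pair[1]]]
  m2 <- grid[[pair[2]]]
  grid$distance <- combined_distance(m1, m2)
  sig <- if (!is.null(grid$significant)) grid$significant else rep(FALSE, nrow(grid))
  grid$cell <- sprintf("%.2f|%.2f%s", m1, m2, ifelse(sig, "*", ""))
  wide <- function(col, fmt = identity) {
    out <- data.frame(approach = approaches, stringsAsFactors = FALSE)
    for (d in datasets) {
      v <- grid[[col]][match(paste(approaches, d), got)]
      out[[d]] <- fmt(v)
    }
    out
  }
  avg_by <- function(key) {
    v <- tapply(grid$distance, grid[[key]], mean)
    round(v[unique(grid[[key]])], 2)
  }
  structure(list(
    values = wide("cell"),
    distances = wide("distance", fmt = function(v) round(v, 2)),
    method_avg = avg_by("approach"),
    dataset_avg = avg_by("dataset"),
    datatype_avg = if (!is.null(grid$data_type)) avg_by("data_type") else NULL),
    class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat("Method averages (combined distance):\n")
  print(x$method_avg)
  cat("Dataset averages:\n")
  print(x$dataset_avg)
  if (!is.null(x$datatype_avg)) {
    cat("Data-type averages:\n")
    print(x$datatype_avg)
  }
  invisible(x)
}
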