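#' Accuracy of reconstructing a single TF's sub-network
#'
#' Restricts the confusion universe to the candidate pairs with `tf` as
#' regulator (the TF's sub-network of direct regulatory interactions) and
#' computes core and combined metrics on that restriction.
#'
#' @param inferred an `undirected_network`.
#' @param gold a `directed_edge_set`; `tf` must be among its regulators.
#' @param tf transcription-factor identifier.
#' @return A `metric_set` (0/0 ratios flagged as undefined).
#' @examples
#' gold <- directed_edge_set(data.frame(regulator = c("A", "A"), target = c("B", "C"), sign = "+"),
#'                           regulators = "A", universe = c("A", "B", "C", "D"))
#' inf <- undirected_network(data.frame(gene_a = "A", gene_b = "B"), universe = gold$universe)
#' tf_subnetwork_accuracy(inf, gold, "A")
#' @export
tf_subnetwork_accuracy <- function(inferred, gold, tf) {
  if (!tf %in% gold$regulators) stop("tf not among gold-standard regulators: ", tf)
  targets <- setdiff(gold$universe, tf)
  if (length(targets) == 0L) stop("tf has an empty candidate row")
  core_metrics(confusion_counts(
    inferred, gold,
    universe_spec = data.frame(regulator = tf, target = targets,
                               stringsAsFactors = FALSE)))
}

#' Per-TF connectivity and sub-network accuracy
#'
#' Vectorized per-TF report used by the correlation analysis: for every
#' gold-standard regulator, its connectivity in the gold and the inferred
#' network, restricted confusion counts over its candidate row, and the
#' three combined distance metrics. Equivalent to calling
#' [tf_subnetwork_accuracy()] and [connectivity()] TF by TF.
#'
#' @param inferred an `undirected_network` over (a subset of) the gold
#'   universe.
#' @param gold a `directed_edge_set`.
#' @return A data.frame with one row per gold regulator: `tf`,
#'   `connectivity_gold`, `connectivity_inferred`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `d_ss`, `d_pn`, `d_rp`
#'   (0/0 ratios are `NA`).
#' @export
tf_subnet_metrics <- function(inferred, gold) {
  tfs <- gold$regulators
  nu <- length(gold$universe)
  gold_keys <- edge_key(gold$edges$regulator, gold$edges$target)
  pa <- inferred$pairs$gene_a
  pb <- inferred$pairs$gene_b
  in_u <- pa %in% gold$universe & pb %in% gold$universe
  pa <- pa[in_u]; pb <- pb[in_u]
  cnt <- function(x) as.integer(table(factor(x, levels = tfs)))
  pred <- cnt(c(pa, pb))                       # pairs incident to each TF
  hit_ab <- edge_key(pa, pb) %in% gold_keys
  hit_ba <- edge_key(pb, pa) %in% gold_keys
  tp <- cnt(c(pa[hit_ab], pb[hit_ba]))
  gold_out <- cnt(gold$edges$regulator)
  fp <- pred - tp
  fn <- gold_out - tp
  tn <- (nu - 1L) - tp - fp - fn
  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  sens <- ratio(tp, tp + fn); spec <- ratio(tn, tn + fp)
  ppv <- ratio(tp, tp + fp); npv <- ratio(tn, tn + fn)
  data.frame(tf = tfs,
             connectivity_gold = cnt(gold$edges$regulator) +
               cnt(gold$edges$target),
             connectivity_inferred = pred,
             tp = tp, fp = fp, tn = tn, fn = fn,
             sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
             d_ss = combined_distance(sens, spec),
             d_pn = combined_distance(ppv, npv),
             d_rp = combined_distance(sens, ppv),
             stringsAsFactors = FALSE)
}

#' Total connectivity of a node
#'
#' Degree of a gene in a network: the number of incident pairs in an
#' undirected network, or in-degree plus out-degree in a directed one.
#'
#' @param network an `undirected_network` or `directed_edge_set`.
#' @param node gene identifier (must be in the network's universe).
#' @return Integer degree.
#' @examples
#' net <- undirected_network(data.frame(gene_a = "A", gene_b = c("B", "C")))
#' connectivity(net, "A")
#' @export
connectivity <- function(network, node) {
  if (!node %in% network$universe) stop("unknown node: ", node)
  if (inherits(network, "undirected_network")) {
    sum(network$pairs$gene_a == node) + sum(network$pairs$gene_b == node)
  } else if (inherits(network, "directed_edge_set")) {
    sum(network$edges$regulator == node) + sum(network$edges$target == node)
  } else {
    stop("unsupported network class")
  }
}

#' Correlation between TF connectivity and sub-network accuracy
#'
#' For every gold-standard TF, measures its total connectivity (in the
#' inferred or the gold-standard network, per `which`) and the accuracy of
#' reconstructing its sub-network (one of the combined distance metrics),
#' then computes the Spearman correlation across TFs. Because TFs are not
#' independent observations, significance comes from an exact permutation
#' test: gene identifiers of the selected network are relabelled uniformly
#' at random with the topology fixed, per-TF connectivity and sub-network
#' metrics are recomputed, and the null distribution of the correlation is
#' accumulated over `n_perm` permutations. The two-sided p-value uses the
#' add-one convention `(1 + #{|rho_perm| >= |rho_obs|}) / (n_perm + 1)`.
#'
#' @param inferred an `undirected_network`.
#' @param gold a `directed_edge_set` with >= 3 regulators.
#' @param which network in which connectivity is assessed: `"inferred"`
#'   (default) or `"gold"`; the permutation relabels that same network.
#' @param metric `"d_pn"`, `"d_ss"` or `"d_rp"`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param recompute_metrics recompute per-TF accuracy after relabelling
#'   (default); `FALSE` permutes only the connectivity vector.
#' @return An object of class `tf_subnet_report`: per-TF data.frame
#'   (`tf`, `connectivity`, `metric`), `rho`, `perm_p`, `n_perm`,
#'   `null_rho` (numeric vector), or `rho = NA` with a `reason` when the
#'   correlation is undefined (fewer than 3 usable TFs or a constant
#'   vector).
#' @export
connectivity_accuracy_correlation <- function(inferred, gold,
                                              which = c("inferred", "gold"),
                                              metric = c("d_pn", "d_ss", "d_rp"),
                                              n_perm = 1000, seed = 1L,
                                              recompute_metrics = TRUE) {
  which <- match.arg(which)
  metric <- match.arg(metric)
  stopifnot(n_perm >= 1)
  observe <- function(inf_net, gold_net) {
    df <- tf_subnet_metrics(inf_net, gold_net)
    conn <- if (which == "inferred") df$connectivity_inferred
            else df$connectivity_gold
    data.frame(tf = df$tf, connectivity = conn, metric = df[[metric]],
               stringsAsFactors = FALSE)
  }
  rho_of <- function(df) {
    ok <- complete.cases(df[, c("connectivity", "metric")])
    if (sum(ok) < 3) return(NA_real_)
    if (sd(df$connectivity[ok]) == 0 || sd(df$metric[ok]) == 0) return(NA_real_)
    cor(df$connectivity[ok], df$metric[ok], method = "spearman")
  }
  per_tf <- observe(inferred, gold)
  rho <- rho_of(per_tf)
  if (is.na(rho)) {
    return(structure(list(per_tf = per_tf, rho = NA_real_, perm_p = NA_real_,
                          n_perm = n_perm, null_rho = numeric(0),
                          reason = "constant or insufficient connectivity/metric values"),
                     class = "tf_subnet_report"))
  }
  # Degree of every universe gene in the network whose labels get permuted;
  # under relabelling, the degree of label t becomes the degree of the gene
  # originally holding the label mapped to t.
  deg_all <- node_degrees(if (which == "inferred") inferred else gold,
                          gold$universe)
  # Permuted networks are rebuilt without constructor validation: the
  # relabelling is a bijection on the universe, so the invariants hold.
  null_rho <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    relabel <- setNames(sample(gold$universe), gold$universe)
    if (!recompute_metrics) {
      inv <- setNames(names(relabel), relabel)
      df <- per_tf
      df$connectivity <- unname(deg_all[inv[per_tf$tf]])
      return(rho_of(df))
    }
    if (which == "inferred") {
      inf_p <- structure(list(
        pairs = data.frame(gene_a = unname(relabel[inferred$pairs$gene_a]),
                           gene_b = unname(relabel[inferred$pairs$gene_b]),
                           stringsAsFactors = FALSE),
        universe = gold$universe), class = "undirected_network")
      rho_of(observe(inf_p, gold))
    } else {
      gold_p <- structure(list(
        edges = data.frame(regulator = unname(relabel[gold$edges$regulator]),
                           target = unname(relabel[gold$edges$target]),
                           sign = gold$edges$sign, stringsAsFactors = FALSE),
        regulators = sort(unname(relabel[gold$regulators])),
        universe = gold$universe), class = "directed_edge_set")
      rho_of(observe(inferred, gold_p))
    }
  }, numeric(1)))
  exceed <- sum(abs(null_rho) >= abs(rho), na.rm = TRUE)
  structure(list(per_tf = per_tf, rho = rho,
                 perm_p = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm, null_rho = null_rho, reason = NULL),
            class = "tf_subnet_report")
}

#' @export
print.tf_subnet_report <- function(x, ...) {
  if (is.na(x$rho)) {
    cat("TF connectivity/accuracy correlation undefined:", x$reason, "\n")
  } else {
    cat(sprintf("Spearman rho = %.3f, permutation p = %.4g (%d permutations, %d TFs)\n",
                x$rho, x$perm_p, x$n_perm, nrow(x$per_tf)))
  }
  invisible(x)
}

# Degree of every gene in `universe` within `network`, as a named vector.
node_degrees <- function(network, universe) {
  incident <- if (inherits(network, "undirected_network")) {
    c(network$pairs$gene_a, network$pairs$gene_b)
  } else {
    c(network$edges$regulator, network$edges$target)
  }
  tab <- table(factor(incident, levels = universe))
  setNames(as.integer(tab), universe)
}

#' Count significant connectivity-accuracy correlations over a grid
#'
#' Applies Benjamini-Hochberg globally over all permutation p-values of a
#' benchmark grid and, for every (approach, connectivity source, metric)
#' combination, counts the datasets whose correlation survives at `alpha`.
#'
#' @param reports data.frame with columns `approach`, `dataset`, `which`,
#'   `metric`, `perm_p` (one row per correlation test performed).
#' @param alpha significance level after global adjustment (default 0.05).
#' @return A data.frame (`approach`, `which`, `metric`, `n_significant`,
#'   `n_datasets`).
#' @export
significance_count_table <- function(reports, alpha = 0.05) {
  reports <- as.data.frame(reports, stringsAsFactors = FALSE)
  stopifnot(all(c("approach", "dataset", "which", "metric", "perm_p") %in%
                  names(reports)))
  usable <- !is.na(reports$perm_p)
  sig <- logical(nrow(reports))
  sig[usable] <- batch_adjust(reports$perm_p[usable], alpha)$significant
  key <- interaction(reports$approach, reports$which, reports$metric,
                     drop = TRUE, sep = "\r")
  agg <- lapply(split(seq_len(nrow(reports)), key), function(idx) {
    data.frame(approach = reports$approach[idx[1]],
               which = reports$which[idx[1]],
               metric = reports$metric[idx[1]],
               n_significant = sum(sig[idx]),
               n_datasets = length(unique(reports$dataset[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$approach, out$which, out$metric), , drop = FALSE]
  rownames(out) <- NULL
  out
}
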