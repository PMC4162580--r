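#' Build the regulatory network from mutant differential-expression calls
#'
#' For each mutant (perturbed TF) independently, applies Benjamini-Hochberg
#' step-up across that mutant's gene p-values and keeps (mutant, gene) pairs
#' surviving at `fdr_level`, with the recorded sign of the expression change.
#' Mutants with no survivors contribute no edges. This is the
#' perturbation-evidence half of the gold standard.
#'
#' @param de data.frame with columns `mutant`, `gene`, `p_value` and
#'   optionally `sign`.
#' @param fdr_level false-discovery-rate level (default 0.05).
#' @param universe optional gene universe; defaults to all mutants and genes
#'   in `de`.
#' @return A `directed_edge_set` whose regulators are all mutants present in
#'   `de` (whether or not they contributed edges).
#' @examples
#' de <- data.frame(mutant = "A", gene = c("g1", "g2", "g3"),
#'                  p_value = c(0.001, 0.02, 0.9), sign = "+")
#' build_regulatory_network(de)$edges
#' @export
build_regulatory_network <- function(de, fdr_level = 0.05, universe = NULL) {
  de <- as.data.frame(de, stringsAsFactors = FALSE)
  regulators <- sort(unique(as.character(de$mutant)))
  universe <- universe %||% c(regulators, unique(as.character(de$gene)))
  if (nrow(de) == 0L) {
    warning("empty differential-expression table: returning empty network")
    return(directed_edge_set(NULL, regulators = regulators, universe = universe))
  }
  stopifnot(all(c("mutant", "gene", "p_value") %in% names(de)))
  if (any(de$p_value < 0 | de$p_value > 1)) stop("p-values must be in [0, 1]")
  if (is.null(de$sign)) de$sign <- "?"
  kept <- do.call(rbind, lapply(split(de, de$mutant), function(block) {
    block[p.adjust(block$p_value, method = "BH") <= fdr_level, , drop = FALSE]
  }))
  edges <- data.frame(regulator = kept$mutant, target = kept$gene,
                      sign = kept$sign, stringsAsFactors = FALSE)
  directed_edge_set(edges, regulators = regulators, universe = universe)
}

#' Build a binding network by thresholding ChIP scores
#'
#' Keeps (TF, gene) pairs whose binding p-value is at most `threshold` and
#' whose binding-sequence conservation count (number of related
#' \emph{Saccharomyces} species, 0-2) is at least `min_conservation`. The
#' canonical stringency levels are (0.001, 2), (0.005, 1) and (0.005, 0),
#' which produce nested networks by filter monotonicity.
#'
#' @param binding_scores data.frame with columns `tf`, `gene`, `p`,
#'   `conservation`.
#' @param threshold binding p-value threshold.
#' @param min_conservation minimum conservation count in {0, 1, 2}.
#' @param universe optional gene universe; defaults to all TFs and genes in
#'   `binding_scores`.
#' @return A `directed_edge_set` with sign `"?"` (binding evidence carries
#'   no direction of effect).
#' @examples
#' sc <- data.frame(tf = "A", gene = c("g1", "g2"), p = c(5e-4, 5e-4),
#'                  conservation = c(2L, 1L))
#' n_edges(build_binding_network(sc, 0.001, 2))
#' @export
build_binding_network <- function(binding_scores, threshold, min_conservation,
                                  universe = NULL) {
  sc <- as.data.frame(binding_scores, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "gene", "p", "conservation") %in% names(sc)) ||
              nrow(sc) == 0L)
  if (nrow(sc) > 0L && !all(sc$conservation %in% 0:2)) {
    stop("conservation counts must be 0, 1 or 2")
  }
  regulators <- sort(unique(as.character(sc$tf)))
  universe <- universe %||% c(regulators, unique(as.character(sc$gene)))
  keep <- sc$p <= threshold & sc$conservation >= min_conservation
  edges <- data.frame(regulator = sc$tf[keep], target = sc$gene[keep],
                      sign = "?", stringsAsFactors = FALSE)
  directed_edge_set(edges, regulators = regulators, universe = universe)
}

#' Intersect regulatory and binding networks into a gold standard
#'
#' A TF -> gene edge is a \emph{direct regulatory interaction} when it is
#' supported by both perturbation evidence (the regulatory network) and
#' physical evidence (the binding network). Signs are taken from the
#' regulatory network; the universe is the intersection of the two
#' universes and the regulators are the TFs appearing in both regulator
#' sets.
#'
#' @param regulatory,binding `directed_edge_set`s in a shared identifier
#'   namespace.
#' @return A `directed_edge_set`; a warning is emitted when the
#'   intersection is empty.
#' @examples
#' r <- directed_edge_set(data.frame(regulator = c("A", "A"), target = c("B", "C"), sign = "+"))
#' b <- directed_edge_set(data.frame(regulator = "A", target = "B"))
#' intersect_networks(r, b)$edges
#' @export
intersect_networks <- function(regulatory, binding) {
  stopifnot(inherits(regulatory, "directed_edge_set"),
            inherits(binding, "directed_edge_set"))
  in_binding <- edge_key(regulatory$edges$regulator, regulatory$edges$target) %in%
    edge_key(binding$edges$regulator, binding$edges$target)
  edges <- regulatory$edges[in_binding, c("regulator", "target", "sign"),
                            drop = FALSE]
  if (nrow(edges) == 0L) {
    warning("regulatory and binding networks have no common edges")
  }
  directed_edge_set(edges,
                    regulators = intersect(regulatory$regulators,
                                           binding$regulators),
                    universe = intersect(regulatory$universe,
                                         binding$universe))
}

#' Hypergeometric significance of a network overlap
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between a regulatory and a binding network: from a population of
#' `universe_pairs` candidate TF -> gene pairs containing the regulatory
#' edges as successes, draw as many pairs as the binding network has edges
#' and count hits. The universe of candidate pairs is an explicit argument
#' because reasonable choices differ (all TF x gene pairs of the common
#' namespace being the usual one).
#'
#' @param regulatory,binding `directed_edge_set`s.
#' @param universe_pairs total number of candidate pairs (>= both edge
#'   counts).
#' @param log.p return the natural-log probability (the tail is computed in
#'   log space either way, so extremely small values do not underflow to 0
#'   prematurely).
#' @return The tail probability `P[X >= overlap]` (or its log).
#' @examples
#' r <- directed_edge_set(data.frame(regulator = "A", target = paste0("g", 1:5)))
#' overlap_significance(r, r, universe_pairs = 10)  # 1 / choose(10, 5)
#' @export
overlap_significance <- function(regulatory, binding, universe_pairs,
                                 log.p = FALSE) {
  k <- n_edges(intersect_networks_quiet(regulatory, binding))
  K <- n_edges(regulatory)
  m <- n_edges(binding)
  if (universe_pairs < max(K, m)) {
    stop("universe_pairs must be at least as large as either network")
  }
  if (K + m - k > universe_pairs) {
    stop("inconsistent counts: union of networks exceeds universe_pairs")
  }
  lp <- phyper(k - 1, K, universe_pairs - K, m,
               lower.tail = FALSE, log.p = TRUE)
  if (log.p) lp else exp(lp)
}

intersect_networks_quiet <- function(a, b) {
  suppressWarnings(intersect_networks(a, b))
}
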