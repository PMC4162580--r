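#' Directed regulator-to-target edge set
#'
#' Container for directed TF -> gene networks: the regulatory network called
#' from knockout experiments, ChIP binding networks, and their intersection
#' (the gold standard of direct regulatory interactions). Edges carry a sign:
#' `"+"` (excitatory), `"-"` (inhibitory) or `"?"` (unknown, e.g. binding
#' evidence alone).
#'
#' @param edges data.frame with columns `regulator`, `target` and optionally
#'   `sign` (defaults to `"?"`).
#' @param regulators character vector of transcription-factor identifiers;
#'   defaults to the regulators appearing in `edges`.
#' @param universe character vector of all gene identifiers under
#'   consideration; defaults to the union of regulators and targets.
#' @return An object of class `directed_edge_set` with components `edges`
#'   (data.frame `regulator`, `target`, `sign`), `regulators` and `universe`.
#' @examples
#' gs <- directed_edge_set(data.frame(regulator = "A", target = "B", sign = "+"),
#'                         regulators = "A", universe = c("A", "B", "C"))
#' n_edges(gs)
#' @export
directed_edge_set <- function(edges, regulators = NULL, universe = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(regulator = character(), target = character(),
                        sign = character(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("regulator", "target") %in% names(edges))) {
    stop("`edges` must have columns 'regulator' and 'target'")
  }
  if (is.null(edges$sign)) edges$sign <- rep("?", nrow(edges))
  edges <- edges[, c("regulator", "target", "sign")]
  edges$regulator <- as.character(edges$regulator)
  edges$target <- as.character(edges$target)
  edges$sign <- as.character(edges$sign)
  if (any(edges$regulator == edges$target)) {
    bad <- edges$regulator[edges$regulator == edges$target]
    stop("self-edges are not allowed: ", paste(unique(bad), collapse = ", "))
  }
  if (anyDuplicated(edge_key(edges$regulator, edges$target))) {
    stop("duplicate (regulator, target) pairs are not allowed")
  }
  if (!all(edges$sign %in% c("+", "-", "?"))) {
    stop("edge signs must be '+', '-' or '?'")
  }
  regulators <- sort(unique(as.character(regulators %||% edges$regulator)))
  universe <- sort(unique(as.character(
    universe %||% c(regulators, edges$regulator, edges$target))))
  if (!all(edges$regulator %in% regulators)) {
    stop("every edge regulator must be listed in `regulators`")
  }
  if (!all(regulators %in% universe)) {
    stop("`regulators` must be a subset of `universe`")
  }
  if (!all(edges$target %in% universe)) {
    stop("every edge target must be in `universe`")
  }
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, regulators = regulators, universe = universe),
            class = "directed_edge_set")
}

#' Undirected network of unordered gene pairs
#'
#' The inference approaches in this package output undirected networks: a set
#' of unordered gene pairs. Pairs are normalized so `gene_a < gene_b`
#' lexicographically.
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @param universe character vector of all gene identifiers; defaults to the
#'   genes appearing in `pairs`.
#' @return An object of class `undirected_network` with components `pairs`
#'   and `universe`.
#' @examples
#' undirected_network(data.frame(gene_a = "B", gene_b = "A"), universe = c("A", "B", "C"))
#' @export
undirected_network <- function(pairs, universe = NULL) {
  if (is.null(pairs) || nrow(as.data.frame(pairs)) == 0L) {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(pairs))) {
    stop("`pairs` must have columns 'gene_a' and 'gene_b'")
  }
  a <- as.character(pairs$gene_a)
  b <- as.character(pairs$gene_b)
  if (any(a == b)) stop("self-pairs are not allowed")
  pairs <- data.frame(gene_a = pmin(a, b), gene_b = pmax(a, b),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  universe <- sort(unique(as.character(
    universe %||% c(pairs$gene_a, pairs$gene_b))))
  if (!all(c(pairs$gene_a, pairs$gene_b) %in% universe)) {
    stop("all genes in `pairs` must be in `universe`")
  }
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, universe = universe),
            class = "undirected_network")
}

#' Number of edges in a network
#'
#' @param x a `directed_edge_set` or `undirected_network`.
#' @return Integer edge (pair) count.
#' @export
n_edges <- function(x) {
  if (inherits(x, "directed_edge_set")) return(nrow(x$edges))
  if (inherits(x, "undirected_network")) return(nrow(x$pairs))
  stop("unsupported network class")
}

#' @export
print.directed_edge_set <- function(x, ...) {
  cat(sprintf("Directed edge set: %d edges, %d regulators, %d genes in universe\n",
              nrow(x$edges), length(x$regulators), length(x$universe)))
  if (nrow(x$edges) > 0L) print(head(x$edges, 6L))
  invisible(x)
}

#' @export
print.undirected_network <- function(x, ...) {
  cat(sprintf("Undirected network: %d pairs over %d genes\n",
              nrow(x$pairs), length(x$universe)))
  if (nrow(x$pairs) > 0L) print(head(x$pairs, 6L))
  invisible(x)
}

#' Read or write edge-list TSV files
#'
#' Directed networks are stored as three tab-separated columns
#' (`regulator`, `target`, `sign`); undirected networks as two
#' (`gene_a`, `gene_b`, normalized lexicographically on write). Round trips
#' are stable.
#'
#' @param path file path.
#' @param directed logical: read as a directed edge set (default) or an
#'   undirected network.
#' @param universe optional gene universe to attach (identifiers not present
#'   in the file are allowed in the universe, not vice versa).
#' @return `read_edges_tsv()` returns a `directed_edge_set` or
#'   `undirected_network`; `write_edges_tsv()` invisibly returns `path`.
#' @export
read_edges_tsv <- function(path, directed = TRUE, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (directed) {
    directed_edge_set(df, universe = universe)
  } else {
    undirected_network(df, universe = universe)
  }
}

#' @param x a `directed_edge_set` or `undirected_network`.
#' @rdname read_edges_tsv
#' @export
write_edges_tsv <- function(x, path) {
  df <- if (inherits(x, "directed_edge_set")) x$edges
        else if (inherits(x, "undirected_network")) x$pairs
        else stop("unsupported network class")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network in SIF format
#'
#' Writes simple-interaction-format lines for use in graph viewers such as
#' Cytoscape: `regulator<TAB>pd<TAB>target` for directed networks
#' (protein-DNA convention) and `gene_a<TAB>pp<TAB>gene_b` for undirected
#' ones. Isolated genes are omitted, as SIF has no single-node rows with
#' relations.
#'
#' @param x a `directed_edge_set` or `undirected_network`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
export_sif <- function(x, path) {
  if (inherits(x, "directed_edge_set")) {
    lines <- sprintf("%s\tpd\t%s", x$edges$regulator, x$edges$target)
  } else if (inherits(x, "undirected_network")) {
    lines <- sprintf("%s\tpp\t%s", x$pairs$gene_a, x$pairs$gene_b)
  } else {
    stop("unsupported network class")
  }
  writeLines(lines, path)
  invisible(path)
}
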