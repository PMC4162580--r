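#' Specify a network reverse-engineering approach
#'
#' An inference approach is determined by the association test (Fisher's Z
#' on continuous data or G2 on ternary-discretized data), the maximum
#' conditioning-set size (`max_k = 0` is bivariate screening; 1-3 is
#' Generalized Local Learning), the thresholding rule (raw `alpha` or
#' per-gene BH `fdr`) and the symmetrization rule used to assemble per-gene
#' neighbour lists into an undirected network (`AND`, `OR`, or `none`).
#' Exactly eighteen combinations are valid: for each test, bivariate with
#' FDR-AND, FDR-OR or plain alpha, and GLL at `max_k` 1-3 with AND or OR.
#'
#' @param test `"fisher_z"` or `"g2"`.
#' @param max_k maximum conditioning-set size, 0-3.
#' @param threshold_rule `"alpha"` or `"fdr"` (bivariate only; GLL always
#'   thresholds individual tests at `alpha_level`).
#' @param combine `"AND"`, `"OR"` or `"none"`.
#' @param alpha_level significance (or FDR) level, default 0.05.
#' @return An object of class `inference_spec`.
#' @examples
#' inference_spec("fisher_z", max_k = 0, threshold_rule = "fdr", combine = "AND")
#' @export
inference_spec <- function(test = c("fisher_z", "g2"), max_k = 0,
                           threshold_rule = c("alpha", "fdr"),
                           combine = c("none", "AND", "OR"),
                           alpha_level = 0.05) {
  test <- match.arg(test)
  threshold_rule <- match.arg(threshold_rule)
  combine <- match.arg(combine)
  stopifnot(max_k %in% 0:3, alpha_level > 0, alpha_level < 1)
  if (max_k == 0) {
    if (threshold_rule == "alpha" && combine != "none") {
      stop("bivariate screening with the alpha rule is symmetric; use combine = 'none'")
    }
    if (threshold_rule == "fdr" && combine == "none") {
      stop("per-gene FDR thresholding is asymmetric; choose combine 'AND' or 'OR'")
    }
  } else {
    if (threshold_rule != "alpha") {
      stop("GLL approaches threshold individual tests at alpha; use threshold_rule = 'alpha'")
    }
    if (combine == "none") {
      stop("GLL neighbourhoods must be assembled with combine 'AND' or 'OR'")
    }
  }
  structure(list(test = test, max_k = as.integer(max_k),
                 threshold_rule = threshold_rule, combine = combine,
                 alpha_level = alpha_level),
            class = "inference_spec")
}

#' @export
print.inference_spec <- function(x, ...) {
  cat(approach_label(x), "\n")
  invisible(x)
}

#' Label an inference approach
#'
#' Standard abbreviation, e.g. `BIVARIATE_Z_FDR_AND` or `GLL_G_3_OR`.
#'
#' @param spec an `inference_spec`.
#' @return A character scalar.
#' @export
approach_label <- function(spec) {
  t <- if (spec$test == "fisher_z") "Z" else "G"
  if (spec$max_k == 0) {
    if (spec$threshold_rule == "alpha") sprintf("BIVARIATE_%s_ALPHA", t)
    else sprintf("BIVARIATE_%s_FDR_%s", t, spec$combine)
  } else {
    sprintf("GLL_%s_%d_%s", t, spec$max_k, spec$combine)
  }
}

#' The eighteen benchmark approaches
#'
#' Enumerates the full benchmark family: for each of the two tests,
#' bivariate FDR-AND, bivariate FDR-OR, bivariate alpha, and GLL with
#' conditioning up to 1, 2 or 3 genes under AND and OR assembly.
#'
#' @param alpha_level significance/FDR level shared by all approaches.
#' @return A named list of 18 `inference_spec` objects, named by
#'   [approach_label()].
#' @examples
#' names(benchmark_approaches())
#' @export
benchmark_approaches <- function(alpha_level = 0.05) {
  specs <- list()
  for (test in c("fisher_z", "g2")) {
    specs <- c(specs, list(
      inference_spec(test, 0, "fdr", "AND", alpha_level),
      inference_spec(test, 0, "fdr", "OR", alpha_level),
      inference_spec(test, 0, "alpha", "none", alpha_level)))
    for (k in 1:3) for (comb in c("AND", "OR")) {
      specs <- c(specs, list(inference_spec(test, k, "alpha", comb, alpha_level)))
    }
  }
  names(specs) <- vapply(specs, approach_label, character(1))
  specs
}

# All pairwise association p-values (and statistics) for the given test
# ("fisher_z", "g2", or a custom function(data, i, j, cond) returning a
# ci_test_result). Returns list(p, stat, reliable) gene x gene matrices.
pairwise_tests <- function(data, test) {
  genes <- rownames(data)
  m <- length(genes)
  n <- ncol(data)
  if (is.function(test)) {
    p <- matrix(1, m, m, dimnames = list(genes, genes))
    stat <- matrix(0, m, m, dimnames = list(genes, genes))
    reliable <- matrix(TRUE, m, m, dimnames = list(genes, genes))
    for (a in seq_len(m - 1)) {
      for (b in seq.int(a + 1, m)) {
        res <- test(data, genes[a], genes[b], character(0))
        p[a, b] <- p[b, a] <- res$p_value
        stat[a, b] <- stat[b, a] <- res$statistic
        reliable[a, b] <- reliable[b, a] <- res$reliable
      }
    }
    return(list(p = p, stat = stat, reliable = reliable))
  }
  if (test == "fisher_z") {
    R0 <- suppressWarnings(cor(t(data)))
    reliable <- is.finite(R0)
    R0[!is.finite(R0)] <- 0            # constant genes: no association
    R <- pmin(pmax(R0, -(1 - 1e-7)), 1 - 1e-7)
    stat <- sqrt(n - 3) * abs(atanh(R))
    p <- 2 * pnorm(-stat)
    diag(p) <- 1
    diag(stat) <- 0
    dimnames(p) <- dimnames(stat) <- dimnames(reliable) <- list(genes, genes)
    return(list(p = p, stat = stat, reliable = reliable, R = R0))
  } else {
    p <- matrix(1, m, m, dimnames = list(genes, genes))
    stat <- matrix(0, m, m, dimnames = list(genes, genes))
    reliable <- matrix(TRUE, m, m, dimnames = list(genes, genes))
    for (a in seq_len(m - 1)) {
      for (b in seq.int(a + 1, m)) {
        res <- g2_test(data, genes[a], genes[b])
        p[a, b] <- p[b, a] <- res$p_value
        stat[a, b] <- stat[b, a] <- res$statistic
        reliable[a, b] <- reliable[b, a] <- res$reliable
      }
    }
  }
  diag(p) <- 1
  diag(stat) <- 0
  dimnames(p) <- dimnames(stat) <- dimnames(reliable) <- list(genes, genes)
  list(p = p, stat = stat, reliable = reliable)
}

#' Bivariate association screening
#'
#' Computes all pairwise association tests once and thresholds them. Under
#' the `alpha` rule, unordered pairs with p <= `alpha_level` are kept
#' (symmetric, no assembly). Under the `fdr` rule, each gene's (m - 1)
#' p-values are BH-adjusted independently, giving a per-gene neighbour
#' list that is then symmetrized with the spec's AND/OR rule.
#'
#' @param data genes x samples matrix, continuous for Fisher's Z or ternary
#'   for G2 (>= 4 samples).
#' @param spec an `inference_spec` with `max_k = 0`.
#' @param pairwise optional precomputed [pairwise_tests()] result.
#' @return An `undirected_network` over the genes of `data`.
#' @export
bivariate_screen <- function(data, spec, pairwise = NULL) {
  stopifnot(inherits(spec, "inference_spec"), spec$max_k == 0L)
  if (ncol(data) < 4) stop("bivariate screening needs at least 4 samples")
  genes <- rownames(data)
  pt <- pairwise %||% pairwise_tests(data, spec$test)
  if (spec$threshold_rule == "alpha") {
    keep <- which(upper.tri(pt$p) & pt$p <= spec$alpha_level, arr.ind = TRUE)
    return(undirected_network(
      data.frame(gene_a = genes[keep[, 1]], gene_b = genes[keep[, 2]]),
      universe = genes))
  }
  neighbours <- lapply(seq_along(genes), function(g) {
    p <- pt$p[g, -g]
    names(p)[p.adjust(p, method = "BH") <= spec$alpha_level]
  })
  names(neighbours) <- genes
  assemble_network(neighbours, spec$combine, universe = genes)
}

#' Generalized Local Learning neighbourhood discovery for one gene
#'
#' Interleaved inclusion/elimination in the HITON-PC style. Candidates are
#' ranked by unconditional association strength with the target (statistic
#' descending, ties broken by gene identifier). The best remaining
#' candidate is admitted, after which every current member X is put on
#' trial: all subsets S of the other current members with `|S| <= max_k`
#' (the empty set included, smallest subsets first) are searched, and X is
#' removed on the first \emph{reliable} test with p above `alpha_level`.
#' Unreliable tests (singular correlation submatrices for Fisher's Z,
#' sparse tables for G2) can never remove an edge. The surviving set
#' estimates the genes directly upstream or downstream of the target.
#'
#' @param data genes x samples matrix (continuous for `fisher_z`, ternary
#'   for `g2`).
#' @param target gene identifier.
#' @param test `"fisher_z"`, `"g2"`, or a custom conditional-independence
#'   test `function(data, i, j, cond)` returning an object with fields
#'   `p_value`, `statistic`, `reliable` (e.g. an exact d-separation oracle
#'   for algorithm-correctness checks).
#' @param max_k maximum conditioning-set size (>= 1).
#' @param alpha_level per-test significance level.
#' @param pairwise optional precomputed [pairwise_tests()] result, reused
#'   across targets by [run_approach()].
#' @return Character vector of neighbour gene identifiers.
#' @export
gll_neighbors <- function(data, target, test = "fisher_z",
                          max_k = 1, alpha_level = 0.05, pairwise = NULL) {
  if (!is.function(test)) {
    test <- match.arg(test, c("fisher_z", "g2"))
  }
  stopifnot(max_k >= 1)
  genes <- rownames(data)
  target <- as.character(target)
  if (!target %in% genes) stop("target gene not in data: ", target)
  if (is.null(pairwise)) pairwise <- pairwise_tests(data, test)
  ci <- if (is.function(test)) {
    function(a, b, S) test(data, a, b, S)
  } else if (test == "fisher_z") {
    # conditional tests reuse the cached sample correlation matrix: the
    # partial correlation only depends on the submatrix of {a, b} + S
    n <- ncol(data)
    R <- pairwise$R
    function(a, b, S) {
      if (n <= length(S) + 3) stop("need more than |cond| + 3 samples")
      r <- tryCatch({
        sub <- R[c(a, b, S), c(a, b, S), drop = FALSE]
        if (length(S) == 0L) sub[1, 2] else {
          P <- solve(sub)
          -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
        }
      }, error = function(e) NA_real_)
      if (!is.finite(r)) return(ci_test_result(0, 1, n, length(S), FALSE))
      r <- max(min(r, 1 - 1e-7), -(1 - 1e-7))
      stat <- sqrt(n - length(S) - 3) * abs(atanh(r))
      ci_test_result(stat, 2 * pnorm(-stat), n, length(S), TRUE)
    }
  } else {
    function(a, b, S) g2_test(data, a, b, S)
  }
  others <- setdiff(genes, target)
  p0 <- pairwise$p[target, others]
  s0 <- pairwise$stat[target, others]
  r0 <- pairwise$reliable[target, others]
  # drop candidates already independent at the unconditional (empty-set)
  # test; unreliable tests cannot eliminate, so those candidates stay
  queue <- others[!(r0 & p0 > alpha_level)]
  queue <- queue[order(-s0[queue], queue)]
  tpc <- character(0)
  for (cand in queue) {
    tpc <- c(tpc, cand)
    removed <- character(0)
    for (x in tpc) {
      rest <- setdiff(tpc, c(x, removed))
      if (eliminate_member(ci, x, target, rest, max_k, alpha_level)) {
        removed <- c(removed, x)
      }
    }
    tpc <- setdiff(tpc, removed)
  }
  sort(tpc)
}

# TRUE when some reliable test over subsets of `rest` (sizes 1..max_k;
# the empty set was already checked at admission) renders x independent
# of the target.
eliminate_member <- function(ci, x, target, rest, max_k, alpha_level) {
  for (k in seq_len(min(max_k, length(rest)))) {
    subsets <- combn(sort(rest), k, simplify = FALSE)
    for (S in subsets) {
      res <- ci(x, target, S)
      if (res$reliable && res$p_value > alpha_level) return(TRUE)
    }
  }
  FALSE
}

#' Assemble per-gene neighbour lists into an undirected network
#'
#' `AND`: an unordered pair is kept iff each gene lists the other.
#' `OR`: kept iff either gene lists the other.
#'
#' @param neighbour_map named list mapping every gene to a character vector
#'   of neighbours.
#' @param combine `"AND"` or `"OR"`.
#' @param universe gene universe; defaults to the names of `neighbour_map`.
#' @return An `undirected_network`.
#' @examples
#' assemble_network(list(X = "Y", Y = character(), Z = character()), "OR")$pairs
#' @export
assemble_network <- function(neighbour_map, combine = c("AND", "OR"),
                             universe = NULL) {
  combine <- match.arg(combine)
  universe <- universe %||% names(neighbour_map)
  if (is.null(names(neighbour_map)) || !all(universe %in% c(names(neighbour_map)))) {
    stop("`neighbour_map` must be named and defined for every gene")
  }
  claims <- unlist(lapply(names(neighbour_map), function(g) {
    nb <- neighbour_map[[g]]
    if (length(nb)) pair_key(g, nb) else character(0)
  }))
  tab <- table(claims)
  keep <- if (combine == "AND") names(tab)[tab == 2L] else names(tab)
  parts <- strsplit(keep, "\r", fixed = TRUE)
  undirected_network(
    data.frame(gene_a = vapply(parts, `[`, "", 1L),
               gene_b = vapply(parts, `[`, "", 2L)),
    universe = universe)
}

#' Run one benchmark approach on an expression matrix
#'
#' Dispatches to [bivariate_screen()] (`max_k = 0`) or per-gene
#' [gll_neighbors()] followed by [assemble_network()]. G2-based approaches
#' discretize the input with [discretize_ternary()] first (a matrix that is
#' already ternary is used as is).
#'
#' @param data numeric genes x samples matrix.
#' @param spec an `inference_spec`.
#' @param verbose log per-gene progress and the final edge count.
#' @param pairwise optional precomputed [pairwise_tests()] result for the
#'   spec's test on (the discretized form of) `data`; computed when absent.
#' @return An `undirected_network`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(80), 4, 20, dimnames = list(paste0("g", 1:4), NULL))
#' run_approach(x, inference_spec("fisher_z", 0, "alpha", "none"))
#' @export
run_approach <- function(data, spec, verbose = FALSE, pairwise = NULL) {
  stopifnot(inherits(spec, "inference_spec"))
  if (spec$test == "g2" && !is_ternary(data)) data <- discretize_ternary(data)
  if (verbose) message("approach ", approach_label(spec))
  if (spec$max_k == 0L) {
    net <- bivariate_screen(data, spec, pairwise = pairwise)
  } else {
    pw <- pairwise %||% pairwise_tests(data, spec$test)
    genes <- rownames(data)
    neighbours <- lapply(genes, function(g) {
      if (verbose) message("  neighbours(", g, ")")
      gll_neighbors(data, g, spec$test, spec$max_k, spec$alpha_level,
                    pairwise = pw)
    })
    names(neighbours) <- genes
    net <- assemble_network(neighbours, spec$combine, universe = genes)
  }
  if (verbose) message("  ", nrow(net$pairs), " edges")
  net
}

is_ternary <- function(x) {
  is.numeric(x) && all(x %in% 0:2)
}
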