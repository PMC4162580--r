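#' Generate a ground-truth transcription-factor network
#'
#' Draws a directed, acyclic TF -> gene network with heavy-tailed TF
#' out-degrees: each of the `round(n_tfs * mean_out_degree)` edges is
#' assigned to a TF with probability proportional to its current out-degree
#' plus one (a Yule / preferential-attachment scheme), so a few TFs become
#' hubs, as observed in curated yeast regulatory networks. Acyclicity is
#' enforced by a fixed TF ordering: genes are indexed `g001, g002, ...`, the
#' first `n_tfs` indices are TFs, and a TF may only target genes with a
#' strictly larger index. Each edge carries a sign drawn Bernoulli(0.5) and a
#' weight drawn uniformly on \[0.5, 1.5\] times the sign.
#'
#' @param n_genes total number of genes (>= 1).
#' @param n_tfs number of transcription factors, `1 <= n_tfs <= n_genes`.
#' @param mean_out_degree desired mean number of targets per TF; the total
#'   edge count is fixed at `round(n_tfs * mean_out_degree)`.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   networks.
#' @return A `directed_edge_set` whose `edges` data.frame carries an extra
#'   numeric `weight` column (signed effect size).
#' @examples
#' net <- generate_true_network(n_genes = 30, n_tfs = 5, mean_out_degree = 3, seed = 1)
#' n_edges(net)
#' @export
generate_true_network <- function(n_genes, n_tfs, mean_out_degree, seed) {
  stopifnot(n_genes >= 1, n_tfs >= 1, n_tfs <= n_genes, mean_out_degree >= 0)
  genes <- gene_ids(n_genes)
  tfs <- genes[seq_len(n_tfs)]
  n_edge <- as.integer(round(n_tfs * mean_out_degree))
  capacity <- n_genes - seq_len(n_tfs)  # targets with larger index than TF i
  if (n_edge > sum(capacity)) {
    stop(sprintf("infeasible degree request: %d edges exceed capacity %d",
                 n_edge, sum(capacity)))
  }
  if (n_edge == 0L) {
    return(empty_true_network(tfs, genes))
  }
  with_seed(seed, {
    out_deg <- integer(n_tfs)
    targets_used <- vector("list", n_tfs)  # indices already targeted per TF
    reg_idx <- integer(n_edge)
    tgt_idx <- integer(n_edge)
    for (e in seq_len(n_edge)) {
      open <- which(out_deg < capacity)
      w <- out_deg[open] + 1
      tf <- open[sample.int(length(open), 1L, prob = w)]
      avail <- setdiff(seq.int(tf + 1L, n_genes), targets_used[[tf]])
      tgt <- if (length(avail) == 1L) avail else avail[sample.int(length(avail), 1L)]
      targets_used[[tf]] <- c(targets_used[[tf]], tgt)
      out_deg[tf] <- out_deg[tf] + 1L
      reg_idx[e] <- tf
      tgt_idx[e] <- tgt
    }
    sgn <- ifelse(runif(n_edge) < 0.5, 1, -1)
    weight <- runif(n_edge, 0.5, 1.5) * sgn
    edges <- data.frame(regulator = genes[reg_idx], target = genes[tgt_idx],
                        sign = ifelse(sgn > 0, "+", "-"), weight = weight,
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
    rownames(edges) <- NULL
    net <- directed_edge_set(edges[, c("regulator", "target", "sign")],
                             regulators = tfs, universe = genes)
    net$edges$weight <- edges$weight
    net
  })
}

gene_ids <- function(n) sprintf("g%0*d", max(3L, nchar(n)), seq_len(n))

empty_true_network <- function(tfs, genes) {
  net <- directed_edge_set(NULL, regulators = tfs, universe = genes)
  net$edges$weight <- numeric(0)
  net
}

#' Bundle a true network and simulation parameters into a synthetic world
#'
#' A `synthetic_world` is the single source of truth for downstream
#' simulation: the directed signed/weighted network, the gene and TF
#' identifier sets, the structural noise level and the seed.
#'
#' @param true_network a `directed_edge_set` with a `weight` column, e.g.
#'   from [generate_true_network()].
#' @param noise_sd standard deviation of the structural noise added to
#'   regulated genes (parentless genes always receive unit-variance
#'   exogenous input, which sets the scale of the system).
#' @param seed integer seed recorded with the world.
#' @return An object of class `synthetic_world`.
#' @examples
#' w <- synthetic_world(generate_true_network(20, 4, 2, seed = 1), noise_sd = 0.3, seed = 1)
#' @export
synthetic_world <- function(true_network, noise_sd = 0.5, seed = 1L) {
  stopifnot(inherits(true_network, "directed_edge_set"), noise_sd >= 0)
  if (is.null(true_network$edges$weight)) {
    true_network$edges$weight <-
      ifelse(true_network$edges$sign == "-", -1, 1)
  }
  structure(list(true_network = true_network,
                 n_genes = length(true_network$universe),
                 genes = true_network$universe,
                 tf_ids = true_network$regulators,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d genes (%d TFs), %d true edges, noise_sd = %g\n",
              x$n_genes, length(x$tf_ids), nrow(x$true_network$edges), x$noise_sd))
  invisible(x)
}

# Core linear-Gaussian structural simulator. `clamp_gene` is a character
# vector of length n_samples (NA = unperturbed); clamped genes are fixed at
# `clamp_value` before their children are evaluated. `tf_drive` is an
# optional n_tfs x n_samples matrix added to TF equations (latent condition
# signal). Genes are evaluated in index order, which is a topological order
# by construction of the true network.
simulate_sem <- function(world, n_samples, clamp_gene = NULL,
                         clamp_value = -3, tf_drive = NULL) {
  genes <- world$genes
  ng <- length(genes)
  edges <- world$true_network$edges
  has_parent <- genes %in% edges$target
  x <- matrix(0, nrow = ng, ncol = n_samples,
              dimnames = list(genes, sprintf("s%04d", seq_len(n_samples))))
  noise <- matrix(rnorm(ng * n_samples), ng, n_samples)
  noise[has_parent, ] <- noise[has_parent, , drop = FALSE] * world$noise_sd
  parents <- split(seq_len(nrow(edges)), edges$target)
  clamp_idx <- if (is.null(clamp_gene)) rep(NA_integer_, n_samples)
               else match(clamp_gene, genes)
  for (g in seq_len(ng)) {
    row <- noise[g, ]
    pe <- parents[[genes[g]]]
    if (!is.null(pe)) {
      pidx <- match(edges$regulator[pe], genes)
      row <- row + drop(crossprod(x[pidx, , drop = FALSE], edges$weight[pe]))
    }
    if (!is.null(tf_drive) && genes[g] %in% rownames(tf_drive)) {
      row <- row + tf_drive[genes[g], ]
    }
    clamped <- which(clamp_idx == g)
    if (length(clamped)) row[clamped] <- clamp_value
    x[g, ] <- row
  }
  x
}

#' Simulate an expression matrix under one of the four study designs
#'
#' Evaluates the world's linear-Gaussian structural model in topological
#' order (`x_g = sum_parents weight * x_parent + noise`), with design-specific
#' modifiers that emulate the four kinds of microarray datasets used for
#' network inference:
#' \describe{
#'   \item{`replicates`}{wild-type biological replicates; no exogenous
#'     variation beyond the structural noise.}
#'   \item{`environment_time`}{a smooth latent condition signal (one period
#'     of a sine across the sample series) feeds a random half of the TFs,
#'     emulating environmental/time-course variation.}
#'   \item{`compendium`}{each sample independently clamps one random gene to
#'     a low value (-3 on the standardized scale), emulating a merged,
#'     predominantly perturbation-based compendium.}
#'   \item{`perturbation`}{samples cycle through TF knockouts, clamping the
#'     knocked-out TF to -3.}
#' }
#' Sample annotations record the design and the perturbed gene (attributes
#' `design` and `perturbed`); inference methods never see them.
#'
#' @param world a `synthetic_world`.
#' @param design one of `"replicates"`, `"environment_time"`,
#'   `"compendium"`, `"perturbation"`.
#' @param n_samples number of samples (>= 2).
#' @param seed integer seed.
#' @return A numeric genes x samples matrix with attributes `design` and
#'   `perturbed` (character vector, `NA` where no gene was perturbed).
#' @examples
#' w <- synthetic_world(generate_true_network(20, 4, 2, seed = 1), noise_sd = 0.3, seed = 1)
#' x <- simulate_expression(w, "perturbation", n_samples = 8, seed = 2)
#' attr(x, "perturbed")
#' @export
simulate_expression <- function(world, design, n_samples, seed) {
  stopifnot(inherits(world, "synthetic_world"), n_samples >= 2)
  designs <- c("replicates", "environment_time", "compendium", "perturbation")
  if (!(is.character(design) && length(design) == 1L && design %in% designs)) {
    stop("`design` must be one of: ", paste(designs, collapse = ", "))
  }
  with_seed(seed, {
    perturbed <- rep(NA_character_, n_samples)
    tf_drive <- NULL
    if (design == "environment_time") {
      cond <- sin(2 * pi * seq_len(n_samples) / n_samples)
      n_driven <- max(1L, ceiling(length(world$tf_ids) / 2))
      driven <- sort(sample(world$tf_ids, n_driven))
      tf_drive <- matrix(rep(cond, each = n_driven), nrow = n_driven,
                         dimnames = list(driven, NULL))
    } else if (design == "compendium") {
      perturbed <- sample(world$genes, n_samples, replace = TRUE)
    } else if (design == "perturbation") {
      perturbed <- world$tf_ids[(seq_len(n_samples) - 1L) %% length(world$tf_ids) + 1L]
    }
    x <- simulate_sem(world, n_samples,
                      clamp_gene = if (all(is.na(perturbed))) NULL else perturbed,
                      tf_drive = tf_drive)
    attr(x, "design") <- design
    attr(x, "perturbed") <- perturbed
    x
  })
}

#' Simulate per-mutant differential-expression p-values
#'
#' Emulates the upstream differential-expression calls of a TF-deletion
#' compendium: for every TF in the world, `n_mut` knockout replicates
#' (TF clamped to -3) are compared with a common set of `n_wt` wild-type
#' replicates by a Welch two-sample t-test, gene by gene. The recorded sign
#' follows the deletion convention: a target that goes \emph{down} when its
#' regulator is deleted is recorded as excitatory (`"+"`), a target that
#' goes up as inhibitory (`"-"`).
#'
#' @param world a `synthetic_world`.
#' @param n_wt number of wild-type replicates (>= 2).
#' @param n_mut number of mutant replicates per TF (>= 2).
#' @param seed integer seed.
#' @return A data.frame (`mutant`, `gene`, `p_value`, `sign`) with one row
#'   per (TF, other gene) pair. Genes with degenerate (zero) variance in
#'   both groups get `p_value = 1`.
#' @examples
#' w <- synthetic_world(generate_true_network(15, 3, 2, seed = 1), noise_sd = 0.2, seed = 1)
#' de <- simulate_mutant_pvalues(w, n_wt = 10, n_mut = 10, seed = 3)
#' head(de)
#' @export
simulate_mutant_pvalues <- function(world, n_wt, n_mut, seed) {
  stopifnot(inherits(world, "synthetic_world"), n_wt >= 2, n_mut >= 2)
  with_seed(seed, {
    wt <- simulate_sem(world, n_wt)
    res <- lapply(world$tf_ids, function(tf) {
      mut <- simulate_sem(world, n_mut, clamp_gene = rep(tf, n_mut))
      keep <- setdiff(world$genes, tf)
      tt <- welch_rows(mut[keep, , drop = FALSE], wt[keep, , drop = FALSE])
      data.frame(mutant = tf, gene = keep, p_value = tt$p,
                 sign = ifelse(tt$diff < 0, "+", "-"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

# Row-wise Welch t-test of group 1 (mutant) vs group 2 (wild-type).
# Returns two-sided p and the mean difference (mutant - wild-type).
welch_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- apply(x1, 1, var); v2 <- apply(x2, 1, var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- !is.finite(tstat) | !is.finite(df) | se2 == 0
  p[degenerate] <- 1
  list(p = p, diff = m1 - m2)
}

#' Simulate three nested ChIP binding networks
#'
#' Emulates binding evidence at three stringency levels. A per-pair score
#' table is drawn first: each true edge survives with probability
#' `1 - fnr` and then receives a small binding p-value (skewed below the
#' liberal threshold 0.005) and a conservation count in {0, 1, 2} biased
#' towards 2; missed true edges are recorded with sub-threshold scores.
#' False TF -> gene pairs enter at rate `fpr` with a uniform p-value below
#' 0.005 and a conservation count biased towards 0. The three networks are
#' then exactly the stringency filters applied to that table:
#' conservative = (p <= 0.001, conservation 2), intermediate =
#' (p <= 0.005, conservation >= 1), liberal = (p <= 0.005, any
#' conservation), so conservative \eqn{\subseteq} intermediate
#' \eqn{\subseteq} liberal by filter monotonicity, and true edges are
#' preferentially retained at higher stringency.
#'
#' @param world a `synthetic_world`.
#' @param fnr probability that a true edge is missed by the binding assay.
#' @param fpr probability that a non-edge TF -> gene pair enters the score
#'   table with a significant score.
#' @param seed integer seed.
#' @return A list of class `binding_networks` with components `scores`
#'   (data.frame `tf`, `gene`, `p`, `conservation`), `conservative`,
#'   `intermediate`, `liberal` (nested `directed_edge_set`s).
#' @examples
#' w <- synthetic_world(generate_true_network(20, 4, 2, seed = 1), seed = 1)
#' b <- simulate_binding(w, fnr = 0, fpr = 0, seed = 4)
#' n_edges(b$liberal) == n_edges(w$true_network)
#' @export
simulate_binding <- function(world, fnr, fpr, seed) {
  stopifnot(inherits(world, "synthetic_world"),
            fnr >= 0, fnr <= 1, fpr >= 0, fpr <= 1)
  with_seed(seed, {
    true <- world$true_network$edges
    n_true <- nrow(true)
    rows <- list()
    if (n_true > 0L) {
      missed <- runif(n_true) < fnr
      cons <- sample(0:2, n_true, replace = TRUE, prob = c(0.1, 0.2, 0.7))
      p <- 0.005 * runif(n_true)^3            # skewed small: detected edges
      p[missed] <- runif(sum(missed), 0.005, 1)  # recorded but sub-threshold
      rows$true <- data.frame(tf = true$regulator, gene = true$target,
                              p = p, conservation = cons,
                              stringsAsFactors = FALSE)
    }
    # candidate false pairs: TF -> gene, no self, not a true edge
    cand_tf <- rep(world$tf_ids, each = world$n_genes)
    cand_gene <- rep(world$genes, times = length(world$tf_ids))
    ok <- cand_tf != cand_gene &
      !(edge_key(cand_tf, cand_gene) %in% edge_key(true$regulator, true$target))
    cand_tf <- cand_tf[ok]; cand_gene <- cand_gene[ok]
    fp <- runif(length(cand_tf)) < fpr
    if (any(fp)) {
      rows$false <- data.frame(tf = cand_tf[fp], gene = cand_gene[fp],
                               p = runif(sum(fp), 0, 0.005),
                               conservation = sample(0:2, sum(fp), replace = TRUE,
                                                     prob = c(0.5, 0.3, 0.2)),
                               stringsAsFactors = FALSE)
    }
    scores <- if (length(rows)) do.call(rbind, rows) else
      data.frame(tf = character(), gene = character(), p = numeric(),
                 conservation = integer(), stringsAsFactors = FALSE)
    scores <- scores[order(scores$tf, scores$gene), , drop = FALSE]
    rownames(scores) <- NULL
    structure(list(
      scores = scores,
      conservative = build_binding_network(scores, 0.001, 2,
                                           universe = world$genes),
      intermediate = build_binding_network(scores, 0.005, 1,
                                           universe = world$genes),
      liberal = build_binding_network(scores, 0.005, 0,
                                      universe = world$genes)),
      class = "binding_networks")
  })
}

#' Write an expression matrix as TSV
#'
#' First column holds gene identifiers (header `gene`), remaining columns
#' are samples. The inverse of [read_expression_tsv()].
#'
#' @param x numeric genes x samples matrix with dimnames.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
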