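# d-separation oracle on a true DAG, used as the independent reference for
# constraint-based inference tests.

# Adjacency matrix (amat[i, j] = TRUE iff i -> j) from a directed_edge_set.
dag_amat <- function(net) {
  g <- net$universe
  amat <- matrix(FALSE, length(g), length(g), dimnames = list(g, g))
  if (nrow(net$edges)) {
    amat[cbind(net$edges$regulator, net$edges$target)] <- TRUE
  }
  amat
}

# Classic ancestral-moral-graph test: x and y are d-separated given S iff
# they are disconnected in the moralized ancestral graph of {x, y} + S
# after removing S.
dsep <- function(amat, x, y, S = character()) {
  g <- rownames(amat)
  anc <- unique(c(x, y, S))
  repeat {
    parents <- g[rowSums(amat[, anc, drop = FALSE]) > 0]
    grown <- union(anc, parents)
    if (length(grown) == length(anc)) break
    anc <- grown
  }
  sub <- amat[anc, anc, drop = FALSE]
  undir <- sub | t(sub)
  # moralize: connect co-parents of every child
  for (child in anc) {
    pa <- anc[sub[, child]]
    if (length(pa) > 1) undir[pa, pa] <- TRUE
  }
  diag(undir) <- FALSE
  keep <- setdiff(anc, S)
  undir <- undir[keep, keep, drop = FALSE]
  if (!(x %in% keep) || !(y %in% keep)) return(TRUE)
  # BFS from x
  seen <- x
  frontier <- x
  while (length(frontier)) {
    nxt <- keep[colSums(undir[frontier, , drop = FALSE]) > 0]
    frontier <- setdiff(nxt, seen)
    seen <- union(seen, frontier)
  }
  !(y %in% seen)
}

# CI-test function backed by the d-separation oracle, pluggable into
# gll_neighbors(): independent pairs get p = 1, dependent pairs p = 0.
dsep_oracle <- function(net) {
  amat <- dag_amat(net)
  function(data, i, j, cond) {
    indep <- dsep(amat, i, j, cond)
    list(statistic = if (indep) 0 else 1,
         p_value = if (indep) 1 else 0,
         n = ncol(data), cond_size = length(cond), reliable = TRUE)
  }
}

# True undirected skeleton as sorted pair keys.
skeleton_keys <- function(net) {
  sort(paste(pmin(net$edges$regulator, net$edges$target),
             pmax(net$edges$regulator, net$edges$target)))
}

adjacency_of <- function(net, g) {
  sort(unique(c(net$edges$target[net$edges$regulator == g],
                net$edges$regulator[net$edges$target == g])))
}
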