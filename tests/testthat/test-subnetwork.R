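test_that("TF sub-network accuracy restricts the universe to the TF's row", {
  gold <- directed_edge_set(
    data.frame(regulator = c("A", "A"), target = c("B", "C"), sign = "+"),
    regulators = "A", universe = c("A", "B", "C", "D"))
  inf <- undirected_network(data.frame(gene_a = "A", gene_b = "B"),
                            universe = gold$universe)
  m <- tf_subnetwork_accuracy(inf, gold, "A")
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$ppv, 1)
  # no inferred pairs with the TF: sensitivity 0, specificity 1
  inf0 <- undirected_network(data.frame(gene_a = "B", gene_b = "C"),
                             universe = gold$universe)
  m0 <- tf_subnetwork_accuracy(inf0, gold, "A")
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 1)
  expect_error(tf_subnetwork_accuracy(inf, gold, "B"), "regulators")
  # with a single TF the restriction is the whole problem
  expect_equal(m$d_ss, core_metrics(confusion_counts(inf, gold))$d_ss)
})

test_that("connectivity is the incident degree in either network kind", {
  star <- undirected_network(
    data.frame(gene_a = "hub", gene_b = paste0("t", 1:7)))
  expect_equal(connectivity(star, "hub"), 7)
  expect_equal(connectivity(star, "t1"), 1)
  iso <- undirected_network(NULL, universe = c("a", "b"))
  expect_equal(connectivity(iso, "a"), 0)
  expect_error(connectivity(star, "zz"), "unknown")
  # handshake lemma
  degs <- vapply(star$universe, function(g) connectivity(star, g), numeric(1))
  expect_equal(sum(degs), 2 * n_edges(star))
  dir <- directed_edge_set(
    data.frame(regulator = c("A", "B"), target = c("B", "C"), sign = "+"))
  expect_equal(connectivity(dir, "B"), 2)   # in-degree + out-degree
})

test_that("vectorized per-TF metrics agree with the one-TF operations", {
  w <- synthetic_world(generate_true_network(25, 5, 3, seed = 17),
                       noise_sd = 0.3, seed = 17)
  gold <- directed_edge_set(w$true_network$edges[, 1:3],
                            regulators = w$tf_ids, universe = w$genes)
  x <- simulate_expression(w, "compendium", 80, seed = 18)
  inf <- run_approach(x, inference_spec("fisher_z", 0, "fdr", "OR"))
  fast <- tf_subnet_metrics(inf, gold)
  for (tf in gold$regulators) {
    slow <- tf_subnetwork_accuracy(inf, gold, tf)
    row <- fast[fast$tf == tf, ]
    expect_equal(row$d_pn, slow$d_pn)
    expect_equal(row$sensitivity, slow$sensitivity)
    expect_equal(row$connectivity_inferred, connectivity(inf, tf))
    expect_equal(row$connectivity_gold, connectivity(gold, tf))
  }
})

test_that("a perfectly monotone connectivity/accuracy relation is detected", {
  # 10 TFs; TF i regulates i + 1 distinct targets, and the inferred network
  # recovers the first i - 1 of them (no false positives), so sub-network
  # accuracy improves strictly with gold connectivity
  tfs <- sprintf("tf%02d", 1:10)
  targets <- sprintf("t%03d", 1:65)
  off <- function(i) (i - 1) + (i - 1) * i / 2   # cumulative sum of j + 1
  edges <- do.call(rbind, lapply(seq_along(tfs), function(i) {
    data.frame(regulator = tfs[i], target = targets[off(i) + seq_len(i + 1)],
               sign = "+")
  }))
  gold <- directed_edge_set(edges, regulators = tfs,
                            universe = c(tfs, targets))
  inf_pairs <- do.call(rbind, lapply(2:10, function(i) {
    data.frame(gene_a = tfs[i], gene_b = targets[off(i) + seq_len(i - 1)])
  }))
  inf <- undirected_network(inf_pairs, universe = gold$universe)
  rep_ <- connectivity_accuracy_correlation(inf, gold, which = "gold",
                                            metric = "d_ss", n_perm = 1000,
                                            seed = 19)
  expect_lt(rep_$rho, -0.9)
  expect_lt(rep_$perm_p, 0.05)
  expect_gte(rep_$perm_p, 1 / 1001)
})

test_that("degenerate inputs give an explicit undefined correlation", {
  tfs <- c("a", "b", "c")
  gold <- directed_edge_set(
    data.frame(regulator = tfs, target = c("x", "y", "z"), sign = "+"),
    regulators = tfs, universe = c(tfs, "x", "y", "z"))
  inf <- undirected_network(NULL, universe = gold$universe)
  rep_ <- connectivity_accuracy_correlation(inf, gold, which = "inferred",
                                            metric = "d_ss", n_perm = 10,
                                            seed = 20)
  expect_true(is.na(rep_$rho))
  expect_match(rep_$reason, "constant")
})

test_that("permutation p-values are reproducible with the add-one floor", {
  w <- synthetic_world(generate_true_network(20, 5, 3, seed = 21),
                       noise_sd = 0.3, seed = 21)
  gold <- directed_edge_set(w$true_network$edges[, 1:3],
                            regulators = w$tf_ids, universe = w$genes)
  x <- simulate_expression(w, "perturbation", 60, seed = 22)
  inf <- run_approach(x, inference_spec("fisher_z", 0, "alpha", "none"))
  r1 <- connectivity_accuracy_correlation(inf, gold, "inferred", "d_pn",
                                          n_perm = 99, seed = 23)
  r2 <- connectivity_accuracy_correlation(inf, gold, "inferred", "d_pn",
                                          n_perm = 99, seed = 23)
  expect_identical(r1$null_rho, r2$null_rho)
  expect_identical(r1$perm_p, r2$perm_p)
  expect_gte(r1$perm_p, 1 / 100)
  expect_lte(r1$perm_p, 1)
  # permute-connectivity-only switch also runs and is reproducible
  r3 <- connectivity_accuracy_correlation(inf, gold, "gold", "d_pn",
                                          n_perm = 49, seed = 24,
                                          recompute_metrics = FALSE)
  expect_gte(r3$perm_p, 1 / 50)
})

test_that("significant-correlation counts respect global BH and bounds", {
  grid <- expand.grid(approach = c("m1", "m2"), dataset = c("d1", "d2"),
                      which = c("gold", "inferred"),
                      metric = c("d_ss", "d_pn"), stringsAsFactors = FALSE)
  grid$perm_p <- 1
  all_null <- significance_count_table(grid)
  expect_true(all(all_null$n_significant == 0))
  grid$perm_p <- 0.001
  all_floor <- significance_count_table(grid)
  expect_true(all(all_floor$n_significant == all_floor$n_datasets))
  expect_true(all(all_floor$n_significant <= all_floor$n_datasets))
  grid$perm_p[1] <- NA
  with_na <- significance_count_table(grid)
  expect_true(all(with_na$n_significant <= with_na$n_datasets))
})
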