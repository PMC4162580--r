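make_counts <- function(tp, fp, tn, fn) {
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 universe_size = tp + fp + tn + fn, universe_spec = "test"),
            class = "confusion_counts")
}

test_that("confusion counts follow the directed candidate universe", {
  gold <- directed_edge_set(data.frame(regulator = "A", target = "B", sign = "+"),
                            regulators = "A", universe = c("A", "B", "C"))
  inf <- undirected_network(data.frame(gene_a = c("A", "A"), gene_b = c("B", "C")),
                            universe = c("A", "B", "C"))
  cc <- confusion_counts(inf, gold)
  expect_equal(c(cc$tp, cc$fp, cc$fn, cc$tn), c(1, 1, 0, 0))
  m <- core_metrics(cc)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$ppv, 0.5)
  # empty inference: sensitivity 0, specificity 1
  cc0 <- confusion_counts(undirected_network(NULL, universe = c("A", "B", "C")),
                          gold)
  m0 <- core_metrics(cc0)
  expect_equal(m0$sensitivity, 0)
  expect_equal(m0$specificity, 1)
  # perfect reconstruction of the gold skeleton
  gold2 <- directed_edge_set(
    data.frame(regulator = "A", target = c("B", "C"), sign = "+"),
    regulators = "A", universe = c("A", "B", "C"))
  infp <- undirected_network(data.frame(gene_a = "A", gene_b = c("B", "C")))
  mp <- core_metrics(confusion_counts(infp, gold2))
  expect_equal(c(mp$sensitivity, mp$specificity, mp$ppv, mp$npv), c(1, NA, 1, NA))
  expect_setequal(mp$undefined, c("specificity", "npv"))
})

test_that("pairs between two regulators are predicted in both directions", {
  gold <- directed_edge_set(
    data.frame(regulator = c("A", "B"), target = c("B", "A"), sign = "+"),
    regulators = c("A", "B"), universe = c("A", "B", "C"))
  inf <- undirected_network(data.frame(gene_a = "A", gene_b = "B"),
                            universe = gold$universe)
  cc <- confusion_counts(inf, gold)
  expect_equal(cc$tp, 2)   # A->B and B->A both credited
  expect_equal(cc$universe_size, 4)
  # inferred pairs outside the universe are ignored
  inf2 <- undirected_network(data.frame(gene_a = c("A", "C"), gene_b = c("B", "D")),
                             universe = c("A", "B", "C", "D"))
  expect_equal(confusion_counts(inf2, gold)$fp, 0)
})

test_that("core metrics compute the four ratios with explicit undefined flags", {
  m <- core_metrics(make_counts(5, 5, 85, 5))
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 85 / 90)
  expect_equal(m$ppv, 0.5)
  expect_equal(m$npv, 85 / 90)
  expect_length(m$undefined, 0L)
  m2 <- core_metrics(make_counts(1, 1, 0, 0))
  expect_equal(m2$specificity, 0)
  expect_true(is.na(m2$npv))
  expect_identical(m2$undefined, "npv")
  m3 <- core_metrics(make_counts(3, 0, 7, 0))
  expect_equal(c(m3$sensitivity, m3$specificity, m3$ppv, m3$npv), rep(1, 4))
  expect_equal(c(m3$d_ss, m3$d_pn, m3$d_rp), rep(0, 3))
})

test_that("combined distance anchors and monotonicity hold", {
  expect_equal(combined_distance(1, 1), 0)
  expect_equal(combined_distance(0, 0), sqrt(2))
  expect_error(combined_distance(1.2, 0.5), "0, 1")
  grid <- seq(0, 1, by = 0.1)
  for (m2 in c(0.2, 0.7)) {
    d <- combined_distance(grid, m2)
    expect_true(all(diff(d) < 0))   # increasing m1 decreases the distance
  }
})

test_that("network significance matches brute-force enumeration", {
  brute <- function(N, K, m, k) {
    sum(vapply(k:min(K, m), function(i)
      choose(K, i) * choose(N - K, m - i) / choose(N, m), numeric(1)))
  }
  for (case in list(c(20, 5, 6, 2), c(30, 10, 8, 5), c(12, 4, 4, 0))) {
    N <- case[1]; K <- case[2]; m <- case[3]; k <- case[4]
    cc <- make_counts(tp = k, fp = m - k, fn = K - k, tn = N - K - (m - k))
    expect_equal(network_significance(cc), brute(N, K, m, k), tolerance = 1e-12)
  }
  # perfect recovery is the most significant cell possible
  best <- network_significance(make_counts(10, 0, 90, 0))
  worse <- network_significance(make_counts(9, 1, 89, 1))
  expect_lt(best, worse)
})

test_that("batch BH adjustment flags equal-p grids wholesale", {
  res <- batch_adjust(rep(0.01, 100))
  expect_true(all(res$significant))
  expect_equal(res$p_adjusted, rep(0.01, 100))
  mixed <- batch_adjust(c(0.0001, 0.5, 0.9))
  expect_identical(mixed$significant, c(TRUE, FALSE, FALSE))
})

test_that("Pareto frontier keeps optimal points and integrates correctly", {
  perfect <- pareto_roc(data.frame(sensitivity = 1, specificity = 1))
  expect_equal(perfect$auroc, 1)
  expect_equal(perfect$frontier,
               data.frame(fpr = c(0, 0, 1), tpr = c(0, 1, 1)))
  diag_pts <- data.frame(sensitivity = c(0.2, 0.5, 0.8),
                         specificity = c(0.8, 0.5, 0.2))
  expect_equal(pareto_roc(diag_pts)$auroc, 0.5)
  dom <- pareto_roc(data.frame(sensitivity = c(0.4, 0.5),
                               specificity = c(0.4, 0.6)))
  expect_false(any(dom$frontier$fpr == 0.6 & dom$frontier$tpr == 0.4))
  expect_true(any(dom$frontier$fpr == 0.4 & dom$frontier$tpr == 0.5))
  # Hanley-McNeil p only when counts are supplied, and small for good curves
  expect_true(is.na(dom$p_value))
  good <- pareto_roc(data.frame(sensitivity = 0.9, specificity = 0.9),
                     n_pos = 50, n_neg = 500)
  expect_lt(good$p_value, 1e-6)
})

test_that("frontier dominates subset frontiers and stays in [0, 1]", {
  set.seed(16)
  pts <- data.frame(sensitivity = runif(20), specificity = runif(20))
  roc <- pareto_roc(pts)
  expect_gte(roc$auroc, 0)
  expect_lte(roc$auroc, 1)
  fr <- roc$frontier
  for (i in 1:5) {
    sub_fr <- pareto_roc(pts[sample(20, 10), ])$frontier
    for (j in seq_len(nrow(sub_fr))) {
      expect_true(any(fr$fpr <= sub_fr$fpr[j] & fr$tpr >= sub_fr$tpr[j]))
    }
  }
  expect_true(all(diff(fr$fpr) >= 0))
  expect_true(all(diff(fr$tpr) >= 0))
})

test_that("metric tables average distances by method, dataset and data type", {
  grid <- expand.grid(approach = c("m1", "m2"), dataset = c("d1", "d2", "d3"),
                      stringsAsFactors = FALSE)
  grid$data_type <- ifelse(grid$dataset == "d3", "typeB", "typeA")
  grid$sensitivity <- c(0.5, 0.1, 0.6, 0.2, 0.7, 0.3)
  grid$specificity <- c(0.9, 0.95, 0.8, 0.9, 0.7, 0.85)
  grid$significant <- c(TRUE, rep(FALSE, 5))
  tab <- metrics_table(grid, c("sensitivity", "specificity"))
  d <- combined_distance(grid$sensitivity, grid$specificity)
  expect_equal(unname(tab$method_avg["m1"]), round(mean(d[grid$approach == "m1"]), 2))
  expect_equal(unname(tab$dataset_avg["d2"]), round(mean(d[grid$dataset == "d2"]), 2))
  expect_equal(unname(tab$datatype_avg["typeA"]),
               round(mean(d[grid$data_type == "typeA"]), 2))
  expect_match(tab$values$d1[1], "^0\\.50\\|0\\.90\\*$")   # significance marker
  # single-cell grid: averages equal the cell
  one <- metrics_table(grid[1, ], c("sensitivity", "specificity"))
  expect_equal(unname(one$method_avg), round(d[1], 2))
  expect_equal(unname(one$dataset_avg), round(d[1], 2))
  # incomplete grids fail loudly, naming the hole
  expect_error(metrics_table(grid[-2, ], c("sensitivity", "specificity")),
               "missing cells.*m2 d1")
})
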