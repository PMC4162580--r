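test_that("exactly the eighteen benchmark approach configurations are valid", {
  specs <- benchmark_approaches()
  expect_length(specs, 18L)
  expect_equal(anyDuplicated(names(specs)), 0L)
  expect_setequal(
    names(specs)[vapply(specs, function(s) s$max_k == 0, logical(1))],
    c("BIVARIATE_Z_FDR_AND", "BIVARIATE_Z_FDR_OR", "BIVARIATE_Z_ALPHA",
      "BIVARIATE_G_FDR_AND", "BIVARIATE_G_FDR_OR", "BIVARIATE_G_ALPHA"))
  expect_error(inference_spec("fisher_z", 0, "alpha", "AND"), "symmetric")
  expect_error(inference_spec("fisher_z", 0, "fdr", "none"), "asymmetric")
  expect_error(inference_spec("fisher_z", 2, "fdr", "AND"), "alpha")
  expect_error(inference_spec("fisher_z", 1, "alpha", "none"), "AND")
  expect_error(inference_spec("fisher_z", 5, "alpha", "AND"))
})

test_that("bivariate screening finds the dependent pair and only it", {
  set.seed(6)
  xv <- rnorm(1000)
  x <- rbind(X = xv, Y = xv + rnorm(1000, sd = 0.2), Z = rnorm(1000))
  # stringent alpha so that the d-separation-oracle answer {X, Y} is also
  # the overwhelmingly probable finite-sample answer
  net <- bivariate_screen(x, inference_spec("fisher_z", 0, "alpha", "none",
                                            alpha_level = 0.001))
  expect_identical(net$pairs,
                   data.frame(gene_a = "X", gene_b = "Y"))
})

test_that("bivariate alpha keeps about alpha of independent pairs", {
  set.seed(7)
  x <- matrix(rnorm(20 * 500), 20, 500,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  net <- bivariate_screen(x, inference_spec("fisher_z", 0, "alpha", "none"))
  frac <- n_edges(net) / choose(20, 2)
  expect_lt(abs(frac - 0.05), 0.035)
  expect_error(bivariate_screen(x[, 1:3],
                                inference_spec("fisher_z", 0, "alpha", "none")),
               "samples")
})

test_that("FDR-OR networks contain FDR-AND networks", {
  w <- synthetic_world(generate_true_network(20, 4, 2, seed = 8),
                       noise_sd = 0.4, seed = 8)
  x <- simulate_expression(w, "compendium", 120, seed = 9)
  for (test in c("fisher_z", "g2")) {
    and_net <- run_approach(x, inference_spec(test, 0, "fdr", "AND"))
    or_net <- run_approach(x, inference_spec(test, 0, "fdr", "OR"))
    ka <- paste(and_net$pairs$gene_a, and_net$pairs$gene_b)
    ko <- paste(or_net$pairs$gene_a, or_net$pairs$gene_b)
    expect_true(all(ka %in% ko))
  }
})

test_that("neighbour-list assembly follows the AND/OR definitions", {
  m <- list(X = "Y", Y = character(), Z = character())
  expect_equal(n_edges(assemble_network(m, "AND")), 0L)
  expect_identical(assemble_network(m, "OR")$pairs,
                   data.frame(gene_a = "X", gene_b = "Y"))
  sym <- list(X = "Y", Y = "X", Z = character())
  expect_identical(assemble_network(sym, "AND")$pairs,
                   assemble_network(sym, "OR")$pairs)
  # AND subset of OR on arbitrary maps
  m2 <- list(a = c("b", "c"), b = "a", c = character(), d = "c")
  ka <- with(assemble_network(m2, "AND")$pairs, paste(gene_a, gene_b))
  ko <- with(assemble_network(m2, "OR")$pairs, paste(gene_a, gene_b))
  expect_true(all(ka %in% ko))
})

test_that("GLL recovers chain and collider local structure", {
  x <- simulate_expression(chain_world(noise_sd = 0.5), "replicates", 2000,
                           seed = 10)
  expect_identical(gll_neighbors(x, "g002", "fisher_z", max_k = 1),
                   c("g001", "g003"))
  expect_identical(gll_neighbors(x, "g001", "fisher_z", max_k = 1), "g002")
  xc <- simulate_expression(collider_world(noise_sd = 0.5), "replicates", 2000,
                            seed = 11)
  expect_identical(gll_neighbors(xc, "g003", "fisher_z", max_k = 1),
                   c("g001", "g002"))
  expect_false("g002" %in% gll_neighbors(xc, "g001", "fisher_z", max_k = 1))
  expect_error(gll_neighbors(x, "nope", "fisher_z"), "not in data")
})

test_that("GLL with a d-separation oracle recovers the exact skeleton", {
  # Per-gene outputs may contain extra non-adjacent genes whose separating
  # sets lie outside the target's neighbour set (the classic local-search
  # asymmetry); they can never miss a true neighbour, and the AND
  # symmetrization removes every false positive.
  for (seed in 1:5) {
    net <- generate_true_network(8, 8, 1.5, seed = seed)
    x <- matrix(0, 8, 10, dimnames = list(net$universe, NULL))  # data unused
    oracle <- dsep_oracle(net)
    nb <- lapply(net$universe, function(g) gll_neighbors(x, g, oracle, max_k = 6))
    names(nb) <- net$universe
    for (g in net$universe) {
      expect_true(all(adjacency_of(net, g) %in% nb[[g]]))
    }
    skel <- assemble_network(nb, "AND")
    expect_identical(paste(skel$pairs$gene_a, skel$pairs$gene_b),
                     skeleton_keys(net))
  }
})

test_that("run_approach dispatches, is deterministic, and nests within bivariate", {
  w <- synthetic_world(generate_true_network(15, 3, 2, seed = 12),
                       noise_sd = 0.4, seed = 12)
  x <- simulate_expression(w, "compendium", 150, seed = 13)
  spec_biv <- inference_spec("fisher_z", 0, "alpha", "none")
  expect_identical(run_approach(x, spec_biv)$pairs,
                   bivariate_screen(x, spec_biv)$pairs)
  biv_keys <- with(bivariate_screen(x, spec_biv)$pairs, paste(gene_a, gene_b))
  for (comb in c("AND", "OR")) {
    gll <- run_approach(x, inference_spec("fisher_z", 1, "alpha", comb))
    expect_true(all(paste(gll$pairs$gene_a, gll$pairs$gene_b) %in% biv_keys))
  }
  expect_identical(run_approach(x, inference_spec("fisher_z", 2, "alpha", "AND")),
                   run_approach(x, inference_spec("fisher_z", 2, "alpha", "AND")))
})

test_that("all eighteen approaches run on a 20-gene dataset", {
  w <- synthetic_world(generate_true_network(20, 4, 2, seed = 14),
                       noise_sd = 0.4, seed = 14)
  x <- simulate_expression(w, "perturbation", 60, seed = 15)
  for (spec in benchmark_approaches()) {
    net <- run_approach(x, spec)
    expect_s3_class(net, "undirected_network")
    expect_identical(net$universe, w$genes)
  }
})

test_that("deeper conditioning never adds edges under AND assembly", {
  w <- synthetic_world(generate_true_network(15, 15, 1.2, seed = 3),
                       noise_sd = 1, seed = 3)
  x <- simulate_expression(w, "replicates", 500, seed = 4)
  keys <- lapply(1:3, function(k) {
    net <- run_approach(x, inference_spec("fisher_z", k, "alpha", "AND"))
    paste(net$pairs$gene_a, net$pairs$gene_b)
  })
  expect_true(all(keys[[2]] %in% keys[[1]]))
  expect_true(all(keys[[3]] %in% keys[[2]]))
})
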