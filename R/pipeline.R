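#' Run the full benchmark grid on a synthetic world
#'
#' End-to-end driver: generates a ground-truth TF network and the four
#' study-design expression datasets, simulates mutant differential
#' expression and binding scores, builds the three nested gold standards
#' (regulatory evidence intersected with each binding stringency), runs the
#' selected inference approaches on every dataset, evaluates every
#' (gold standard, approach, dataset) cell with core and combined metrics,
#' adjusts the hypergeometric network p-values by Benjamini-Hochberg over
#' the whole grid, summarizes sensitivity/specificity pairs with a
#' Pareto-frontier ROC (overall and per data type), and tests the TF
#' connectivity-accuracy correlation for every inferred network against the
#' most conservative gold standard.
#'
#' All randomness derives from `config$seed`. With identical configuration
#' the result is identical, including any files written.
#'
#' @param config a `run_config` from [read_run_config()].
#' @param write_outputs write TSV artifacts (networks, per-cell metrics,
#'   summary tables, Pareto frontier, correlation counts) under
#'   `config$out_dir`.
#' @param verbose log per-stage progress with timings.
#' @return A list of class `benchmark_result`: `world`, `gold_standards`
#'   (list of 3 `directed_edge_set`s), `networks` (nested list
#'   dataset -> approach), `cells` (long data.frame of per-cell metrics and
#'   significance), `tables` (per gold standard, `metrics_table` objects
#'   for the three metric pairs), `pareto` (overall and per-design
#'   `pareto_roc` against gold standard 1), `subnet` (correlation grid and
#'   [significance_count_table()] output).
#' @examples
#' \donttest{
#' cfg <- read_run_config(overrides = list(n_genes = 20L, n_tfs = 3L,
#'   approaches = c("BIVARIATE_Z_ALPHA", "GLL_Z_1_AND"), n_perm = 20L))
#' res <- run_benchmark(cfg, write_outputs = FALSE)
#' res$cells[1:3, ]
#' }
#' @export
run_benchmark <- function(config = read_run_config(), write_outputs = TRUE,
                          verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_stage <- function(...) {
    if (verbose) message(sprintf("[%5.1fs] ", as.numeric(Sys.time() - t0)), ...)
  }
  seed <- as.integer(config$seed)

  log_stage("simulating world (", config$n_genes, " genes, ",
            config$n_tfs, " TFs, seed ", seed, ")")
  net <- generate_true_network(config$n_genes, config$n_tfs,
                               config$mean_out_degree, seed = seed)
  world <- synthetic_world(net, noise_sd = config$noise_sd, seed = seed)

  datasets <- list()
  for (i in seq_along(config$designs)) {
    d <- config$designs[i]
    datasets[[d]] <- simulate_expression(world, d, config$n_samples,
                                         seed = seed + 100L + i)
  }

  log_stage("building gold standards")
  de <- simulate_mutant_pvalues(world, config$n_wt, config$n_mut,
                                seed = seed + 200L)
  regulatory <- build_regulatory_network(de, config$fdr_level,
                                         universe = world$genes)
  binding <- simulate_binding(world, config$fnr, config$fpr,
                              seed = seed + 300L)
  gold_standards <- suppressWarnings(list(
    gs1 = intersect_networks(regulatory, binding$conservative),
    gs2 = intersect_networks(regulatory, binding$intermediate),
    gs3 = intersect_networks(regulatory, binding$liberal)))

  specs <- benchmark_approaches(config$alpha_level)[config$approaches]
  networks <- list()
  for (d in names(datasets)) {
    networks[[d]] <- list()
    tern <- discretize_ternary(datasets[[d]])
    # pairwise test matrices are shared by every approach using the same test
    pw <- list()
    for (a in names(specs)) {
      log_stage("inferring ", a, " on ", d)
      test <- specs[[a]]$test
      input <- if (test == "g2") tern else datasets[[d]]
      if (is.null(pw[[test]])) pw[[test]] <- pairwise_tests(input, test)
      networks[[d]][[a]] <- run_approach(input, specs[[a]], pairwise = pw[[test]])
    }
  }

  log_stage("evaluating ", length(gold_standards) * length(datasets) *
              length(specs), " cells")
  cells <- list()
  for (g in names(gold_standards)) {
    for (d in names(datasets)) {
      for (a in names(specs)) {
        cc <- confusion_counts(networks[[d]][[a]], gold_standards[[g]])
        ms <- core_metrics(cc)
        cells[[length(cells) + 1L]] <- data.frame(
          gold = g, approach = a, dataset = d, data_type = d,
          tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
          sensitivity = ms$sensitivity, specificity = ms$specificity,
          ppv = ms$ppv, npv = ms$npv,
          d_ss = ms$d_ss, d_pn = ms$d_pn, d_rp = ms$d_rp,
          p_value = network_significance(cc),
          stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, cells)
  adj <- batch_adjust(cells$p_value, config$alpha_level)
  cells$p_adjusted <- adj$p_adjusted
  cells$significant <- adj$significant

  tables <- lapply(split(cells, cells$gold), function(block) {
    list(sens_spec = metrics_table(block, c("sensitivity", "specificity")),
         ppv_npv = metrics_table(block, c("ppv", "npv")),
         recall_precision = metrics_table(block, c("sensitivity", "ppv")))
  })

  gs1_cells <- cells[cells$gold == "gs1", , drop = FALSE]
  n_pos <- gs1_cells$tp[1] + gs1_cells$fn[1]
  n_neg <- gs1_cells$tn[1] + gs1_cells$fp[1]
  pareto <- list(overall = pareto_roc(gs1_cells, n_pos, n_neg))
  for (d in unique(gs1_cells$dataset)) {
    pareto[[d]] <- pareto_roc(gs1_cells[gs1_cells$dataset == d, ],
                              n_pos, n_neg)
  }

  log_stage("TF connectivity/accuracy correlations (",
            config$n_perm, " permutations)")
  subnet_rows <- list()
  for (d in names(datasets)) {
    for (a in names(specs)) {
      for (w in c("gold", "inferred")) {
        for (m in c("d_ss", "d_pn", "d_rp")) {
          rep_ <- connectivity_accuracy_correlation(
            networks[[d]][[a]], gold_standards$gs1, which = w, metric = m,
            n_perm = config$n_perm, seed = seed + 400L)
          subnet_rows[[length(subnet_rows) + 1L]] <- data.frame(
            approach = a, dataset = d, which = w, metric = m,
            rho = rep_$rho, perm_p = rep_$perm_p, stringsAsFactors = FALSE)
        }
      }
    }
  }
  subnet_grid <- do.call(rbind, subnet_rows)
  subnet <- list(grid = subnet_grid,
                 counts = significance_count_table(subnet_grid,
                                                   config$alpha_level))

  result <- structure(list(config = config, world = world,
                           gold_standards = gold_standards,
                           networks = networks, cells = cells,
                           tables = tables, pareto = pareto, subnet = subnet),
                      class = "benchmark_result")
  if (write_outputs) {
    log_stage("writing outputs to ", config$out_dir)
    write_benchmark_outputs(result, config$out_dir)
  }
  log_stage("done")
  result
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark run: %d genes, %d approaches, %d datasets, %d gold standards\n",
              x$world$n_genes, length(x$config$approaches),
              length(x$networks), length(x$gold_standards)))
  cat(sprintf("Overall Pareto AUROC (gold standard 1): %.3f\n",
              x$pareto$overall$auroc))
  invisible(x)
}

# Write every grid artifact as TSV under `dir`.
write_benchmark_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  for (g in names(result$gold_standards)) {
    write_edges_tsv(result$gold_standards[[g]],
                    file.path(dir, paste0("gold_", g, ".tsv")))
    export_sif(result$gold_standards[[g]],
               file.path(dir, paste0("gold_", g, ".sif")))
  }
  for (d in names(result$networks)) {
    for (a in names(result$networks[[d]])) {
      write_edges_tsv(result$networks[[d]][[a]],
                      file.path(dir, sprintf("inferred_%s_%s.tsv", d, a)))
    }
  }
  wt(result$cells, "cell_metrics.tsv")
  for (g in names(result$tables)) {
    for (p in names(result$tables[[g]])) {
      tab <- result$tables[[g]][[p]]
      wt(tab$values, sprintf("table_%s_%s_values.tsv", g, p))
      wt(tab$distances, sprintf("table_%s_%s_distance.tsv", g, p))
      wt(data.frame(approach = names(tab$method_avg),
                    mean_distance = as.numeric(tab$method_avg)),
         sprintf("table_%s_%s_method_avg.tsv", g, p))
      wt(data.frame(dataset = names(tab$dataset_avg),
                    mean_distance = as.numeric(tab$dataset_avg)),
         sprintf("table_%s_%s_dataset_avg.tsv", g, p))
    }
  }
  wt(result$pareto$overall$frontier, "pareto_frontier.tsv")
  auroc <- data.frame(scope = names(result$pareto),
                      auroc = vapply(result$pareto, function(p) p$auroc,
                                     numeric(1)),
                      p_value = vapply(result$pareto, function(p) p$p_value,
                                       numeric(1)))
  wt(auroc, "pareto_auroc.tsv")
  wt(result$subnet$grid, "subnet_correlations.tsv")
  wt(result$subnet$counts, "subnet_significance_counts.tsv")
  invisible(dir)
}
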