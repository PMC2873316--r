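test_that("simulation_config validates itself", {
  expect_s3_class(simulation_config(), "simulation_config")
  expect_error(simulation_config(n_nodes = 20, n_planted_targets = 50),
               class = "netreg_validation_error")
  expect_error(simulation_config(class_props = c(ligand = 1)),
               class = "netreg_validation_error")
  expect_error(simulation_config(n_pairs = 1),
               class = "netreg_validation_error")
})

test_that("generate_network obeys the stated world", {
  cfg <- simulation_config(n_nodes = 150, seed = 3)
  sim <- generate_network(cfg)
  net <- sim$network
  # seed reproducibility
  sim2 <- generate_network(cfg)
  expect_identical(net$edges, sim2$network$edges)
  expect_identical(sim$truth$planted_targets, sim2$truth$planted_targets)
  # class-respecting edges
  for (i in seq_len(nrow(net$edges))) {
    src_cls <- net$node_class[net$edges$source[i]]
    tgt_cls <- net$node_class[net$edges$target[i]]
    expect_true(switch(src_cls,
      ligand = tgt_cls == "receptor",
      receptor = tgt_cls %in% c("kinase", "transcription_factor"),
      kinase = tgt_cls %in% c("kinase", "transcription_factor"),
      transcription_factor = tgt_cls == "generic",
      FALSE))
  }
  # TF edges are transcription regulation
  tf_rows <- net$node_class[net$edges$source] == "transcription_factor"
  expect_true(all(net$edges$mechanism[tf_rows] == "transcription_regulation"))
  # degree-sum invariant
  degs <- vapply(net$nodes, function(v) node_degree(net, v), integer(1))
  expect_identical(sum(degs), 2L * n_interactions(net))
  # cascade is inside the network
  key <- function(e) paste(e$source, e$target, e$effect, e$mechanism)
  expect_true(all(key(sim$truth$cascade_edges) %in% key(net$edges)))
  # planted target fold changes exceed 1
  expect_true(all(sim$truth$planted_fold_changes > 1))
})

test_that("every planted target is reachable by an even-parity activation
           path from every planted receptor", {
  for (seed in c(1, 2)) {
    cfg <- simulation_config(seed = seed)
    sim <- generate_network(cfg)
    idx <- build_path_index(sim$network,
                            targets = sim$truth$planted_targets)
    expect_setequal(idx$targets, sim$truth$planted_targets)
    for (rec in sim$truth$planted_receptors) {
      expect_true(all(idx$containment[rec, sim$truth$planted_targets] > 0))
    }
  }
})

test_that("zero inhibition probability gives an all-activation network", {
  cfg <- simulation_config(n_nodes = 80, inhibition_prob = 0, seed = 2)
  sim <- generate_network(cfg)
  expect_true(all(sim$network$edges$effect == "activation"))
})

test_that("expression generator: dimensions, noiseless limit, calibration", {
  cfg <- simulation_config(n_nodes = 60, n_pairs = 6,
                           n_planted_targets = 4, seed = 4)
  sim <- generate_network(cfg)
  x <- generate_expression(sim$truth, cfg)
  expect_identical(dim(x$values), c(60L, 12L))
  expect_identical(nrow(x$pair_map), 6L)

  # noiseless limit: per-pair ratio equals the planted fold change exactly
  cfg0 <- simulation_config(n_nodes = 60, n_pairs = 4, n_planted_targets = 4,
                            noise_sd = 0, pair_effect_sd = 0,
                            log2fc_sd = 0, log2fc_mean = 2, seed = 4)
  sim0 <- generate_network(cfg0)
  x0 <- generate_expression(sim0$truth, cfg0)
  g <- sim0$truth$planted_targets[1]
  ratio <- x0$values[g, x0$pair_map$lesional] /
    x0$values[g, x0$pair_map$nonlesional]
  expect_equal(unname(ratio), rep(4, 4), tolerance = 1e-12)

  # per-pair log2 difference is centred on the planted log2 FC (3 SE)
  cfgN <- simulation_config(n_nodes = 30, n_pairs = 1000,
                            n_planted_targets = 2, noise_sd = 0.5,
                            pair_effect_sd = 0, log2fc_sd = 0, seed = 9)
  simN <- generate_network(cfgN)
  xN <- generate_expression(simN$truth, cfgN)
  gN <- simN$truth$planted_targets[1]
  d <- log2(xN$values[gN, xN$pair_map$lesional]) -
    log2(xN$values[gN, xN$pair_map$nonlesional])
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 2), 3 * se)
})

test_that("degenerate FC at 1 yields only ~q-level false positives", {
  fp <- vapply(1:25, function(seed) {
    cfg <- simulation_config(n_nodes = 120, log2fc_mean = 0, log2fc_sd = 0,
                             overexpress_regulators = FALSE, seed = seed)
    sim <- generate_network(cfg)
    x <- generate_expression(sim$truth, cfg)
    de <- paired_de_test(median_normalize(x))
    mean(de$q_value < 0.01)
  }, numeric(1))
  expect_lte(mean(fp), 0.02)
})

test_that("recovery_report computes ranks and precision/recall", {
  cfg <- simulation_config(n_nodes = 100, seed = 10)
  sim <- generate_network(cfg)
  s <- gene_set("t", sim$truth$planted_targets)
  tfr <- rank_hidden_nodes(sim$network, s, "transcription_factor")
  rep <- recovery_report(sim$truth,
                         de_set = gene_set("de", c(
                           sim$truth$planted_targets[1:10], "GEN999x")),
                         tf_ranking = tfr)
  expect_equal(rep$de$recall, 10 / length(sim$truth$planted_targets))
  expect_equal(rep$de$precision, 10 / 11)
  expect_true(all(!is.na(rep$tf_ranks)))
  # perfect and empty cases
  perfect <- recovery_report(sim$truth,
                             de_set = gene_set("de", sim$truth$planted_targets))
  expect_equal(perfect$de$precision, 1)
  expect_equal(perfect$de$recall, 1)
  empty <- recovery_report(sim$truth, de_set = gene_set("de", character()))
  expect_true(is.na(empty$de$precision))
  expect_equal(empty$de$recall, 0)
})

test_that("write_simulation emits a complete plain-text scenario", {
  td <- withr::local_tempdir()
  cfg <- simulation_config(n_nodes = 50, n_pairs = 4,
                           n_planted_targets = 5, seed = 12)
  out <- write_simulation(cfg, td)
  for (f in c("network_edges.tsv", "node_classes.tsv",
              "planted_targets.gmt", "expression.tsv", "pair_map.tsv",
              "ground_truth.json")) {
    expect_true(file.exists(file.path(td, f)))
  }
  back <- read_network(file.path(td, "network_edges.tsv"),
                       file.path(td, "node_classes.tsv"))
  expect_identical(n_interactions(back), n_interactions(out$network))
  gt <- jsonlite::read_json(file.path(td, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_setequal(gt$planted_targets, out$truth$planted_targets)
})
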