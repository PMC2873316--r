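test_that("chain fixture: 4 activation paths to T, K contained in 3", {
  net <- chain_network()
  idx <- build_path_index(net, keep_paths = TRUE)
  expect_identical(idx$n_paths, 4L)
  expect_identical(unname(idx$per_target["T"]), 4L)
  expect_identical(sum(idx$containment["K", ]), 3L)
  expect_identical(sum(idx$containment["T", ]), 4L)  # terminal counts
  expect_identical(sum(idx$containment["L", ]), 1L)
  lens <- sort(vapply(idx$paths, length, integer(1)) - 1L)
  expect_identical(lens, c(1L, 2L, 3L, 4L))
})

test_that("parity even excludes exactly the paths through one inhibition", {
  net <- chain_network(k_tf_effect = "inhibition")
  idx <- build_path_index(net, keep_paths = TRUE)
  # only the single-edge TF -> T path survives
  expect_identical(idx$n_paths, 1L)
  expect_identical(unlist(idx$paths), c("TF", "T"))
  # the literal odd-parity reading recovers the excluded three
  odd <- build_path_index(net, parity = "odd")
  expect_identical(odd$n_paths, 3L)
})

test_that("all equal-length shortest paths are enumerated", {
  net <- interaction_network(rbind(
    edge_df("S", c("A", "B")),
    edge_df(c("A", "B"), "TF"),
    edge_df("TF", "T", mechanism = "transcription_regulation")),
    node_class = c(TF = "transcription_factor"))
  idx <- build_path_index(net)
  # sources: S (2 parallel shortest), A, B, TF
  expect_identical(idx$n_paths, 5L)
  expect_identical(sum(idx$containment["S", ]), 2L)
})

test_that("parallel edges of different sign count as distinct paths", {
  net <- interaction_network(rbind(
    edge_df("TF", "T", effect = "activation",
            mechanism = "transcription_regulation"),
    edge_df("TF", "T", effect = "inhibition",
            mechanism = "transcription_regulation")),
    node_class = c(TF = "transcription_factor"))
  expect_identical(build_path_index(net)$n_paths, 1L)
  expect_identical(build_path_index(net, parity = "odd")$n_paths, 1L)
})

test_that("unspecified effects count as activating; can be excluded", {
  net <- interaction_network(rbind(
    edge_df("K", "TF", effect = "unspecified"),
    edge_df("TF", "T", mechanism = "transcription_regulation")),
    node_class = c(K = "kinase", TF = "transcription_factor"))
  expect_identical(build_path_index(net)$n_paths, 2L)
  expect_identical(build_path_index(net, exclude_unspecified = TRUE)$n_paths,
                   1L)
})

test_that("index matches the brute-force enumerator on random networks", {
  for (seed in c(1:15, 77)) {
    net <- random_small_network(seed)
    idx <- suppressWarnings(build_path_index(net))  # some nets have 0 paths
    bf <- brute_force_path_index(net)
    expect_identical(idx$n_paths, bf$n_paths)
    expect_identical(idx$per_target, bf$per_target)
    expect_identical(idx$containment, bf$containment)
  }
})

test_that("every indexed path satisfies the admissibility predicates", {
  net <- random_small_network(3)
  idx <- build_path_index(net, keep_paths = TRUE)
  expect_gt(idx$n_paths, 0)
  e <- net$edges
  for (i in seq_along(idx$paths)) {
    p <- idx$paths[[i]]
    expect_identical(p[length(p)], idx$path_target[i])
    expect_lte(length(p) - 1L, idx$max_len)
    expect_gt(length(p), 1L)
    # a terminal TR-from-TF edge exists
    last_ok <- any(e$source == p[length(p) - 1] & e$target == p[length(p)] &
                     e$mechanism == "transcription_regulation" &
                     net$node_class[p[length(p) - 1]] ==
                       "transcription_factor")
    expect_true(last_ok)
    # some edge realisation of the node sequence has even inhibition parity
    expect_true(any(vapply(seq_len(length(p) - 1), function(j) {
      any(e$source == p[j] & e$target == p[j + 1])
    }, logical(1))))
  }
})

test_that("hidden_node_pvalue degenerate cases", {
  net <- chain_network()
  idx <- build_path_index(net)
  # targets = all terminals: R = N so p = 1 everywhere
  for (v in net$nodes) {
    expect_identical(hidden_node_pvalue(idx, v, idx$targets), 1)
  }
  # node on no path
  net2 <- interaction_network(rbind(
    net$edges, edge_df("K", "DEAD")), node_class = net$node_class)
  idx2 <- build_path_index(net2)
  expect_identical(hidden_node_pvalue(idx2, "DEAD", "T"), 1)
})

test_that("two-layer network: only regulators of the set are significant", {
  # TF1 -> targets in s, TF2 -> other genes
  net <- interaction_network(rbind(
    edge_df("TF1", c("a1", "a2", "a3"),
            mechanism = "transcription_regulation"),
    edge_df("TF2", c("b1", "b2", "b3"),
            mechanism = "transcription_regulation")),
    node_class = c(TF1 = "transcription_factor",
                   TF2 = "transcription_factor"))
  idx <- build_path_index(net)
  s <- c("a1", "a2", "a3")
  expect_identical(hidden_node_pvalue(idx, "TF2", s), 1)
  expect_lt(hidden_node_pvalue(idx, "TF1", s), 0.1)
})

test_that("p-value agrees with a target-label permutation oracle", {
  # two-layer star forest: every terminal carries exactly one path (its TR
  # edge), so shuffling target labels over terminals IS the hypergeometric
  # draw over paths and the oracle is exact in distribution
  tfs <- sprintf("TF%02d", 1:3)
  terminals <- sprintf("T%02d", 1:18)
  e <- rbind(edge_df(tfs[1], terminals[1:6],
                     mechanism = "transcription_regulation"),
             edge_df(tfs[2], terminals[7:12],
                     mechanism = "transcription_regulation"),
             edge_df(tfs[3], terminals[13:18],
                     mechanism = "transcription_regulation"))
  net <- interaction_network(
    e, setNames(rep("transcription_factor", 3), tfs))
  idx <- build_path_index(net)
  expect_identical(idx$n_paths, 18L)
  s <- terminals[c(1:3, 7)]    # 3 of TF01's targets + 1 of TF02's
  p <- hidden_node_pvalue(idx, "TF01", s)
  pr <- netreg:::hidden_node_params(idx, "TF01", s)
  expect_identical(unlist(pr), c(r = 3L, R = 4L, n = 6L, N = 18L))
  B <- 10000
  phat <- withr::with_seed(11, {
    on_path <- idx$containment["TF01", ] > 0
    mean(vapply(seq_len(B), function(i) {
      sum(on_path[sample(18, length(s))]) >= pr$r
    }, logical(1)))
  })
  se <- sqrt(max(p * (1 - p), phat * (1 - phat)) / B)
  expect_lte(abs(p - phat), 2 * se + 1 / B)
})

test_that("rank_hidden_nodes recovers a planted cascade receptor", {
  wins <- vapply(1:10, function(seed) {
    cfg <- simulation_config(n_nodes = 150, seed = seed)
    sim <- generate_network(cfg)
    rl <- rank_hidden_nodes(sim$network,
                            gene_set("t", sim$truth$planted_targets),
                            "receptor")
    all(match(sim$truth$planted_receptors, rl$node) <= 10)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
  # structural contract
  cfg <- simulation_config(n_nodes = 100, seed = 1)
  sim <- generate_network(cfg)
  s <- gene_set("t", sim$truth$planted_targets)
  rl <- rank_hidden_nodes(sim$network, s, "receptor")
  expect_setequal(rl$node, nodes_of_class(sim$network, "receptor"))
  one <- rank_hidden_nodes(sim$network, s,
                           nodes_of_class(sim$network, "receptor")[1])
  expect_identical(nrow(one), 1L)
  expect_error(rank_hidden_nodes(sim$network, s, character()),
               class = "netreg_validation_error")
})

test_that("empty scope warns and yields p = 1 downstream", {
  net <- interaction_network(edge_df("A", "B"))
  expect_warning(idx <- build_path_index(net), "no admissible")
  expect_identical(hidden_node_pvalue(idx, "A", "B"), 1)
})
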