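fixture_net <- function() {
  interaction_network(rbind(
    edge_df("LigA", "R1"),
    edge_df("LigB", "R2"),
    edge_df("R1", "K1"), edge_df("K1", "TF1"),
    edge_df("R1", "K2"), edge_df("K2", "TF1"),   # two equal-length routes
    edge_df("R2", "K3"),                         # dead end, no TF
    edge_df("TF1", c("t1", "t2"), mechanism = "transcription_regulation"),
    edge_df("TF2", "t3", mechanism = "transcription_regulation"),
    edge_df("TF3", "x1"),                        # TR-less "TF"
    edge_df("TF2", "K3")),
    node_class = c(LigA = "ligand", LigB = "ligand", R1 = "receptor",
                   R2 = "receptor", K1 = "kinase", K2 = "kinase",
                   K3 = "kinase", TF1 = "transcription_factor",
                   TF2 = "transcription_factor",
                   TF3 = "transcription_factor"))
}

test_that("select_direct_tfs applies the TR-edge predicate", {
  net <- fixture_net()
  s <- gene_set("s", c("t1", "t3", "x1"))
  # TF3 -> x1 has mechanism other: not selected; TF1, TF2 are
  expect_identical(select_direct_tfs(net, s), c("TF1", "TF2"))
  expect_identical(select_direct_tfs(net, gene_set("s", "x1")), character(0))
})

test_that("select_receptors_by_ligand needs a ligand-class in-neighbour", {
  net <- fixture_net()
  expect_identical(select_receptors_by_ligand(net, gene_set("s", "LigA")),
                   "R1")
  # K1 -> TF1 source is not ligand class; t1 has no receptor out-edge
  expect_identical(select_receptors_by_ligand(net, gene_set("s", "K1")),
                   character(0))
  expect_identical(
    select_receptors_by_ligand(net, gene_set("s", c("LigA", "LigB"))),
    c("R1", "R2"))
})

test_that("build_receptor_network keeps all shortest paths plus set targets", {
  net <- fixture_net()
  s <- gene_set("s", c("t1", "t2"))
  sn <- build_receptor_network(net, "R1", tfs = "TF1", s = s)
  # both equal-length branches K1/K2 retained, plus TF targets in s
  expect_setequal(sn$nodes, c("R1", "K1", "K2", "TF1", "t1", "t2"))
  expect_identical(sn$kind, "receptor_series")
  expect_true(all(sn$edges$source %in% sn$nodes &
                    sn$edges$target %in% sn$nodes))
  # unreachable TF contributes nothing / skipped entirely
  expect_message(
    expect_null(build_receptor_network(net, "R2", tfs = "TF1", s = s)),
    "skipped")
  sn2 <- build_receptor_network(net, "R1", tfs = c("TF1", "TF2"), s = s)
  expect_setequal(sn2$nodes, sn$nodes)  # TF2 unreachable from R1
  expect_error(build_receptor_network(net, "nope", "TF1", s),
               class = "netreg_lookup_error")
})

test_that("receptor-network edges lie on admissible paths or target layer", {
  net <- fixture_net()
  s <- gene_set("s", c("t1", "t2"))
  sn <- build_receptor_network(net, "R1", tfs = "TF1", s = s)
  for (i in seq_len(nrow(sn$edges))) {
    src <- sn$edges$source[i]; tgt <- sn$edges$target[i]
    on_path <- src %in% c("R1", "K1", "K2") & tgt %in% c("K1", "K2", "TF1")
    tf_target <- src == "TF1" & tgt %in% s$members &
      sn$edges$mechanism[i] == "transcription_regulation"
    expect_true(on_path || tf_target)
  }
})

test_that("expand_tf_network grows greedily and deterministically", {
  net <- fixture_net()
  s <- gene_set("s", c("t1", "t2"))
  expect_identical(expand_tf_network(net, "TF1", s, size = 1)$nodes, "TF1")
  # set members adjacent to the seed join before any non-member
  sn3 <- expand_tf_network(net, "TF1", s, size = 3)
  expect_setequal(sn3$nodes, c("TF1", "t1", "t2"))
  # size larger than the component: whole connected component of the seed
  big <- expand_tf_network(net, "TF1", s, size = 100)
  expect_setequal(big$nodes, c("LigA", "R1", "K1", "K2", "TF1", "t1", "t2"))
  # determinism and the size cap
  for (size in c(2, 4, 6)) {
    a <- expand_tf_network(net, "TF1", s, size = size)
    b <- expand_tf_network(net, "TF1", s, size = size)
    expect_identical(a$nodes, b$nodes)
    expect_lte(length(a$nodes), size)
  }
})

test_that("greedy priority: set membership beats link count and name", {
  # frontier after {TF}: N1, Q (non-members), M1 (member): member joins first
  net <- interaction_network(rbind(
    edge_df("TF", c("N1", "M1"), mechanism = "transcription_regulation"),
    edge_df("N1", "Q"), edge_df("Q", "N1"),
    edge_df("Q", "TF")),
    node_class = c(TF = "transcription_factor"))
  sn <- expand_tf_network(net, "TF", gene_set("s", "M1"), size = 2)
  expect_setequal(sn$nodes, c("TF", "M1"))
})

test_that("enrichment_pvalue uses the node universe", {
  net <- fixture_net()
  s <- gene_set("s", c("t1", "t2", "t3", "x1"))
  sn <- enrichment_pvalue(expand_tf_network(net, "TF1", s, size = 3), s, net)
  # N = 14 nodes, n = 4, R = 3, r = 2 (t1, t2; TF1 not in s)
  expect_equal(sn$enrichment_p, hyper_tail_enum(2, 3, 4, 14),
               tolerance = 1e-12)
  # r = 0 case
  sn0 <- enrichment_pvalue(expand_tf_network(net, "TF3", s, size = 1), s, net)
  expect_identical(sn0$enrichment_p, 1)
  expect_error(
    enrichment_pvalue(structure(list(seed = "z", nodes = "zz",
                                     edges = net$edges[0, ],
                                     kind = "tf_expansion",
                                     enrichment_p = NA_real_,
                                     r = NA_integer_),
                                class = "subnetwork"), s, net),
    class = "netreg_validation_error")
})

test_that("rank_networks sorts by p, then larger r, then seed", {
  mk <- function(seed, p, r) {
    structure(list(seed = seed, nodes = "a", edges = NULL, kind = "x",
                   enrichment_p = p, r = r), class = "subnetwork")
  }
  out <- rank_networks(list(mk("s3", 0.5, 1), mk("s1", 0.1, 2),
                            mk("s2", 0.1, 3), mk("s4", 0.1, 3)))
  expect_identical(vapply(out, function(x) x$seed, character(1)),
                   c("s2", "s4", "s1", "s3"))
  expect_identical(rank_networks(list()), list())
  one <- rank_networks(list(mk("only", 0.2, 1)))
  expect_identical(length(one), 1L)
})
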