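# Fixtures built in code; no binary data anywhere.

edge_df <- function(source, target, effect = "activation",
                    mechanism = "other") {
  data.frame(source = source, target = target, effect = effect,
             mechanism = mechanism, stringsAsFactors = FALSE)
}

# 5-node all-activating cascade L -> R -> K -> TF -TR-> T
chain_network <- function(k_tf_effect = "activation") {
  interaction_network(
    edge_df(c("L", "R", "K", "TF"), c("R", "K", "TF", "T"),
            effect = c("activation", "activation", k_tf_effect,
                       "activation"),
            mechanism = c("other", "other", "other",
                          "transcription_regulation")),
    node_class = c(L = "ligand", R = "receptor", K = "kinase",
                   TF = "transcription_factor", T = "generic"))
}

# arbitrary random signed network (more adversarial than the class-ruled
# generator): <= n_max nodes, random classes, signs and mechanisms
random_small_network <- function(seed, n_max = 12) {
  withr::with_seed(seed, {
    n <- sample(4:n_max, 1)
    nodes <- sprintf("N%02d", seq_len(n))
    cls <- sample(c("ligand", "receptor", "kinase", "transcription_factor",
                    "generic"), n, replace = TRUE)
    pairs <- expand.grid(source = nodes, target = nodes,
                         stringsAsFactors = FALSE)
    pairs <- pairs[pairs$source != pairs$target, ]
    m <- min(nrow(pairs), rpois(1, 2.5 * n) + 2)
    pick <- pairs[sample(nrow(pairs), m), ]
    pick$effect <- sample(c("activation", "inhibition", "unspecified"), m,
                          replace = TRUE, prob = c(0.5, 0.3, 0.2))
    pick$mechanism <- sample(c("transcription_regulation", "other"), m,
                             replace = TRUE, prob = c(0.4, 0.6))
    interaction_network(pick, setNames(cls, nodes))
  })
}

# tiny paired expression matrix with chosen per-gene true fold changes
make_expression <- function(fc, n_pairs = 28, noise_sd = 0.3, seed = 1,
                            baseline = 100) {
  withr::with_seed(seed, {
    genes <- names(fc)
    non <- matrix(rlnorm(length(fc) * n_pairs, log(baseline), 1),
                  nrow = length(fc),
                  dimnames = list(genes, sprintf("P%02d_N", seq_len(n_pairs))))
    les <- non * 2^(log2(fc) + matrix(rnorm(length(fc) * n_pairs, 0, noise_sd),
                                      nrow = length(fc)))
    colnames(les) <- sprintf("P%02d_L", seq_len(n_pairs))
    paired_expression(cbind(les, non),
                      data.frame(lesional = colnames(les),
                                 nonlesional = colnames(non)))
  })
}

# forge a de_result honouring its documented data contract
fake_de_result <- function(gene, fold_change, q_value,
                           fc_threshold = 2.5, q_threshold = 0.01) {
  tab <- data.frame(gene = gene, fold_change = fold_change,
                    p_value = q_value, q_value = q_value,
                    passes = fold_change > fc_threshold &
                      q_value < q_threshold,
                    stringsAsFactors = FALSE)
  structure(tab, class = c("de_result", "data.frame"),
            fc_threshold = fc_threshold, q_threshold = q_threshold,
            method = "paired", direction = "up", n_pairs = 28L)
}

# fixture planting 2 receptor-only / 3 ligand-only / 1 both overexpressed
# receptors, all hidden-significant, plus one insignificant decoy:
# every receptor feeds K -> TF -TR-> targets so hidden-nodes p is small
# for receptors on many target paths.
classification_fixture <- function() {
  receptors <- sprintf("R%d", 1:7)   # R7 = decoy, no route to targets
  ligands <- sprintf("L%d", 1:7)
  targets <- sprintf("T%02d", 1:12)
  decoys <- sprintf("D%02d", 1:12)   # TR targets outside the set of interest
  e <- rbind(
    edge_df(ligands, receptors),                      # ligand -> receptor
    edge_df(receptors[1:6], "K1"),                    # receptors -> kinase
    edge_df("R7", "K2"),                              # decoy branch
    edge_df("K1", "TF1"),
    edge_df("K2", "TF2"),
    edge_df("TF1", targets, mechanism = "transcription_regulation"),
    edge_df("TF2", decoys, mechanism = "transcription_regulation"))
  cls <- c(setNames(rep("ligand", 7), ligands),
           setNames(rep("receptor", 7), receptors),
           K1 = "kinase", K2 = "kinase", TF1 = "transcription_factor",
           TF2 = "transcription_factor",
           setNames(rep("generic", 24), c(targets, decoys)))
  net <- interaction_network(e, cls)
  # overexpression plan: R1,R2 receptor_only; L3,L4,L5 ligand_only (their
  # receptors R3..R5); R6+L6 both; everything else flat
  de <- fake_de_result(
    gene = c(receptors, ligands, targets),
    fold_change = c(4, 4, 1, 1, 1, 4, 4,      # receptors (R7 oe but decoy)
                    1, 1, 4, 4, 4, 4, 1,      # ligands
                    rep(4, 12)),
    q_value = 0.001)
  list(net = net, de = de, targets = targets,
       expected = c(receptor_only = 2, ligand_only = 3, both = 1))
}
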