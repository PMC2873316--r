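## Synthetic benchmark generator: signed scale-free-ish regulatory networks
## with a planted ligand -> receptor -> kinase -> TF -> target cascade, and
## paired lesional/non-lesional expression with planted overexpression.
## Every stage of the pipeline has a recovery-testable input with full
## ground truth.

#' Simulation configuration
#'
#' Defaults describe the benchmark scenario the package is validated
#' against: a 200-node signed network with class-structured wiring, a
#' planted all-activating cascade (2 ligands, 2 receptors, 2 kinases, 2
#' transcription factors, 20 targets), 28 lesional/non-lesional sample
#' pairs, planted target overexpression of mean 2 on the log2 scale, and
#' log-normal measurement noise of sd 0.5 (log2).
#'
#' @param n_nodes total nodes
#' @param class_props named proportions for `ligand`, `receptor`, `kinase`,
#'   `transcription_factor`, `generic`; must sum to 1
#' @param edges_per_node mean background out-edges per node
#' @param pa_power preferential-attachment exponent on target in-degree
#' @param inhibition_prob probability a background edge is inhibitory
#' @param n_planted_ligands,n_planted_receptors,n_planted_kinases,n_planted_tfs,n_planted_targets
#'   planted cascade sizes
#' @param n_pairs sample pairs in the expression matrix
#' @param log2fc_mean,log2fc_sd planted target log2 fold-change distribution
#' @param overexpress_regulators also plant overexpression on the planted
#'   ligand and receptor genes
#' @param regulator_log2fc_mean planted log2 FC for regulators
#' @param baseline_meanlog,baseline_sdlog log-normal baseline intensity
#' @param noise_sd per-observation log2 noise on the lesional channel
#' @param pair_effect_sd sd of the pair-level (sample-wide) log2 effect;
#'   removed by median normalization
#' @param seed RNG seed
#' @return object of class `simulation_config`
#' @export
simulation_config <- function(
    n_nodes = 200,
    class_props = c(ligand = 0.10, receptor = 0.15, kinase = 0.20,
                    transcription_factor = 0.15, generic = 0.40),
    edges_per_node = 2.5, pa_power = 1, inhibition_prob = 0.2,
    n_planted_ligands = 2, n_planted_receptors = 2, n_planted_kinases = 2,
    n_planted_tfs = 2, n_planted_targets = 20,
    n_pairs = 28, log2fc_mean = 2, log2fc_sd = 0.25,
    overexpress_regulators = TRUE, regulator_log2fc_mean = 2,
    baseline_meanlog = log(100), baseline_sdlog = 1,
    noise_sd = 0.5, pair_effect_sd = 0.1, seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(class_props) - 1) > 1e-8) {
    nr_validation_error("class proportions must sum to 1")
  }
  if (!setequal(names(class_props), NODE_CLASSES)) {
    nr_validation_error(sprintf("class_props must name exactly: %s",
                                paste(NODE_CLASSES, collapse = ", ")))
  }
  counts <- class_counts(cfg)
  if (n_planted_ligands > counts["ligand"] ||
      n_planted_receptors > counts["receptor"] ||
      n_planted_kinases > counts["kinase"] ||
      n_planted_tfs > counts["transcription_factor"] ||
      n_planted_targets > counts["generic"]) {
    nr_validation_error("planted counts exceed the nodes available per class")
  }
  if (n_pairs < 2) nr_validation_error("need n_pairs >= 2")
  structure(cfg, class = "simulation_config")
}

class_counts <- function(cfg) {
  props <- cfg$class_props[NODE_CLASSES]
  counts <- floor(props * cfg$n_nodes)
  # distribute the remainder by largest fractional part
  rem <- cfg$n_nodes - sum(counts)
  if (rem > 0) {
    frac <- props * cfg$n_nodes - counts
    counts[order(-frac)[seq_len(rem)]] <-
      counts[order(-frac)[seq_len(rem)]] + 1
  }
  setNames(as.integer(counts), NODE_CLASSES)
}

# class-compatibility rules for background edges
EDGE_RULES <- list(
  ligand = "receptor",
  receptor = c("kinase", "transcription_factor"),
  kinase = c("kinase", "transcription_factor"),
  transcription_factor = "generic"
)

#' Generate a synthetic signed regulatory network with a planted cascade
#'
#' The background graph is sampled first: edges follow class-compatibility
#' rules (ligand to receptor, receptor/kinase to kinase/TF, TF to generic
#' via transcription-regulation edges) with preferential attachment on
#' degree, each edge inhibitory with the configured probability.  Planted
#' nodes are then chosen uniformly within their classes -- they are ordinary
#' nodes, not background hubs -- and the cascade is wired on top with
#' all-activating edges: every planted ligand feeds a planted receptor,
#' receptors connect to all planted kinases, kinases to all planted TFs
#' (redundant routes, as in real signaling modules), and every planted TF
#' regulates every planted target by transcription regulation.  Parity-even
#' activation paths from every planted receptor to every planted target
#' therefore exist by construction.  Planted receptors signal exclusively
#' through the cascade: their background out-edges are removed, emulating
#' receptors whose canonical downstream adaptors are the planted pathway.
#'
#' @param cfg a `simulation_config`
#' @return list with `network` (an `interaction_network`) and `truth`
#'   (a `ground_truth`: planted node sets, planted fold changes, cascade
#'   edges)
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    counts <- class_counts(cfg)
    ids <- list(
      ligand = sprintf("LIG%03d", seq_len(counts["ligand"])),
      receptor = sprintf("REC%03d", seq_len(counts["receptor"])),
      kinase = sprintf("KIN%03d", seq_len(counts["kinase"])),
      transcription_factor = sprintf("TF%03d",
                                     seq_len(counts["transcription_factor"])),
      generic = sprintf("GEN%03d", seq_len(counts["generic"]))
    )
    node_class <- setNames(rep(names(ids), lengths(ids)), unlist(ids))
    nodes <- names(node_class)

    # background edges: preferential attachment within class rules
    n_bg <- round(cfg$edges_per_node * cfg$n_nodes)
    sources_pool <- nodes[node_class %in% names(EDGE_RULES)]
    indeg <- setNames(numeric(length(nodes)), nodes)
    outdeg <- setNames(numeric(length(nodes)), nodes)
    seen <- new.env(hash = TRUE, parent = emptyenv())
    bg <- vector("list", n_bg)
    made <- 0L
    attempts <- 0L
    while (made < n_bg && attempts < 20L * n_bg) {
      attempts <- attempts + 1L
      src <- sample(sources_pool, 1,
                    prob = (outdeg[sources_pool] + 1)^cfg$pa_power)
      tgt_pool <- nodes[node_class %in% EDGE_RULES[[node_class[src]]]]
      tgt_pool <- setdiff(tgt_pool, src)
      if (!length(tgt_pool)) next
      tgt <- if (length(tgt_pool) == 1) tgt_pool else
        sample(tgt_pool, 1, prob = (indeg[tgt_pool] + 1)^cfg$pa_power)
      effect <- if (runif(1) < cfg$inhibition_prob) "inhibition" else
        "activation"
      mechanism <- if (node_class[src] == "transcription_factor")
        "transcription_regulation" else "other"
      key <- paste(src, tgt, effect, mechanism, sep = "\r")
      if (exists(key, envir = seen, inherits = FALSE)) next
      assign(key, TRUE, envir = seen)
      made <- made + 1L
      bg[[made]] <- data.frame(source = src, target = tgt, effect = effect,
                               mechanism = mechanism,
                               stringsAsFactors = FALSE)
      indeg[tgt] <- indeg[tgt] + 1
      outdeg[src] <- outdeg[src] + 1
    }
    bg <- do.call(rbind, bg[seq_len(made)])

    planted <- list(
      ligands = sample(ids$ligand, cfg$n_planted_ligands),
      receptors = sample(ids$receptor, cfg$n_planted_receptors),
      kinases = sample(ids$kinase, cfg$n_planted_kinases),
      tfs = sample(ids$transcription_factor, cfg$n_planted_tfs),
      targets = sample(ids$generic, cfg$n_planted_targets)
    )
    # planted receptors use the cascade as their only signaling route
    bg <- bg[!(bg$source %in% planted$receptors), , drop = FALSE]

    # planted cascade, all activating
    cascade <- rbind(
      data.frame(source = planted$ligands,
                 target = planted$receptors[
                   rep_len(seq_along(planted$receptors),
                           length(planted$ligands))],
                 stringsAsFactors = FALSE),
      expand.grid(source = planted$receptors, target = planted$kinases,
                  stringsAsFactors = FALSE),
      expand.grid(source = planted$kinases, target = planted$tfs,
                  stringsAsFactors = FALSE),
      expand.grid(source = planted$tfs, target = planted$targets,
                  stringsAsFactors = FALSE)
    )
    cascade$effect <- "activation"
    cascade$mechanism <- ifelse(
      node_class[cascade$source] == "transcription_factor",
      "transcription_regulation", "other")

    edges <- rbind(bg, cascade)
    key <- paste(edges$source, edges$target, edges$effect, edges$mechanism,
                 sep = "\r")
    edges <- edges[!duplicated(key), , drop = FALSE]
    net <- interaction_network(edges, node_class)

    # degenerate sd = 0 gives exact fold changes (including the null FC = 1);
    # otherwise draws are clamped just above 1 so planted targets stay "up"
    draw_fc <- function(n, mean) {
      if (cfg$log2fc_sd == 0) rep(2^mean, n) else
        2^pmax(rnorm(n, mean, cfg$log2fc_sd), log2(1.1))
    }
    planted_fc <- setNames(draw_fc(length(planted$targets), cfg$log2fc_mean),
                           planted$targets)
    if (cfg$overexpress_regulators) {
      regs <- c(planted$receptors, planted$ligands)
      planted_fc <- c(planted_fc,
                      setNames(draw_fc(length(regs),
                                       cfg$regulator_log2fc_mean), regs))
    }

    truth <- structure(
      list(planted_ligands = planted$ligands,
           planted_receptors = planted$receptors,
           planted_kinases = planted$kinases,
           planted_tfs = planted$tfs,
           planted_targets = planted$targets,
           planted_fold_changes = planted_fc,
           cascade_edges = cascade,
           gene_ids = nodes),
      class = "ground_truth")
    list(network = net, truth = truth)
  })
}

#' Generate paired expression with planted overexpression
#'
#' Non-lesional intensities are i.i.d. log-normal; the lesional value of a
#' gene is its paired non-lesional value shifted by the planted log2 fold
#' change (zero for non-planted genes) plus a pair-level sample-wide effect
#' and per-observation log2 noise.  With both noise terms at zero the
#' per-pair ratio of a planted gene equals its planted fold change exactly.
#'
#' @param truth a `ground_truth` from [generate_network()]
#' @param cfg the same `simulation_config`
#' @param seed RNG seed (default `cfg$seed + 1000` so network and
#'   expression draws are decoupled)
#' @return a `paired_expression` over all network genes
#' @export
generate_expression <- function(truth, cfg, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(cfg, "simulation_config"))
  seed <- seed %||% (cfg$seed + 1000)
  with_seed(seed, {
    genes <- truth$gene_ids
    ng <- length(genes)
    np <- cfg$n_pairs
    log2fc <- setNames(numeric(ng), genes)
    log2fc[names(truth$planted_fold_changes)] <-
      log2(truth$planted_fold_changes)

    nonles <- matrix(rlnorm(ng * np, cfg$baseline_meanlog,
                            cfg$baseline_sdlog),
                     nrow = ng,
                     dimnames = list(genes, sprintf("P%02d_N", seq_len(np))))
    pair_eff <- rnorm(np, 0, cfg$pair_effect_sd)
    noise <- matrix(rnorm(ng * np, 0, cfg$noise_sd), nrow = ng)
    les <- nonles * 2^(log2fc + rep(pair_eff, each = ng) + noise)
    colnames(les) <- sprintf("P%02d_L", seq_len(np))

    paired_expression(
      cbind(les, nonles),
      data.frame(lesional = colnames(les), nonlesional = colnames(nonles),
                 stringsAsFactors = FALSE))
  })
}

#' Recovery metrics of pipeline outputs against the planted ground truth
#'
#' @param truth a `ground_truth`
#' @param de_set optional `gene_set` from [de_gene_set()]
#' @param tf_ranking optional `ranked_list` over transcription factors
#' @param receptor_ranking optional `ranked_list` over receptors
#' @param classification optional result of [classify_receptors()]
#' @return list of metrics: per-planted-node ranks, DE precision/recall,
#'   per-category classification agreement
#' @export
recovery_report <- function(truth, de_set = NULL, tf_ranking = NULL,
                            receptor_ranking = NULL, classification = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  out <- list()
  if (!is.null(de_set)) {
    found <- gene_set_members(de_set)
    tp <- length(intersect(found, truth$planted_targets))
    out$de <- list(
      precision = if (length(found)) tp / length(found) else NA_real_,
      recall = tp / length(truth$planted_targets),
      n_found = length(found))
  }
  if (!is.null(tf_ranking)) {
    out$tf_ranks <- setNames(
      match(truth$planted_tfs, tf_ranking$node), truth$planted_tfs)
  }
  if (!is.null(receptor_ranking)) {
    out$receptor_ranks <- setNames(
      match(truth$planted_receptors, receptor_ranking$node),
      truth$planted_receptors)
  }
  if (!is.null(classification)) {
    cls <- classification
    out$classification <- setNames(
      cls$category[match(truth$planted_receptors, cls$receptor)],
      truth$planted_receptors)
  }
  out
}

#' Write a simulated scenario to disk as plain-text pipeline inputs
#'
#' @param cfg a `simulation_config`
#' @param dir output directory (created if needed)
#' @return invisibly, a list with the generated `network`, `truth` and
#'   `expression`
#' @export
write_simulation <- function(cfg, dir) {
  stopifnot(inherits(cfg, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- generate_network(cfg)
  expr <- generate_expression(sim$truth, cfg)
  write_network(sim$network, file.path(dir, "network_edges.tsv"),
                file.path(dir, "node_classes.tsv"))
  write_gmt(gene_set("planted_targets", sim$truth$planted_targets),
            file.path(dir, "planted_targets.gmt"))
  vals <- data.frame(gene = rownames(expr$values), expr$values,
                     check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_report(vals, file.path(dir, "expression.tsv"))
  write_tsv_report(expr$pair_map, file.path(dir, "pair_map.tsv"))
  jsonlite::write_json(
    list(planted_ligands = sim$truth$planted_ligands,
         planted_receptors = sim$truth$planted_receptors,
         planted_kinases = sim$truth$planted_kinases,
         planted_tfs = sim$truth$planted_tfs,
         planted_targets = sim$truth$planted_targets,
         planted_fold_changes = as.list(sim$truth$planted_fold_changes)),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(network = sim$network, truth = sim$truth,
                 expression = expr))
}
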