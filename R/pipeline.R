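## End-to-end orchestration: common-TF identification across two data
## types, receptor significance + expression filtering + pathway
## co-membership, classification and reporting.

#' Common transcription factors across two data types
#'
#' For each gene set (e.g. the transcriptomics DE list and the proteomics
#' marker list): ranks all transcription factors by overconnectivity and by
#' the hidden-nodes statistic, truncates both rankings to `k`, and
#' aggregates them into one optimal list of size `k` by weighted
#' Spearman-footrule rank aggregation.  The common TFs are the intersection
#' of the two aggregated lists.  Supplemental TFs are the seeds of the
#' top-`m` TF-expansion subnetworks by enrichment (per data type) that are
#' not already in the intersection.
#'
#' @param net an `interaction_network`
#' @param set_tx transcriptomics gene set of interest
#' @param set_prot proteomics gene set of interest
#' @param k per-method and aggregated list size (default 20)
#' @param m_supplemental TF-expansion seeds to consider per data type
#' @param parity,max_len hidden-nodes settings, see [build_path_index()]
#' @param expansion_size TF-expansion subnetwork size threshold
#' @param ga_config genetic-algorithm settings, see [aggregation_problem()]
#' @param idx optional pre-built universe path index
#' @return object of class `common_regulator_result`: per-data-type
#'   rankings and aggregated lists, `common_tfs`, `supplemental_tfs`
#' @export
find_common_tfs <- function(net, set_tx, set_prot, k = 20,
                            m_supplemental = 5,
                            parity = c("even", "odd"), max_len = 6,
                            expansion_size = 50, ga_config = list(),
                            idx = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  parity <- match.arg(parity)
  tf_all <- nodes_of_class(net, "transcription_factor")
  if (!length(tf_all)) nr_validation_error("network has no transcription_factor node")
  if (!length(gene_set_members(set_tx)) || !length(gene_set_members(set_prot))) {
    nr_validation_error("both gene sets must be non-empty")
  }
  if (is.null(idx)) {
    idx <- build_path_index(net, targets = NULL, parity = parity,
                            max_len = max_len)
  }
  per_type <- lapply(list(tx = set_tx, prot = set_prot), function(s) {
    over <- rank_overconnected(net, s, tf_all)
    hidden <- rank_hidden_nodes(net, s, tf_all, parity = parity,
                                max_len = max_len, idx = idx)
    prob <- aggregation_problem(list(over, hidden), k = k,
                                ga_config = ga_config)
    agg <- aggregate_rankings(prob)
    list(overconnectivity = over, hidden = hidden, problem = prob,
         aggregated = agg$nodes, fitness = agg$fitness)
  })
  common <- intersect(per_type$tx$aggregated, per_type$prot$aggregated)
  if (!length(common)) {
    warning("no transcription factor common to both aggregated lists",
            call. = FALSE)
  }

  supplemental <- character()
  for (s in list(set_tx, set_prot)) {
    nets <- lapply(tf_all, function(tf)
      enrichment_pvalue(expand_tf_network(net, tf, s, size = expansion_size),
                        s, net))
    nets <- rank_networks(nets)
    seeds <- vapply(head(nets, m_supplemental), function(x) x$seed,
                    character(1))
    supplemental <- union(supplemental, seeds)
  }
  supplemental <- sort(setdiff(supplemental, common))

  structure(list(per_type = per_type, common_tfs = sort(common),
                 supplemental_tfs = supplemental, k = k),
            class = "common_regulator_result")
}

#' @export
print.common_regulator_result <- function(x, ...) {
  cat(sprintf("common_regulator_result: %d common TFs (%s)\n",
              length(x$common_tfs), paste(x$common_tfs, collapse = ", ")))
  cat(sprintf("  supplemental (subnetwork-based): %s\n",
              paste(x$supplemental_tfs, collapse = ", ")))
  invisible(x)
}

#' Pathway co-membership of a receptor with the common TFs
#'
#' Operationalized as directed reachability: `TRUE` iff a directed path of
#' at most `max_len` hops leads from the receptor to at least one common
#' TF.
#'
#' @param net an `interaction_network`
#' @param receptor receptor node id
#' @param common_tfs character vector of TF node ids
#' @param max_len hop cap (default 6)
#' @return logical
#' @export
pathway_linked <- function(net, receptor, common_tfs, max_len = 6) {
  stopifnot(inherits(net, "interaction_network"))
  if (!(receptor %in% net$nodes)) {
    nr_lookup_error(sprintf("unknown node '%s'", receptor))
  }
  common_tfs <- intersect(common_tfs, net$nodes)
  if (!length(common_tfs)) return(FALSE)
  g <- as_igraph(net)
  d <- igraph::distances(g, v = receptor, to = common_tfs, mode = "out")
  any(is.finite(d) & d <= max_len)
}

#' Classify candidate upstream receptors
#'
#' Retains receptors that are topologically significant (hidden-nodes
#' p-value below `p_cut`), whose own gene or at least one ligand (a
#' ligand-class in-neighbour) is overexpressed above `fc_cut` at the DE
#' q-threshold, and that share a pathway with a common TF
#' (see [pathway_linked()]).  Retained receptors are categorized as
#' `receptor_only`, `ligand_only` or `both`; all others are `rejected`.
#'
#' @param net an `interaction_network`
#' @param hidden_ranking a `ranked_list` over receptor-class candidates
#'   (from [rank_hidden_nodes()])
#' @param de a `de_result` covering the network's gene ids (genes missing
#'   from it count as not overexpressed)
#' @param common_tfs character vector of common TF ids
#' @param p_cut hidden-nodes significance cut-off (strict `<`, default 0.05)
#' @param fc_cut overexpression fold-change cut-off (strict `>`, default
#'   2.5)
#' @param max_len hop cap for pathway co-membership
#' @return data.frame of class `receptor_classification` with columns
#'   `receptor`, `hidden_p`, `receptor_overexpressed`,
#'   `ligand_overexpressed`, `pathway_linked`, `category`
#' @export
classify_receptors <- function(net, hidden_ranking, de, common_tfs,
                               p_cut = 0.05, fc_cut = 2.5, max_len = 6) {
  stopifnot(inherits(net, "interaction_network"),
            inherits(hidden_ranking, "ranked_list"),
            inherits(de, "de_result"))
  q_thr <- attr(de, "q_threshold")
  overexpressed <- function(genes) {
    i <- match(genes, de$gene)
    ok <- !is.na(i)
    res <- logical(length(genes))
    res[ok] <- de$fold_change[i[ok]] > fc_cut & de$q_value[i[ok]] < q_thr
    res
  }
  missing <- setdiff(hidden_ranking$node, de$gene)
  if (length(missing)) {
    message(sprintf(
      "classify_receptors: %d receptor gene(s) absent from the DE table treated as not overexpressed",
      length(missing)))
  }
  e <- net$edges
  rows <- lapply(seq_len(nrow(hidden_ranking)), function(i) {
    rec <- hidden_ranking$node[i]
    hp <- hidden_ranking$p_value[i]
    rec_oe <- overexpressed(rec)
    ligands <- unique(e$source[e$target == rec &
                                 net$node_class[e$source] == "ligand"])
    lig_oe <- length(ligands) > 0 && any(overexpressed(ligands))
    linked <- pathway_linked(net, rec, common_tfs, max_len = max_len)
    retained <- hp < p_cut && (rec_oe || lig_oe) && linked
    category <- if (!retained) "rejected"
      else if (rec_oe && lig_oe) "both"
      else if (rec_oe) "receptor_only"
      else "ligand_only"
    data.frame(receptor = rec, hidden_p = hp,
               receptor_overexpressed = rec_oe,
               ligand_overexpressed = lig_oe,
               pathway_linked = linked, category = category,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$category != "rejected")) {
    warning("no receptor retained by the classification filters",
            call. = FALSE)
  }
  structure(out, class = c("receptor_classification", "data.frame"),
            p_cut = p_cut, fc_cut = fc_cut)
}

#' Default pipeline configuration
#'
#' @param overrides named list of settings to override
#' @return named list of configuration values
#' @export
default_config <- function(overrides = list()) {
  modifyList(list(
    network_edges = NULL, node_classes = NULL, proteomics_gmt = NULL,
    expression = NULL, pair_map = NULL, out_dir = "netreg_out",
    fc_threshold = 2.5, q_threshold = 0.01, p_cut = 0.05,
    k = 20, expansion_size = 50, m_supplemental = 5,
    parity = "even", max_len = 6, seed = 1
  ), overrides)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file
#' @return configuration list (missing settings filled with defaults)
#' @export
read_config <- function(path) {
  if (!file.exists(path)) nr_io_error(sprintf("config file not found: %s", path))
  default_config(yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Stages: paired differential expression on the transcriptomics matrix;
#' overconnectivity and hidden-nodes rankings of transcription factors for
#' both the DE gene set and the proteomics set; per-data-type rank
#' aggregation and intersection into the common TFs; TF-expansion
#' subnetworks; per-receptor shortest-path subnetworks; hidden-nodes
#' ranking of receptors and their classification by overexpression and
#' pathway co-membership.  All reports are written as TSV into
#' `config$out_dir`; re-running with an identical configuration reproduces
#' byte-identical reports.
#'
#' @param config configuration list, see [default_config()] /
#'   [read_config()]
#' @return invisibly, a list with all intermediate objects and the paths of
#'   the written reports
#' @export
run_pipeline <- function(config) {
  cfg <- default_config(config)
  t0 <- proc.time()[["elapsed"]]
  log_lines <- c(sprintf("netreg pipeline (seed %s)", cfg$seed),
                 sprintf("parameters: fc>%s q<%s p<%s k=%s size=%s parity=%s max_len=%s",
                         cfg$fc_threshold, cfg$q_threshold, cfg$p_cut,
                         cfg$k, cfg$expansion_size, cfg$parity, cfg$max_len))
  stage <- function(name, expr) {
    t <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      nr_abort(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), class = "netreg_stage_error")
    })
    log_lines <<- c(log_lines, sprintf("stage %-18s %.2fs", name,
                                       proc.time()[["elapsed"]] - t))
    res
  }
  for (f in c("network_edges", "proteomics_gmt", "expression", "pair_map")) {
    if (is.null(cfg[[f]])) {
      nr_validation_error(sprintf("config entry '%s' is required", f))
    }
    if (!file.exists(cfg[[f]])) {
      nr_io_error(sprintf("input file for '%s' not found: %s", f, cfg[[f]]))
    }
  }
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  report <- function(tab, name) {
    p <- file.path(cfg$out_dir, name)
    write_tsv_report(tab, p)
    paths[[name]] <<- p
    p
  }

  net <- stage("read_network",
               read_network(cfg$network_edges, cfg$node_classes))
  set_prot <- stage("read_gmt", read_gmt(cfg$proteomics_gmt)[[1]])

  de <- stage("diffexpr", {
    expr <- median_normalize(read_expression(cfg$expression, cfg$pair_map))
    paired_de_test(expr, fc_threshold = cfg$fc_threshold,
                   q_threshold = cfg$q_threshold)
  })
  report(as.data.frame(de), "de_table.tsv")
  set_tx <- de_gene_set(de)
  if (!length(set_tx$members)) {
    nr_validation_error("no differentially expressed gene passes the filters")
  }
  log_lines <- c(log_lines, sprintf("DE genes passing filters: %d",
                                    length(set_tx$members)))

  idx <- stage("path_index", build_path_index(net, targets = NULL,
                                              parity = cfg$parity,
                                              max_len = cfg$max_len))
  common <- stage("common_tfs", find_common_tfs(
    net, set_tx, set_prot, k = cfg$k, m_supplemental = cfg$m_supplemental,
    parity = cfg$parity, max_len = cfg$max_len,
    expansion_size = cfg$expansion_size,
    ga_config = list(seed = cfg$seed), idx = idx))
  for (ty in names(common$per_type)) {
    report(as.data.frame(common$per_type[[ty]]$overconnectivity),
           sprintf("overconnectivity_%s.tsv", ty))
    report(as.data.frame(common$per_type[[ty]]$hidden),
           sprintf("hidden_nodes_%s.tsv", ty))
    report(data.frame(rank = seq_along(common$per_type[[ty]]$aggregated),
                      node = common$per_type[[ty]]$aggregated),
           sprintf("aggregated_%s.tsv", ty))
  }
  report(data.frame(node = c(common$common_tfs, common$supplemental_tfs),
                    source = c(rep("common", length(common$common_tfs)),
                               rep("subnetwork",
                                   length(common$supplemental_tfs)))),
         "common_tfs.tsv")

  subnets <- stage("receptor_networks", {
    tfs <- select_direct_tfs(net, set_tx)
    receptors <- select_receptors_by_ligand(net, set_tx)
    nets <- lapply(receptors, function(rc)
      build_receptor_network(net, rc, tfs, set_tx, max_len = cfg$max_len))
    nets <- Filter(Negate(is.null), nets)
    rank_networks(lapply(nets, enrichment_pvalue, s = set_tx,
                         universe = net))
  })
  if (length(subnets)) {
    report(subnetwork_summary(subnets), "receptor_networks.tsv")
  }

  receptors_cls <- stage("classify_receptors", {
    rec_rank <- rank_hidden_nodes(net, set_tx, "receptor",
                                  parity = cfg$parity,
                                  max_len = cfg$max_len, idx = idx)
    report(as.data.frame(rec_rank), "receptor_ranking.tsv")
    classify_receptors(net, rec_rank, de,
                       c(common$common_tfs, common$supplemental_tfs),
                       p_cut = cfg$p_cut, fc_cut = cfg$fc_threshold,
                       max_len = cfg$max_len)
  })
  report(as.data.frame(receptors_cls), "receptor_classification.tsv")
  retained <- receptors_cls[receptors_cls$category != "rejected", ]
  log_lines <- c(log_lines,
                 sprintf("receptors retained: %d (receptor_only %d, ligand_only %d, both %d)",
                         nrow(retained),
                         sum(retained$category == "receptor_only"),
                         sum(retained$category == "ligand_only"),
                         sum(retained$category == "both")),
                 sprintf("total elapsed %.2fs",
                         proc.time()[["elapsed"]] - t0))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(network = net, de = de, set_tx = set_tx,
                 set_prot = set_prot, index = idx, common = common,
                 receptor_networks = subnets,
                 receptor_classification = receptors_cls,
                 reports = paths, config = cfg))
}
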