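## Subnetwork construction: per-receptor shortest-path regulatory networks
## and TF-centred greedy expansion networks, each scored by hypergeometric
## enrichment in the list of interest and sorted.

as_igraph <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  igraph::graph_from_data_frame(
    net$edges[, c("source", "target", "effect", "mechanism")],
    directed = TRUE, vertices = net$nodes)
}

#' Transcription factors directly regulating a gene set
#'
#' @param net an `interaction_network`
#' @param s a `gene_set` (non-empty)
#' @return character vector of transcription-factor nodes with at least one
#'   outgoing transcription-regulation edge into `s` (possibly empty)
#' @export
select_direct_tfs <- function(net, s) {
  stopifnot(inherits(net, "interaction_network"))
  members <- gene_set_members(s)
  if (!length(members)) nr_validation_error("gene set of interest is empty")
  e <- net$edges
  hit <- e$mechanism == "transcription_regulation" &
    net$node_class[e$source] == "transcription_factor" &
    e$target %in% members
  tfs <- sort(unique(e$source[hit]))
  if (!length(tfs)) {
    message("select_direct_tfs: no transcription factor directly regulates the set")
  }
  tfs
}

#' Receptors whose ligands are in a gene set
#'
#' Ligand-receptor links are directed interactions from a ligand-class node
#' into a receptor-class node.
#'
#' @param net an `interaction_network`
#' @param s a `gene_set` (non-empty)
#' @return character vector of receptor nodes with at least one incoming
#'   edge from a ligand in `s` (possibly empty)
#' @export
select_receptors_by_ligand <- function(net, s) {
  stopifnot(inherits(net, "interaction_network"))
  members <- gene_set_members(s)
  if (!length(members)) nr_validation_error("gene set of interest is empty")
  e <- net$edges
  hit <- net$node_class[e$source] == "ligand" & e$source %in% members &
    net$node_class[e$target] == "receptor"
  recs <- sort(unique(e$target[hit]))
  if (!length(recs)) {
    message("select_receptors_by_ligand: no receptor has a ligand in the set")
  }
  recs
}

make_subnetwork <- function(net, seed, nodes, kind) {
  nodes <- sort(unique(nodes))
  keep <- net$edges$source %in% nodes & net$edges$target %in% nodes
  structure(list(seed = seed, nodes = nodes,
                 edges = net$edges[keep, , drop = FALSE],
                 kind = kind, enrichment_p = NA_real_, r = NA_integer_),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf("subnetwork (%s) seeded at %s: %d nodes, %d edges",
              x$kind, x$seed, length(x$nodes), nrow(x$edges)))
  if (!is.na(x$enrichment_p)) cat(sprintf(", enrichment p = %.3g", x$enrichment_p))
  cat("\n")
  invisible(x)
}

#' Per-receptor shortest-path regulatory network
#'
#' Collects all directed shortest paths (hop count at most `max_len`) from
#' the receptor to each selected transcription factor, then adds the
#' targets of those reachable TFs that belong to the list of interest
#' (transcription-regulation edges only).  Paths are not sign-constrained
#' unless `parity` is given.
#'
#' @param net an `interaction_network`
#' @param receptor seed receptor node id
#' @param tfs character vector of selected transcription factors (see
#'   [select_direct_tfs()])
#' @param s the list of interest (`gene_set` or character)
#' @param max_len maximum hop count for the receptor-to-TF paths
#' @param parity optional `"even"`/`"odd"` sign-parity filter on the paths
#' @param all_targets include every transcription-regulation target of the
#'   reachable TFs, not only those in `s`
#' @return a `subnetwork` of kind `receptor_series`, or `NULL` (with a
#'   message) when no TF is reachable
#' @export
build_receptor_network <- function(net, receptor, tfs, s, max_len = 6,
                                   parity = NULL, all_targets = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  if (!(receptor %in% net$nodes)) {
    nr_lookup_error(sprintf("unknown node '%s'", receptor))
  }
  members <- gene_set_members(s)
  g <- as_igraph(net)
  nodes <- character()
  reachable_tfs <- character()
  for (tf in intersect(tfs, net$nodes)) {
    if (tf == receptor) {
      reachable_tfs <- c(reachable_tfs, tf)
      nodes <- c(nodes, tf)
      next
    }
    sp <- suppressWarnings(
      igraph::all_shortest_paths(g, from = receptor, to = tf, mode = "out"))
    if (!length(sp$res)) next
    plen <- length(sp$res[[1]]) - 1L
    if (plen > max_len) next
    path_nodes <- lapply(sp$res, function(p) names(p))
    if (!is.null(parity)) {
      path_nodes <- Filter(function(pn) path_parity_ok(net, pn, parity),
                           path_nodes)
      if (!length(path_nodes)) next
    }
    reachable_tfs <- c(reachable_tfs, tf)
    nodes <- c(nodes, unlist(path_nodes))
  }
  if (!length(reachable_tfs)) {
    message(sprintf(
      "build_receptor_network: receptor %s reaches no selected TF; skipped",
      receptor))
    return(NULL)
  }
  e <- net$edges
  tr_targets <- e$target[e$mechanism == "transcription_regulation" &
                           e$source %in% reachable_tfs]
  if (!all_targets) tr_targets <- intersect(tr_targets, members)
  make_subnetwork(net, receptor, c(receptor, nodes, tr_targets),
                  "receptor_series")
}

# net sign parity of a node sequence; unspecified counts as activating
path_parity_ok <- function(net, path_nodes, parity) {
  n_inhib <- 0L
  e <- net$edges
  for (i in seq_len(length(path_nodes) - 1)) {
    effs <- e$effect[e$source == path_nodes[i] & e$target == path_nodes[i + 1]]
    # with parallel edges, an activating variant suffices
    n_inhib <- n_inhib + as.integer(all(effs == "inhibition"))
  }
  (n_inhib %% 2L) == (if (parity == "even") 0L else 1L)
}

#' TF-centred greedy expansion network
#'
#' Starting from the transcription factor, repeatedly adds the frontier
#' node (any neighbour of the current node set, in either direction) that
#' ranks highest under: member of the list of interest first, then most
#' interaction records with the current set, then lexicographic node id;
#' stops at the size threshold or when the frontier is empty.  Fully
#' deterministic.
#'
#' @param net an `interaction_network`
#' @param tf seed transcription-factor node id
#' @param s the list of interest
#' @param size node-count threshold (default 50)
#' @return a `subnetwork` of kind `tf_expansion`
#' @export
expand_tf_network <- function(net, tf, s, size = 50) {
  stopifnot(inherits(net, "interaction_network"))
  if (!(tf %in% net$nodes)) nr_lookup_error(sprintf("unknown node '%s'", tf))
  members <- gene_set_members(s)
  e <- net$edges
  current <- tf
  while (length(current) < size) {
    incident <- e$source %in% current | e$target %in% current
    others <- c(e$target[e$source %in% current], e$source[e$target %in% current])
    frontier <- setdiff(unique(others), current)
    if (!length(frontier)) break
    links <- vapply(frontier, function(v) {
      sum((e$source == v & e$target %in% current) |
            (e$target == v & e$source %in% current))
    }, numeric(1))
    in_set <- frontier %in% members
    ord <- order(-as.integer(in_set), -links, frontier)
    current <- c(current, frontier[ord[1]])
  }
  make_subnetwork(net, tf, current, "tf_expansion")
}

#' Hypergeometric enrichment of a subnetwork in the list of interest
#'
#' Parameters over the node universe of the parent network: `N` = nodes in
#' the universe, `n` = set members present in the universe, `R` = subnetwork
#' nodes, `r` = subnetwork nodes in the set.  The scored subnetwork is
#' returned with `enrichment_p` and `r` filled in.
#'
#' @param subnet a `subnetwork`
#' @param s the list of interest
#' @param universe the parent `interaction_network`
#' @return the `subnetwork`, scored
#' @export
enrichment_pvalue <- function(subnet, s, universe) {
  stopifnot(inherits(subnet, "subnetwork"),
            inherits(universe, "interaction_network"))
  if (!all(subnet$nodes %in% universe$nodes)) {
    nr_validation_error("subnetwork nodes must lie inside the universe")
  }
  members <- intersect(gene_set_members(s), universe$nodes)
  r <- length(intersect(subnet$nodes, members))
  subnet$r <- r
  subnet$enrichment_p <- hypergeom_tail(
    r = r, R = length(subnet$nodes), n = length(members),
    N = length(universe$nodes))
  subnet
}

#' Sort scored subnetworks by enrichment
#'
#' Ascending by enrichment p-value; ties break by larger `r`, then by seed
#' node id.
#'
#' @param subnets list of scored `subnetwork` objects
#' @return the same list, sorted
#' @export
rank_networks <- function(subnets) {
  subnets <- Filter(Negate(is.null), subnets)
  if (!length(subnets)) return(subnets)
  p <- vapply(subnets, function(x) x$enrichment_p, numeric(1))
  if (anyNA(p)) nr_validation_error("all subnetworks must be scored first")
  r <- vapply(subnets, function(x) as.numeric(x$r), numeric(1))
  seeds <- vapply(subnets, function(x) x$seed, character(1))
  subnets[order(p, -r, seeds)]
}

#' Summary table for a list of scored subnetworks
#' @param subnets list of scored `subnetwork` objects (e.g. from
#'   [rank_networks()])
#' @return data.frame with seed, kind, n_nodes, r, enrichment_p, rank
#' @export
subnetwork_summary <- function(subnets) {
  subnets <- Filter(Negate(is.null), subnets)
  data.frame(
    seed = vapply(subnets, function(x) x$seed, character(1)),
    kind = vapply(subnets, function(x) x$kind, character(1)),
    n_nodes = vapply(subnets, function(x) length(x$nodes), integer(1)),
    r = vapply(subnets, function(x) as.integer(x$r), integer(1)),
    enrichment_p = vapply(subnets, function(x) x$enrichment_p, numeric(1)),
    rank = seq_along(subnets),
    stringsAsFactors = FALSE)
}
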