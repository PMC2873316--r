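## Direct-neighbour topological significance: hypergeometric tail test of a
## node's links into the list of interest, and ranking of candidate nodes.

#' Upper hypergeometric tail probability P(X >= r)
#'
#' `X` is the number of successes when `R` items are drawn without
#' replacement from a population of `N` items of which `n` are successes.
#' This single primitive backs the overconnectivity, hidden-nodes and
#' subnetwork-enrichment statistics.
#'
#' @param r observed successes (tail starts here)
#' @param R number of draws
#' @param n successes in the population
#' @param N population size
#' @return P(X >= r), in \[0, 1\]
#' @export
hypergeom_tail <- function(r, R, n, N) {
  r <- as.integer(r); R <- as.integer(R); n <- as.integer(n); N <- as.integer(N)
  if (anyNA(c(r, R, n, N))) nr_validation_error("hypergeometric parameters must be integers")
  if (N < 0 || n < 0 || R < 0 || r < 0 || n > N || R > N || r > min(R, n)) {
    nr_validation_error(sprintf(
      "invalid hypergeometric parameters r=%d R=%d n=%d N=%d (need 0 <= r <= min(R, n), R <= N, n <= N)",
      r, R, n, N))
  }
  if (r == 0) return(1)
  phyper(r - 1L, m = n, n = N - n, k = R, lower.tail = FALSE)
}

#' Overconnectivity p-value of a node with a gene set
#'
#' A node is overconnected with the list of interest when it has more direct
#' interactions with set members than expected by chance given its degree.
#' The hypergeometric parameters are assembled from the network: `r` = the
#' node's interactions with set members, `R` = the node's degree, `n` = the
#' summed degree of the set members, `N` = total interactions in the
#' network.
#'
#' @param net an `interaction_network`
#' @param v candidate node id
#' @param s a `gene_set` (non-empty)
#' @param exclude_self_from_population when `v` itself belongs to `s`,
#'   remove `v`'s own degree (and its links counted through membership) from
#'   `n`; default `FALSE` keeps the literal parameter definitions
#' @return p-value; an isolated node (`R = 0`) returns 1 with attribute
#'   `diagnostic = "isolated"`
#' @export
overconnection_pvalue <- function(net, v, s,
                                  exclude_self_from_population = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  members <- gene_set_members(s)
  if (!length(members)) nr_validation_error("gene set of interest is empty")
  p <- overconnection_params(net, v, s, exclude_self_from_population)
  if (p$R == 0) {
    return(structure(1, diagnostic = "isolated"))
  }
  hypergeom_tail(p$r, p$R, p$n, p$N)
}

overconnection_params <- function(net, v, s,
                                  exclude_self_from_population = FALSE) {
  members <- gene_set_members(s)
  r <- links_to_set(net, v, members)
  R <- node_degree(net, v)
  in_net <- intersect(members, net$nodes)
  n <- sum(vapply(in_net, function(g) node_degree(net, g), integer(1)))
  if (exclude_self_from_population && v %in% in_net) {
    n <- n - R
    r <- links_to_set(net, v, setdiff(members, v))
  }
  N <- n_interactions(net)
  # summed member degree double-counts set-internal interactions and can
  # exceed the record count; the hypergeometric population is capped at N
  capped <- n > N
  n <- min(n, N)
  list(r = r, R = R, n = n, N = N, n_capped = capped)
}

#' Construct a ranked list of nodes with p-values
#'
#' Entries are sorted ascending by p-value; ties break by larger `r`
#' (stronger raw signal first) and then lexicographic node id, so rankings
#' are fully deterministic.
#'
#' @param tab data.frame with at least columns `node` and `p_value`;
#'   optional `r` used for tie-breaks, other columns carried through
#' @param weights optional per-entry weights (default: the p-values)
#' @return object of class `ranked_list` (a data.frame)
#' @export
ranked_list <- function(tab, weights = NULL) {
  stopifnot(is.data.frame(tab), all(c("node", "p_value") %in% names(tab)))
  if (anyDuplicated(tab$node)) nr_validation_error("duplicate nodes in ranked list")
  r_tie <- if ("r" %in% names(tab)) -as.numeric(tab$r) else rep(0, nrow(tab))
  ord <- order(tab$p_value, r_tie, tab$node)
  tab <- tab[ord, , drop = FALSE]
  tab$weight <- if (is.null(weights)) tab$p_value else weights[ord]
  rownames(tab) <- NULL
  structure(tab, class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, n = 10, ...) {
  cat(sprintf("ranked_list: %d entries\n", nrow(x)))
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

#' Top-k node ids of a ranked list
#' @param x a `ranked_list`
#' @param k list length
#' @return character vector of length `min(k, nrow(x))`
#' @export
top_k <- function(x, k) {
  stopifnot(inherits(x, "ranked_list"))
  head(x$node, k)
}

#' Rank candidate nodes by overconnectivity with a gene set
#'
#' @param net an `interaction_network`
#' @param s a `gene_set` (non-empty)
#' @param candidates character vector of candidate node ids, or a node
#'   class name (e.g. `"transcription_factor"`, `"receptor"`) selecting all
#'   nodes of that class
#' @param exclude_self_from_population see [overconnection_pvalue()]
#' @return a `ranked_list` with columns `node`, `class`, `r`, `R`, `n`,
#'   `N`, `p_value`
#' @export
rank_overconnected <- function(net, s, candidates = "transcription_factor",
                               exclude_self_from_population = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  cand <- resolve_candidates(net, candidates)
  if (!length(cand)) nr_validation_error("empty candidate set")
  members <- gene_set_members(s)
  if (!length(members)) nr_validation_error("gene set of interest is empty")
  rows <- lapply(cand, function(v) {
    pr <- overconnection_params(net, v, s, exclude_self_from_population)
    pv <- if (pr$R == 0) 1 else hypergeom_tail(pr$r, pr$R, pr$n, pr$N)
    data.frame(node = v, class = unname(net$node_class[v]),
               r = pr$r, R = pr$R, n = pr$n, N = pr$N, p_value = pv,
               stringsAsFactors = FALSE)
  })
  ranked_list(do.call(rbind, rows))
}

resolve_candidates <- function(net, candidates) {
  if (length(candidates) == 1 && candidates %in% NODE_CLASSES) {
    nodes_of_class(net, candidates)
  } else {
    unknown <- setdiff(candidates, net$nodes)
    if (length(unknown)) {
      nr_lookup_error(sprintf("unknown candidate node(s): %s",
                              paste(head(unknown, 5), collapse = ", ")))
    }
    unique(candidates)
  }
}

#' Write a ranked list as a TSV report
#'
#' Mirrors the structure of published over-connection tables: one row per
#' node with the hypergeometric parameters and raw p-value; optionally a
#' BH-adjusted column (topology p-values are reported raw by default).
#'
#' @param x a `ranked_list`
#' @param path output path
#' @param adjust add a `q_value` BH column
#' @return invisibly, `path`
#' @export
write_ranking <- function(x, path, adjust = FALSE) {
  stopifnot(inherits(x, "ranked_list"))
  tab <- as.data.frame(x)
  if (adjust) tab$q_value <- p.adjust(tab$p_value, method = "BH")
  write_tsv_report(tab, path)
}
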