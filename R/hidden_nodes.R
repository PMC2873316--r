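## Multi-step topological significance ("hidden nodes"): nodes are scored by
## over-representation on transcription-activation shortest paths leading to
## the genes of interest, against the universe of all such paths.

#' Build the transcription-activation shortest-path index
#'
#' Enumerates, for every ordered (source, target) pair with the target in
#' scope, all admissible shortest paths: directed simple paths of hop count
#' at most `max_len` whose final edge is a transcription-regulation edge
#' leaving a transcription-factor node, and whose number of inhibitory edges
#' has the configured parity (default even, i.e. net-activating; edges with
#' effect `unspecified` count as non-inhibiting).  All equally short
#' admissible paths per pair are kept; parallel edges give distinct paths.
#'
#' The index stores, per node, in how many paths it appears (a node counts
#' once per path; source and terminal target both count as contained), plus
#' per-target path counts and the total path count.  These counts are the
#' hypergeometric parameters of [hidden_node_pvalue()].
#'
#' @param net an `interaction_network`
#' @param targets scope of terminal targets: a `gene_set`, a character
#'   vector, or `NULL` (default) for all nodes with at least one incoming
#'   transcription-regulation edge from a transcription factor -- the whole
#'   universe, as needed for ranking
#' @param parity `"even"` (default, net activation) or `"odd"` (the
#'   literal uneven-inhibition reading)
#' @param max_len maximum hop count per path (default 6)
#' @param exclude_unspecified drop edges with effect `unspecified` from
#'   admissible paths entirely (default `FALSE`: they count as activating)
#' @param keep_paths also return the enumerated paths (node-id vectors) for
#'   audit; off by default to save memory
#' @return object of class `activation_path_index`
#' @export
build_path_index <- function(net, targets = NULL,
                             parity = c("even", "odd"), max_len = 6,
                             exclude_unspecified = FALSE,
                             keep_paths = FALSE) {
  stopifnot(inherits(net, "interaction_network"))
  parity <- match.arg(parity)
  edges <- net$edges
  if (exclude_unspecified) edges <- edges[edges$effect != "unspecified", ,
                                          drop = FALSE]
  nodes <- net$nodes
  node_idx <- setNames(seq_along(nodes), nodes)

  terminal <- edges$mechanism == "transcription_regulation" &
    net$node_class[edges$source] == "transcription_factor"
  tr_targets <- sort(unique(edges$target[terminal]))

  if (is.null(targets)) {
    scope <- tr_targets
    skipped <- character()
  } else {
    want <- gene_set_members(targets)
    if (!length(want)) nr_validation_error("target set is empty")
    scope <- intersect(want, tr_targets)
    skipped <- setdiff(want, scope)
    if (length(skipped)) {
      message(sprintf(
        "build_path_index: %d target(s) without an incoming TF transcription-regulation edge skipped: %s",
        length(skipped), paste(head(skipped, 5), collapse = ", ")))
    }
  }

  if (!length(scope) || !nrow(edges)) {
    idx <- structure(
      list(nodes = nodes, targets = character(), n_paths = 0L,
           per_target = setNames(integer(), character()),
           containment = matrix(
             0L, nrow = length(nodes), ncol = 0,
             dimnames = list(nodes, character())),
           parity = parity, max_len = max_len, skipped = skipped,
           paths = if (keep_paths) list() else NULL),
      class = "activation_path_index")
    warning("no admissible transcription-activation path found; ",
            "hidden-node p-values will all be 1", call. = FALSE)
    return(idx)
  }

  res <- enumerate_activation_paths_cpp(
    n_nodes = length(nodes),
    edge_from = unname(node_idx[edges$source]),
    edge_to = unname(node_idx[edges$target]),
    edge_inhib = edges$effect == "inhibition",
    edge_terminal = terminal,
    targets = unname(node_idx[scope]),
    max_len = as.integer(max_len),
    parity = if (parity == "even") 0L else 1L,
    keep_paths = keep_paths)

  containment <- res$containment
  dimnames(containment) <- list(nodes, scope)
  paths <- NULL
  path_target <- NULL
  if (keep_paths) {
    paths <- lapply(res$paths, function(p) nodes[p])
    path_target <- nodes[res$path_target]
  }
  if (res$n_paths == 0) {
    warning("no admissible transcription-activation path found; ",
            "hidden-node p-values will all be 1", call. = FALSE)
  }
  structure(
    list(nodes = nodes, targets = scope, n_paths = res$n_paths,
         per_target = setNames(as.integer(res$per_target), scope),
         containment = containment, parity = parity, max_len = max_len,
         skipped = skipped, paths = paths, path_target = path_target),
    class = "activation_path_index")
}

#' @export
print.activation_path_index <- function(x, ...) {
  cat(sprintf(
    "activation_path_index: %d paths to %d targets (parity %s, max_len %d)\n",
    x$n_paths, length(x$targets), x$parity, x$max_len))
  invisible(x)
}

#' Hidden-node p-value of a candidate regulator
#'
#' Hypergeometric tail test of the candidate's presence on shortest
#' activation paths leading to the genes of interest: `r` = paths to set
#' members containing the candidate, `R` = all paths to set members,
#' `n` = all indexed paths containing the candidate, `N` = all indexed
#' paths.  The index must be built over the full universe (`targets = NULL`
#' in [build_path_index()]) so that paths to the set are a subset of the
#' indexed paths.
#'
#' @param idx an `activation_path_index`
#' @param v candidate node id
#' @param targets the gene set of interest (`gene_set` or character)
#' @return p-value in \[0, 1\]; 1 when the candidate lies on no path or the
#'   index is empty
#' @export
hidden_node_pvalue <- function(idx, v, targets) {
  stopifnot(inherits(idx, "activation_path_index"))
  pr <- hidden_node_params(idx, v, targets)
  if (pr$N == 0 || pr$n == 0 || pr$R == 0) return(1)
  hypergeom_tail(pr$r, pr$R, pr$n, pr$N)
}

hidden_node_params <- function(idx, v, targets) {
  members <- gene_set_members(targets)
  hit <- intersect(members, idx$targets)
  N <- idx$n_paths
  R <- sum(idx$per_target[hit])
  if (!(v %in% idx$nodes)) {
    return(list(r = 0L, R = R, n = 0L, N = N))
  }
  n <- sum(idx$containment[v, ])
  r <- sum(idx$containment[v, hit, drop = FALSE])
  list(r = as.integer(r), R = as.integer(R), n = as.integer(n),
       N = as.integer(N))
}

#' Rank candidate nodes by the hidden-nodes statistic
#'
#' Builds (or reuses) the path index over the full network as universe and
#' ranks the candidates ascending by [hidden_node_pvalue()].
#'
#' @param net an `interaction_network`
#' @param targets the gene set of interest
#' @param candidates candidate node ids or a node class name (default
#'   `"transcription_factor"`)
#' @param parity,max_len,exclude_unspecified see [build_path_index()]
#' @param idx optional pre-built universe index (saves recomputation when
#'   ranking several candidate classes or gene sets on one network)
#' @return a `ranked_list` with columns `node`, `class`, `r`, `R`, `n`,
#'   `N`, `p_value`
#' @export
rank_hidden_nodes <- function(net, targets,
                              candidates = "transcription_factor",
                              parity = c("even", "odd"), max_len = 6,
                              exclude_unspecified = FALSE, idx = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  parity <- match.arg(parity)
  cand <- resolve_candidates(net, candidates)
  if (!length(cand)) nr_validation_error("empty candidate set")
  members <- gene_set_members(targets)
  if (!length(members)) nr_validation_error("gene set of interest is empty")
  if (is.null(idx)) {
    idx <- build_path_index(net, targets = NULL, parity = parity,
                            max_len = max_len,
                            exclude_unspecified = exclude_unspecified)
  }
  rows <- lapply(cand, function(v) {
    pr <- hidden_node_params(idx, v, members)
    pv <- if (pr$N == 0 || pr$n == 0 || pr$R == 0) 1 else
      hypergeom_tail(pr$r, pr$R, pr$n, pr$N)
    data.frame(node = v, class = unname(net$node_class[v]),
               r = pr$r, R = pr$R, n = pr$n, N = pr$N, p_value = pv,
               stringsAsFactors = FALSE)
  })
  ranked_list(do.call(rbind, rows))
}

#' Dump indexed paths for audit
#'
#' One path per row, node ids comma-joined; requires an index built with
#' `keep_paths = TRUE`.
#'
#' @param idx an `activation_path_index`
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_path_dump <- function(idx, path) {
  stopifnot(inherits(idx, "activation_path_index"))
  if (is.null(idx$paths)) {
    nr_validation_error("index was built with keep_paths = FALSE")
  }
  write_tsv_report(
    data.frame(target = idx$path_target %||% character(),
               length = vapply(idx$paths, function(p) length(p) - 1L,
                               integer(1)),
               path = vapply(idx$paths, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE),
    path)
}
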