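## Data model and I/O for signed directed interaction networks, node
## attributes and gene sets, plus the counting primitives every
## hypergeometric statistic in the package builds on.

NODE_CLASSES <- c("ligand", "receptor", "kinase", "transcription_factor",
                  "generic")
EDGE_EFFECTS <- c("activation", "inhibition", "unspecified")
EDGE_MECHANISMS <- c("transcription_regulation", "other")

#' Construct a signed directed interaction network
#'
#' The network is the analysis universe for every statistic in the package:
#' a set of typed nodes (ligand, receptor, kinase, transcription factor or
#' generic) and a multiset of directed, signed interactions.  The total
#' number of stored interaction records is the population size `N` used by
#' the overconnectivity statistic.
#'
#' Parallel edges between the same ordered node pair are permitted only when
#' they differ in `(effect, mechanism)`; exact duplicate records are
#' rejected.  Self-loops are rejected unless `allow_self_loops = TRUE`.
#'
#' @param edges data.frame with character columns `source`, `target`,
#'   `effect` (one of `activation`, `inhibition`, `unspecified`) and
#'   `mechanism` (one of `transcription_regulation`, `other`).
#' @param node_class named character vector mapping node ids to classes;
#'   nodes present in `edges` but absent here default to `generic`.
#' @param allow_self_loops permit `source == target` records.
#' @return an object of class `interaction_network`.
#' @export
interaction_network <- function(edges, node_class = character(),
                                allow_self_loops = FALSE) {
  req <- c("source", "target", "effect", "mechanism")
  if (!is.data.frame(edges) || !all(req %in% names(edges))) {
    nr_validation_error(
      "edges must be a data.frame with columns source, target, effect, mechanism")
  }
  edges <- data.frame(
    source = trimws(as.character(edges$source)),
    target = trimws(as.character(edges$target)),
    effect = as.character(edges$effect),
    mechanism = as.character(edges$mechanism),
    stringsAsFactors = FALSE
  )
  bad_eff <- which(!(edges$effect %in% EDGE_EFFECTS))
  if (length(bad_eff)) {
    nr_validation_error(sprintf(
      "unknown effect '%s' in edge record %d (allowed: %s)",
      edges$effect[bad_eff[1]], bad_eff[1], paste(EDGE_EFFECTS, collapse = ", ")))
  }
  bad_mech <- which(!(edges$mechanism %in% EDGE_MECHANISMS))
  if (length(bad_mech)) {
    nr_validation_error(sprintf(
      "unknown mechanism '%s' in edge record %d (allowed: %s)",
      edges$mechanism[bad_mech[1]], bad_mech[1],
      paste(EDGE_MECHANISMS, collapse = ", ")))
  }
  if (!allow_self_loops && any(edges$source == edges$target)) {
    i <- which(edges$source == edges$target)[1]
    nr_validation_error(sprintf(
      "self-loop on node '%s' (edge record %d); set allow_self_loops = TRUE to permit",
      edges$source[i], i))
  }
  key <- paste(edges$source, edges$target, edges$effect, edges$mechanism,
               sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    nr_validation_error(sprintf(
      "duplicate interaction record %d (%s -> %s, %s, %s); parallel edges must differ in (effect, mechanism)",
      i, edges$source[i], edges$target[i], edges$effect[i], edges$mechanism[i]))
  }

  nodes <- sort(unique(c(edges$source, edges$target, names(node_class))))
  cls <- setNames(rep("generic", length(nodes)), nodes)
  if (length(node_class)) {
    node_class <- setNames(as.character(node_class),
                           trimws(names(node_class)))
    unknown <- !(node_class %in% NODE_CLASSES)
    node_class[unknown] <- "generic"
    cls[names(node_class)] <- node_class
  }

  idx <- seq_len(nrow(edges))
  adj_out <- split(idx, factor(edges$source, levels = nodes))
  adj_in <- split(idx, factor(edges$target, levels = nodes))

  structure(
    list(nodes = nodes, node_class = cls, edges = edges,
         adj_out = adj_out, adj_in = adj_in,
         allow_self_loops = allow_self_loops),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d interaction records\n",
              length(x$nodes), nrow(x$edges)))
  tb <- table(factor(x$node_class, levels = NODE_CLASSES))
  cat("  node classes:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  cat(sprintf("  transcription-regulation edges: %d\n",
              sum(x$edges$mechanism == "transcription_regulation")))
  invisible(x)
}

#' Total number of stored interaction records (the universe size N)
#' @param net an `interaction_network`
#' @return integer count
#' @export
n_interactions <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  nrow(net$edges)
}

#' Interaction-count diagnostics under both counting conventions
#'
#' The population size of the overconnectivity statistic can be read either
#' as stored interaction records (one per mechanism/sign variant) or as
#' unique ordered node pairs.  The package counts records everywhere; this
#' helper exposes both numbers so users can compare conventions.
#'
#' @param net an `interaction_network`
#' @return named list with `n_records` and `n_unique_pairs`
#' @export
network_counts <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  list(
    n_records = nrow(net$edges),
    n_unique_pairs = nrow(unique(net$edges[, c("source", "target")]))
  )
}

#' Degree of a node
#'
#' Counts interaction records incident to `v` (incoming plus outgoing), each
#' stored record once.  A reciprocal A->B / B->A pair therefore contributes
#' 2 to both endpoints, so that summed degree equals twice the number of
#' interactions.
#'
#' @param net an `interaction_network`
#' @param v node identifier
#' @return integer degree
#' @export
node_degree <- function(net, v) {
  stopifnot(inherits(net, "interaction_network"))
  if (!(v %in% net$nodes)) nr_lookup_error(sprintf("unknown node '%s'", v))
  length(net$adj_out[[v]]) + length(net$adj_in[[v]])
}

#' Number of interactions between a node and a gene set
#'
#' Counts stored interaction records for which the endpoint opposite `v`
#' belongs to `s`, in either direction.  A record with both endpoints in the
#' set (one of them `v`) counts once; `v`'s own membership in `s` adds
#' nothing by itself.
#'
#' @param net an `interaction_network`
#' @param v node identifier
#' @param s a `gene_set` or character vector of members
#' @return integer count
#' @export
links_to_set <- function(net, v, s) {
  stopifnot(inherits(net, "interaction_network"))
  if (!(v %in% net$nodes)) nr_lookup_error(sprintf("unknown node '%s'", v))
  members <- gene_set_members(s)
  sum(net$edges$target[net$adj_out[[v]]] %in% members) +
    sum(net$edges$source[net$adj_in[[v]]] %in% members)
}

#' Construct a named gene set ("list of interest")
#'
#' @param name set name
#' @param members character vector of node identifiers; whitespace-trimmed,
#'   duplicates removed
#' @return object of class `gene_set`
#' @export
gene_set <- function(name, members) {
  members <- unique(trimws(as.character(members)))
  members <- members[nzchar(members)]
  structure(list(name = as.character(name), members = members),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members\n", x$name, length(x$members)))
  invisible(x)
}

gene_set_members <- function(s) {
  if (inherits(s, "gene_set")) s$members else unique(trimws(as.character(s)))
}

#' Read a signed directed network from edge-list and node-attribute TSVs
#'
#' The edge file must be tab-separated with header
#' `source\ttarget\teffect\tmechanism`; the attribute file has header
#' `node\tclass`.  Unknown node classes fall back to `generic`; unknown
#' effect or mechanism strings are an error naming the offending line.
#'
#' @param edge_path path to the edge-list TSV
#' @param attr_path optional path to the node-attribute TSV
#' @param allow_self_loops see [interaction_network()]
#' @return an `interaction_network`
#' @export
read_network <- function(edge_path, attr_path = NULL,
                         allow_self_loops = FALSE) {
  edges <- read_tsv_file(edge_path, "edge file")
  req <- c("source", "target", "effect", "mechanism")
  if (!all(req %in% names(edges))) {
    nr_parse_error(sprintf(
      "edge file %s: header must contain columns %s",
      edge_path, paste(req, collapse = ", ")))
  }
  if (nrow(edges)) {
    bad <- which(!(edges$effect %in% EDGE_EFFECTS))
    if (length(bad)) {
      nr_parse_error(sprintf(
        "edge file %s line %d: unknown effect '%s'",
        edge_path, bad[1] + 1L, edges$effect[bad[1]]))
    }
    bad <- which(!(edges$mechanism %in% EDGE_MECHANISMS))
    if (length(bad)) {
      nr_parse_error(sprintf(
        "edge file %s line %d: unknown mechanism '%s'",
        edge_path, bad[1] + 1L, edges$mechanism[bad[1]]))
    }
    incomplete <- which(!nzchar(trimws(edges$source)) |
                          !nzchar(trimws(edges$target)))
    if (length(incomplete)) {
      nr_parse_error(sprintf("edge file %s line %d: empty node identifier",
                             edge_path, incomplete[1] + 1L))
    }
  }
  node_class <- character()
  if (!is.null(attr_path)) {
    attrs <- read_tsv_file(attr_path, "node-attribute file")
    if (!all(c("node", "class") %in% names(attrs))) {
      nr_parse_error(sprintf(
        "node-attribute file %s: header must contain columns node, class",
        attr_path))
    }
    node_class <- setNames(as.character(attrs$class),
                           as.character(attrs$node))
  }
  interaction_network(edges, node_class,
                      allow_self_loops = allow_self_loops)
}

#' Write a network back to edge-list and node-attribute TSVs
#'
#' Inverse of [read_network()]: a read/write/read round trip reproduces the
#' node set, the edge multiset and all node attributes.
#'
#' @param net an `interaction_network`
#' @param edge_path output path for the edge-list TSV
#' @param attr_path optional output path for the node-attribute TSV
#' @return invisibly, `net`
#' @export
write_network <- function(net, edge_path, attr_path = NULL) {
  stopifnot(inherits(net, "interaction_network"))
  write_tsv_report(net$edges, edge_path)
  if (!is.null(attr_path)) {
    write_tsv_report(
      data.frame(node = names(net$node_class),
                 class = unname(net$node_class),
                 stringsAsFactors = FALSE),
      attr_path)
  }
  invisible(net)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then members.  Duplicate members collapse.
#'
#' @param path GMT file path
#' @return list of `gene_set` objects
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) nr_io_error(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      nr_parse_error(sprintf(
        "GMT file %s line %d: expected >= 3 tab-separated fields, got %d",
        path, i, length(fields)))
    }
    out[[i]] <- gene_set(fields[1], fields[-(1:2)])
  }
  out
}

#' Write gene sets to a GMT file
#' @param sets list of `gene_set` objects (or a single one)
#' @param path output path
#' @param description description field (recycled)
#' @return invisibly, `path`
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, description, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Nodes of a given class
#' @param net an `interaction_network`
#' @param class one of `ligand`, `receptor`, `kinase`,
#'   `transcription_factor`, `generic`
#' @return character vector of node ids (sorted)
#' @export
nodes_of_class <- function(net, class) {
  stopifnot(inherits(net, "interaction_network"))
  class <- match.arg(class, NODE_CLASSES)
  sort(names(net$node_class)[net$node_class == class])
}
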