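# Independent oracles: brute-force/exhaustive computations kept deliberately
# separate from the package's own code paths.

# exhaustive hypergeometric tail: enumerate every C(N, R) draw
hyper_tail_enum <- function(r, R, n, N) {
  if (R == 0 || N == 0) return(as.numeric(r == 0))
  pop <- c(rep(1, n), rep(0, N - n))
  draws <- utils::combn(N, R)
  mean(colSums(matrix(pop[draws], nrow = R)) >= r)
}

# brute-force activation-path index: enumerate ALL simple directed paths
# (edge sequences) up to max_len, filter by terminal TR-from-TF edge,
# parity, and shortest-per-(source, target); return the same counts as
# build_path_index
brute_force_path_index <- function(net, scope = NULL, parity = "even",
                                   max_len = 6) {
  e <- net$edges
  nodes <- net$nodes
  terminal <- e$mechanism == "transcription_regulation" &
    net$node_class[e$source] == "transcription_factor"
  if (is.null(scope)) scope <- sort(unique(e$target[terminal]))

  paths <- list()  # each: list(nodes, target, len, inhib)
  grow <- function(node_seq, edge_seq) {
    len <- length(edge_seq)
    if (len > 0) {
      last <- edge_seq[len]
      if (terminal[last] && e$target[last] %in% scope) {
        inhib <- sum(e$effect[edge_seq] == "inhibition")
        want <- if (parity == "even") 0L else 1L
        if (inhib %% 2L == want) {
          paths[[length(paths) + 1L]] <<- list(
            nodes = node_seq, source = node_seq[1],
            target = node_seq[length(node_seq)], len = len)
        }
      }
    }
    if (len == max_len) return()
    v <- node_seq[length(node_seq)]
    for (ei in which(e$source == v)) {
      if (e$target[ei] %in% node_seq) next
      grow(c(node_seq, e$target[ei]), c(edge_seq, ei))
    }
  }
  for (s in nodes) grow(s, integer())

  # shortest per ordered (source, target) pair
  if (length(paths)) {
    key <- vapply(paths, function(p) paste(p$source, p$target), character(1))
    lens <- vapply(paths, function(p) p$len, integer(1))
    keep <- unlist(lapply(split(seq_along(paths), key), function(i) {
      i[lens[i] == min(lens[i])]
    }))
    paths <- paths[sort(keep)]
  }

  containment <- matrix(0L, nrow = length(nodes), ncol = length(scope),
                        dimnames = list(nodes, scope))
  per_target <- setNames(integer(length(scope)), scope)
  for (p in paths) {
    per_target[p$target] <- per_target[p$target] + 1L
    containment[unique(p$nodes), p$target] <-
      containment[unique(p$nodes), p$target] + 1L
  }
  list(n_paths = length(paths), per_target = per_target,
       containment = containment, paths = paths)
}

# permutation-null estimate of the overconnectivity p-value: the candidate's
# R interactions are re-drawn uniformly without replacement from all N
# records; success = the record involves a set member
perm_overconnection <- function(net, v, s, B = 10000, seed = 7) {
  members <- if (inherits(s, "gene_set")) s$members else s
  involves <- net$edges$source %in% members | net$edges$target %in% members
  R <- node_degree(net, v)
  r_obs <- links_to_set(net, v, s)
  withr::with_seed(seed, {
    hits <- vapply(seq_len(B), function(i) sum(sample(involves, R)),
                   numeric(1))
    mean(hits >= r_obs)
  })
}

# exhaustive weighted-footrule optimum over all ordered k-subsets
exhaustive_aggregate <- function(problem) {
  u <- problem$universe
  k <- problem$k
  stopifnot(length(u) <= 7, k <= 3)
  idx <- seq_along(u)
  combos <- if (k == 1) matrix(idx, nrow = 1) else
    utils::combn(idx, k)
  best <- Inf
  best_list <- NULL
  perm_rows <- perms(k)
  for (j in seq_len(ncol(combos))) {
    for (pr in seq_len(nrow(perm_rows))) {
      cand <- u[combos[, j][perm_rows[pr, ]]]
      f <- aggregation_fitness(cand, problem)
      if (f < best - 1e-12) {
        best <- f
        best_list <- cand
      }
    }
  }
  list(fitness = best, nodes = best_list)
}

perms <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow = nrow(sub))))
  }
  unname(out)
}
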