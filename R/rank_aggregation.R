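## Weighted Spearman-footrule rank aggregation: combine several p-value
## rankings of the same candidate space into one optimal ordered list of
## size k, minimizing the summed weighted footrule distance with a genetic
## algorithm.

#' Position weights of a reference list
#'
#' Importance decreases linearly down the list: position j of a k-list gets
#' weight `1 - (j - 1) / (k + 1)`; position `k + 1` (the rank assigned to
#' elements absent from the list) gets the smallest, still positive, weight
#' `1 / (k + 1)`.  With `scheme = "uniform"` all weights are 1 and the
#' distance reduces to the plain Spearman footrule.
#'
#' @param k list size
#' @param scheme `"pvalue_rank"` (default) or `"uniform"`
#' @return numeric vector of length `k + 1`
#' @export
footrule_weights <- function(k, scheme = c("pvalue_rank", "uniform")) {
  scheme <- match.arg(scheme)
  j <- seq_len(k + 1)
  if (scheme == "uniform") rep(1, k + 1) else 1 - (j - 1) / (k + 1)
}

#' Weighted Spearman footrule distance to a reference ranked list
#'
#' Over the union of the candidate list and the reference's top-k, sums the
#' importance-weighted absolute rank differences.  An element absent from a
#' list takes rank `k + 1`; element importance is the reference list's
#' position weight (see [footrule_weights()]).  The distance is 0 exactly
#' when the candidate reproduces the reference top-k in order.
#'
#' @param candidate character vector of length `k`, no duplicates
#' @param ref a `ranked_list` (or character vector already in rank order)
#' @param k list size (default: length of `candidate`)
#' @param scheme weight scheme, see [footrule_weights()]
#' @return non-negative distance
#' @export
weighted_spearman_distance <- function(candidate, ref,
                                       k = length(candidate),
                                       scheme = c("pvalue_rank", "uniform")) {
  scheme <- match.arg(scheme)
  candidate <- as.character(candidate)
  if (length(candidate) != k) {
    nr_validation_error(sprintf("candidate must have length k = %d", k))
  }
  if (anyDuplicated(candidate)) {
    nr_validation_error("duplicate elements in candidate list")
  }
  ref_top <- if (inherits(ref, "ranked_list")) top_k(ref, k) else
    head(as.character(ref), k)
  w <- footrule_weights(k, scheme)
  universe <- union(candidate, ref_top)
  rc <- match(universe, candidate, nomatch = k + 1L)
  rr <- match(universe, ref_top, nomatch = k + 1L)
  sum(w[rr] * abs(rc - rr))
}

#' Define a rank-aggregation problem
#'
#' @param lists list of two or more `ranked_list` objects (or character
#'   vectors in rank order); each is truncated to its top-k
#' @param k target aggregated list size (default 20, capped at the shortest
#'   input list)
#' @param scheme weight scheme, see [footrule_weights()]
#' @param ga_config named list overriding genetic-algorithm settings:
#'   `pop_size` (100), `generations` (500), `crossover_rate` (0.8),
#'   `mutation_rate` (0.05), `convergence_window` (50), `seed` (1)
#' @return object of class `aggregation_problem`
#' @export
aggregation_problem <- function(lists, k = 20,
                                scheme = c("pvalue_rank", "uniform"),
                                ga_config = list()) {
  scheme <- match.arg(scheme)
  if (!is.list(lists) || length(lists) < 2) {
    nr_validation_error("need at least two input ranked lists")
  }
  tops <- lapply(lists, function(l) {
    v <- if (inherits(l, "ranked_list")) l$node else as.character(l)
    if (!length(v)) nr_validation_error("empty input ranked list")
    head(v, k)
  })
  k <- min(k, min(lengths(tops)))
  tops <- lapply(tops, head, k)
  # canonical list order: aggregation must not depend on argument order
  tops <- tops[order(vapply(tops, paste, character(1), collapse = "\r"))]
  universe <- sort(unique(unlist(tops)))
  if (k > length(universe)) {
    nr_validation_error("k exceeds the union of candidates")
  }
  cfg <- modifyList(
    list(pop_size = 100L, generations = 500L, crossover_rate = 0.8,
         mutation_rate = 0.05, convergence_window = 50L, seed = 1L),
    ga_config)
  structure(list(tops = tops, k = k, scheme = scheme, universe = universe,
                 ga_config = cfg),
            class = "aggregation_problem")
}

#' Total aggregation fitness of a candidate ordered list
#'
#' Sum of [weighted_spearman_distance()] to every input list of the
#' problem; the objective the genetic algorithm minimizes.
#'
#' @param candidate character vector of length `k`
#' @param problem an `aggregation_problem`
#' @return non-negative fitness
#' @export
aggregation_fitness <- function(candidate, problem) {
  stopifnot(inherits(problem, "aggregation_problem"))
  sum(vapply(problem$tops, function(ref) {
    weighted_spearman_distance(candidate, ref, k = problem$k,
                               scheme = problem$scheme)
  }, numeric(1)))
}

#' Aggregate ranked lists into one optimal list of size k
#'
#' Genetic algorithm over ordered k-subsets of the candidate union:
#' population seeded with every input list's top-k plus random lists,
#' tournament selection, order-preserving crossover, point mutation that
#' swaps a member with an element outside the list (or transposes two
#' positions when the universe is exhausted), elitism of one, stopping
#' after `generations` or when the best fitness has not improved for
#' `convergence_window` generations.  Reproducible given the seed and
#' invariant to the order in which input lists are supplied.
#'
#' @param problem an `aggregation_problem`
#' @return list with `nodes` (the aggregated list), `fitness`,
#'   `per_list_distance`, `generations_run`, `best_history`
#' @export
aggregate_rankings <- function(problem) {
  stopifnot(inherits(problem, "aggregation_problem"))
  k <- problem$k
  universe <- problem$universe
  nu <- length(universe)
  cfg <- problem$ga_config
  w <- footrule_weights(k, problem$scheme)

  # per-list reference ranks over the universe (k+1 = absent)
  ref_ranks <- lapply(problem$tops, function(tp) {
    match(universe, tp, nomatch = k + 1L)
  })
  fitness_of <- function(ind) {  # ind: integer k-vector of universe indices
    rc <- rep.int(k + 1L, nu)
    rc[ind] <- seq_len(k)
    tot <- 0
    for (rr in ref_ranks) {
      touched <- rr <= k | rc <= k
      tot <- tot + sum(w[rr[touched]] * abs(rc[touched] - rr[touched]))
    }
    tot
  }

  with_seed(cfg$seed, {
    pop_size <- max(cfg$pop_size, length(problem$tops) + 1L)
    pop <- vector("list", pop_size)
    seeds <- lapply(problem$tops, function(tp) match(tp, universe))
    for (i in seq_len(pop_size)) {
      pop[[i]] <- if (i <= length(seeds)) seeds[[i]] else sample.int(nu, k)
    }
    fit <- vapply(pop, fitness_of, numeric(1))

    best_i <- which.min(fit)
    best <- pop[[best_i]]
    best_fit <- fit[best_i]
    history <- best_fit
    stall <- 0L
    gens_run <- 0L

    for (gen in seq_len(cfg$generations)) {
      gens_run <- gen
      newpop <- vector("list", pop_size)
      newpop[[1]] <- best  # elitism
      for (i in 2:pop_size) {
        # tournament selection, size 2
        a <- sample.int(pop_size, 2)
        pa <- pop[[if (fit[a[1]] <= fit[a[2]]) a[1] else a[2]]]
        b <- sample.int(pop_size, 2)
        pb <- pop[[if (fit[b[1]] <= fit[b[2]]) b[1] else b[2]]]
        child <- pa
        if (runif(1) < cfg$crossover_rate && k > 1) {
          cut <- sample.int(k - 1, 1)
          rest <- pb[!(pb %in% pa[seq_len(cut)])]
          child <- c(pa[seq_len(cut)], rest[seq_len(k - cut)])
        }
        mut <- runif(k) < cfg$mutation_rate
        if (any(mut)) {
          outside <- setdiff(seq_len(nu), child)
          for (pos in which(mut)) {
            if (length(outside)) {
              pick <- outside[sample.int(length(outside), 1)]
              outside[outside == pick] <- child[pos]
              child[pos] <- pick
            } else if (k > 1) {
              other <- sample.int(k, 1)
              tmp <- child[pos]; child[pos] <- child[other]; child[other] <- tmp
            }
          }
        }
        newpop[[i]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, fitness_of, numeric(1))
      gen_best <- which.min(fit)
      if (fit[gen_best] < best_fit - 1e-12) {
        best_fit <- fit[gen_best]
        best <- pop[[gen_best]]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history <- c(history, best_fit)
      if (stall >= cfg$convergence_window) break
    }

    nodes <- universe[best]
    list(nodes = nodes, fitness = best_fit,
         per_list_distance = vapply(problem$tops, function(ref) {
           weighted_spearman_distance(nodes, ref, k = k,
                                      scheme = problem$scheme)
         }, numeric(1)),
         generations_run = gens_run, best_history = history)
  })
}

#' Write an aggregated list with per-source ranks
#'
#' @param agg result of [aggregate_rankings()]
#' @param problem the `aggregation_problem` it solved
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_aggregate_report <- function(agg, problem, path) {
  tab <- data.frame(rank = seq_along(agg$nodes), node = agg$nodes,
                    stringsAsFactors = FALSE)
  for (i in seq_along(problem$tops)) {
    tab[[sprintf("source_rank_%d", i)]] <-
      match(agg$nodes, problem$tops[[i]], nomatch = NA_integer_)
  }
  write_tsv_report(tab, path)
}
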