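# Bitmask conventions: node i (1-based in `nodes`) occupies bit 2^(i-1);
# a set of nodes is the sum of its bits. With d <= ~20 this fits in a double.

mask_bits <- function(mask, d) which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1L))) != 0L)

#' Score every (node, parent set) pair
#'
#' Precomputes [local_bic()] for each node and every candidate parent set up
#' to `max_parents` parents, the input to exact and heuristic search.
#'
#' @param table Volume table.
#' @param nodes Node (ROI column) names; defaults to [dmn_nodes()]
#'   intersected with the table's columns.
#' @param max_parents Maximum parent-set size; `NULL` (default) means
#'   unrestricted, i.e. up to d - 1 parents.
#' @param param_count Passed to [local_bic()].
#' @return Object of class `score_cache`: `nodes`, `max_parents`, and
#'   `scores`, a list (one element per node) of numeric vectors indexed by
#'   parent-set bitmask + 1 (NA for sets containing the node itself or
#'   exceeding the size limit).
#' @export
score_all_parent_sets <- function(table, nodes = NULL, max_parents = NULL,
                                  param_count = "full") {
  if (is.null(nodes)) nodes <- intersect(dmn_nodes(), names(table))
  d <- length(nodes)
  if (is.null(max_parents)) max_parents <- d - 1L
  if (nrow(table) <= max_parents + 1L) {
    stop("need more than max_parents + 1 = ", max_parents + 1L, " rows")
  }
  scores <- vector("list", d)
  names(scores) <- nodes
  sizes <- vapply(0:(2^d - 1L), function(m) length(mask_bits(m, d)), numeric(1))
  for (j in seq_len(d)) {
    sj <- rep(NA_real_, 2^d)
    own <- bitwShiftL(1L, j - 1L)
    for (m in 0:(2^d - 1L)) {
      if (bitwAnd(m, own) != 0L || sizes[m + 1L] > max_parents) next
      pa <- nodes[mask_bits(m, d)]
      sj[m + 1L] <- local_bic(table, nodes[j], pa, param_count = param_count)
    }
    scores[[j]] <- sj
  }
  structure(list(nodes = nodes, max_parents = max_parents, scores = scores),
            class = "score_cache")
}

#' Look up a cached local score
#'
#' @param cache A `score_cache`.
#' @param node Node name.
#' @param parents Parent names.
#' @return Scalar score.
#' @export
cache_score <- function(cache, node, parents = character(0)) {
  d <- length(cache$nodes)
  idx <- match(parents, cache$nodes)
  if (anyNA(idx)) stop("unknown parent name")
  mask <- if (length(idx)) sum(bitwShiftL(1L, idx - 1L)) else 0L
  s <- cache$scores[[node]][mask + 1L]
  if (is.na(s)) stop("score not cached for this (node, parent set)")
  s
}

#' Exact BIC-optimal DAG by dynamic programming
#'
#' Finds a structure maximizing the decomposable network score using the
#' best-sink subset recursion: for every subset S of nodes, the best DAG on
#' S ends in some sink v whose parents are its best-scoring subset of
#' S - v. Deterministic: ties prefer fewer edges, then the smallest parent
#' set and earliest sink in the canonical node order. With d = 8 this visits
#' 256 subsets and is exact (no search heuristic).
#'
#' @param cache A complete `score_cache` (unrestricted `max_parents`, or the
#'   restriction applies to the optimum too).
#' @return A `dag_structure` maximizing the total score.
#' @export
exact_search <- function(cache) {
  stopifnot(inherits(cache, "score_cache"))
  nodes <- cache$nodes
  d <- length(nodes)
  n_masks <- 2^d
  if (any(vapply(seq_len(d), function(j) {
    own <- bitwShiftL(1L, j - 1L)
    sizes_ok <- vapply(0:(n_masks - 1L), function(m) {
      bitwAnd(m, own) != 0L || length(mask_bits(m, d)) > cache$max_parents ||
        !is.na(cache$scores[[j]][m + 1L])
    }, logical(1))
    !all(sizes_ok)
  }, logical(1)))) {
    stop("incomplete score cache")
  }

  # bps[[j]]: for each candidate-set mask C (excluding j), the best subset
  # P <= C by score, ties to smaller then lexicographically smaller P.
  bps <- vector("list", d)
  subset_order <- order(vapply(0:(n_masks - 1L), function(m)
    length(mask_bits(m, d)), numeric(1)), 0:(n_masks - 1L)) - 1L
  for (j in seq_len(d)) {
    own <- bitwShiftL(1L, j - 1L)
    bscore <- rep(-Inf, n_masks)
    bset <- rep(0L, n_masks)
    for (C in 0:(n_masks - 1L)) {
      if (bitwAnd(C, own) != 0L) next
      # enumerate subsets P of C in (size, mask) order
      for (m in subset_order) {
        if (bitwAnd(m, C) != m) next
        s <- cache$scores[[j]][m + 1L]
        if (!is.na(s) && s > bscore[C + 1L]) {
          bscore[C + 1L] <- s
          bset[C + 1L] <- m
        }
      }
    }
    bps[[j]] <- list(score = bscore, set = bset)
  }

  # best(S): optimal score of a DAG on the node subset S
  best <- rep(0, n_masks)
  best_edges <- rep(0L, n_masks)        # edge count of the chosen optimum
  sink_of <- rep(NA_integer_, n_masks)
  for (S in 1:(n_masks - 1L)) {
    members <- mask_bits(S, d)
    bs <- -Inf; be <- NA_integer_; bj <- NA_integer_
    for (j in members) {
      rest <- S - bitwShiftL(1L, j - 1L)
      pset <- bps[[j]]$set[rest + 1L]
      sc <- best[rest + 1L] + bps[[j]]$score[rest + 1L]
      ec <- best_edges[rest + 1L] + length(mask_bits(pset, d))
      if (sc > bs + 1e-12 ||
          (abs(sc - bs) <= 1e-12 && (is.na(be) || ec < be))) {
        bs <- sc; be <- ec; bj <- j
      }
    }
    best[S + 1L] <- bs
    best_edges[S + 1L] <- be
    sink_of[S + 1L] <- bj
  }

  parents <- stats::setNames(rep(list(character(0)), d), nodes)
  S <- n_masks - 1L
  while (S > 0L) {
    j <- sink_of[S + 1L]
    rest <- S - bitwShiftL(1L, j - 1L)
    pmask <- bps[[j]]$set[rest + 1L]
    parents[[nodes[j]]] <- nodes[mask_bits(pmask, d)]
    S <- rest
  }
  dag_structure(nodes, parents)
}

#' Total cached score of a DAG
#'
#' @param cache A `score_cache`.
#' @param dag A `dag_structure` over the cache's nodes.
#' @return Scalar network score from cached local scores.
#' @export
dag_score <- function(cache, dag) {
  sum(vapply(dag$nodes, function(v) cache_score(cache, v, dag$parents[[v]]),
             numeric(1)))
}

#' Enumerate every DAG on a small node set
#'
#' Generates all labelled DAGs by combining node permutations (topological
#' orders) with subsets of the forward edges and de-duplicating; exact but
#' exponential, so restricted to 5 or fewer nodes (29281 DAGs at d = 5).
#'
#' @param nodes Character vector of at most 5 node names.
#' @return List of `dag_structure` objects, one per distinct DAG.
#' @export
enumerate_dags <- function(nodes) {
  d <- length(nodes)
  if (d > 5L) stop("DAG enumeration refused for more than 5 nodes")
  if (d == 1L) return(list(dag_structure(nodes)))
  perms <- all_permutations(seq_len(d))
  pairs <- utils::combn(d, 2L)           # forward pairs within an order
  n_pairs <- ncol(pairs)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (p in perms) {
    for (mask in 0:(2^n_pairs - 1L)) {
      parents <- stats::setNames(rep(list(character(0)), d), nodes)
      if (mask > 0L) {
        use <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n_pairs - 1L))) != 0L)
        for (k in use) {
          u <- nodes[p[pairs[1L, k]]]
          v <- nodes[p[pairs[2L, k]]]
          parents[[v]] <- c(parents[[v]], u)
        }
      }
      key <- paste(vapply(nodes, function(v)
        paste(sort(parents[[v]]), collapse = ","), character(1)),
        collapse = ";")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <- dag_structure(nodes, parents)
    }
  }
  out
}

all_permutations <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Exhaustive structure search (test oracle for small node sets)
#'
#' Scores every DAG on the given nodes and returns the maximizer under the
#' same tie-breaking as [exact_search()] (fewest edges, then canonical
#' parent-set order). Exponential; refuses more than 5 nodes.
#'
#' @param table Volume table.
#' @param nodes Node names (at most 5).
#' @param param_count Passed to the scoring.
#' @return A `dag_structure`.
#' @export
exhaustive_search <- function(table, nodes, param_count = "full") {
  d <- length(nodes)
  if (d > 5L) stop("exhaustive search refused for more than 5 nodes")
  cache <- score_all_parent_sets(table, nodes = nodes,
                                 param_count = param_count)
  dags <- enumerate_dags(nodes)
  best <- NULL; bs <- -Inf; be <- NA_integer_
  for (g in dags) {
    sc <- dag_score(cache, g)
    ec <- n_edges(g)
    if (sc > bs + 1e-12 || (abs(sc - bs) <= 1e-12 && ec < be)) {
      bs <- sc; be <- ec; best <- g
    }
  }
  best
}

#' Greedy hill-climbing structure search with perturbation restarts
#'
#' Repeatedly applies the best score-improving single-edge move (add,
#' delete or reverse, keeping the graph acyclic) until no move improves
#' the score. The first climb starts from the empty graph; each further
#' restart perturbs the best structure found so far with a few random
#' moves and re-climbs (iterated local search), which escapes the
#' orientation local optima that plain restarts tend to re-enter. The best
#' structure over all restarts is returned; deterministic given `seed`.
#' Kept as a robustness check against [exact_search()], which is exact and
#' preferred at 8 nodes.
#'
#' @param table Volume table.
#' @param nodes Node names; defaults as in [score_all_parent_sets()].
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of starts (>= 1).
#' @param max_parents Parent-set size limit (default unrestricted).
#' @param param_count Passed to the scoring.
#' @return A `dag_structure`.
#' @export
hill_climb <- function(table, nodes = NULL, seed = 1L, n_restarts = 20L,
                       max_parents = NULL, param_count = "full") {
  if (is.null(nodes)) nodes <- intersect(dmn_nodes(), names(table))
  d <- length(nodes)
  if (d == 1L) return(dag_structure(nodes))
  cache <- score_all_parent_sets(table, nodes = nodes,
                                 max_parents = max_parents,
                                 param_count = param_count)
  climb_one <- function(start) {
    g <- start
    sc <- dag_score(cache, g)
    repeat {
      cand <- propose_moves(g, cache$max_parents)
      if (!length(cand)) break
      scores <- vapply(cand, function(h) dag_score(cache, h), numeric(1))
      k <- which.max(scores)
      if (scores[k] > sc + 1e-12) {
        g <- cand[[k]]
        sc <- scores[k]
      } else break
    }
    list(dag = g, score = sc)
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      start <- if (r == 1L) {
        dag_structure(nodes)
      } else {
        perturb_dag(best$dag, n_moves = 8L, max_parents = cache$max_parents)
      }
      res <- climb_one(start)
      if (is.null(best) || res$score > best$score + 1e-12 ||
          (abs(res$score - best$score) <= 1e-12 &&
           n_edges(res$dag) < n_edges(best$dag))) {
        best <- res
      }
    }
  })
  best$dag
}

# apply a few random legal single-edge moves (the restart kick)
perturb_dag <- function(g, n_moves, max_parents) {
  for (k in seq_len(n_moves)) {
    cand <- propose_moves(g, max_parents)
    if (!length(cand)) break
    g <- cand[[sample.int(length(cand), 1L)]]
  }
  g
}

# all single-edge neighbours of g that stay acyclic and within max_parents
propose_moves <- function(g, max_parents) {
  nodes <- g$nodes
  out <- list()
  add <- function(parents) {
    dag <- tryCatch(dag_structure(nodes, parents), error = function(e) NULL)
    if (!is.null(dag)) out[[length(out) + 1L]] <<- dag
  }
  for (u in nodes) for (v in nodes) {
    if (u == v) next
    p <- g$parents
    if (u %in% p[[v]]) {
      q <- p; q[[v]] <- setdiff(q[[v]], u)          # delete u -> v
      add(q)
      if (length(q[[u]]) < max_parents) {           # reverse to v -> u
        q2 <- q; q2[[u]] <- c(q2[[u]], v)
        add(q2)
      }
    } else if (length(p[[v]]) < max_parents) {      # add u -> v
      q <- p; q[[v]] <- c(q[[v]], u)
      add(q)
    }
  }
  out
}

# random DAG: random topological order, each forward edge kept with prob
random_dag <- function(nodes, prob) {
  d <- length(nodes)
  ord <- sample(nodes)
  parents <- stats::setNames(rep(list(character(0)), d), nodes)
  for (i in seq_len(d - 1L)) {
    for (j in seq(i + 1L, d)) {
      if (stats::runif(1) < prob) {
        parents[[ord[j]]] <- c(parents[[ord[j]]], ord[i])
      }
    }
  }
  dag_structure(nodes, parents)
}

#' Learn a structure from data
#'
#' Thin wrapper selecting the search algorithm: `"exact"` (default, dynamic
#' programming, guaranteed optimum at 8 nodes) or `"hillclimb"`.
#'
#' @param table Volume table.
#' @param nodes Node names; defaults as in [score_all_parent_sets()].
#' @param algorithm `"exact"` or `"hillclimb"`.
#' @param max_parents Parent-set size limit (default unrestricted).
#' @param seed Seed for hill climbing restarts (ignored by exact search).
#' @param param_count Passed to the scoring.
#' @return A `dag_structure`.
#' @export
learn_structure <- function(table, nodes = NULL,
                            algorithm = c("exact", "hillclimb"),
                            max_parents = NULL, seed = 1L,
                            param_count = "full") {
  algorithm <- match.arg(algorithm)
  if (is.null(nodes)) nodes <- intersect(dmn_nodes(), names(table))
  if (algorithm == "exact") {
    cache <- score_all_parent_sets(table, nodes = nodes,
                                   max_parents = max_parents,
                                   param_count = param_count)
    exact_search(cache)
  } else {
    hill_climb(table, nodes = nodes, seed = seed, max_parents = max_parents,
               param_count = param_count)
  }
}
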