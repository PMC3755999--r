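#' The eight default-mode-network regions of interest, in canonical order
#'
#' Fixed node order used throughout the package for deterministic
#' tie-breaking: posterior cingulate (PCC), medial prefrontal (mPFC),
#' left/right hippocampus (lHP, rHP), left/right inferior parietal
#' (lIPC, rIPC), left/right inferior temporal (lITC, rITC).
#'
#' @return Character vector of the 8 ROI abbreviations.
#' @export
dmn_nodes <- function() {
  c("PCC", "mPFC", "lHP", "rHP", "lIPC", "rIPC", "lITC", "rITC")
}

#' Directed acyclic graph over named nodes
#'
#' A `dag_structure` stores an ordered node list and, for each node, its
#' ordered parent set. Construction validates that parents are known nodes,
#' that there are no self-loops, and that the graph admits a topological
#' order (i.e. is acyclic).
#'
#' @param nodes Character vector of node names (unique, non-empty).
#' @param parents Named list mapping a node to a character vector of its
#'   parents. Nodes absent from the list get an empty parent set.
#' @return An object of class `dag_structure` with elements `nodes` and
#'   `parents` (complete named list, one entry per node).
#' @export
dag_structure <- function(nodes, parents = list()) {
  if (!is.character(nodes) || length(nodes) < 1L || anyDuplicated(nodes)) {
    stop("'nodes' must be a character vector of unique names")
  }
  if (length(parents) && (is.null(names(parents)) || any(!nzchar(names(parents))))) {
    stop("'parents' must be a named list")
  }
  unknown <- setdiff(names(parents), nodes)
  if (length(unknown)) {
    stop("parent sets given for unknown nodes: ", paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) {
    p <- unique(as.character(parents[[v]] %||% character(0)))
    bad <- setdiff(p, nodes)
    if (length(bad)) {
      stop("unknown parent(s) of ", v, ": ", paste(bad, collapse = ", "))
    }
    if (v %in% p) stop("self-loop at node ", v)
    full[[v]] <- p
  }
  dag <- structure(list(nodes = nodes, parents = full), class = "dag_structure")
  if (is.null(topological_order(dag))) {
    stop("edge set contains a directed cycle")
  }
  dag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a DAG from an edge list
#'
#' @param nodes Character vector of node names.
#' @param edges Two-column matrix or data.frame with columns (parent, child),
#'   or a list of length-2 character vectors.
#' @return A `dag_structure`.
#' @export
dag_from_edges <- function(nodes, edges) {
  parents <- stats::setNames(rep(list(character(0)), length(nodes)), nodes)
  em <- as_edge_matrix(edges)
  if (nrow(em)) {
    for (i in seq_len(nrow(em))) {
      parents[[em[i, 2L]]] <- c(parents[[em[i, 2L]]], em[i, 1L])
    }
  }
  dag_structure(nodes, parents)
}

# normalize the accepted edge representations to a 2-column character matrix
as_edge_matrix <- function(edges) {
  if (is.null(edges) || (is.list(edges) && !is.data.frame(edges) && !length(edges))) {
    return(matrix(character(0), ncol = 2L))
  }
  if (is.data.frame(edges)) {
    em <- cbind(as.character(edges[[1L]]), as.character(edges[[2L]]))
  } else if (is.matrix(edges)) {
    em <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
  } else if (is.list(edges)) {
    em <- do.call(rbind, lapply(edges, function(e) as.character(e[1:2])))
  } else {
    stop("unsupported edge representation")
  }
  if (ncol(em) != 2L) stop("edges must have two columns (parent, child)")
  em
}

#' Edge list of a DAG
#'
#' @param dag A `dag_structure`.
#' @return Data frame with columns `parent` and `child`, one row per edge,
#'   ordered by child then parent in the DAG's node order.
#' @export
dag_edges <- function(dag) {
  stopifnot(inherits(dag, "dag_structure"))
  out <- do.call(rbind, lapply(dag$nodes, function(v) {
    p <- dag$parents[[v]]
    if (!length(p)) return(NULL)
    data.frame(parent = p, child = v, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(parent = character(0), child = character(0))
  }
  out
}

#' Topological order of a DAG, or NULL if cyclic
#'
#' Kahn's algorithm; among simultaneously available nodes the earliest in
#' the stored node order is emitted first, so the result is deterministic.
#'
#' @param dag A `dag_structure` (or a bare list with `nodes`/`parents`).
#' @return Character vector of nodes in topological order, or `NULL` when
#'   the edge set has a directed cycle.
#' @export
topological_order <- function(dag) {
  nodes <- dag$nodes
  parents <- dag$parents
  remaining <- nodes
  placed <- character(0)
  while (length(remaining)) {
    avail <- remaining[vapply(remaining, function(v) {
      all(parents[[v]] %in% placed)
    }, logical(1))]
    if (!length(avail)) return(NULL)
    placed <- c(placed, avail[1L])
    remaining <- setdiff(remaining, avail[1L])
  }
  placed
}

#' Number of edges in a DAG
#' @param dag A `dag_structure`.
#' @return Integer edge count.
#' @export
n_edges <- function(dag) {
  sum(lengths(dag$parents))
}

#' Undirected skeleton of a DAG
#'
#' @param dag A `dag_structure`.
#' @return Character vector of unordered edges encoded `"a--b"` with the
#'   endpoints sorted in node order; sorted, so comparable with `identical`.
#' @export
dag_skeleton <- function(dag) {
  em <- dag_edges(dag)
  if (!nrow(em)) return(character(0))
  idx <- match(c(em$parent, em$child), dag$nodes)
  a <- matrix(idx, ncol = 2L)
  key <- apply(a, 1L, function(r) paste(dag$nodes[sort(r)], collapse = "--"))
  sort(unique(key))
}

#' V-structures (unshielded colliders) of a DAG
#'
#' A v-structure is a triple a -> c <- b where a and b are not adjacent.
#' Together with the skeleton it identifies the Markov equivalence class.
#'
#' @param dag A `dag_structure`.
#' @return Sorted character vector of keys `"a->c<-b"` with a before b in
#'   node order.
#' @export
dag_v_structures <- function(dag) {
  skel <- dag_skeleton(dag)
  adjacent <- function(x, y) {
    key <- paste(dag$nodes[sort(match(c(x, y), dag$nodes))], collapse = "--")
    key %in% skel
  }
  out <- character(0)
  for (v in dag$nodes) {
    p <- dag$parents[[v]]
    if (length(p) < 2L) next
    p <- p[order(match(p, dag$nodes))]
    for (i in seq_len(length(p) - 1L)) {
      for (j in seq(i + 1L, length(p))) {
        if (!adjacent(p[i], p[j])) {
          out <- c(out, paste0(p[i], "->", v, "<-", p[j]))
        }
      }
    }
  }
  sort(out)
}

#' Markov equivalence class key
#'
#' Two DAGs are Markov equivalent iff they share skeleton and v-structures;
#' this returns a single string identifying the class, usable for grouping.
#'
#' @param dag A `dag_structure`.
#' @return Character scalar.
#' @export
equivalence_class_key <- function(dag) {
  paste(
    paste(dag_skeleton(dag), collapse = ","),
    paste(dag_v_structures(dag), collapse = ","),
    sep = " | "
  )
}

#' @export
print.dag_structure <- function(x, ...) {
  cat("DAG over", length(x$nodes), "nodes,", n_edges(x), "edges\n")
  em <- dag_edges(x)
  if (nrow(em)) {
    for (i in seq_len(nrow(em))) {
      cat("  ", em$parent[i], "->", em$child[i], "\n")
    }
  }
  invisible(x)
}
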