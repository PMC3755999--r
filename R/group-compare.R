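#' Fit one network per subject group
#'
#' Splits the volume table by its `group` column, learns a structure and
#' fits parameters independently for each group.
#'
#' @param table Volume table with both `"NC"` and `"AD"` rows (at least 10
#'   subjects per group).
#' @param nodes Node names; defaults to the 8 DMN ROIs.
#' @param algorithm Structure search algorithm, see [learn_structure()].
#' @param max_parents,seed,param_count Passed to [learn_structure()].
#' @return Named list with fitted `gaussian_bn` elements `NC` and `AD`.
#' @export
fit_group_models <- function(table, nodes = NULL,
                             algorithm = c("exact", "hillclimb"),
                             max_parents = NULL, seed = 1L,
                             param_count = "full") {
  algorithm <- match.arg(algorithm)
  if (is.null(nodes)) nodes <- intersect(dmn_nodes(), names(table))
  validate_volume_table(table, roi_names = nodes)
  out <- list()
  for (g in c("NC", "AD")) {
    sub <- table[table$group == g, , drop = FALSE]
    if (nrow(sub) <= 9L) {
      stop("group ", g, " has ", nrow(sub),
           " subjects; at least 10 are required for model fitting")
    }
    dag <- learn_structure(sub, nodes = nodes, algorithm = algorithm,
                           max_parents = max_parents, seed = seed,
                           param_count = param_count)
    out[[g]] <- fit_gbn(sub, dag)
  }
  out
}

#' Regression coefficient of one edge given a conditioning set
#'
#' Coefficient of `parent` in the least-squares regression of `child` on
#' `{parent} union conditioning` (with intercept), computed on the rows of
#' `subtable`. This is the per-edge quantity compared between groups.
#'
#' @param subtable Rows of one (pseudo-)group.
#' @param edge Length-2 character vector `(parent, child)`.
#' @param conditioning Additional regressors (must exclude the child).
#' @return Scalar coefficient.
#' @export
edge_coefficient <- function(subtable, edge, conditioning = character(0)) {
  parent <- edge[[1L]]; child <- edge[[2L]]
  if (child %in% conditioning) stop("conditioning set must exclude the child")
  regressors <- unique(c(parent, setdiff(conditioning, parent)))
  X <- cbind(1, as.matrix(subtable[, regressors, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    stop("collinear regressors for edge ", parent, " -> ", child)
  }
  beta <- solve(crossprod(X), crossprod(X, subtable[[child]]))[, 1L]
  unname(beta[2L])
}

#' Permutation test of between-group edge-coefficient differences
#'
#' For each edge, the observed difference is the NC-group coefficient minus
#' the AD-group coefficient (conditioning sets held fixed). The null
#' distribution comes from `B` random relabelings of the subjects into
#' pseudo-groups of the original sizes; structures (and hence conditioning
#' sets) stay fixed at those learned on the true labels and only
#' coefficients are refitted per relabeling. One-sided type-I error
#' probabilities are reported in both directions:
#' `p_nc_gt_ad = #(permuted diff >= observed) / B` and
#' `p_ad_gt_nc = 1 - p_nc_gt_ad`, so the two always sum to one (permuted
#' differences exactly equal to the observed one count toward the `>=`
#' side, and no +1 smoothing is applied). Rows are sorted by `subject_id`
#' before permuting, so p-values do not depend on input row order.
#'
#' The pooled table is standardized once before any coefficient is
#' computed, putting coefficients on the standardized-weight scale; as a
#' shared affine transform this leaves the p-values identical to those
#' from raw volumes.
#'
#' @param table Volume table with both groups.
#' @param edges Edges to test: data.frame with columns (parent, child), or
#'   a list of length-2 vectors.
#' @param conditioning Named list mapping `"parent->child"` to the
#'   conditioning set for that edge; entries default to `character(0)`
#'   (simple regression). [compare_groups()] supplies the union-of-parents
#'   sets derived from the learned structures.
#' @param B Number of permutations (default 5000).
#' @param seed Integer seed for the permutation stream.
#' @param alpha Per-direction significance level (default 0.05).
#' @return Object of class `permutation_result`: data.frame `tests` with
#'   columns `parent`, `child`, `observed_diff`, `p_nc_gt_ad`,
#'   `p_ad_gt_nc`, `sig_nc_gt_ad`, `sig_ad_gt_nc`; plus `B`, `seed`,
#'   `alpha`.
#' @export
permutation_test <- function(table, edges, conditioning = list(),
                             B = 5000L, seed = 1L, alpha = 0.05) {
  if (B < 1L) stop("'B' must be at least 1")
  em <- as_edge_matrix(edges)
  if (!nrow(em)) stop("'edges' must be nonempty")
  nodes <- unique(c(em[, 1L], em[, 2L], unlist(conditioning, use.names = FALSE)))
  bad <- setdiff(nodes, names(table))
  if (length(bad)) stop("edge endpoint(s) not in table: ", paste(bad, collapse = ", "))

  tab <- table[order(table$subject_id), , drop = FALSE]
  roi <- intersect(dmn_nodes(), names(tab))
  tab <- standardize_volumes(tab, roi_names = roi)$table
  is_nc <- tab$group == "NC"
  n_nc <- sum(is_nc); n_ad <- sum(!is_nc)
  if (n_nc == 0L || n_ad == 0L) stop("both groups must be present")
  n <- n_nc + n_ad

  edge_key <- paste0(em[, 1L], "->", em[, 2L])
  csets <- lapply(edge_key, function(k) {
    cs <- conditioning[[k]] %||% character(0)
    as.character(cs)
  })

  # per-edge fixed design columns; coefficient via normal equations
  designs <- lapply(seq_len(nrow(em)), function(i) {
    regressors <- unique(c(em[i, 1L], setdiff(csets[[i]], em[i, 1L])))
    list(X = cbind(1, as.matrix(tab[, regressors, drop = FALSE])),
         y = tab[[em[i, 2L]]])
  })
  coef_diff <- function(nc_rows) {
    vapply(designs, function(dz) {
      Xn <- dz$X[nc_rows, , drop = FALSE]
      Xa <- dz$X[!nc_rows, , drop = FALSE]
      bn <- solve(crossprod(Xn), crossprod(Xn, dz$y[nc_rows]))[2L, 1L]
      ba <- solve(crossprod(Xa), crossprod(Xa, dz$y[!nc_rows]))[2L, 1L]
      bn - ba
    }, numeric(1))
  }

  observed <- coef_diff(is_nc)
  ge_count <- integer(nrow(em))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      perm_nc <- logical(n)
      perm_nc[sample.int(n, n_nc)] <- TRUE
      ge_count <- ge_count + (coef_diff(perm_nc) >= observed)
    }
  })
  p_nc <- ge_count / B
  tests <- data.frame(
    parent = em[, 1L], child = em[, 2L],
    observed_diff = observed,
    p_nc_gt_ad = p_nc, p_ad_gt_nc = 1 - p_nc,
    sig_nc_gt_ad = p_nc < alpha, sig_ad_gt_nc = (1 - p_nc) < alpha,
    stringsAsFactors = FALSE
  )
  structure(list(tests = tests, B = as.integer(B), seed = as.integer(seed),
                 alpha = alpha),
            class = "permutation_result")
}

#' Learn group models and test all their edges
#'
#' End-to-end group comparison: fits the NC and AD networks, takes the
#' union of the two learned edge sets as the edges to test, and runs the
#' permutation test. The conditioning set of an edge (u -> v) is the union
#' of v's parents across the two group structures minus v itself — the
#' same, well-defined regression for edges present in only one group.
#'
#' @param table Volume table with both groups.
#' @param B,seed,alpha Passed to [permutation_test()].
#' @param algorithm,max_parents,param_count Passed to [fit_group_models()].
#' @return List with `models` (the two `gaussian_bn`s) and `result`
#'   (a `permutation_result`).
#' @export
compare_groups <- function(table, B = 5000L, seed = 1L, alpha = 0.05,
                           algorithm = "exact", max_parents = NULL,
                           param_count = "full") {
  models <- fit_group_models(table, algorithm = algorithm,
                             max_parents = max_parents, seed = seed,
                             param_count = param_count)
  e_nc <- dag_edges(models$NC$structure)
  e_ad <- dag_edges(models$AD$structure)
  all_edges <- unique(rbind(e_nc, e_ad))
  conditioning <- list()
  for (i in seq_len(nrow(all_edges))) {
    v <- all_edges$child[i]
    cs <- setdiff(union(models$NC$structure$parents[[v]],
                        models$AD$structure$parents[[v]]), v)
    conditioning[[paste0(all_edges$parent[i], "->", v)]] <- cs
  }
  res <- permutation_test(table, all_edges, conditioning = conditioning,
                          B = B, seed = seed, alpha = alpha)
  list(models = models, result = res)
}

#' Write edge tests as CSV
#'
#' Mirrors the published between-group table layout: one row per edge with
#' the two one-sided type-I error probabilities and significance flags.
#'
#' @param result A `permutation_result`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_edge_tests <- function(result, path) {
  stopifnot(inherits(result, "permutation_result"))
  tab <- result$tests
  tab$edge <- paste0(tab$parent, "_", tab$child)
  utils::write.csv(
    tab[, c("edge", "observed_diff", "p_nc_gt_ad", "p_ad_gt_nc",
            "sig_nc_gt_ad", "sig_ad_gt_nc")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Permutation test:", nrow(x$tests), "edges, B =", x$B,
      ", alpha =", x$alpha, "\n")
  print(x$tests, digits = 4)
  invisible(x)
}
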