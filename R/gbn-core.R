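#' Z-score the ROI columns of a volume table
#'
#' Centres and scales each ROI column to mean 0, sd 1 (denominator n-1),
#' returning the statistics so the same transform can be applied to new
#' subjects — required when a model fitted on one cohort scores another.
#'
#' @param table Volume table (see [build_volume_table()]).
#' @param roi_names ROI columns to standardize.
#' @param stats Optional previously computed statistics (as returned in
#'   `$stats`); when given, they are applied instead of being re-estimated.
#' @return List with `table` (standardized copy) and `stats` (data.frame
#'   with columns `node`, `mean`, `sd`).
#' @export
standardize_volumes <- function(table, roi_names = dmn_nodes(), stats = NULL) {
  stopifnot(is.data.frame(table), nrow(table) >= 2L || !is.null(stats))
  if (is.null(stats)) {
    mu <- vapply(roi_names, function(v) mean(table[[v]]), numeric(1))
    sdv <- vapply(roi_names, function(v) stats::sd(table[[v]]), numeric(1))
    zero <- !is.finite(sdv) | sdv <= 0
    if (any(zero)) {
      stop("zero-variance ROI column(s): ", paste(roi_names[zero], collapse = ", "))
    }
    stats <- data.frame(node = roi_names, mean = unname(mu), sd = unname(sdv),
                        stringsAsFactors = FALSE)
  }
  out <- table
  for (i in seq_along(stats$node)) {
    v <- stats$node[i]
    out[[v]] <- (table[[v]] - stats$mean[i]) / stats$sd[i]
  }
  list(table = out, stats = stats)
}

#' Maximum-likelihood fit of one node given its parents
#'
#' Ordinary least squares of the node on its parents (with intercept);
#' the noise variance is the ML estimate, residual sum of squares divided
#' by n (not n - p).
#'
#' @param table Volume table (standardized or raw; fitted on the values as
#'   given).
#' @param node Child node name.
#' @param parents Character vector of parent names (possibly empty).
#' @return List of class `node_params`: `intercept`, `weights` (named
#'   numeric over parents), `noise_variance`.
#' @export
fit_node_mle <- function(table, node, parents = character(0)) {
  y <- table[[node]]
  n <- length(y)
  if (n <= length(parents) + 1L) {
    stop("too few rows (n = ", n, ") to fit node ", node, " with ",
         length(parents), " parent(s)")
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  if (length(parents)) {
    X <- cbind(X, as.matrix(table[, parents, drop = FALSE]))
  }
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design fitting node ", node,
         " (collinear parents: ", paste(parents, collapse = ", "), ")")
  }
  beta <- solve(crossprod(X), crossprod(X, y))[, 1L]
  resid <- y - X %*% beta
  sigma2 <- sum(resid^2) / n
  if (sigma2 < 1e-12) {
    stop("degenerate zero-residual fit for node ", node,
         " (exact linear dependence in the data)")
  }
  structure(
    list(intercept = unname(beta[1L]),
         weights = if (length(parents)) stats::setNames(unname(beta[-1L]), parents)
                   else stats::setNames(numeric(0), character(0)),
         noise_variance = sigma2),
    class = "node_params"
  )
}

#' Conditional Gaussian log-likelihood of one node
#'
#' Sum over subjects of the log of the normal density of the node value
#' given the linear prediction from its parents, under `params`.
#'
#' @param table Volume table.
#' @param node Child node name.
#' @param parents Parent names; must match `params$weights`.
#' @param params A `node_params` (e.g. from [fit_node_mle()]).
#' @return Scalar log-likelihood.
#' @export
local_log_likelihood <- function(table, node, parents, params) {
  if (!setequal(names(params$weights), parents)) {
    stop("params' weights do not match the given parent set for node ", node)
  }
  if (params$noise_variance <= 0) stop("noise variance must be positive")
  mu <- rep(params$intercept, nrow(table))
  for (u in parents) mu <- mu + params$weights[[u]] * table[[u]]
  sum(stats::dnorm(table[[node]], mean = mu,
                   sd = sqrt(params$noise_variance), log = TRUE))
}

#' Local BIC score of a (node, parent set) pair
#'
#' Maximized conditional log-likelihood penalized for complexity:
#'   score = loglik_max - (log n / 2) * k,
#' higher is better. By default k counts all free parameters of the local
#' model, `|parents| + 2` (weights, intercept, variance);
#' `param_count = "weights_only"` uses k = `|parents|`, the alternative
#' convention in which terms shared by every structure cancel.
#'
#' @param table Volume table.
#' @param node Child node name.
#' @param parents Parent names.
#' @param param_count `"full"` (default) or `"weights_only"`.
#' @return Scalar score (higher is better).
#' @export
local_bic <- function(table, node, parents = character(0),
                      param_count = c("full", "weights_only")) {
  param_count <- match.arg(param_count)
  params <- fit_node_mle(table, node, parents)
  ll <- local_log_likelihood(table, node, parents, params)
  k <- if (param_count == "full") length(parents) + 2 else length(parents)
  ll - (log(nrow(table)) / 2) * k
}

#' Network BIC score of a DAG
#'
#' Decomposable sum of [local_bic()] over all nodes with their parent sets.
#' Markov-equivalent DAGs (same skeleton and v-structures) receive equal
#' scores, so structure search identifies an equivalence class; the directed
#' representative is fixed by the search's tie-breaking rule.
#'
#' @param table Volume table.
#' @param dag A `dag_structure` whose nodes are ROI columns of `table`.
#' @param param_count Passed to [local_bic()].
#' @return Scalar score (higher is better).
#' @export
network_bic <- function(table, dag, param_count = "full") {
  stopifnot(inherits(dag, "dag_structure"))
  sum(vapply(dag$nodes, function(v) {
    local_bic(table, v, dag$parents[[v]], param_count = param_count)
  }, numeric(1)))
}

#' Fit a Gaussian Bayesian network with a given structure
#'
#' Standardizes the ROI columns (storing the statistics in the model), then
#' fits every node by maximum likelihood given its parents.
#'
#' @param table Volume table.
#' @param dag A `dag_structure` over the ROI columns.
#' @param standardize Standardize before fitting (default TRUE). When FALSE
#'   the stored statistics are mean 0, sd 1 (identity transform).
#' @return Object of class `gaussian_bn`: `structure`, `params` (named list
#'   of `node_params`), `standardization` (data.frame node/mean/sd), `n_fit`.
#' @export
fit_gbn <- function(table, dag, standardize = TRUE) {
  stopifnot(inherits(dag, "dag_structure"))
  if (standardize) {
    std <- standardize_volumes(table, roi_names = dag$nodes)
    tab <- std$table
    stats <- std$stats
  } else {
    tab <- table
    stats <- data.frame(node = dag$nodes, mean = 0, sd = 1,
                        stringsAsFactors = FALSE)
  }
  params <- lapply(dag$nodes, function(v) fit_node_mle(tab, v, dag$parents[[v]]))
  names(params) <- dag$nodes
  structure(
    list(structure = dag, params = params, standardization = stats,
         n_fit = nrow(table)),
    class = "gaussian_bn"
  )
}

#' Joint log-density of subjects under a fitted network
#'
#' Applies the model's stored standardization to the ROI values, sums the
#' conditional Gaussian log-densities of all nodes given their parents, and
#' subtracts the log of the standardization scale factors (the Jacobian of
#' the z-transform), so densities are on the original volume scale and
#' comparable across models with different standardizations.
#'
#' @param bn A fitted `gaussian_bn`.
#' @param table Volume table (or any data.frame containing the ROI columns);
#'   one log-density per row.
#' @return Numeric vector of log-densities.
#' @export
joint_log_density <- function(bn, table) {
  stopifnot(inherits(bn, "gaussian_bn"))
  nodes <- bn$structure$nodes
  missing_cols <- setdiff(nodes, names(table))
  if (length(missing_cols)) {
    stop("missing ROI value(s): ", paste(missing_cols, collapse = ", "))
  }
  z <- standardize_volumes(table, roi_names = nodes, stats = bn$standardization)$table
  n <- nrow(table)
  ld <- rep(-sum(log(bn$standardization$sd)), n)
  for (v in nodes) {
    p <- bn$params[[v]]
    mu <- rep(p$intercept, n)
    for (u in names(p$weights)) mu <- mu + p$weights[[u]] * z[[u]]
    ld <- ld + stats::dnorm(z[[v]], mean = mu, sd = sqrt(p$noise_variance),
                            log = TRUE)
  }
  ld
}

#' Serialize / deserialize a fitted network as JSON
#'
#' The JSON object records nodes, parent lists, intercepts, weights,
#' noise variances, standardization statistics and the fitting sample size;
#' `read_gbn(write_gbn(bn, path))` reproduces the model exactly.
#'
#' @param bn A `gaussian_bn`.
#' @param path JSON file path.
#' @return `write_gbn` returns `path` invisibly; `read_gbn` a `gaussian_bn`.
#' @export
write_gbn <- function(bn, path) {
  stopifnot(inherits(bn, "gaussian_bn"))
  obj <- list(
    nodes = bn$structure$nodes,
    parents = bn$structure$parents,
    params = lapply(bn$params, function(p) {
      list(intercept = p$intercept, weights = as.list(p$weights),
           noise_variance = p$noise_variance)
    }),
    standardization = bn$standardization,
    n_fit = bn$n_fit
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gbn
#' @export
read_gbn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parents <- lapply(obj$parents, function(p) as.character(unlist(p)))
  dag <- dag_structure(as.character(obj$nodes), parents)
  params <- lapply(obj$params, function(p) {
    w <- unlist(p$weights)
    structure(
      list(intercept = as.numeric(p$intercept),
           weights = if (length(w)) stats::setNames(as.numeric(w), names(w))
                     else stats::setNames(numeric(0), character(0)),
           noise_variance = as.numeric(p$noise_variance)),
      class = "node_params"
    )
  })
  names(params) <- names(obj$params)
  std <- as.data.frame(obj$standardization, stringsAsFactors = FALSE)
  structure(
    list(structure = dag, params = params[dag$nodes],
         standardization = std[match(dag$nodes, std$node), , drop = FALSE],
         n_fit = as.integer(obj$n_fit)),
    class = "gaussian_bn"
  )
}

#' @export
print.gaussian_bn <- function(x, ...) {
  cat("Gaussian Bayesian network:", length(x$structure$nodes), "nodes,",
      n_edges(x$structure), "edges, fitted on n =", x$n_fit, "\n")
  em <- dag_edges(x$structure)
  if (nrow(em)) {
    for (i in seq_len(nrow(em))) {
      w <- x$params[[em$child[i]]]$weights[[em$parent[i]]]
      cat(sprintf("  %s -> %s  % .4f\n", em$parent[i], em$child[i], w))
    }
  }
  invisible(x)
}
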