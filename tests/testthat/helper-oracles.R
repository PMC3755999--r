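# Independent oracles used across the suite. These are deliberately written
# against textbook formulas and never call the code paths they check.

# Implied moments of a linear-Gaussian SEM: with W[child, parent] holding
# the weights and D = diag(noise variances), x = (I - W)^{-1} (mu0 + eps),
# so mean = (I - W)^{-1} mu0 and cov = (I - W)^{-1} D (I - W)^{-T}.
oracle_sem_moments <- function(nodes, edges, intercepts = NULL,
                               noise_variances = NULL) {
  d <- length(nodes)
  W <- matrix(0, d, d, dimnames = list(nodes, nodes))
  if (!is.null(edges) && nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      W[edges$child[i], edges$parent[i]] <- edges$weight[i]
    }
  }
  mu0 <- stats::setNames(rep(0, d), nodes)
  if (!is.null(intercepts)) mu0[names(intercepts)] <- intercepts
  nv <- stats::setNames(rep(1, d), nodes)
  if (!is.null(noise_variances)) nv[names(noise_variances)] <- noise_variances
  A <- solve(diag(d) - W)
  list(mean = as.numeric(A %*% mu0),
       cov = A %*% diag(nv, d) %*% t(A),
       nodes = nodes)
}

# multivariate normal log-density from first principles
oracle_mvn_logdensity <- function(x, mean, cov) {
  d <- length(mean)
  -0.5 * (d * log(2 * pi) + determinant(cov, logarithm = TRUE)$modulus +
            stats::mahalanobis(x, center = mean, cov = cov))
}

# explicit normal-equations least squares (oracle for fit_node_mle)
oracle_ols <- function(y, X) {
  Xi <- cbind(1, X)
  as.numeric(solve(t(Xi) %*% Xi) %*% t(Xi) %*% y)
}

# random weighted DAG over `nodes`: random order, forward edges kept with
# probability `prob`, weights uniform on +-[0.3, 0.9]
random_sem_edges <- function(nodes, prob = 0.5) {
  d <- length(nodes)
  ord <- sample(nodes)
  out <- NULL
  for (i in seq_len(d - 1L)) {
    for (j in seq(i + 1L, d)) {
      if (stats::runif(1) < prob) {
        w <- sample(c(-1, 1), 1) * stats::runif(1, 0.3, 0.9)
        out <- rbind(out, data.frame(parent = ord[i], child = ord[j],
                                     weight = w))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(parent = character(0), child = character(0),
                      weight = numeric(0))
  }
  out
}

# small random volume table with independent standard-normal columns
random_table <- function(n, nodes, group = "NC") {
  tab <- data.frame(subject_id = sprintf("r%04d", seq_len(n)),
                    group = group, stringsAsFactors = FALSE)
  for (v in nodes) tab[[v]] <- stats::rnorm(n)
  tab
}
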