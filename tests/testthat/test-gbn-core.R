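test_that("standardization matches hand computation and round-trips", {
  tab <- data.frame(subject_id = c("a", "b"), group = "NC", A = c(1, 3))
  std <- standardize_volumes(tab, roi_names = "A")
  expect_equal(std$table$A, c(-1, 1) / sqrt(2))     # sd convention: n - 1
  expect_equal(std$stats$mean, 2)
  expect_equal(std$stats$sd, sqrt(2))
  # idempotence: re-standardizing standardized data gives (0, 1) stats
  std2 <- standardize_volumes(std$table, roi_names = "A")
  expect_equal(std2$stats$mean, 0)
  expect_equal(std2$stats$sd, 1)
  # applying stored statistics reproduces the standardized table
  reapplied <- standardize_volumes(tab, roi_names = "A", stats = std$stats)
  expect_equal(reapplied$table$A, std$table$A)
  tab$B <- 5
  expect_error(standardize_volumes(tab, roi_names = c("A", "B")),
               "zero-variance.*B")
})

test_that("fit_node_mle matches the normal-equations oracle and closed forms", {
  # parents = empty: intercept = mean, variance = ML (divide by n)
  y <- c(1, 2, 4, 9)
  tab <- data.frame(A = y)
  p0 <- fit_node_mle(tab, "A")
  expect_equal(p0$intercept, mean(y))
  expect_equal(p0$noise_variance, mean((y - mean(y))^2))

  # one parent, 4 rows: explicit (X'X)^{-1} X'y oracle
  tab2 <- data.frame(X = c(0, 1, 2, 3), Y = c(0.2, 1.1, 1.7, 3.4))
  p1 <- fit_node_mle(tab2, "Y", "X")
  oracle <- oracle_ols(tab2$Y, as.matrix(tab2[, "X", drop = FALSE]))
  expect_equal(p1$intercept, oracle[1])
  expect_equal(p1$weights[["X"]], oracle[2])

  # error paths
  expect_error(fit_node_mle(tab2[1:2, ], "Y", "X"), "too few rows")
  tab3 <- data.frame(X = 1:10, X2 = 2 * (1:10), Y = stats::rnorm(10))
  expect_error(fit_node_mle(tab3, "Y", c("X", "X2")), "collinear")
  tab4 <- data.frame(X = 1:10, Y = 2 * (1:10) + 1)
  expect_error(fit_node_mle(tab4, "Y", "X"), "degenerate")
})

test_that("local log-likelihood agrees with its closed form at the MLE", {
  withr::with_seed(51, {
    y <- stats::rnorm(40)
  })
  tab <- data.frame(A = y)
  params <- fit_node_mle(tab, "A")
  ll <- local_log_likelihood(tab, "A", character(0), params)
  n <- length(y)
  sigma2 <- params$noise_variance
  expect_equal(ll, -(n / 2) * (log(2 * pi * sigma2) + 1))
  # single subject at the conditional mean, variance 1
  one <- data.frame(A = 0.7)
  p1 <- structure(list(intercept = 0.7,
                       weights = stats::setNames(numeric(0), character(0)),
                       noise_variance = 1), class = "node_params")
  expect_equal(local_log_likelihood(one, "A", character(0), p1),
               -0.5 * log(2 * pi))
  expect_error(local_log_likelihood(one, "A", "B", p1), "weights")
})

test_that("adding a parent never decreases the maximized log-likelihood", {
  withr::with_seed(52, {
    tab <- random_table(60, c("A", "B", "C"))
  })
  prev_ll <- -Inf
  for (pa in list(character(0), "B", c("B", "C"))) {
    ll <- local_log_likelihood(tab, "A", pa, fit_node_mle(tab, "A", pa))
    expect_gte(ll, prev_ll - 1e-10)
    prev_ll <- ll
  }
})

test_that("local BIC penalizes an irrelevant parent on independent data", {
  withr::with_seed(53, {
    worse <- replicate(40, {
      tab <- random_table(500, c("A", "B"))
      local_bic(tab, "A", "B") < local_bic(tab, "A")
    })
  })
  expect_gt(mean(worse), 0.9)   # penalty dominates the ~1/2 likelihood gain
  # closed form with empty parents on standardized data
  withr::with_seed(54, {
    tab <- random_table(100, "A")
  })
  tab <- standardize_volumes(tab, "A")$table
  s2 <- mean((tab$A - mean(tab$A))^2)
  expect_equal(local_bic(tab, "A"),
               -(100 / 2) * (log(2 * pi * s2) + 1) - (log(100) / 2) * 2)
  # the weights-only penalty toggle drops the constant 2
  expect_equal(local_bic(tab, "A", param_count = "weights_only"),
               -(100 / 2) * (log(2 * pi * s2) + 1))
})

test_that("network score is decomposable and score-equivalent", {
  withr::with_seed(55, {
    tab <- random_table(80, c("A", "B", "C"))
  })
  g0 <- dag_structure(c("A", "B", "C"))
  expect_equal(network_bic(tab, g0),
               local_bic(tab, "A") + local_bic(tab, "B") + local_bic(tab, "C"))
  # bivariate reversal: score(X) + score(Y|X) = score(Y) + score(X|Y)
  expect_equal(local_bic(tab, "A") + local_bic(tab, "B", "A"),
               local_bic(tab, "B") + local_bic(tab, "A", "B"),
               tolerance = 1e-10)
  # changing one node's parents changes only that node's local score
  expect_equal(
    network_bic(tab, dag_structure(c("A", "B", "C"), list(B = "A"))) -
      network_bic(tab, g0),
    local_bic(tab, "B", "A") - local_bic(tab, "B"),
    tolerance = 1e-10)
})

test_that("all Markov-equivalent 3-node DAGs score identically", {
  nodes <- c("A", "B", "C")
  dags <- enumerate_dags(nodes)
  withr::with_seed(56, {
    for (rep in 1:5) {
      edges <- random_sem_edges(nodes, prob = 0.6)
      cfg <- generator_config(nodes, edges, n_subjects = 60,
                              seed = sample.int(1e6, 1))
      tab <- sample_sem(cfg)
      scores <- vapply(dags, function(g) network_bic(tab, g), numeric(1))
      keys <- vapply(dags, equivalence_class_key, character(1))
      for (k in unique(keys)) {
        cls <- scores[keys == k]
        expect_lt(max(cls) - min(cls), 1e-8)
      }
    }
  })
})

test_that("joint log-density matches the implied-covariance MVN oracle", {
  # no-edge unit model at the all-zeros sample: -(d/2) log(2*pi)
  nodes <- dmn_nodes()
  tab0 <- random_table(30, nodes)
  bn0 <- fit_gbn(tab0, dag_structure(nodes), standardize = FALSE)
  for (v in nodes) {
    bn0$params[[v]]$intercept <- 0
    bn0$params[[v]]$noise_variance <- 1
  }
  zero <- as.data.frame(as.list(stats::setNames(rep(0, 8), nodes)))
  expect_equal(joint_log_density(bn0, zero), -4 * log(2 * pi))

  # fitted models vs the (I - W)^{-1} oracle, raw and standardized fits
  withr::with_seed(57, {
    for (rep in 1:4) {
      d <- sample(3:5, 1)
      nodes <- paste0("V", seq_len(d))
      edges <- random_sem_edges(nodes, prob = 0.5)
      cfg <- generator_config(nodes, edges, n_subjects = 200,
                              seed = sample.int(1e6, 1))
      tab <- sample_sem(cfg)
      for (standardize in c(TRUE, FALSE)) {
        bn <- fit_gbn(tab, cfg$dag, standardize = standardize)
        # implied moments of the *fitted* model, mapped back to raw scale:
        # z = (x - m) / s, z ~ N(mu_z, S_z)  =>  x ~ N(m + s mu_z, D S_z D)
        fe <- dag_edges(bn$structure)
        fe$weight <- vapply(seq_len(nrow(fe)), function(i) {
          bn$params[[fe$child[i]]]$weights[[fe$parent[i]]]
        }, numeric(1))
        mom <- oracle_sem_moments(
          nodes, fe,
          intercepts = vapply(bn$params, `[[`, numeric(1), "intercept"),
          noise_variances = vapply(bn$params, `[[`, numeric(1),
                                   "noise_variance"))
        s <- bn$standardization$sd
        m <- bn$standardization$mean
        mean_raw <- m + s * mom$mean
        cov_raw <- diag(s, d) %*% mom$cov %*% diag(s, d)
        test_rows <- tab[sample.int(nrow(tab), 25), ]
        got <- joint_log_density(bn, test_rows)
        want <- oracle_mvn_logdensity(as.matrix(test_rows[, nodes]),
                                      mean_raw, cov_raw)
        expect_equal(got, as.numeric(want), tolerance = 1e-8)
      }
    }
  })
})

test_that("joint log-density is invariant to evaluation node order", {
  withr::with_seed(58, {
    tab <- random_table(50, dmn_nodes())
  })
  gens <- dmn_reference_generators()
  bn <- fit_gbn(sample_sem(gens$NC), gens$NC$dag)
  perm <- rev(dmn_nodes())
  tab_perm <- tab[, c("subject_id", "group", perm)]
  expect_equal(joint_log_density(bn, tab), joint_log_density(bn, tab_perm))
  expect_error(joint_log_density(bn, tab[, 1:6]), "missing ROI")
})

test_that("fitted weights converge to generating weights with n", {
  gens <- dmn_reference_generators()
  errs <- vapply(c(100L, 1600L), function(n) {
    withr::with_seed(59, {
      mean(abs(replicate(20, {
        cfg <- gens$NC; cfg$n_subjects <- n; cfg$seed <- sample.int(1e6, 1)
        tab <- sample_sem(cfg)
        fit_node_mle(tab, "rITC", "lITC")$weights[["lITC"]] - 0.8118
      })))
    })
  }, numeric(1))
  # error shrinks roughly as 1/sqrt(n): 4x the n, about half the error
  expect_lt(errs[2], 0.7 * errs[1])
})

test_that("models serialize to JSON and back without loss", {
  gens <- dmn_reference_generators(n_nc = 40, n_ad = 40)
  tab <- sample_sem(gens$AD, group = "AD")
  bn <- fit_gbn(tab, gens$AD$dag)
  f <- tempfile(fileext = ".json")
  write_gbn(bn, f)
  back <- read_gbn(f)
  expect_identical(back$structure$parents, bn$structure$parents)
  expect_equal(back$params, bn$params)
  expect_equal(joint_log_density(back, tab), joint_log_density(bn, tab))
  expect_identical(back$n_fit, bn$n_fit)
})
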