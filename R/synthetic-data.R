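#' Configuration of a linear-Gaussian structural equation model generator
#'
#' Defines the data-generating process for a synthetic cohort: each node is
#' a linear function of its parents plus independent Gaussian noise,
#'   X_v = intercept_v + sum_{u in pa(v)} w_{u->v} X_u + eps_v,
#'   eps_v ~ N(0, noise_variance_v),
#' sampled in a topological order of the DAG. Exogenous nodes with unit
#' variance and zero intercept are standard normal; children carry the
#' implied (generally non-unit) variance.
#'
#' @param nodes Character vector of node names (default the 8 DMN ROIs).
#' @param edges Edge list with weights: data.frame with columns
#'   (parent, child, weight), or a list of `list(parent, child, weight)`.
#' @param intercepts Named numeric vector of per-node intercepts; nodes not
#'   named default to 0.
#' @param noise_variances Named numeric vector of per-node noise variances
#'   (> 0); nodes not named default to 1.
#' @param n_subjects Positive integer number of subjects to generate.
#' @param seed Integer seed making [sample_sem()] deterministic.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(nodes = dmn_nodes(), edges = NULL,
                             intercepts = NULL, noise_variances = NULL,
                             n_subjects = 100L, seed = 1L) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1) {
    stop("'n_subjects' must be a positive integer")
  }
  weights <- weighted_edge_frame(edges)
  bad <- setdiff(unique(c(weights$parent, weights$child)), nodes)
  if (length(bad)) stop("edge endpoint(s) not in nodes: ", paste(bad, collapse = ", "))
  # acyclicity enforced by dag_structure construction
  dag <- dag_from_edges(nodes, weights[, c("parent", "child")])

  ic <- stats::setNames(rep(0, length(nodes)), nodes)
  if (!is.null(intercepts)) ic[names(intercepts)] <- intercepts
  nv <- stats::setNames(rep(1, length(nodes)), nodes)
  if (!is.null(noise_variances)) nv[names(noise_variances)] <- noise_variances
  if (any(!is.finite(nv)) || any(nv <= 0)) {
    stop("noise variances must be positive: ",
         paste(names(nv)[!(is.finite(nv) & nv > 0)], collapse = ", "))
  }
  structure(
    list(nodes = nodes, edges = weights, dag = dag, intercepts = ic,
         noise_variances = nv, n_subjects = as.integer(n_subjects),
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

weighted_edge_frame <- function(edges) {
  if (is.null(edges) || (is.list(edges) && !is.data.frame(edges) && !length(edges))) {
    return(data.frame(parent = character(0), child = character(0),
                      weight = numeric(0)))
  }
  if (is.data.frame(edges)) {
    stopifnot(ncol(edges) >= 3L)
    out <- data.frame(parent = as.character(edges[[1L]]),
                      child = as.character(edges[[2L]]),
                      weight = as.numeric(edges[[3L]]),
                      stringsAsFactors = FALSE)
  } else if (is.list(edges)) {
    out <- do.call(rbind, lapply(edges, function(e) {
      data.frame(parent = as.character(e[[1L]]), child = as.character(e[[2L]]),
                 weight = as.numeric(e[[3L]]), stringsAsFactors = FALSE)
    }))
  } else {
    stop("unsupported edge representation")
  }
  if (anyDuplicated(paste(out$parent, out$child))) stop("duplicate edges")
  out
}

#' Sample a synthetic cohort from a linear-Gaussian SEM
#'
#' Draws `n_subjects` i.i.d. subject vectors by ancestral sampling: nodes
#' are visited in topological order and each value is its intercept plus the
#' weighted sum of already-sampled parent values plus Gaussian noise.
#' Bitwise reproducible given the config (including its seed).
#'
#' @param config A [generator_config()].
#' @param group Group label stored in the output table (default `"NC"`).
#' @param subject_prefix Prefix for generated subject identifiers.
#' @return A volume table: data.frame with columns `subject_id`, `group`,
#'   then one numeric column per node.
#' @export
sample_sem <- function(config, group = "NC", subject_prefix = "S") {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_subjects
  nodes <- config$nodes
  order <- topological_order(config$dag)
  X <- matrix(NA_real_, nrow = n, ncol = length(nodes),
              dimnames = list(NULL, nodes))
  withr::with_seed(config$seed, {
    for (v in order) {
      eps <- stats::rnorm(n, mean = 0, sd = sqrt(config$noise_variances[[v]]))
      val <- config$intercepts[[v]] + eps
      for (u in config$dag$parents[[v]]) {
        w <- config$edges$weight[config$edges$parent == u & config$edges$child == v]
        val <- val + w * X[, u]
      }
      X[, v] <- val
    }
  })
  out <- data.frame(
    subject_id = sprintf("%s%03d", subject_prefix, seq_len(n)),
    group = rep(group, n),
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(X))
}

#' Reference network generators for the NC and AD groups
#'
#' Returns the two packaged data-generating models whose edge sets and
#' standardized weight coefficients are those of the fitted NC and AD
#' default-mode-network models (10 edges for NC, 11 for AD; the groups share
#' five bilateral/parietal edges, each group has exclusive edges, and three
#' connections appear with opposite orientation). Intercepts are zero and
#' noise variances one: the published models report only weights, and these
#' defaults make ordinary-least-squares parameter recovery well defined.
#'
#' @param n_nc,n_ad Cohort sizes (defaults 101 and 80, the study group sizes).
#' @param seed_nc,seed_ad Seeds stored in the two configs.
#' @return Named list with elements `NC` and `AD`, each a `generator_config`.
#' @export
dmn_reference_generators <- function(n_nc = 101L, n_ad = 80L,
                                     seed_nc = 101L, seed_ad = 80L) {
  nc_edges <- data.frame(
    parent = c("lITC", "lIPC", "lIPC", "lIPC", "lIPC",
               "mPFC", "mPFC", "rHP", "rITC", "PCC"),
    child  = c("rITC", "rIPC", "PCC", "lITC", "mPFC",
               "lITC", "rHP", "lHP", "rHP", "rIPC"),
    weight = c(0.8118, 0.4035, 0.6841, 0.3021, 0.5990,
               0.3506, 0.3199, 0.8421, 0.4000, 0.3397)
  )
  ad_edges <- data.frame(
    parent = c("lITC", "lIPC", "lIPC", "lIPC", "lIPC",
               "lITC", "rITC", "lHP", "lHP", "rHP", "rIPC"),
    child  = c("rITC", "rIPC", "PCC", "lITC", "mPFC",
               "lHP", "rIPC", "rITC", "rHP", "rITC", "PCC"),
    weight = c(0.7026, 0.5992, 0.4065, 0.3930, 0.4888,
               0.6596, 0.2626, -0.6363, 0.8023, 0.7691, 0.3723)
  )
  list(
    NC = generator_config(dmn_nodes(), nc_edges, n_subjects = n_nc, seed = seed_nc),
    AD = generator_config(dmn_nodes(), ad_edges, n_subjects = n_ad, seed = seed_ad)
  )
}

#' Specification of a small synthetic NIfTI fixture
#'
#' Describes a 3-D grid holding axis-aligned rectangular "ROIs": an atlas
#' image with one integer label per block, and a grey-matter image whose
#' voxels are `target_mean + noise` inside each block and `background_value`
#' outside. Target means must exceed the 0.15 extraction threshold so ROI
#' voxels survive it; the background must not exceed it.
#'
#' @param grid_shape Integer vector of 3 positive extents.
#' @param roi_labels Named integer vector: ROI abbreviation -> atlas label
#'   (distinct positive integers).
#' @param target_means Named numeric vector in (0.15, 1], same names.
#' @param background_value Scalar in [0, 0.15].
#' @param noise_sd Nonnegative scalar noise standard deviation.
#' @param seed Integer seed.
#' @return An object of class `image_fixture_spec`.
#' @export
image_fixture_spec <- function(grid_shape = c(12L, 12L, 12L),
                               roi_labels, target_means,
                               background_value = 0.05, noise_sd = 0,
                               seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L))
  labs <- as.integer(roi_labels)
  if (is.null(names(roi_labels)) || anyDuplicated(labs) || any(labs <= 0L)) {
    stop("'roi_labels' must be named, distinct, positive integers")
  }
  if (!setequal(names(roi_labels), names(target_means))) {
    stop("'target_means' must name the same ROIs as 'roi_labels'")
  }
  tm <- target_means[names(roi_labels)]
  if (any(tm <= 0.15) || any(tm > 1)) {
    stop("target means must lie in (0.15, 1] so the extraction threshold keeps ROI voxels")
  }
  if (background_value < 0 || background_value > 0.15) {
    stop("'background_value' must lie in [0, 0.15]")
  }
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  structure(
    list(grid_shape = as.integer(grid_shape),
         roi_labels = stats::setNames(labs, names(roi_labels)),
         target_means = tm, background_value = background_value,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "image_fixture_spec"
  )
}

#' Build a grey-matter image and matching atlas from a fixture spec
#'
#' ROIs are laid out as disjoint axis-aligned slabs along the first grid
#' axis, in the order of `roi_labels`. Both images share the grid shape and
#' an identity affine, so they can be written as NIfTI-1 and fed directly to
#' [build_volume_table()].
#'
#' @param spec An [image_fixture_spec()].
#' @return List with elements `grey_matter` and `atlas`, both `niftiImage`
#'   arrays of the requested shape.
#' @export
make_image_fixture <- function(spec) {
  stopifnot(inherits(spec, "image_fixture_spec"))
  shape <- spec$grid_shape
  rois <- names(spec$roi_labels)
  n_roi <- length(rois)
  if (shape[1L] < n_roi + 1L) {
    stop("grid too small: need one slab per ROI plus background along the first axis")
  }
  atlas <- array(0L, dim = shape)
  gm <- array(spec$background_value, dim = shape)
  # one contiguous slab of x-planes per ROI; the remaining planes stay
  # background (label 0), so every fixture has out-of-ROI voxels
  width <- max(1L, shape[1L] %/% (n_roi + 1L))
  withr::with_seed(spec$seed, {
    for (i in seq_len(n_roi)) {
      xs <- seq((i - 1L) * width + 1L, i * width)
      atlas[xs, , ] <- spec$roi_labels[[i]]
      nvox <- length(xs) * shape[2L] * shape[3L]
      gm[xs, , ] <- spec$target_means[[i]] +
        if (spec$noise_sd > 0) stats::rnorm(nvox, 0, spec$noise_sd) else 0
    }
  })
  list(
    grey_matter = RNifti::asNifti(gm),
    atlas = RNifti::asNifti(atlas)
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("linear-Gaussian SEM generator:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges, n =", x$n_subjects, ", seed =", x$seed, "\n")
  invisible(x)
}
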