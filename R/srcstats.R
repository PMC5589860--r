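#' Node-wise 2 x 2 mixed ANOVA on current densities
#'
#' Applies the same 2 x 2 mixed design as the sensor-space analysis to the
#' per-node scalar current densities: one two-level between-subject factor
#' (group) and one two-level within factor (stimulus class or session).
#' Each node reproduces [mixed_anova_2x2()] exactly.
#'
#' @param D1,D2 subjects x nodes matrices of current densities at
#'   within-level 1 and 2
#' @param group group label per subject (two levels)
#' @param design free-text tag stored in the result
#' @return object of class `source_stat_map` with per-node `f` and `p`
#' @export
nodewise_interaction <- function(D1, D2, group, design = "group-x-stimulus") {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  res <- .mixed_map(D1, D2, group)
  structure(list(f = res$F_interaction, p = res$p_interaction,
                 f_between = res$F_between, p_between = res$p_between,
                 f_within = res$F_within, p_within = res$p_within,
                 df = c(1, res$df_den), design = design,
                 n_nodes = ncol(D1)),
            class = "source_stat_map")
}

#' @export
print.source_stat_map <- function(x, ...) {
  cat(sprintf("<source_stat_map> %s: %d nodes, F(%d, %d), %d with p < 0.05\n",
              x$design, x$n_nodes, x$df[1], x$df[2], sum(x$p < 0.05)))
  invisible(x)
}

# connected components of the node subset `sel` under a precomputed
# adjacency list; returns a list of integer node-index vectors
.components <- function(sel, adj) {
  sel <- sort(sel)
  in_sel <- logical(length(adj)); in_sel[sel] <- TRUE
  visited <- logical(length(adj))
  comps <- list()
  for (s in sel) {
    if (visited[s]) next
    comp <- integer(0); queue <- s; visited[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[in_sel[nb] & !visited[nb]]
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

#' Spatial-extent cluster formation on the source grid
#'
#' Forms connected components of the sub-threshold node set (`p < alpha`)
#' under the given connection radius (8.5 mm on a 6-mm grid connects face
#' and edge neighbors but not corner diagonals) and discards components
#' smaller than the spatial-extent criterion `k_e`.
#'
#' @param p per-node p-values (or a `source_stat_map`)
#' @param space the [build_source_grid()] the map was computed on
#' @param alpha node-wise threshold
#' @param k_e minimum cluster size in nodes
#' @param radius connection radius in mm
#' @param f optional per-node F values (defines each cluster's peak node)
#' @param densities optional named list of subjects x nodes matrices (one per
#'   design cell); per-cluster cell means are reported when given
#' @return list of clusters, each with `nodes`, `size`, `peak_node`,
#'   `peak_coord`, and optionally `peak_f`, `cell_means`
#' @export
find_clusters <- function(p, space, alpha = 0.05, k_e = 15, radius = 8.5,
                          f = NULL, densities = NULL) {
  if (inherits(p, "source_stat_map")) {
    if (is.null(f)) f <- p$f
    p <- p$p
  }
  stopifnot(inherits(space, "source_space"), length(p) == nrow(space$nodes))
  sel <- which(p < alpha)
  if (!length(sel)) return(list())
  adj <- grid_adjacency(space, radius)
  comps <- Filter(function(cc) length(cc) >= k_e, .components(sel, adj))
  lapply(comps, function(cc) {
    peak <- if (!is.null(f)) cc[which.max(f[cc])] else cc[which.min(p[cc])]
    out <- list(nodes = cc, size = length(cc), peak_node = peak,
                peak_coord = space$nodes[peak, ])
    if (!is.null(f)) out$peak_f <- f[peak]
    if (!is.null(densities))
      out$cell_means <- vapply(densities, function(d) mean(d[, cc]), 0)
    out
  })
}

# Sparse Gaussian smoothing operator over node distances, rows scaled to
# unit L2 norm so that smoothed white noise keeps unit marginal variance.
.smoothing_operator <- function(space, fwhm, cutoff_sigmas = 3.5) {
  n <- nrow(space$nodes)
  if (fwhm <= 0) return(Matrix::Diagonal(n))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  cutoff <- cutoff_sigmas * sigma
  adj <- grid_adjacency(space, cutoff)
  ii <- rep.int(seq_len(n), lengths(adj))
  jj <- unlist(adj)
  keep_self <- seq_len(n)
  d2 <- rowSums((space$nodes[ii, , drop = FALSE] -
                   space$nodes[jj, , drop = FALSE])^2)
  w <- exp(-d2 / (2 * sigma^2))
  S <- Matrix::sparseMatrix(i = c(ii, keep_self), j = c(jj, keep_self),
                            x = c(w, rep(1, n)), dims = c(n, n))
  nrm <- sqrt(Matrix::rowSums(S^2))
  Matrix::Diagonal(x = 1 / nrm) %*% S
}

#' Null maximum cluster sizes under smoothed Gaussian noise
#'
#' One Monte-Carlo iteration draws white Gaussian noise at every node,
#' smooths it with an FWHM-parameterized Gaussian kernel over node
#' distances, re-standardizes to unit variance, thresholds two-sided at
#' `alpha`, forms clusters at the given connection radius, and records the
#' maximum cluster size (0 when no node survives).
#'
#' @param space a [build_source_grid()] result
#' @param fwhm smoothing kernel full width at half maximum, mm (0 = none)
#' @param alpha two-sided node-wise threshold
#' @param n_iter Monte-Carlo iterations
#' @param radius cluster connection radius, mm
#' @param seed optional RNG seed
#' @return integer vector of `n_iter` maximum cluster sizes
#' @export
mc_max_cluster_sizes <- function(space, fwhm = 6, alpha = 0.05,
                                 n_iter = 2000, radius = 8.5, seed = NULL) {
  stopifnot(inherits(space, "source_space"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(space$nodes)
  S <- .smoothing_operator(space, fwhm)
  adj <- grid_adjacency(space, radius)
  zcrit <- stats::qnorm(1 - alpha / 2)
  sizes <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    y <- as.vector(S %*% stats::rnorm(n))
    sel <- which(abs(y) > zcrit)
    if (!length(sel)) next
    comps <- .components(sel, adj)
    sizes[it] <- max(lengths(comps))
  }
  sizes
}

#' Monte-Carlo calibration of the cluster-extent criterion
#'
#' Runs [mc_max_cluster_sizes()] and returns the smallest extent `k` for
#' which the empirical probability of a null cluster *larger* than `k`
#' stays below `fp_target`.
#'
#' @inheritParams mc_max_cluster_sizes
#' @param fp_target family-wise false-positive probability to control
#' @return list with `k_e`, the empirical exceedance table
#'   (`prob_exceeding[k] = P(max cluster > k)`), and the raw sizes
#' @export
montecarlo_cluster_threshold <- function(space, fwhm = 6, alpha = 0.05,
                                         fp_target = 0.005, n_iter = 2000,
                                         radius = 8.5, seed = NULL) {
  if (n_iter < 2 / fp_target)
    warning("n_iter too small to resolve fp_target = ", fp_target)
  sizes <- mc_max_cluster_sizes(space, fwhm, alpha, n_iter, radius, seed)
  kmax <- max(sizes, 1L)
  prob <- vapply(seq_len(kmax), function(k) mean(sizes > k), 0)
  k_e <- which(prob < fp_target)[1]
  if (is.na(k_e)) k_e <- kmax + 1L
  list(k_e = as.integer(k_e), prob_exceeding = prob, sizes = sizes)
}
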