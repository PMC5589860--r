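#' Minimum-norm inverse operator with LAURA regularization
#'
#' Builds a weighted-minimum-norm inverse kernel for a distributed source
#' grid. The local autoregressive average (LAURA) constraint drives each
#' node's moment toward a distance-weighted average of its neighbors: with
#' `A` the row-normalized neighbor matrix (weights proportional to
#' `d^-falloff_exponent` within the 26-cell neighborhood) and
#' `W = I - ar_rho * A`, the source metric is `M = (W'W)^-1`, applied
#' identically to the x/y/z moment components. The autoregressive
#' coefficient `ar_rho` must be strictly below 1: with `ar_rho = 1` the
#' constraint matrix annihilates constant fields and `W'W` is singular;
#' values near 1 keep the neighbor-average reading while making `W`
#' strictly diagonally dominant. The kernel is
#' `K = M L' (L M L' + lambda I)^-1`, with
#' `lambda = trace(L M L') / (n_electrodes * lambda_snr^2)`.
#'
#' @param lf a [compute_lead_field()] result
#' @param space the matching [build_source_grid()]
#' @param lambda_snr assumed amplitude signal-to-noise ratio for the
#'   regularization level (dimensionless)
#' @param falloff_exponent neighbor-weight distance exponent (2 = inverse
#'   square, the potential-field law; 3 = vector-field convention)
#' @param ar_rho spatial autoregressive coefficient in `(0, 1)`
#' @param plain if `TRUE`, skip the LAURA metric (`W = I`): classical
#'   unweighted minimum norm
#' @return object of class `inverse_operator` with kernel blocks
#'   `K$x`, `K$y`, `K$z` (nodes x electrodes) and metadata
#' @export
build_laura_operator <- function(lf, space, lambda_snr = 3,
                                 falloff_exponent = 2, ar_rho = 0.95,
                                 plain = FALSE) {
  stopifnot(inherits(lf, "lead_field"), inherits(space, "source_space"),
            lf$n_nodes == nrow(space$nodes), lambda_snr > 0,
            ar_rho > 0, ar_rho < 1)
  n <- lf$n_nodes; ne <- lf$n_electrodes
  if (plain) {
    Xc <- lapply(lf$G, t)                        # M = I
  } else {
    radius <- sqrt(3) * space$spacing + 1e-9
    adj <- grid_adjacency(space, radius)
    ii <- rep.int(seq_len(n), lengths(adj))
    jj <- unlist(adj)
    d <- sqrt(rowSums((space$nodes[ii, , drop = FALSE] -
                         space$nodes[jj, , drop = FALSE])^2))
    w <- d^(-falloff_exponent)
    A <- Matrix::sparseMatrix(i = ii, j = jj, x = w, dims = c(n, n))
    rs <- Matrix::rowSums(A)
    rs[rs == 0] <- 1                             # isolated node: A row = 0
    A <- Matrix::Diagonal(x = 1 / rs) %*% A
    W <- Matrix::Diagonal(n) - ar_rho * A
    WtW <- Matrix::forceSymmetric(Matrix::crossprod(W))
    ch <- Matrix::Cholesky(WtW, LDL = FALSE)
    Xc <- lapply(lf$G, function(Gc)
      as.matrix(Matrix::solve(ch, t(Gc), system = "A")))
  }
  LML <- matrix(0, ne, ne)
  for (c in names(lf$G)) LML <- LML + lf$G[[c]] %*% Xc[[c]]
  lambda <- sum(diag(LML)) / (ne * lambda_snr^2)
  Vinv <- solve(LML + lambda * diag(ne))
  K <- lapply(Xc, function(X) X %*% Vinv)
  structure(list(K = K, lambda = lambda, lambda_snr = lambda_snr,
                 falloff_exponent = falloff_exponent, ar_rho = ar_rho,
                 plain = plain,
                 n_nodes = n, n_electrodes = ne),
            class = "inverse_operator")
}

#' @export
print.inverse_operator <- function(x, ...) {
  cat(sprintf("<inverse_operator> %s, %d nodes x %d electrodes, lambda = %.3g\n",
              if (x$plain) "minimum norm" else "LAURA",
              x$n_nodes, x$n_electrodes, x$lambda))
  invisible(x)
}

#' Average an ERP over a time period of interest
#'
#' Returns the per-electrode mean over the frames whose sample centers fall
#' inside `[period[1], period[2]]` (inclusive). At 1024 Hz the 218-245 ms
#' period covers 28 frames.
#'
#' @param e an [erp()]
#' @param period `c(start_ms, end_ms)`
#' @return numeric vector, one value per electrode
#' @export
average_erp_period <- function(e, period) {
  stopifnot(inherits(e, "erp"), length(period) == 2, period[1] <= period[2])
  t_ms <- sample_times(e$fs, e$window, ncol(e$data))
  idx <- which(t_ms >= period[1] & t_ms <= period[2])
  if (!length(idx)) stop("no sample centers inside the requested period")
  rowMeans(e$data[, idx, drop = FALSE])
}

#' Apply an inverse operator to a scalp topography
#'
#' Estimates per-node dipole moments from an electrode vector and reports
#' the scalar current density (Euclidean norm of the moment vector) at every
#' node.
#'
#' @param op a [build_laura_operator()] result
#' @param topography numeric vector of electrode potentials (microvolts)
#' @param ... tags stored on the estimate (e.g. `subject`, `condition`,
#'   `period`)
#' @return object of class `source_estimate` with `density` (nodes) and
#'   `moments` (nodes x 3)
#' @export
apply_inverse <- function(op, topography, ...) {
  stopifnot(inherits(op, "inverse_operator"))
  v <- as.numeric(topography)
  if (length(v) != op$n_electrodes)
    stop("topography length does not match the operator's electrode count")
  mom <- vapply(op$K, function(K) as.numeric(K %*% v),
                numeric(op$n_nodes))
  structure(list(density = sqrt(rowSums(mom^2)), moments = mom,
                 tags = list(...)),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat(sprintf("<source_estimate> %d nodes, peak density %.3g at node %d\n",
              length(x$density), max(x$density), which.max(x$density)))
  invisible(x)
}

#' Write a source estimate as a node table
#'
#' TSV with columns `node_id`, `x`, `y`, `z`, `density`.
#'
#' @param est a [apply_inverse()] result
#' @param space the matching source grid
#' @param path output file
#' @export
write_source_estimate <- function(est, space, path) {
  stopifnot(inherits(est, "source_estimate"), inherits(space, "source_space"))
  tab <- data.frame(node_id = seq_along(est$density), space$nodes,
                    density = est$density)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
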