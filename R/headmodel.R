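#' Regular source grid clipped to a spherical shell
#'
#' Builds a cubic grid of candidate source nodes (spacing in mm) and keeps the
#' nodes falling inside a spherical shell, a geometric stand-in for a
#' gray-matter volume. The outer shell fraction is kept fixed and the inner
#' fraction is adjusted (bisection on the inner radius) until the node count
#' is within `tol_frac` of `target_n`; the shell therefore ends up as a
#' cortex-like crust just under the outer radius.
#'
#' @param head_radius scalp sphere radius, mm
#' @param spacing grid spacing, mm (6 mm gives the classical ~3000-node grid)
#' @param shell requested inner/outer radii as fractions of `head_radius`
#' @param target_n desired node count (`NULL` keeps the requested shell as is)
#' @param tol_frac relative tolerance on the achieved node count
#' @return an object of class `source_space` with fields `nodes` (n x 3 mm
#'   matrix), `spacing`, `head_radius`, `inner_r`, `outer_r`
#' @export
build_source_grid <- function(head_radius = 85, spacing = 6,
                              shell = c(0.35, 0.80), target_n = 3005,
                              tol_frac = 0.10) {
  stopifnot(spacing > 0, length(shell) == 2, shell[1] >= 0,
            shell[1] < shell[2], shell[2] <= 1)
  outer_r <- shell[2] * head_radius
  k <- floor(outer_r / spacing)
  if (k < 0) k <- 0
  ax <- spacing * (-k:k)
  grid <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  r <- sqrt(rowSums(grid^2))

  count_at <- function(inner_r) sum(r >= inner_r & r <= outer_r)
  inner_r <- shell[1] * head_radius
  if (!is.null(target_n)) {
    n0 <- count_at(inner_r)
    if (abs(n0 - target_n) > tol_frac * target_n) {
      lo <- 0; hi <- outer_r   # count decreases in inner_r
      if (count_at(0) < (1 - tol_frac) * target_n) {
        warning(sprintf(
          "target of %d nodes unattainable; achieved %d with a full sphere",
          target_n, count_at(0)))
        inner_r <- 0
      } else {
        for (i in 1:60) {
          mid <- (lo + hi) / 2
          if (count_at(mid) >= target_n) lo <- mid else hi <- mid
        }
        # lo is the largest radius still meeting target_n; pick closer count
        inner_r <- if (abs(count_at(lo) - target_n) <= abs(count_at(hi) - target_n))
          lo else hi
      }
    }
  }
  keep <- r >= inner_r & r <= outer_r
  nodes <- grid[keep, , drop = FALSE]
  dimnames(nodes) <- list(NULL, c("x", "y", "z"))
  structure(list(nodes = nodes, spacing = spacing, head_radius = head_radius,
                 inner_r = inner_r, outer_r = outer_r,
                 shell_requested = shell),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d nodes, %.0f mm spacing, shell %.1f-%.1f mm\n",
              nrow(x$nodes), x$spacing, x$inner_r, x$outer_r))
  invisible(x)
}

# Integer-coordinate hash of grid nodes; nodes are exact multiples of spacing.
.grid_key <- function(ijk) paste(ijk[, 1], ijk[, 2], ijk[, 3], sep = ",")

#' Node adjacency at a given connection radius
#'
#' Two nodes are neighbors when their Euclidean distance is at most `radius`.
#' On a 6-mm grid a radius of 8.5 mm yields the 18-neighborhood (6 face + 12
#' edge neighbors), and `sqrt(3) * spacing` the 26-neighborhood.
#'
#' @param space a `source_space`
#' @param radius connection radius in mm
#' @return list of integer neighbor-index vectors, one per node
#' @export
grid_adjacency <- function(space, radius = 8.5) {
  nodes <- space$nodes
  sp <- space$spacing
  ijk <- round(nodes / sp)
  key <- .grid_key(ijk)
  idx <- stats::setNames(seq_len(nrow(nodes)), key)
  m <- floor(radius / sp)
  offs <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  d <- sp * sqrt(rowSums(offs^2))
  offs <- offs[d > 0 & d <= radius + 1e-9, , drop = FALSE]
  lapply(seq_len(nrow(nodes)), function(i) {
    nb <- sweep(offs, 2, ijk[i, ], "+")
    hits <- idx[.grid_key(nb)]
    as.integer(unname(hits[!is.na(hits)]))
  })
}

# Radial transfer coefficients for a dipole inside the innermost region of a
# set of concentric conducting spheres with an insulating exterior.
#
# For each spherical-harmonic degree n, a unit source term r^-(n+1) inside
# region 1 induces a potential f_n at the outer surface. Radii are normalized
# by the outer radius, so all powers stay in a safe numeric range. Solved as
# a small linear system per degree from continuity of V and sigma*dV/dr at
# the interfaces and zero normal current at the scalp.
.shell_transfer <- function(n_max, rho, sigma) {
  n_shell <- length(rho)               # rho: normalized radii, last = 1
  stopifnot(length(sigma) == n_shell)
  if (n_shell == 1) {                  # homogeneous sphere: closed form
    n <- seq_len(n_max)
    return((2 * n + 1) / n)
  }
  f <- numeric(n_max)
  for (n in seq_len(n_max)) {
    # unknowns: A1, then (A_j, B_j) for j = 2..n_shell
    p <- 2 * n_shell - 1
    A <- matrix(0, p, p); rhs <- numeric(p)
    col_A <- function(j) if (j == 1) 1L else as.integer(2 * j - 2)
    col_B <- function(j) as.integer(2 * j - 1)  # j >= 2
    row <- 1
    for (j in seq_len(n_shell - 1)) {           # interface at rho[j]
      rj <- rho[j]
      # potential continuity
      A[row, col_A(j)] <- rj^n
      if (j > 1) A[row, col_B(j)] <- rj^(-(n + 1))
      A[row, col_A(j + 1)] <- -rj^n
      A[row, col_B(j + 1)] <- -rj^(-(n + 1))
      rhs[row] <- if (j == 1) -rj^(-(n + 1)) else 0
      row <- row + 1
      # current continuity
      A[row, col_A(j)] <- sigma[j] * n * rj^(n - 1)
      if (j > 1) A[row, col_B(j)] <- -sigma[j] * (n + 1) * rj^(-(n + 2))
      A[row, col_A(j + 1)] <- -sigma[j + 1] * n * rj^(n - 1)
      A[row, col_B(j + 1)] <- sigma[j + 1] * (n + 1) * rj^(-(n + 2))
      rhs[row] <- if (j == 1) sigma[1] * (n + 1) * rj^(-(n + 2)) else 0
      row <- row + 1
    }
    # insulating outer boundary at rho = 1
    A[row, col_A(n_shell)] <- n
    A[row, col_B(n_shell)] <- -(n + 1)
    # row/column equilibration: entries span ~rho^(-n)..rho^n
    rsc <- apply(abs(A), 1, max)
    A <- A / rsc; rhs <- rhs / rsc
    csc <- apply(abs(A), 2, max)
    sol <- solve(sweep(A, 2, csc, "/"), rhs) / csc
    f[n] <- sol[col_A(n_shell)] + sol[col_B(n_shell)]
  }
  f
}

#' Analytic lead field for concentric-sphere head models
#'
#' Maps unit dipole moments (x, y, z components, nA*m) at each source node to
#' average-referenced scalp potentials (microvolts). The classical
#' concentric-spheres solution is used: the dipole potential is expanded in
#' Legendre polynomials and each degree is propagated through the shells
#' (brain, skull, scalp by default, conductivity ratio 1 : 1/80 : 1). The
#' series is truncated when the geometric factor `(b/r_brain)^n` of the most
#' superficial node falls below `tol`.
#'
#' @param space a [build_source_grid()] result; all nodes must lie strictly
#'   inside the innermost shell
#' @param m a [montage()]; positions are projected onto the scalp sphere
#' @param model `"three_shell"` or `"single_shell"` (homogeneous sphere)
#' @param shells shell outer radii as fractions of the scalp radius
#' @param conductivities shell conductivities in S/m, innermost first
#' @param tol series truncation tolerance
#' @param max_terms hard cap on the number of Legendre terms
#' @return object of class `lead_field`: list `G` of three electrode x node
#'   gain matrices (one per moment component), plus geometry metadata
#' @export
compute_lead_field <- function(space, m, model = c("three_shell", "single_shell"),
                               shells = c(0.87, 0.92, 1.0),
                               conductivities = 0.33 * c(1, 1 / 80, 1),
                               tol = 1e-6, max_terms = 400) {
  model <- match.arg(model)
  stopifnot(inherits(space, "source_space"), inherits(m, "montage"))
  if (length(m$labels) < 32)
    stop("at least 32 electrodes required for a stable inversion")
  if (model == "single_shell") {
    shells <- 1.0
    conductivities <- conductivities[1]
  }
  stopifnot(length(shells) == length(conductivities),
            abs(shells[length(shells)] - 1) < 1e-12)

  R <- space$head_radius
  m <- fit_to_sphere(m, R)
  E <- m$positions / R                     # unit electrode directions
  nodes <- space$nodes
  b <- sqrt(rowSums(nodes^2))
  r_inner_mm <- shells[1] * R
  if (any(b >= r_inner_mm - 1e-3 * R))
    stop("source nodes too close to (or outside) the innermost shell boundary")
  B <- nodes / b                           # unit node directions

  brho <- b / R                            # normalized node radii
  n_terms <- ceiling(log(tol) / log(max(b) / r_inner_mm))
  n_terms <- max(10L, min(max_terms, n_terms))
  f <- .shell_transfer(n_terms, shells, conductivities)

  X <- E %*% t(B)                          # cos(angle) per electrode x node
  X[X > 1] <- 1; X[X < -1] <- -1
  ne <- nrow(E); nn <- nrow(B)

  # accumulate Sr = sum f_n' n P_n(x), T = sum f_n' P_n'(x), with the
  # per-node factor (b/R)^(n-1) folded into f_n'
  Pm1 <- matrix(1, ne, nn); P <- X         # P_0, P_1
  dPm1 <- matrix(0, ne, nn); dP <- matrix(1, ne, nn)
  bpow <- rep(1, nn)                       # (b/R)^(n-1)
  Sr <- matrix(0, ne, nn); Tm <- matrix(0, ne, nn)
  for (n in seq_len(n_terms)) {
    w <- f[n] * bpow
    Sr <- Sr + (n * P) * rep(w, each = ne)
    Tm <- Tm + dP * rep(w, each = ne)
    if (n < n_terms) {
      Pn1 <- ((2 * n + 1) * X * P - n * Pm1) / (n + 1)
      dPn1 <- (2 * n + 1) * P + dPm1
      Pm1 <- P; P <- Pn1
      dPm1 <- dP; dP <- dPn1
      bpow <- bpow * brho
    }
  }

  # physical scale: V = p / (4 pi sigma1 R^2) * series, p in nA*m, R in m,
  # output in microvolts
  scale <- 1e-9 / (4 * pi * conductivities[1] * (R * 1e-3)^2) * 1e6
  G <- vector("list", 3L); names(G) <- c("x", "y", "z")
  for (c in 1:3) {
    Bc <- B[, c]; Ec <- E[, c]
    Gc <- scale * (Sr * rep(Bc, each = ne) +
                     Tm * (matrix(Ec, ne, nn) - X * rep(Bc, each = ne)))
    Gc <- sweep(Gc, 2, colMeans(Gc))       # average reference
    G[[c]] <- Gc
  }
  structure(list(G = G, montage = m, head_radius = R, shells = shells,
                 conductivities = conductivities, n_terms = n_terms,
                 n_nodes = nn, n_electrodes = ne),
            class = "lead_field")
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("<lead_field> %d electrodes x %d nodes, %d shells, %d terms\n",
              x$n_electrodes, x$n_nodes, length(x$shells), x$n_terms))
  invisible(x)
}

#' Scalp topography of an arbitrary dipole configuration
#'
#' Convenience forward projection: `moments` is a node x 3 matrix of dipole
#' moments (nA*m); the result is the average-referenced scalp potential in
#' microvolts.
#'
#' @param lf a `lead_field`
#' @param moments node x 3 moment matrix
#' @return numeric vector, one value per electrode
#' @export
project_sources <- function(lf, moments) {
  stopifnot(inherits(lf, "lead_field"))
  moments <- as.matrix(moments)
  stopifnot(nrow(moments) == lf$n_nodes, ncol(moments) == 3)
  lf$G$x %*% moments[, 1] + lf$G$y %*% moments[, 2] + lf$G$z %*% moments[, 3]
}
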